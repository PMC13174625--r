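# Seeded, truth-annotated synthetic data: CREs with planted motifs,
# barcode count tables under a negative-binomial / Poisson model, and
# family cohorts with planted maternally transmitted X-linked variants.

#' Simulation parameters
#'
#' Defaults emulate the assayed conditions: four replicates, ~135 barcodes
#' per element, negative-binomial DNA counts (mean 50, dispersion 5) with
#' Poisson RNA given DNA, and mild replicate-to-replicate depth variation.
#'
#' @param n_replicates Number of biological replicates (>= 2, default 4).
#' @param bc_mean Mean barcodes per element (default 135).
#' @param bc_size Negative-binomial size for the barcode count draw.
#' @param mu_dna Mean DNA count per barcode (default 50).
#' @param phi_dna Negative-binomial size (dispersion) of DNA counts.
#' @param replicate_scale RNA depth scale per replicate.
#' @param baseline Baseline activity multiplier (default 1).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_replicates = 4L, bc_mean = 135, bc_size = 20,
                       mu_dna = 50, phi_dna = 5,
                       replicate_scale = c(1.0, 0.9, 1.1, 1.0),
                       baseline = 1.0) {
  if (n_replicates < 2) abort("need >= 2 replicates")
  replicate_scale <- rep_len(replicate_scale, n_replicates)
  if (any(c(bc_mean, bc_size, mu_dna, phi_dna, replicate_scale, baseline) <= 0)) {
    abort("all simulation parameters must be positive")
  }
  structure(
    list(n_replicates = as.integer(n_replicates), bc_mean = bc_mean,
         bc_size = bc_size, mu_dna = mu_dna, phi_dna = phi_dna,
         replicate_scale = replicate_scale, baseline = baseline),
    class = "sim_params"
  )
}

#' Generate a synthetic CRE with planted motifs
#'
#' Draws an iid uniform background sequence, embeds each planted consensus
#' at its interval, and rejection-resamples the background until no
#' planted consensus occurs anywhere except at its own interval (forward
#' orientation), so k-mer presence is fully controlled by the design.
#'
#' @param length CRE length in bp (default 970).
#' @param planted A tibble with columns `name`, `consensus`, `start`
#'   (0-based CRE offset), `class` (`"activator"`/`"repressor"`) and
#'   `multiplier` (activity factor; > 1 activator, < 1 repressor).
#' @param seed Integer seed.
#' @param max_attempts Resampling attempts before giving up (default 100).
#' @return A list with `sequence` and `truth` (the planted tibble with an
#'   `end` column added, plus `length` and `seed`).
#' @export
generate_synthetic_cre <- function(length = 970L, planted, seed,
                                   max_attempts = 100L) {
  planted <- as_tibble(planted) %>%
    mutate(end = .data$start + nchar(.data$consensus))
  if (any(planted$end > length) || any(planted$start < 0)) {
    abort("planted intervals must fit within the CRE")
  }
  if (nrow(planted) > 1) {
    iv <- planted[order(planted$start), ]
    if (any(iv$start[-1] < iv$end[-nrow(iv)])) {
      abort("planted intervals must not overlap")
    }
  }
  if (any(planted$multiplier <= 0)) abort("multipliers must be positive")
  check_dna(planted$consensus, allow_n = FALSE, what = "planted consensus")
  seq <- withr::with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      s <- paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
      for (i in seq_len(nrow(planted))) {
        substr(s, planted$start[i] + 1L, planted$end[i]) <- planted$consensus[i]
      }
      ok <- all(vapply(seq_len(nrow(planted)), function(i) {
        hits <- gregexpr(planted$consensus[i], s, fixed = TRUE)[[1]]
        identical(as.integer(hits), planted$start[i] + 1L)
      }, logical(1)))
      if (ok) break
      s <- NULL
    }
    s
  })
  if (is.null(seq)) {
    abort("could not avoid accidental consensus occurrences; use longer consensi")
  }
  list(
    sequence = seq,
    truth = list(planted = planted, length = as.integer(length), seed = seed)
  )
}

#' True activity multiplier of each library element
#'
#' Under the multiplicative model, an element's activity is the baseline
#' times the multipliers of all planted motifs whose interval lies fully
#' inside the element's tile span and is disjoint from the element's
#' mutated interval; a shuffled (or variant-hit) planted motif contributes
#' nothing.
#'
#' @param manifest Library manifest tibble.
#' @param tiles Tile tibble from [tile_cre()] (supplies tile spans).
#' @param truth Truth list from [generate_synthetic_cre()].
#' @param baseline Baseline multiplier (default 1).
#' @return The manifest with a `true_activity` column appended.
#' @export
true_activity <- function(manifest, tiles, truth, baseline = 1.0) {
  tiles <- as_tibble(tiles) %>%
    mutate(tile_len = nchar(.data$sequence))
  planted <- truth$planted
  span <- left_join(as_tibble(manifest),
                    select(tiles, "cre", "tile_index", "offset_start",
                           "tile_len"),
                    by = c("cre", "tile_index"))
  A <- vapply(seq_len(nrow(span)), function(i) {
    el <- span[i, ]
    if (is.na(el$offset_start)) return(baseline) # controls: baseline
    a <- baseline
    for (j in seq_len(nrow(planted))) {
      inside <- planted$start[j] >= el$offset_start &&
        planted$end[j] <= el$offset_start + el$tile_len
      if (!inside) next
      destroyed <- !is.na(el$mutated_start) &&
        el$mutated_start < planted$end[j] && el$mutated_end > planted$start[j]
      if (!destroyed) a <- a * planted$multiplier[j]
    }
    a
  }, numeric(1))
  mutate(as_tibble(manifest), true_activity = A)
}

#' Simulate a barcode count table
#'
#' Per element, the barcode count is negative-binomial around `bc_mean`
#' (floored at 10 so the minimum-barcode filter is exercised separately
#' through `low_barcode_elements`); barcodes are shared across replicates.
#' Per barcode and replicate, DNA is negative-binomial and RNA is Poisson
#' with mean `dna * true_activity * replicate_scale`, so the true activity
#' enters the log2(RNA/DNA) estimand as a clean multiplicative factor.
#'
#' @param manifest_activity Manifest tibble with a `true_activity` column
#'   (from [true_activity()]).
#' @param params A [sim_params()] list.
#' @param seed Integer seed; identical seeds give identical tables.
#' @param low_barcode_elements Element ids forced to 5 barcodes, to
#'   exercise the barcode filter.
#' @return A barcode count tibble (`replicate`, `element_id`, `barcode`,
#'   `dna_count`, `rna_count`).
#' @export
simulate_counts <- function(manifest_activity, params = sim_params(),
                            seed = 1L, low_barcode_elements = character()) {
  m <- as_tibble(manifest_activity)
  if (is.null(m$true_activity)) abort("manifest lacks true_activity; call true_activity() first")
  withr::with_seed(derive_seed(seed, "counts"), {
    n_bc <- pmax(10L, rnbinom(nrow(m), mu = params$bc_mean,
                              size = params$bc_size))
    n_bc[m$element_id %in% low_barcode_elements] <- 5L
    el <- rep(m$element_id, n_bc)
    A <- rep(m$true_activity, n_bc)
    barcode <- paste0(el, "_bc", unlist(lapply(n_bc, seq_len)))
    total <- length(el)
    per_rep <- purrr::map(seq_len(params$n_replicates), function(r) {
      dna <- rnbinom(total, mu = params$mu_dna, size = params$phi_dna)
      rna <- rpois(total, dna * A * params$baseline *
                     params$replicate_scale[r])
      tibble(replicate = sprintf("rep%d", r), element_id = el,
             barcode = barcode, dna_count = dna, rna_count = rna)
    })
    bind_rows(per_rep)
  })
}

#' Simulate a family cohort with planted X-linked PIVs
#'
#' Builds a trio cohort (father, unaffected mother, affected son) with
#' `n_planted` planted private inherited variants — single family,
#' unaffected heterozygous mother, affected hemizygous son, QUAL in
#' (50, 99], DP in [20, 60] — plus one distractor per failure mode: the
#' same variant carried in two families, QUAL exactly 50, proband DP 19,
#' an affected heterozygous daughter instead of a son, a Mendelian
#' violation (mother homozygous reference), and an out-of-region variant.
#' All male genotypes are hemizygous by construction.
#'
#' @param regions Region table; planted variants are placed inside the
#'   first region(s).
#' @param n_planted Number of planted PIVs (default 3).
#' @param n_families Total families (default covers planted + distractors
#'   + carriers-free padding).
#' @param seed Integer seed.
#' @return A list with `variants` (long genotype tibble), `pedigree`, and
#'   `truth` (a tibble of planted/distractor variants with the intended
#'   failing flag).
#' @export
simulate_cohort <- function(regions, n_planted = 3L, n_families = NULL,
                            seed = 1L) {
  regions <- validate_regions(regions)
  distractor_kinds <- c("multi_family", "qual_50", "dp_19", "female_proband",
                        "mendel_violation", "out_of_region")
  n_distract <- length(distractor_kinds)
  n_need <- n_planted + n_distract + 1L # multi_family uses two families
  n_families <- n_families %||% (n_need + 2L)
  if (n_families < n_need) {
    abort(sprintf("need >= %d families for %d planted + distractors",
                  n_need, n_planted))
  }
  fam <- sprintf("F%03d", seq_len(n_families))
  ped <- purrr::map(seq_len(n_families), function(i) {
    f <- fam[i]
    kind_idx <- i - n_planted
    child_is_daughter <- kind_idx >= 1 && kind_idx <= n_distract &&
      distractor_kinds[kind_idx] == "female_proband"
    tibble(
      family = f,
      id = paste0(f, c("_fa", "_mo", "_ch")),
      father = c("0", "0", paste0(f, "_fa")),
      mother = c("0", "0", paste0(f, "_mo")),
      sex = c("male", "female", if (child_is_daughter) "female" else "male"),
      affected = c(FALSE, FALSE, TRUE)
    )
  }) %>% bind_rows()
  withr::with_seed(derive_seed(seed, "cohort"), {
    chrom <- regions$chrom[1]
    n_pos <- n_planted + n_distract
    in_reg <- sample(seq(regions$start[1] + 1, regions$end[1] - 1), n_pos)
    pos <- in_reg
    # the out-of-region distractor sits beyond every region
    pos[n_planted + which(distractor_kinds == "out_of_region")] <-
      max(regions$end) + 5000 + sample(1000, 1)
    ref <- sample(DNA_BASES, n_pos, replace = TRUE)
    alt <- unname(vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1),
                         character(1)))
    qual <- round(runif(n_pos, 55, 99), 1)
    dp_ok <- function(n) sample(20:60, n, replace = TRUE)
    rows <- purrr::map(seq_len(n_pos), function(i) {
      kind <- if (i <= n_planted) "planted" else distractor_kinds[i - n_planted]
      f <- fam[i]
      q <- if (kind == "qual_50") 50 else qual[i]
      mo_gt <- if (kind == "mendel_violation") "0/0" else "0/1"
      ch_gt <- if (kind == "female_proband") "0/1" else "1"
      ch_dp <- if (kind == "dp_19") 19L else dp_ok(1)
      base <- tibble(
        chrom = chrom, pos = pos[i], ref = ref[i], alt = alt[i], qual = q,
        sample = paste0(f, c("_fa", "_mo", "_ch")),
        gt = c("0", mo_gt, ch_gt),
        dp = c(dp_ok(1), dp_ok(1), ch_dp)
      )
      if (kind == "multi_family") {
        f2 <- fam[n_pos + 1L]
        base <- bind_rows(base, tibble(
          chrom = chrom, pos = pos[i], ref = ref[i], alt = alt[i], qual = q,
          sample = paste0(f2, c("_fa", "_mo", "_ch")),
          gt = c("0", "0/1", "1"),
          dp = c(dp_ok(1), dp_ok(1), dp_ok(1))
        ))
      }
      base
    })
    truth <- tibble(
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      kind = c(rep("planted", n_planted), distractor_kinds),
      expected_fail_flag = c(rep(NA_character_, n_planted),
                             c("single_family", "qual_pass", "dp_pass",
                               "male_proband_hemizygous_alt",
                               "mother_het_unaffected", "in_region"))
    )
    list(variants = bind_rows(rows), pedigree = ped, truth = truth)
  })
}

#' Build the default end-to-end synthetic fixture
#'
#' One seeded command produces a self-consistent dataset for the whole
#' pipeline: a 970 bp CRE with one planted activator (x4) and one planted
#' repressor (x0.25), sharply peaked PWMs for both (plus decoys) in MEME
#' format, a full shuffle + variant manifest (with neutral decoy shuffle
#' intervals spaced along the CRE so every bin has coverage), simulated
#' barcode counts over four replicates, a family cohort with planted PIVs,
#' and a TF expression table.
#'
#' @param seed Master integer seed.
#' @param dir Optional output directory; when given, all components are
#'   written as plain-text files (TSV/FASTA/MEME/VCF/PED/JSON).
#' @param params A [sim_params()] list.
#' @param decoy_spacing Spacing (bp) of neutral decoy shuffle intervals
#'   (default 7, which yields over 1,000 shuffle mutations across the CRE,
#'   the saturation regime the binned 10%-of-shuffles rule is designed
#'   for).
#' @return A list with `regions`, `cre`, `motifs`, `tiles`, `hits`,
#'   `manifest`, `counts`, `cohort`, `expression`, `mapping`, and `truth`.
#' @export
make_fixture <- function(seed = 1L, dir = NULL, params = sim_params(),
                         decoy_spacing = 7L) {
  regions <- tibble(chrom = "chrX", start = 154045988, end = 154046957,
                    name = "CRE_A")
  planted <- tibble(
    name = c("ACT1", "REP1"),
    consensus = c("TGACGTCATG", "CCGGAAGTGA"),
    start = c(300L, 620L),
    class = c("activator", "repressor"),
    multiplier = c(4, 0.25)
  )
  cre <- generate_synthetic_cre(970L, planted, seed = derive_seed(seed, "cre"))
  truth <- cre$truth
  tiles <- tile_cre(cre$sequence, cre = "CRE_A")
  motifs <- fixture_motifs(planted)
  hits <- scan_motifs(tiles, motifs)
  decoys <- fixture_decoy_hits(tiles, planted, width = 10L,
                               spacing = decoy_spacing)
  manifest <- build_shuffle_library(tiles, bind_rows(hits, decoys),
                                    seed = derive_seed(seed, "design"))
  # a proband variant inside the repressor motif and a control outside
  var_off <- c(624L, 500L)
  ref_bases <- substring(cre$sequence, var_off + 1L, var_off + 1L)
  variants <- tibble(
    variant_id = c("piv1", "gnomad1"),
    cre = "CRE_A", offset = var_off,
    ref = ref_bases,
    alt = NA_character_,
    class = c("proband_variant", "control_variant")
  )
  variants$alt <- unname(vapply(variants$ref,
                                function(b) setdiff(DNA_BASES, b)[1],
                                character(1)))
  manifest <- bind_rows(manifest, build_variant_elements(tiles, variants))
  manifest_act <- true_activity(manifest, tiles, truth,
                                baseline = params$baseline)
  counts <- simulate_counts(manifest_act, params,
                            seed = derive_seed(seed, "counts"))
  cohort <- simulate_cohort(regions, n_planted = 3L,
                            seed = derive_seed(seed, "cohort"))
  expression <- tibble(
    gene = c("ACT1_TF", "REP1_TF", "DECOY1_TF", "DECOY2_TF"),
    expression = c(50, 30, 0, 12)
  )
  mapping <- tibble(
    motif_id = c("ACT1", "REP1", "DECOY1", "DECOY2"),
    gene = c("ACT1_TF", "REP1_TF", "DECOY1_TF", "DECOY2_TF")
  )
  out <- list(
    regions = regions,
    cre = tibble(name = "CRE_A", sequence = cre$sequence),
    motifs = motifs, tiles = tiles, hits = hits,
    manifest = manifest_act, counts = counts, cohort = cohort,
    expression = expression, mapping = mapping,
    truth = c(truth[setdiff(names(truth), "seed")],
              list(variants = variants, params = params, seed = seed))
  )
  if (!is.null(dir)) write_fixture(out, dir)
  out
}

# Sharply peaked PWMs (0.97 consensus base) for the planted motifs plus
# two decoy PWMs that do not occur in the CRE.
fixture_motifs <- function(planted) {
  sharp <- function(cons) {
    pwm <- matrix(0.01, nrow = 4, ncol = nchar(cons),
                  dimnames = list(DNA_BASES, NULL))
    pwm[cbind(encode_dna(cons), seq_len(nchar(cons)))] <- 0.97
    pwm
  }
  decoys <- c(DECOY1 = "ATATCGCGAT", DECOY2 = "GGTTAACCGG")
  tibble(
    motif_id = c(planted$name, names(decoys)),
    width = rep(10L, nrow(planted) + length(decoys)),
    pwm = c(lapply(planted$consensus, sharp), lapply(unname(decoys), sharp))
  )
}

# Neutral shuffle targets spaced along the CRE, skipping intervals that
# touch a planted motif, emitted as pseudo-hits for every containing tile.
fixture_decoy_hits <- function(tiles, planted, width = 10L, spacing = 15L) {
  cre_len <- max(tiles$offset_start) + nchar(tiles$sequence[1])
  starts <- seq(0L, cre_len - width, by = spacing)
  clash <- vapply(starts, function(s) {
    any(s < planted$start + nchar(planted$consensus) & s + width > planted$start)
  }, logical(1))
  starts <- starts[!clash]
  tile_len <- nchar(tiles$sequence[1])
  purrr::map(starts, function(s) {
    idx <- which(tiles$offset_start <= s & s + width <= tiles$offset_start + tile_len)
    tibble(cre = tiles$cre[idx], tile_index = tiles$tile_index[idx],
           motif_id = sprintf("decoy%03d", s),
           start = s, end = s + width, strand = "+",
           score = NA_real_, p = NA_real_)
  }) %>% bind_rows()
}

write_fixture <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(fx$regions, file.path(dir, "regions.tsv"))
  write_cre_fasta(fx$cre, file.path(dir, "cres.fa"))
  write_meme(fx$motifs, file.path(dir, "motifs.meme"))
  write_manifest(fx$manifest, file.path(dir, "manifest.tsv"))
  readr::write_tsv(fx$counts, file.path(dir, "counts.tsv"))
  write_cohort_vcf(fx$cohort$variants, file.path(dir, "cohort.vcf"))
  write_pedigree(fx$cohort$pedigree, file.path(dir, "cohort.ped"))
  readr::write_tsv(fx$expression, file.path(dir, "expression.tsv"))
  truth <- fx$truth
  truth$params <- unclass(truth$params)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
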