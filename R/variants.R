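#' Filter private maternally transmitted X-linked variants
#'
#' Applies the cohort transmission filter for candidate private inherited
#' variants (PIVs): the variant must lie inside a target region, be carried
#' by exactly one family, be transmitted from an unaffected heterozygous
#' mother to at least one affected hemizygous male child, and pass site
#' quality (`QUAL > qual_min`, strict) and per-sample depth
#' (`DP >= dp_min`, inclusive, in both mother and proband). Each criterion
#' is reported as its own flag so a failing variant shows exactly which
#' rule it breaks; the transmission flags are evaluated within the carrier
#' family that satisfies the most criteria.
#'
#' Data-integrity errors (not filter failures): a chrX male recorded as
#' heterozygous, or a genotyped sample missing from the pedigree.
#'
#' @param variants Long genotype tibble from [read_cohort_vcf()].
#' @param pedigree Pedigree tibble from [read_pedigree()].
#' @param regions Region table (1-based inclusive); see [read_regions()].
#' @param qual_min Site quality threshold, exclusive (default 50).
#' @param dp_min Per-sample depth threshold, inclusive (default 20).
#' @return A tibble with one row per variant: `chrom`, `pos`, `ref`,
#'   `alt`, `family` (the evaluated carrier family), per-criterion flags
#'   `in_region`, `single_family`, `mother_het_unaffected`,
#'   `male_proband_hemizygous_alt`, `qual_pass`, `dp_pass`, and `pass`
#'   (their conjunction).
#' @export
filter_pivs <- function(variants, pedigree, regions,
                        qual_min = 50, dp_min = 20) {
  variants <- as_tibble(variants)
  pedigree <- validate_pedigree(pedigree)
  regions <- validate_regions(regions)
  missing <- setdiff(unique(variants$sample), pedigree$id)
  if (length(missing)) {
    abort(sprintf("genotyped sample(s) missing from the pedigree: %s",
                  paste(missing, collapse = ", ")))
  }
  v <- left_join(variants, pedigree, by = c("sample" = "id"))
  bad_male <- v$sex == "male" & grepl("x", v$chrom, ignore.case = TRUE) &
    grepl("/|\\|", v$gt)
  if (any(bad_male)) {
    abort(sprintf(
      "male sample '%s' has a diploid chrX genotype '%s'; chrX males must be hemizygous",
      v$sample[bad_male][1], v$gt[bad_male][1]))
  }
  v <- mutate(v, carries = has_alt(.data$gt))
  keys <- distinct(v, .data$chrom, .data$pos, .data$ref, .data$alt, .data$qual)
  purrr::map(seq_len(nrow(keys)), function(i) {
    key <- keys[i, ]
    rows <- v[v$chrom == key$chrom & v$pos == key$pos &
                v$ref == key$ref & v$alt == key$alt, ]
    carrier_fams <- unique(rows$family[rows$carries])
    in_region <- any(regions$chrom == key$chrom &
                       regions$start <= key$pos & key$pos <= regions$end)
    single_family <- length(carrier_fams) == 1
    # evaluate transmission within each carrier family, keep the best
    fam_flags <- purrr::map(carrier_fams, function(f) {
      fam <- rows[rows$family == f, ]
      # affected carriers with a recorded mother are the candidate probands
      probands <- fam[fam$affected & fam$carries, ]
      mo_id <- probands$mother
      mo_rows <- fam[match(mo_id, fam$sample), ]
      mo_het <- !is.na(mo_rows$gt) & mo_rows$gt %in% c("0/1", "1/0") &
        !mo_rows$affected
      dp_ok <- !is.na(probands$dp) & probands$dp >= dp_min &
        !is.na(mo_rows$dp) & mo_rows$dp >= dp_min
      list(
        family = f,
        mother_het_unaffected = any(mo_het),
        male_proband_hemizygous_alt = any(probands$sex == "male" &
                                            probands$gt == "1"),
        dp_pass = any(dp_ok)
      )
    })
    if (length(fam_flags)) {
      score <- vapply(fam_flags, function(f) {
        f$mother_het_unaffected + f$male_proband_hemizygous_alt + f$dp_pass
      }, numeric(1))
      best <- fam_flags[[which.max(score)]]
    } else {
      best <- list(family = NA_character_, mother_het_unaffected = FALSE,
                   male_proband_hemizygous_alt = FALSE, dp_pass = FALSE)
    }
    tibble(
      chrom = key$chrom, pos = key$pos, ref = key$ref, alt = key$alt,
      family = best$family,
      in_region = in_region,
      single_family = single_family,
      mother_het_unaffected = best$mother_het_unaffected,
      male_proband_hemizygous_alt = best$male_proband_hemizygous_alt,
      qual_pass = !is.na(key$qual) && key$qual > qual_min,
      dp_pass = best$dp_pass,
      pass = in_region && single_family && best$mother_het_unaffected &&
        best$male_proband_hemizygous_alt &&
        (!is.na(key$qual) && key$qual > qual_min) && best$dp_pass
    )
  }) %>% bind_rows()
}

has_alt <- function(gt) {
  vapply(strsplit(gt, "[/|]"), function(a) any(a == "1"), logical(1))
}

#' Cohort allele frequency for an X-linked variant
#'
#' One counted allele per parent by default (the convention that makes one
#' carrier family among 16,490 unrelated parents an allele frequency of
#' about 6.1e-5); set `per_x_copy = TRUE` to count mothers as two X copies
#' and fathers as one.
#'
#' @param n_carrier_parents Number of carrier parents (>= 0).
#' @param n_parents Total unrelated parents (> 0).
#' @param per_x_copy Count X copies instead of parents (requires
#'   `n_mothers`).
#' @param n_mothers Number of mothers among the parents (only used with
#'   `per_x_copy = TRUE`).
#' @return The allele frequency (a bare number).
#' @examples
#' allele_frequency(1, 16490) # ~6.1e-5
#' @export
allele_frequency <- function(n_carrier_parents, n_parents,
                             per_x_copy = FALSE, n_mothers = NULL) {
  if (n_parents <= 0) abort("n_parents must be positive")
  if (n_carrier_parents < 0 || n_carrier_parents > n_parents) {
    abort("n_carrier_parents must be in [0, n_parents]")
  }
  if (per_x_copy) {
    if (is.null(n_mothers)) abort("per_x_copy counting requires n_mothers")
    n_carrier_parents / (n_parents + n_mothers)
  } else {
    n_carrier_parents / n_parents
  }
}

#' Classify a variant by its MPRA effects against control calibration
#'
#' A variant is `candidate_functional` when it significantly alters
#' activity in at least two tiles (or in its single tile when only one
#' tile is testable) *and* its strongest significant effect exceeds the
#' control threshold: the largest significant absolute effect among the
#' population (gnomAD) control variants, or 0 when no control is
#' significant. A variant significant in exactly one of several tiles, or
#' significant but not exceeding the control threshold, is `indeterminate`
#' (context-dependent or possibly a false positive); otherwise it is
#' `not_supported`.
#'
#' @param variant_effects Effect tibble for one variant, one row per
#'   tested tile (`tile_index`, `mean_effect`, `p_adj`).
#' @param control_effects Effect tibble for the control variants of the
#'   same CRE (`mean_effect`, `p_adj`).
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @return A one-row tibble: `n_tiles`, `n_significant`, `max_sig_effect`
#'   (absolute), `control_threshold`, `class`.
#' @export
classify_variant_mpra <- function(variant_effects, control_effects,
                                  alpha = 0.05) {
  variant_effects <- as_tibble(variant_effects)
  if (!nrow(variant_effects)) abort("variant was tested in no tiles")
  control_effects <- as_tibble(control_effects)
  sig_controls <- control_effects[!is.na(control_effects$p_adj) &
                                    control_effects$p_adj < alpha, ]
  control_threshold <- if (nrow(sig_controls)) {
    max(abs(sig_controls$mean_effect))
  } else 0
  sig <- variant_effects$p_adj < alpha
  n_sig <- sum(sig)
  max_sig <- if (n_sig) max(abs(variant_effects$mean_effect[sig])) else 0
  n_tiles <- nrow(variant_effects)
  class <- if (n_sig == 0) {
    "not_supported"
  } else if ((n_sig >= 2 || n_tiles == 1) && max_sig > control_threshold) {
    "candidate_functional"
  } else {
    "indeterminate"
  }
  tibble(
    n_tiles = n_tiles, n_significant = n_sig, max_sig_effect = max_sig,
    control_threshold = control_threshold, class = class
  )
}

#' Percentile rank of a target promoter's signal per replicate
#'
#' Ranks promoter-level signal values within each replicate (ascending,
#' midranks for ties) and reports the target's percentile
#' `100 * rank / N`. Invariant under any strictly monotone transform of
#' the signals.
#'
#' @param signals A tibble with columns `replicate`, `promoter`, `signal`.
#' @param target Promoter identifier to report.
#' @return A tibble: `replicate`, `signal`, `rank`, `n`, `percentile`.
#' @export
promoter_percentile <- function(signals, target) {
  signals <- as_tibble(signals)
  out <- signals %>%
    group_by(.data$replicate) %>%
    mutate(rank = rank(.data$signal), n = n()) %>%
    ungroup() %>%
    filter(.data$promoter == target) %>%
    mutate(percentile = 100 * .data$rank / .data$n) %>%
    select("replicate", "signal", "rank", "n", "percentile")
  if (nrow(out) < n_distinct(signals$replicate)) {
    abort(sprintf("target promoter '%s' is absent from some replicate", target))
  }
  if (any(table(signals$replicate) < 2)) {
    abort("need >= 2 promoters per replicate to rank")
  }
  out
}
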