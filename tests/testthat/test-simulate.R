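planted <- tibble::tibble(
  name = c("A1", "R1"),
  consensus = c("TGACGTCATG", "CCGGAAGTGA"),
  start = c(300L, 620L),
  class = c("activator", "repressor"),
  multiplier = c(4, 0.25)
)

test_that("synthetic CREs embed each consensus exactly once, deterministically", {
  out <- generate_synthetic_cre(970, planted, seed = 3)
  expect_equal(nchar(out$sequence), 970L)
  for (i in 1:2) {
    expect_equal(substr(out$sequence, planted$start[i] + 1,
                        planted$start[i] + 10), planted$consensus[i])
    occ <- gregexpr(planted$consensus[i], out$sequence, fixed = TRUE)[[1]]
    expect_equal(as.integer(occ), planted$start[i] + 1L)
  }
  expect_identical(generate_synthetic_cre(970, planted, seed = 3)$sequence,
                   out$sequence)
  expect_false(identical(generate_synthetic_cre(970, planted, seed = 4)$sequence,
                         out$sequence))
  overlapping <- dplyr::mutate(planted, start = c(300L, 305L))
  expect_error(generate_synthetic_cre(970, overlapping, seed = 1), "overlap")
  expect_error(generate_synthetic_cre(100, planted, seed = 1), "fit")
})

test_that("true activity is the product of intact planted multipliers", {
  cre <- generate_synthetic_cre(970, planted, seed = 5)
  tiles <- tile_cre(cre$sequence, "CRE_A")
  mk <- function(tile_index, mut = c(NA, NA)) tibble::tibble(
    element_id = "e", class = "motif_shuffle", cre = "CRE_A",
    tile_index = tile_index, mutated_start = mut[1], mutated_end = mut[2],
    shuffle_rep = 1L, unchanged = FALSE, sequence = "x"
  )
  A <- function(m) true_activity(m, tiles, cre$truth)$true_activity
  # tile 5 spans [280, 550): contains the intact activator -> 4
  expect_equal(A(mk(5L)), 4)
  # shuffling the activator inside tile 5 removes its contribution -> 1
  expect_equal(A(mk(5L, c(300L, 310L))), 1)
  # a mutation elsewhere in the tile leaves it intact -> 4
  expect_equal(A(mk(5L, c(400L, 410L))), 4)
  # tile 1 spans [0, 270): contains nothing -> baseline
  expect_equal(A(mk(1L)), 1)
  # a 690-bp-style tile holding both motifs multiplies 4 * 0.25 = 1
  both_seq <- substr(cre$sequence, 291, 290 + 340)
  both <- tibble::tibble(cre = "CRE_A", tile_index = 99L, offset_start = 290L,
                         end_anchored = FALSE, sequence = both_seq)
  tiles_both <- dplyr::bind_rows(tiles, both)
  expect_equal(true_activity(mk(99L), tiles_both, cre$truth)$true_activity, 1)
  # tile 8 spans [490, 760): intact repressor alone -> 0.25, and a
  # single-base variant inside the repressor destroys it -> 1
  expect_equal(A(mk(8L)), 0.25)
  expect_equal(A(mk(8L, c(624L, 625L))), 1)
})

test_that("simulated counts are seeded, integer, and expose the barcode filter", {
  fx_manifest <- tibble::tibble(
    element_id = c("hi", "lo", "few"), class = "reference_tile",
    cre = "c", tile_index = 1:3,
    mutated_start = NA_integer_, mutated_end = NA_integer_,
    shuffle_rep = NA_integer_, unchanged = FALSE, sequence = "x",
    true_activity = c(4, 1, 1)
  )
  counts <- simulate_counts(fx_manifest, sim_params(), seed = 9,
                            low_barcode_elements = "few")
  expect_true(all(counts$dna_count >= 0 & counts$rna_count >= 0))
  expect_true(all(counts$dna_count == floor(counts$dna_count)))
  expect_identical(simulate_counts(fx_manifest, sim_params(), seed = 9,
                                   low_barcode_elements = "few"), counts)
  per_el <- dplyr::count(dplyr::distinct(counts, element_id, barcode),
                         element_id)
  expect_equal(per_el$n[per_el$element_id == "few"], 5L)
  expect_gte(min(per_el$n[per_el$element_id != "few"]), 10L)
  # four replicates with shared barcodes
  expect_equal(dplyr::n_distinct(counts$replicate), 4L)
  act <- compute_activity(counts)
  expect_false("few" %in% act$element_id)
  # the x4 element sits ~2 log2 units above the x1 element
  gap <- mean(act$activity[act$element_id == "hi"]) -
    mean(act$activity[act$element_id == "lo"])
  expect_equal(gap, 2, tolerance = 0.25)
})

test_that("the synthetic cohort is internally consistent and males are hemizygous", {
  regions <- tibble::tibble(chrom = "chrX", start = 154045988,
                            end = 154046957, name = "CRE_A")
  coh <- simulate_cohort(regions, n_planted = 3, seed = 13)
  males <- dplyr::semi_join(
    coh$variants,
    dplyr::filter(coh$pedigree, sex == "male"),
    by = c("sample" = "id"))
  expect_true(all(!grepl("/", males$gt)))
  expect_silent(validate_pedigree(coh$pedigree))
  expect_identical(simulate_cohort(regions, n_planted = 3, seed = 13)$variants,
                   coh$variants)
  # planted PIVs sit in (50, 99] QUAL and [20, 60] DP by construction
  planted_keys <- dplyr::filter(coh$truth, kind == "planted")
  planted_rows <- dplyr::semi_join(coh$variants, planted_keys,
                                   by = c("chrom", "pos", "ref", "alt"))
  expect_true(all(planted_rows$qual > 50 & planted_rows$qual <= 99))
  expect_true(all(planted_rows$dp >= 20 & planted_rows$dp <= 60))
})

test_that("the bundled fixture writes valid files for every pipeline input", {
  dir <- withr::local_tempdir()
  fx <- make_fixture(seed = 21, dir = dir)
  expect_equal(read_regions(file.path(dir, "regions.tsv")), fx$regions)
  expect_equal(read_cre_fasta(file.path(dir, "cres.fa")), fx$cre)
  expect_equal(read_manifest(file.path(dir, "manifest.tsv"))$element_id,
               fx$manifest$element_id)
  expect_equal(nrow(read_counts(file.path(dir, "counts.tsv"))),
               nrow(fx$counts))
  meme <- read_meme(file.path(dir, "motifs.meme"))
  expect_equal(meme$motif_id, fx$motifs$motif_id)
  ped <- read_pedigree(file.path(dir, "cohort.ped"))
  expect_equal(nrow(ped), nrow(fx$cohort$pedigree))
  vcf <- read_cohort_vcf(file.path(dir, "cohort.vcf"))
  expect_equal(dplyr::n_distinct(vcf[c("chrom", "pos", "alt")]),
               dplyr::n_distinct(fx$cohort$variants[c("chrom", "pos", "alt")]))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$params$bc_mean, 135)
  expect_equal(truth$seed, 21)
  expect_equal(vapply(truth$planted, `[[`, character(1), "consensus"),
               fx$truth$planted$consensus)
})
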