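regions <- tibble::tibble(chrom = "chrX", start = 154045988,
                          end = 154046957, name = "CRE_A")

trio <- function(fam, gt_mo = "0/1", gt_ch = "1", dp_mo = 25, dp_ch = 25,
                 qual = 60, pos = 154046100, ref = "T", alt = "C") {
  tibble::tibble(
    chrom = "chrX", pos = pos, ref = ref, alt = alt, qual = qual,
    sample = paste0(fam, c("_fa", "_mo", "_ch")),
    gt = c("0", gt_mo, gt_ch), dp = c(30, dp_mo, dp_ch)
  )
}

ped_for <- function(fams, child_sex = "male") {
  purrr::map(fams, function(f) tibble::tibble(
    family = f, id = paste0(f, c("_fa", "_mo", "_ch")),
    father = c("0", "0", paste0(f, "_fa")),
    mother = c("0", "0", paste0(f, "_mo")),
    sex = c("male", "female", child_sex),
    affected = c(FALSE, FALSE, TRUE)
  )) |> dplyr::bind_rows()
}

test_that("the canonical trio passes and boundary semantics are strict/inclusive", {
  ped <- ped_for("F1")
  pass <- filter_pivs(trio("F1"), ped, regions)
  expect_true(pass$pass)
  expect_true(all(unlist(pass[c("in_region", "single_family",
                                "mother_het_unaffected",
                                "male_proband_hemizygous_alt",
                                "qual_pass", "dp_pass")])))
  # QUAL exactly 50 fails (strict >), DP exactly 20 passes (inclusive >=)
  q50 <- filter_pivs(trio("F1", qual = 50), ped, regions)
  expect_false(q50$qual_pass)
  expect_true(q50$dp_pass)
  dp20 <- filter_pivs(trio("F1", dp_mo = 20, dp_ch = 20), ped, regions)
  expect_true(dp20$dp_pass)
  dp19 <- filter_pivs(trio("F1", dp_ch = 19), ped, regions)
  expect_false(dp19$dp_pass)
  expect_true(dp19$qual_pass)
})

test_that("multi-family carriers, wrong transmission, and bad data are caught", {
  ped2 <- ped_for(c("F1", "F2"))
  two_fam <- dplyr::bind_rows(trio("F1"), trio("F2"))
  res <- filter_pivs(two_fam, ped2, regions)
  expect_equal(nrow(res), 1L)
  expect_false(res$single_family)
  expect_true(res$mother_het_unaffected) # other criteria unaffected
  expect_false(res$pass)
  # unaffected mother must be het: hom-ref mother (Mendelian violation)
  mendel <- filter_pivs(trio("F1", gt_mo = "0/0"), ped_for("F1"), regions)
  expect_false(mendel$mother_het_unaffected)
  expect_true(mendel$male_proband_hemizygous_alt)
  # affected daughter instead of son fails only the proband criterion
  daughter <- filter_pivs(trio("F1", gt_ch = "0/1"),
                          ped_for("F1", child_sex = "female"), regions)
  expect_false(daughter$male_proband_hemizygous_alt)
  expect_true(daughter$mother_het_unaffected)
  expect_true(daughter$dp_pass)
  # out-of-region variant fails only in_region
  out <- filter_pivs(trio("F1", pos = 154200000), ped_for("F1"), regions)
  expect_false(out$in_region)
  expect_true(out$single_family && out$mother_het_unaffected)
  # order invariance and idempotence
  v <- trio("F1")
  expect_equal(filter_pivs(v[seq(nrow(v), 1), ], ped_for("F1"), regions),
               filter_pivs(v, ped_for("F1"), regions))
  # integrity errors
  expect_error(filter_pivs(trio("F1", gt_ch = "0/1"), ped_for("F1"), regions),
               "hemizygous")
  expect_error(filter_pivs(trio("F9"), ped_for("F1"), regions),
               "missing from the pedigree")
})

test_that("allele frequency arithmetic matches the cohort convention", {
  af <- allele_frequency(1, 16490)
  expect_equal(af, 1 / 16490)
  expect_equal(signif(af, 2), 6.1e-5)
  expect_equal(allele_frequency(0, 100), 0)
  expect_equal(allele_frequency(2, 16490), 2 * allele_frequency(1, 16490))
  expect_equal(allele_frequency(1, 10000, per_x_copy = TRUE, n_mothers = 5000),
               1 / 15000)
  expect_error(allele_frequency(1, 0), "positive")
  expect_error(allele_frequency(5, 4))
})

test_that("variant classification follows the multi-tile and control-threshold rule", {
  eff <- function(p, e) tibble::tibble(tile_index = seq_along(p),
                                       mean_effect = e, p_adj = p)
  ctrl <- eff(c(0.01, 0.8), c(0.5, 0.1)) # significant control at |0.5|
  # significant in 1 of 3 tiles, below the control threshold -> indeterminate
  one_weak <- classify_variant_mpra(eff(c(0.01, 0.5, 0.9), c(0.3, 0, 0)), ctrl)
  expect_equal(one_weak$class, "indeterminate")
  expect_equal(one_weak$control_threshold, 0.5)
  # only one testable tile, significant and above threshold -> candidate
  single <- classify_variant_mpra(eff(0.001, 1.2), ctrl)
  expect_equal(single$class, "candidate_functional")
  # two significant tiles above threshold -> candidate
  multi <- classify_variant_mpra(eff(c(0.001, 0.02, 0.7), c(1.2, -0.9, 0)), ctrl)
  expect_equal(multi$class, "candidate_functional")
  # significant in 1 of 3 tiles even when strong -> indeterminate
  ctx <- classify_variant_mpra(eff(c(0.001, 0.5, 0.9), c(2, 0, 0)), ctrl)
  expect_equal(ctx$class, "indeterminate")
  # no significant tile -> not supported
  none <- classify_variant_mpra(eff(c(0.2, 0.6), c(1, 1)), ctrl)
  expect_equal(none$class, "not_supported")
  # no significant control: threshold falls to 0
  free <- classify_variant_mpra(eff(0.01, 0.05), eff(0.9, 2))
  expect_equal(free$control_threshold, 0)
  expect_equal(free$class, "candidate_functional")
  # monotone: amplifying a significant effect never demotes the class
  promoted <- classify_variant_mpra(eff(c(0.01, 0.02, 0.9), c(0.3, 0.3, 0)), ctrl)
  stronger <- classify_variant_mpra(eff(c(0.01, 0.02, 0.9), c(3, 3, 0)), ctrl)
  ranks <- c(not_supported = 1, indeterminate = 2, candidate_functional = 3)
  expect_gte(ranks[stronger$class], ranks[promoted$class])
  expect_error(classify_variant_mpra(eff(numeric(0), numeric(0)), ctrl),
               "no tiles")
})

test_that("promoter percentiles use ascending midranks and survive monotone transforms", {
  sig <- tidyr::expand_grid(replicate = c("r1", "r2"),
                            promoter = paste0("p", 1:100)) |>
    dplyr::mutate(signal = rep(1:100, 2))
  top <- promoter_percentile(sig, "p100")
  expect_equal(top$percentile, c(100, 100))
  med <- promoter_percentile(
    dplyr::filter(sig, promoter %in% paste0("p", 1:99)), "p50")
  expect_equal(med$percentile, rep(100 * 50 / 99, 2))
  # two promoters tied at the top of four: midrank 3.5 -> 87.5
  tied <- tibble::tibble(replicate = "r1", promoter = paste0("p", 1:4),
                         signal = c(1, 2, 9, 9))
  expect_equal(promoter_percentile(tied, "p3")$percentile, 87.5)
  expect_equal(promoter_percentile(tied, "p4")$percentile, 87.5)
  # strictly monotone transform leaves percentiles unchanged
  expect_equal(promoter_percentile(dplyr::mutate(sig, signal = exp(signal / 20)),
                                   "p37")$percentile,
               promoter_percentile(sig, "p37")$percentile)
  expect_error(promoter_percentile(dplyr::filter(sig, promoter != "p7"), "p7"),
               "absent")
})
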