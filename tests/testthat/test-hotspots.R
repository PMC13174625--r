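mk_dp <- function(start, end, direction = "ns", significant = FALSE,
                  cre = "c", id = NULL) {
  if (is.null(id)) id <- sprintf("%s_%d_%d_%s", cre, start, end, direction)
  tibble::tibble(
    element_id = id,
    cre = cre, tile_index = 1L, class = "motif_shuffle",
    mutated_start = as.integer(start), mutated_end = as.integer(end),
    mean_effect = ifelse(direction == "down", -1,
                         ifelse(direction == "up", 1, 0)),
    p_adj = ifelse(significant, 0.01, 0.5),
    direction = direction, significant = significant
  )
}

test_that("mutated nucleotides are binned with conservation and split intervals", {
  dp <- dplyr::bind_rows(
    mk_dp(10, 22, "down", TRUE, id = "a"),   # 12 nt, bin 0 only
    mk_dp(45, 55, "up", TRUE, id = "b"),     # 5 nt in bin 0, 5 in bin 1
    mk_dp(120, 130, id = "c")                # 10 nt in bin 2, ns
  )
  bins <- bin_mutations(dp, cre_length = 200)
  expect_equal(nrow(bins), 4L) # [0,50) [50,100) [100,150) [150,200)
  b0 <- bins[bins$bin_start == 0, ]
  expect_equal(b0$n_mut_nucleotides, 12L + 5L)
  expect_equal(b0$n_datapoints, 2L)
  expect_equal(b0$frac_down, 0.5)
  expect_equal(b0$frac_up, 0.5)
  b1 <- bins[bins$bin_start == 50, ]
  expect_equal(b1$n_mut_nucleotides, 5L)
  expect_equal(b1$frac_up, 1)
  # conservation: binned nucleotide totals equal total mutated positions
  expect_equal(sum(bins$n_mut_nucleotides),
               sum(dp$mutated_end - dp$mutated_start))
  # datapoint order does not matter
  expect_equal(bin_mutations(dp[3:1, ], 200), bins)
  expect_error(bin_mutations(mk_dp(190, 210), 200), "exceed")
})

test_that("hotspot calls follow the coverage-and-fraction rule and merge runs", {
  mk_bin <- function(bin_start, nt, n, down, up, cre = "c") {
    tibble::tibble(cre = cre, bin_start = bin_start,
                   bin_end = bin_start + 50L,
                   n_mut_nucleotides = nt, n_datapoints = n,
                   n_down = down, n_up = up,
                   frac_down = down / n, frac_up = up / n)
  }
  bins <- dplyr::bind_rows(
    mk_bin(0, 60, 40, 5, 0),     # 12.5% down, covered -> activator
    mk_bin(50, 40, 10, 5, 0),    # 50% down but only 40 nt -> no call
    mk_bin(100, 80, 30, 0, 3),   # 10% up exactly (inclusive) -> repressor
    mk_bin(150, 80, 30, 0, 3),   # adjacent same class -> merged
    mk_bin(200, 80, 30, 4, 3),   # both directions >= 10% -> ambiguous
    mk_bin(250, 200, 50, 2, 2)   # 4% both -> no call
  )
  hs <- call_hotspots(bins)
  expect_equal(hs$class, c("activator_binding", "repressor_binding",
                           "ambiguous"))
  expect_equal(hs$start, c(0L, 100L, 200L))
  expect_equal(hs$end, c(50L, 200L, 250L))
  expect_equal(hs$n_bins, c(1L, 2L, 1L))
  # tightening either threshold never adds hotspots
  for (args in list(list(min_nt = 80), list(frac = 0.2),
                    list(min_nt = 100, frac = 0.15))) {
    stricter <- do.call(call_hotspots, c(list(bins), args))
    base_keys <- paste(hs$cre, hs$start)
    expect_lte(nrow(stricter), nrow(hs))
    strict_bins <- sum(stricter$n_bins)
    expect_lte(strict_bins, sum(hs$n_bins))
  }
  expect_equal(nrow(call_hotspots(mk_bin(0, 10, 5, 0, 0))), 0L)
})

test_that("hotspot alignments show the reference slice and flag only mutated positions", {
  fx <- make_fixture(seed = 77)
  hotspot <- tibble::tibble(cre = "CRE_A", start = 300L, end = 350L)
  aln <- extract_hotspot_alignment(hotspot, fx$manifest,
                                   fx$cre$sequence)
  expect_equal(aln$sequence[aln$element_id == "reference"],
               substr(fx$cre$sequence, 301, 350))
  shuffles <- aln[aln$element_id != "reference", ]
  expect_gt(nrow(shuffles), 0)
  man <- fx$manifest
  for (i in seq_len(nrow(shuffles))) {
    el <- man[man$element_id == shuffles$element_id[i], ]
    # every included shuffle overlaps the hotspot
    expect_true(el$mutated_start < 350 && el$mutated_end > 300)
    # flagged positions fall inside that element's mutated interval
    stars <- which(strsplit(shuffles$mismatch_mask[i], "")[[1]] == "*") - 1 +
      shuffles$start[i]
    expect_true(all(stars >= el$mutated_start & stars < el$mutated_end))
  }
  # disjoint shuffles are excluded
  excluded <- man[man$class == "motif_shuffle" &
                    (man$mutated_end <= 300 | man$mutated_start >= 350), ]
  expect_false(any(excluded$element_id %in% shuffles$element_id))
})
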