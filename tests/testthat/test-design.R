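test_that("tiling arithmetic matches the 270/70 design for both CRE lengths", {
  t970 <- tile_cre(random_dna(970, 1), "a")
  expect_equal(nrow(t970), 11L)
  expect_equal(t970$offset_start, seq(0L, 700L, by = 70L))
  t690 <- tile_cre(random_dna(690, 2), "b")
  expect_equal(nrow(t690), 7L)
  expect_equal(t690$offset_start, seq(0L, 420L, by = 70L))
  expect_equal(nrow(tile_cre(random_dna(270, 3), "c")), 1L)
  # consecutive overlap is exactly 200 bp and the union covers every base
  expect_true(all(diff(t970$offset_start) == 70L))
  covered <- sort(unique(unlist(
    purrr::map(t970$offset_start, ~ .x:(.x + 269L)))))
  expect_equal(covered, 0:969)
  expect_true(all(nchar(t970$sequence) == 270L))
  # tiles carry the actual subsequences
  s <- random_dna(970, 4)
  tt <- tile_cre(s, "d")
  expect_equal(tt$sequence[5], substr(s, 281, 550))
  expect_error(tile_cre(random_dna(100, 5), "e"), "shorter")
  # off-grid length gets a flagged end-anchored tile and full coverage
  expect_message(t1000 <- tile_cre(random_dna(1000, 6), "f"), "end-anchored")
  expect_true(t1000$end_anchored[nrow(t1000)])
  expect_equal(max(t1000$offset_start) + 270L, 1000L)
})

test_that("interval shuffling conserves the base multiset and is seeded", {
  s <- random_dna(100, 7)
  out <- shuffle_interval(s, 20, 40, seed = 11)
  expect_equal(nchar(out$sequence), 100)
  expect_equal(substr(out$sequence, 1, 20), substr(s, 1, 20))
  expect_equal(substr(out$sequence, 41, 100), substr(s, 41, 100))
  sorted <- function(x) sort(strsplit(x, "")[[1]])
  expect_equal(sorted(substr(out$sequence, 21, 40)), sorted(substr(s, 21, 40)))
  expect_false(out$unchanged)
  # identical seed, identical result; several seeds give several outcomes
  expect_identical(shuffle_interval(s, 20, 40, seed = 11), out)
  outs <- vapply(1:10, function(i)
    shuffle_interval("ACGTACGT", 0, 8, seed = i)$sequence, character(1))
  expect_gte(length(unique(outs)), 2L)
  # a homopolymer cannot change and is flagged
  homo <- shuffle_interval("AAAATTTT", 0, 4, seed = 1)
  expect_true(homo$unchanged)
  expect_equal(homo$sequence, "AAAATTTT")
  expect_error(shuffle_interval(s, 10, 10, seed = 1), "empty")
  expect_error(shuffle_interval(s, 90, 110, seed = 1), "outside")
})

test_that("the shuffle library has two replicates per contained hit and excludes boundary-crossers", {
  cre <- random_dna(970, 8)
  tiles <- tile_cre(cre, "x")
  hits <- tibble::tibble(
    cre = "x", tile_index = 1L, motif_id = c("m1", "m2", "m3"),
    start = c(10L, 50L, 200L), end = c(20L, 62L, 214L),
    strand = "+", score = 1, p = 1e-5
  )
  lib <- build_shuffle_library(tiles[1, ], hits, seed = 5)
  expect_equal(sum(lib$class == "motif_shuffle"), 6L)
  expect_equal(sum(lib$class == "reference_tile"), 1L)
  # shuffles differ from the reference only inside the mutated interval
  for (i in which(lib$class == "motif_shuffle")) {
    el <- lib[i, ]
    ref <- lib$sequence[lib$class == "reference_tile"]
    a <- el$mutated_start; b <- el$mutated_end
    expect_equal(substr(el$sequence, 1, a), substr(ref, 1, a))
    expect_equal(substr(el$sequence, b + 1, 270), substr(ref, b + 1, 270))
    sorted <- function(x, i, j) sort(strsplit(substr(x, i, j), "")[[1]])
    expect_equal(sorted(el$sequence, a + 1, b), sorted(ref, a + 1, b))
  }
  # replicate pairs differ from each other (or both carry unchanged)
  reps <- dplyr::filter(lib, class == "motif_shuffle") |>
    dplyr::group_by(mutated_start) |>
    dplyr::summarise(distinct = dplyr::n_distinct(sequence),
                     all_unchanged = all(unchanged))
  expect_true(all(reps$distinct == 2 | reps$all_unchanged))
  # same master seed: byte-identical manifest
  expect_identical(build_shuffle_library(tiles[1, ], hits, seed = 5), lib)
  # a hit crossing the tile boundary is excluded with a message
  crossing <- dplyr::mutate(hits[1, ], start = 265L, end = 275L)
  expect_message(
    lib2 <- build_shuffle_library(tiles[1, ], dplyr::bind_rows(hits, crossing),
                                  seed = 5),
    "excluding 1"
  )
  expect_equal(sum(lib2$class == "motif_shuffle"), 6L)
})

test_that("an interval spanning [510,548) is tested exactly in tiles 5 through 8", {
  tiles <- tile_cre(random_dna(970, 9), "x")
  containing <- tiles$tile_index[tiles$offset_start <= 510 &
                                   tiles$offset_start + 270 >= 548]
  expect_equal(containing, 5:8)
})

test_that("variant placement hits every containing tile and guards the reference base", {
  cre <- random_dna(970, 10)
  tiles <- tile_cre(cre, "x")
  expect_equal(tiles_containing_offset(tiles, 901), 11L)
  expect_equal(tiles_containing_offset(tiles, 824), c(9L, 10L, 11L))
  expect_equal(tiles_containing_offset(tiles, 0), 1L)
  ref_at <- function(off) substr(cre, off + 1, off + 1)
  alt_for <- function(b) setdiff(BASES, b)[1]
  vars <- tibble::tibble(
    variant_id = c("v901", "v824", "v0"),
    cre = "x", offset = c(901L, 824L, 0L),
    ref = vapply(c(901L, 824L, 0L), ref_at, character(1)),
    alt = unname(vapply(ref, alt_for, character(1))),
    class = c("proband_variant", "control_variant", "proband_variant")
  )
  els <- build_variant_elements(tiles, vars)
  expect_equal(sum(els$element_id |> grepl(pattern = "v901")), 1L)
  expect_equal(sum(grepl("v824", els$element_id)), 3L)
  expect_equal(sort(els$tile_index[grepl("v824", els$element_id)]), 9:11)
  expect_equal(els$tile_index[grepl("v0", els$element_id)], 1L)
  # the substituted base is the alt, everything else untouched
  e <- els[els$element_id == "x_t11_var_v901", ]
  within <- 901 - 700 # tile 11 starts at offset 700
  expect_equal(substr(e$sequence, within + 1, within + 1), vars$alt[1])
  # mismatched reference base is a hard error
  bad <- dplyr::mutate(vars[1, ], ref = alt_for(ref))
  expect_error(build_variant_elements(tiles, bad), "mismatch")
})

test_that("oligos are handle + 270 bp insert + handle", {
  manifest <- tibble::tibble(element_id = "e1", sequence = random_dna(270, 11))
  h5 <- "AGGACCGGATCAACT"; h3 <- "CATTGCGTGAACCGA"
  ol <- assemble_oligos(manifest, h5, h3)
  expect_equal(nchar(ol$oligo), 300L)
  expect_equal(substr(ol$oligo, 1, 15), h5)
  expect_equal(substr(ol$oligo, 286, 300), h3)
  expect_equal(substr(ol$oligo, 16, 285), manifest$sequence)
  expect_error(assemble_oligos(manifest, "ACGT", h3), "15 bp")
  # technical controls are passed through untiled
  with_ctrl <- add_control_elements(
    manifest |> dplyr::mutate(class = "reference_tile", cre = "x",
                              tile_index = 1L, mutated_start = NA_integer_,
                              mutated_end = NA_integer_,
                              shuffle_rep = NA_integer_, unchanged = FALSE),
    tibble::tibble(name = "p1", sequence = random_dna(270, 12)),
    class = "pos_control")
  expect_equal(sum(with_ctrl$class == "pos_control"), 1L)
  expect_error(add_control_elements(manifest, tibble::tibble(
    name = "bad", sequence = random_dna(100, 13)), "neg_control"), "270")
})
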