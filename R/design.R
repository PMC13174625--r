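#' Tile a CRE into overlapping fixed-length windows
#'
#' Splits a CRE (already in MPRA orientation) into `tile_len` bp tiles
#' offset by `step` bp, so consecutive tiles overlap by `tile_len - step`
#' bp (200 bp with the 270/70 defaults). When the CRE length is not
#' reachable by the regular grid, one final tile anchored at the CRE end is
#' appended and flagged, so every base is covered.
#'
#' @param cre_sequence CRE sequence in MPRA orientation.
#' @param cre CRE identifier.
#' @param tile_len Tile length in bp (default 270).
#' @param step Offset between consecutive tile starts in bp (default 70).
#' @return A tibble with columns `cre`, `tile_index` (1-based),
#'   `offset_start` (0-based CRE offset of the tile start), `end_anchored`
#'   (flag for an irregular final tile) and `sequence`.
#' @examples
#' nrow(tile_cre(strrep("A", 970), "demo")) # 11 tiles
#' @export
tile_cre <- function(cre_sequence, cre = "cre", tile_len = 270L, step = 70L) {
  L <- nchar(cre_sequence)
  if (L < tile_len) {
    abort(sprintf("CRE '%s' (%d bp) is shorter than the tile length %d",
                  cre, L, tile_len))
  }
  starts <- seq(0L, L - tile_len, by = step)
  end_anchored <- rep(FALSE, length(starts))
  if (max(starts) + tile_len < L) {
    starts <- c(starts, L - tile_len)
    end_anchored <- c(end_anchored, TRUE)
    message(sprintf(
      "CRE '%s': length %d not on the %d-bp grid; appended end-anchored tile at offset %d",
      cre, L, step, L - tile_len))
  }
  tibble(
    cre = cre,
    tile_index = seq_along(starts),
    offset_start = as.integer(starts),
    end_anchored = end_anchored,
    sequence = vapply(starts, function(s) slice_seq(cre_sequence, s, s + tile_len),
                      character(1))
  )
}

#' Shuffle the bases inside an interval of a sequence
#'
#' Applies a seeded uniform random permutation to the bases inside the
#' half-open interval `[start, end)` (0-based within `sequence`), leaving
#' all other bases untouched. This is a linear (k = 1) shuffle: the base
#' multiset inside the interval is exactly conserved. If the permutation
#' reproduces the original interval the draw is retried up to 20 times;
#' an interval that cannot change (e.g. a homopolymer) is returned with
#' `unchanged = TRUE`.
#'
#' @param sequence DNA string.
#' @param start,end Half-open 0-based interval within the sequence.
#' @param seed Integer seed; the same seed always yields the same output.
#' @param max_tries Retries when the permutation is a no-op (default 20).
#' @return A list with `sequence` (mutated string) and `unchanged` (logical).
#' @export
shuffle_interval <- function(sequence, start, end, seed, max_tries = 20L) {
  L <- nchar(sequence)
  if (end <= start) abort("empty shuffle interval")
  if (start < 0 || end > L) abort("shuffle interval outside sequence")
  bases <- strsplit(slice_seq(sequence, start, end), "", fixed = TRUE)[[1]]
  shuffled <- withr::with_seed(seed, {
    out <- sample(bases)
    tries <- 1L
    while (identical(out, bases) && tries < max_tries) {
      out <- sample(bases)
      tries <- tries + 1L
    }
    out
  })
  unchanged <- identical(shuffled, bases)
  mutated <- paste0(
    substr(sequence, 1L, start),
    paste(shuffled, collapse = ""),
    substr(sequence, end + 1L, L)
  )
  list(sequence = mutated, unchanged = unchanged)
}

#' Build the motif-shuffle element set
#'
#' For every motif hit fully contained in a tile, emits two independent
#' motif-shuffle elements (shuffle replicates 1 and 2, each with its own
#' seed derived stably from the master seed), plus one reference element
#' per tile. A motif occurring in several overlapping tiles yields
#' independent elements in each tile, which is what enables comparing the
#' same disruption in different flanking contexts. Hits crossing a tile
#' boundary are excluded with a message.
#'
#' @param tiles Tile tibble from [tile_cre()].
#' @param hits Motif-hit tibble from [scan_motifs()] (columns `cre`,
#'   `tile_index`, `motif_id`, `start`, `end`; extra columns ignored).
#' @param seed Master integer seed.
#' @param n_shuffles Shuffle replicates per hit (default 2).
#' @return A manifest tibble: `element_id`, `class`, `cre`, `tile_index`,
#'   `mutated_start`, `mutated_end` (half-open CRE offsets; `NA` for
#'   reference elements), `shuffle_rep`, `unchanged`, `sequence`.
#' @export
build_shuffle_library <- function(tiles, hits, seed, n_shuffles = 2L) {
  tiles <- as_tibble(tiles)
  hits <- as_tibble(hits)
  tile_len <- nchar(tiles$sequence[1])
  reference <- tibble(
    element_id = sprintf("%s_t%02d_ref", tiles$cre, tiles$tile_index),
    class = "reference_tile",
    cre = tiles$cre, tile_index = tiles$tile_index,
    mutated_start = NA_integer_, mutated_end = NA_integer_,
    shuffle_rep = NA_integer_, unchanged = FALSE,
    sequence = tiles$sequence
  )
  key <- paste(tiles$cre, tiles$tile_index)
  hidx <- match(paste(hits$cre, hits$tile_index), key)
  if (anyNA(hidx)) abort("hits reference tiles absent from the tile table")
  t0 <- tiles$offset_start[hidx]
  contained <- hits$start >= t0 & hits$end <= t0 + tile_len
  if (any(!contained)) {
    message(sprintf("excluding %d hit(s) crossing a tile boundary",
                    sum(!contained)))
    hits <- hits[contained, ]
    hidx <- hidx[contained]
    t0 <- t0[contained]
  }
  shuffles <- purrr::map(seq_len(nrow(hits)), function(i) {
    tile_seq <- tiles$sequence[hidx[i]]
    purrr::map(seq_len(n_shuffles), function(rep) {
      s <- derive_seed(seed, hits$cre[i], hits$tile_index[i], hits$motif_id[i],
                       hits$start[i], hits$end[i], rep)
      sh <- shuffle_interval(tile_seq, hits$start[i] - t0[i],
                             hits$end[i] - t0[i], seed = s)
      tibble(
        element_id = sprintf("%s_t%02d_%s_%d-%d_s%d",
                             hits$cre[i], hits$tile_index[i], hits$motif_id[i],
                             hits$start[i], hits$end[i], rep),
        class = "motif_shuffle",
        cre = hits$cre[i], tile_index = hits$tile_index[i],
        mutated_start = as.integer(hits$start[i]),
        mutated_end = as.integer(hits$end[i]),
        shuffle_rep = as.integer(rep), unchanged = sh$unchanged,
        sequence = sh$sequence
      )
    }) %>% bind_rows()
  }) %>% bind_rows()
  bind_rows(reference, shuffles)
}

#' Tiles whose span contains a CRE offset
#'
#' @param tiles Tile tibble for one CRE.
#' @param offset 0-based CRE offset.
#' @return Integer vector of `tile_index` values whose half-open span
#'   `[offset_start, offset_start + tile_len)` contains the offset.
#' @export
tiles_containing_offset <- function(tiles, offset) {
  tile_len <- nchar(tiles$sequence[1])
  tiles$tile_index[tiles$offset_start <= offset &
                     offset < tiles$offset_start + tile_len]
}

#' Insert single-nucleotide variants into library tiles
#'
#' Each variant is placed into every tile whose span contains its offset,
#' yielding one element per (variant, tile). The reference base at the
#' offset must match the tile sequence (in MPRA orientation); a mismatch is
#' a hard error because it almost always indicates an orientation or
#' coordinate bug.
#'
#' @param tiles Tile tibble from [tile_cre()].
#' @param variants A tibble with columns `variant_id`, `cre`, `offset`
#'   (0-based CRE offset), `ref`, `alt` (single bases in MPRA orientation)
#'   and `class` (`"proband_variant"` or `"control_variant"`).
#' @return A manifest tibble with one row per (variant, containing tile);
#'   the mutated interval is the single substituted base.
#' @export
build_variant_elements <- function(tiles, variants) {
  tiles <- as_tibble(tiles)
  variants <- as_tibble(variants)
  if (!all(variants$class %in% c("proband_variant", "control_variant"))) {
    abort("variant class must be proband_variant or control_variant")
  }
  tile_len <- nchar(tiles$sequence[1])
  rows <- purrr::map(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    ct <- tiles[tiles$cre == v$cre, ]
    idx <- which(ct$offset_start <= v$offset &
                   v$offset < ct$offset_start + tile_len)
    if (!length(idx)) {
      abort(sprintf("variant '%s' (offset %d) is not covered by any tile",
                    v$variant_id, as.integer(v$offset)))
    }
    purrr::map(idx, function(j) {
      within <- v$offset - ct$offset_start[j] # 0-based within tile
      have <- substr(ct$sequence[j], within + 1, within + 1)
      if (have != v$ref) {
        abort(sprintf(
          "variant '%s': reference base mismatch at CRE offset %d (tile has '%s', variant says '%s'); check orientation",
          v$variant_id, as.integer(v$offset), have, v$ref))
      }
      seq <- ct$sequence[j]
      substr(seq, within + 1, within + 1) <- v$alt
      tibble(
        element_id = sprintf("%s_t%02d_var_%s", v$cre, ct$tile_index[j],
                             v$variant_id),
        class = v$class,
        cre = v$cre, tile_index = ct$tile_index[j],
        mutated_start = as.integer(v$offset),
        mutated_end = as.integer(v$offset) + 1L,
        shuffle_rep = NA_integer_, unchanged = FALSE,
        sequence = seq
      )
    }) %>% bind_rows()
  })
  bind_rows(rows)
}

#' Append technical control sequences to a manifest
#'
#' Positive and negative control sequences (known high / low activity) are
#' user-supplied and passed through untiled; they must match the insert
#' length of the library.
#'
#' @param manifest A manifest tibble.
#' @param controls A tibble with columns `name`, `sequence`.
#' @param class `"pos_control"` or `"neg_control"`.
#' @return The manifest with control rows appended.
#' @export
add_control_elements <- function(manifest, controls,
                                 class = c("pos_control", "neg_control")) {
  class <- match.arg(class)
  insert_len <- nchar(manifest$sequence[1])
  if (any(nchar(controls$sequence) != insert_len)) {
    abort(sprintf("control sequences must be %d bp", insert_len))
  }
  check_dna(controls$sequence, allow_n = FALSE, what = "control sequence")
  bind_rows(manifest, tibble(
    element_id = paste0(class, "_", controls$name),
    class = class, cre = NA_character_, tile_index = NA_integer_,
    mutated_start = NA_integer_, mutated_end = NA_integer_,
    shuffle_rep = NA_integer_, unchanged = FALSE,
    sequence = controls$sequence
  ))
}

#' Assemble synthesis oligos from library elements
#'
#' Prepends and appends the two 15 bp PCR handles to each 270 bp insert,
#' yielding 300 bp oligos for array synthesis.
#'
#' @param manifest Manifest tibble with `element_id` and `sequence`.
#' @param handle5,handle3 15 bp PCR handle sequences.
#' @return A tibble with columns `element_id`, `oligo`.
#' @export
assemble_oligos <- function(manifest,
                            handle5 = "AGGACCGGATCAACT",
                            handle3 = "CATTGCGTGAACCGA") {
  if (nchar(handle5) != 15L || nchar(handle3) != 15L) {
    abort("PCR handles must be exactly 15 bp")
  }
  check_dna(c(handle5, handle3), allow_n = FALSE, what = "PCR handle")
  check_dna(manifest$sequence, allow_n = FALSE, what = "insert")
  tibble(
    element_id = manifest$element_id,
    oligo = paste0(handle5, manifest$sequence, handle3)
  )
}

#' Read / write a library manifest
#'
#' @param manifest A manifest tibble.
#' @param path TSV path.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(manifest, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    element_id = "c", class = "c", cre = "c",
                    tile_index = "i", mutated_start = "i", mutated_end = "i",
                    shuffle_rep = "i", unchanged = "l", sequence = "c"
                  ))
}
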