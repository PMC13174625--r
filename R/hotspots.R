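#' Bin mutation effects along a CRE
#'
#' Each mutated nucleotide is labelled with its position within the whole
#' CRE and sorted into fixed 50 bp bins `[0,50), [50,100), ...`. A mutation
#' datapoint contributes to every bin containing at least one of its
#' mutated offsets; `n_mut_nucleotides` counts the offsets falling in the
#' bin, and the direction fractions are over the datapoints contributing to
#' the bin.
#'
#' @param datapoints Per-mutation tibble from [summarize_effects()]
#'   (columns `element_id`, `cre`, `mutated_start`, `mutated_end`,
#'   `direction`, `significant`).
#' @param cre_length CRE length in bp (gives the bin grid; a trailing short
#'   bin is kept).
#' @param bin_size Bin width in bp (default 50).
#' @return A tibble of class `mpra_binstats`: `cre`, `bin_start`,
#'   `bin_end`, `n_mut_nucleotides`, `n_datapoints`, `n_down`, `n_up`,
#'   `frac_down`, `frac_up`.
#' @export
bin_mutations <- function(datapoints, cre_length, bin_size = 50L) {
  datapoints <- as_tibble(datapoints)
  if (length(unique(datapoints$cre)) > 1) {
    abort("bin_mutations expects datapoints from a single CRE")
  }
  if (any(datapoints$mutated_end > cre_length, na.rm = TRUE)) {
    abort("mutated offsets exceed the stated CRE length")
  }
  n_bins <- ceiling(cre_length / bin_size)
  grid <- tibble(
    cre = datapoints$cre[1] %||% NA_character_,
    bin_start = (seq_len(n_bins) - 1L) * as.integer(bin_size),
    bin_end = pmin(seq_len(n_bins) * as.integer(bin_size), as.integer(cre_length))
  )
  per_offset <- datapoints %>%
    mutate(.row = row_number()) %>%
    tidyr::uncount(.data$mutated_end - .data$mutated_start, .id = ".k") %>%
    mutate(offset = .data$mutated_start + .data$.k - 1L,
           bin_start = (.data$offset %/% bin_size) * as.integer(bin_size))
  stats <- per_offset %>%
    group_by(.data$cre, .data$bin_start, .data$.row) %>%
    summarise(nt = n(),
              direction = first(.data$direction),
              significant = first(.data$significant),
              .groups = "drop") %>%
    group_by(.data$cre, .data$bin_start) %>%
    summarise(
      n_mut_nucleotides = sum(.data$nt),
      n_datapoints = n(),
      n_down = sum(.data$significant & .data$direction == "down"),
      n_up = sum(.data$significant & .data$direction == "up"),
      .groups = "drop"
    )
  out <- grid %>%
    left_join(stats, by = c("cre", "bin_start")) %>%
    mutate(across(c("n_mut_nucleotides", "n_datapoints", "n_down", "n_up"),
                  ~ tidyr::replace_na(.x, 0L)),
           frac_down = ifelse(.data$n_datapoints > 0,
                              .data$n_down / .data$n_datapoints, 0),
           frac_up = ifelse(.data$n_datapoints > 0,
                            .data$n_up / .data$n_datapoints, 0))
  class(out) <- c("mpra_binstats", class(out))
  out
}

#' Call activator- / repressor-binding hotspots
#'
#' A bin qualifies when it has adequate coverage (at least `min_nt` mutated
#' nucleotides) and at least a fraction `frac` of its shuffle datapoints
#' significantly change activity in one direction. Shuffles that *decrease*
#' activity mark an activator-binding site; shuffles that *increase* it
#' mark a repressor-binding site; a bin qualifying in both directions is
#' `ambiguous`. Adjacent qualifying bins of the same class merge into one
#' hotspot.
#'
#' @param binstats Bin statistics from [bin_mutations()].
#' @param min_nt Minimum mutated nucleotides per bin (default 50).
#' @param frac Minimum fraction of significant same-direction datapoints
#'   (default 0.10); both thresholds are inclusive.
#' @return A tibble of class `mpra_hotspots`: `cre`, `start`, `end`
#'   (half-open CRE offsets), `class`, `n_bins`.
#' @export
call_hotspots <- function(binstats, min_nt = 50L, frac = 0.10) {
  b <- as_tibble(binstats) %>%
    mutate(
      act = .data$n_mut_nucleotides >= min_nt & .data$frac_down >= frac,
      rep = .data$n_mut_nucleotides >= min_nt & .data$frac_up >= frac,
      call = case_when(
        .data$act & .data$rep ~ "ambiguous",
        .data$act ~ "activator_binding",
        .data$rep ~ "repressor_binding",
        TRUE ~ NA_character_
      )
    ) %>%
    arrange(.data$cre, .data$bin_start)
  qual <- filter(b, !is.na(.data$call))
  if (!nrow(qual)) {
    out <- tibble(cre = character(), start = integer(), end = integer(),
                  class = character(), n_bins = integer())
  } else {
    out <- qual %>%
      group_by(.data$cre) %>%
      mutate(new_run = .data$bin_start != dplyr::lag(.data$bin_end,
                                                     default = -1L) |
               .data$call != dplyr::lag(.data$call, default = "")) %>%
      mutate(run = cumsum(.data$new_run)) %>%
      group_by(.data$cre, .data$run) %>%
      summarise(start = min(.data$bin_start), end = max(.data$bin_end),
                class = first(.data$call), n_bins = n(), .groups = "drop") %>%
      select("cre", "start", "end", "class", "n_bins")
  }
  class(out) <- c("mpra_hotspots", class(out))
  out
}

#' Align shuffle sequences under a hotspot
#'
#' Extracts the reference CRE slice over a hotspot interval plus one row
#' per shuffle element whose mutated interval overlaps the hotspot; each
#' shuffle row shows its sequence over the same interval (restricted to its
#' tile's span) with non-reference positions flagged.
#'
#' @param hotspot One-row tibble (`cre`, `start`, `end`).
#' @param manifest Library manifest tibble.
#' @param cre_sequence Full CRE sequence in MPRA orientation.
#' @return A tibble with `element_id` (`"reference"` for the CRE slice),
#'   `start`, `end`, `sequence` and `mismatch_mask` (a string with `*`
#'   flagging non-reference positions).
#' @export
extract_hotspot_alignment <- function(hotspot, manifest, cre_sequence) {
  hs_start <- hotspot$start[1]
  hs_end <- hotspot$end[1]
  ref_slice <- slice_seq(cre_sequence, hs_start, hs_end)
  tile_len <- nchar(manifest$sequence[1])
  overl <- manifest %>%
    filter(.data$class == "motif_shuffle", .data$cre == hotspot$cre[1],
           .data$mutated_start < hs_end, .data$mutated_end > hs_start)
  rows <- purrr::map(seq_len(nrow(overl)), function(i) {
    el <- overl[i, ]
    # tile span in CRE offsets; recover the tile start from the reference id
    ref_el <- manifest[manifest$class == "reference_tile" &
                         manifest$cre == el$cre &
                         manifest$tile_index == el$tile_index, ]
    # reference and shuffle share the tile span; locate it via the mutated
    # interval: tile spans [t0, t0 + tile_len) with t0 = tile start
    t0 <- find_tile_start(ref_el$sequence, cre_sequence, el$mutated_start,
                          tile_len)
    a <- max(hs_start, t0)
    bnd <- min(hs_end, t0 + tile_len)
    if (a >= bnd) return(NULL)
    slice <- slice_seq(el$sequence, a - t0, bnd - t0)
    ref <- slice_seq(cre_sequence, a, bnd)
    mask <- paste(ifelse(strsplit(slice, "")[[1]] != strsplit(ref, "")[[1]],
                         "*", "."), collapse = "")
    tibble(element_id = el$element_id, start = a, end = bnd,
           sequence = slice, mismatch_mask = mask)
  })
  bind_rows(
    tibble(element_id = "reference", start = hs_start, end = hs_end,
           sequence = ref_slice,
           mismatch_mask = strrep(".", hs_end - hs_start)),
    bind_rows(rows)
  )
}

# Locate a tile's start offset in the CRE: the tile sequence must match the
# CRE slice at exactly one offset consistent with containing `inside`.
find_tile_start <- function(tile_sequence, cre_sequence, inside, tile_len) {
  cand <- seq(max(0L, inside - tile_len + 1L), inside)
  for (t0 in cand) {
    if (t0 + tile_len <= nchar(cre_sequence) &&
        slice_seq(cre_sequence, t0, t0 + tile_len) == tile_sequence) {
      return(t0)
    }
  }
  abort("reference tile sequence not found in the CRE at a compatible offset")
}
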