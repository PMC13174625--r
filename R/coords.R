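#' Coordinate conventions: genomic vs MPRA offsets
#'
#' A cis-regulatory element (CRE) region is stored with 1-based inclusive
#' genomic coordinates on the plus strand. MPRA offsets are 0-based positions
#' counted in gene orientation: for a minus-strand gene such as *MECP2*,
#' offset 0 is the base at the region's *higher* genomic coordinate (the end
#' nearer the TSS for downstream elements), so that
#' `offset = end - pos`.
#'
#' All internal intervals on the MPRA axis are half-open `[a, b)`.
#'
#' @param regions A data frame of regions with columns `chrom`, `start`,
#'   `end` (1-based inclusive) and `name`.
#' @param name Character vector of region names (recycled against `pos` /
#'   `offset`).
#' @param pos Integer vector of 1-based genomic coordinates.
#' @param offset Integer vector of 0-based MPRA offsets.
#'
#' @return A tibble with one row per query: `cre`, `pos`, `offset`.
#'
#' @examples
#' regions <- tibble::tibble(
#'   chrom = "chrX", start = 154045988, end = 154046957, name = "CRE_A"
#' )
#' map_genomic_to_mpra(regions, "CRE_A", 154046133) # offset 824
#' map_mpra_to_genomic(regions, "CRE_A", 824)       # pos 154046133
#' @export
map_genomic_to_mpra <- function(regions, name, pos) {
  regions <- validate_regions(regions)
  n <- max(length(name), length(pos))
  name <- rep_len(name, n)
  pos <- rep_len(as.numeric(pos), n)
  idx <- match(name, regions$name)
  if (anyNA(idx)) {
    abort(sprintf("unknown region name(s): %s",
                  paste(unique(name[is.na(idx)]), collapse = ", ")))
  }
  rs <- regions$start[idx]
  re <- regions$end[idx]
  out <- pos < rs | pos > re
  if (any(out)) {
    i <- which(out)[1]
    abort(sprintf(
      "position %s is outside region '%s' (%s:%s-%s)",
      format(pos[i], scientific = FALSE), name[i],
      regions$chrom[idx[i]], format(rs[i], scientific = FALSE),
      format(re[i], scientific = FALSE)
    ))
  }
  tibble(cre = name, pos = pos, offset = re - pos)
}

#' @rdname map_genomic_to_mpra
#' @export
map_mpra_to_genomic <- function(regions, name, offset) {
  regions <- validate_regions(regions)
  n <- max(length(name), length(offset))
  name <- rep_len(name, n)
  offset <- rep_len(as.numeric(offset), n)
  idx <- match(name, regions$name)
  if (anyNA(idx)) {
    abort(sprintf("unknown region name(s): %s",
                  paste(unique(name[is.na(idx)]), collapse = ", ")))
  }
  len <- regions$end[idx] - regions$start[idx] + 1
  out <- offset < 0 | offset >= len
  if (any(out)) {
    i <- which(out)[1]
    abort(sprintf("offset %d is outside region '%s' (length %d)",
                  as.integer(offset[i]), name[i], as.integer(len[i])))
  }
  tibble(cre = name, offset = offset, pos = regions$end[idx] - offset)
}

#' Orient a plus-strand genomic slice into MPRA orientation
#'
#' Library sequences are represented 5'->3' on the gene (minus) strand, so
#' that string index `i + 1` corresponds to MPRA offset `i`. This is the
#' reverse complement of the plus-strand slice. The orientation choice is
#' isolated here; pass `reverse = FALSE` to keep plus-strand orientation.
#'
#' @param plus_strand_slice Character vector of plus-strand DNA slices
#'   (alphabet A/C/G/T/N).
#' @param reverse Reverse-complement the input (default `TRUE`).
#' @return Character vector of oriented sequences, same lengths as input.
#' @examples
#' orient_sequence("AAAC") # "GTTT"
#' @export
orient_sequence <- function(plus_strand_slice, reverse = TRUE) {
  check_dna(plus_strand_slice, allow_n = TRUE, what = "genomic slice")
  if (reverse) revcomp(plus_strand_slice) else plus_strand_slice
}

validate_regions <- function(regions) {
  regions <- as_tibble(regions)
  need <- c("chrom", "start", "end", "name")
  missing <- setdiff(need, names(regions))
  if (length(missing)) {
    abort(sprintf("region table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (any(regions$start > regions$end)) {
    abort("region table has start > end; coordinates are 1-based inclusive")
  }
  if (anyDuplicated(regions$name)) abort("duplicated region names")
  regions
}

region_length <- function(regions) {
  regions$end - regions$start + 1
}
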