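#' Read a region table
#'
#' Regions are TSV with header columns `chrom`, `start`, `end`, `name`,
#' where `start`/`end` are 1-based inclusive genomic coordinates (the
#' convention of the printed target intervals). Use [read_regions_bed()] for
#' BED input (0-based half-open), which is converted on load.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`.
#' @export
read_regions <- function(path) {
  regions <- readr::read_tsv(path, show_col_types = FALSE,
                             col_types = readr::cols(
                               chrom = "c", start = "d", end = "d", name = "c"
                             ))
  validate_regions(regions)
}

#' @rdname read_regions
#' @export
read_regions_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                         show_col_types = FALSE,
                         col_types = readr::cols(
                           chrom = "c", start = "d", end = "d", name = "c"
                         ))
  message("BED input: converting 0-based half-open to 1-based inclusive")
  validate_regions(dplyr::mutate(bed, start = .data$start + 1))
}

#' Read / write CRE sequences as FASTA
#'
#' Record ids must equal region names. Returns a tibble so sequences join
#' naturally onto region and manifest tables.
#'
#' @param path FASTA file path.
#' @return `read_cre_fasta()`: a tibble with columns `name`, `sequence`.
#' @export
read_cre_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  tibble(
    name = sub("\\s.*$", "", names(seqs)),
    sequence = unname(as.character(seqs))
  )
}

#' @rdname read_cre_fasta
#' @param sequences A tibble with columns `name`, `sequence`.
#' @export
write_cre_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(setNames(sequences$sequence, sequences$name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a MEME minimal-format motif database
#'
#' Parses the MEME minimal text format (a `MEME version` line, optional
#' `ALPHABET`/`Background` lines, and one `MOTIF` block per motif with a
#' `letter-probability matrix` header). Only the ACGT alphabet is supported.
#'
#' @param path Path to a MEME minimal format file.
#' @return A tibble with columns `motif_id`, `width`, and `pwm` (a
#'   list-column of 4 x width probability matrices with rows A, C, G, T;
#'   each column sums to 1).
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^MEME version", lines))) {
    abort("not a MEME minimal format file (no 'MEME version' line)")
  }
  motif_starts <- grep("^MOTIF\\b", lines)
  if (!length(motif_starts)) abort("no MOTIF blocks found")
  motifs <- purrr::map(seq_along(motif_starts), function(i) {
    from <- motif_starts[i]
    to <- if (i < length(motif_starts)) motif_starts[i + 1] - 1 else length(lines)
    block <- lines[from:to]
    id <- strsplit(trimws(block[1]), "\\s+")[[1]][2]
    hdr <- grep("^letter-probability matrix", block)
    if (!length(hdr)) abort(sprintf("motif '%s' lacks a letter-probability matrix", id))
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", block[hdr[1]]))
    rows <- block[(hdr[1] + 1):length(block)]
    rows <- rows[grepl("^\\s*[0-9.eE+-]", rows)]
    rows <- head(rows, w)
    if (length(rows) != w) abort(sprintf("motif '%s': expected %d matrix rows", id, w))
    m <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4]),
                  numeric(4), USE.NAMES = FALSE))
    pwm <- t(m) # 4 x width
    rownames(pwm) <- DNA_BASES
    # absorb plain-text rounding before validating
    sums <- colSums(pwm)
    if (all(abs(sums - 1) <= 1e-4)) pwm <- sweep(pwm, 2, sums, "/")
    validate_pwm(pwm, id)
    list(motif_id = id, width = w, pwm = pwm)
  })
  tibble(
    motif_id = purrr::map_chr(motifs, "motif_id"),
    width = purrr::map_int(motifs, "width"),
    pwm = purrr::map(motifs, "pwm")
  )
}

#' @rdname read_meme
#' @param motifs A motif tibble as returned by `read_meme()`.
#' @export
write_meme <- function(motifs, path) {
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "",
           "strands: + -", "",
           "Background letter frequencies",
           "A 0.25 C 0.25 G 0.25 T 0.25", "")
  for (i in seq_len(nrow(motifs))) {
    pwm <- motifs$pwm[[i]]
    out <- c(out,
             sprintf("MOTIF %s", motifs$motif_id[i]),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                     ncol(pwm)),
             apply(pwm, 2, function(col) paste(sprintf("%.8f", col), collapse = " ")),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

validate_pwm <- function(pwm, id = "motif") {
  if (any(pwm < 0)) abort(sprintf("motif '%s' has negative probabilities", id))
  sums <- colSums(pwm)
  if (any(abs(sums - 1) > 1e-6)) {
    abort(sprintf("motif '%s': columns must sum to 1 (max deviation %.2g)",
                  id, max(abs(sums - 1))))
  }
  if (ncol(pwm) < 4) abort(sprintf("motif '%s' is narrower than 4 columns", id))
  invisible(pwm)
}

#' Read a barcode count table
#'
#' TSV with header columns `replicate`, `element_id`, `barcode`,
#' `dna_count`, `rna_count`. Counts must be non-negative integers and
#' `(replicate, element_id, barcode)` unique.
#'
#' @param path Path to the TSV.
#' @return A tibble of barcode counts.
#' @export
read_counts <- function(path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              replicate = "c", element_id = "c", barcode = "c",
                              dna_count = "d", rna_count = "d"
                            ))
  validate_counts(counts)
}

validate_counts <- function(counts) {
  counts <- as_tibble(counts)
  need <- c("replicate", "element_id", "barcode", "dna_count", "rna_count")
  missing <- setdiff(need, names(counts))
  if (length(missing)) {
    abort(sprintf("count table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  cnt <- c(counts$dna_count, counts$rna_count)
  if (any(cnt < 0) || any(cnt != floor(cnt))) {
    abort("counts must be non-negative integers")
  }
  if (anyDuplicated(counts[c("replicate", "element_id", "barcode")])) {
    abort("(replicate, element_id, barcode) rows must be unique")
  }
  counts
}

#' Read a 6-column PED pedigree file
#'
#' Columns: family, individual, father, mother, sex (1 = male, 2 = female),
#' phenotype (2 = affected, 1 = unaffected). `0` denotes a missing parent.
#'
#' @param path Path to the PED file (whitespace-delimited, no header).
#' @return A tibble with columns `family`, `id`, `father`, `mother`,
#'   `sex` (`"male"`/`"female"`) and `affected` (logical).
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_table(path,
                           col_names = c("family", "id", "father", "mother",
                                         "sex", "phenotype"),
                           col_types = "ccccii", show_col_types = FALSE)
  validate_pedigree(tibble(
    family = ped$family, id = ped$id,
    father = ped$father, mother = ped$mother,
    sex = c("male", "female")[ped$sex],
    affected = ped$phenotype == 2L
  ))
}

validate_pedigree <- function(ped) {
  ped <- as_tibble(ped)
  need <- c("family", "id", "father", "mother", "sex", "affected")
  missing <- setdiff(need, names(ped))
  if (length(missing)) {
    abort(sprintf("pedigree lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  if (!all(ped$sex %in% c("male", "female"))) abort("pedigree sex must be male/female")
  # every named parent must exist within the same family
  for (col in c("father", "mother")) {
    p <- ped[[col]]
    named <- !is.na(p) & p != "0"
    ok <- paste(ped$family[named], p[named]) %in% paste(ped$family, ped$id)
    if (!all(ok)) {
      abort(sprintf("pedigree: %s '%s' not found in family '%s'",
                    col, p[named][!ok][1], ped$family[named][!ok][1]))
    }
  }
  ped
}

#' @rdname read_pedigree
#' @param ped A pedigree tibble.
#' @export
write_pedigree <- function(ped, path) {
  ped <- validate_pedigree(ped)
  out <- data.frame(
    ped$family, ped$id, ped$father, ped$mother,
    ifelse(ped$sex == "male", 1L, 2L),
    ifelse(ped$affected, 2L, 1L)
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a cohort VCF into a long genotype table
#'
#' Reads a VCF v4.2 subset (single-allelic SNVs, FORMAT `GT:DP`) via the
#' vcfR parser and returns one row per (variant, sample). Male chrX
#' genotypes are expected hemizygous (a single allele, e.g. `"1"`).
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `sample`, `gt`, `dp`.
#' @export
read_cohort_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    abort("multi-allelic sites are not supported; split or filter upstream")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  long <- tibble(
    chrom = rep(fix$CHROM, ncol(gt)),
    pos = rep(as.numeric(fix$POS), ncol(gt)),
    ref = rep(fix$REF, ncol(gt)),
    alt = rep(fix$ALT, ncol(gt)),
    qual = rep(as.numeric(fix$QUAL), ncol(gt)),
    sample = rep(colnames(gt), each = nrow(gt)),
    gt = as.vector(gt),
    dp = as.vector(dp)
  )
  dplyr::filter(long, !is.na(.data$gt))
}

#' Write a long genotype table as VCF v4.2
#'
#' Inverse of [read_cohort_vcf()] for the `GT:DP` subset this package uses;
#' mainly serves the synthetic cohort generator.
#'
#' @param variants Long genotype tibble (`chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `sample`, `gt`, `dp`).
#' @param path Output path.
#' @export
write_cohort_vcf <- function(variants, path) {
  samples <- sort(unique(variants$sample))
  key <- dplyr::distinct(variants, .data$chrom, .data$pos, .data$ref,
                         .data$alt, .data$qual) %>%
    arrange(.data$chrom, .data$pos, .data$alt)
  body <- vapply(seq_len(nrow(key)), function(i) {
    k <- key[i, ]
    rows <- variants[variants$chrom == k$chrom & variants$pos == k$pos &
                       variants$alt == k$alt & variants$ref == k$ref, ]
    cells <- setNames(paste0(rows$gt, ":", rows$dp), rows$sample)
    geno <- ifelse(samples %in% rows$sample, cells[samples], "./.:.")
    paste(c(k$chrom, format(k$pos, scientific = FALSE), ".", k$ref, k$alt,
            format(k$qual), "PASS", ".", "GT:DP", geno), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}
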