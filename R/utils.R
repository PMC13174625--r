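# Internal helpers shared across modules.

# Deterministic 31-bit seed from a master seed plus arbitrary string parts.
# Stable across runs and platforms, so adding library elements never perturbs
# the seeds of existing ones.
derive_seed <- function(master, ...) {
  parts <- paste(c(format(master), ...), collapse = "\r")
  h <- abs(as.numeric(master)) %% 2147483647
  for (code in utf8ToInt(parts)) h <- (h * 31 + code) %% 2147483647
  as.integer(h + 1)
}

check_dna <- function(x, allow_n = TRUE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains characters outside {A,C,G,T%s} (first offender: '%s')",
      what, if (allow_n) ",N" else "", substr(x[bad][1], 1, 30)
    ))
  }
  invisible(x)
}

# Reverse complement of plain DNA strings (vectorised).
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(
    strsplit(comp, "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""),
    character(1)
  )
}

# 0-based half-open substring of a 1-based R string.
slice_seq <- function(x, start, end) substr(x, start + 1L, end)

DNA_BASES <- c("A", "C", "G", "T")

encode_dna <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], DNA_BASES)
}
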