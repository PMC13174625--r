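# Shared fixture builders and independent oracles.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(BASES, n, replace = TRUE), collapse = ""))
}

# Sharply peaked PWM whose consensus is `cons`.
sharp_pwm <- function(cons, peak = 0.97) {
  w <- nchar(cons)
  m <- matrix((1 - peak) / 3, nrow = 4, ncol = w,
              dimnames = list(BASES, NULL))
  m[cbind(match(strsplit(cons, "")[[1]], BASES), seq_len(w))] <- peak
  m
}

random_pwm <- function(w, seed) {
  withr::with_seed(seed, {
    m <- matrix(rgamma(4 * w, shape = 1), nrow = 4)
  })
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- BASES
  m
}

motif_tbl <- function(...) {
  pwms <- list(...)
  tibble::tibble(
    motif_id = names(pwms),
    width = unname(vapply(pwms, ncol, integer(1))),
    pwm = unname(pwms)
  )
}

# Independent Brunner-Munzel statistic oracle (textbook formulas, written
# against the published definition, not the package internals).
bm_stat_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y)); r1 <- r[1:n1]; r2 <- r[-(1:n1)]
  h1 <- rank(x); h2 <- rank(y)
  m1 <- mean(r1); m2 <- mean(r2)
  s1 <- sum((r1 - h1 - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  s2 <- sum((r2 - h2 - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  pooled <- n1 * s1 + n2 * s2
  if (pooled <= 0) return(sign(m2 - m1) * Inf)
  n1 * n2 * (m2 - m1) / (N * sqrt(pooled))
}

# Exhaustive two-sided permutation p of the Brunner-Munzel statistic.
bm_perm_p_oracle <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pool), n1)
  obs <- abs(bm_stat_oracle(x, y))
  stats <- apply(idx, 2, function(ix) abs(bm_stat_oracle(pool[ix], pool[-ix])))
  mean(stats >= obs - 1e-12)
}

# A small deterministic count table: one reference and one shuffle element,
# chosen RNA/DNA sums, n_bc barcodes each, across replicates.
counts_from_sums <- function(spec_rows) {
  purrr::pmap(spec_rows, function(replicate, element_id, n_bc, dna, rna) {
    tibble::tibble(
      replicate = replicate, element_id = element_id,
      barcode = paste0(element_id, "_b", seq_len(n_bc)),
      dna_count = diff(round(seq(0, dna, length.out = n_bc + 1))),
      rna_count = diff(round(seq(0, rna, length.out = n_bc + 1)))
    )
  }) |> dplyr::bind_rows()
}

# 200-element dense-shuffle family: every element shuffles one random 70 bp
# window of a shared 270 bp background, giving k-mer presence fractions in
# the informative range.
dense_shuffle_family <- function(n = 200, seed = 1, window = 70L) {
  base <- random_dna(270, seed)
  starts <- withr::with_seed(seed + 1, sample(0:(270 - window), n, replace = TRUE))
  seqs <- vapply(seq_len(n), function(i) {
    shuffle_interval(base, starts[i], starts[i] + window,
                     seed = seed * 10000 + i)$sequence
  }, character(1))
  tibble::tibble(element_id = paste0("e", seq_len(n)), sequence = seqs)
}
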