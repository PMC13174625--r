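#' Build a k-mer presence/absence matrix for a sequence family
#'
#' Extracts all 8-14 bp k-mers from each sequence (forward orientation;
#' all library sequences share the MPRA orientation) and keeps the
#' informative ones: k-mers both present in at least `min_frac` and absent
#' in at least `min_frac` of the sequences. Shuffle-induced presence and
#' absence of motif words is exactly the variation this is meant to
#' capture.
#'
#' @param sequences A tibble with columns `element_id`, `sequence`,
#'   `activity` (one activity value per sequence, e.g. the mean over
#'   replicates).
#' @param kmin,kmax k-mer length range (defaults 8 and 14).
#' @param min_frac Minimum presence *and* absence fraction (default 0.2,
#'   inclusive on both sides).
#' @return An object of class `kmer_matrix`: a list with `kmers`
#'   (character), `presence` (logical elements x kmers matrix),
#'   `activity`, and `element_id`.
#' @export
build_kmer_matrix <- function(sequences, kmin = 8L, kmax = 14L,
                              min_frac = 0.2) {
  sequences <- as_tibble(sequences)
  n <- nrow(sequences)
  if (n < 10) abort("need >= 10 sequences for k-mer association")
  check_dna(sequences$sequence, allow_n = FALSE, what = "element sequence")
  kmer_sets <- purrr::map(sequences$sequence, function(s) {
    L <- nchar(s)
    unique(unlist(lapply(kmin:kmax, function(k) {
      if (L < k) return(character())
      unique(substring(s, 1:(L - k + 1), k:L))
    })))
  })
  counts <- table(unlist(kmer_sets))
  lo <- ceiling(min_frac * n)
  hi <- n - lo
  keep <- names(counts)[counts >= lo & counts <= hi]
  if (!length(keep)) {
    presence <- matrix(FALSE, nrow = n, ncol = 0)
  } else {
    presence <- vapply(kmer_sets, function(ks) keep %in% ks,
                       logical(length(keep)))
    presence <- if (length(keep) == 1L) matrix(presence, nrow = n) else t(presence)
    colnames(presence) <- keep
  }
  structure(
    list(kmers = keep, presence = presence,
         activity = sequences$activity, element_id = sequences$element_id,
         kmin = kmin, kmax = kmax, min_frac = min_frac),
    class = "kmer_matrix"
  )
}

#' @export
print.kmer_matrix <- function(x, ...) {
  cat(sprintf("kmer_matrix: %d sequences, %d retained %d-%d-mers (prevalence in [%.0f%%, %.0f%%])\n",
              length(x$element_id), length(x$kmers), x$kmin, x$kmax,
              100 * x$min_frac, 100 * (1 - x$min_frac)))
  invisible(x)
}

#' Brunner-Munzel two-sample rank test
#'
#' Tests the stochastic superiority `p_hat = P(X < Y) + 0.5 P(X = Y)`
#' against 1/2 with the studentised rank statistic of Brunner and Munzel:
#' placement-based variance estimates and Satterthwaite-approximated
#' degrees of freedom, two-sided p from the t distribution. When the
#' variance estimate degenerates (complete separation or all-tied samples)
#' the test falls back to a seeded permutation p-value on `p_hat`
#' (exhaustive when `choose(n + m, n)` is small, Monte Carlo otherwise)
#' and flags it.
#'
#' @param x,y Numeric samples (e.g. activities where a k-mer is absent /
#'   present), each of length >= 2.
#' @param seed Seed for the Monte Carlo permutation fallback.
#' @param exhaustive_limit Maximum number of label assignments enumerated
#'   exactly in the fallback (default 2e5).
#' @param n_perm Monte Carlo permutations when above the limit.
#' @return An object of class `bm_test`: `statistic`, `df`, `p.value`,
#'   `p_hat`, `method` (`"t"` or `"permutation"`).
#' @export
brunner_munzel <- function(x, y, seed = 1L, exhaustive_limit = 2e5,
                           n_perm = 1e4) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2 || n2 < 2) abort("both samples must have >= 2 values")
  N <- n1 + n2
  r <- rank(c(x, y))
  r1 <- r[seq_len(n1)]
  r2 <- r[n1 + seq_len(n2)]
  h1 <- rank(x)
  h2 <- rank(y)
  m1 <- mean(r1)
  m2 <- mean(r2)
  p_hat <- (m2 - (n2 + 1) / 2) / n1
  s1sq <- sum((r1 - h1 - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  s2sq <- sum((r2 - h2 - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  pooled <- n1 * s1sq + n2 * s2sq
  if (pooled <= 0) {
    # degenerate variance: permutation on the effect estimate
    p <- bm_permutation_p(x, y, seed = seed,
                          exhaustive_limit = exhaustive_limit,
                          n_perm = n_perm)
    out <- list(statistic = if (p_hat > 0.5) Inf else if (p_hat < 0.5) -Inf else 0,
                df = NA_real_, p.value = p, p_hat = p_hat,
                method = "permutation")
  } else {
    stat <- n1 * n2 * (m2 - m1) / (N * sqrt(pooled))
    df <- pooled^2 / ((n1 * s1sq)^2 / (n1 - 1) + (n2 * s2sq)^2 / (n2 - 1))
    out <- list(statistic = stat, df = df,
                p.value = 2 * pt(-abs(stat), df), p_hat = p_hat,
                method = "t")
  }
  structure(out, class = "bm_test")
}

# Two-sided permutation p-value on |p_hat - 1/2| under label exchange.
bm_permutation_p <- function(x, y, seed, exhaustive_limit, n_perm) {
  n1 <- length(x)
  n2 <- length(y)
  pool <- c(x, y)
  r <- rank(pool)
  obs <- abs(p_hat_from_ranks(r, seq_len(n1), n1, n2) - 0.5)
  n_comb <- choose(n1 + n2, n1)
  if (n_comb <= exhaustive_limit) {
    idx <- combn(n1 + n2, n1)
    stats <- apply(idx, 2, function(ix) abs(p_hat_from_ranks(r, ix, n1, n2) - 0.5))
    mean(stats >= obs - 1e-12)
  } else {
    withr::with_seed(seed, {
      stats <- replicate(n_perm, {
        ix <- sample.int(n1 + n2, n1)
        abs(p_hat_from_ranks(r, ix, n1, n2) - 0.5)
      })
      (1 + sum(stats >= obs - 1e-12)) / (n_perm + 1)
    })
  }
}

p_hat_from_ranks <- function(pooled_ranks, x_idx, n1, n2) {
  m2 <- (sum(pooled_ranks) - sum(pooled_ranks[x_idx])) / n2
  (m2 - (n2 + 1) / 2) / n1
}

#' @export
print.bm_test <- function(x, ...) {
  cat(sprintf(
    "Brunner-Munzel test (%s): statistic = %.4g, df = %.3g, p = %.4g, p_hat = %.4g\n",
    x$method, x$statistic, x$df, x$p.value, x$p_hat))
  invisible(x)
}

#' @rdname brunner_munzel
#' @param ... Unused.
#' @export
tidy.bm_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
         p_hat = x$p_hat, method = x$method)
}

#' Associate retained k-mers with reporter activity
#'
#' Runs the Brunner-Munzel test per retained k-mer, comparing activities of
#' sequences lacking the k-mer (x) to those containing it (y). No multiple
#' testing correction is applied; the stringent raw threshold `p_cut`
#' plays that role.
#'
#' @param kmat A `kmer_matrix` from [build_kmer_matrix()].
#' @param p_cut Raw two-sided significance threshold (default 1e-3).
#' @param all Return all tested k-mers (with a `significant` flag) instead
#'   of only the significant ones.
#' @param seed Seed for degenerate-variance permutation fallbacks.
#' @return A tibble: `kmer`, `k`, `statistic`, `df`, `p`, `p_hat`,
#'   `direction` (`"higher"` when presence associates with higher
#'   activity), `method`, `significant`.
#' @export
associate_kmers <- function(kmat, p_cut = 1e-3, all = FALSE, seed = 1L) {
  if (!inherits(kmat, "kmer_matrix")) abort("kmat must be a kmer_matrix")
  res <- purrr::map(seq_along(kmat$kmers), function(j) {
    present <- kmat$presence[, j]
    fit <- brunner_munzel(kmat$activity[!present], kmat$activity[present],
                          seed = derive_seed(seed, kmat$kmers[j]))
    tibble(
      kmer = kmat$kmers[j], k = nchar(kmat$kmers[j]),
      statistic = fit$statistic, df = fit$df, p = fit$p.value,
      p_hat = fit$p_hat,
      direction = ifelse(fit$p_hat >= 0.5, "higher", "lower"),
      method = fit$method
    )
  }) %>% bind_rows()
  if (!nrow(res)) {
    res <- tibble(kmer = character(), k = integer(), statistic = numeric(),
                  df = numeric(), p = numeric(), p_hat = numeric(),
                  direction = character(), method = character())
  }
  res <- mutate(res, significant = .data$p < p_cut)
  if (all) res else filter(res, .data$significant)
}
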