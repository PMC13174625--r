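# k-mer -> PWM attribution: ungapped column-correlation matching with a
# seeded Monte Carlo null, plus iterative refinement to the minimal k-mer.

#' Encode a k-mer as a pseudocount probability matrix
#'
#' One column per base: probability `(1 + pc/4) / (1 + pc)` for the
#' observed base and `pc/4 / (1 + pc)` for the others.
#'
#' @param kmer DNA string (A/C/G/T).
#' @param pseudocount Pseudocount mass (default 0.1).
#' @return A 4 x nchar(kmer) probability matrix, rows A, C, G, T.
#' @export
kmer_to_pwm <- function(kmer, pseudocount = 0.1) {
  e <- encode_dna(kmer)
  if (anyNA(e)) abort("kmer must contain only A/C/G/T")
  m <- matrix(pseudocount * 0.25 / (1 + pseudocount), nrow = 4,
              ncol = length(e), dimnames = list(DNA_BASES, NULL))
  m[cbind(e, seq_along(e))] <- (1 + pseudocount * 0.25) / (1 + pseudocount)
  m
}

# Reverse complement of a probability PWM: reverse columns, swap A<->T and
# C<->G rows.
pwm_revcomp <- function(pwm) {
  out <- pwm[4:1, rev(seq_len(ncol(pwm))), drop = FALSE]
  rownames(out) <- DNA_BASES
  out
}

# Centred columns and their norms, precomputed once per PWM so alignment
# scoring reduces to column-wise dot products.
prep_pwm_cols <- function(pwm) {
  centred <- sweep(pwm, 2, colMeans(pwm))
  list(c = centred, n = sqrt(colSums(centred^2)))
}

# Best ungapped alignment score between a query PWM and a target PWM on one
# strand: slide with >= min_overlap overlapping columns; per-offset score is
# the sum of per-column Pearson correlations between aligned probability
# columns (zero-variance columns contribute 0). Summing rather than
# averaging rewards longer agreement, so a full-width match outranks a
# chance short one.
pwm_align_score <- function(qp, tp, min_overlap = 4L) {
  wq <- ncol(qp$c)
  wt <- ncol(tp$c)
  best <- list(score = -Inf, offset = NA_integer_)
  # offset = position of query column 1 relative to target column 1
  for (off in seq(-(wq - min_overlap), wt - min_overlap)) {
    qi <- max(1L, 1L - off)
    ti <- qi + off
    len <- min(wq - qi, wt - ti) + 1L
    if (len < min_overlap) next
    qs <- qi:(qi + len - 1L)
    ts <- ti:(ti + len - 1L)
    num <- colSums(qp$c[, qs, drop = FALSE] * tp$c[, ts, drop = FALSE])
    den <- qp$n[qs] * tp$n[ts]
    sc <- sum(ifelse(den > 0, num / den, 0))
    if (sc > best$score) best <- list(score = sc, offset = off)
  }
  best
}

# Best score of a query against a target over both strands. Accepts raw
# PWMs; `query_prep`/`target_prep` allow reuse of precomputed columns.
pwm_best_match <- function(query, target, min_overlap = 4L,
                           query_prep = NULL, target_prep = NULL) {
  qp <- query_prep %||% prep_pwm_cols(query)
  fwd <- pwm_align_score(qp, target_prep %||% prep_pwm_cols(target),
                         min_overlap)
  rev_ <- pwm_align_score(qp, prep_pwm_cols(pwm_revcomp(target)), min_overlap)
  if (fwd$score >= rev_$score) {
    c(fwd, list(strand = "+"))
  } else {
    c(rev_, list(strand = "-"))
  }
}

#' Match a k-mer against a PWM database
#'
#' Encodes the k-mer as a probability matrix ([kmer_to_pwm()]) and aligns
#' it (ungapped, both strands, at least `min_overlap` overlapping columns)
#' against every database motif, scoring each offset by the sum of
#' per-column Pearson correlations (so longer agreement outranks a chance
#' short overlap). Match p-values come from a seeded Monte Carlo null:
#' scores of the same k-mer against column-order-shuffled database motifs.
#'
#' @param kmer DNA string of length >= 4.
#' @param motifs Motif tibble from [read_meme()].
#' @param p_cut Report matches with `p < p_cut` (default 0.01).
#' @param n_null Monte Carlo null draws (default 1000).
#' @param seed Integer seed for the null.
#' @param min_overlap Minimum aligned columns (default 4).
#' @return A tibble of matches, best first: `kmer`, `motif_id`, `offset`
#'   (k-mer start relative to motif start), `strand`, `score`, `p`.
#' @export
match_kmer_to_motifs <- function(kmer, motifs, p_cut = 0.01, n_null = 1000L,
                                 seed = 1L, min_overlap = 4L) {
  if (nchar(kmer) < 4) abort("kmer must be at least 4 bp")
  if (!nrow(motifs)) abort("empty motif set")
  query <- kmer_to_pwm(kmer)
  qp <- prep_pwm_cols(query)
  obs <- purrr::map(motifs$pwm, function(tgt) {
    pwm_best_match(query, tgt, min_overlap, query_prep = qp)
  })
  null_scores <- withr::with_seed(derive_seed(seed, kmer), {
    vapply(seq_len(n_null), function(b) {
      tgt <- motifs$pwm[[((b - 1L) %% nrow(motifs)) + 1L]]
      shuf <- tgt[, sample.int(ncol(tgt)), drop = FALSE]
      pwm_best_match(query, shuf, min_overlap, query_prep = qp)$score
    }, numeric(1))
  })
  res <- tibble(
    kmer = kmer,
    motif_id = motifs$motif_id,
    offset = purrr::map_int(obs, ~ as.integer(.x$offset)),
    strand = purrr::map_chr(obs, "strand"),
    score = purrr::map_dbl(obs, "score"),
    p = purrr::map_dbl(obs, ~ (1 + sum(null_scores >= .x$score - 1e-12)) /
                         (n_null + 1))
  )
  res %>%
    filter(.data$p < p_cut) %>%
    arrange(.data$p, dplyr::desc(.data$score))
}

#' Refine a significant k-mer to its minimal motif-matching core
#'
#' Seeks the smallest k-mer that still optimises the motif match: greedily
#' deletes one terminal base at a time (trying both ends each round) and
#' keeps a deletion if and only if the best database match does not worsen
#' on the lexicographic objective (match p-value, then alignment score).
#' Uninformative flanking bases leave both p and score unchanged and are
#' trimmed; deleting into the motif core drops the score and stops the
#' search. Ties between the two ends prefer the left deletion. Stops at
#' `min_len`; the output is never longer than the input.
#'
#' @param kmer Significant k-mer to refine.
#' @param motifs Motif tibble from [read_meme()].
#' @param min_len Shortest k-mer considered (default 6).
#' @param ... Passed to [match_kmer_to_motifs()] (`n_null`, `seed`, ...).
#' @return A list with `kmer` (the refined k-mer) and `match` (its best
#'   match row, or an empty tibble when nothing matches).
#' @export
refine_kmer <- function(kmer, motifs, min_len = 6L, ...) {
  best_obj <- function(k) {
    m <- match_kmer_to_motifs(k, motifs, p_cut = 1 + 1e-9, ...)
    if (nrow(m)) list(p = m$p[1], score = m$score[1]) else list(p = 1, score = -Inf)
  }
  no_worse <- function(cand, cur) {
    cand$p < cur$p - 1e-12 ||
      (cand$p <= cur$p + 1e-12 && cand$score >= cur$score - 1e-9)
  }
  current <- kmer
  cur <- best_obj(current)
  while (nchar(current) > min_len) {
    left <- substr(current, 2L, nchar(current))
    right <- substr(current, 1L, nchar(current) - 1L)
    obj_l <- best_obj(left)
    obj_r <- best_obj(right)
    if (no_worse(obj_l, cur) &&
        (obj_l$p < obj_r$p + 1e-12 || !no_worse(obj_r, cur))) {
      current <- left
      cur <- obj_l
    } else if (no_worse(obj_r, cur)) {
      current <- right
      cur <- obj_r
    } else {
      break
    }
  }
  match <- match_kmer_to_motifs(current, motifs, p_cut = 1 + 1e-9, ...)
  list(kmer = current, match = utils::head(match, 1))
}

#' Keep motif matches whose TF is expressed in the assayed cell type
#'
#' Cross-references matched motifs against an expression table (e.g.
#' neuronal RNA-seq) through a motif-to-gene mapping. Matches whose TF
#' falls below `min_expression` are dropped; motifs with no gene mapping
#' are retained but flagged, since absence of a mapping is not evidence of
#' absence of expression.
#'
#' @param matches Match tibble from [match_kmer_to_motifs()].
#' @param expression A tibble with columns `gene`, `expression`.
#' @param mapping A tibble with columns `motif_id`, `gene`.
#' @param min_expression Minimum expression to retain a mapped match.
#' @return The matches with `gene`, `expression`, `expressed` and
#'   `unmapped` columns; mapped-and-unexpressed rows removed.
#' @export
filter_expressed <- function(matches, expression, mapping,
                             min_expression = 1) {
  out <- matches %>%
    left_join(as_tibble(mapping), by = "motif_id") %>%
    left_join(as_tibble(expression), by = "gene") %>%
    mutate(
      unmapped = is.na(.data$gene),
      expressed = !is.na(.data$expression) & .data$expression >= min_expression
    ) %>%
    filter(.data$unmapped | .data$expressed)
  out
}
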