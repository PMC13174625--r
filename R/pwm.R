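#' Exact PWM score null distribution
#'
#' Converts a probability PWM to integer-binned log-odds scores against an
#' iid uniform background and computes, by dynamic programming (column-wise
#' convolution), the exact null distribution of the total score of a random
#' word. The tail probabilities are the exact p-values used by
#' [scan_motifs()]: the probability that a random width-w word scores at
#' least as high as an observed site.
#'
#' Scores are `log2((p + pseudocount * bg) / (1 + pseudocount) / bg)` in
#' bits, discretised into `bin`-bit integer bins; the DP is exact for the
#' binned scores, so discretisation is the only approximation.
#'
#' @param pwm A 4 x width probability matrix (rows A, C, G, T).
#' @param pseudocount Pseudocount mass distributed by the background before
#'   taking log-odds (default 0.1).
#' @param bin Score discretisation in bits (default 0.001).
#' @param background Background base probability (uniform, default 0.25).
#' @return An object of class `pwm_dist` with the integer score matrix, the
#'   minimal/maximal total scores and the exact tail distribution.
#' @export
pwm_score_dist <- function(pwm, pseudocount = 0.1, bin = 0.001,
                           background = 0.25) {
  validate_pwm(pwm)
  lod <- log2((pwm + pseudocount * background) / (1 + pseudocount) / background)
  int_scores <- round(lod / bin)
  storage.mode(int_scores) <- "integer"
  w <- ncol(int_scores)
  col_min <- apply(int_scores, 2, min)
  min_total <- sum(col_min)
  pmf <- 1
  for (j in seq_len(w)) {
    rel <- int_scores[, j] - col_min[j]
    new <- numeric(length(pmf) + max(rel))
    for (b in 1:4) {
      idx <- seq_along(pmf) + rel[b]
      new[idx] <- new[idx] + pmf * background
    }
    pmf <- new
  }
  tail <- rev(cumsum(rev(pmf)))
  tail <- pmin(tail, 1)
  structure(
    list(int_scores = int_scores, width = w, bin = bin,
         min_total = min_total, max_total = min_total + length(pmf) - 1L,
         tail = tail),
    class = "pwm_dist"
  )
}

#' @rdname pwm_score_dist
#' @param dist A `pwm_dist` object.
#' @param int_total Integer total scores (in `bin` units).
#' @return `pwm_tail_p()`: exact p-values `P(score >= int_total)`.
#' @export
pwm_tail_p <- function(dist, int_total) {
  i <- pmax(int_total, dist$min_total) - dist$min_total + 1
  p <- rep(1, length(int_total))
  inside <- int_total <= dist$max_total
  p[inside] <- dist$tail[i[inside]]
  p[int_total > dist$max_total] <- 0
  p
}

#' @rdname pwm_score_dist
#' @param word A DNA word of the motif's width.
#' @return `pwm_score_word()`: a list with the integer score, the score in
#'   bits, and the exact p-value of the word.
#' @export
pwm_score_word <- function(dist, word) {
  e <- encode_dna(word)
  if (length(e) != dist$width || anyNA(e)) {
    abort("word must be an ACGT string of the motif width")
  }
  s <- sum(dist$int_scores[cbind(e, seq_len(dist$width))])
  list(int_score = s, bits = s * dist$bin, p = pwm_tail_p(dist, s))
}

# Smallest integer total score whose exact tail p-value is <= p_threshold,
# or NA when no achievable score reaches it (e.g. a uniform PWM).
pwm_score_threshold <- function(dist, p_threshold) {
  ok <- which(dist$tail <= p_threshold)
  if (!length(ok)) return(NA_integer_)
  dist$min_total + ok[1] - 1L
}

#' FIMO-style PWM scan of library tiles
#'
#' Scores every position of every tile on both strands with log-odds PWM
#' scores and reports sites whose exact p-value (the probability that a
#' random word of the motif's width scores at least as high, under an iid
#' uniform background; see [pwm_score_dist()]) is at most `p_threshold`.
#' Hit intervals are half-open `[start, end)` in CRE offsets.
#'
#' @param tiles A tile tibble from [tile_cre()] (columns `cre`,
#'   `tile_index`, `offset_start`, `sequence`).
#' @param motifs A motif tibble from [read_meme()].
#' @param p_threshold Exact p-value threshold for reporting a site
#'   (default 1e-4, the common scan default).
#' @param pseudocount,bin Passed to [pwm_score_dist()].
#' @return A tibble of motif hits: `cre`, `tile_index`, `motif_id`,
#'   `start`, `end`, `strand`, `score` (bits), `p`.
#' @export
scan_motifs <- function(tiles, motifs, p_threshold = 1e-4,
                        pseudocount = 0.1, bin = 0.001) {
  tiles <- as_tibble(tiles)
  check_dna(tiles$sequence, allow_n = FALSE, what = "tile sequence")
  if (any(motifs$width > min(nchar(tiles$sequence)))) {
    abort("a motif is wider than a tile")
  }
  prepared <- purrr::map(motifs$pwm, pwm_score_dist,
                         pseudocount = pseudocount, bin = bin)
  hits <- purrr::map(seq_len(nrow(tiles)), function(ti) {
    e <- encode_dna(tiles$sequence[ti])
    L <- length(e)
    per_motif <- purrr::map(seq_along(prepared), function(mi) {
      dist <- prepared[[mi]]
      thr <- pwm_score_threshold(dist, p_threshold)
      if (is.na(thr)) return(NULL)
      w <- dist$width
      S <- dist$int_scores
      # reverse-complement scoring matrix: complement bases, reverse columns
      S_rc <- S[4:1, w:1, drop = FALSE]
      nc <- L - w + 1
      fwd <- integer(nc)
      rev_ <- integer(nc)
      for (j in seq_len(w)) {
        idx <- e[j:(j + nc - 1)]
        fwd <- fwd + unname(S[idx, j])
        rev_ <- rev_ + unname(S_rc[idx, j])
      }
      rows <- list()
      for (strand in c("+", "-")) {
        sc <- if (strand == "+") fwd else rev_
        hit_at <- which(sc >= thr)
        if (!length(hit_at)) next
        rows[[strand]] <- tibble(
          cre = tiles$cre[ti], tile_index = tiles$tile_index[ti],
          motif_id = motifs$motif_id[mi],
          start = tiles$offset_start[ti] + hit_at - 1L,
          end = tiles$offset_start[ti] + hit_at - 1L + w,
          strand = strand,
          score = sc[hit_at] * dist$bin,
          p = pwm_tail_p(dist, sc[hit_at])
        )
      }
      bind_rows(rows)
    })
    bind_rows(per_motif)
  })
  out <- bind_rows(hits)
  if (!nrow(out)) {
    out <- tibble(cre = character(), tile_index = integer(),
                  motif_id = character(), start = integer(), end = integer(),
                  strand = character(), score = numeric(), p = numeric())
  }
  out
}
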