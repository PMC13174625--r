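#' Per-element, per-replicate reporter activity
#'
#' Collapses a barcode count table to one activity value per (element,
#' replicate): the depth-normalised log2 RNA/DNA ratio
#' `log2(((sum RNA + 1) / R_tot) / ((sum DNA + 1) / D_tot))`, where the
#' totals are replicate-wide. Elements represented by fewer than
#' `min_barcodes` unique barcodes in a replicate are dropped from that
#' replicate.
#'
#' @param counts Barcode count tibble (`replicate`, `element_id`,
#'   `barcode`, `dna_count`, `rna_count`); see [read_counts()].
#' @param min_barcodes Minimum unique barcodes per element per replicate
#'   (default 10).
#' @return A tibble with columns `element_id`, `replicate`, `activity`
#'   (log2 units) and `n_barcodes`.
#' @export
compute_activity <- function(counts, min_barcodes = 10L) {
  counts <- validate_counts(counts)
  totals <- counts %>%
    group_by(.data$replicate) %>%
    summarise(d_tot = sum(.data$dna_count), r_tot = sum(.data$rna_count),
              .groups = "drop")
  if (any(totals$d_tot == 0)) {
    abort(sprintf("replicate '%s' has zero total DNA counts",
                  totals$replicate[totals$d_tot == 0][1]))
  }
  counts %>%
    group_by(.data$replicate, .data$element_id) %>%
    summarise(
      n_barcodes = n_distinct(.data$barcode),
      dna_sum = sum(.data$dna_count),
      rna_sum = sum(.data$rna_count),
      .groups = "drop"
    ) %>%
    filter(.data$n_barcodes >= min_barcodes) %>%
    left_join(totals, by = "replicate") %>%
    mutate(activity = log2(((.data$rna_sum + 1) / .data$r_tot) /
                             ((.data$dna_sum + 1) / .data$d_tot))) %>%
    select("element_id", "replicate", "activity", "n_barcodes")
}

# Monte Carlo sample of max_j |T_j| under the joint Dunnett null for a
# many-to-one design: group i mean difference vs control scaled by the
# pooled error variance (chi-square with `df` degrees of freedom), with the
# correlation induced by the shared control mean.
dunnett_null_maxt <- function(n_ref, n_groups, df, mc_draws = 1e5, seed = 1L) {
  m <- length(n_groups)
  withr::with_seed(seed, {
    z0 <- rnorm(mc_draws, sd = sqrt(1 / n_ref))
    v <- rchisq(mc_draws, df) / df
    maxt <- numeric(mc_draws)
    for (i in seq_len(m)) {
      zi <- rnorm(mc_draws, sd = sqrt(1 / n_groups[i]))
      ti <- abs(zi - z0) / sqrt(v * (1 / n_groups[i] + 1 / n_ref))
      maxt <- pmax(maxt, ti)
    }
    maxt
  })
}

#' Dunnett many-to-one comparisons by seeded Monte Carlo
#'
#' Compares each of `m` treatment groups to a shared control with the
#' one-way-ANOVA pooled error variance, adjusting the two-sided p-values
#' for the family of `m` correlated t statistics:
#' `p_adj_i = P(max_j |T_j| >= |t_i|)` under the joint null, estimated by
#' seeded Monte Carlo. With `m = 1` this reduces to the unadjusted pooled
#' two-sample t test (within Monte Carlo tolerance). Unbalanced group sizes
#' are supported.
#'
#' @param ref Numeric vector of control (reference) values, length >= 2.
#' @param groups A named list of numeric vectors, one per treatment group.
#' @param alpha Familywise significance level for the `direction` call
#'   (default 0.05).
#' @param mc_draws Monte Carlo draws for the null of the max statistic
#'   (default 1e5).
#' @param seed Integer seed for the Monte Carlo draws.
#' @param null_maxt Optional precomputed Monte Carlo sample of
#'   `max_j |T_j|` (from repeated testing of identical designs); when
#'   supplied, `mc_draws`/`seed` are ignored.
#' @return An object of class `dunnett_mc`: a list with a `comparisons`
#'   tibble (`group`, `n`, `mean_effect`, `statistic`, `p_adj`,
#'   `direction`) and the design facts (`n_ref`, `df`, `s2`, `alpha`,
#'   `mc_draws`).
#' @export
dunnett_mc <- function(ref, groups, alpha = 0.05, mc_draws = 1e5, seed = 1L,
                       null_maxt = NULL) {
  if (length(ref) < 2) abort("need >= 2 control replicates")
  if (!length(groups)) abort("need >= 1 comparison group")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes < 1)) abort("empty comparison group")
  all_groups <- c(list(.ref = ref), groups)
  df <- sum(lengths(all_groups) - 1)
  if (df < 1) abort("no residual degrees of freedom")
  ss <- sum(vapply(all_groups,
                   function(g) sum((g - mean(g))^2), numeric(1)))
  s2 <- ss / df
  if (s2 <= 0) {
    abort("pooled within-group variance is zero; Dunnett test is degenerate")
  }
  means <- vapply(groups, mean, numeric(1))
  eff <- means - mean(ref)
  tstat <- eff / sqrt(s2 * (1 / sizes + 1 / length(ref)))
  if (is.null(null_maxt)) {
    null_maxt <- dunnett_null_maxt(length(ref), sizes, df,
                                   mc_draws = mc_draws, seed = seed)
  }
  p_adj <- vapply(abs(tstat), function(t0) mean(null_maxt >= t0), numeric(1))
  comparisons <- tibble(
    group = names(groups),
    n = as.integer(sizes),
    mean_effect = unname(eff),
    statistic = unname(tstat),
    p_adj = unname(p_adj),
    direction = case_when(
      p_adj >= alpha ~ "ns",
      eff > 0 ~ "up",
      TRUE ~ "down"
    )
  )
  structure(
    list(comparisons = comparisons, n_ref = length(ref), df = df, s2 = s2,
         alpha = alpha, mc_draws = length(null_maxt)),
    class = "dunnett_mc"
  )
}

#' @export
print.dunnett_mc <- function(x, ...) {
  cat(sprintf(
    "Dunnett many-to-one Monte Carlo test: %d comparisons, n_ref = %d, df = %d\n",
    nrow(x$comparisons), x$n_ref, x$df))
  print(x$comparisons, ...)
  invisible(x)
}

#' @rdname dunnett_mc
#' @param x A `dunnett_mc` object.
#' @param ... Unused.
#' @export
tidy.dunnett_mc <- function(x, ...) x$comparisons

#' @rdname dunnett_mc
#' @export
glance.dunnett_mc <- function(x, ...) {
  tibble(
    n_comparisons = nrow(x$comparisons), n_ref = x$n_ref, df = x$df,
    s2 = x$s2, alpha = x$alpha, mc_draws = x$mc_draws,
    n_significant = sum(x$comparisons$p_adj < x$alpha)
  )
}

#' Shuffle- and variant-vs-reference effects across the library
#'
#' Runs one Dunnett family per (CRE, tile, element kind): all motif-shuffle
#' elements of a tile are compared to that tile's reference element in one
#' family, and all variant elements of a tile form a separate family
#' (variants are tested apart from shuffles). Elements missing from some
#' replicates enter with reduced n rather than being dropped.
#'
#' Monte Carlo null samples are cached across families sharing the same
#' design (same group sizes and error degrees of freedom), which keeps
#' whole-library testing fast without changing any p-value.
#'
#' @param activities Activity tibble from [compute_activity()].
#' @param manifest Library manifest tibble.
#' @param alpha Familywise significance level (default 0.05).
#' @param mc_draws Monte Carlo draws per null design (default 1e5).
#' @param seed Integer seed.
#' @return An effect tibble of class `mpra_effects`: `element_id`,
#'   `reference_id`, `cre`, `tile_index`, `class`, `mutated_start`,
#'   `mutated_end`, `shuffle_rep`, `unchanged`, `n_replicates`,
#'   `mean_effect`, `statistic`, `p_adj`, `direction`, `significant`.
#' @export
test_shuffle_effects <- function(activities, manifest, alpha = 0.05,
                                 mc_draws = 1e5, seed = 1L) {
  manifest <- as_tibble(manifest)
  act <- left_join(activities,
                   select(manifest, "element_id", "class", "cre",
                          "tile_index"),
                   by = "element_id")
  act <- filter(act, !is.na(.data$class))
  null_cache <- new.env(parent = emptyenv())
  families <- act %>%
    filter(.data$class != "pos_control", .data$class != "neg_control") %>%
    mutate(kind = ifelse(.data$class == "motif_shuffle", "shuffle",
                         ifelse(.data$class == "reference_tile", "ref", "variant"))) %>%
    group_by(.data$cre, .data$tile_index)
  keys <- dplyr::group_keys(families)
  split_fams <- dplyr::group_split(families)
  out <- purrr::map(seq_along(split_fams), function(fi) {
    fam <- split_fams[[fi]]
    ref_vals <- fam$activity[fam$kind == "ref"]
    if (length(ref_vals) < 2) return(NULL)
    ref_id <- fam$element_id[fam$kind == "ref"][1]
    per_kind <- purrr::map(c("shuffle", "variant"), function(kind) {
      sub <- fam[fam$kind == kind, ]
      if (!nrow(sub)) return(NULL)
      groups <- split(sub$activity, sub$element_id)
      groups <- groups[lengths(groups) >= 1]
      cache_key <- paste(length(ref_vals),
                         paste(sort(lengths(groups)), collapse = ","))
      if (is.null(null_cache[[cache_key]])) {
        df <- (length(ref_vals) - 1) + sum(lengths(groups) - 1)
        # seed per design so families with different designs stay independent
        null_cache[[cache_key]] <- dunnett_null_maxt(
          length(ref_vals), lengths(groups), df,
          mc_draws = mc_draws, seed = derive_seed(seed, cache_key))
      }
      fit <- dunnett_mc(ref_vals, groups, alpha = alpha,
                        null_maxt = null_cache[[cache_key]])
      fit$comparisons %>%
        rename(element_id = "group", n_replicates = "n") %>%
        mutate(reference_id = ref_id)
    })
    bind_rows(per_kind)
  }) %>% bind_rows()
  if (!nrow(out)) abort("no testable families (need reference activities in >= 2 replicates)")
  res <- out %>%
    left_join(select(manifest, "element_id", "cre", "tile_index", "class",
                     "mutated_start", "mutated_end", "shuffle_rep",
                     "unchanged"),
              by = "element_id") %>%
    mutate(significant = .data$p_adj < alpha) %>%
    select("element_id", "reference_id", "cre", "tile_index", "class",
           "mutated_start", "mutated_end", "shuffle_rep", "unchanged",
           "n_replicates", "mean_effect", "statistic", "p_adj", "direction",
           "significant")
  class(res) <- c("mpra_effects", class(res))
  res
}

#' Per-mutation effect summary keyed by mutated CRE offsets
#'
#' One row per mutated element (shuffle or variant) carrying its average
#' effect size across replicates, adjusted p-value, direction, and the
#' mutated CRE interval used downstream for binning.
#'
#' @param effects Effect tibble from [test_shuffle_effects()].
#' @param classes Element classes to keep (default motif shuffles).
#' @return A tibble of mutation datapoints (class `mpra_effects`).
#' @export
summarize_effects <- function(effects, classes = "motif_shuffle") {
  out <- effects %>%
    filter(.data$class %in% classes) %>%
    select("element_id", "cre", "tile_index", "class", "mutated_start",
           "mutated_end", "mean_effect", "p_adj", "direction", "significant")
  class(out) <- c("mpra_effects", class(out))
  out
}
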