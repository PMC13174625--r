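# ggplot2 views of the main result types.

#' Plot per-mutation effects along a CRE
#'
#' Each point is one shuffle (or variant) element at the midpoint of its
#' mutated interval; significant effects are coloured by direction
#' (decreased activity marks activator binding, increased marks repressor
#' binding). Hotspot intervals can be overlaid as shaded boxes.
#'
#' @param object An `mpra_effects` tibble from [test_shuffle_effects()] or
#'   [summarize_effects()].
#' @param hotspots Optional `mpra_hotspots` tibble to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mpra_effects <- function(object, hotspots = NULL, ...) {
  df <- as_tibble(object) %>%
    filter(!is.na(.data$mutated_start)) %>%
    mutate(midpoint = (.data$mutated_start + .data$mutated_end) / 2)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$midpoint,
                                        y = .data$mean_effect))
  if (!is.null(hotspots) && nrow(hotspots)) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(hotspots),
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf, fill = .data$class),
      alpha = 0.15, inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$direction), size = 1) +
    ggplot2::scale_colour_manual(
      values = c(down = "#d95f8a", up = "#4c72b0", ns = "grey70")) +
    ggplot2::labs(x = "MPRA position (bp)",
                  y = expression(log[2] ~ "effect vs reference tile"),
                  colour = "direction", fill = "hotspot") +
    ggplot2::theme_minimal()
}

#' Plot binned hotspot statistics
#'
#' Bars give the fraction of shuffle datapoints per 50 bp bin that
#' significantly decrease (activator binding) or increase (repressor
#' binding) activity; bins failing the coverage requirement are greyed.
#'
#' @param object An `mpra_binstats` tibble from [bin_mutations()].
#' @param min_nt Coverage threshold used for shading (default 50).
#' @param frac Fraction threshold drawn as a dashed line (default 0.10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mpra_binstats <- function(object, min_nt = 50L, frac = 0.10, ...) {
  df <- as_tibble(object) %>%
    tidyr::pivot_longer(c("frac_down", "frac_up"), names_to = "side",
                        values_to = "fraction") %>%
    mutate(covered = .data$n_mut_nucleotides >= min_nt,
           side = ifelse(.data$side == "frac_down",
                         "decreased (activator site)",
                         "increased (repressor site)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_start, y = .data$fraction,
                                   fill = .data$side,
                                   alpha = .data$covered)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = frac, linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3),
                                guide = "none") +
    ggplot2::scale_fill_manual(values = c("#d95f8a", "#4c72b0")) +
    ggplot2::labs(x = "bin start (MPRA position, bp)",
                  y = "fraction of significant shuffles", fill = NULL) +
    ggplot2::theme_minimal()
}
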