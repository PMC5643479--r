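# ggplot2 renderings of the three result types: gradient DNA profiles,
# activity heatmaps, and IRMS group comparisons.

#' Line chart of paired gradient DNA profiles
#'
#' Percent-of-gradient DNA against buoyant density for the labeled and
#' control gradients of one experiment, the standard visual check that
#' labeled DNA has shifted toward the dense end of the gradient. Pooling
#' windows, when supplied, are drawn as shaded density ranges.
#'
#' @param labeled,control Normalized fraction profiles.
#' @param scheme Optional [pooling_scheme()] to overlay.
#' @param value `"dna_percent"` (default) or `"copies_percent"`.
#' @return A ggplot object.
#' @export
plot_gradient <- function(labeled, control, scheme = NULL,
                          value = c("dna_percent", "copies_percent")) {
  value <- match.arg(value)
  df <- dplyr::bind_rows(
    mutate(as_tibble(labeled), treatment = "labeled"),
    mutate(as_tibble(control), treatment = "control")
  )
  if (!value %in% names(df)) abort("Profiles must be normalized first.")
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$density_g_ml, y = .data[[value]],
    colour = .data$treatment, shape = .data$treatment
  ))
  if (!is.null(scheme)) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(scheme),
      ggplot2::aes(xmin = .data$low, xmax = .data$high, fill = .data$name),
      ymin = -Inf, ymax = Inf, alpha = 0.15, inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(labeled = "grey50", control = "black")) +
    ggplot2::labs(
      x = "Buoyant density (g/ml)",
      y = if (value == "dna_percent") "% of gradient DNA" else "% of gradient 16S copies",
      colour = NULL, shape = NULL, fill = "pooled fraction"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of taxon activity in dense pooled fractions
#'
#' Tiles colored from blue (underrepresentation) through white to yellow
#' (enrichment), annotated with significance symbols (`**` q < 0.01,
#' `*` q < 0.05, `+` q < 0.1).
#'
#' @param object A `sip_activity` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sip_activity
#' @export
autoplot.sip_activity <- function(object, ...) {
  df <- tidy(object)
  lim <- max(abs(df$A), 1e-9)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pool, y = .data$taxon,
                                   fill = .data$A)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$symbol), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#FFD92F", limits = c(-lim, lim)) +
    ggplot2::labs(x = "dense pooled fraction", y = NULL,
                  fill = "activity A\n(% points)") +
    ggplot2::theme_minimal()
}

#' Bar chart of tissue delta-15N by treatment
#'
#' Group means with SEM error bars per tissue, faceted by life stage;
#' asterisks mark significant 15N vs 14N comparisons.
#'
#' @param object A `sip_irms` tibble from [compare_treatments()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sip_irms
#' @export
autoplot.sip_irms <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(
      cols = c("mean_15N", "mean_14N"),
      names_to = "treatment", values_to = "mean_delta"
    ) |>
    mutate(
      treatment = sub("mean_", "", .data$treatment),
      sem = dplyr::if_else(.data$treatment == "15N", .data$sem_15N, .data$sem_14N)
    )
  stars <- tidy(object) |> filter(.data$significant)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$tissue, y = .data$mean_delta,
                                        fill = .data$treatment)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_delta - .data$sem,
                   ymax = .data$mean_delta + .data$sem),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::facet_wrap(~life_stage) +
    ggplot2::scale_fill_manual(values = c(`14N` = "grey70", `15N` = "grey30")) +
    ggplot2::labs(x = NULL, y = expression(delta^15 * N ~ ("‰")),
                  fill = NULL) +
    ggplot2::theme_minimal()
  if (nrow(stars)) {
    p <- p + ggplot2::geom_text(
      data = mutate(stars, label = "*",
                    y = pmax(.data$mean_15N + .data$sem_15N,
                             .data$mean_14N + .data$sem_14N) * 1.05),
      ggplot2::aes(x = .data$tissue, y = .data$y, label = .data$label),
      inherit.aes = FALSE, size = 6
    )
  }
  p
}

#' Heatmap of KO enrichment in dense labeled pools
#'
#' @param enrichment Result of [ko_enrichment()].
#' @return A ggplot object.
#' @export
plot_ko_heatmap <- function(enrichment) {
  lim <- max(abs(enrichment$enrichment), 1e-9)
  ggplot2::ggplot(enrichment, ggplot2::aes(x = .data$pool, y = .data$ko,
                                           fill = .data$enrichment)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#FFD92F", limits = c(-lim, lim)) +
    ggplot2::labs(x = "dense pooled fraction", y = NULL,
                  fill = "enrichment\n(% points)") +
    ggplot2::theme_minimal()
}
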