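#' Plot geNorm results
#'
#' Bar chart of stepwise M values, genes ordered least to most stable, as the
#' classic geNorm chart is drawn.
#'
#' @param object A `genorm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genorm_fit <- function(object, ...) {
  d <- dplyr::arrange(object$stability, dplyr::desc(.data$rank))
  d$gene <- factor(d$gene, levels = d$gene)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene, y = .data$m)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "geNorm stability M",
                  subtitle = "least stable (left) to most stable (right)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the geNorm pairwise-variation curve
#'
#' V(n/n+1) against n with the decision threshold; the smallest n under the
#' line is the recommended number of reference genes.
#'
#' @param fit A `genorm_fit`.
#' @return A ggplot object.
#' @export
plot_pairwise_variation <- function(fit) {
  stopifnot(inherits(fit, "genorm_fit"))
  ggplot2::ggplot(fit$pairwise_variation, ggplot2::aes(x = .data$n, y = .data$v)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = fit$v_threshold, linetype = "dashed", colour = "red") +
    ggplot2::scale_x_continuous(breaks = fit$pairwise_variation$n,
                                labels = paste0("V", fit$pairwise_variation$n, "/",
                                                fit$pairwise_variation$n + 1)) +
    ggplot2::labs(x = NULL, y = "pairwise variation V") +
    ggplot2::theme_minimal()
}

#' Plot fitted standard curves
#'
#' Ct against log10 relative concentration with the per-primer least-squares
#' line, faceted by primer.
#'
#' @param object A `standard_curve` tibble (needs the original points: pass
#'   them via `points`).
#' @param points The dilution table the curves were fitted from.
#' @param base Fold-step of the series.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.standard_curve <- function(object, points, base = 5, ...) {
  pts <- dplyr::mutate(tibble::as_tibble(points), log_conc = -.data$level * log10(base))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$log_conc, y = .data$ct)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(data = tibble::as_tibble(object),
                         ggplot2::aes(slope = .data$slope, intercept = .data$intercept),
                         colour = "steelblue") +
    ggplot2::facet_wrap(~primer) +
    ggplot2::labs(x = "log10 relative concentration", y = "Ct (cycles)") +
    ggplot2::theme_minimal()
}

#' Plot an expression time course
#'
#' Mean relative quantity with SEM error bars per treatment, significance
#' stars above the points.
#'
#' @param object An `expression_profile`, or the significance-annotated
#'   `rq_profile` tibble from [timepoint_significance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.expression_profile <- function(object, ...) {
  d <- if (inherits(object, "expression_profile")) object$profile else tibble::as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$timepoint, y = .data$rq_mean)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rq_mean - .data$rq_sem,
                                        ymax = .data$rq_mean + .data$rq_sem), width = 0.8) +
    ggplot2::facet_wrap(~treatment, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = expression(2^{-Delta * Delta * C[T]} ~ "relative expression")) +
    ggplot2::theme_minimal()
  if ("stars" %in% names(d)) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$stars,
                                             y = .data$rq_mean + .data$rq_sem),
                                vjust = -0.4, na.rm = TRUE)
  }
  p
}

#' @rdname autoplot.expression_profile
#' @export
autoplot.rq_profile <- function(object, ...) {
  autoplot.expression_profile(tibble::as_tibble(object), ...)
}

#' Plot a consensus ranking
#'
#' Dot plot of per-method ranks with the consensus geometric-mean rank
#' highlighted.
#'
#' @param consensus A `consensus_ranking` from [aggregate_ranks()].
#' @return A ggplot object.
#' @export
plot_consensus <- function(consensus) {
  d <- tibble::as_tibble(consensus)
  long <- tidyr::pivot_longer(d, dplyr::starts_with("rank_"),
                              names_to = "method", values_to = "rank",
                              names_prefix = "rank_")
  ord <- d$gene[order(d$final_rank)]
  long$gene <- factor(long$gene, levels = rev(ord))
  d$gene <- factor(d$gene, levels = rev(ord))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$gene)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$method), alpha = 0.7) +
    ggplot2::geom_point(data = d, ggplot2::aes(x = .data$geomean_rank),
                        shape = 18, size = 3, colour = "black") +
    ggplot2::labs(x = "rank (1 = most stable); diamond = geometric mean",
                  y = NULL, colour = "method") +
    ggplot2::theme_minimal()
}
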