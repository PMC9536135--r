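# ggplot2 views of the fitted objects. Each autoplot() returns a ggplot
# the caller can restyle.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_step
#'   geom_line geom_col scale_fill_gradient2 labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' @describeIn normalize_es NES heatmap (samples x gene sets).
#' @param object The fitted object to plot.
#' @param ... Unused, for generic consistency.
#' @export
autoplot.enrichment_profile <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$sample, y = .data$gene_set,
                           fill = .data$nes)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B") +
    labs(x = NULL, y = NULL, fill = "NES") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @describeIn pca_decompose Sample scores on two components.
#' @param object The fitted object to plot.
#' @param ... Unused, for generic consistency.
#' @param components Which two components to display.
#' @param labels Optional cluster labels to color samples by.
#' @export
autoplot.pca_result <- function(object, components = c(1, 2), labels = NULL, ...) {
  df <- tibble::tibble(sample = rownames(object$scores),
                       x = object$scores[, components[[1]]],
                       y = object$scores[, components[[2]]])
  evr <- 100 * object$explained_variance_ratio[components]
  p <- if (is.null(labels)) {
    ggplot(df, aes(.data$x, .data$y))
  } else {
    df$cluster <- factor(resolve_labels(labels, df$sample))
    ggplot(df, aes(.data$x, .data$y, colour = .data$cluster))
  }
  p + geom_point(size = 2) +
    labs(x = sprintf("PC%d (%.1f%%)", components[[1]], evr[[1]]),
         y = sprintf("PC%d (%.1f%%)", components[[2]], evr[[2]])) +
    theme_minimal()
}

#' @describeIn consensus_cluster PAC against k; the chosen k is marked.
#' @param object The fitted object to plot.
#' @param ... Unused, for generic consistency.
#' @export
autoplot.consensus_result <- function(object, ...) {
  df <- tibble::tibble(k = object$k_range, pac = unname(object$pac))
  ggplot(df, aes(.data$k, .data$pac)) +
    geom_line() + geom_point() +
    geom_point(data = df[df$k == object$chosen_k, ], colour = "#B2182B",
               size = 3) +
    labs(x = "k", y = "PAC (proportion ambiguous)") +
    theme_minimal()
}

#' Consensus-matrix heatmap at one k
#'
#' @param result A `consensus_result`.
#' @param k Which k to display (default the chosen one).
#' @return A ggplot.
#' @export
plot_consensus_matrix <- function(result, k = result$chosen_k) {
  cons <- result$consensus[[paste0("k", k)]]
  ord <- stats::hclust(stats::as.dist(1 - cons), method = "average")$order
  cons <- cons[ord, ord]
  df <- tibble::as_tibble(as.table(cons), .name_repair = "minimal") |>
    stats::setNames(c("sample1", "sample2", "consensus"))
  df$sample1 <- factor(df$sample1, levels = rownames(cons))
  df$sample2 <- factor(df$sample2, levels = rownames(cons))
  ggplot(df, aes(.data$sample1, .data$sample2, fill = .data$consensus)) +
    geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166AC", limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = sprintf("consensus (k=%d)", k)) +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @describeIn km_curve Step plot of the survival curve.
#' @param object The fitted object to plot.
#' @param ... Unused, for generic consistency.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::bind_rows(tibble::tibble(time = 0, survival = 1), object$steps)
  ggplot(df, aes(.data$time, .data$survival)) +
    geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    labs(x = "time", y = "S(t)") +
    theme_minimal()
}

#' Kaplan-Meier curves for all groups of a survival table
#'
#' @param table Survival tibble with a `group` column (or `labels`).
#' @param labels Optional labels overriding `table$group`.
#' @return A ggplot with one step curve per group.
#' @export
plot_km <- function(table, labels = NULL) {
  table <- as_survival_table(table)
  if (!is.null(labels)) table$group <- resolve_labels(labels, table$sample)
  groups <- sort(unique(table$group))
  df <- purrr::map_dfr(groups, function(g) {
    km <- km_curve(table, group = g)
    dplyr::bind_rows(tibble::tibble(time = 0, survival = 1), km$steps) |>
      dplyr::mutate(group = factor(g))
  })
  ggplot(df, aes(.data$time, .data$survival, colour = .data$group)) +
    geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    labs(x = "time", y = "S(t)", colour = "cluster") +
    theme_minimal()
}

#' @describeIn correlation_map Dual-diagonal correlation heatmap: the lower
#'   triangle is blanked where the raw p is not significant, the upper
#'   triangle where the FDR-adjusted p is not.
#' @param object The fitted object to plot.
#' @param ... Unused, for generic consistency.
#' @export
autoplot.correlation_map <- function(object, ...) {
  ord <- object$hclust$order
  r <- object$r[ord, ord]
  sig <- object$sig_raw[ord, ord]
  sig[upper.tri(sig)] <- object$sig_adj[ord, ord][upper.tri(sig)]
  df <- tibble::as_tibble(as.table(r), .name_repair = "minimal") |>
    stats::setNames(c("signature1", "signature2", "r"))
  df$significant <- as.vector(sig)
  df$signature1 <- factor(df$signature1, levels = rownames(r))
  df$signature2 <- factor(df$signature2, levels = rownames(r))
  ggplot(df, aes(.data$signature1, .data$signature2)) +
    geom_tile(aes(fill = .data$r)) +
    geom_point(data = df[!is.na(df$significant) & !df$significant, ],
               shape = 4, size = 2) +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                         limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "r",
         caption = "lower triangle: raw p; upper: FDR-adjusted (x = not significant)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}

#' @describeIn lda_frequency Log fraction of negative wells against dose
#'   with the fitted single-hit line.
#' @param object The fitted object to plot.
#' @param ... Unused, for generic consistency.
#' @export
autoplot.lda_result <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot(df, aes(.data$dose, log(.data$fraction_negative))) +
    geom_point() +
    labs(x = "cells per well", y = "log fraction negative wells") +
    theme_minimal()
  if (!object$boundary) {
    p <- p + ggplot2::geom_abline(slope = -object$frequency, intercept = 0,
                                  linetype = 2)
  }
  p
}

#' @describeIn detect_modules Module eigengene heatmap across samples.
#' @param object The fitted object to plot.
#' @param ... Unused, for generic consistency.
#' @export
autoplot.module_set <- function(object, ...) {
  df <- tibble::as_tibble(as.table(object$eigengenes), .name_repair = "minimal") |>
    stats::setNames(c("sample", "module", "eigengene"))
  ggplot(df, aes(.data$sample, .data$module, fill = .data$eigengene)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B") +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
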