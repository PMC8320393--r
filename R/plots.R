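#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_tile geom_col
#'   geom_boxplot geom_hline facet_wrap labs scale_fill_gradient2 autoplot
#'   theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Elbow plot of the within-cluster sum of squares
#'
#' @param object An [elbow_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot elbow_curve
#' @export
autoplot.elbow_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$k, y = .data$tot_withinss)) +
    geom_line() + geom_point() +
    labs(x = "number of clusters k", y = "total within-cluster SS",
         title = "Elbow curve") +
    theme_minimal()
}

#' Silhouette plot of a clustering solution
#'
#' Per-point silhouette widths, grouped and sorted within cluster; the
#' average width is the cluster-integrity summary.
#'
#' @param object A `cluster_solution` (with `k >= 2`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cluster_solution
#' @export
autoplot.cluster_solution <- function(object, ...) {
  if (is.null(object$silhouette)) abort("no silhouette widths (k < 2)")
  df <- object$silhouette |>
    arrange(.data$cluster, desc(.data$width)) |>
    mutate(pos = row_number())
  ggplot(df, aes(x = .data$pos, y = .data$width,
                 fill = factor(.data$cluster))) +
    geom_col(width = 1) +
    geom_hline(yintercept = attr(object$silhouette, "average"),
               linetype = "dashed") +
    labs(x = NULL, y = "silhouette width", fill = "cluster",
         title = sprintf("Average silhouette width %.2f",
                         object$avg_silhouette)) +
    theme_minimal()
}

#' Coded-level map of a design
#'
#' @param design A `dsd_design` tibble.
#' @return A ggplot tile map of runs by components.
#' @export
plot_design <- function(design) {
  ids <- design_factors(design)
  df <- design |>
    tidyr::pivot_longer(dplyr::all_of(ids), names_to = "factor_id",
                        values_to = "level")
  ggplot(df, aes(x = .data$factor_id, y = .data$run_id,
                 fill = .data$level)) +
    geom_tile(color = "grey80") +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         na.value = "grey60") +
    labs(x = NULL, y = NULL, fill = "coded level") +
    theme_minimal()
}

#' Principal-component projection of the candidate pool
#'
#' Projects the scaled pool onto its first two principal components,
#' coloured by cluster; the caption reports the fraction of variance the
#' two displayed dimensions explain (computed, not assumed).
#'
#' @param pool The `candidate_pool`.
#' @param solution The matching `cluster_solution`.
#' @return A ggplot.
#' @export
plot_pool_pca <- function(pool, solution) {
  X <- scale_pool(pool)
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  pc <- stats::prcomp(X[, keep, drop = FALSE], center = FALSE, scale. = FALSE)
  expl <- 100 * sum(pc$sdev[1:2]^2) / sum(pc$sdev^2)
  df <- tibble(PC1 = pc$x[, 1], PC2 = pc$x[, 2],
               cluster = factor(solution$assignments))
  ggplot(df, aes(x = .data$PC1, y = .data$PC2, color = .data$cluster)) +
    geom_point(alpha = 0.7) +
    labs(title = "Candidate pool, first two principal components",
         caption = sprintf("PC1 + PC2 explain %.1f%% of the variance", expl)) +
    theme_minimal()
}

#' Component distributions of the cluster medium formulations
#'
#' Member formulations per cluster and component, with the component-wise
#' median (the cluster medium formulation) marked.
#'
#' @param pool The `candidate_pool`.
#' @param solution The `cluster_solution`.
#' @return A ggplot.
#' @export
plot_cluster_media <- function(pool, solution) {
  ids <- design_factors(pool)
  df <- as_tibble(pool)[, ids]
  df$cluster <- factor(solution$assignments)
  long <- tidyr::pivot_longer(df, dplyr::all_of(ids),
                              names_to = "component", values_to = "level")
  ggplot(long, aes(x = .data$component, y = .data$level)) +
    geom_boxplot(outlier.size = 0.4) +
    facet_wrap(~cluster) +
    labs(x = NULL, y = "coded level",
         title = "Cluster medium formulations (component-wise medians)") +
    theme_minimal()
}
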