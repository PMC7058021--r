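# ggplot2 views of the main result types. These are convenience displays;
# every number they show comes from the tidied result tibbles.

#' Plot per-gene statistics of a dataset fit
#'
#' Heterogeneity change (rho) against expression change (beta1), colored by
#' heterogeneity significance.
#'
#' @param object A `dataset_change` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dataset_change
#' @export
autoplot.dataset_change <- function(object, ...) {
  tab <- tidy(object)
  ggplot(tab, aes(x = .data$beta1, y = .data$rho,
                  color = .data$q_rho < 0.05)) +
    geom_point(alpha = 0.5, size = 0.8) +
    geom_hline(yintercept = 0, linetype = "dashed") +
    scale_color_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick"),
                       name = "q_rho < 0.05") +
    labs(x = "expression change (beta1)",
         y = "heterogeneity change (rho)",
         title = sprintf("%s [%s]", object$dataset, object$period)) +
    theme_minimal()
}

#' Plot observed vs expected consistency counts
#'
#' Observed number of genes at each cross-dataset consistency level against
#' the permutation null (mean and 2.5-97.5% band).
#'
#' @param object A `consistency_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot consistency_table
#' @export
autoplot.consistency_table <- function(object, ...) {
  lv <- object$levels
  qs <- apply(object$null_counts, 2L, quantile, probs = c(0.025, 0.975))
  lv$lo <- qs[1, -1]
  lv$hi <- qs[2, -1]
  ggplot(lv, aes(x = .data$n_datasets)) +
    geom_ribbon(aes(ymin = .data$lo, ymax = .data$hi), fill = "grey80") +
    geom_line(aes(y = .data$expected_mean), color = "grey40") +
    geom_point(aes(y = .data$observed), color = "firebrick") +
    labs(x = sprintf("datasets with heterogeneity %s", object$direction),
         y = "number of genes",
         title = "observed (points) vs permutation-expected (band)") +
    theme_minimal()
}

#' Plot cluster-mean heterogeneity trajectories
#'
#' @param object A `trajectory_clusters` object.
#' @param ... Unused.
#' @return A ggplot, one facet per cluster, one line per dataset.
#' @method autoplot trajectory_clusters
#' @export
autoplot.trajectory_clusters <- function(object, ...) {
  ggplot(object$cluster_means,
         aes(x = .data$age_years, y = .data$mean_scaled_heterogeneity,
             group = .data$dataset)) +
    geom_line(alpha = 0.5) +
    facet_wrap(~cluster) +
    labs(x = "age (years)", y = "mean scaled heterogeneity") +
    theme_minimal()
}

#' Plot dataset positions on PC1-PC2
#'
#' @param object A `pca_dispersion` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pca_dispersion
#' @export
autoplot.pca_dispersion <- function(object, ...) {
  ggplot(object$coords, aes(x = .data$PC1, y = .data$PC2,
                            color = .data$period)) +
    geom_point(size = 2) +
    labs(x = sprintf("PC1 (%.0f%%)", 100 * object$var_explained[1]),
         y = sprintf("PC2 (%.0f%%)", 100 * object$var_explained[2])) +
    theme_minimal()
}
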