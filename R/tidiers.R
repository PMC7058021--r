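# broom-style tidiers for the package's result objects.

#' Tidy a per-dataset change fit
#'
#' @param x A `dataset_change` object.
#' @param ... Unused.
#' @return The per-gene tibble (`gene_id`, `beta1`, `p_beta`, `q_beta`,
#'   `rho`, `p_rho`, `q_rho`, ...), with `dataset` and `period` columns
#'   prepended.
#' @method tidy dataset_change
#' @export
tidy.dataset_change <- function(x, ...) {
  mutate(x$table, dataset = x$dataset, period = x$period, .before = 1)
}

#' @rdname tidy.dataset_change
#' @method glance dataset_change
#' @export
glance.dataset_change <- function(x, ...) {
  tibble(dataset = x$dataset, period = x$period,
         n_genes = nrow(x$table), n_samples = ncol(x$residuals),
         median_beta1 = median(x$table$beta1),
         median_rho = median(x$table$rho),
         n_sig_beta = sum(x$table$q_beta < 0.05),
         n_sig_rho = sum(x$table$q_rho < 0.05))
}

#' Tidy a consistency table
#'
#' @param x A `consistency_table`.
#' @param ... Unused.
#' @return Per-gene tibble (`gene_id`, `n_up`).
#' @method tidy consistency_table
#' @export
tidy.consistency_table <- function(x, ...) x$genes

#' @rdname tidy.consistency_table
#' @method glance consistency_table
#' @export
glance.consistency_table <- function(x, ...) {
  top <- x$levels[x$n_datasets, ]
  tibble(n_datasets = x$n_datasets, direction = x$direction,
         n_fully_consistent = top$observed,
         expected_fully_consistent = top$expected_mean,
         p_fully_consistent = top$p)
}

#' Tidy trajectory clusters
#'
#' @param x A `trajectory_clusters` object.
#' @param ... Unused.
#' @return Tibble of gene -> cluster assignments.
#' @method tidy trajectory_clusters
#' @export
tidy.trajectory_clusters <- function(x, ...) x$assignments

#' @rdname tidy.trajectory_clusters
#' @method glance trajectory_clusters
#' @export
glance.trajectory_clusters <- function(x, ...) {
  tibble(k = x$k, n_genes = nrow(x$assignments),
         wcss = x$wcss, totss = x$totss, betweenss = x$betweenss)
}

#' Tidy a PCA dispersion summary
#'
#' @param x A `pca_dispersion` object.
#' @param ... Unused.
#' @return Tibble of dataset PC coordinates.
#' @method tidy pca_dispersion
#' @export
tidy.pca_dispersion <- function(x, ...) x$coords

#' @rdname tidy.pca_dispersion
#' @method glance pca_dispersion
#' @export
glance.pca_dispersion <- function(x, ...) {
  pivot_wider(x$dispersion, names_from = "period",
              values_from = "median_distance",
              names_prefix = "median_distance_") |>
    mutate(var_pc1 = x$var_explained[1], var_pc2 = x$var_explained[2])
}
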