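# Heterogeneity trajectory clustering: genes that are consistently
# heterogeneous are grouped by the *shape* of their heterogeneity-vs-age
# profile, pooled across datasets on a common interpolation grid.

#' Smooth and interpolate heterogeneity trajectories
#'
#' Per gene and dataset, the heterogeneity level (absolute residual from the
#' age model) is scaled to mean 0 / sd 1, fit with a cubic smoothing spline
#' at `df` effective degrees of freedom against the transformed age, and
#' evaluated at `n_points` equally spaced transformed ages spanning that
#' dataset's age range. Interpolating every dataset onto the same number of
#' points (11 by default, the smallest dataset size in the motivating
#' design) keeps datasets with different sample sizes equally weighted in
#' the clustering.
#'
#' @param fits Named list of `dataset_change` objects (one period).
#' @param gene_set Character vector of gene ids to include.
#' @param df Effective degrees of freedom of the smoothing spline, default 3.
#' @param n_points Interpolation grid size per dataset, default 11.
#' @return Object of class `trajectory_matrix`: list with `values` (genes x
#'   (datasets * n_points) matrix), `grid` (tibble `dataset`, `point`,
#'   `age_t`, `age_years`), `dropped` (genes removed for constant
#'   heterogeneity), `n_points`.
#' @export
smooth_and_interpolate <- function(fits, gene_set, df = 3, n_points = 11) {
  if (length(gene_set) == 0) stop_agevar("gene_set is empty")
  small <- names(fits)[vapply(fits, function(f) ncol(f$residuals) < n_points,
                              logical(1))]
  if (length(small) > 0) {
    stop_agevar("dataset(s) smaller than the %d-point grid: %s", n_points,
                paste(small, collapse = ", "))
  }
  missing <- setdiff(gene_set, rownames(fits[[1]]$residuals))
  if (length(missing) > 0) {
    stop_agevar("gene(s) absent from fits: %s",
                paste(head(missing, 5), collapse = ", "))
  }
  # drop genes whose heterogeneity is constant in any dataset (spline input
  # would be degenerate after scaling)
  dropped <- character(0)
  for (f in fits) {
    h <- abs(f$residuals[gene_set, , drop = FALSE])
    s <- apply(h, 1L, sd)
    dropped <- union(dropped, gene_set[s == 0])
  }
  if (length(dropped) > 0) {
    rlang::warn(sprintf("dropping %d gene(s) with constant heterogeneity: %s",
                        length(dropped),
                        paste(head(dropped, 5), collapse = ", ")))
    gene_set <- setdiff(gene_set, dropped)
    if (length(gene_set) == 0) stop_agevar("no genes left after dropping")
  }
  blocks <- list()
  grid_rows <- list()
  for (nm in names(fits)) {
    f <- fits[[nm]]
    h <- abs(f$residuals[gene_set, , drop = FALSE])
    hs <- (h - rowMeans(h)) / apply(h, 1L, sd)
    grid <- seq(min(f$age_t), max(f$age_t), length.out = n_points)
    vals <- t(apply(hs, 1L, function(y) {
      ss <- smooth.spline(f$age_t, y, df = df)
      predict(ss, grid)$y
    }))
    colnames(vals) <- sprintf("%s_p%02d", nm, seq_len(n_points))
    blocks[[nm]] <- vals
    grid_rows[[nm]] <- tibble(dataset = nm, point = seq_len(n_points),
                              age_t = grid, age_years = grid^4 / 365)
  }
  structure(list(values = do.call(cbind, blocks),
                 grid = bind_rows(grid_rows),
                 dropped = dropped, n_points = n_points),
            class = "trajectory_matrix")
}

#' @export
print.trajectory_matrix <- function(x, ...) {
  cat(sprintf("<trajectory_matrix> %d genes x %d columns (%d datasets x %d points)\n",
              nrow(x$values), ncol(x$values),
              ncol(x$values) / x$n_points, x$n_points))
  invisible(x)
}

#' Cluster heterogeneity trajectories with k-means
#'
#' Runs k-means on the rows of a [smooth_and_interpolate()] matrix with
#' multiple restarts (best within-cluster sum of squares kept), under a
#' fixed seed so assignments are reproducible.
#'
#' @param traj A `trajectory_matrix`.
#' @param k Number of clusters, default 8.
#' @param seed Integer seed.
#' @param n_init Number of random restarts, default 10.
#' @return Object of class `trajectory_clusters`: list with `assignments`
#'   (tibble `gene_id`, `cluster`), `centers`, `wcss`, `totss`,
#'   `cluster_means` (tibble `cluster`, `dataset`, `point`, `age_years`,
#'   `mean_scaled_heterogeneity`), `k`.
#' @export
cluster_trajectories <- function(traj, k = 8, seed = 1L, n_init = 10) {
  stopifnot(inherits(traj, "trajectory_matrix"))
  if (k > nrow(traj$values)) {
    stop_agevar("k = %d exceeds the number of genes (%d)", k, nrow(traj$values))
  }
  km <- with_seed(seed, kmeans(traj$values, centers = k, nstart = n_init,
                               iter.max = 100))
  assignments <- tibble(gene_id = rownames(traj$values),
                        cluster = as.integer(km$cluster))
  centers_long <- as_tibble(km$centers) |>
    mutate(cluster = seq_len(k)) |>
    pivot_longer(-"cluster", names_to = "column",
                 values_to = "mean_scaled_heterogeneity") |>
    mutate(dataset = sub("_p\\d+$", "", .data$column),
           point = as.integer(sub("^.*_p", "", .data$column))) |>
    left_join(traj$grid, by = c("dataset", "point")) |>
    select("cluster", "dataset", "point", "age_years",
           "mean_scaled_heterogeneity")
  structure(list(assignments = assignments, centers = km$centers,
                 wcss = km$tot.withinss, totss = km$totss,
                 betweenss = km$betweenss,
                 cluster_means = centers_long, k = k),
            class = "trajectory_clusters")
}

#' @export
print.trajectory_clusters <- function(x, ...) {
  cat(sprintf("<trajectory_clusters> k = %d, %d genes, WCSS/TSS = %.3f\n",
              x$k, nrow(x$assignments), x$wcss / x$totss))
  print(table(x$assignments$cluster))
  invisible(x)
}
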