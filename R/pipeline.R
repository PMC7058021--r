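# End-to-end orchestration: preprocess -> per-dataset fits -> permutation
# consistency -> trajectory clustering -> enrichment, with a manifest that
# records seed and parameters so a run is reproducible from its config.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the defaults used
#' throughout the package: 20-year period cutoff, fourth-root age scale,
#' 1,000 individual-level age permutations, k = 8 trajectory clusters on
#' 3-df splines interpolated at 11 points, gene-set sizes 5-500 (10-500 for
#' regulator target sets).
#'
#' @param input_dir Directory of `*_expr.tsv` / `*_meta.tsv` pairs (see
#'   [read_collection()]), or `NULL` to simulate.
#' @param simulation A [sim_config()] (used when `input_dir` is `NULL`).
#' @param out_dir Output directory.
#' @param seed Global seed; all stage seeds derive from it.
#' @param n_perm Number of age permutations (>= 100).
#' @param age_cutoff_years,age_scale Period boundary and age transform.
#' @param k_clusters,spline_df,interpolation_points Trajectory clustering
#'   parameters.
#' @param gsea_bounds,regulator_bounds Length-2 integer set-size bounds.
#' @param gmt_path Optional GMT file for the enrichment stage.
#' @param quantile_norm,scale Logical switches for the preprocessing steps.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, simulation = NULL,
                            out_dir = tempfile("agevar_run_"),
                            seed = 1L, n_perm = 1000L,
                            age_cutoff_years = 20, age_scale = "fourth_root",
                            k_clusters = 8L, spline_df = 3,
                            interpolation_points = 11L,
                            gsea_bounds = c(5L, 500L),
                            regulator_bounds = c(10L, 500L),
                            gmt_path = NULL,
                            quantile_norm = TRUE, scale = TRUE) {
  if (n_perm < 100) stop_agevar("n_perm must be >= 100 (got %d)", n_perm)
  if (is.null(input_dir) && is.null(simulation)) {
    stop_agevar("provide input_dir or a simulation config")
  }
  structure(list(input_dir = input_dir, simulation = simulation,
                 out_dir = out_dir, seed = as.integer(seed),
                 n_perm = as.integer(n_perm),
                 age_cutoff_years = age_cutoff_years, age_scale = age_scale,
                 k_clusters = as.integer(k_clusters), spline_df = spline_df,
                 interpolation_points = as.integer(interpolation_points),
                 gsea_bounds = as.integer(gsea_bounds),
                 regulator_bounds = as.integer(regulator_bounds),
                 gmt_path = gmt_path, quantile_norm = isTRUE(quantile_norm),
                 scale = isTRUE(scale)),
            class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [pipeline_config()] arguments; a `simulation` block
#' maps to [sim_config()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) {
    y$simulation <- do.call(sim_config, y$simulation)
  }
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Stages: load or simulate the collection; preprocess (quantile
#' normalization, gene scaling, common-gene intersection); split into
#' development and aging; fit the per-gene change models per dataset and
#' period; build the individual-level permutation set; cross-dataset
#' consistency analysis (both periods) and period-difference tests;
#' trajectory clustering of the fully consistent aging genes; optional
#' preranked enrichment on the consistency counts. All tabular outputs are
#' written as TSV, summaries and the manifest as JSON; re-running with the
#' same config and seed reproduces the statistical outputs exactly.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results (`collection`,
#'   `fits`, `consistency`, `period_tests`, `clusters`, `gsea`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "load"
  result <- tryCatch({
    log_info <- function(fmt, ...) message(sprintf(paste0("[agevar] ", fmt), ...))

    collection <- if (!is.null(config$input_dir)) {
      read_collection(config$input_dir)
    } else {
      simulate_collection(config$simulation)
    }
    log_info("loaded %d datasets (%d genes, %d total samples)",
             length(collection), nrow(collection[[1]]$expr),
             sum(vapply(collection, function(d) ncol(d$expr), numeric(1))))

    stage <- "preprocess"
    collection <- intersect_common_genes(collection)
    pre <- lapply(collection, function(d) {
      if (config$quantile_norm) d$expr <- quantile_normalize(d$expr)
      if (length(unique(d$meta$batch)) > 1 && all(nzchar(d$meta$batch))) {
        d$expr <- batch_mean_restore(d$expr, d$meta$batch)
      }
      if (config$scale) d$expr <- scale_genes(d$expr)
      d
    })
    collection <- study_collection(pre)

    stage <- "split_periods"
    periods <- split_collection_periods(collection, config$age_cutoff_years)
    log_info("development: %d datasets; aging: %d datasets",
             length(periods$development), length(periods$aging))

    stage <- "fit"
    fits <- lapply(periods, fit_collection_changes, age_scale = config$age_scale)
    for (p in names(fits)) {
      write_change_tables(fits[[p]], file.path(config$out_dir, "changes"))
    }

    stage <- "permutations"
    perm_set <- permute_individual_ages(collection, config$n_perm,
                                        derive_seed(config$seed, "perm"))

    stage <- "consistency"
    consistency <- lapply(fits, heterogeneity_consistency, perm_set = perm_set)
    cons_tab <- full_join(
      rename(consistency$aging$genes, n_up_aging = "n_up"),
      rename(consistency$development$genes, n_up_development = "n_up"),
      by = "gene_id")
    readr::write_tsv(cons_tab,
                     file.path(config$out_dir, "consistency_counts.tsv"),
                     progress = FALSE)
    for (p in names(consistency)) {
      readr::write_tsv(consistency[[p]]$levels,
                       file.path(config$out_dir,
                                 sprintf("consistency_levels_%s.tsv", p)),
                       progress = FALSE)
    }

    stage <- "period_tests"
    period_tests <- lapply(
      c(median_rho_diff = "median_rho_diff",
        median_correlation_diff = "median_correlation_diff"),
      function(st) {
        r <- period_difference_test(fits$development, fits$aging, perm_set,
                                    statistic = st)
        r[c("statistic", "observed", "p")]
      })
    jsonlite::write_json(
      list(seed = config$seed, n_perm = config$n_perm, tests = period_tests),
      file.path(config$out_dir, "period_tests.json"),
      auto_unbox = TRUE, digits = NA)

    stage <- "trajectories"
    K <- consistency$aging$n_datasets
    consistent_genes <- consistency$aging$genes |>
      filter(.data$n_up == K) |>
      pull("gene_id")
    clusters <- NULL
    if (length(consistent_genes) >= config$k_clusters) {
      traj <- smooth_and_interpolate(fits$aging, consistent_genes,
                                     df = config$spline_df,
                                     n_points = config$interpolation_points)
      clusters <- cluster_trajectories(traj, k = config$k_clusters,
                                       seed = derive_seed(config$seed, "kmeans"))
      readr::write_tsv(clusters$assignments,
                       file.path(config$out_dir, "trajectory_clusters.tsv"),
                       progress = FALSE)
      readr::write_tsv(clusters$cluster_means,
                       file.path(config$out_dir, "trajectory_cluster_means.tsv"),
                       progress = FALSE)
    } else {
      log_info("only %d fully consistent genes (< k = %d); skipping clustering",
               length(consistent_genes), config$k_clusters)
    }

    stage <- "enrichment"
    gsea <- NULL
    if (!is.null(config$gmt_path)) {
      scores <- setNames(consistency$aging$genes$n_up,
                         consistency$aging$genes$gene_id)
      gsea <- preranked_gsea(scores, read_gmt(config$gmt_path),
                             n_perm = config$n_perm,
                             seed = derive_seed(config$seed, "gsea"),
                             min_size = config$gsea_bounds[1],
                             max_size = config$gsea_bounds[2])
      readr::write_tsv(gsea, file.path(config$out_dir, "gsea.tsv"),
                       progress = FALSE)
    }

    stage <- "manifest"
    cfg_plain <- unclass(config)
    cfg_plain$simulation <- if (!is.null(config$simulation)) unclass(config$simulation)
    out_files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("agevar")),
      seed = config$seed,
      config = cfg_plain,
      n_datasets = length(collection),
      n_common_genes = nrow(collection[[1]]$expr),
      output_checksums = as.list(tools::md5sum(out_files)))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")

    list(collection = collection, fits = fits, consistency = consistency,
         period_tests = period_tests, clusters = clusters, gsea = gsea,
         manifest = manifest)
  }, error = function(e) {
    writeLines(sprintf("stage: %s\n%s", stage, conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    stop_agevar("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(result)
}
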