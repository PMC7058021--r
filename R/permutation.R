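# Dependence-aware permutation machinery: ages are shuffled among
# *individuals* within each study and propagated to every sample of that
# individual in every region dataset, so the null preserves the coupling
# between datasets that share donors.

#' Build an individual-level age permutation set
#'
#' For each study, the observed individual ages are randomly permuted among
#' that study's individuals `n_perm` times. All samples of one individual --
#' in every region dataset of the study -- receive the same permuted age, so
#' the age multiset per study is conserved and the cross-dataset dependence
#' structure is retained under the null.
#'
#' @param collection A [study_collection].
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; the set is fully reproducible.
#' @return Object of class `permutation_set`: per study a list with
#'   `individual_id`, `age_days` and `perm` (individuals x n_perm matrix of
#'   permuted ages), plus `n_perm` and `seed`.
#' @export
permute_individual_ages <- function(collection, n_perm = 1000, seed = 1L) {
  stopifnot(inherits(collection, "study_collection"))
  if (n_perm < 1) stop_agevar("n_perm must be positive")
  ind <- purrr::map_dfr(collection, function(d) {
    distinct(d$meta, .data$study, .data$individual_id, .data$age_days)
  }) |> distinct()
  studies <- split(ind, ind$study)
  out <- with_seed(seed, lapply(studies, function(si) {
    k <- nrow(si)
    if (k < 2) {
      stop_agevar("study '%s' has a single individual; ages cannot be permuted",
                  si$study[1])
    }
    perm <- vapply(seq_len(n_perm), function(i) sample(si$age_days),
                   numeric(k))
    list(individual_id = si$individual_id, age_days = si$age_days,
         perm = perm)
  }))
  structure(list(studies = out, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "permutation_set")
}

#' Permuted ages for the samples of one dataset
#'
#' @param perm_set A [permute_individual_ages()] result.
#' @param meta Sample metadata tibble of the dataset.
#' @return Samples x n_perm matrix of permuted ages (days).
#' @export
perm_sample_ages <- function(perm_set, meta) {
  st <- meta$study[1]
  ps <- perm_set$studies[[st]]
  if (is.null(ps)) stop_agevar("study '%s' not present in permutation set", st)
  idx <- match(meta$individual_id, ps$individual_id)
  if (anyNA(idx)) stop_agevar("individual(s) missing from permutation set")
  ps$perm[idx, , drop = FALSE]
}

#' Heterogeneity statistics under permuted ages
#'
#' For each permutation and gene, the Spearman correlation between the
#' *observed-age* absolute residuals and the permuted ages. Residuals are
#' deliberately not refit: the mean model keeps its relationship to true
#' age, and only the heterogeneity-age link is broken, which makes the null
#' specific to the heterogeneity signal.
#'
#' @param fits Named list of `dataset_change` objects (from
#'   [fit_collection_changes()]).
#' @param perm_set A `permutation_set` built on the same collection.
#' @return Named list, per dataset a genes x n_perm matrix of permuted rho.
#' @export
permuted_heterogeneity <- function(fits, perm_set) {
  genes <- rownames(fits[[1]]$residuals)
  lapply(fits, function(f) {
    if (!identical(rownames(f$residuals), genes)) {
      stop_agevar("datasets have mismatched gene sets; run intersect_common_genes()")
    }
    A <- perm_sample_ages(perm_set, f$meta)
    ra <- apply(A, 2L, rank, ties.method = "average")
    rr <- row_ranks(abs(f$residuals))
    deg <- apply(rr, 1L, sd) == 0
    out <- suppressWarnings(cor(t(rr), ra))
    out[deg, ] <- 0
    rownames(out) <- genes
    out
  })
}

#' Expression-change statistics under permuted ages
#'
#' Unlike the heterogeneity null, the slope *is* refit against the permuted
#' (transformed) ages, because the statistic under test is the age-expression
#' relationship itself.
#'
#' @inheritParams permuted_heterogeneity
#' @param age_scale Age transform used for the refits.
#' @return Named list, per dataset a genes x n_perm matrix of permuted beta1.
#' @export
permuted_expression_change <- function(fits, perm_set, age_scale = "fourth_root") {
  lapply(fits, function(f) {
    # centered expression reconstructed from the stored fit
    xc <- f$age_t - mean(f$age_t)
    Yc <- f$residuals + outer(f$table$beta1, xc)
    A <- perm_sample_ages(perm_set, f$meta)
    X <- transform_age(A, age_scale)
    Xc <- sweep(X, 2L, colMeans(X))
    denom <- colSums(Xc^2)
    out <- sweep(Yc %*% Xc, 2L, denom, "/")
    rownames(out) <- rownames(f$residuals)
    out
  })
}

#' Per-gene cross-dataset consistency counts
#'
#' @param stat_matrix Genes x datasets matrix of statistics (rho or beta).
#' @return Tibble with `gene_id` and `n_up`, the number of datasets where the
#'   statistic is strictly positive (zero counts as not-up).
#' @export
consistency_counts <- function(stat_matrix) {
  check_numeric_matrix(stat_matrix, "stat_matrix")
  if (anyNA(stat_matrix)) stop_agevar("stat_matrix contains missing values")
  tibble(gene_id = rownames(stat_matrix) %||%
           as.character(seq_len(nrow(stat_matrix))),
         n_up = as.integer(rowSums(stat_matrix > 0)))
}

# counts of genes at each consistency level N = 0..K
tally_counts <- function(n_up, K) {
  tabulate(n_up + 1L, nbins = K + 1L)
}

#' Test observed consistency against the permutation null
#'
#' For each consistency level `N` in 1..K, compares the observed number of
#' genes whose statistic is positive in exactly `N` datasets against the
#' distribution of that count over the age permutations; one-sided empirical
#' p with the +1 convention (so the floor at 1,000 permutations is about
#' 0.001).
#'
#' @param observed_counts Integer vector of length K+1: number of genes at
#'   each level `N = 0..K` (as from `tally_counts` on observed `n_up`).
#' @param perm_counts n_perm x (K+1) matrix of the same tallies under each
#'   permutation.
#' @return Tibble with `n_datasets` (1..K), `observed`, `expected_mean`, `p`.
#' @export
consistency_null_test <- function(observed_counts, perm_counts) {
  if (nrow(perm_counts) < 100) {
    stop_agevar("need at least 100 permutations (got %d)", nrow(perm_counts))
  }
  K <- length(observed_counts) - 1L
  stopifnot(ncol(perm_counts) == K + 1L)
  res <- lapply(seq_len(K), function(N) {
    obs <- observed_counts[N + 1L]
    nulls <- perm_counts[, N + 1L]
    tibble(n_datasets = N, observed = obs,
           expected_mean = mean(nulls),
           p = empirical_p(nulls, obs, "greater"))
  })
  bind_rows(res)
}

#' Full cross-dataset heterogeneity consistency analysis
#'
#' Counts, per gene, the datasets with a positive heterogeneity change, and
#' tests the per-level tallies against the individual-age permutation null.
#' Setting `direction = "decrease"` flips the statistic sign to score
#' consistent heterogeneity decrease instead.
#'
#' @param fits Named list of `dataset_change` objects (one period).
#' @param perm_set A `permutation_set`.
#' @param direction `"increase"` (default) or `"decrease"`.
#' @return Object of class `consistency_table`: list with `genes` (tibble
#'   `gene_id`, `n_up`), `levels` (the [consistency_null_test()] tibble),
#'   `null_counts` (n_perm x K+1), `n_datasets`, `direction`.
#' @export
heterogeneity_consistency <- function(fits, perm_set, direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  sgn <- if (direction == "increase") 1 else -1
  obs_mat <- sgn * rho_matrix(fits)
  K <- ncol(obs_mat)
  genes <- consistency_counts(obs_mat)
  perm_rho <- permuted_heterogeneity(fits, perm_set)
  up <- Reduce(`+`, lapply(perm_rho, function(m) (sgn * m) > 0))
  perm_counts <- t(apply(up, 2L, tally_counts, K = K))
  levels <- consistency_null_test(tally_counts(genes$n_up, K), perm_counts)
  structure(list(genes = genes, levels = levels, null_counts = perm_counts,
                 n_datasets = K, direction = direction),
            class = "consistency_table")
}

#' @export
print.consistency_table <- function(x, ...) {
  cat(sprintf("<consistency_table> %d genes x %d datasets (%s)\n",
              nrow(x$genes), x$n_datasets, x$direction))
  top <- x$levels[x$n_datasets, ]
  cat(sprintf("  genes consistent in all %d datasets: %d (expected %.1f, p = %.3g)\n",
              x$n_datasets, top$observed, top$expected_mean, top$p))
  invisible(x)
}

#' Assemble a genes x datasets statistic matrix from fits
#'
#' @param fits Named list of `dataset_change` objects.
#' @param stat Column of the change table to extract (`"rho"` or `"beta1"`).
#' @return Genes x datasets numeric matrix.
#' @export
rho_matrix <- function(fits, stat = "rho") {
  m <- vapply(fits, function(f) f$table[[stat]], numeric(nrow(fits[[1]]$table)))
  rownames(m) <- fits[[1]]$table$gene_id
  m
}

#' @rdname rho_matrix
#' @export
beta_matrix <- function(fits) rho_matrix(fits, stat = "beta1")

# median over genes of pairwise Spearman correlations between dataset columns
pairwise_spearman <- function(stat_matrix) {
  suppressWarnings(cor(stat_matrix, method = "spearman"))
}

#' Independent-subset correlation test
#'
#' Within one period the pairwise dataset correlations are dominated by
#' dependent pairs (datasets sharing donors). This test enumerates every
#' combination of one dataset per study (e.g. 16 x 2 x 1 = 32 combinations
#' for studies contributing 16, 2 and 1 datasets), computes the median of
#' the pairwise Spearman correlations within each combination, and takes the
#' median over combinations as the observed statistic; its null comes from
#' recomputing under each age permutation.
#'
#' @param stat_matrix Genes x datasets matrix (rho or beta values).
#' @param grouping Named character vector mapping dataset (column) names to
#'   their study.
#' @param perm_stats Named list per dataset of genes x n_perm permuted
#'   statistic matrices ([permuted_heterogeneity()] or
#'   [permuted_expression_change()]).
#' @return List with `observed` (median over combinations), `p` (one-sided,
#'   greater), `n_combinations`, `null` (per-permutation statistics).
#' @export
independent_triple_correlation_test <- function(stat_matrix, grouping, perm_stats) {
  cols <- colnames(stat_matrix)
  grouping <- grouping[cols]
  if (anyNA(grouping)) stop_agevar("grouping must cover every dataset")
  by_study <- split(cols, grouping)
  if (any(lengths(by_study) == 0)) stop_agevar("a study has no datasets in this period")
  combos <- expand.grid(by_study, stringsAsFactors = FALSE)
  stat_of <- function(cmat) {
    apply(combos, 1L, function(sel) {
      cc <- cmat[sel, sel, drop = FALSE]
      median(cc[upper.tri(cc)])
    }) |> median()
  }
  observed <- stat_of(pairwise_spearman(stat_matrix))
  n_perm <- ncol(perm_stats[[1]])
  null <- vapply(seq_len(n_perm), function(k) {
    pm <- vapply(cols, function(d) perm_stats[[d]][, k], numeric(nrow(stat_matrix)))
    stat_of(pairwise_spearman(pm))
  }, numeric(1))
  list(observed = observed, p = empirical_p(null, observed, "greater"),
       n_combinations = nrow(combos), null = null)
}

#' Development vs aging period-difference tests
#'
#' Compares a summary of the aging datasets against the matched development
#' datasets, with significance from the shared individual-age permutations.
#' One-sided: aging greater than development.
#'
#' Statistics:
#' \describe{
#'   \item{`median_rho_diff`}{Per matched dataset, the difference between the
#'     median heterogeneity change (rho) in aging and in development; the
#'     observed statistic is the median of those differences.}
#'   \item{`median_correlation_diff`}{Median pairwise Spearman correlation
#'     among aging datasets minus the same among development datasets.}
#'   \item{`n_significant_diff`}{Total number of genes with BH-adjusted
#'     heterogeneity p below `alpha` across aging datasets minus the same
#'     across development datasets.}
#' }
#'
#' @param dev_fits,aging_fits Named lists of `dataset_change` objects; names
#'   identify matched datasets (equal base names in both lists).
#' @param perm_set A `permutation_set` covering both periods' studies.
#' @param statistic One of the statistics above.
#' @param alpha Significance cutoff for `n_significant_diff`, default 0.05.
#' @return List with `observed`, `p`, `statistic`, `null`.
#' @export
period_difference_test <- function(dev_fits, aging_fits, perm_set,
                                   statistic = c("median_rho_diff",
                                                 "median_correlation_diff",
                                                 "n_significant_diff"),
                                   alpha = 0.05) {
  statistic <- match.arg(statistic)
  if (perm_set$n_perm < 1) stop_agevar("permutation set is empty")
  perm_dev <- permuted_heterogeneity(dev_fits, perm_set)
  perm_aging <- permuted_heterogeneity(aging_fits, perm_set)
  rho_dev <- rho_matrix(dev_fits)
  rho_aging <- rho_matrix(aging_fits)
  n_perm <- perm_set$n_perm

  if (statistic == "median_rho_diff") {
    common <- intersect(names(dev_fits), names(aging_fits))
    if (length(common) == 0) stop_agevar("no matched dataset pairs across periods")
    observed <- median(apply(rho_aging[, common, drop = FALSE], 2L, median) -
                         apply(rho_dev[, common, drop = FALSE], 2L, median))
    null <- vapply(seq_len(n_perm), function(k) {
      median(vapply(common, function(d) {
        median(perm_aging[[d]][, k]) - median(perm_dev[[d]][, k])
      }, numeric(1)))
    }, numeric(1))
  } else if (statistic == "median_correlation_diff") {
    med_cor <- function(m) {
      cc <- pairwise_spearman(m)
      median(cc[upper.tri(cc)])
    }
    observed <- med_cor(rho_aging) - med_cor(rho_dev)
    col_k <- function(perm_list, k) {
      vapply(names(perm_list), function(d) perm_list[[d]][, k],
             numeric(nrow(perm_list[[1]])))
    }
    null <- vapply(seq_len(n_perm), function(k) {
      med_cor(col_k(perm_aging, k)) - med_cor(col_k(perm_dev, k))
    }, numeric(1))
  } else {
    n_sig <- function(fits_list) {
      sum(vapply(fits_list, function(f) sum(f$table$q_rho < alpha), numeric(1)))
    }
    observed <- n_sig(aging_fits) - n_sig(dev_fits)
    sig_perm <- function(perm_list, fits_list, k) {
      sum(vapply(names(perm_list), function(d) {
        n <- ncol(fits_list[[d]]$residuals)
        r <- perm_list[[d]][, k]
        tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
        p <- pmin(2 * pt(-abs(tt), df = n - 2), 1)
        sum(adjust_fdr(p) < alpha)
      }, numeric(1)))
    }
    null <- vapply(seq_len(n_perm), function(k) {
      sig_perm(perm_aging, aging_fits, k) - sig_perm(perm_dev, dev_fits, k)
    }, numeric(1))
  }
  list(observed = observed, p = empirical_p(null, observed, "greater"),
       statistic = statistic, null = null)
}

#' PCA dispersion of datasets in statistic space
#'
#' Treats each dataset's per-gene statistic vector (beta or rho) as one
#' observation, scales each dataset's vector to mean 0 / sd 1, extracts
#' principal components by singular value decomposition (no further
#' centering beyond the per-dataset scaling), and summarizes each period's
#' spread as the median pairwise Euclidean distance on PC1-PC2.
#'
#' @param stat_matrix Genes x datasets matrix.
#' @param period_labels Character vector, one period label per dataset.
#' @return Object of class `pca_dispersion`: list with `coords` (tibble:
#'   `dataset`, `period`, `PC1`, `PC2`), `dispersion` (tibble: `period`,
#'   `median_distance`), `var_explained` (fractions for PC1, PC2).
#' @export
pca_dispersion_summary <- function(stat_matrix, period_labels) {
  check_numeric_matrix(stat_matrix, "stat_matrix")
  if (ncol(stat_matrix) < 3) stop_agevar("need at least 3 datasets")
  if (nrow(stat_matrix) < 2) stop_agevar("need at least 2 genes")
  stopifnot(length(period_labels) == ncol(stat_matrix))
  X <- t(scale(stat_matrix))          # datasets x genes, per-dataset scaling
  sv <- svd(X)
  pcs <- sv$u %*% diag(sv$d)
  coords <- tibble(dataset = colnames(stat_matrix) %||%
                     as.character(seq_len(ncol(stat_matrix))),
                   period = period_labels,
                   PC1 = pcs[, 1], PC2 = pcs[, 2])
  disp <- coords |>
    group_by(.data$period) |>
    summarise(median_distance = {
      d <- dist(cbind(.data$PC1, .data$PC2))
      if (length(d) == 0) 0 else median(d)
    }, .groups = "drop")
  structure(list(coords = coords, dispersion = disp,
                 var_explained = (sv$d^2 / sum(sv$d^2))[1:2]),
            class = "pca_dispersion")
}
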