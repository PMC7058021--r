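make_small_collection <- function(seed = 5, regions = c(2, 1), n_ind = 16,
                                  n_genes = 40, frac_inc = 0) {
  simulate_collection(sim_config(regions_per_study = regions,
                                 n_individuals = n_ind, n_genes = n_genes,
                                 frac_het_increase = frac_inc, seed = seed))
}

test_that("individual-level permutations preserve age multisets and donor coupling", {
  col <- make_small_collection()
  ps <- permute_individual_ages(col, n_perm = 50, seed = 2)

  for (st in names(ps$studies)) {
    s <- ps$studies[[st]]
    for (k in seq_len(50)) {
      expect_identical(sort(s$perm[, k]), sort(s$age_days))
    }
  }

  # two region datasets of study1 receive the same permuted age per donor
  s1 <- names(col)[study_of(col) == "study1"]
  a1 <- perm_sample_ages(ps, col[[s1[1]]]$meta)
  a2 <- perm_sample_ages(ps, col[[s1[2]]]$meta)
  m1 <- match(col[[s1[1]]]$meta$individual_id, col[[s1[2]]]$meta$individual_id)
  expect_identical(a1, a2[m1, , drop = FALSE])

  # determinism
  ps2 <- permute_individual_ages(col, n_perm = 50, seed = 2)
  expect_identical(ps$studies, ps2$studies)

  # a swap of two donors propagates to both region datasets coherently
  expect_error({
    single <- col[[1]]
    single$meta$individual_id <- rep("only_one", nrow(single$meta))
    single$meta$age_days <- rep(3650, nrow(single$meta))
    permute_individual_ages(study_collection(list(x = single)), 10, 1)
  }, "single individual")
})

test_that("identity permutation reproduces the observed heterogeneity exactly", {
  col <- make_small_collection()
  fits <- fit_collection_changes(study_collection(col))
  ps <- permute_individual_ages(col, n_perm = 5, seed = 3)
  # overwrite permutation 1 with the observed ages
  for (st in names(ps$studies)) ps$studies[[st]]$perm[, 1] <- ps$studies[[st]]$age_days
  pr <- permuted_heterogeneity(fits, ps)
  obs <- rho_matrix(fits)
  for (nm in names(fits)) {
    expect_equal(unname(pr[[nm]][, 1]), unname(obs[, nm]), tolerance = 1e-10)
  }
})

test_that("permuted expression change refits the slope against permuted ages", {
  col <- make_small_collection()
  fits <- fit_collection_changes(study_collection(col))
  ps <- permute_individual_ages(col, n_perm = 3, seed = 4)
  pb <- permuted_expression_change(fits, ps)
  nm <- names(fits)[1]
  f <- fits[[nm]]
  ages_k <- perm_sample_ages(ps, f$meta)[, 2]
  x <- transform_age(ages_k)
  d <- col[[nm]]
  manual <- apply(d$expr, 1, function(y) {
    sum((y - mean(y)) * (x - mean(x))) / sum((x - mean(x))^2)
  })
  expect_equal(unname(pb[[nm]][, 2]), unname(manual), tolerance = 1e-10)
})

test_that("consistency counts follow the sign rule and the negation identity", {
  m <- rbind(g1 = c(0.1, -0.2, 0.3), g2 = c(0, 0.5, -0.1), g3 = c(1, 1, 1))
  colnames(m) <- paste0("d", 1:3)
  cc <- consistency_counts(m)
  expect_equal(cc$n_up, c(2L, 1L, 3L))
  # negation: n_up(-m) = K - n_up(m) - #zeros
  n_zero <- rowSums(m == 0)
  cc_neg <- consistency_counts(-m)
  expect_equal(cc_neg$n_up, 3L - cc$n_up - as.integer(n_zero))
})

test_that("consistency null test uses the one-sided +1 empirical convention", {
  perm <- matrix(0L, 200, 4)          # levels N = 0..3, all null counts zero
  perm[, 4] <- withr::with_seed(1, rpois(200, 2))
  obs <- c(0L, 0L, 0L, max(perm[, 4]) + 5L)
  res <- consistency_null_test(obs, perm)
  expect_equal(res$p[res$n_datasets == 3], 1 / 201)
  # observed at the permutation median -> p near 0.5
  obs2 <- c(0L, 0L, 0L, as.integer(median(perm[, 4])))
  res2 <- consistency_null_test(obs2, perm)
  expect_gt(res2$p[res2$n_datasets == 3], 0.3)
  expect_error(consistency_null_test(obs, perm[1:50, ]), "100")
})

test_that("independent synthetic datasets match the binomial consistency null", {
  # five single-region studies with no shared donors and no planted signal:
  # per gene P(rho > 0) ~ 1/2 independently, so P(n_up = 5) ~ 2^-5
  col <- make_small_collection(seed = 77, regions = rep(1, 5), n_ind = 40,
                               n_genes = 2000)
  fits <- fit_collection_changes(split_collection_periods(col)$aging)
  cc <- consistency_counts(rho_matrix(fits))
  frac <- mean(cc$n_up == 5)
  expect_lt(abs(frac - 2^-5), 3 * sqrt(2^-5 * (1 - 2^-5) / 2000) + 0.01)
})

test_that("donor-sharing makes the consistency null wider than independent shuffles", {
  # one study, four regions, same donors: permuted rho is identical across
  # datasets up to noise, inflating the variance of the count at N = K
  col_dep <- make_small_collection(seed = 31, regions = 4, n_ind = 20,
                                   n_genes = 150)
  fits_dep <- fit_collection_changes(study_collection(col_dep))
  ps_dep <- permute_individual_ages(col_dep, n_perm = 300, seed = 8)
  cons_dep <- heterogeneity_consistency(fits_dep, ps_dep)

  # same data relabelled so every dataset has private donors -> independent
  col_ind <- col_dep
  for (i in seq_along(col_ind)) {
    d <- col_ind[[i]]
    d$meta$individual_id <- paste0(d$meta$individual_id, "_ds", i)
    d$meta$study <- paste0("study_ds", i)
    col_ind[[i]] <- d
  }
  col_ind <- study_collection(col_ind)
  fits_ind <- fit_collection_changes(col_ind)
  ps_ind <- permute_individual_ages(col_ind, n_perm = 300, seed = 8)
  cons_ind <- heterogeneity_consistency(fits_ind, ps_ind)

  K <- 4
  v_dep <- var(cons_dep$null_counts[, K + 1])
  v_ind <- var(cons_ind$null_counts[, K + 1])
  expect_gte(v_dep, v_ind)
})

test_that("independent-subset correlation test enumerates one dataset per study", {
  withr::with_seed(6, {
    K <- 19
    sizes <- c(16, 2, 1)
    grouping <- setNames(rep(paste0("st", 1:3), sizes), paste0("d", 1:K))
    signal <- rnorm(100)
    stat <- vapply(1:K, function(i) signal, numeric(100))  # identical columns
    colnames(stat) <- names(grouping)
    perm_stats <- setNames(lapply(1:K, function(i) {
      matrix(rnorm(100 * 20), 100, 20)
    }), names(grouping))
  })
  res <- independent_triple_correlation_test(stat, grouping, perm_stats)
  expect_equal(res$n_combinations, 32)      # 16 x 2 x 1
  expect_equal(res$observed, 1)             # identical signal, no noise
  expect_equal(res$p, 1 / 21)               # above every random null
  expect_error(independent_triple_correlation_test(
    stat, setNames(rep("st1", K), names(grouping))[1:(K - 1)], perm_stats),
    "cover")
})

test_that("period-difference test detects planted aging heteroskedasticity", {
  col <- simulate_collection(sim_config(regions_per_study = c(2, 1),
                                        n_individuals = 120, n_genes = 300,
                                        frac_het_increase = 0.3,
                                        var_slope_range = c(1, 1), seed = 21))
  periods <- split_collection_periods(col)
  fits <- lapply(periods, fit_collection_changes)
  ps <- permute_individual_ages(col, n_perm = 200, seed = 9)
  res <- period_difference_test(fits$development, fits$aging, ps,
                                "median_rho_diff")
  expect_lte(res$p, 0.05)
  expect_gt(res$observed, 0)

  expect_error(period_difference_test(fits$development, fits$aging, ps,
                                      "not_a_statistic"), "should be one of")
  expect_error(permute_individual_ages(col, n_perm = 0, seed = 1), "positive")
})

test_that("PCA dispersion summary has the documented invariances", {
  withr::with_seed(13, {
    base <- rnorm(60)
    stat <- cbind(a = base, b = base, c = rnorm(60), d = rnorm(60))
  })
  res <- pca_dispersion_summary(stat, c("p1", "p1", "p2", "p2"))
  # identical datasets land on the same PC coordinates
  d_same <- sqrt((res$coords$PC1[1] - res$coords$PC1[2])^2 +
                   (res$coords$PC2[1] - res$coords$PC2[2])^2)
  expect_lt(d_same, 1e-8)
  expect_equal(res$dispersion$median_distance[res$dispersion$period == "p1"], 0,
               tolerance = 1e-8)

  # permuting gene order leaves distances unchanged
  perm <- withr::with_seed(2, sample(nrow(stat)))
  res2 <- pca_dispersion_summary(stat[perm, ], c("p1", "p1", "p2", "p2"))
  expect_equal(res$dispersion$median_distance, res2$dispersion$median_distance,
               tolerance = 1e-8)

  expect_error(pca_dispersion_summary(stat[, 1:2], c("p1", "p1")), "3 datasets")
})
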