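make_period_fits <- function(seed = 3, n_genes = 60) {
  col <- simulate_collection(sim_config(regions_per_study = c(2, 1),
                                        n_individuals = 20, n_genes = n_genes,
                                        seed = seed))
  lapply(split_collection_periods(col), fit_collection_changes)
}

test_that("regulator-count association handles signal, degenerate and error cases", {
  col <- simulate_collection(sim_config(regions_per_study = c(4, 2),
                                        n_individuals = 20, n_genes = 60,
                                        seed = 3))
  fits <- lapply(split_collection_periods(col), fit_collection_changes)
  genes <- fits$aging[[1]]$table$gene_id

  # counts tracking the mean aging rho: every aging correlation beats its
  # development counterpart and the permutation p is small
  counts <- setNames(rank(rowMeans(rho_matrix(fits$aging))), genes)
  res <- regulator_count_association(fits$development, fits$aging, counts,
                                     n_perm = 200, seed = 2)
  expect_equal(nrow(res$per_dataset), 12L)   # 6 datasets x 2 periods
  expect_equal(res$observed_fraction, 1)
  expect_lte(res$p, 0.1)

  # constant counts: correlations undefined -> flagged zero with a warning
  expect_warning(
    res0 <- regulator_count_association(fits$development, fits$aging,
                                        setNames(rep(3, length(genes)), genes),
                                        n_perm = 50, seed = 2),
    "constant")
  expect_true(all(res0$per_dataset$correlation == 0))

  expect_error(regulator_count_association(
    fits$development, fits$aging, c(not_a_gene = 5), n_perm = 100, seed = 1),
    "no genes")
})

test_that("interaction-degree resampling matches the exhaustive 1-gene enumeration", {
  net <- tibble::tibble(gene_a = c("A", "B"), gene_b = c("B", "C"),
                        combined_score = c(900, 700))
  # path A-B-C: degrees (1, 2, 1); drawing 1 of 3 genes, P(median >= 2) = 1/3
  res <- ppi_degree_test("B", net, score_cutoff = 400, n_samples = 6000, seed = 1)
  expect_equal(res$median_degree, 2)
  expect_equal(res$k, 1L)
  expect_lt(abs(res$p - 1 / 3), 0.03)
  expect_gte(res$p, 1 / 6001)
  expect_lte(res$p, 1)

  # all nodes as targets: observed median equals the population median
  res_all <- ppi_degree_test(c("A", "B", "C"), net, 400, n_samples = 500, seed = 1)
  expect_gt(res_all$p, 0.3)

  expect_error(ppi_degree_test("B", net, score_cutoff = 1000), "no edges")
  expect_error(ppi_degree_test("ZZZ", net, 400), "k = 0")
})

test_that("Cohen's D matches the pooled-sd hand computation", {
  # group [3,5] vs rest [0,2]: pooled sd = sqrt(2), D = 3/sqrt(2) ~ 2.12
  expect_equal(cohens_d(c(3, 5), c(0, 2)), 3 / sqrt(2), tolerance = 1e-12)
  expect_equal(cohens_d(c(0, 2), c(3, 5)), -3 / sqrt(2), tolerance = 1e-12)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_true(is.na(cohens_d(c(1, 1), c(1, 1))))
})

test_that("cell-type specificity calls respect the D >= 2 boundary", {
  # gene g_hit: astro replicates [3,5], others [0,2,0,2] -> D ~ 2.45, specific
  # gene g_near: astro [2.9,2.9] vs pooled sd 1 -> D = 1.9, below the boundary
  expr <- rbind(
    g_hit = c(3, 5, 0, 2, 0, 2),
    g_near = c(2.9, 2.9, 0, 2, 0, 2),
    g_flat = c(1, 1, 1, 1, 1, 1))
  colnames(expr) <- c("astro.1", "astro.2", "oligo.1", "oligo.2", "neuron.1",
                      "neuron.2")
  profiles <- list(expr = expr, cell_type = sub("\\..*", "", colnames(expr)))
  res <- cell_type_specific_genes(profiles)
  expect_true(res$specific[res$gene_id == "g_hit" & res$cell_type == "astro"])
  d_near <- res$cohens_d[res$gene_id == "g_near" & res$cell_type == "astro"]
  expect_lt(d_near, 2)
  expect_false(res$specific[res$gene_id == "g_near" & res$cell_type == "astro"])
  expect_true(all(is.na(res$cohens_d[res$gene_id == "g_flat"])))
  expect_false(any(res$specific[res$gene_id == "g_flat"]))
})

test_that("Fisher overlap test matches hypergeometric enumeration", {
  universe <- paste0("g", 1:4)
  res <- gene_set_overlap_test(c("g1", "g2"), c("g1", "g2"), universe)
  # margins (2,2) on 4 genes, overlap 2: P(a=2)+P(a=0) = 1/6+1/6 = 1/3
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)

  # disjoint halves covering the universe: odds ratio 0
  res0 <- gene_set_overlap_test(c("g1", "g2"), c("g3", "g4"), universe)
  expect_equal(res0$odds_ratio, 0)
  expect_error(gene_set_overlap_test("a", "b", character(0)), "empty")
})

test_that("deconvolution recovers noiseless mixtures exactly", {
  withr::with_seed(10, {
    profiles <- qr.Q(qr(matrix(rnorm(40 * 4), 40, 4))) * 5  # orthogonal columns
  })
  colnames(profiles) <- c("astro", "oligo", "opc", "neuron")
  rownames(profiles) <- paste0("g", 1:40)

  # sample equal to one profile
  s1 <- setNames(profiles[, "astro"], rownames(profiles))
  r1 <- deconvolve_cell_types(s1, profiles)
  expect_equal(unname(r1$coefficients), c(1, 0, 0, 0), tolerance = 1e-8)
  expect_equal(r1$intercept, 0, tolerance = 1e-8)

  # 50/50 mixture on orthogonal profiles
  s2 <- setNames(0.5 * profiles[, "astro"] + 0.5 * profiles[, "neuron"],
                 rownames(profiles))
  r2 <- deconvolve_cell_types(s2, profiles)
  expect_equal(unname(r2$coefficients), c(0.5, 0, 0, 0.5), tolerance = 1e-8)

  # random positive mixture recovered to 1e-8
  w <- c(0.4, 0.3, 0.2, 0.1)
  s3 <- setNames(as.vector(profiles %*% w), rownames(profiles))
  r3 <- deconvolve_cell_types(s3, profiles)
  expect_equal(unname(r3$coefficients), w, tolerance = 1e-8)

  dup <- profiles
  dup[, 2] <- dup[, 1]
  expect_error(deconvolve_cell_types(s1, dup), "rank deficient")
})

test_that("sex-difference check uses the exact rank-sum null on small samples", {
  absres <- rbind(gA = c(1, 2, 3, 4), gB = c(5, 5, 5, 5))
  fit <- fake_fit(absres, age_t = c(9, 10, 11, 12))
  fit$meta$sex <- c("female", "female", "male", "male")
  res <- sex_difference_check(fit)
  # enumeration oracle: C(4,2) = 6 assignments, [1,2] vs [3,4] extreme both
  # directions -> two-sided p = 2/6
  expect_equal(res$p[res$gene_id == "gA"], 1 / 3, tolerance = 1e-12)
  expect_true(res$skipped[res$gene_id == "gB"])   # constant residuals

  fit$meta$sex <- rep("female", 4)
  res2 <- sex_difference_check(fit)
  expect_true(all(res2$skipped))
})
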