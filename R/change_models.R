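# Per-gene, per-dataset statistics: expression change (OLS slope on
# transformed age) and heterogeneity change (Spearman correlation of
# absolute residuals with age), plus the two sensitivity alternatives
# (Breusch-Pagan score test, loess residuals).

# Spearman correlation with mid-rank ties + two-sided p-value.
# t-approximation for n >= 10; exact permutation enumeration below that
# (n <= 9, all n! permutations, vectorized).
spearman_test <- function(x, y) {
  n <- length(x)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(list(rho = 0, p = 1, degenerate = TRUE))
  }
  rho <- cor(rx, ry)
  if (n >= 10) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
  } else {
    perms <- all_permutations(n)
    # correlation is linear in the permuted vector given fixed ranks
    rho_null <- as.vector(perms_cor(rx, ry, perms))
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
  }
  list(rho = rho, p = min(p, 1), degenerate = FALSE)
}

# Correlations of rx with every row-permutation of ry; every row of `perms`
# is a permutation of indices, so mean/sd of ry are unchanged and the
# correlation is linear in the permuted vector.
perms_cor <- function(rx, ry, perms) {
  sx <- (rx - mean(rx)) / sd(rx)
  sy <- (ry - mean(ry)) / sd(ry)
  sy_perm <- matrix(sy[perms], nrow(perms), ncol(perms))
  as.vector(sy_perm %*% sx) / (length(rx) - 1)
}

#' Fit the per-gene age-trend model
#'
#' Ordinary least squares of one gene's (scaled log2) expression on the
#' transformed age: `Y = beta0 + beta1 * age_t + eps`. The slope `beta1`
#' measures age-related expression change; the residuals feed the
#' heterogeneity statistic.
#'
#' @param expr Numeric expression vector (one value per sample).
#' @param age_t Transformed ages (same length, not constant).
#' @return List with `beta0`, `beta1`, `p_beta` (two-sided slope t-test),
#'   `residuals`, and `degenerate` (`TRUE` for a constant expression vector,
#'   which is returned as `beta1 = 0`, `p_beta = 1` rather than an error so
#'   large synthetic runs survive pathological genes).
#' @export
fit_expression_change <- function(expr, age_t) {
  n <- length(expr)
  if (n < 4 || length(age_t) != n) {
    stop_agevar("need >= 4 paired observations (got %d and %d)", n, length(age_t))
  }
  if (sd(age_t) == 0) stop_agevar("age_t is constant")
  if (sd(expr) == 0) {
    return(list(beta0 = expr[1], beta1 = 0, p_beta = 1,
                residuals = rep(0, n), degenerate = TRUE))
  }
  xc <- age_t - mean(age_t)
  sxx <- sum(xc^2)
  beta1 <- sum((expr - mean(expr)) * xc) / sxx
  beta0 <- mean(expr) - beta1 * mean(age_t)
  res <- expr - beta0 - beta1 * age_t
  sigma2 <- sum(res^2) / (n - 2)
  if (sigma2 == 0) {
    p <- 0
  } else {
    tt <- beta1 / sqrt(sigma2 / sxx)
    p <- 2 * pt(-abs(tt), df = n - 2)
  }
  list(beta0 = beta0, beta1 = beta1, p_beta = p, residuals = res,
       degenerate = FALSE)
}

#' Heterogeneity change for one gene
#'
#' Spearman correlation (mid-rank ties) between the absolute model residuals
#' and age: positive values mean inter-individual spread grows with age. As a
#' rank statistic it is invariant to any strictly monotone transform of age,
#' so raw or transformed ages give identical results.
#'
#' @param residuals Residuals from [fit_expression_change()].
#' @param age Ages (any strictly monotone scale).
#' @return List with `rho`, `p_rho`, `degenerate` (`TRUE` when all absolute
#'   residuals are equal, returned as `rho = 0`, `p = 1`).
#' @export
heterogeneity_change <- function(residuals, age) {
  if (length(residuals) != length(age) || length(age) < 4) {
    stop_agevar("residuals and age must have equal length >= 4")
  }
  st <- spearman_test(abs(residuals), age)
  list(rho = st$rho, p_rho = st$p, degenerate = st$degenerate)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control with cumulative-minimum enforcement
#' (delegates to [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
adjust_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop_agevar("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Breusch-Pagan heteroskedasticity check for one gene
#'
#' Score-test variant: regress the squared age-model residuals on the
#' transformed age; the statistic is `n * R^2`, chi-square with 1 df under
#' homoskedasticity. Provided as an independent confirmation of the
#' rank-based heterogeneity statistic.
#'
#' @inheritParams fit_expression_change
#' @return List with `statistic` and `p`.
#' @export
breusch_pagan_check <- function(expr, age_t) {
  fit <- fit_expression_change(expr, age_t)
  u2 <- fit$residuals^2
  n <- length(u2)
  if (sd(u2) == 0) return(list(statistic = 0, p = 1))
  r <- cor(u2, age_t)
  stat <- n * r^2
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Loess-based heterogeneity change (sensitivity analysis)
#'
#' Replaces the linear age model with a local regression fit before the
#' Spearman step. More flexible in the mean, but more sensitive to sample
#' size and span, so it is exposed for sensitivity analysis only; the linear
#' model remains the primary statistic.
#'
#' @param expr Expression vector (>= 10 samples).
#' @param age Ages in days.
#' @param span Loess span in `(0, 1]`; the default roughly matches the
#'   smoothness of a 3-df spline on lifespan-sized datasets.
#' @param age_scale Age transform applied before fitting (see
#'   [transform_age()]).
#' @return List with `rho`, `p_rho`, `degenerate`.
#' @export
loess_heterogeneity <- function(expr, age, span = 0.75,
                                age_scale = "fourth_root") {
  n <- length(expr)
  if (n < 10) stop_agevar("loess heterogeneity needs >= 10 samples")
  if (span <= 0 || span > 1) stop_agevar("span must lie in (0, 1]")
  age_t <- transform_age(age, age_scale)
  fit <- loess(expr ~ age_t, span = span, degree = 2,
               control = stats::loess.control(surface = "direct"))
  st <- spearman_test(abs(resid(fit)), age)
  list(rho = st$rho, p_rho = st$p, degenerate = st$degenerate)
}

#' Fit age-trend and heterogeneity statistics for every gene of a dataset
#'
#' Vectorized over genes: one design per dataset, closed-form OLS slopes,
#' residual matrix, slope t-tests, Spearman rho of absolute residuals with
#' age, and BH-adjusted q-values for both families. This is the workhorse
#' behind every downstream stage; the scalar [fit_expression_change()] /
#' [heterogeneity_change()] define its per-gene contract.
#'
#' @param dataset An [expr_dataset] with >= 4 samples.
#' @param age_scale Age transform (see [transform_age()]).
#' @return Object of class `dataset_change`: list with `table` (tibble with
#'   columns `gene_id`, `beta0`, `beta1`, `p_beta`, `q_beta`, `rho`, `p_rho`,
#'   `q_rho`, `n_samples`, `degenerate`), `residuals` (genes x samples),
#'   `age_days`, `age_t`, `dataset`, `period`, `meta`.
#' @export
fit_dataset_changes <- function(dataset, age_scale = "fourth_root") {
  stopifnot(inherits(dataset, "expr_dataset"))
  Y <- dataset$expr
  n <- ncol(Y)
  if (n < 4) stop_agevar("dataset '%s' has fewer than 4 samples", dataset$name)
  age_days <- dataset$meta$age_days
  x <- transform_age(age_days, age_scale)
  if (sd(x) == 0) stop_agevar("constant age in dataset '%s'", dataset$name)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  ym <- unname(rowMeans(Y))
  beta1 <- as.vector((Y - rowMeans(Y)) %*% xc) / sxx
  beta0 <- ym - beta1 * mean(x)
  res <- Y - ym - outer(beta1, xc)
  const_gene <- apply(Y, 1L, sd) == 0
  beta1[const_gene] <- 0
  beta0[const_gene] <- ym[const_gene]
  res[const_gene, ] <- 0
  sigma2 <- unname(rowSums(res^2)) / (n - 2)
  p_beta <- ifelse(sigma2 > 0,
                   2 * pt(-abs(beta1 / sqrt(sigma2 / sxx)), df = n - 2),
                   ifelse(beta1 == 0, 1, 0))
  p_beta[const_gene] <- 1

  absr <- abs(res)
  deg_rho <- apply(absr, 1L, function(v) diff(range(v)) == 0)
  rho <- numeric(nrow(Y))
  p_rho <- rep(1, nrow(Y))
  if (any(!deg_rho)) {
    if (n >= 10) {
      rr <- row_ranks(absr[!deg_rho, , drop = FALSE])
      rx <- rank(x, ties.method = "average")
      rv <- as.vector(cor(t(rr), rx))
      rho[!deg_rho] <- rv
      tt <- rv * sqrt((n - 2) / pmax(1 - rv^2, .Machine$double.eps))
      p_rho[!deg_rho] <- pmin(2 * pt(-abs(tt), df = n - 2), 1)
    } else {
      for (i in which(!deg_rho)) {
        st <- spearman_test(absr[i, ], x)
        rho[i] <- st$rho
        p_rho[i] <- st$p
      }
    }
  }

  tab <- tibble(gene_id = rownames(Y),
                beta0 = beta0, beta1 = beta1,
                p_beta = p_beta, q_beta = adjust_fdr(p_beta),
                rho = rho, p_rho = p_rho, q_rho = adjust_fdr(p_rho),
                n_samples = n,
                degenerate = const_gene | deg_rho)
  structure(list(table = tab, residuals = res, age_days = age_days,
                 age_t = x, dataset = dataset$name, period = dataset$period,
                 meta = dataset$meta),
            class = "dataset_change")
}

#' @export
print.dataset_change <- function(x, ...) {
  cat(sprintf("<dataset_change '%s' [%s]> %d genes, %d samples\n",
              x$dataset, x$period, nrow(x$table), ncol(x$residuals)))
  cat(sprintf("  median beta1 = %.3g, median rho = %.3g, %d genes q_rho < 0.05\n",
              median(x$table$beta1), median(x$table$rho),
              sum(x$table$q_rho < 0.05)))
  invisible(x)
}

#' Fit change models for every dataset of a collection
#'
#' @param collection A [study_collection].
#' @param age_scale Age transform.
#' @return Named list of `dataset_change` objects.
#' @export
fit_collection_changes <- function(collection, age_scale = "fourth_root") {
  lapply(collection, fit_dataset_changes, age_scale = age_scale)
}

#' Write per-dataset change tables as TSV
#'
#' @param fits Named list of `dataset_change` objects.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_change_tables <- function(fits, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(fits), function(nm) {
    p <- file.path(dir, sprintf("%s_%s_changes.tsv", nm, fits[[nm]]$period))
    readr::write_tsv(fits[[nm]]$table, p, progress = FALSE)
    p
  }, character(1))
  invisible(paths)
}
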