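#' Simulation configuration
#'
#' Describes a multi-study collection with the statistical structure the
#' analysis assumes: several studies, each contributing one dataset per brain
#' region with the *same* individuals across its regions; per-gene linear
#' mean trends on the transformed age scale; and per-gene age-dependent
#' residual spread in the aging period for a configurable fraction of genes.
#'
#' Defaults mirror the motivating study design: three sources with 16, 2 and
#' 1 region datasets (19 datasets in total), ages spanning 0-98 years drawn
#' uniformly on the fourth-root-of-days scale and split evenly between the
#' development and aging periods, residual sd 0.5 at baseline, and 5% of
#' genes with heterogeneity increasing over aging with log-sd slopes drawn
#' from (0.5, 1.5).
#'
#' @param regions_per_study Integer vector, one entry per study, giving how
#'   many region datasets that study contributes.
#' @param n_individuals Individuals per study (recycled across studies). Each
#'   individual yields one sample in every region dataset of its study.
#' @param age_range_years Length-2 numeric, youngest and oldest age in years.
#' @param n_genes Number of genes (shared across all datasets).
#' @param frac_het_increase,frac_het_decrease Fractions of genes whose
#'   residual spread increases / decreases with age during aging; the rest
#'   are homoskedastic. Must sum to at most 1.
#' @param beta_params Length-2 numeric `(mean, sd)` of the true per-period
#'   mean-trend slopes (per unit transformed age); each gene draws one slope
#'   per period, shared across all datasets.
#' @param base_sd Residual sd at the age where the standardized transformed
#'   age is zero; must be positive.
#' @param var_slope_range Length-2 numeric; heteroskedastic genes draw their
#'   log-sd-per-standardized-age slope uniformly from this range (negated for
#'   the decreasing class).
#' @param age_cutoff_years Development/aging boundary used when planting the
#'   period-specific heteroskedasticity, default 20.
#' @param seed Integer seed; the same config is bitwise reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(regions_per_study = c(16L, 2L, 1L),
                       n_individuals = 40L,
                       age_range_years = c(0, 98),
                       n_genes = 1000L,
                       frac_het_increase = 0.05,
                       frac_het_decrease = 0,
                       beta_params = c(0, 1),
                       base_sd = 0.5,
                       var_slope_range = c(0.5, 1.5),
                       age_cutoff_years = 20,
                       seed = 1L) {
  cfg <- list(regions_per_study = as.integer(regions_per_study),
              n_individuals = rep_len(as.integer(n_individuals),
                                      length(regions_per_study)),
              age_range_years = as.numeric(age_range_years),
              n_genes = as.integer(n_genes),
              frac_het_increase = frac_het_increase,
              frac_het_decrease = frac_het_decrease,
              beta_params = as.numeric(beta_params),
              base_sd = as.numeric(base_sd),
              var_slope_range = as.numeric(var_slope_range),
              age_cutoff_years = as.numeric(age_cutoff_years),
              seed = as.integer(seed))
  if (any(cfg$regions_per_study < 1)) stop_agevar("regions_per_study must be >= 1")
  if (cfg$base_sd <= 0) stop_agevar("base_sd must be positive")
  if (cfg$frac_het_increase < 0 || cfg$frac_het_decrease < 0 ||
      cfg$frac_het_increase + cfg$frac_het_decrease > 1) {
    stop_agevar("frac_het_increase + frac_het_decrease must lie in [0, 1]")
  }
  if (any(cfg$n_individuals < 8)) {
    stop_agevar("need at least 8 individuals per study (4 per period)")
  }
  if (diff(cfg$age_range_years) <= 0 || any(cfg$age_range_years < 0)) {
    stop_agevar("age_range_years must be an increasing non-negative pair")
  }
  structure(cfg, class = c("sim_config", "list"))
}

#' Simulate one gene's expression profile
#'
#' Generates `Y = beta0 + beta1 * t + eps` over the supplied transformed ages
#' `t`, with Gaussian residuals whose standard deviation is
#' `base_sd * exp(var_slope * z)` where `z` is the standardized transformed
#' age. A positive `var_slope` therefore makes the residual spread strictly
#' increase with age (multiplicative form keeps the sd positive for any
#' slope).
#'
#' @param ages_t Numeric vector of transformed ages (>= 4 values).
#' @param beta1 True mean-trend slope.
#' @param var_slope Log-sd slope per standardized transformed age.
#' @param base_sd Residual sd at the mean age; must be positive.
#' @param beta0 Intercept, default 0.
#' @param seed Optional seed for a reproducible draw.
#' @return Numeric expression vector, one value per age.
#' @export
simulate_gene_profile <- function(ages_t, beta1, var_slope, base_sd,
                                  beta0 = 0, seed = NULL) {
  if (base_sd <= 0) stop_agevar("base_sd must be positive")
  if (length(ages_t) < 4) stop_agevar("need at least 4 ages")
  z <- if (sd(ages_t) > 0) (ages_t - mean(ages_t)) / sd(ages_t) else rep(0, length(ages_t))
  draw <- function() {
    beta0 + beta1 * ages_t + rnorm(length(ages_t), 0, base_sd * exp(var_slope * z))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Ages uniform on the fourth-root-of-days scale, half the individuals below
# the period cutoff and half at/above it so both periods are populated.
sim_ages_days <- function(n, range_years, cutoff_years) {
  lo <- range_years[1] * 365
  hi <- range_years[2] * 365
  cut <- cutoff_years * 365
  if (cut <= lo || cut >= hi) {
    u <- runif(n, lo^0.25, hi^0.25)
    return(round(u^4))
  }
  n_dev <- floor(n / 2)
  u <- c(runif(n_dev, lo^0.25, (cut - 1)^0.25),
         runif(n - n_dev, cut^0.25, hi^0.25))
  ages <- round(u^4)
  pmin(pmax(ages, lo), hi)
}

#' Simulate a multi-study collection
#'
#' Every study draws its own individuals (ages, sexes) once and reuses them
#' in each of its region datasets, so the shared-donor dependence the
#' permutation scheme relies on is present by construction. Gene identities,
#' their heterogeneity classes (increase / decrease / null during aging) and
#' their true per-period slopes are shared across *all* datasets, so
#' cross-dataset consistency is meaningful; the residual noise is drawn
#' independently per dataset.
#'
#' @param config A [sim_config()].
#' @return A [study_collection]; planted gene classes are recorded in the
#'   `"truth"` attribute (tibble with `gene_id`, `het_class`, `var_slope`,
#'   `beta_dev`, `beta_aging`).
#' @export
simulate_collection <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    ng <- config$n_genes
    genes <- sprintf("G%05d", seq_len(ng))
    n_inc <- round(config$frac_het_increase * ng)
    n_dec <- round(config$frac_het_decrease * ng)
    if (n_inc + n_dec > ng) stop_agevar("infeasible heterogeneity fractions")
    classes <- rep("null", ng)
    classes[seq_len(n_inc)] <- "increase"
    if (n_dec > 0) classes[n_inc + seq_len(n_dec)] <- "decrease"
    vs <- numeric(ng)
    vs[classes == "increase"] <- runif(n_inc, config$var_slope_range[1],
                                       config$var_slope_range[2])
    vs[classes == "decrease"] <- -runif(n_dec, config$var_slope_range[1],
                                        config$var_slope_range[2])
    beta0 <- rnorm(ng, 0, 1)
    beta_dev <- rnorm(ng, config$beta_params[1], config$beta_params[2])
    beta_aging <- rnorm(ng, config$beta_params[1], config$beta_params[2])
    t_cut <- (config$age_cutoff_years * 365)^0.25

    datasets <- list()
    for (s in seq_along(config$regions_per_study)) {
      study <- sprintf("study%d", s)
      n_ind <- config$n_individuals[s]
      ind_ids <- sprintf("%s_i%03d", study, seq_len(n_ind))
      ages <- sim_ages_days(n_ind, config$age_range_years,
                            config$age_cutoff_years)
      sexes <- sample(c("female", "male"), n_ind, replace = TRUE)
      t_age <- ages^0.25
      is_aging <- ages / 365 >= config$age_cutoff_years
      # period-wise standardized transformed age drives the planted
      # heteroskedasticity (aging period only; development is homoskedastic)
      z <- rep(0, n_ind)
      if (sum(is_aging) >= 2) {
        ta <- t_age[is_aging]
        z[is_aging] <- (ta - mean(ta)) / sd(ta)
      }
      mu_gene <- outer(beta0, rep(1, n_ind)) +
        outer(beta_dev, ifelse(is_aging, 0, t_age - t_cut)) +
        outer(beta_aging, ifelse(is_aging, t_age - t_cut, 0))
      for (r in seq_len(config$regions_per_study[s])) {
        region <- sprintf("region%02d", r)
        sd_mat <- config$base_sd * exp(outer(vs, z))
        sd_mat[, !is_aging] <- config$base_sd
        noise <- matrix(rnorm(ng * n_ind), ng, n_ind) * sd_mat
        expr <- mu_gene + noise
        sample_ids <- paste(study, region, ind_ids, sep = ".")
        dimnames(expr) <- list(genes, sample_ids)
        meta <- tibble(sample_id = sample_ids, individual_id = ind_ids,
                       age_days = as.numeric(ages), sex = sexes,
                       region = region, study = study, batch = "")
        nm <- paste(study, region, sep = "_")
        datasets[[nm]] <- expr_dataset(expr, meta, name = nm)
      }
    }
    out <- study_collection(datasets)
    attr(out, "truth") <- tibble(gene_id = genes, het_class = classes,
                                 var_slope = vs, beta_dev = beta_dev,
                                 beta_aging = beta_aging)
    out
  })
}
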