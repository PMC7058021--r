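# Downstream association analyses: regulator counts, protein-interaction
# degree, cell-type specificity and deconvolution, and sex effects on
# residuals.

#' Regulator-count association with heterogeneity change
#'
#' Tests whether genes with more distinct regulators (TFs or miRNAs) show a
#' larger age-related heterogeneity increase, and whether that association is
#' stronger in aging than in development. Per dataset the association is the
#' Spearman correlation between the heterogeneity change (rho) and the
#' regulator count; the cross-period statistic is the fraction of matched
#' datasets whose aging correlation exceeds the development correlation, with
#' a null built by randomizing the regulator counts across genes (one shared
#' randomization applied to every dataset per iteration).
#'
#' @param dev_fits,aging_fits Named lists of `dataset_change` objects with
#'   matching names.
#' @param regulator_counts Named integer vector, gene id -> number of
#'   distinct regulators.
#' @param n_perm Count randomizations, default 1000.
#' @param seed Integer seed.
#' @return List with `per_dataset` (tibble: `dataset`, `period`,
#'   `correlation`), `observed_fraction`, `p` (one-sided, greater).
#' @export
regulator_count_association <- function(dev_fits, aging_fits, regulator_counts,
                                        n_perm = 1000, seed = 1L) {
  genes <- fits_genes(aging_fits)
  counts <- regulator_counts[genes]
  if (all(is.na(counts))) stop_agevar("regulator counts share no genes with the fits")
  counts[is.na(counts)] <- 0
  if (sd(counts) == 0) {
    rlang::warn("regulator counts are constant; correlations undefined, returning 0")
  }
  common <- intersect(names(dev_fits), names(aging_fits))
  if (length(common) < 2) stop_agevar("need >= 2 matched datasets per period")
  cor_with <- function(fits_list, v) {
    vapply(fits_list, function(f) {
      if (sd(v) == 0) return(0)
      suppressWarnings(cor(f$table$rho, v, method = "spearman"))
    }, numeric(1))
  }
  cor_dev <- cor_with(dev_fits[common], counts)
  cor_aging <- cor_with(aging_fits[common], counts)
  observed <- mean(cor_aging > cor_dev)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    shuf <- sample(counts)
    mean(cor_with(aging_fits[common], shuf) > cor_with(dev_fits[common], shuf))
  }, numeric(1)))
  per_dataset <- bind_rows(
    tibble(dataset = common, period = "development", correlation = cor_dev),
    tibble(dataset = common, period = "aging", correlation = cor_aging))
  list(per_dataset = per_dataset, observed_fraction = observed,
       p = empirical_p(null, observed, "greater"))
}

fits_genes <- function(fits) fits[[1]]$table$gene_id

#' Read a protein-interaction edge list
#'
#' @param path TSV with columns `gene_a`, `gene_b`, `combined_score`
#'   (integer confidence 0-1000). Self-loops are dropped.
#' @return Tibble of edges.
#' @export
read_interaction_network <- function(path) {
  edges <- readr::read_tsv(path, col_types = readr::cols(
    gene_a = "c", gene_b = "c", combined_score = "d"), progress = FALSE)
  filter(edges, .data$gene_a != .data$gene_b)
}

#' Interaction-degree resampling test
#'
#' Asks whether a target gene list is more central in the interaction
#' network than random gene sets of the same size: degrees are computed on
#' edges at or above the confidence cutoff, and the observed median target
#' degree is compared with medians of `n_samples` random draws of the same
#' number of genes from the network.
#'
#' @param target_genes Character vector of genes of interest.
#' @param network Edge tibble (`gene_a`, `gene_b`, `combined_score`).
#' @param score_cutoff Minimum confidence score (edges with
#'   `combined_score >= cutoff` are kept).
#' @param n_samples Random samples, default 10000.
#' @param seed Integer seed.
#' @return List with `median_degree`, `p` (one-sided, greater), `k` (targets
#'   found in the filtered network), `null_medians`.
#' @export
ppi_degree_test <- function(target_genes, network, score_cutoff = 400,
                            n_samples = 10000, seed = 1L) {
  edges <- filter(network, .data$combined_score >= score_cutoff)
  if (nrow(edges) == 0) stop_agevar("no edges at score cutoff %s", score_cutoff)
  deg_tab <- table(c(edges$gene_a, edges$gene_b))
  nodes <- names(deg_tab)
  degrees <- as.numeric(deg_tab)
  targets <- intersect(target_genes, nodes)
  k <- length(targets)
  if (k == 0) stop_agevar("no target genes in the network (k = 0)")
  observed <- median(degrees[match(targets, nodes)])
  null <- with_seed(seed, vapply(seq_len(n_samples), function(i) {
    median(degrees[sample.int(length(nodes), k)])
  }, numeric(1)))
  list(median_degree = observed, p = empirical_p(null, observed, "greater"),
       k = k, null_medians = null)
}

#' Read cell-type expression profiles
#'
#' @param path TSV with first column `gene_id` and one column per cell-type
#'   replicate, named `<celltype>.<replicate>` (e.g. `astrocyte.1`).
#' @return List with `expr` (genes x replicates matrix), `cell_type`
#'   (character per column).
#' @export
read_cell_type_profiles <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  genes <- raw$gene_id
  m <- apply(as.matrix(raw[, -1]), 2L, as.numeric)
  rownames(m) <- genes
  list(expr = m, cell_type = sub("\\.[^.]*$", "", colnames(m)))
}

#' Cell-type specific genes by effect size
#'
#' Per gene and cell type, Cohen's D of that cell type's replicates against
#' all other replicates pooled (mean difference over pooled sd, n - 1);
#' genes with `D >= 2` are called specific to the cell type. Lists are not
#' forced to be disjoint -- at this stringent cutoff they typically are.
#'
#' @param profiles List as from [read_cell_type_profiles()] (replicate-level
#'   matrix + cell-type labels); >= 2 replicates per cell type.
#' @param d_cutoff Effect-size threshold, default 2 (boundary included).
#' @return Tibble with `gene_id`, `cell_type`, `cohens_d`, `specific`.
#'   Genes with zero pooled sd in a comparison are flagged `NA` and excluded
#'   from specificity calls.
#' @export
cell_type_specific_genes <- function(profiles, d_cutoff = 2) {
  m <- profiles$expr
  ct <- profiles$cell_type
  if (any(table(ct) < 2)) stop_agevar("need >= 2 replicates per cell type")
  res <- lapply(unique(ct), function(cc) {
    d <- apply(m, 1L, function(v) cohens_d(v[ct == cc], v[ct != cc]))
    tibble(gene_id = rownames(m), cell_type = cc, cohens_d = d,
           specific = !is.na(d) & d >= d_cutoff)
  })
  bind_rows(res)
}

#' Cohen's D of a group against the rest
#'
#' Mean difference divided by the pooled standard deviation (n - 1 within
#' each group). Antisymmetric: swapping group and rest flips the sign.
#'
#' @param group,rest Numeric vectors (>= 2 values each).
#' @return Effect size, or `NA` when the pooled sd is zero.
#' @export
cohens_d <- function(group, rest) {
  n1 <- length(group); n2 <- length(rest)
  if (n1 < 2 || n2 < 2) stop_agevar("both groups need >= 2 values")
  sp2 <- ((n1 - 1) * var(group) + (n2 - 1) * var(rest)) / (n1 + n2 - 2)
  if (sp2 == 0) return(NA_real_)
  (mean(group) - mean(rest)) / sqrt(sp2)
}

#' Fisher's exact overlap test between two gene sets
#'
#' @param set_a,set_b Character vectors, both subsets of `universe`.
#' @param universe Character vector of all eligible genes.
#' @return List with `odds_ratio`, `p` (two-sided), `table` (2x2 counts).
#' @export
gene_set_overlap_test <- function(set_a, set_b, universe) {
  if (length(universe) == 0) stop_agevar("empty universe")
  set_a <- intersect(set_a, universe)
  set_b <- intersect(set_b, universe)
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  tab <- table(factor(in_a, c(TRUE, FALSE)), factor(in_b, c(TRUE, FALSE)))
  ft <- fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}

#' Deconvolve a bulk sample into cell-type contributions
#'
#' Ordinary least squares of the sample's per-gene expression on cell-type
#' mean profiles plus an intercept:
#' `Expr = a + sum_c beta_c * profile_c + eps`. The coefficients estimate
#' the relative contribution of each cell type; applied across samples, the
#' per-sample coefficient series can be fed back into
#' [fit_expression_change()] / [heterogeneity_change()] to ask whether
#' cell-type composition changes or becomes heterogeneous with age.
#'
#' @param sample_expr Named numeric vector of per-gene expression (positive
#'   scale recommended).
#' @param profiles Genes x cell-types matrix of mean profiles (replicates
#'   averaged), rownames matching `sample_expr` genes.
#' @return List with `coefficients` (named per cell type), `intercept`,
#'   `residuals`.
#' @export
deconvolve_cell_types <- function(sample_expr, profiles) {
  check_numeric_matrix(profiles, "profiles")
  genes <- intersect(names(sample_expr), rownames(profiles))
  if (length(genes) < ncol(profiles) + 1) {
    stop_agevar("need at least %d shared genes", ncol(profiles) + 1)
  }
  X <- profiles[genes, , drop = FALSE]
  qx <- qr(cbind(1, X))
  if (qx$rank < ncol(X) + 1) {
    cc <- cor(X)
    diag(cc) <- 0
    pair <- which(abs(cc) > 0.999999, arr.ind = TRUE)
    hint <- if (nrow(pair) > 0) {
      paste(colnames(X)[pair[1, ]], collapse = " ~ ")
    } else "unknown"
    stop_agevar("cell-type profiles are rank deficient (collinear: %s)", hint)
  }
  fit <- lm(sample_expr[genes] ~ X)
  co <- coef(fit)
  list(coefficients = setNames(co[-1], colnames(X)),
       intercept = unname(co[1]),
       residuals = unname(resid(fit)))
}

#' Per-gene sex differences in signed residuals
#'
#' Two-sample Wilcoxon rank-sum test on the *signed* residuals of each gene,
#' female vs male: a significant shift means the sexes follow different
#' expression trajectories around the common age trend, which could
#' masquerade as inter-individual heterogeneity. Exact null for combined
#' n <= 20 without ties, normal approximation with continuity correction
#' otherwise; BH adjustment across genes.
#'
#' @param fit A `dataset_change` object.
#' @return Tibble with `gene_id`, `p`, `q`, `skipped` (genes with one sex
#'   absent or all residuals equal).
#' @export
sex_difference_check <- function(fit) {
  sex <- fit$meta$sex
  f <- sex == "female"
  m <- sex == "male"
  if (sum(f) < 2 || sum(m) < 2) {
    return(tibble(gene_id = fit$table$gene_id, p = NA_real_, q = NA_real_,
                  skipped = TRUE))
  }
  n_tot <- sum(f) + sum(m)
  p <- unname(apply(fit$residuals, 1L, function(r) {
    rf <- r[f]; rm <- r[m]
    if (diff(range(c(rf, rm))) == 0) return(NA_real_)
    exact <- n_tot <= 20 && !any(duplicated(c(rf, rm)))
    suppressWarnings(wilcox.test(rf, rm, exact = exact, correct = TRUE)$p.value)
  }))
  skipped <- is.na(p)
  q <- rep(NA_real_, length(p))
  q[!skipped] <- adjust_fdr(p[!skipped])
  tibble(gene_id = fit$table$gene_id, p = p, q = q, skipped = skipped)
}
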