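#' Quantile normalize an expression matrix
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' reference is the vector of row-wise means of the column-sorted matrix, and
#' each column's values are replaced by the reference value at their rank.
#' Ties within a column all receive the mean of the reference values over
#' their tied rank span.
#'
#' @param m Numeric genes x samples matrix.
#' @return Matrix of the same shape and dimnames; every column has the same
#'   sorted value multiset.
#' @export
quantile_normalize <- function(m) {
  check_numeric_matrix(m, "expression matrix")
  ref <- rowMeans(apply(m, 2L, sort))
  cs <- c(0, cumsum(ref))
  out <- apply(m, 2L, function(x) {
    lo <- rank(x, ties.method = "min")
    hi <- rank(x, ties.method = "max")
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Remove batch effects by within-batch standardization
#'
#' Per gene: compute the grand mean M across all samples, standardize each
#' batch separately to mean 0 and sd 1 (sample sd, n - 1), then add M back.
#' After the transform every batch has mean M for every gene, so batch-level
#' location and scale differences are removed while the grand mean is kept.
#'
#' @param m Numeric genes x samples matrix.
#' @param batch_labels Character/factor of length `ncol(m)`.
#' @return Matrix of the same shape.
#' @export
batch_mean_restore <- function(m, batch_labels) {
  check_numeric_matrix(m, "expression matrix")
  if (length(batch_labels) != ncol(m)) {
    stop_agevar("batch_labels must have one entry per sample")
  }
  batch_labels <- as.character(batch_labels)
  sizes <- table(batch_labels)
  if (any(sizes < 2)) {
    stop_agevar("batch(es) with fewer than 2 samples: %s",
                paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  grand <- rowMeans(m)
  out <- m
  for (b in unique(batch_labels)) {
    idx <- which(batch_labels == b)
    sub <- m[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    s <- apply(sub, 1L, sd)
    if (any(s == 0)) {
      g <- rownames(m)[which(s == 0)[1]] %||% which(s == 0)[1]
      stop_agevar("zero within-batch variance for gene '%s' in batch '%s'", g, b)
    }
    out[, idx] <- (sub - mu) / s + grand
  }
  out
}

#' Scale genes to mean 0, sd 1
#'
#' Row-wise standardization (sample sd, n - 1). Downstream slopes are
#' therefore in units of within-gene standard deviations per unit transformed
#' age, making genes comparable.
#'
#' @param m Numeric genes x samples matrix.
#' @return Matrix with every row at mean 0, sd 1.
#' @export
scale_genes <- function(m) {
  check_numeric_matrix(m, "expression matrix")
  s <- apply(m, 1L, sd)
  if (any(s == 0)) {
    bad <- rownames(m)[s == 0] %||% which(s == 0)
    stop_agevar("constant gene(s), cannot scale: %s",
                paste(head(bad, 5), collapse = ", "))
  }
  out <- (m - rowMeans(m)) / s
  dimnames(out) <- dimnames(m)
  out
}

#' Transform age to the modelling scale
#'
#' The default fourth-root-of-days scale spreads samples roughly uniformly
#' over the human lifespan, giving an approximately linear age-expression
#' relationship in both periods; the alternatives support sensitivity
#' analyses.
#'
#' @param age_days Numeric vector of ages in days (>= 0).
#' @param scale One of `"fourth_root"` (default), `"linear"`, `"sqrt"`,
#'   `"log2"` (computed as `log2(age_days + 1)` so age 0 stays finite).
#' @return Numeric vector of transformed ages.
#' @export
transform_age <- function(age_days, scale = c("fourth_root", "linear", "sqrt", "log2")) {
  scale <- match.arg(scale)
  if (any(age_days < 0)) stop_agevar("age_days must be non-negative")
  switch(scale,
    fourth_root = age_days^0.25,
    linear = age_days,
    sqrt = sqrt(age_days),
    log2 = log2(age_days + 1)
  )
}

#' Split a dataset into development and aging periods
#'
#' Samples younger than `cutoff_years` form the development dataset; samples
#' at or above the cutoff form the aging dataset (the boundary age belongs to
#' aging so each sample has exactly one period). Age in years is
#' `age_days / 365`.
#'
#' @param dataset An [expr_dataset].
#' @param cutoff_years Period boundary, default 20.
#' @return Named list with elements `development` and `aging`, each an
#'   [expr_dataset] (possibly with zero samples, with a warning).
#' @export
split_periods <- function(dataset, cutoff_years = 20) {
  stopifnot(inherits(dataset, "expr_dataset"))
  yrs <- dataset$meta$age_days / 365
  take <- function(idx, period) {
    if (length(idx) == 0) {
      rlang::warn(sprintf("dataset '%s': empty %s period", dataset$name, period))
      empty <- dataset
      empty$expr <- dataset$expr[, idx, drop = FALSE]
      empty$meta <- dataset$meta[idx, , drop = FALSE]
      empty$period <- period
      return(empty)
    }
    sub <- dataset
    sub$expr <- dataset$expr[, idx, drop = FALSE]
    sub$meta <- dataset$meta[idx, , drop = FALSE]
    sub$period <- period
    sub
  }
  list(development = take(which(yrs < cutoff_years), "development"),
       aging = take(which(yrs >= cutoff_years), "aging"))
}

#' Split every dataset of a collection into periods
#'
#' @param collection A [study_collection].
#' @param cutoff_years Period boundary, default 20.
#' @return List with `development` and `aging`, each a [study_collection]
#'   containing the non-empty period datasets (names preserved).
#' @export
split_collection_periods <- function(collection, cutoff_years = 20) {
  parts <- suppressWarnings(
    lapply(collection, split_periods, cutoff_years = cutoff_years)
  )
  pick <- function(period) {
    ds <- lapply(parts, `[[`, period)
    ds <- ds[vapply(ds, function(d) ncol(d$expr) > 0, logical(1))]
    if (length(ds) == 0) stop_agevar("no dataset has samples in the %s period", period)
    study_collection(ds)
  }
  suppressWarnings(list(development = pick("development"), aging = pick("aging")))
}
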