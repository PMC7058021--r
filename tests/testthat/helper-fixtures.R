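# Shared fixture builders; everything is generated in code at test time.

toy_meta <- function(sample_ids, ages_years, study = "s1", region = "r1",
                     individual_ids = NULL, sex = NULL, batch = "") {
  tibble::tibble(
    sample_id = sample_ids,
    individual_id = individual_ids %||% paste0("i_", sample_ids),
    age_days = ages_years * 365,
    sex = sex %||% rep("unknown", length(sample_ids)),
    region = region, study = study, batch = batch)
}

toy_dataset <- function(n_genes = 5, ages_years = c(1, 10, 25, 40, 60, 80),
                        seed = 1, study = "s1", region = "r1", name = "toy") {
  withr::with_seed(seed, {
    n <- length(ages_years)
    m <- matrix(rnorm(n_genes * n), n_genes, n,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                sprintf("%s_smp%02d", name, seq_len(n))))
    agevar::expr_dataset(m, toy_meta(colnames(m), ages_years, study, region),
                         name = name)
  })
}

# a minimal dataset_change-like object for trajectory tests
fake_fit <- function(absres, age_t, name = "ds1") {
  res <- absres  # signs irrelevant downstream (abs is taken)
  meta <- toy_meta(colnames(absres) %||% paste0("s", seq_len(ncol(absres))),
                   ages_years = (age_t^4) / 365)
  structure(list(residuals = res, age_t = age_t, age_days = age_t^4,
                 meta = meta, dataset = name, period = "aging",
                 table = tibble::tibble(gene_id = rownames(absres))),
            class = "dataset_change")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force permutation enumerator, independent oracle for exact
# rank-statistic p-values
gtools_perm <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_perm(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1))
  }))
}
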