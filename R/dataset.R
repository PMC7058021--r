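#' Expression dataset container
#'
#' Bundles a genes x samples matrix of (log scale, typically quantile
#' normalized) expression values with per-sample metadata. One
#' `expr_dataset` is one study x brain-region dataset, the unit of analysis
#' throughout the package.
#'
#' @param expr Numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids).
#' @param meta Data frame with one row per sample, columns `sample_id`,
#'   `individual_id`, `age_days`, `sex` (`"female"`, `"male"` or `"unknown"`),
#'   `region`, `study` and `batch` (may be empty strings). Rows are matched to
#'   matrix columns by `sample_id`.
#' @param name Dataset label, e.g. `"study1_pfc"`.
#' @param period One of `"full"`, `"development"`, `"aging"`.
#'
#' @return An object of class `expr_dataset`: a list with elements `expr`,
#'   `meta` (tibble ordered as the matrix columns), `name`, `period`.
#' @export
expr_dataset <- function(expr, meta, name = "dataset", period = "full") {
  check_numeric_matrix(expr, "expr")
  period <- match.arg(period, c("full", "development", "aging"))
  meta <- as_tibble(meta)
  required <- c("sample_id", "individual_id", "age_days", "sex", "region",
                "study", "batch")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    stop_agevar("metadata is missing column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop_agevar("expression matrix needs gene rownames and sample colnames")
  }
  dup <- unique(rownames(expr)[duplicated(rownames(expr))])
  if (length(dup) > 0) {
    stop_agevar("duplicate gene id(s): %s", paste(head(dup, 5), collapse = ", "))
  }
  absent <- setdiff(colnames(expr), meta$sample_id)
  if (length(absent) > 0) {
    stop_agevar("sample(s) missing from metadata: %s",
                paste(head(absent, 5), collapse = ", "))
  }
  meta <- meta[match(colnames(expr), meta$sample_id), , drop = FALSE]
  if (anyDuplicated(meta$sample_id)) {
    stop_agevar("duplicated sample_id in metadata")
  }
  if (any(meta$age_days < 0)) stop_agevar("age_days must be non-negative")
  if (anyNA(expr)) stop_agevar("expression matrix contains missing values")
  bad_sex <- setdiff(unique(meta$sex), c("female", "male", "unknown"))
  if (length(bad_sex) > 0) {
    stop_agevar("sex must be female/male/unknown, found: %s",
                paste(bad_sex, collapse = ", "))
  }
  # samples of one individual must agree on age and sex
  chk <- meta |>
    group_by(.data$individual_id) |>
    summarise(ok = n_distinct(.data$age_days) == 1 & n_distinct(.data$sex) == 1,
              .groups = "drop")
  if (!all(chk$ok)) {
    stop_agevar("individual(s) with inconsistent age or sex: %s",
                paste(head(chk$individual_id[!chk$ok], 5), collapse = ", "))
  }
  structure(list(expr = expr, meta = meta, name = name, period = period),
            class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("<expr_dataset '%s'> %d genes x %d samples [%s]\n",
              x$name, nrow(x$expr), ncol(x$expr), x$period))
  cat(sprintf("  ages %.1f-%.1f years, %d individuals, study '%s'\n",
              min(x$meta$age_days) / 365, max(x$meta$age_days) / 365,
              n_distinct(x$meta$individual_id), x$meta$study[1]))
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$expr)

#' Study collection
#'
#' A named list of [expr_dataset] objects. Datasets belonging to the same
#' study (equal `study` metadata) are assumed to share individuals across
#' regions; individuals appearing in several datasets of one study must carry
#' identical ages, which is validated here. This shared-donor structure is
#' what the individual-level permutation scheme preserves.
#'
#' @param datasets Named list of [expr_dataset] objects.
#' @return Object of class `study_collection` (a named list).
#' @export
study_collection <- function(datasets) {
  if (length(datasets) < 1) stop_agevar("need at least one dataset")
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    names(datasets) <- vapply(datasets, function(d) d$name, character(1))
  }
  stopifnot(all(vapply(datasets, inherits, logical(1), "expr_dataset")))
  ind <- purrr::map_dfr(datasets, function(d) {
    distinct(d$meta, .data$study, .data$individual_id, .data$age_days)
  })
  bad <- ind |>
    group_by(.data$study, .data$individual_id) |>
    summarise(n_ages = n_distinct(.data$age_days), .groups = "drop") |>
    filter(.data$n_ages > 1)
  if (nrow(bad) > 0) {
    stop_agevar("individual(s) with conflicting ages across datasets of one study: %s",
                paste(head(bad$individual_id, 5), collapse = ", "))
  }
  structure(datasets, class = c("study_collection", "list"))
}

#' @export
print.study_collection <- function(x, ...) {
  studies <- vapply(x, function(d) d$meta$study[1], character(1))
  cat(sprintf("<study_collection> %d datasets from %d studies\n",
              length(x), n_distinct(studies)))
  for (nm in names(x)) {
    cat(sprintf("  %-24s %5d genes x %4d samples [%s]\n", nm,
                nrow(x[[nm]]$expr), ncol(x[[nm]]$expr), x[[nm]]$period))
  }
  invisible(x)
}

#' Map datasets to their study
#' @param collection A [study_collection].
#' @return Named character vector, dataset name -> study.
#' @export
study_of <- function(collection) {
  vapply(collection, function(d) d$meta$study[1], character(1))
}

#' Read one expression dataset from TSV files
#'
#' The expression matrix TSV has a first column `gene_id` and one column per
#' sample; the metadata TSV has one row per sample with columns `sample_id`,
#' `individual_id`, `age_days`, `sex`, `region`, `study`, `batch`.
#'
#' @param expr_path Path to the expression TSV.
#' @param meta_path Path to the metadata TSV.
#' @param exclude Optional path to a sample exclusion list (one sample_id per
#'   line), or a character vector of sample ids; applied before validation.
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` to the matrix (for
#'   inputs delivered on the linear scale).
#' @param min_median_expression If non-`NULL`, drop genes whose median value
#'   is at or below this threshold (generic analogue of excluding genes with
#'   median RPKM of zero in RNA-seq inputs).
#' @param name,period Passed to [expr_dataset()].
#' @return An [expr_dataset].
#' @export
read_expression_dataset <- function(expr_path, meta_path, exclude = NULL,
                                    log2_transform = FALSE,
                                    min_median_expression = NULL,
                                    name = NULL, period = "full") {
  raw <- readr::read_tsv(expr_path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (names(raw)[1] != "gene_id") {
    stop_agevar("first column of %s must be 'gene_id'", expr_path)
  }
  genes <- raw$gene_id
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    stop_agevar("duplicate gene id(s) in %s: %s", expr_path,
                paste(head(dup, 5), collapse = ", "))
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num) && !all(is.na(num) == is.na(vals))) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1, ]
    stop_agevar("non-numeric value at gene '%s', sample '%s' in %s",
                genes[bad[1]], colnames(vals)[bad[2]], expr_path)
  }
  dimnames(num) <- list(genes, colnames(vals))
  meta <- readr::read_tsv(meta_path, col_types = readr::cols(
    sample_id = "c", individual_id = "c", age_days = "d", sex = "c",
    region = "c", study = "c", batch = "c"), progress = FALSE)
  meta$batch[is.na(meta$batch)] <- ""
  if (!is.null(exclude)) {
    ids <- if (length(exclude) == 1 && file.exists(exclude)) {
      readLines(exclude, warn = FALSE)
    } else {
      as.character(exclude)
    }
    ids <- ids[nzchar(ids)]
    num <- num[, !(colnames(num) %in% ids), drop = FALSE]
    meta <- meta[!(meta$sample_id %in% ids), , drop = FALSE]
  }
  if (log2_transform) num <- log2(num + 1)
  if (!is.null(min_median_expression)) {
    keep <- apply(num, 1L, stats::median) > min_median_expression
    num <- num[keep, , drop = FALSE]
  }
  if (is.null(name)) {
    name <- sub("\\.(tsv|txt)$", "", basename(expr_path))
  }
  expr_dataset(num, meta, name = name, period = period)
}

#' Write an expression dataset as TSV files
#'
#' Inverse of [read_expression_dataset()]; the pair round-trips exactly up to
#' numeric printing precision.
#'
#' @param dataset An [expr_dataset].
#' @param expr_path,meta_path Output paths.
#' @return Invisibly, the dataset.
#' @export
write_expression_dataset <- function(dataset, expr_path, meta_path) {
  tab <- as_tibble(dataset$expr, rownames = "gene_id")
  readr::write_tsv(tab, expr_path, progress = FALSE)
  readr::write_tsv(dataset$meta, meta_path, progress = FALSE)
  invisible(dataset)
}

#' Write / read a whole collection
#'
#' Each dataset becomes `<name>_expr.tsv` + `<name>_meta.tsv` in `dir`.
#'
#' @param collection A [study_collection].
#' @param dir Directory (created if needed).
#' @return `write_collection()`: invisibly the collection;
#'   `read_collection()`: a [study_collection].
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(collection)) {
    write_expression_dataset(collection[[nm]],
                             file.path(dir, paste0(nm, "_expr.tsv")),
                             file.path(dir, paste0(nm, "_meta.tsv")))
  }
  invisible(collection)
}

#' @rdname write_collection
#' @export
read_collection <- function(dir) {
  expr_files <- sort(list.files(dir, pattern = "_expr\\.tsv$", full.names = TRUE))
  if (length(expr_files) == 0) stop_agevar("no *_expr.tsv files in %s", dir)
  datasets <- lapply(expr_files, function(f) {
    nm <- sub("_expr\\.tsv$", "", basename(f))
    read_expression_dataset(f, file.path(dir, paste0(nm, "_meta.tsv")),
                            name = nm)
  })
  names(datasets) <- vapply(datasets, function(d) d$name, character(1))
  study_collection(datasets)
}

#' Restrict all datasets to their common genes
#'
#' Cross-dataset consistency statistics are defined on genes measured in every
#' dataset; this restricts each matrix to that intersection, in one canonical
#' (sorted) order.
#'
#' @param collection A [study_collection].
#' @return The collection with every dataset subset to the shared genes.
#' @export
intersect_common_genes <- function(collection) {
  gene_lists <- lapply(collection, function(d) rownames(d$expr))
  common <- Reduce(intersect, gene_lists)
  if (length(common) == 0) stop_agevar("datasets share no genes")
  common <- sort(common)
  out <- lapply(collection, function(d) {
    d$expr <- d$expr[common, , drop = FALSE]
    d
  })
  study_collection(out)
}
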