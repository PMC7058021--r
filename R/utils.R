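# Internal helpers shared across modules.

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a stage seed from a global seed; keeps results < 2^31 and decoupled
# across stages so adding a stage does not shift the streams of the others.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483563) + 1L
}

stop_agevar <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "agevar_error")
}

check_numeric_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_agevar("%s must be a numeric matrix", what)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop_agevar("%s must have at least one row and one column", what)
  }
  invisible(x)
}

# Empirical one-sided p-value with the +1 correction so p is never zero;
# at 1,000 permutations the floor is 1/1001, matching "p < 0.001" reporting.
empirical_p <- function(null, observed, tail = c("greater", "less")) {
  tail <- match.arg(tail)
  null <- null[!is.na(null)]
  hits <- if (tail == "greater") sum(null >= observed) else sum(null <= observed)
  (1 + hits) / (length(null) + 1)
}

# rank() per row of a matrix, mid-ranks for ties.
row_ranks <- function(m) {
  t(apply(m, 1L, rank, ties.method = "average"))
}

# All permutations of seq_len(n), one per row. Used for exact small-sample
# Spearman p-values; guarded to n <= 9 (9! = 362,880 rows).
all_permutations <- function(n) {
  stopifnot(n >= 1L, n <= 9L)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}
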