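# Preranked gene set enrichment on consistency counts (or per-dataset rho),
# with the weighted Kolmogorov-Smirnov running-sum statistic and a
# tie-robustness rerun for integer-valued rankings.

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (set name, description, member genes per
#'   line, tab separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Filter gene sets to a score universe and size bounds
#'
#' @param sets Named list of gene id vectors.
#' @param universe Character vector of genes with scores.
#' @param min_size,max_size Size bounds applied after restricting each set to
#'   the universe (5-500 for pathway/ontology sets, 10-500 for regulator
#'   target sets in the default analyses).
#' @return Filtered named list; skipped sets are reported via a message.
#' @export
filter_gene_sets <- function(sets, universe, min_size = 5, max_size = 500) {
  trimmed <- lapply(sets, intersect, y = universe)
  sizes <- lengths(trimmed)
  keep <- sizes >= min_size & sizes <= max_size
  if (any(!keep)) {
    rlang::inform(sprintf("skipping %d gene set(s) outside size bounds [%d, %d]",
                          sum(!keep), min_size, max_size))
  }
  trimmed[keep]
}

# Weighted KS running-sum enrichment score on an already-ordered ranking.
# hit increments proportional to |score|^weight (normalized within the set),
# uniform miss decrements; ES is the extremum of the running deviation.
gsea_es <- function(scores_sorted, hit, weight = 1) {
  n <- length(scores_sorted)
  nh <- sum(hit)
  w <- abs(scores_sorted)^weight
  wh <- sum(w[hit])
  inc <- if (wh == 0) as.numeric(hit) / nh else ifelse(hit, w, 0) / wh
  dev <- cumsum(inc) - cumsum(!hit) / (n - nh)
  dev[which.max(abs(dev))]
}

#' Preranked gene set enrichment analysis
#'
#' Genes are sorted by score (descending); each set's enrichment score (ES)
#' is the extremum of a running sum that increases by `|score|^weight`
#' (normalized within the set) at member genes and decreases uniformly at
#' non-members. The null is a gene-label permutation: member positions are
#' redrawn at random `n_perm` times. The normalized enrichment score (NES)
#' is the ES divided by the mean magnitude of same-sign permutation scores,
#' the p-value is one-sided among same-sign permutation scores, and q-values
#' are BH-adjusted across sets. Permutation nulls are shared across sets of
#' equal size (the null depends only on set size for a fixed ranking).
#'
#' @param scores Named numeric vector, gene id -> ranking score.
#' @param sets Named list of gene sets.
#' @param weight KS weight exponent; 1 (default) is standard preranked GSEA,
#'   0 gives the classical unweighted KS statistic.
#' @param n_perm Gene-label permutations, default 1000.
#' @param seed Integer seed.
#' @param min_size,max_size Set size bounds (see [filter_gene_sets()]).
#' @return Tibble with `set`, `size`, `ES`, `NES`, `p`, `q`, sorted by p.
#' @export
preranked_gsea <- function(scores, sets, weight = 1, n_perm = 1000, seed = 1L,
                           min_size = 5, max_size = 500) {
  if (is.null(names(scores))) stop_agevar("scores must be a named vector")
  sets <- filter_gene_sets(sets, names(scores), min_size, max_size)
  if (length(sets) == 0) {
    return(tibble(set = character(0), size = integer(0), ES = numeric(0),
                  NES = numeric(0), p = numeric(0), q = numeric(0)))
  }
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  genes_sorted <- names(scores)[ord]
  n <- length(scores)

  es_obs <- vapply(sets, function(g) {
    gsea_es(s_sorted, genes_sorted %in% g, weight)
  }, numeric(1))
  sizes <- lengths(sets)

  with_seed(seed, {
    null_by_size <- lapply(sort(unique(sizes)), function(sz) {
      vapply(seq_len(n_perm), function(i) {
        hit <- logical(n)
        hit[sample.int(n, sz)] <- TRUE
        gsea_es(s_sorted, hit, weight)
      }, numeric(1))
    })
  })
  names(null_by_size) <- as.character(sort(unique(sizes)))

  res <- purrr::imap(sets, function(g, nm) {
    es <- es_obs[[nm]]
    null <- null_by_size[[as.character(length(g))]]
    same <- null[sign(null) == sign(es)]
    if (length(same) == 0) {
      nes <- 0
      p <- 1 / (n_perm + 1)
    } else {
      nes <- es / mean(abs(same))
      p <- (1 + sum(abs(same) >= abs(es))) / (length(same) + 1)
    }
    tibble(set = nm, size = length(g), ES = es, NES = nes, p = p)
  })
  out <- bind_rows(res)
  out$q <- adjust_fdr(out$p)
  arrange(out, .data$p)
}

#' Tie-robustness of GSEA on an integer-valued ranking
#'
#' Consistency counts are small integers, so the ranking carries large tie
#' blocks and the running-sum statistic depends on how ties are ordered.
#' Each repetition re-breaks ties by an independent random shuffle within
#' tie blocks, reruns the enrichment analysis (with a fixed internal
#' permutation seed, so a tie-free ranking yields identical results every
#' repetition), and the reported frequency is the fraction of repetitions
#' in which the set was significant at `q_cutoff`.
#'
#' @inheritParams preranked_gsea
#' @param n_reps Number of tie-breaking repetitions, default 1000.
#' @param q_cutoff Significance cutoff on the BH q-value, default 0.05.
#' @return Tibble with `set`, `size`, `robustness_frequency`, plus the
#'   ES/NES/p/q of the first repetition for reference.
#' @export
tie_robustness_gsea <- function(scores, sets, n_reps = 1000, seed = 1L,
                                weight = 1, n_perm = 1000,
                                q_cutoff = 0.05, min_size = 5, max_size = 500) {
  inner_seed <- derive_seed(seed, "gsea_inner")
  run_once <- function(rep_seed) {
    jitter <- with_seed(rep_seed, runif(length(scores)))
    ord <- order(scores, jitter, decreasing = TRUE)
    # re-ranked scores: same values, tie order randomized; feed in the
    # shuffled order and disable re-sorting ambiguity by tiny monotone offsets
    shuffled <- scores[ord]
    eps <- seq(length(scores) * 1e-9, 1e-9, length.out = length(scores))
    preranked_gsea(setNames(shuffled + eps, names(scores)[ord]), sets,
                   weight = weight, n_perm = n_perm, seed = inner_seed,
                   min_size = min_size, max_size = max_size)
  }
  first <- run_once(derive_seed(seed, "rep_1"))
  sig <- matrix(FALSE, n_reps, nrow(first))
  colnames(sig) <- first$set
  sig[1, ] <- first$q < q_cutoff
  if (n_reps > 1) {
    for (r in 2:n_reps) {
      res <- run_once(derive_seed(seed, paste0("rep_", r)))
      sig[r, ] <- res$q[match(first$set, res$set)] < q_cutoff
    }
  }
  first |>
    mutate(robustness_frequency = colMeans(sig)[.data$set]) |>
    select("set", "size", "robustness_frequency", "ES", "NES", "p", "q")
}
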