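#' Weighted running-sum enrichment score
#'
#' Classic gene-set enrichment statistic: walk the ranking from the top; a
#' gene in the set increments the running sum by
#' `|stat|^weight / sum over the set of |stat|^weight`, a gene outside it
#' decrements by `1 / (N - set size)`.  The enrichment score is the running
#' sum's signed extremum of largest magnitude (the positive extremum on an
#' exact magnitude tie).  ES is in `[-1, 1]`; a set concentrated at the top of
#' the ranking scores near +1, at the bottom near -1.
#'
#' @param ranking data.frame with `gene` and `stat`; sorted by `stat`
#'   descending internally (stable for ties).  Gene ids must be unique.
#' @param gene_set character vector; must intersect the ranking.
#' @param weight exponent on `|stat|` for hit increments (1 = classic
#'   weighted statistic; 0 = Kolmogorov-Smirnov).
#' @return single numeric ES.
#' @export
gsea_enrichment_score <- function(ranking, gene_set, weight = 1) {
  stopifnot(all(c("gene", "stat") %in% names(ranking)))
  if (anyDuplicated(ranking$gene)) stop("duplicate gene ids in ranking")
  ranking <- ranking[order(-ranking$stat), , drop = FALSE]
  hit <- ranking$gene %in% gene_set
  if (!any(hit)) stop("gene set disjoint from ranking")
  n <- nrow(ranking)
  n_hit <- sum(hit)
  if (n_hit == n) return(1)  # no misses: the sum climbs straight to 1
  w <- abs(ranking$stat)^weight
  inc <- ifelse(hit, w / sum(w[hit]), 0)
  dec <- ifelse(hit, 0, 1 / (n - n_hit))
  running <- cumsum(inc - dec)
  hi <- max(running); lo <- min(running)
  # positive extremum wins magnitude ties (compared at 1e-9 so that the
  # declared tie rule is robust to summation round-off)
  if (hi >= abs(lo) - 1e-9) hi else lo
}

#' Permutation significance of an enrichment score
#'
#' Gene-set permutation null: `n_perm` random gene sets of the same size are
#' drawn from the ranking and scored.  The p-value is
#' `(1 + #null ES of the same sign with |ES| >= |observed|) /
#'  (1 + #null ES of the same sign)`, deterministic given the seed.
#'
#' @inheritParams gsea_enrichment_score
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return list with `es`, `p`, `n_perm`, `set_size`.
#' @export
gsea_permutation_p <- function(ranking, gene_set, n_perm = 10000, seed = 1,
                               weight = 1) {
  stopifnot(n_perm >= 100)
  es_obs <- gsea_enrichment_score(ranking, gene_set, weight)
  size <- sum(ranking$gene %in% gene_set)
  set.seed(substream_seed(seed, "gsea"))
  es_null <- vapply(seq_len(n_perm), function(i)
    gsea_enrichment_score(ranking, sample(ranking$gene, size), weight),
    numeric(1))
  same_sign <- if (es_obs >= 0) es_null >= 0 else es_null < 0
  p <- (1 + sum(same_sign & abs(es_null) >= abs(es_obs))) /
    (1 + sum(same_sign))
  list(es = es_obs, p = p, n_perm = n_perm, set_size = size)
}
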