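#' Nonreciprocal interval intersection
#'
#' Reports each interval of `a`, unmodified and at most once, that overlaps
#' at least one base of any interval of `b` — the `-wa -u` style intersection
#' used to combine two peak callers' outputs.  Intervals are 0-based
#' half-open, so abutting intervals do not overlap.
#'
#' @param a,b BED-style data frames (`chrom`, `start`, `end`).
#' @return the overlapping subset of `a` (row order preserved).
#' @export
intersect_nonreciprocal <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(a[integer(0), , drop = FALSE])
  hits <- GenomicRanges::findOverlaps(as_granges0(a), as_granges0(b),
                                      ignore.strand = TRUE)
  out <- a[sort(unique(S4Vectors::queryHits(hits))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus peaks across replicates
#'
#' Single-linkage clusters all replicate intervals by >= 1 bp overlap
#' (strand ignored) and emits, for every cluster supported by at least
#' `min_support` distinct replicates, the union (merged span) of its member
#' intervals, with the distinct-replicate count as support.  Output intervals
#' never overlap one another.
#'
#' @param replicate_peaks list of BED-style data frames, one per replicate.
#' @param min_support minimum number of distinct supporting replicates.
#' @return BED-style data.frame `chrom`, `start`, `end`, `support`.
#' @export
replicate_consensus <- function(replicate_peaks, min_support = 2) {
  if (min_support > length(replicate_peaks))
    stop("min_support exceeds the number of replicates")
  nonempty <- vapply(replicate_peaks, nrow, integer(1)) > 0
  if (!any(nonempty))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), support = integer(0)))
  pooled <- do.call(rbind, lapply(which(nonempty), function(i) {
    d <- replicate_peaks[[i]][, c("chrom", "start", "end")]
    d$replicate <- i
    d
  }))
  gr <- as_granges0(pooled)
  clusters <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(clusters, gr, ignore.strand = TRUE)
  support <- vapply(seq_along(clusters), function(i) {
    members <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    length(unique(pooled$replicate[members]))
  }, integer(1))
  out <- as_bed0(clusters)[, c("chrom", "start", "end")]
  out$support <- support
  out <- out[out$support >= min_support, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus origins from per-replicate, per-caller peak sets
#'
#' Mirrors the published pipeline order: within each replicate the two (or
#' more) callers' peaks are combined by nonreciprocal intersection (the first
#' caller's intervals overlapping every other caller are kept), then
#' replicate-level consensus requires `min_support` of the replicates.
#'
#' @param peaks nested list: `peaks[[replicate]][[caller]]` BED data frames
#'   (as produced by [gen_peak_replicates()]).
#' @param min_support minimum supporting replicates.
#' @return consensus BED data.frame with `support` (see
#'   [replicate_consensus()]).
#' @export
consensus_origins <- function(peaks, min_support = 2) {
  per_rep <- lapply(peaks, function(callers) {
    common <- callers[[1]]
    for (other in callers[-1]) common <- intersect_nonreciprocal(common, other)
    common
  })
  replicate_consensus(per_rep, min_support = min_support)
}

#' Origin enrichment at the TSSs of a gene set
#'
#' A gene "has an origin" when its TSS +/- `tss_flank_bp` window overlaps at
#' least one consensus interval.  The test asks whether origin-bearing genes
#' are over-represented among `genes_of_interest` relative to `all_genes`
#' (upper-tail exact hypergeometric via [hypergeometric_overlap()]).
#'
#' @param consensus consensus origin BED data.frame.
#' @param genes_of_interest,all_genes BED6-style gene tables (`name`,
#'   `strand`); the interest set must be a subset of `all_genes`.
#' @param tss_flank_bp flank on each side of the TSS (> 0).
#' @return list with `table` (2x2 counts: origin-bearing / not x interest /
#'   other), `k`, `p`.
#' @export
tss_enrichment <- function(consensus, genes_of_interest, all_genes,
                           tss_flank_bp = 1000) {
  if (tss_flank_bp <= 0) stop("tss_flank_bp must be positive")
  if (nrow(genes_of_interest) == 0 || nrow(all_genes) == 0)
    stop("empty gene set")
  if (!all(genes_of_interest$name %in% all_genes$name))
    stop("genes_of_interest must be a subset of all_genes")
  tss <- tss_positions(all_genes)
  windows <- data.frame(chrom = all_genes$chrom,
                        start = pmax(0L, tss - as.integer(tss_flank_bp)),
                        end = tss + as.integer(tss_flank_bp) + 1L)
  has_origin <- rep(FALSE, nrow(all_genes))
  if (nrow(consensus) > 0) {
    hits <- GenomicRanges::findOverlaps(as_granges0(windows),
                                        as_granges0(consensus),
                                        ignore.strand = TRUE)
    has_origin[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  origin_genes <- all_genes$name[has_origin]
  hg <- hypergeometric_overlap(origin_genes, genes_of_interest$name,
                               all_genes$name)
  interest <- all_genes$name %in% genes_of_interest$name
  tab <- table(origin = factor(has_origin, c(TRUE, FALSE)),
               interest = factor(interest, c(TRUE, FALSE)))
  list(table = tab, k = hg$k, p = hg$p)
}
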