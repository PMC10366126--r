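#' Construct a per-nucleotide crosslink event track
#'
#' A `crosslink_track` stores stranded per-nucleotide crosslink event counts
#' (0-based positions) and the library size (total events).
#'
#' @param events data.frame with `chrom`, `pos` (0-based), `strand`,
#'   `count` (positive integers); duplicate keys are summed.
#' @return a `crosslink_track`: list with `events` (sorted, unique keys) and
#'   `library_size`.
#' @export
crosslink_track <- function(events) {
  stopifnot(all(c("chrom", "pos", "strand", "count") %in% names(events)))
  if (nrow(events) > 0) {
    if (any(events$count < 0)) stop("negative counts")
    key <- paste(events$chrom, events$strand, events$pos)
    if (anyDuplicated(key)) {
      agg <- stats::aggregate(count ~ chrom + pos + strand, events, sum)
      events <- agg
    }
    events <- events[events$count > 0, , drop = FALSE]
    events <- events[order(events$chrom, events$strand, events$pos), ,
                     drop = FALSE]
    rownames(events) <- NULL
  }
  structure(list(events = events, library_size = sum(events$count)),
            class = "crosslink_track")
}

#' Assign crosslink sites from read alignments
#'
#' Allocates the nucleotide preceding each sequencing read (in transcript
#' orientation) as the crosslink site event, the standard truncation-site
#' convention: a `+` read `[s, e)` yields an event at `s - 1`; a `-` read
#' `[s, e)` yields an event at `e`.  Events that would fall at negative
#' coordinates are dropped; the number dropped is attached as attribute
#' `n_dropped`.
#'
#' @param reads data.frame of read spans: `chrom`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @return a `crosslink_track`.
#' @export
assign_crosslink_sites <- function(reads) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(reads)))
  if (nrow(reads) > 0 && any(reads$end <= reads$start))
    stop("malformed read interval: end <= start")
  pos <- ifelse(reads$strand == "+", reads$start - 1L, reads$end)
  keep <- pos >= 0
  ev <- data.frame(chrom = reads$chrom[keep], pos = as.integer(pos[keep]),
                   strand = reads$strand[keep], count = rep(1L, sum(keep)),
                   stringsAsFactors = FALSE)
  tr <- crosslink_track(ev)
  attr(tr, "n_dropped") <- sum(!keep)
  tr
}

#' Counts-per-million normalization of a crosslink track
#'
#' @param track a `crosslink_track` with positive library size.
#' @return the track with an additional `cpm` column
#'   (`count * 1e6 / library_size`; column sums to 1e6).
#' @export
cpm_normalize <- function(track) {
  stopifnot(inherits(track, "crosslink_track"))
  if (track$library_size == 0) stop("empty library")
  track$events$cpm <- track$events$count * 1e6 / track$library_size
  track
}

# running sum of counts in a centered window of odd width
window_scores <- function(counts, window_nt) {
  half <- (window_nt - 1L) %/% 2L
  padded <- c(rep(0L, half), counts, rep(0L, half))
  as.numeric(stats::filter(padded, rep(1, window_nt), sides = 2))[
    (half + 1L):(half + length(counts))]
}

# permutation FDR within one region: events re-placed uniformly and
# independently across the region's nucleotides, preserving the total
region_site_fdr <- function(counts, window_nt, n_perm) {
  obs_sites <- which(counts > 0L)
  if (length(obs_sites) == 0)
    return(data.frame(offset = integer(0), count = integer(0),
                      score = numeric(0), fdr = numeric(0)))
  scores <- window_scores(counts, window_nt)
  obs_scores <- scores[obs_sites]
  thresholds <- sort(unique(obs_scores))
  n_events <- sum(counts)
  len <- length(counts)
  # observed number of sites at or above each threshold
  obs_ge <- vapply(thresholds, function(s) sum(obs_scores >= s), numeric(1))
  perm_ge <- matrix(0, n_perm, length(thresholds))
  for (p in seq_len(n_perm)) {
    perm_counts <- tabulate(sample.int(len, n_events, replace = TRUE), len)
    nz <- which(perm_counts > 0L)
    ps <- window_scores(perm_counts, window_nt)[nz]
    perm_ge[p, ] <- vapply(thresholds, function(s) sum(ps >= s), numeric(1))
  }
  fdr_at <- pmin(colMeans(perm_ge) / obs_ge, 1)
  # monotone non-increasing in score: cumulative maximum from high scores down
  fdr_at <- rev(cummax(rev(fdr_at)))
  data.frame(offset = obs_sites - 1L, count = counts[obs_sites],
             score = obs_scores,
             fdr = fdr_at[match(obs_scores, thresholds)])
}

#' Call significant crosslink sites by permutation FDR
#'
#' Within each co-transcribed region (on its own strand), every nucleotide
#' with at least one crosslink event is scored by the total events in a
#' centered window of `window_nt` nucleotides.  A null distribution is built
#' by `n_perm` uniform re-placements of the region's events across the
#' region's nucleotides, scored identically; for an observed score s,
#' `FDR(s) = mean permuted count of sites with score >= s / observed count of
#' sites with score >= s`, capped at 1 and made monotone non-increasing in s.
#' Sites with `FDR < fdr_threshold` are returned.
#'
#' @param track a `crosslink_track`.
#' @param regions BED-style data.frame of co-transcribed regions with
#'   `strand`; regions must not overlap on the same strand.
#' @param window_nt odd window width, nt.
#' @param n_perm number of permutations.
#' @param fdr_threshold significance cut-off.
#' @param seed integer seed (permutations are deterministic given it).
#' @return data.frame of site calls: `chrom`, `strand`, `pos`, `count`,
#'   `score`, `fdr`, `region`.
#' @export
call_significant_sites <- function(track, regions, window_nt = 3,
                                   n_perm = 100, fdr_threshold = 0.05,
                                   seed = 1) {
  stopifnot(inherits(track, "crosslink_track"),
            window_nt %% 2 == 1, window_nt >= 1, n_perm >= 1)
  for (s in c("+", "-")) {
    rs <- regions[regions$strand == s, , drop = FALSE]
    if (nrow(rs) > 1) {
      gr <- as_granges0(rs)
      if (any(GenomicRanges::countOverlaps(gr, gr) > 1))
        stop("regions overlap on strand ", s)
    }
  }
  set.seed(substream_seed(seed, "peakperm"))
  ev <- track$events
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    len <- r$end - r$start
    sel <- ev$chrom == r$chrom & ev$strand == r$strand &
      ev$pos >= r$start & ev$pos < r$end
    counts <- integer(len)
    counts[ev$pos[sel] - r$start + 1L] <- ev$count[sel]
    calls <- region_site_fdr(counts, window_nt, n_perm)
    calls <- calls[calls$fdr < fdr_threshold, , drop = FALSE]
    if (nrow(calls) > 0)
      out[[i]] <- data.frame(
        chrom = r$chrom, strand = r$strand, pos = r$start + calls$offset,
        count = calls$count, score = calls$score, fdr = calls$fdr,
        region = if (!is.null(r$name)) r$name else as.character(i),
        stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(chrom = character(0), strand = character(0),
                      pos = integer(0), count = integer(0),
                      score = numeric(0), fdr = numeric(0),
                      region = character(0))
  rownames(res) <- NULL
  res
}

# assign positions to genes: same strand, position inside the gene; the
# longest containing gene wins nested/ambiguous overlaps
assign_to_genes <- function(chrom, pos, strand, genes) {
  gene_len <- genes$end - genes$start
  vapply(seq_along(pos), function(k) {
    hit <- which(genes$chrom == chrom[k] & genes$strand == strand[k] &
                   genes$start <= pos[k] & pos[k] < genes$end)
    if (length(hit) == 0) return(NA_character_)
    genes$name[hit[which.max(gene_len[hit])]]
  }, character(1))
}

#' Per-gene summary of crosslink evidence
#'
#' Aggregates significant site calls and raw crosslink events per gene:
#' number of significant sites, total events, CTPM (crosslink tags per
#' million: gene events x 1e6 / library size), and a convenience flag
#' `passes_iclip_threshold` marking genes with at least `min_sites`
#' significant sites.  Calls or events falling outside all genes are
#' discarded; their count is attached as attribute `n_unassigned`.
#'
#' @param calls site calls from [call_significant_sites()].
#' @param track the underlying `crosslink_track`.
#' @param genes BED6-style gene table (with `name`, `strand`).
#' @param min_sites significant-site threshold for the flag.
#' @return data.frame `gene_id`, `n_sites`, `n_events`, `ctpm`,
#'   `passes_iclip_threshold`.
#' @export
summarize_genes <- function(calls, track, genes, min_sites = 5) {
  stopifnot(inherits(track, "crosslink_track"))
  ev <- track$events
  ev_gene <- assign_to_genes(ev$chrom, ev$pos, ev$strand, genes)
  call_gene <- assign_to_genes(calls$chrom, calls$pos, calls$strand, genes)
  n_events <- vapply(genes$name, function(g)
    sum(ev$count[!is.na(ev_gene) & ev_gene == g]), numeric(1))
  n_sites <- vapply(genes$name, function(g)
    sum(!is.na(call_gene) & call_gene == g), numeric(1))
  out <- data.frame(
    gene_id = genes$name,
    n_sites = as.integer(n_sites),
    n_events = as.integer(n_events),
    ctpm = if (track$library_size > 0)
      n_events * 1e6 / track$library_size else 0,
    passes_iclip_threshold = n_sites >= min_sites,
    stringsAsFactors = FALSE
  )
  attr(out, "n_unassigned") <- sum(is.na(call_gene))
  rownames(out) <- NULL
  out
}
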