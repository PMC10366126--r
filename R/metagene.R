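#' TSS-centered binned coverage matrix
#'
#' Builds the genes x bins matrix of mean normalized signal around each
#' gene's TSS: the window spans `flank_bp` on each side, split into bins of
#' `bin_bp` nucleotides (so `2 * flank_bp / bin_bp` columns).  Positions with
#' no track record count as 0; windows exceeding chromosome bounds are
#' truncated to zero signal outside (the number of affected genes is attached
#' as attribute `n_truncated`).  Minus-strand genes' bins are reversed so
#' column order always reads promoter-upstream to gene-body-downstream.
#'
#' @param track bedGraph-style data.frame `chrom`, `start`, `end`, `value`
#'   (0-based half-open runs).
#' @param genes BED6-style gene table (`name`, `strand`).
#' @param flank_bp half-window, nt; must be divisible by `bin_bp`.
#' @param bin_bp bin width, nt.
#' @return numeric matrix, rownames = gene names, with attribute
#'   `bin_bp`.
#' @export
coverage_matrix <- function(track, genes, flank_bp = 5000, bin_bp = 10) {
  stopifnot(flank_bp %% bin_bp == 0, bin_bp >= 1)
  n_bins <- as.integer(2 * flank_bp / bin_bp)
  tss <- tss_positions(genes)
  # expand track runs into per-chromosome position/value vectors
  chroms <- unique(genes$chrom)
  vecs <- list()
  for (ch in chroms) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    len <- max(c(tr$end, tss[genes$chrom == ch] + flank_bp + 1L), 0L)
    v <- numeric(len)
    if (nrow(tr) > 0) {
      for (r in seq_len(nrow(tr)))
        v[(tr$start[r] + 1L):tr$end[r]] <- tr$value[r]
    }
    vecs[[ch]] <- v
  }
  mat <- matrix(0, nrow(genes), n_bins,
                dimnames = list(genes$name, NULL))
  n_truncated <- 0L
  for (i in seq_len(nrow(genes))) {
    v <- vecs[[genes$chrom[i]]]
    pos <- (tss[i] - flank_bp):(tss[i] + flank_bp - 1L)  # 0-based
    inside <- pos >= 0 & pos < length(v)
    if (!all(inside)) n_truncated <- n_truncated + 1L
    vals <- numeric(length(pos))
    vals[inside] <- v[pos[inside] + 1L]
    binned <- colMeans(matrix(vals, nrow = bin_bp))
    if (genes$strand[i] == "-") binned <- rev(binned)
    mat[i, ] <- binned
  }
  attr(mat, "bin_bp") <- bin_bp
  attr(mat, "n_truncated") <- n_truncated
  mat
}

#' Compare two conditions' TSS metagene profiles
#'
#' Reduces each coverage matrix to its mean profile (column means), then
#' compares the two profiles by a paired two-tailed t-test across bins,
#' reports the Euclidean distance between them, and the fold change as the
#' ratio of grand means (condition A over condition B).  Identical matrices
#' give distance 0, fold change 1 and p = 1 by convention (the zero-variance
#' pairing carries no evidence).
#'
#' @param mat_a,mat_b matrices from [coverage_matrix()] with identical genes
#'   and bins.
#' @return list with `mean_a`, `mean_b` (bin profiles), `t`, `p`,
#'   `distance`, `fold_change`.
#' @export
profile_compare <- function(mat_a, mat_b) {
  if (!identical(dim(mat_a), dim(mat_b)))
    stop("matrices must share genes and bins")
  mean_a <- colMeans(mat_a)
  mean_b <- colMeans(mat_b)
  diffs <- mean_a - mean_b
  if (sd(diffs) == 0) {
    t_stat <- 0
    p <- if (all(diffs == 0)) 1 else 0
  } else {
    tt <- t.test(mean_a, mean_b, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  list(mean_a = mean_a, mean_b = mean_b, t = t_stat, p = p,
       distance = sqrt(sum(diffs^2)),
       fold_change = mean(mat_a) / mean(mat_b))
}
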