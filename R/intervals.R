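#' Interval tables and GRanges conversion
#'
#' User-facing interval sets in this package are plain data frames in BED
#' order (`chrom`, `start`, `end`, then optionally `name`, `score`, `strand`),
#' 0-based half-open.  Overlap machinery is delegated to GenomicRanges; these
#' helpers translate between the two conventions (GRanges is 1-based closed).
#'
#' @param bed data.frame with at least `chrom`, `start`, `end`; optional
#'   `name`, `score`, `strand`.
#' @return `as_granges0()` returns a [GenomicRanges::GRanges] whose metadata
#'   columns preserve `name`/`score`; `as_bed0()` inverts it.
#' @keywords internal
as_granges0 <- function(bed) {
  stopifnot(all(c("chrom", "start", "end") %in% names(bed)))
  if (nrow(bed) > 0 && any(bed$end <= bed$start))
    stop("invalid interval: end <= start")
  strand <- if ("strand" %in% names(bed)) bed$strand else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = bed$chrom,
    ranges = IRanges::IRanges(start = bed$start + 1L, end = bed$end),
    strand = strand
  )
  if ("name" %in% names(bed)) gr$name <- bed$name
  if ("score" %in% names(bed)) gr$score <- bed$score
  gr
}

#' @rdname as_granges0
#' @param gr a GRanges object.
#' @keywords internal
as_bed0 <- function(gr) {
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (!is.null(gr$name)) out$name <- gr$name
  if (!is.null(gr$score)) out$score <- gr$score
  out$strand <- as.character(GenomicRanges::strand(gr))
  out
}

#' Transcription start sites of a stranded gene table
#'
#' The TSS of a `+` gene `[start, end)` is `start`; of a `-` gene it is
#' `end - 1` (both 0-based nucleotide positions).
#'
#' @param genes BED-style data.frame with `strand`.
#' @return integer vector of 0-based TSS positions, one per gene.
#' @export
tss_positions <- function(genes) {
  stopifnot(all(genes$strand %in% c("+", "-")))
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}
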