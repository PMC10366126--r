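#' Read and write interval and track files
#'
#' Thin wrappers over rtracklayer for the on-disk formats the pipeline uses.
#' All in-memory coordinates are 0-based half-open; rtracklayer handles the
#' BED/bedGraph conversion.
#'
#' @param bed BED-style data.frame (`chrom`, `start`, `end`, optional
#'   `name`, `score`, `strand`).
#' @param path file path.
#' @return `read_bed()` returns a BED-style data.frame; writers return the
#'   path invisibly.
#' @export
write_bed <- function(bed, path) {
  rtracklayer::export(as_granges0(bed), path, format = "BED")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  as_bed0(rtracklayer::import(path, format = "BED"))
}

#' @rdname write_bed
#' @param track bedGraph-style data.frame (`chrom`, `start`, `end`,
#'   `value`).
#' @export
write_bedgraph <- function(track, path) {
  gr <- as_granges0(track[, c("chrom", "start", "end")])
  gr$score <- track$value
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- as_bed0(gr)
  names(out)[names(out) == "score"] <- "value"
  out[, c("chrom", "start", "end", "value")]
}

#' Write and read a stranded crosslink track as a bedGraph pair
#'
#' Stranded per-nucleotide event tracks are stored as two bedGraph files,
#' `<stem>.plus.bedgraph` and `<stem>.minus.bedgraph`.
#'
#' @param track a `crosslink_track`.
#' @param stem path stem (without extension).
#' @return `read_crosslink_track()` returns a `crosslink_track`; the writer
#'   returns the stem invisibly.
#' @export
write_crosslink_track <- function(track, stem) {
  for (s in c("+", "-")) {
    ev <- track$events[track$events$strand == s, , drop = FALSE]
    tr <- data.frame(chrom = ev$chrom, start = ev$pos, end = ev$pos + 1L,
                     value = ev$count)
    suffix <- if (s == "+") "plus" else "minus"
    path <- sprintf("%s.%s.bedgraph", stem, suffix)
    if (nrow(tr) > 0) write_bedgraph(tr, path) else
      writeLines(character(0), path)
  }
  invisible(stem)
}

#' @rdname write_crosslink_track
#' @export
read_crosslink_track <- function(stem) {
  parts <- lapply(c(plus = "+", minus = "-"), function(s) s)
  ev <- do.call(rbind, lapply(names(parts), function(suffix) {
    path <- sprintf("%s.%s.bedgraph", stem, suffix)
    if (file.size(path) == 0)
      return(data.frame(chrom = character(0), pos = integer(0),
                        strand = character(0), count = integer(0)))
    tr <- read_bedgraph(path)
    # runs wider than 1 nt expand back to per-nucleotide records
    data.frame(chrom = rep(tr$chrom, tr$end - tr$start),
               pos = unlist(mapply(seq, tr$start, tr$end - 1L,
                                   SIMPLIFY = FALSE)),
               strand = parts[[suffix]],
               count = rep(tr$value, tr$end - tr$start),
               stringsAsFactors = FALSE)
  }))
  crosslink_track(ev)
}

#' Tab-separated tables and localization CSVs
#'
#' @param df data.frame to write.
#' @param path file path.
#' @return readers return data frames; writers return the path invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname write_tsv
#' @export
write_locs_csv <- function(df, path) {
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_locs_csv <- function(path) {
  read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
}
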