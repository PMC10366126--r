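#' RNA immunoprecipitation enrichment over input
#'
#' Library-size-aware ratio test per gene: the log2 fold change is
#' `log2(((ip + pc) / lib_ip) / ((input + pc) / lib_input))` and the p-value
#' comes from a two-sided exact binomial test of the gene's IP count against
#' `n = ip + input` trials with success probability
#' `lib_ip / (lib_ip + lib_input)`.  Benjamini-Hochberg adjusted p-values are
#' reported alongside; the `enriched` flag applies the classical
#' `log2FC > lfc_threshold` and `p < p_threshold` rule (on raw or adjusted p
#' per `use_adjusted`).
#'
#' @param counts data.frame with `gene_id`, `ip`, `input`.
#' @param lib_ip,lib_input library sizes (default: column totals).
#' @param pseudocount added to both counts for the fold change only.
#' @param lfc_threshold,p_threshold enrichment thresholds.
#' @param use_adjusted flag enrichment on BH-adjusted p-values instead of raw.
#' @return data.frame `gene_id`, `ip`, `input`, `log2fc`, `p`, `padj`,
#'   `enriched`.
#' @export
rip_enrichment <- function(counts, lib_ip = sum(counts$ip),
                           lib_input = sum(counts$input), pseudocount = 0.5,
                           lfc_threshold = 1, p_threshold = 0.05,
                           use_adjusted = FALSE) {
  stopifnot(lib_ip > 0, lib_input > 0, all(counts$ip >= 0),
            all(counts$input >= 0))
  p0 <- lib_ip / (lib_ip + lib_input)
  log2fc <- ifelse(
    counts$ip == 0 & counts$input == 0, 0,
    log2(((counts$ip + pseudocount) / lib_ip) /
           ((counts$input + pseudocount) / lib_input)))
  p <- vapply(seq_len(nrow(counts)), function(i) {
    n <- counts$ip[i] + counts$input[i]
    if (n == 0) return(1)
    binom.test(counts$ip[i], n, p = p0)$p.value
  }, numeric(1))
  padj <- p.adjust(p, method = "BH")
  p_used <- if (use_adjusted) padj else p
  data.frame(gene_id = counts$gene_id, ip = counts$ip, input = counts$input,
             log2fc = log2fc, p = p, padj = padj,
             enriched = log2fc > lfc_threshold & p_used < p_threshold,
             stringsAsFactors = FALSE)
}

#' Build RNA-interactor sets from RIP and iCLIP evidence
#'
#' Combines the two evidence channels into the four interactor sets used
#' throughout the analysis: RIP-enriched genes, genes passing the iCLIP
#' significant-site threshold, their union (the broad interactor set) and
#' their overlap (the high-confidence set).
#'
#' @param rip output of [rip_enrichment()] (or a character vector of
#'   RIP-enriched gene ids).
#' @param gene_summaries output of [summarize_genes()] (or a character vector
#'   of iCLIP-passing gene ids).
#' @param universe character vector of all candidate gene ids.
#' @return list with `rip_genes`, `iclip_genes`, `union`, `overlap`,
#'   `universe` (all sorted character vectors).
#' @export
define_sets <- function(rip, gene_summaries, universe) {
  if (length(universe) == 0) stop("empty universe")
  rip_genes <- if (is.data.frame(rip)) rip$gene_id[rip$enriched] else rip
  iclip_genes <- if (is.data.frame(gene_summaries))
    gene_summaries$gene_id[gene_summaries$passes_iclip_threshold]
  else gene_summaries
  rip_genes <- intersect(rip_genes, universe)
  iclip_genes <- intersect(iclip_genes, universe)
  list(rip_genes = sort(rip_genes), iclip_genes = sort(iclip_genes),
       union = sort(union(rip_genes, iclip_genes)),
       overlap = sort(intersect(rip_genes, iclip_genes)),
       universe = sort(unique(universe)))
}

#' Exact hypergeometric test of a set overlap
#'
#' Upper-tail probability of observing at least `k = |A intersect B|`
#' successes when `|B|` genes are drawn without replacement from a universe of
#' `N` containing `|A|` marked genes.
#'
#' @param set_a,set_b character vectors (subsets of `universe`).
#' @param universe character vector of all genes.
#' @return list with `k` (observed overlap), `n_a`, `n_b`, `n_universe`, `p`.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("sets must be subsets of the universe")
  N <- length(universe); K <- length(set_a); n <- length(set_b)
  k <- length(intersect(set_a, set_b))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, n_a = K, n_b = n, n_universe = N, p = p)
}

#' Pooled two-proportion z-test
#'
#' Classical pooled two-sided z-test for the difference of two proportions
#' `k1/n1` and `k2/n2`.  A degenerate pooled proportion (0 or 1) returns
#' `z = 0`, `p = 1` by convention.
#'
#' @param k1,n1,k2,n2 successes and trials per group.
#' @return list with `z`, `p`, `p1`, `p2`.
#' @export
two_proportion_z <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p_pool <- (k1 + k2) / (n1 + n2)
  p1 <- k1 / n1; p2 <- k2 / n2
  if (p_pool <= 0 || p_pool >= 1)
    return(list(z = 0, p = 1, p1 = p1, p2 = p2))
  z <- (p1 - p2) / sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' Stratify interactor genes into binding quantiles
#'
#' Ranks genes by CTPM descending (ties broken by gene id, so the assignment
#' is deterministic) and splits them into `n_quantiles` contiguous groups of
#' near-equal size, labelled `Q1` (strongest binding) to `Qn`.  When sizes
#' cannot be equal, earlier (stronger) quantiles take the extra genes.
#'
#' @param gene_summaries data.frame with `gene_id` and `ctpm` (e.g. the
#'   [summarize_genes()] rows for the interactor union set).
#' @param n_quantiles number of quantiles (>= 2).
#' @return data.frame `gene_id`, `ctpm`, `quantile` (factor Q1..Qn).
#' @export
assign_quantiles <- function(gene_summaries, n_quantiles = 6) {
  stopifnot(n_quantiles >= 2)
  n <- nrow(gene_summaries)
  if (n < n_quantiles) stop("fewer genes than quantiles")
  ord <- order(-gene_summaries$ctpm, gene_summaries$gene_id)
  sizes <- rep(n %/% n_quantiles, n_quantiles)
  extra <- n %% n_quantiles
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- factor(rep(sprintf("Q%d", seq_len(n_quantiles)), sizes),
                   levels = sprintf("Q%d", seq_len(n_quantiles)))
  out <- data.frame(gene_id = gene_summaries$gene_id[ord],
                    ctpm = gene_summaries$ctpm[ord],
                    quantile = labels, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
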