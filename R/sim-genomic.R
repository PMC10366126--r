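#' Simulate non-overlapping stranded genes on a flat chromosome
#'
#' Places `n_genes` non-overlapping genes (uniform random lengths within
#' `length_range`) on a single chromosome `chrom` of length `chrom_length`.
#' Coordinates are 0-based half-open; the TSS of a `+` gene is its start and
#' of a `-` gene its `end - 1`.
#'
#' @param n_genes number of genes.
#' @param chrom_length chromosome length, nt.
#' @param length_range two-vector of min/max gene length.
#' @param gap_min minimum gap enforced between adjacent genes.
#' @param seed integer seed.
#' @param chrom chromosome name.
#' @return BED6-style data.frame: `chrom`, `start`, `end`, `name` (gene id),
#'   `score`, `strand`.
#' @export
gen_genes <- function(n_genes, chrom_length = 1e6, length_range = c(1000, 5000),
                      gap_min = 100, seed = 1, chrom = "chrS1") {
  set.seed(substream_seed(seed, "genes"))
  stopifnot(n_genes >= 1, length_range[1] <= length_range[2])
  lens <- if (length_range[1] == length_range[2]) {
    rep(length_range[1], n_genes)
  } else {
    sample(seq(length_range[1], length_range[2]), n_genes, replace = TRUE)
  }
  needed <- sum(lens) + gap_min * (n_genes - 1)
  if (needed > chrom_length)
    stop("cannot place ", n_genes, " non-overlapping genes in ", chrom_length,
         " nt (need >= ", needed, ")")
  # distribute the leftover space as random gaps between consecutive genes
  slack <- chrom_length - needed
  cuts <- sort(sample.int(slack + 1L, n_genes, replace = TRUE) - 1L)
  gaps <- diff(c(0L, cuts))
  starts <- integer(n_genes)
  pos <- 0L
  for (i in seq_len(n_genes)) {
    pos <- pos + gaps[i] + if (i > 1) gap_min else 0L
    starts[i] <- pos
    pos <- pos + lens[i]
  }
  data.frame(
    chrom = chrom,
    start = starts,
    end = starts + lens,
    name = sprintf("g%04d", seq_len(n_genes)),
    score = 0L,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Simulate a stranded per-nucleotide crosslink event track
#'
#' Within each gene, per-nucleotide background events are Poisson with mean
#' `background_rate`; in addition, `sites_per_gene` true binding sites per
#' gene each receive `site_events` extra events at a single nucleotide.
#' Outside genes the track is zero.  Events inherit the gene's strand.
#'
#' @param genes gene table from [gen_genes()].
#' @param background_rate Poisson mean per gene nucleotide.
#' @param sites_per_gene number of embedded true sites per gene.
#' @param site_events events added at each true site.
#' @param seed integer seed.
#' @return list with `track` (a `crosslink_track`, see
#'   [crosslink_track()]) and `truth` (data.frame of true sites:
#'   `gene`, `chrom`, `pos`, `strand`, `events`).
#' @export
gen_crosslink_track <- function(genes, background_rate = 0.01,
                                sites_per_gene = 1, site_events = 10,
                                seed = 1) {
  stopifnot(background_rate >= 0, sites_per_gene >= 0, site_events >= 0)
  set.seed(substream_seed(seed, "crosslink"))
  ev <- list(); tr <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    len <- g$end - g$start
    counts <- if (background_rate > 0) rpois(len, background_rate) else
      integer(len)
    site_pos <- integer(0)
    if (sites_per_gene > 0 && site_events > 0) {
      site_pos <- sample.int(len, min(sites_per_gene, len))
      counts[site_pos] <- counts[site_pos] + site_events
      tr[[length(tr) + 1L]] <- data.frame(
        gene = g$name, chrom = g$chrom, pos = g$start + site_pos - 1L,
        strand = g$strand, events = site_events, stringsAsFactors = FALSE)
    }
    nz <- which(counts > 0L)
    if (length(nz) > 0)
      ev[[length(ev) + 1L]] <- data.frame(
        chrom = g$chrom, pos = g$start + nz - 1L, strand = g$strand,
        count = counts[nz], stringsAsFactors = FALSE)
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(chrom = character(0), pos = integer(0), strand = character(0),
               count = integer(0))
  truth <- if (length(tr)) do.call(rbind, tr) else
    data.frame(gene = character(0), chrom = character(0), pos = integer(0),
               strand = character(0), events = integer(0))
  list(track = crosslink_track(events), truth = truth)
}

#' Simulate IP/input RNA immunoprecipitation count tables
#'
#' Hierarchical Gamma-Poisson model: each gene draws a base abundance
#' uniformly from `mean_range` and a shared Gamma latent factor with variance
#' `dispersion` (so marginal counts are negative-binomial with that
#' dispersion; `dispersion = 0` gives Poisson counts).  IP and input counts
#' are Poisson around the shared latent abundance scaled by their library
#' sizes, with the IP mean of a random `enriched_n`-gene subset multiplied by
#' `fold_change`.  Sharing the latent factor between IP and input mimics
#' biological co-variation of the two libraries and leaves the IP-vs-input
#' ratio binomially distributed for unenriched genes.
#'
#' @param n_genes total genes.
#' @param enriched_n number of truly enriched genes.
#' @param fold_change IP mean multiplier for enriched genes (> 1).
#' @param mean_range two-vector; per-gene base mean range at unit library.
#' @param dispersion NB dispersion (variance of the shared Gamma factor).
#' @param lib_ip,lib_input library scale factors.
#' @param seed integer seed.
#' @return list with `counts` (data.frame `gene_id`, `ip`, `input`) and
#'   `truth` (list with `enriched` gene ids and `fold_change`).
#' @export
gen_rip_counts <- function(n_genes = 1000, enriched_n = 100, fold_change = 4,
                           mean_range = c(10, 500), dispersion = 0.1,
                           lib_ip = 1, lib_input = 1, seed = 1) {
  stopifnot(dispersion >= 0, enriched_n <= n_genes, lib_ip > 0, lib_input > 0)
  if (enriched_n > 0 && fold_change <= 1)
    stop("fold_change must be > 1 for enriched genes")
  set.seed(substream_seed(seed, "rip"))
  ids <- sprintf("g%04d", seq_len(n_genes))
  base <- runif(n_genes, mean_range[1], mean_range[2])
  latent <- if (dispersion > 0)
    base * rgamma(n_genes, shape = 1 / dispersion, scale = dispersion)
  else base
  enriched <- sample(ids, enriched_n)
  fc <- ifelse(ids %in% enriched, fold_change, 1)
  counts <- data.frame(
    gene_id = ids,
    ip = rpois(n_genes, latent * lib_ip * fc),
    input = rpois(n_genes, latent * lib_input),
    stringsAsFactors = FALSE
  )
  list(counts = counts,
       truth = list(enriched = sort(enriched), fold_change = fold_change))
}

#' Simulate TSS-anchored coverage tracks for two conditions
#'
#' Each gene gets a Gaussian-shaped coverage bump centered on its TSS whose
#' height decreases with its binding-quantile rank: quantile `q` (1 =
#' strongest) has amplitude `base_amplitude + (max(q) - q) * amplitude_step`.
#' Condition B multiplies bump heights by `condition_effect` for the genes in
#' `affected_genes`.  Gaussian noise of sd `noise_sd` is added per nucleotide
#' (truncated at 0).
#'
#' @param genes gene table.
#' @param quantile_labels integer vector (same length as `genes`) of quantile
#'   ranks, 1 = strongest binding.
#' @param base_amplitude amplitude of the weakest quantile's bump.
#' @param amplitude_step amplitude increment per quantile rank.
#' @param peak_width Gaussian sd of the bump, nt.
#' @param noise_sd per-nucleotide Gaussian noise sd.
#' @param condition_effect multiplier applied in condition B.
#' @param affected_genes gene names affected by `condition_effect`
#'   (default: all genes).
#' @param flank_bp half-width of the simulated window around each TSS.
#' @param seed integer seed.
#' @return list with `track_a`, `track_b` (bedGraph-style data frames
#'   `chrom`, `start`, `end`, `value`; one row per nonzero nucleotide) and
#'   `truth` (data.frame `name`, `quantile`, `amplitude_a`, `amplitude_b`).
#' @export
gen_coverage_tracks <- function(genes, quantile_labels,
                                base_amplitude = 1, amplitude_step = 1,
                                peak_width = 300, noise_sd = 0,
                                condition_effect = 1, affected_genes = NULL,
                                flank_bp = 5000, seed = 1) {
  stopifnot(base_amplitude >= 0, amplitude_step >= 0, peak_width > 0,
            length(quantile_labels) == nrow(genes))
  set.seed(substream_seed(seed, "coverage"))
  affected_genes <- affected_genes %||% genes$name
  tss <- tss_positions(genes)
  amp_a <- base_amplitude + (max(quantile_labels) - quantile_labels) *
    amplitude_step
  amp_b <- amp_a * ifelse(genes$name %in% affected_genes, condition_effect, 1)

  one_track <- function(amps) {
    rows <- vector("list", nrow(genes))
    for (i in seq_len(nrow(genes))) {
      pos <- (tss[i] - flank_bp):(tss[i] + flank_bp - 1L)
      keep <- pos >= 0
      pos <- pos[keep]
      val <- amps[i] * exp(-((pos - tss[i])^2) / (2 * peak_width^2))
      if (noise_sd > 0) val <- pmax(val + rnorm(length(val), 0, noise_sd), 0)
      nz <- val != 0
      rows[[i]] <- data.frame(chrom = genes$chrom[i], start = pos[nz],
                              end = pos[nz] + 1L, value = val[nz],
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out[order(out$chrom, out$start), , drop = FALSE]
  }
  list(track_a = one_track(amp_a), track_b = one_track(amp_b),
       truth = data.frame(name = genes$name, quantile = quantile_labels,
                          amplitude_a = amp_a, amplitude_b = amp_b,
                          stringsAsFactors = FALSE))
}

#' Simulate replicate/caller origin peak sets around known true origins
#'
#' Each replicate detects each true origin with probability `1 - dropout`
#' (dropout acts at the replicate level: an origin missing from a replicate is
#' reported by neither caller).  Every caller in a detecting replicate reports
#' the origin with independently jittered boundaries (Gaussian sd
#' `jitter_sd`), plus `rpois(extra_rate * n_true)` spurious intervals placed
#' uniformly on the chromosome.
#'
#' @param true_origins BED-style data.frame of true origin intervals.
#' @param n_replicates number of replicates.
#' @param n_callers peak callers per replicate.
#' @param jitter_sd boundary jitter sd, nt.
#' @param dropout per-replicate miss probability in `[0, 1)`.
#' @param extra_rate spurious peaks per true origin per caller.
#' @param chrom_length chromosome length for spurious placement.
#' @param seed integer seed.
#' @return list with `peaks` (list of replicates, each a list of caller BED
#'   data frames) and `truth` (the input `true_origins`).
#' @export
gen_peak_replicates <- function(true_origins, n_replicates = 3, n_callers = 2,
                                jitter_sd = 20, dropout = 0.2,
                                extra_rate = 0.05, chrom_length = 1e6,
                                seed = 1) {
  stopifnot(dropout >= 0, dropout < 1, n_replicates >= 1, n_callers >= 1)
  set.seed(substream_seed(seed, "peaks"))
  n_true <- nrow(true_origins)
  peaks <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    detected <- runif(n_true) >= dropout
    callers <- vector("list", n_callers)
    for (cl in seq_len(n_callers)) {
      kept <- true_origins[detected, , drop = FALSE]
      if (nrow(kept) > 0 && jitter_sd > 0) {
        kept$start <- pmax(0L, as.integer(round(
          kept$start + rnorm(nrow(kept), 0, jitter_sd))))
        kept$end <- pmax(kept$start + 1L, as.integer(round(
          kept$end + rnorm(nrow(kept), 0, jitter_sd))))
      }
      n_extra <- if (extra_rate > 0) rpois(1, extra_rate * n_true) else 0L
      if (n_extra > 0) {
        w <- if (n_true > 0) round(mean(true_origins$end - true_origins$start))
        else 200L
        s <- as.integer(runif(n_extra, 0, chrom_length - w))
        extra <- data.frame(chrom = true_origins$chrom[1] %||% "chrS1",
                            start = s, end = s + as.integer(w),
                            stringsAsFactors = FALSE)
        kept <- rbind(kept[, c("chrom", "start", "end")], extra)
      } else {
        kept <- kept[, c("chrom", "start", "end"), drop = FALSE]
      }
      kept <- kept[order(kept$chrom, kept$start), , drop = FALSE]
      rownames(kept) <- NULL
      callers[[cl]] <- kept
    }
    names(callers) <- sprintf("caller%s", LETTERS[seq_len(n_callers)])
    peaks[[r]] <- callers
  }
  names(peaks) <- sprintf("rep%d", seq_len(n_replicates))
  list(peaks = peaks, truth = true_origins)
}
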