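#!/usr/bin/env Rscript
# Generate every synthetic dataset the downstream analyses consume, with
# known ground truth, and write them under results/data/.  All later scripts
# read only these files (or regenerate with the same seed), so the whole
# workflow is reproducible from a single seed.

suppressMessages(library(oricorr))
seed <- 20260922L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

# Two-channel localization ROIs at a half-colocalized fraction, the regime
# the colocalization statistic is meant to distinguish from random.
smlm <- gen_smlm_rois(30, co_fraction = 0.5, seed = seed)
write_locs_csv(smlm_locs_table(smlm$rois), "results/data/smlm_locs.csv")
write_tsv(smlm$truth, "results/data/smlm_truth.tsv")

# Gene annotation plus a crosslink track with one 10-event binding site per
# gene over 0.01 events/nt background.
genes <- gen_genes(150, chrom_length = 4e5, length_range = c(1000, 1000),
                   seed = seed)
write_bed(genes, "results/data/genes.bed")
xl <- gen_crosslink_track(genes, background_rate = 0.01, sites_per_gene = 1,
                          site_events = 10, seed = seed)
write_crosslink_track(xl$track, "results/data/crosslinks")
write_tsv(xl$truth, "results/data/crosslink_truth.tsv")

# IP/input RIP counts: 100 of 1000 genes enriched four-fold, NB dispersion
# 0.1 (shared-latent Gamma-Poisson).
rip <- gen_rip_counts(1000, 100, fold_change = 4, dispersion = 0.1,
                      seed = seed)
write_tsv(rip$counts, "results/data/rip_counts.tsv")
writeLines(rip$truth$enriched, "results/data/rip_truth_enriched.txt")

# Three SNS-like replicates x two callers around 500 true origins with 20%
# replicate dropout and small boundary jitter.
origins <- data.frame(chrom = "chrS1",
                      start = seq(0L, 499L * 2000L, by = 2000L),
                      end = seq(0L, 499L * 2000L, by = 2000L) + 300L)
write_bed(cbind(origins, name = sprintf("ori%03d", 1:500), score = 0L,
                strand = "*"), "results/data/true_origins.bed")
peaks <- gen_peak_replicates(origins, 3, jitter_sd = 10, dropout = 0.2,
                             extra_rate = 0.05, chrom_length = 1002000,
                             seed = seed)
for (r in names(peaks$peaks))
  for (cl in names(peaks$peaks[[r]]))
    write_bed(peaks$peaks[[r]][[cl]],
              sprintf("results/data/peaks_%s_%s.bed", r, cl))

# TSS coverage for two conditions: quantile-scaled bumps; condition B
# halves the bump height at strongly bound genes only (quantiles 1-3),
# the known origin-activity defect the enrichment test should find.
mg_genes <- gen_genes(24, chrom_length = 2e6, length_range = c(3000, 3000),
                      gap_min = 10000, seed = seed)
write_bed(mg_genes, "results/data/metagene_genes.bed")
mg_quant <- rep(1:6, each = 4)
cov <- gen_coverage_tracks(mg_genes, mg_quant, base_amplitude = 1,
                           amplitude_step = 1, peak_width = 300,
                           noise_sd = 0.05, condition_effect = 0.5,
                           affected_genes = mg_genes$name[mg_quant <= 3],
                           flank_bp = 5000, seed = seed)
write_bedgraph(cov$track_a, "results/data/coverage_a.bedgraph")
write_bedgraph(cov$track_b, "results/data/coverage_b.bedgraph")
write_tsv(cov$truth, "results/data/coverage_truth.tsv")

# Fibers for two conditions: control at 1.0 kb/min and a faster-fork
# condition at 1.3 kb/min (the compensation signature of reduced firing).
fib_a <- gen_fiber_measurements(150, fork_speed_kb_min = 1.0, noise = 0.15,
                                n_origins = 4, n_origin_fibers = 80,
                                spacing_mean_kb = 100, seed = seed)
fib_b <- gen_fiber_measurements(150, fork_speed_kb_min = 1.3, noise = 0.15,
                                n_origins = 4, n_origin_fibers = 80,
                                spacing_mean_kb = 160, seed = seed + 1)
write_tsv(fib_a$fibers, "results/data/fibers_ctrl.tsv")
write_tsv(fib_b$fibers, "results/data/fibers_fast.tsv")
write_tsv(fib_a$origins, "results/data/fiber_origins_ctrl.tsv")
write_tsv(fib_b$origins, "results/data/fiber_origins_fast.tsv")

cat("simulated inputs written to results/data/ (seed", seed, ")\n")
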