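#!/usr/bin/env Rscript
# RIP enrichment calls, integration with the crosslink evidence into
# union/overlap interactor sets, hypergeometric overlap test, and the
# six-quantile stratification by CTPM.

suppressMessages(library(oricorr))
dir.create("results", showWarnings = FALSE)

counts <- read_tsv("results/data/rip_counts.tsv")
truth <- readLines("results/data/rip_truth_enriched.txt")

rip <- rip_enrichment(counts, use_adjusted = TRUE)
write_tsv(rip, "results/rip_results.tsv")
called <- rip$gene_id[rip$enriched]
cat(sprintf("RIP: %d genes called enriched; sensitivity %.2f, empirical FDR %.3f\n",
            length(called), mean(truth %in% called),
            mean(!(called %in% truth))))

# iCLIP side from the peak-calling step (03)
summ <- read_tsv("results/clip_gene_summary.tsv")
iclip_genes <- summ$gene_id[summ$n_sites >= 1]

universe <- union(counts$gene_id, summ$gene_id)
sets <- define_sets(called, iclip_genes, universe)
jsonlite::write_json(sets, "results/interactor_sets.json",
                     auto_unbox = FALSE)

hg <- hypergeometric_overlap(sets$rip_genes, sets$iclip_genes,
                             sets$universe)
cat(sprintf("evidence overlap: %d genes shared (hypergeometric p = %.3g over %d universe genes)\n",
            hg$k, hg$p, hg$n_universe))
cat("the two evidence channels were simulated with independent truth sets, so this overlap is a negative control: p should not be small\n")

# binding quantiles over the union set, strongest binders first
union_summ <- summ[summ$gene_id %in% sets$union, ]
if (nrow(union_summ) >= 6) {
  q <- assign_quantiles(union_summ, 6)
  write_tsv(q, "results/binding_quantiles.tsv")
  cat(sprintf("quantiles: Q1 median CTPM %.1f vs Q6 median CTPM %.1f\n",
              median(q$ctpm[q$quantile == "Q1"]),
              median(q$ctpm[q$quantile == "Q6"])))
}
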