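# oricorr

Quantitative pipelines connecting a chromatin protein's RNA-binding activity
with replication-origin usage, for genomicists studying how transcription
shapes DNA replication initiation. The package implements, as tested and
reusable R functions, the statistical backbone of such a study:

- **Colocalization by pair cross-correlation.** For two single-molecule
  localization channels with local densities ρ₁(R), ρ₂(R), the correlation at
  displacement **r** is

  c(**r**) = ⟨δρ₁(**R**) δρ₂(**R**+**r**)⟩_R / (⟨ρ₁⟩_R ⟨ρ₂⟩_R),
  δρᵢ = ρᵢ − ⟨ρᵢ⟩_R,

  angularly averaged to a radial profile c(r) and summarized as the mean over
  r ≤ 200 nm (the "association magnitude"). Cross-pairing channels from
  *different* nuclei (ROIs) provides the randomized null; experimental and
  randomized magnitudes are compared by a Welch unpaired two-sample t-test.
- **iCLIP-style crosslink peak calling.** Read truncation sites become
  per-nucleotide crosslink events (the nucleotide preceding the read); sites
  are scored by 3-nt window sums within co-transcribed regions and tested
  against 100 uniform within-region permutations with a monotone permutation
  FDR at 0.05.
- **RNA-interactor sets.** RIP enrichment over input (library-scaled log₂
  fold change with an exact binomial test, BH correction) is combined with
  the crosslink evidence (≥ 5 significant sites) into union and overlap
  (high-confidence) sets; overlaps are tested by exact hypergeometric tests,
  and interactors are stratified into six CTPM quantiles (Q1 = strongest
  binding).
- **Consensus replication origins.** Two callers per replicate are combined
  by nonreciprocal (`-wa -u` style) intersection; intervals present in ≥ 2 of
  3 replicates (single-linkage, ≥ 1 bp) form the consensus, whose enrichment
  at interactor TSSs is tested hypergeometrically.
- **TSS metagenes and permutation GSEA.** Coverage in ±5 kb / 10-bp bins
  around TSSs, strand-oriented; conditions compared by a paired t-test across
  bins, Euclidean distance and grand-mean fold change; gene sets tested
  against a ranked statistic by the classic weighted running-sum enrichment
  score with gene-set permutations.
- **DNA-fiber metrics.** Fork rate = IdU track length × 2.59 kb/µm ÷ 20 min;
  inter-origin distances from adjacent initiation events; groups compared by
  the exact Mann–Whitney U test (normal approximation with tie correction for
  larger samples).

Every stage has a synthetic-data generator with known ground truth
(`gen_smlm_rois()`, `gen_genes()`, `gen_crosslink_track()`,
`gen_rip_counts()`, `gen_coverage_tracks()`, `gen_peak_replicates()`,
`gen_fiber_measurements()`), so sensitivity, false-discovery control and
calibration are measurable without any sequencing download.

## Worked example

```r
library(oricorr)

sim <- gen_smlm_rois(30, co_fraction = 0.5, seed = 20260922)
exp_mag <- smlm_experimental(sim$rois)          # per-ROI magnitudes
rnd_mag <- randomized_control(sim$rois, seed = 20260922)
cmp <- compare_exp_vs_random(exp_mag, rnd_mag)
```

With half of the clusters truly shared between the channels this prints

```
association magnitude: experimental 0.921 +/- 0.025
                       vs randomized -0.011 +/- 0.024
                       (Welch t = 26.9, p = 2.03e-34)
```

i.e. the experimental ROIs carry a strong short-range density correlation
while cross-ROI pairings sit at zero, exactly the contrast the statistic is
designed to detect. The full workflow lives in `analysis/01_simulate.R`
through `analysis/07_fibers.R`; each script prints what it found and writes
its tables under `results/`. For instance `analysis/07_fibers.R` reports

```
fork rate: median 1.02 vs 1.34 kb/min (MW p = 1.12e-32, n = 150/150)
inter-origin distance: median 77 vs 98 kb (MW p = 7.37e-03, n = 240/240)
```

recovering the simulated fork-speed shift and the wider origin spacing that
accompanies reduced firing.

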