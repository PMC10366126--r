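---
title: "Methods: models, conventions and calibration in oricorr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and calibration in oricorr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oricorr)
```

oricorr implements the statistical machinery of a study linking a chromatin
protein's RNA binding to replication-origin activation: imaging
colocalization, crosslink peak calling, interactor-set construction, origin
consensus, metagene comparison with gene-set enrichment, and fiber metrics.
This vignette records the models behind each component, the conventions we
had to fix where the procedures are commonly under-specified, and what the
synthetic-data calibrations do and do not demonstrate.

Throughout the package genomic coordinates are 0-based half-open (BED
convention) on a flat chromosome namespace; a `+` gene `[s, e)` has its TSS
at `s`, a `-` gene at `e - 1`. All generators derive independent per-module
random substreams deterministically from one global seed, so any result is
reproducible from a single integer.

## Colocalization by pair cross-correlation

Two localization channels are rasterized to local-density images (default
pixel 20 nm, a typical STORM rendering scale: fine enough to resolve
cluster-scale structure, coarse enough that pixels are well populated). The
fluctuation cross-correlation

$$c(\mathbf r) = \frac{\langle \delta\rho_1(\mathbf R)\,
\delta\rho_2(\mathbf R + \mathbf r)\rangle_{\mathbf R}}
{\langle\rho_1\rangle_{\mathbf R}\,\langle\rho_2\rangle_{\mathbf R}}$$

is evaluated on the grid either by a zero-padded FFT (default) or by an
explicit double loop; the two agree to machine precision, and the tests
assert `< 1e-10` over random grids. Numerical choices:

- **Boundary handling.** Nuclei are not periodic, so shifted images are
  cropped to their valid overlap; per-displacement means divide by the
  overlap pixel count, while the normalizing means $\langle\rho_i\rangle$
  are always full-grid. This is unbiased at small r and only mildly
  conservative at large r.
- **Radial profile.** $c(\mathbf r)$ is averaged over angle in annuli one
  pixel wide; empty annuli are reported as missing, never zero-filled.
- **Scalar summary.** The per-ROI "association magnitude" is the mean of
  c(r) over r ≤ 200 nm. The summary radius is a declared convention (the
  scalar is rarely defined explicitly in imaging papers); it is exposed as
  an argument, and conclusions should be checked for stability against it.
- **Randomization null.** Channel 1 of each ROI is paired with channel 2 of
  a different ROI. The default is one seeded derangement, giving a control
  group the same size as the experimental one for the Welch t-test; the
  alternative `scheme = "all"` enumerates every ordered cross pair. Welch
  rather than pooled-variance t is used because group variances have no
  reason to be equal.

The ROI generator plants Gaussian clusters (default sd 30 nm, 25 molecules)
over a uniform background, with a fraction `co_fraction` of cluster centers
shared between channels. Cluster scale and density are not dictated by any
measurement; they were chosen once as plausible nuclear values and stay
fixed. The generator reproduces the *statistical* structure the correlation
assumes — clustered point patterns with a tunable shared component — but not
detector artifacts, localization drift, or hand-drawn nuclear outlines
(ROIs are axis-aligned squares). Calibration on 100 independent-channel ROIs
shows the mean profile within ±3 SE of zero at every radius, and the
magnitude increases strictly with `co_fraction`; passing these says the
statistic is unbiased and monotone on its intended signal, not that real
nuclei lack confounders.

## Crosslink sites and permutation peak calling

Crosslink events are the nucleotide preceding the read in transcript
orientation: a `+` read `[s, e)` yields an event at `s − 1`, a `-` read at
`e`. The minus-strand reading of "preceding" follows the standard iCLIP
truncation convention. CPM normalization is `count × 1e6 / library size`.

Within each co-transcribed region, each nucleotide with events is scored by
the 3-nt centered window sum. The null re-places the region's events
uniformly and independently across the region's nucleotides (preserving the
total), 100 times; for observed score s,

FDR(s) = mean permuted number of sites scoring ≥ s ÷ observed number
scoring ≥ s,

capped at 1 and made monotone non-increasing in s by a cumulative maximum
from high scores downward, so thresholding is coherent. Sites with
FDR < 0.05 are reported. The uniform exchangeable null is the simplest
reading of "randomized data within co-transcribed regions"; it ignores
within-gene coverage gradients, so on real data regions should be chosen at
a scale where uniformity is defensible. On synthetic tracks the caller
recovers 10-event sites over 0.01 events/nt background with sensitivity
≈ 1 while calling < 1 % of background nucleotides.

Gene-level summaries count significant sites and events per gene; CTPM is
gene events × 1e6 / library size. Where evidence sets are built, the site
threshold is ≥ 5 (the stricter published wording ">5" appears alongside
"5 or more" in equivalent contexts; we fixed ≥ 5 and made it an argument
rather than guessing intent). Nested or ambiguous gene overlaps resolve to
the longest containing same-strand gene, a deterministic stand-in for
annotation-hierarchy rules that live in external software.

## RIP enrichment and interactor sets

The published analysis used a full shrinkage-based differential package for
RIP calls; re-implementing that estimator is out of scope, so the package
substitutes a declared simpler test: log₂ fold change of library-scaled
abundances (pseudocount 0.5 by default) and a two-sided exact binomial test
of the IP count among `ip + input` trials with success probability
`lib_ip / (lib_ip + lib_input)`, BH-corrected. Replicating any published
gene list is explicitly *not* a goal; the test surface is recovery on
synthetic truth.

The count generator is a shared-latent Gamma–Poisson: each gene draws one
Gamma factor (variance = `dispersion`) multiplying a base abundance, and IP
and input are Poisson around that shared latent value. Marginally each
count is negative-binomial with the stated dispersion (`dispersion = 0`
degenerates to Poisson), and — because biological variability is shared
between the two libraries of the same gene — the IP/total ratio of an
unenriched gene is exactly binomial, so the test is calibrated by
construction. This models IP and input drawn from the same underlying
population; it does not model batch effects between libraries or
gene-specific IP efficiency. Under it, 100 genes enriched four-fold among
1000 (dispersion 0.1) are recovered with sensitivity 1.0 at empirical
FDR ≈ 0.01.

Evidence sets follow set algebra (union = broad interactors, overlap =
high-confidence), tested by exact upper-tail hypergeometric p-values. The
universe is an explicit argument — published hypergeometric p-values are
rarely recoverable because the universe is unstated, which is why the
package forces the caller to name one. Quantiles Q1…Q6 are equal-count by
CTPM descending (Q1 strongest, matching the use of "Q1–Q3" for stronger
binders); ties break by gene id and remainders go to the stronger
quantiles, so the partition is deterministic. Equal-count (not
equal-range) quantiles were chosen because the stratification is used for
group comparisons that need balanced sizes.

## Consensus origins

Per replicate, caller A's peaks overlapping ≥ 1 bp of caller B are kept
unmodified (nonreciprocal intersection). Across replicates, intervals are
single-linkage clustered by ≥ 1 bp overlap and clusters touched by at least
2 distinct replicates are emitted as the union of their members — "present
in at least two replicates" needs a merged-coordinate rule, and the union
is order-independent and deterministic. Origins are unstranded. With
replicate-level dropout d = 0.2 and three replicates, expected consensus
recall is 3(1−d)²d + (1−d)³ = 0.896; the simulation reproduces it within
its binomial confidence interval, and dropout 0 recovers truth exactly.
TSS enrichment declares a gene origin-bearing when TSS ± flank (default
1 kb) overlaps any consensus interval, then applies the hypergeometric
test.

## Metagenes and gene-set enrichment

Coverage matrices are genes × bins of mean signal in TSS ± 5 kb, 10-bp bins
(1000 columns), minus-strand rows reversed so columns always read
upstream → downstream; windows beyond chromosome ends are truncated to
zero and counted. Two conditions are reduced to their mean bin profiles and
compared by (i) a paired two-tailed t-test *across bins* — the pairing unit
is the bin of the two mean profiles, the reading that yields one Euclidean
distance per comparison as published workflows report — (ii) the Euclidean
distance between the profiles, and (iii) the fold change as the ratio of
grand means (a mean of per-bin ratios would explode at empty bins).
Identical inputs return distance 0, fold change 1, p = 1.

The enrichment score is the classic weighted running sum: hits add
$|s|^w/\sum_{set}|s|^w$, misses subtract $1/(N-|set|)$, ES is the signed
extremum of largest magnitude with the positive extremum preferred on ties
(compared at 1e-9 so round-off cannot flip the declared rule).
Significance uses gene-set permutation — random same-size sets — because
the ranked statistic is precomputed per gene and no sample labels exist to
permute; p = (1 + same-sign exceedances) / (1 + same-sign nulls). This is
the classic statistic, not the multilevel refinement used by modern GSEA
software, so very small p-values saturate at ~1/n_perm. Tests verify the
ES against an exhaustive independent walk for every subset of rankings up
to eight genes, and that null sets give near-uniform p.

## Fiber metrics

Fork rate converts the IdU track length with the standard stretching
factor, 2.59 kb/µm, divided by the 20-min pulse; inter-origin distances are
consecutive differences of origin positions (IdU-CldU-IdU patterns) in kb.
No filtering of unidirectional forks or track-end artifacts is applied
beyond the pattern rule itself. Group comparisons use the Mann–Whitney U
test ("Mann–Whitney t-test" in common usage) — exact for combined n ≤ 20
without ties, normal approximation with tie correction otherwise — and the
exact branch is verified against full permutation enumeration. The fiber
generator uses multiplicative Gaussian measurement noise (relative sd 0.15
by default, a realistic manual-measurement error) and exponential origin
spacing; at zero noise the metrics round-trip the generating parameters
exactly.

## Problem sizes, degenerate inputs, limitations

The shipped analyses and tests run at deliberately desk-sized scales —
30–100 ROIs of 2 µm, 150–200 genes of 1 kb for peak calling, 1000 genes
for RIP, 500 origins, 24 metagene genes, 150 fibers per group, 100–10,000
permutations — chosen so each calibration has clear statistical resolution
(e.g. binomial CIs around 0.896, ±3 SE null bands) at interactive runtimes.
The headline-scale numbers of a real study (tens of thousands of origins,
genome-wide annotations) are deliberately out of scope: they depend on
deposited sequencing data, whereas the package's claims are about the
correctness and calibration of the procedures.

Degenerate inputs are defined, not crashed on: zero-variance group
comparisons return p = 1 on equal means; empty regions yield no calls;
both-zero RIP counts give log₂FC 0, p 1; degenerate pooled proportions give
z = 0, p = 1; empty radial bins are flagged. Errors are reserved for
contract violations (points outside bounds, end ≤ start, single-ROI
randomization, fewer genes than quantiles).

What passing the synthetic calibrations shows is that each detector is
unbiased under its own null and recovers planted signal under its own
generative model. Real data violate these models in known ways — spatial
inhomogeneity of nuclei, coverage gradients along genes, IP efficiency
variation, caller-specific peak-shape biases — and the corresponding
parameters (summary radius, region choice, universe, quantile count) are
exposed precisely so those checks can be repeated under the user's own
assumptions.
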