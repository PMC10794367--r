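---
title: "Building and evaluating population-specific recombination maps with recombmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and evaluating population-specific recombination maps with recombmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recombmap)
```

## The problem

LD-based methods estimate the *population-scaled* recombination rate
$\rho = 4N_e r$ in overlapping windows of SNPs, where $r$ is the
per-generation sex-averaged rate and $N_e$ the effective population size.
Turning those window estimates into a usable genetic map requires stitching
the windows together, removing the demographic scale factor $4N_e$, and
guarding the result against artifacts in regions where the marker panel is
too sparse to support reliable inference.  Once a map exists, the question
that matters to practitioners is how much the choice of map changes the
analyses that consume it: IBD-based relatedness, local-ancestry inference,
imputation, and haplotype-based selection scans (iHS).

`recombmap` implements that entire post-estimation pipeline, plus a
synthetic-data module that generates every input with the statistical
structure the analyses assume, so the whole chain is testable without any
cohort data.

## Map assembly and rescaling

**Stitching.** Adjacent estimation windows share a block of overlap SNPs,
each with an independently estimated $\rho$.  `stitch_windows()` keeps the
proximal half of every overlap: for $o$ shared SNPs the left window
contributes intervals up to shared SNP $\lfloor o/2\rfloor$ and the right
window contributes from there on.  For odd $o$ the cut is taken
$\lfloor o/2\rfloor$ SNPs from the left (a deterministic, documented
tie-break); for $o = 1$ the single shared SNP is the cut.  Any divergence in
the shared positions is a hard error naming the first divergent position,
because it indicates the windows were not built from the same marker list.

**$4N_e$ estimation.** `estimate_fourNe()` regresses window means of
$\rho$ (per bp) on window means of a reference map's $r$ (per bp) in 5 Mb
windows anchored at coordinate 0; because $\rho = 4N_e r$ passes through the
origin, the default fit has no intercept and its slope is the dimensionless
$4N_e$ (an intercept variant is available via `intercept = TRUE`).  The
reference rate is first projected onto the $\rho$ track's SNP intervals
(bp-weighted mean per interval), and both tracks are then aggregated from
that identical piecewise structure, with masked bp excluded from the
weights.  This choice — aggregating *corresponding* rates at the positions
where $\rho$ was estimated — makes the estimator exact in the noiseless
limit: if $\rho_i = 4N_e \bar r_i$ on every interval, every window mean
satisfies the same proportionality and the slope recovers $4N_e$ to
floating-point accuracy.  The alternative (aggregating each track on its own
support) leaves window-boundary fragments where the two tracks average over
different structures, and is not exact.

Under multiplicative lognormal noise $\varepsilon\sim\mathrm{LN}(0,\sigma^2)$
the slope estimates $4N_e\,E[\varepsilon] = 4N_e e^{\sigma^2/2}$ — a +4.6%
bias at $\sigma = 0.3$ that is inherent to regressing a noisy multiplicative
quantity, visible in the recovery tests, and well inside their 10% band.

**Rescaling.** `rescale_to_cM()` divides each interval's $\rho$ by the
fitted $4N_e$ and converts units ($\rho/\mathrm{kb} \times 10^5 / 4N_e$ =
cM/Mb), accumulating cumulative cM from 0 at the first SNP.  Released maps
in the wild differ on whether the cM origin sits at position 0 or the first
SNP; we anchor at the first SNP and state it here.

## Comparing landscapes

`bin_map()` averages rates into fixed non-overlapping bins anchored at
coordinate 0 (so maps from different cohorts share a bin universe),
bp-weighted over unmasked covered bp.  Bins with no unmasked coverage, or
more than 90% of their width masked, are flagged missing — a partially
masked bin estimated from a sliver of sequence would otherwise contribute
single-interval noise.  `correlate_maps()` computes Pearson correlations
over jointly non-missing bins (pairwise exclusion, no imputation);
`call_hotspots()` takes the top $\lceil qn\rceil$ non-missing 50 kb bins by
mean rate (ties to the lower index, for determinism), and
`hotspot_sharing()` reports $|A\cap B|/|A|$, which is symmetric because both
sets have the same size by construction.  Hotspot percentiles are computed
genome-wide over the supplied track; per-chromosome calling can be had by
comparing per-chromosome tracks.

A caution that the package's own tests document: when the simulated
landscape has only fine-scale structure (i.i.d. 10 kb background blocks and
an i.i.d. Poisson hotspot process) and the estimation noise is i.i.d. per
marker interval, binned signal variance and binned noise variance both decay
as $1/\text{bin width}$, so the expected replicate-pair correlation is
essentially *scale-free* (~0.92 at every resolution from 10 kb to 5 Mb at
the default settings) rather than increasing with coarsening.  Real
LD-based maps show correlations that rise with bin size because real
landscapes carry broad regional structure and real estimation error is
autocorrelated; reproducing that pattern would require a multi-scale
landscape model, which the generator deliberately does not include.  Passing
correlation tests here therefore demonstrate concordance levels, not the
coarsening trend.

## Analysis masks

`build_density_mask()` flags 500 kb tiling windows (50 kb steps) containing
fewer than 15 markers and unions the flagged windows into a mask; window
membership is half-open $[s, s+500\text{kb})$ so boundary markers are
counted exactly once.  Masking the whole flagged window (rather than the
50 kb increment) is the conservative reading and the default; a trailing
partial window of width $w$ is tested against the proportional threshold
$\lceil 15\,w/500\text{kb}\rceil$ so chromosome ends are not auto-masked.
`apply_mask_to_map()` zeroes genetic distance across masked bp — partially
overlapped map intervals are shortened proportionally — so the total map
length drops by exactly the masked genetic length, and
`mask_intersect()` performs exact half-open interval subtraction for
segment data.

## IBD and kinship

`merge_segments()` merges segments on the same haplotype pair whose genetic
gap is under 0.6 cM (the conventional setting for kinship work; 0.5 cM is
conventional when the segments feed IBD-based map inference), applied
transitively.  The companion genotype-discordance check used by the standard
merge tool ("1 allowed error") requires genotypes, which never enter this
pipeline; merging here is gap-only and flagged as such.  After
`trim_and_measure()` excises masked portions, `kinship()` computes
$\varphi = \sum \text{IBD cM} / (4\,L_{\text{cM}})$ with $L_{\text{cM}}$
the genetic length of the *masked* map — numerator and denominator always
refer to the same map and mask.  All haplotype-pair segments of a pair are
summed without deduplication, so regions of IBD2 count twice, consistent
with the formula's plain reading.  Degrees use the standard powers-of-two
thresholds with a strict cutoff at 0.0442: a pair at exactly 0.0442 is not
3rd degree or closer.  $\varphi$ is invariant to uniform rescaling of the
map, since both sides of the ratio scale together — a property test.

The IBD generator draws, for a pair separated by $m$ meioses, segments of
Exponential(mean $100/m$ cM) genetic length with a *deterministic* count
$n = \mathrm{round}(4\varphi^* L/\text{mean len})$, $\varphi^* = 2^{-(m+1)}$,
placed uniformly without overlap on one of the four haplotype-pair channels
(long segments first, to keep placement failures negligible).  A Poisson
count would match the same expectation but inflates the variance of
$\hat\varphi$ enough that the degree-recovery targets cannot be met even in
principle at a human-genome scale; the deterministic count keeps the
generator's marginal segment-length law while representing the
between-relative variance conservatively.  Parent–offspring ($m=1$) is one
fully shared haplotype per chromosome, so $\hat\varphi = 0.25$ exactly.
Note $\varphi^* = 2^{-(m+1)}$ counts a single genealogical path: $m = 3$
corresponds to the 3rd-degree kinship band and $m = 4$ falls below the
0.0442 cutoff ("unrelated/distant"), which is how the truth table labels
it.

## Local ancestry and imputation metrics

`lai_concordance()` compares two call sets under a four-way ancestry model
(PNS/AFR/EAS/EUR by default).  Haplotype order is arbitrary between runs, so
per site and individual both pairings of the two haplotype calls are
evaluated and the one with more label agreements wins; agreement ties are
resolved toward the pairing with the larger joint probability mass, which
makes the choice — and hence the concordance — exactly invariant under
haplotype column order in either input (a tie broken by column order would
not be).  For each
matched haplotype the product of the two runs' marginal probabilities for
their called labels is accumulated at cell (call$_a$, call$_b$) of a 4×4
joint matrix; concordance is the diagonal share of the total mass, and is
exactly 100% for identical tracks or for tracks differing only by haplotype
swaps.  Every haplotype-site is weighted equally; per-individual averaging
would be the natural alternative if individuals had very different call
counts.  `hard_calls = TRUE` switches to counting matched argmax calls.

`imputation_accuracy()` is the squared Pearson correlation of imputed
dosage with sequenced genotype per SNP (zero-variance SNPs dropped and
counted), and `compare_accuracy()` runs a paired Wilcoxon signed-rank test
over SNP-matched $r^2$ values — exact for $\le 25$ non-zero differences,
normal approximation with continuity correction otherwise, zero differences
dropped (the classical treatment; the count is reported) — alongside
medians in the 0.5–1%, 1–5% and 5–50% MAF bins.

## The selection scan

`ehh()` computes extended haplotype homozygosity exactly: the proportion of
carrier pairs identical over every SNP from the core outward, which is 1 at
the core and non-increasing.  `ihs_unstandardized()` integrates EHH against
genetic distance (trapezoid on the cM scale from `interpolate_cM()`)
outward in both directions, truncating after the first point below the EHH
cutoff (default 0.05, the reference implementation's default, exposed as a
flag), and flags a SNP rather than scoring it when the walk reaches a
chromosome end before decaying, crosses a physical gap larger than 200 kb,
or either allele has fewer than two carriers.  The unstandardized score is
$\ln(\mathrm{iHH}_A/\mathrm{iHH}_D)$; `normalize_ihs()` standardizes within
50 equal-width derived-frequency bins (100 bins is brittle at desk-scale SNP
counts; the bin count is a flag), merging bins with fewer than two scores or
zero variance into their nearest populated neighbour.  Flagged SNPs are
excluded from normalization and counted.  Two invariances are asserted by
tests: swapping derived/ancestral labels negates the score, and uniformly
scaling the map leaves every $Z$ unchanged (the scale cancels in the
log-ratio).  The hot loops (the EHH walk and the Wright–Fisher generation
loop) are implemented in C++; the R-level `ehh()` keeps the readable
definition and both are checked against a brute-force all-pairs oracle.

`cross_map_discordance()` reports SNPs significant under one map
($|Z| > 4$) but attenuated under another ($|Z| < 2$), clustered into loci
at 100 kb.  `permutation_null()` estimates the between-run baseline for
that count by re-analysing disjoint random haplotype subsets under a single
map.  "Permutations using the same map" admits several constructions; the
disjoint-subsample scheme is one reading, chosen because it needs no
external data and upper-bounds between-run variability (two half-size
subsets differ more than two full-sample runs would), and it is documented
as an interpretation, not asserted as canonical.

## The Wright–Fisher generator and what it does not emulate

`simulate_haplotypes()` runs a discrete-generation Wright–Fisher population
of `N_wf` diploids (default 150) for `generations` generations (default
120), with crossovers per meiosis Poisson with mean $L_{\text{cM}}/100$
placed by inverse interpolation through the map, and optional additive
selection ($w = 1 + s g$) at one site, restarting with a perturbed seed if
the selected allele is lost.  Sites are seeded at initialization with
independent derived-allele frequencies drawn from a $1/p$ density on
[0.05, 0.95]; LD then accrues through drift and recombination.  This
desk-scale design has consequences the tests are written around:

* Haplotype identity at long range reflects coalescence *within the
  simulated generations* only.  Chromosomes used for iHS work are given at
  least ~50 cM of genetic length so EHH decays below the 0.05 cutoff away
  from chromosome ends; SNPs whose walk hits an end are flagged, exactly as
  on real data near telomeres.
* Neutral raw iHS has a standard deviation of ~1.2–1.35 at these population
  sizes — genealogical noise that does not shrink appreciably with `N_wf`.
  Scores beyond $|Z| \approx 4$ are therefore rare at a few thousand SNPs,
  whereas a cohort-scale scan of ~500k SNPs has a far deeper tail.  The
  map-sensitivity tests consequently assert the *directional* effect — a
  ×10 rate inflation over 1 Mb changes $|Z|$ about three-fold more inside
  the region than outside — which reproduces robustly, while counts of
  4-vs-2 threshold flips at this scale sit at zero against a subsample null
  of ~0.3–1 and are reported rather than asserted.
* Sweeps seeded at 10% frequency are soft (dozens of independent founder
  backgrounds) and carry little haplotype signal; the sweep-detection test
  uses a single-copy hard sweep ($s = 0.12$, 60 generations) conditioned on
  an incomplete final frequency in [0.6, 0.9], where the sweep's
  neighbourhood ranks in the genome-wide top 5% of $|Z|$.

## Generator defaults

| Parameter | Default | Why |
|---|---|---|
| background rate | 1 cM/Mb, gamma(shape 2) per 10 kb block | genome-average human rate with realistic fine-scale dispersion |
| hotspots | 10 per Mb, 2 kb wide, ×20 | ~100 kb spacing and intensities typical of human hotspot maps |
| $4N_e$ | 20,000 | order of LD-based estimates for large human populations |
| $\rho$ noise | lognormal, $\sigma = 0.3$ | multiplicative, keeps $\rho \ge 0$, matches the roughly multiplicative error of posterior-mean estimates |
| marker density | 0.485 per kb | 242.5 markers per 500 kb, a genotyping-array density |
| window layout | 4000 SNPs, 200 overlap | the standard windowing for LD-based estimation |
| WF population | 150 diploids, 120 generations | desk-scale: large enough for haplotype structure, small enough for seconds-per-simulation |

Simulation sizes quoted in the tests (20–100 Mb genomes, 8k–20k seeded
sites, 200 sampled haplotypes, 500 pairs per relatedness degree) were chosen
so each statistic is estimated with comfortable margin at desk scale.

## Numerical conventions

Internally every coordinate is 0-based half-open; map and IBD files are
converted from their native 1-based conventions at the I/O boundary, and BED
passes through unchanged.  Interpolation outside a map's span clamps to the
terminal cumulative value (zero-rate extrapolation) — conservative, since
extrapolating a terminal rate would invent genetic distance where there are
no markers.  Inverse interpolation across zero-rate stretches returns the
left endpoint.  Map writing uses shortest round-tripping decimal
representations, so write–read–write is byte-stable.

## Known limitations

The generators emulate the *statistical structure* the pipeline assumes,
not population-genetic reality: no coalescent ancestry, no realistic site
frequency spectrum, no sex-specific maps, no genotyping error, and a
single-scale landscape model (see the caveat under *Comparing landscapes*).
Passing tests demonstrate that the pipeline's algebra, conventions and
statistical machinery are correct and that parameter recovery works under
the stated noise models; they do not certify performance on any particular
cohort.
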