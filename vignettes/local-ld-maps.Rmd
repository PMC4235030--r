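---
title: "Local LD maps and persistence of phase: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local LD maps and persistence of phase: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldscape)
```

## The quantities

`ldscape` works on phased haplotype panels: biallelic SNPs with physical
positions, two haplotypes per diploid individual, one panel per
population. Three quantities drive everything else.

**Signed r and r².** For markers $i$ and $j$, with $p_i$, $p_j$ the
alternate-allele frequencies and $p_{ij}$ the frequency of the
(alt, alt) haplotype,

$$r_{ij} = \frac{p_{ij} - p_i p_j}{\sqrt{p_i(1-p_i)\,p_j(1-p_j)}},
\qquad r^2_{ij} = r_{ij}^2 .$$

Because the input is phased, $p_{ij}$ is counted directly — no EM
composite-LD estimate is needed, and the formula is exact on the sample.
The sign convention is fixed by the alternate allele; relabelling the
alleles of exactly one marker of a pair negates $r$ and leaves $r^2$
unchanged, which is why allele matching matters for phase comparisons
(below). $r^2$ rather than $D'$ is used throughout: it is less sensitive
to allele frequencies and directly relevant to association and genomic
prediction.

**Persistence of phase.** For two populations $A$, $B$ and a set $P$ of
marker pairs formed from markers present in both,

$$\mathrm{cor}(r_{A,B}) =
\frac{\sum_{(i,j)\in P}(r_{ij(A)}-\bar r_A)(r_{ij(B)}-\bar r_B)}
     {S_A\, S_B},$$

a plain Pearson correlation of the signed $r$ vectors. High values mean
the same allele combinations travel together in both populations, so
marker effects estimated in one population should transfer to the other.

**The decay model.** Under drift–recombination equilibrium in an
isolated random-mating population, $E(r^2) = 1/(1+4cN_e)$ with $c$ the
recombination fraction and $N_e$ the effective population size
(`sved_expected_r2()`). Without a reliable genetic map, $4cN_e$ cannot
be decomposed, so the package models physical distance $d$ (Mb)
directly:

$$E(r^2_{ij}) = \frac{1}{1+\alpha d_{ij}},$$

with a single per-Mb decay rate $\alpha$ that conflates local
recombination rate and local effective size. The conditional
distribution of $r^2$ given $d$ is taken to be Gamma — empirically the
variance of $r^2$ grows roughly quadratically with its mean — so the
model is a Gamma GLM with inverse link. The linear predictor is
$\eta = 1 + \alpha d$: **the intercept is fixed at 1** (an offset), not
estimated, because the model form forces $E(r^2)\to 1$ as $d \to 0$. A
free-intercept fit would no longer be interpretable as a decay rate and
is deliberately not offered as a primary path.

## Fitting α

`fit_alpha()` minimises the Gamma deviance in the single parameter
$\alpha$. The inverse link is canonical for the Gamma family, so the
score equation is $\sum_k d_k (y_k - \mu_k) = 0$ with
$\mu_k = 1/(1+\alpha d_k)$, and the deviance is strictly convex on the
admissible region $1+\alpha d_k > 0$. The solver runs Newton steps with
a bisection fallback on the bracket
$(-1/d_{\max} + 10^{-9},\; 10^4)$, stopping when successive iterates
move by less than $10^{-10}$ (at most 100 iterations). This
one-dimensional scheme is guaranteed to terminate and avoids the IRLS
divergence that can occur when a window's trend is flat. The Gamma shape
(dispersion) cancels from the point estimate; it is estimated by the
Pearson moment only to report a standard error,
$\mathrm{se} = \sqrt{\hat\phi / \sum_k d_k^2/\eta_k^2}$. On data
generated from the noise-free mean curve the estimate is exact to
numerical tolerance, and on Gamma-noise data it matches `stats::glm`
with an offset term to seven digits (both facts are asserted in the test
suite).

Three conventions worth knowing:

* **Zero exclusion.** Pairs with $r^2 = 0$ (within a $10^{-12}$
  floating-point guard) are removed before fitting: a Gamma response is
  strictly positive, and exact zeros arise only from the degenerate
  rational-count case $p_{ij} = p_i p_j$.
* **Negative α.** A window in which LD *increases* with distance yields
  a negative $\hat\alpha$. It is reported as-is, never clamped —
  clamping would bias the map — and the derived $E(r^2)$ at the fixed
  display distance is reported missing whenever
  $1 + \hat\alpha d \le 0$.
* **Boundary hits.** If the score has no interior root the fit returns
  the bracket boundary flagged `converged = FALSE`.

## Sliding-window LD maps

`ld_map()` slides a window of $N$ consecutive markers (default
$N = 100$) along each chromosome, one marker per step, so a chromosome
with $m$ markers yields $m - N + 1$ windows. All $N(N-1)/2$ within-window
pairs feed one `fit_alpha()`; the result is recorded at the *middle*
marker of the window, taken as 0-based index $\lfloor N/2\rfloor$ (the
upper-middle marker for even $N$). A fixed marker count rather than a
fixed physical span keeps the fitting sample size constant across
windows, at the cost of a window span that varies with marker density.
Larger $N$ smooths the track toward the chromosome mean; smaller $N$
resolves finer structure with more fluctuation — comparing
$N \in \{50, 100, 200\}$ overlays is the intended diagnostic
(`plot_ld_map()`).

For display, $\hat\alpha$ is transformed to $E(r^2) = 1/(1+\hat\alpha d)$
at a fixed moderate distance, default $d = 10$ Mb (about the span of a
100-marker window at 100-kb spacing). The choice of $d$ is arbitrary
but monotone in $\hat\alpha$, so it changes the scale, not the shape, of
the map. Because $\hat\alpha$ depends on the distance range represented
in the fitted pairs, α values should only be compared between fits that
saw comparable distance ranges.

`chromosome_alpha()` estimates a whole-chromosome α by drawing
`n_pairs = 10000` pairs uniformly *without replacement* from all
within-chromosome pairs, fitting, and repeating `n_replicates = 1000`
times; the mean and standard deviation of the replicate estimates are
reported. Replicates draw sequentially from one generator seeded by the
`seed` argument, which makes the whole procedure reproducible; an
optional distance cap restricts the candidate pairs (by default all
within-chromosome pairs are candidates).

## Genome-wide curves and summaries

`binned_decay()` pools pairs (within chromosomes only — pairs never
cross a chromosome) into half-open 100-kb distance bins $[lo, hi)$ from
0 to 10 Mb and averages $r^2$ per bin. The half-open convention means a
pair at exactly the cap is excluded and a pair on an interior edge
counts in the upper bin; the pair-count-weighted mean of the bin means
reproduces the overall mean exactly. `ld_at_distances()` tabulates mean
$r^2$ per chromosome in 100-kb half-open windows *below* each target
distance (so "0.5 Mb" means $d \in [0.4, 0.5)$) — a bin-local reading,
with the window width exposed as an argument. `adjacent_summary()`
reports spacing and $r^2$ summaries for consecutive-marker pairs, and
`compare_adjacent_ld()` compares two populations' adjacent-pair $r^2$
with a Welch (unequal-variance) two-sample t-test, the appropriate
choice when pair counts and spreads differ; the fully degenerate case
(both groups constant) is handled explicitly.

## Persistence of phase: scenarios and sign hygiene

Marker matching across panels (`common_markers()`) is by (chromosome,
position) with an allele-set check, not by SNP id, because id dialects
differ between datasets. A matched marker whose ref/alt labels are
swapped in one panel is kept with a *flip flag*; its $r$ values in that
panel are negated during phase computations (one flipped marker in a
pair negates the pair's $r$; two flips cancel). Markers whose allele
sets simply do not match are dropped with a logged count — no strand
guessing is attempted, so ambiguous flips are lost rather than silently
mis-signed.

Two common-marker scenarios mirror standard practice for a trio of
populations: Scenario I intersects markers across all three populations
(one shared marker list; curves for different pairs are directly
comparable), Scenario II intersects each pair separately (more markers
per pair; sensitive to pair-specific chip content). Scenario I's set is
a subset of every Scenario II set by construction. `binned_phase_decay()`
computes the per-distance-bin phase correlation over matched pairs
(bins with fewer than three pairs are flagged missing), and
`local_phase()` computes it in sliding windows of $N = 50$ matched
markers, recorded at the middle matched marker, with zero-variance
windows flagged.

## Quality control

`filter_samples_by_missingness()` removes individuals missing more than
10% of genotypes (a fraction exactly at the threshold is kept). Marker
filtering applies, in order: call rate < 0.90, minor allele frequency
below 0.05 (exactly 0.05 is kept), and an exact Hardy–Weinberg test at
$P < 10^{-7}$; each removed marker is attributed to the first failing
rule. The HWE test is the exact conditional test (sum of probabilities
of heterozygote counts no more probable than the observed one, given the
allele counts): at a $10^{-7}$ threshold the decision lives in the
extreme tail where the chi-square approximation is unreliable.
`prune_relatives()` removes family structure the standard way — drop any
sampled animal that is a recorded parent of another sample, then keep
one animal per full-sib group (both parents known and shared), chosen
uniformly at random under a seed. MAF and HWE are computed on observed
(non-missing) data; downstream LD functions require complete data, so
panels with residual missingness after QC must be imputed externally or
subset.

## The synthetic generator

Real multi-breed chip data are rarely shareable, so the package carries
its own generator, used by every end-to-end test.

* **Founder mosaic** (`gen_mosaic_population()`): $K$ founder
  haplotypes, i.i.d. Bernoulli(0.5) per site; each sample haplotype
  copies a founder and switches to a uniformly drawn founder between
  consecutive markers with probability $1-\exp(-\rho\,\Delta d)$. LD
  therefore decays with distance at a rate controlled by $\rho$
  (expected switches per Mb). The short-range $r^2$ plateau is set by
  founder diversity, approximately $1/(K-1)$, so the default $K = 4$
  gives a plateau near 0.33 — the strong adjacent-marker LD typical of
  intensively selected livestock populations; the default $\rho = 1$
  with ~100-kb marker spacing gives curves that decay over a few Mb.
  Defaults: 3000 markers on one 300-Mb chromosome (a pig-chromosome-1
  scale), 100 diploids. Markers monomorphic in the sample are dropped
  with a message.
* **Diverged populations** (`gen_diverged_populations()`): a base
  population of `Ne` diploids from the mosaic model; each daughter
  evolves independently for $t$ generations of Wright–Fisher
  reproduction (random mating with replacement, no mutation) with
  per-interval crossover probability
  $\tfrac12(1-e^{-2c\,\Delta d})$ at `rec_rate_mb` Morgans/Mb (default
  0.01, i.e. 1 cM/Mb, a typical mammalian average — a separate knob from
  $\rho$, which shapes the *base* haplotype pool). Sampled individuals
  are offspring of a final reproduction round. Divergence is by drift
  and recombination only, so daughter panels stay marker-matched by
  construction; markers fixed within a daughter are dropped from that
  daughter, as per-population QC would do. Short-distance phase
  correlation between daughters decreases with divergence time, and a
  recently split pair retains more shared phase than either member does
  with an anciently diverged third population — the qualitative
  behaviour expected of breed pairs with recent common ancestry.
* **Distribution-level pairs** (`gen_glm_pairs()`): $(d, r^2)$ draws
  with $d$ uniform and $r^2 \sim$ Gamma with mean $1/(1+\alpha d)$ —
  the fitter's own noise model, used for exact-recovery and
  unbiasedness checks with known truth.

What the generator does **not** emulate: chip ascertainment bias,
mutation, selection, genotyping error, non-autosomal inheritance, and
realistic site-frequency spectra. Passing tests therefore demonstrate
correctness of the estimators under a controlled LD-generating process,
not robustness to every artefact of real chip data.

**Problem sizes.** The test suite and the acceptance script run at desk
scale, chosen so the full suite completes in a few minutes: panels of
300–500 markers over 30–50 Mb for single-population checks; `Ne` of
100–150 with divergence times up to 500 generations for the
Wright–Fisher designs (an `Ne` large enough that markers survive the
longest split); 10,000-pair subsamples with 200–1000 replicates for the
α recovery and chromosome-level analyses. The ancient-split design in
the three-population comparison uses $t = 200$ generations at
$N_e = 100$ (two coalescent time units), old enough to erode most
shared phase while leaving enough polymorphic markers to measure it.

## Known limitations

* α is a *composite* of local recombination and local effective size;
  the package deliberately does not try to disentangle them.
* LD functions require complete phased data; phasing and imputation are
  upstream concerns.
* Distance-binned and windowed estimates inherit the usual caveats of
  fixed marker-count windows: physical span varies with marker density,
  and α comparisons are only meaningful between fits over comparable
  distance ranges.
* The exact HWE test assumes autosomal diploid genotypes; no
  X-chromosome handling.
* Strand-ambiguous (A/T, C/G) markers whose labels disagree across
  panels are dropped during matching rather than resolved by frequency.
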