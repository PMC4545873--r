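---
title: "Cross-population selection scans: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-population selection scans: models, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sweepscan` detects signatures of recent positive selection by contrasting a
focal population against a reference population, the design used when a
selected breed is compared against related breeds. This vignette describes
the statistical models the package implements, the parameters that matter
and their defaults, what the built-in simulators emulate, and the numerical
and design choices a maintainer would want to know about.

## The haplotype statistic: XP-EHH

Extended haplotype homozygosity (EHH) between a core site and a target site
is the probability that two haplotypes drawn without replacement from a
population are identical over the inclusive span between the two sites:

$$\mathrm{EHH} = \frac{\sum_g \binom{n_g}{2}}{\binom{n}{2}},$$

where the $n_g$ are the sizes of the haplotype identity groups over the
span. A recent sweep creates one long common haplotype, so EHH decays
slowly with distance from a selected core. The integrated haplotype
homozygosity iHH is the trapezoidal integral of EHH against physical
position, walked outward from the core in both directions, and

$$\mathrm{XP\text{-}EHH}_{\mathrm{raw}} = \ln\!\left(\frac{\mathrm{iHH}_{\mathrm{focal}}}{\mathrm{iHH}_{\mathrm{ref}}}\right),$$

standardised genome-wide to mean 0 and variance 1. Large positive
standardised scores mean unusually extended haplotypes — a recent sweep —
in the focal population.

Choices worth knowing:

* **EHH at zero distance** is the core-site homozygosity (the grouping
  includes the core site), not 1. This makes EHH a pure function of the
  span, keeps it consistent with the brute-force identical-pair oracle used
  in the tests, and only shifts both populations' integrals by the same
  convention.
* **Common truncation span.** Both populations are integrated over the
  span decided by the *pooled* two-population EHH dropping below `cutoff`
  (default 0.05). A per-population truncation would integrate the two
  populations over different intervals and bias the log-ratio wherever one
  population's diversity is locally reduced — which is exactly where the
  statistic should be large.
* **Edges and gaps.** Integration stops at the chromosome's data edge or
  at an inter-site gap above `max_gap` (default 200 kb, guarding against
  assembly gaps); such scores are kept but flagged `edge_flag`, since
  dropping them silently would remove precisely the long-haplotype cores.
* **Physical distance.** Integration is over bp; no genetic map is used. A
  map-scaling constant would multiply both integrals alike and cancel in
  the ratio wherever it is locally constant.
* Sites where either iHH is 0 (the span collapsed to the core point) have
  an undefined log-ratio and are excluded from standardisation.

The inner identity-grouping walk is implemented in C++ (as the haplotype
statistics in this field's packages are); grouping is incremental, so each
extension step costs O(haplotypes).

## The frequency statistic: a composite-likelihood sweep scan

The second scan contrasts, at each grid position along the chromosome, a
neutral drift model for the focal population's allele frequencies given the
reference population's against a hitchhiking model:

* **Neutral model.** Given the reference frequency $p$, the focal
  pre-sampling frequency $q$ follows a Brownian drift approximation,
  $q \sim \mathcal{N}(p,\ \omega\, p(1-p))$, truncated to $(0,1)$ with the
  spill-over mass placed as point masses at 0 and 1. The observed focal
  count is binomial given $q$.
* **Drift scale.** $\omega$ is estimated genome-wide by the method of
  moments, $\hat\omega = \mathrm{mean}\left[(\hat q - p)^2 / (p(1-p))\right]$
  over sites with $0.05 < p < 0.95$. Because $\hat q$ is a sample
  frequency, this moment contains an extra sampling term of order
  $1/n_{\mathrm{focal}}$; at resequencing-scale haplotype counts it is
  small, and the package's recovery checks use deep sampling
  ($n_{\mathrm{focal}} = 1000$) so the moment isolates the drift scale.
* **Sweep model.** A sweep at distance $d$ lets a lineage escape with
  probability $c = 1 - e^{-r\, d\, t_s}$, with sweep duration
  $t_s = \ln(2Ns)/s$. Conditional on the neutral $q$, the post-sweep
  frequency is $1 - c + cq$ with probability $q$ (the site hitchhikes with
  the swept background) and $cq$ with probability $1-q$. At $c = 1$ the
  transform is the identity and the sweep model collapses onto the neutral
  one; at $c = 0$ all frequency mass moves to the boundaries.
* **Score.** At each grid point (spacing 2500 bp), sites within
  `window_radius` (12.5 kb) contribute independent log-likelihood terms;
  $\mathrm{CLR} = 2(\max_s \ell_{\mathrm{sweep}} - \ell_{\mathrm{neutral}})$
  over a geometric grid of 10 selection coefficients in $[10^{-4}, 0.5]$,
  floored at 0 (grid-resolution artifacts can otherwise produce small
  negative values). Ties in the argmax resolve toward the smaller, more
  conservative $s$; grid values with $2Ns \le 1$ are skipped because the
  sweep-duration formula is undefined there.

Numerical integration uses a fixed grid of 512 interior points with *exact
Gaussian cell masses* (`diff(pnorm(breaks))`) rather than density-times-width
weights: the weights and the two boundary masses then sum to 1 to machine
precision for any drift scale, and a deviation beyond 1e-6 can only signal
a genuine numerical failure. The test suite checks the quadrature against a
$10^6$-draw Monte-Carlo integration of the same integral.

Sites monomorphic in the reference population are excluded from the
composite likelihood: the drift law is degenerate there and assigns zero
likelihood to any focal polymorphism (there is no mutation in the model).
The original formulation of this scan family also down-weights sites in
high LD within a window; that weighting is intentionally not implemented
here, so strongly correlated sites contribute as if independent and CLR
magnitudes are comparable only within a run.

## Windows and significance

Both scans are summarised over consecutive non-overlapping 25-kb windows,
each represented by the maximum per-site (or per-grid-point) statistic it
contains. For XP-EHH, windows are binned by SNP count in increments of 200
(1–200, 201–400, 401–600, and a single >600 bin; upper edges inclusive) and
ranked within bins: `empirical_p = rank / B` with rank 1 for the largest
value, ties taking the worst rank of the tied set (the conservative
convention; the binning removes the dependence of a maximum on the number
of sites it is taken over). Windows with an empirical p strictly below 0.01
are flagged. For the composite-likelihood scan the threshold is the
empirical top-1% order statistic (the `ceiling(0.01 W)`-th largest window
value, no interpolation) and windows at or above it are flagged. Windows
containing no scored site are dropped — they have no maximum to rank —
rather than assigned p = 1.

Note a structural consequence of the strict cut: a run with $B \le 100$
windows in a bin cannot produce `empirical_p < 0.01` at all (the best
possible rank gives exactly $1/B \ge 0.01$). Single short simulated
chromosomes therefore validate the ranking machinery and the relative
elevation of the sweep region, not absolute significance calls; those need
genome-scale window counts.

## Gene annotation and set intersection

Significant windows are intersected with gene intervals under the shared
0-based half-open convention (≥1 bp overlap; a configurable flank defaults
to 0), each gene reported once per comparison and method with its
supporting windows. Candidate sets from different comparisons or methods
are combined with plain set algebra (`"xpehh & xpclr"`), mirroring the
cross-comparison intersections such analyses report.

## Breed-specific enrichment

For categorical per-haplotype site data (amino-acid residue classes, or
Indel presence Y/N), every (site, focal breed, focal category) combination
yields a 2×2 table — focal breed vs others, focal category vs others — and
a one-sided Fisher's exact test of odds ratio > 1 (upper hypergeometric
tail). In amino-acid mode the categories tested at a site are those
observed there across all breeds ($3 k_{\mathrm{site}}$ tests per site);
Indel mode always tests both Y and N ($3 \cdot 2$ per site). Counting is
per haplotype (two per diploid animal); a per-individual dominant coding
would halve the counts and weaken power but not change the design.
Bonferroni correction defaults to the per-gene family (all tests emitted
for that gene), matching a per-targeted-gene correction; a global scope is
available. Profile tables expose $-\log_{10} p$ per site together with both
reference lines (the Bonferroni cutoff $\alpha/m$ and the nominal
$\alpha = 0.05$).

## What the simulators emulate — and what they do not

`simulate_two_pop_sweep()` is a forward diploid Wright–Fisher model chosen
over a coalescent because the sweep, recombination, and two-population
structure are all explicit and the default scale (N = 500 diploids per
population, T = 200 generations, M = 2000 segregating sites on a 2.5-Mb
chromosome, r = 1e-8 per bp per generation) runs in seconds. Ancestral
variation follows the neutral SFS shape (derived count $i$ with probability
$\propto 1/i$); there is no new mutation after the split, so both
populations segregate one joint site set, matching a jointly called variant
panel. The beneficial allele starts as a *single copy* (a hard sweep) with
additive fitness 1, 1+s, 1+2s and the focal run restarts from the split
with a fresh deterministic sub-seed whenever the allele is lost (restart
count recorded; the reference population's stream is derived independently
of restarts, so conditioning the sweep never perturbs the drift control).
Monomorphic pooled sites are dropped on output.

It does **not** emulate realistic pig demography, mutation, background
selection, gene conversion, or sequencing error, and a 2.5-Mb chromosome
with r = 1e-8 has a total map length of only 0.025 crossovers per meiosis —
so a completed hard sweep affects most of the simulated chromosome rather
than a narrow locus. Passing power tests therefore show that the statistics
rank the sweep region above the background under idealised phased input,
not that real-data thresholds or gene lists would reproduce.

`simulate_freq_table()` draws allele-frequency data directly from the
generative model of the composite-likelihood scan (Gaussian drift, optional
two-branch hitchhiking transform, binomial sampling), which makes it the
right instrument for parameter-recovery checks but a tautological one for
model criticism. For the localisation experiment the package uses
r = 1e-7 with s = 0.05 on a 1-Mb chromosome: the hitchhiking footprint
scale $1/(r\, t_s)$ is then ≈ 130 kb, safely contained within the
chromosome, so the argmax-within-one-window check measures localisation
rather than the flat-plateau behaviour that arises when the footprint
exceeds the simulated region (at r = 1e-8 and s = 0.05 the footprint is
≈ 1.3 Mb). `simulate_gene_sites()` draws per-site baseline category
distributions from a flat Dirichlet shared across breeds and multiplies the
focal breed's odds of the focal category at enriched sites.

Problem sizes used by the validation suite are chosen to keep each check in
the seconds-to-minutes range at one CPU: 100 random haplotype sets for the
EHH oracle, 50 Monte-Carlo instances for the quadrature, 50 localisation
replicates, 20 end-to-end sweep replicates, and ≥10,000 Fisher tests for
the null-calibration bound.

## Degenerate inputs and tie-breaking, collected

* Multi-allelic, unphased, or missing genotypes exclude the whole site at
  load (counted and reported); the scans assume complete phased input.
* REF/ALT polarity is taken as-is (no ancestral polarisation): the
  log-ratio is polarity-free and the frequency models are symmetric, so
  polarity flips frequency-difference signs but not window ranks.
* Chromosomes are processed as found in the VCF; non-autosome handling is
  the caller's concern.
* Empirical-p ties: worst rank. CLR argmax ties: smaller s. Top-1%
  threshold ties: everything at the threshold is flagged.
* `clr` is floored at 0; grid points with no contributing sites are
  emitted with `clr = NA` and excluded from windows.

## Known limitations

* No LD down-weighting in the composite likelihood (see above).
* The drift model has no mutation; reference-monomorphic sites carry no
  information and are skipped.
* The moment estimator of $\omega$ absorbs a $1/n_{\mathrm{focal}}$
  sampling term at shallow sampling depths.
* Absolute significance calls need genome-scale window counts; short
  simulated chromosomes only support relative comparisons.
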