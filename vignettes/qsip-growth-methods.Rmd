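---
title: "Estimating taxon-specific growth from 18O-water qSIP: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating taxon-specific growth from 18O-water qSIP: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipgrowth)
```

## The measurement and its model

Quantitative stable isotope probing (qSIP) with ¹⁸O-labeled water measures
the growth of individual microbial taxa without adding any substrate other
than water: growing cells synthesize new DNA, and the oxygen in that DNA
comes largely from cellular water, so DNA built during the incubation is
heavier than DNA built before it. After incubation, community DNA is
spun to equilibrium in a CsCl gradient, fractionated by buoyant density,
and each fraction is characterized by (i) its total 16S rRNA gene copies
(qPCR) and (ii) the relative abundance of every taxon (amplicon
sequencing). The data unit `sipgrowth` consumes is that fraction table:
for every tube, a strictly increasing density grid $x_i$ (g mL⁻¹), total
copies per fraction, and per-taxon relative abundances $p_i$.

A taxon's position in the gradient is summarized by its **weighted average
density (WAD)**,

$$W = \frac{\sum_i x_i\, y_i}{\sum_i y_i}, \qquad y_i = p_i \times
\text{(total 16S copies in fraction } i),$$

and growth is inferred from the WAD shift between a labeled (¹⁸O) tube and
its paired unlabeled (¹⁶O) reference. The chain from shift to **excess atom
fraction (EAF)** runs through the taxon's GC content, because GC sets both
the unlabeled density and the nucleotide molecular weight:

$$G = \frac{W_{light} - 1.646057}{0.083506}, \qquad
M_{light} = 0.496\,G + 307.691,$$

$$M_{lab} = \left(\frac{W_{label} - W_{light}}{W_{light}} + 1\right)
M_{light}, \qquad
\mathrm{EAF} = \frac{M_{lab} - M_{light}}{12.07747}\,(1 - 0.002000429).$$

The constant 12.07747 g mol⁻¹ is the mass gain of a fully
¹⁸O-substituted average nucleotide and 0.002000429 the natural abundance
of ¹⁸O. These constants live in one table (`qsip_constants()`) shared by
the estimator and the forward simulator, so simulate-then-estimate round
trips are exact by construction rather than approximately consistent.

### Filters and aggregation

Two policies guard the raw estimates. A taxon qualifies in a tube only if
it occurs in **at least three consecutive fractions**
(`consecutive_fraction_filter`); scattered single-fraction detections are
treated as noise. And after per-block EAFs are averaged into a treatment
mean, **negative means are truncated to zero** (flagged), since negative
EAF is physically meaningless and arises from density noise around zero
growth. Truncation is applied at the treatment level; the raw per-block
values are retained for resampling.

The estimator (`qsip()`) averages per-block EAFs rather than per-block
density shifts; averaging the shifts first and converting once is
available via `average = "wad"`. The unlabeled reference is the paired
¹⁶O tube of the same block; when the taxon fails the occurrence filter
there, the mean WAD across the treatment's qualifying ¹⁶O tubes is used
instead and the estimate is flagged (`ref_fallback`), which retains taxa
that would otherwise be lost to one noisy reference tube.

Confidence intervals come from a percentile bootstrap over experimental
blocks (default 1000 resamples, 90% two-sided), the block being the unit
of independent replication.

## Downstream statistics

**Assemblage contrasts.** Treatment means of taxon-level EAF are compared
by one-way ANOVA with Tukey HSD and a compact letter display
(`assemblage_mean_contrast`). The taxon is the replication unit, matching
the assemblage-level comparison this supports; because taxa within a
block share environment, this is pseudo-replicated in the strict sense,
and a block-level alternative (`unit = "block"`) is provided.

**Warming responses.** Per-taxon $\Delta EAF = EAF_{treatment} -
EAF_{control}$ is computed for taxa growing in both treatments, with a
joint block bootstrap (the same resampled block set applied to both
treatments, preserving pairing) and a CI-based three-way classification
(positive / neutral / negative). Percent increases and van't Hoff
temperature sensitivities $Q_{10} = \text{ratio}^{10/\Delta T}$ translate
assemblage means into the community-level response scale. The default
$\Delta T$ is 1.6 °C: the field warming is usually described as
"approximately 1.5 °C", but 1.6 °C is the value consistent with the
jointly reported $Q_{10}$ pair (6.83 and 315) for assemblage ratios of
1.36 and 2.51, so it is the default and is exposed in `sip_config()`.

**Bootstrap calibration with four blocks.** A plain percentile interval
over $n = 4$ blocks undercovers substantially: in null simulations
(no treatment effect) it classifies roughly 10% of taxa per tail as
responders at a nominal 90% interval. `delta_eaf()` therefore defaults to
the *expanded* percentile interval, which reads the bootstrap
distribution at tails
$\Phi\!\left(-\sqrt{n/(n-1)}\; t_{\alpha/2,\,n-1}\right)$ instead of
$\alpha/2$ — the standard small-sample correction for exactly this
failure mode. With it, null misclassification falls to ~5–6% per tail.
The uncorrected interval remains available (`ci_method = "percentile"`).

**Occurrence partition.** Growing taxa (post-truncation EAF > 0) are
assigned to the $2^k - 1$ treatment-membership categories of a Venn
diagram; per-category treatment means are contrasted by Student's t test
(two member treatments) or ANOVA + Tukey (three or more).

**Rank aggregation.** Group means and $\Delta EAF$ at a chosen rank
(default order) are reported only for groups with at least three growing
representatives in *both* the warming treatment and the control; the
group $\Delta EAF$ is the mean taxon-level difference over representatives
growing in both.

## Phylogenetic signal

Blomberg's $K$ and Pagel's $\lambda$ are implemented from first
principles on the Brownian-motion covariance $C$ of the tree
($C_{ij}$ = root-to-MRCA depth; `tree_to_covariance`). All solves use a
Cholesky factorization — the inverse of $C$ is never formed — with an
eigendecomposition fallback (eigenvalues clipped at $10^{-10}$ of the
largest) for trees whose recent divergences make $C$ numerically
near-singular. When a tip subset is analyzed, $C$ is subset by index so
shared path lengths keep the full tree's root as origin.

$K$ compares the observed ratio of trait variance to GLS-whitened
variance against its Brownian expectation; $K = 1$ on average under BM,
and exactly 1 on a star tree. Significance comes from tip-label
permutation ($p = (1 + \#\{K_{perm} \ge K_{obs}\})/(1 + n_{perm})$,
default 999 permutations). $\lambda$ rescales off-diagonal covariance and
is estimated by ML with the root state and rate profiled out
analytically; the search runs on $[0, 1]$ by default (a larger cap is
honored up to the positive-definiteness bound, found by bisection), and
endpoint likelihoods are evaluated explicitly so boundary optima are
exact. The $\lambda$ test is a likelihood-ratio test against
$\lambda = 0$ on $\chi^2_1$; being a boundary test it is conservative.
Star phylogenies, where $\lambda$ does not enter the likelihood, are
rejected explicitly rather than returning an arbitrary number. Both
statistics are invariant to positive affine transformation of the trait,
and both agree with the reference implementation in `phytools` to
numerical precision (checked in the test suite).

Tips without a measurable trait (no growth) are pruned before analysis.

## Taxonomic variance components

`fit_nested_varcomp` decomposes trait variance across nested taxonomic
ranks (default phylum → genus, plus the among-taxon residual) with a
random-intercepts model fitted by REML via `lme4`. Grouping factors are
built by pasting each taxon's lineage down to the rank, so identically
named clades under different parents remain distinct and the design is
strictly nested. On balanced designs the REML solution coincides with the
expected-mean-squares (nested ANOVA) estimator, which the test suite
checks to $10^{-6}$. Significance against the no-grouping null uses a
likelihood-ratio test (ML refits) on $\chi^2_k$ for $k$ components —
conservative at the boundary, with an optional 50:50 mixture correction.
Requested levels with fewer than two groups raise an error naming the
level; the pipeline wrapper instead drops such levels with a note.

## The forward simulator

`simulate_experiment()` generates a complete paired-isotope experiment
with known truth so every stage has a parameter-recovery surface. Its
defaults emulate the field warming study design this package grew out of:

* **Layout:** 3 treatments (control, short-term warming STW, long-term
  warming LTW) × 4 blocks × paired ¹⁶O/¹⁸O tubes = 24 tubes; 18 fractions
  spanning 1.640–1.760 g mL⁻¹ (fraction count and range are conventional
  CsCl qSIP values, config-exposed).
* **Growth trait:** a latent trait evolves by Brownian motion
  (σ² = 0.01, root 0.07) on a unit-height pure-birth tree, so EAF carries
  phylogenetic signal; treatments add shifts (0, +0.025, +0.106) chosen
  so the latent treatment means match the published assemblage means
  0.070 / 0.095 / 0.176. Values are clamped to [0, 0.6] — the ceiling
  imposed by ~66 atom % labeling water — and clamping (plus the
  zero-truncation of the negative tail) raises realized community means
  somewhat above the latent targets.
* **Measurement:** a taxon's DNA sits at its GC-determined density
  (ρ = 1.646057 + 0.083506·GC), shifted in ¹⁸O tubes through the exact
  inverse of the EAF equations, and is spread over the grid as a Gaussian
  with sd 0.006 g mL⁻¹ (diffusion broadening; common to all taxa).
  Per-fraction totals get lognormal qPCR noise (CV 0.15); counts are
  multinomial at 10,000 reads per fraction; relative abundances below a
  detection floor (0.002) drop out first, which is what exercises the
  consecutive-fraction filter. GC is drawn Beta(20, 20) (≈ 0.35–0.65,
  the bacterial range), and biomass weights are lognormal.
* **Reproducibility:** all randomness flows from one seed through a
  documented splitter (`split_seed`); identical configs give
  byte-identical outputs.

What the simulator does *not* emulate: compositional drift between tubes,
primer/copy-number bias, chimeras and denoising artifacts, tube-specific
gradient deformation, or abundance responses to treatment (biomass
weights are shared across tubes). Passing recovery tests therefore shows
the estimator inverts the stated measurement model at realistic noise;
it does not certify robustness to those unmodeled effects.

## Numerical and design choices

* With noise off (`qpcr_cv = 0`, `sequencing_depth = Inf`,
  `detection_floor = 0`) the pipeline recovers true EAF to ~10⁻⁹
  (discretization of the Gaussian profile is the only approximation);
  at default noise the median absolute error on a 200-taxon, 24-tube
  experiment is ≈ 0.006–0.007.
* Problem sizes used by the validation suite were chosen to make each
  property decisive yet quick: 200 Brownian simulations on 100-tip trees
  for signal calibration, 400/200 replicates for permutation/LR type-I
  rates, 100 simulations for the 50% order-share recovery (40 orders ×
  10 taxa), 10 null experiments of 100 taxa for ΔEAF calibration, and
  exhaustive enumeration of all 2⁷ presence patterns for the occurrence
  filter.
* Taxonomy simulation cuts the ultrametric tree at six increasing depths
  (phylum → species; domain fixed). A tip's clade at depth $d$ is the
  child end of the edge crossing $d$; $d = 0$ yields a single clade and
  $d = 1$ one clade per tip, and deeper cuts always refine shallower
  ones, so ranks are strictly nested by construction.
* Zero-length terminal branches (common in insertion trees) are perturbed
  to 10⁻⁸ × tree height with a warning; coincident tips are an error
  naming the tips.
* Exact ties in the Tukey letter display (zero residual variance) are
  resolved decisively: distinct means separate, equal means share a
  letter.

## Known limitations

* Four blocks is very little replication for any resampling scheme; even
  the expanded interval is approximate, and CI widths for taxa observed
  in fewer than four blocks borrow the global block count for the
  expansion factor.
* The GC→density and GC→molecular-weight relations are linear
  calibrations; organisms with unusual genome chemistry will violate
  them, and EAF inherits that error.
* The variance-component LRT and the λ LR test are both boundary tests;
  their p-values are conservative.
* Order-level aggregation reports means over growing representatives
  only, so rank tables are conditioned on detection — a selection effect
  shared with the field workflow it mirrors.
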