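---
title: "Brain-network graph metrics and BOLD variability after cranial radiotherapy: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-network graph metrics and BOLD variability after cranial radiotherapy: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connvar)
```

## What this package computes

`connvar` implements a resting-state fMRI analysis chain for studying
late effects of cranial radiotherapy (RT) in young brain-tumor survivors.
Two families of imaging markers are computed from parcellated BOLD time
series and related to clinical covariates:

* **Graph metrics.** Each subject's 132-parcel time series yields a Pearson
  connectivity matrix; thresholding at $r > 0.5$ (strictly, on the $r$
  scale) gives an undirected binary graph whose nodes are parcels. On this
  graph the package computes **global modularity**

  $$Q = \sum_{i=1}^{N} \left( e_{ii} - a_i^2 \right),$$

  where $e_{ii}$ is the fraction of edges with both endpoints in community
  $i$ and $a_i$ the fraction of edge endpoints attached to community $i$,
  and **global efficiency**

  $$E = \frac{\sum_{u \neq v} d(u,v)^{-1}}{n^2 - n},$$

  the mean inverse shortest-path length over ordered node pairs, with
  unreachable pairs contributing $0$. Both statistics are authored in this
  package; community detection uses Louvain maximization (igraph) with ten
  seeded restarts, and for graphs of at most ten nodes an exact mode
  enumerates every set partition and returns the global optimum, which the
  test suite uses as a self-check against independent oracles.

* **Network BOLD variability.** Group spatial ICA (FastICA fixed-point with
  deflation and a tanh contrast, five restarts keeping the best negentropy;
  implemented here) decomposes the temporally concatenated,
  dimensionality-reduced cohort into spatial components. Components are
  matched to canonical-network templates (salience, frontoparietal and
  left/right dorsal attention) by greedy assignment on absolute spatial
  correlation with a 0.3 floor, subject-specific time courses are obtained
  by dual-regression backprojection, and variability is the sample standard
  deviation of each course.

Group statistics follow the study design: Wilcoxon rank-sum comparisons and
a Spearman trend along the exposure ladder (healthy controls < no RT <
focal/WVRT < WBRT), Pearson correlations of age-normalized metrics with the
memory z-score, microbleed-burden binning with a quadratic trend, and linear
regressions of age-normalized metrics on the risk factors age-at-RT and
time-since-RT.

## The synthetic cohort generator

No public dataset accompanies the study conditions, so the generator is a
first-class, tested module that produces cohorts with the statistical
structure the analyses assume. Defaults encode the studied acquisition and
cohort: 132 parcels, 125 timepoints at TR = 4 s, and group sizes of 19
healthy controls plus 19 patients (4 no-RT, 5 WVRT, 2 focal, 4 low- and 4
high-dose WBRT).

Per subject the generator draws:

* a **spatial covariance** with planted modules: within-module correlation
  0.6, between-module 0.2, plus a per-group additive offset on the
  between-module level (0 to 0.12, monotone along the exposure ordering) —
  the hyperconnectivity effect. Clipping to $(-1, 1)$ is followed, if ever
  needed, by a nearest-PSD repair (eigenvalues clipped at $10^{-8}$,
  rescaled back to unit diagonal);
* **AR(1) noise** (lag-1 coefficient 0.3) with that spatial covariance —
  the simplest model matching the temporal smoothness of band-limited BOLD;
* **planted network signals**: four smooth disjoint-peak parcel-weight maps
  stand in for the SN, FPN, L-DAN and R-DAN templates; each carries an
  independent super-Gaussian time course (AR-smoothed noise through
  $x \mapsto x\lvert x \rvert$) scaled by the group's variability multiplier
  (1.0 to 1.7, monotone in exposure) with 10% lognormal subject jitter;
* **confounds**: linear-plus-cosine drift (slope 0.002 signal units/s,
  identical in every parcel so the parcel-mean trend equals the configured
  slope), 12 motion regressors (random-walk rigid-body parameters and
  derivatives) leaked into parcels through a random rank-3 mixing, 20
  tissue channels (the first two carrying the drift basis, as anatomical
  noise components do for scanner drift), and single-frame spikes whose
  simulated translation exceeds 2 mm, occurring with per-frame probability
  0.02;
* **covariates**: ages uniform on 12–25 years, RT doses by group, a memory
  (ISL) z-score built as $0.5 z + \sqrt{1-0.5^2}\,\varepsilon$ from the
  standardized planted-amplitude composite (target correlation 0.5), and
  microbleed counts drawn from low (0–2), moderate (4–47) and very-high
  (92–205) burden strata. The planted variability amplitude is modulated by
  a parabola in $\log(1+\mathrm{CMB})$ peaking at moderate burden
  (amplitude 0.25, clipped), so burden-bin analyses see a mid-burden
  maximum; the quadratic lives on the variability channel, the one the
  burden analysis consumes. About 10% of patients have their count set
  missing, emulating unusable susceptibility-weighted scans.

The free choices here — effect sizes, noise levels, the quadratic's
scale — reproduce the *qualitative* structure (orderings, signs,
correlation targets) because no effect magnitudes are published for these
quantities; passing tests therefore demonstrate that the pipeline recovers
planted structure of realistic shape and size, not that it reproduces any
particular patient cohort. Features of real data the generator does not
attempt: hemodynamic response shapes, physiological (cardiac/respiratory)
noise, scanner-specific drift spectra, spatial registration error, and
lesion-induced signal dropout.

## Denoising

The chain is scrub → regress → filter:

1. `detect_outlier_frames()` flags frames whose frame-to-frame composite
   translation (Euclidean norm of the differenced x/y/z translations)
   exceeds 2 mm, keeping at most the 30 largest excursions — outliers enter
   the regression as spike indicator columns rather than being deleted,
   preserving series length for ICA.
2. `regress_confounds()` residualizes every parcel against intercept,
   motion, tissue and spike columns by OLS, recording
   $\mathrm{dof} = T - \mathrm{rank}(X)$ and erroring below 30 remaining
   degrees of freedom.
3. `bandpass()` applies a zero-phase order-4 Butterworth filter
   forward-backward with reflective padding sized to the low-edge settling
   time (about $2/f_\text{low}$ seconds). The per-parcel mean is removed
   first — DC lies outside any passband, and removing it avoids edge
   artifacts on short series. At TR = 4 s the conventional 0.01–0.25 Hz
   band exceeds the 0.125 Hz Nyquist frequency; the upper edge is clamped
   to $0.99 \times$ Nyquist with a warning, making the filter effectively a
   high-pass, which is the only physically realizable reading of that band
   at this sampling rate. Zero-phase Butterworth filtering is idempotent
   only for passband-interior content and away from the series edges; the
   suite tests it there.

`check_connectivity_normality()` operationalizes the "connectivity values
normally distributed after denoising" criterion as $|\text{skewness}| <
0.5$ and $|\text{excess kurtosis}| < 1$ on the Fisher-z off-diagonal
values — conventional cutoffs, since only the goal, not the test, is
specified in the source methodology. No per-subject auto-tuning is
attempted; the report records pass/fail. On synthetic cohorts this check
typically *fails*: the planted covariance takes exactly two off-diagonal
levels, so the z distribution is a sharp two-component mixture
(platykurtic) rather than the broad unimodal spread of real whole-brain
connectivity. The check behaves correctly under null data (standard-normal
z values pass; exponential values fail on skewness), which is what the
suite asserts.

Volumetric-mode spatial smoothing (`smooth_volume()`) is separable Gaussian
convolution with FWHM in mm (kernels truncated at $4\sigma$, unit sum,
mass-conserving). For parcellated data, `smooth_parcels()` provides the
parcel-space analog — Gaussian weights over synthetic parcel coordinates —
used by the reproducibility sweep, where voxelwise smoothing has no direct
meaning.

## Numerical and design choices

* **Threshold ties.** Edges require $r$ strictly above the threshold, so
  ties at exactly 0.5 are excluded, reproducibly.
* **Unreachable pairs** contribute zero inverse distance to $E$ (the
  standard convention; the defining sum is silent on disconnection).
* **Community ids** are contiguous 1-based integers relabeled by first
  appearance; exact-mode ties are broken by enumeration order, Louvain ties
  by seeded restart order keeping the best $Q$.
* **Wilcoxon rank-sum.** Exact enumeration p-values when the combined
  sample size is at most 12 without ties. Larger tie-free samples use a
  continuity-corrected normal approximation with the Edgeworth kurtosis
  term, using the closed-form excess kurtosis of the Mann–Whitney
  statistic, $-\tfrac{6}{5}(m^2+n^2+mn+m+n)/(mn(m+n+1))$; this keeps the
  worst-case two-sided discrepancy from the exact distribution below 0.002
  even at $m=n=6$, where the plain corrected normal errs by 0.015. Tied
  data fall back on the standard tie-corrected normal approximation.
  Extreme-tail approximate p-values are floored at $2 \times 10^{-16}$.
* **ICA determinism.** The whitened dimensions' signs are canonicalized
  (largest-magnitude sample positive) before FastICA: SVD column signs are
  otherwise arbitrary and steer the fixed-point iteration into different
  basins for reordered input. Spatial maps are unit-normalized with the
  dominant loading positive and components ordered by explained variance,
  so a given seed yields a bit-reproducible decomposition and the output is
  invariant to parcel permutation.
* **Template matching** is greedy one-component-per-template: labeling every
  component above the floor would let several noisy components split one
  network's backprojected amplitude and make settings incomparable. The
  left/right split rule is preserved through the separate hemispheric
  templates, and a combined DAN template is offered for low model orders in
  which the network does not split.
* **Variability is subject-level**, computed on backprojected
  (dual-regression) time courses rather than group time courses — the
  per-subject statistics require it, and it is the common convention where
  the choice is ambiguous.
* **Band-direction comparisons** (narrower vs wider passband) are reported
  with the spatial maps held fixed (estimated on the wide band): with the
  maps fixed, a nested passband can only lower the variability of the same
  component on the same data, which is the clean frequency-response
  statement. Re-estimating the ICA per band — which the reproducibility
  sweep also does, for the cross-setting correlations — additionally
  changes the maps and their scales, and in simulation that decomposition
  noise can mask the filtering effect.
* **Risk-factor models** are ordinary least squares with normal-theory 95%
  confidence intervals; the tabulated quantity in the source publication is
  labeled an "incidence rate ratio" while the text describes linear
  regression — the linear-model coefficient is what is implemented. No
  multiple-testing correction is applied (nominal p-values are reported
  throughout); `p.adjust` can be applied downstream if desired.
* **Burden bins** default to ≤2 / 3–90 / ≥91 microbleeds, configurable,
  since the original grouping was derived from the distribution of the
  data; the quadratic trend is fit on the $\log(1+\text{count})$ scale to
  match the strata's logarithmic spacing.

## Problem sizes used by the tests

The suite runs the full variability pipeline at 30 subjects per group over
four exposure groups (five seeds) for the ordering and trend checks, a
30-subject cohort for the 20- vs 40-component coherence, 200 random graphs
of up to 8 nodes for the exact-enumeration cross-check, 500 null
simulations for test calibration, and 1000 replicates for confidence
interval coverage (keeping the Monte-Carlo error of a 95% coverage estimate
near 0.7%). These sizes were chosen to give the planted effects comfortable
statistical power while keeping the default test run short.

## Known limitations

* The generator's group effects are calibrated to orderings and signs, not
  published magnitudes; absolute metric values are not comparable to any
  real cohort.
* The normality check's cutoffs are conventional, not derived; and, as
  noted, the planted two-level covariance fails them by construction.
* The exact community-detection mode is limited to small graphs
  (Bell-number growth); at 132 parcels, results depend on the seeded
  Louvain heuristic, as in common toolbox practice.
* FastICA on 132-dimensional spatial samples at high model order can be
  sensitive to initialization when planted sources are weak; seeded
  restarts make it reproducible but not globally optimal.
* Voxelwise seed-based t-maps are replaced by the parcel-level seed
  correlation analog throughout.
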