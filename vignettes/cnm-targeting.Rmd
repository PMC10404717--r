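---
title: "Individualized TMS targeting from core-network fMRI connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized TMS targeting from core-network fMRI connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnmtarget)
```

## The problem and the model

Repetitive TMS for major depressive disorder is delivered over the
dorsolateral prefrontal cortex (DLPFC), and there is growing evidence that
*where* in the DLPFC the coil is placed matters: subregions functionally
connected to depression-related deep structures appear to be better targets.
The classical functional-targeting approach seeds a single region, the
subgenual anterior cingulate cortex (sgACC), and looks for the DLPFC voxel
most anticorrelated with it. The sgACC, however, sits in a region of poor
fMRI signal-to-noise, and single-seed connectivity maps repeat poorly within
a subject.

`cnmtarget` implements a multi-seed alternative, a *core network model*
(CNM) of emotion regulation in depression. Eight seed regions are used:
bilateral anterior insula and dorsal anterior cingulate cortex (the
cingulo-opercular, "regulatory" system, positively connected to the DLPFC)
and bilateral amygdala and sgACC (the "regulated" emotion-processing system,
negatively connected to the DLPFC). For one subject and one seed $k$ the
package computes the voxelwise Pearson correlation map
$r_k(v) = \mathrm{cor}\big(\bar{s}_k(t),\, x_v(t)\big)$
between the mean seed time course and every voxel's time course. The target
map is the **sign-reversed average**

$$T(v) = \frac{1}{8}\sum_{k=1}^{8} \sigma_k\, r_k(v), \qquad
  \sigma_k = \begin{cases} +1 & \text{regulatory seeds} \\
                           -1 & \text{regulated seeds} \end{cases}$$

Without the sign reversal the positive and negative connectivities cancel;
with it, a DLPFC voxel that is coupled *into* the regulation circuit in the
expected directions accumulates evidence from all eight seeds. Setting
$\sigma_k \equiv +1$ recovers the naive average, and restricting the seed
table to the sgACC rows reproduces the single-seed comparison model — both
are the same code path, which the tests exploit.

The individual TMS target is then the set of the $K = 100$ strongest DLPFC
voxels of $T$ per hemisphere, and the *target connectivity strength* is the
mean of $T$ over those voxels (optionally pooled across hemispheres).

## Assumptions

* Input BOLD series are already motion-corrected and normalized to MNI
  space; the package starts from a 4D NIfTI plus a 6-parameter motion trace.
* The DLPFC mask is supplied by the user (in the original construction it
  came from a database-derived DLPFC cluster intersected with a cortical
  atlas mask, which involves resources outside this package's scope).
* Seed *shapes* are approximated as spheres of configurable radius (default
  6 mm) around the published peak coordinates, because the exact cluster
  extents are not published. `build_seed_masks()` accepts exact per-seed
  NIfTI masks where available.
* The seed table's coordinates default to the "major depression" association
  peaks; where a seed has a separate emotion-regulation peak the two are
  close, and which one defined the original cluster centres is not recorded,
  so the choice is fixed and documented rather than guessed per seed.
* No spatial smoothing anywhere: smoothing inflates apparent repeatability
  at the cost of the spatial accuracy targeting needs.

## Preprocessing

`preprocess_bold()` applies, in a fixed, recorded order:

1. **Nuisance regression** — OLS residualization of every voxel on an
   intercept, the 6 motion parameters and (by default) their element-wise
   squares, plus mean CSF and white-matter signals. "Motion parameters and
   their exponentials" is interpreted as the standard quadratic expansion;
   a literal $e^{x}$ of a motion trace is not an established regressor, and
   the squares can be disabled by flag.
2. **Bandpass filtering** at 0.01–0.1 Hz, realized as an ideal
   frequency-domain mask after linear detrending (the DPABI-style "IDEAL"
   filter). The contract is stated in power terms (≥ 90% passband retention,
   ≤ 10% stopband leakage at half/twice the edges), so any realization
   meeting it is conforming.
3. **Scrubbing** — framewise displacement in the Power convention
   ($\mathrm{FD}_i = \sum |\Delta d_i| + 50\,\mathrm{mm} \cdot \sum
   |\Delta \theta_i|$, rotations in radians), censoring each volume with
   FD > 0.5 mm together with 1 preceding and 2 following volumes.

Censoring is non-destructive: flags are kept alongside the data so motion
traces stay index-aligned, and every correlation downstream simply excludes
censored volumes. The step order (regression → filter → censor-aware use) is
one defensible ordering of steps that the original description lists without
ordering; it is configurable but fixed by default so runs are
bit-reproducible. Zero-variance voxels are flagged undefined (`NA`) rather
than silently zeroed, and undefinedness propagates through the signed
average — a flat voxel can never masquerade as a weak or strong target.

## Repeatability statistics

Within-subject repeatability is measured by splitting a run into
floor($n$/length) equal, contiguous segments (tail volumes dropped — 1000
volumes give 8×125, 4×250, 2×500), computing a target map per segment, and
correlating map pairs over the bilateral DLPFC mask:
$r_{\mathrm{spat}}$ is the mean over all $\binom{m}{2}$ pairwise Pearson
correlations. Pairs are averaged in $r$ space by default (that is how the
quantity is defined); a Fisher-$Z$-space averaging mode exists behind a
flag, since the $Z$ transform is required for *tests* on correlations, not
necessarily for their summary. Inference between conditions uses the paired
$t$ test on per-subject Fisher-$Z$ values, and `variance_fold()` expresses
differences as the squared correlation ratio.

The dependence of repeatability on scan time $t$ (minutes) is modelled as
the saturating exponential

$$r_{\mathrm{spat}}(t) = r_{\mathrm{spatmax}} - e^{-t/a},$$

fitted by bounded Levenberg–Marquardt least squares with
$r_{\mathrm{spatmax}} \in (0, 1]$ and $a > 0$. A single start can stall on
the $r_{\mathrm{spatmax}} = 1$ bound, so the fit uses a small deterministic
grid of starts around $r_{\mathrm{spatmax}, 0} = \max r + 0.05$ and
$a_0 = \mathrm{median}(t)$ and keeps the converged fit with the lowest
residual sum of squares; non-convergence of all starts is reported
explicitly. Scan time for a segment defaults to nominal
$\mathrm{length} \times \mathrm{TR} / 60$; a censoring-adjusted effective
time is available by flag. Fitting can pool subject-level points or group
means — both are meaningful, and `repeatability_curve()` returns the points
so either can be fitted.

## Group-level target geometry and outcome analysis

`group_overlap_map()` binarizes each subject's top-$K$ set, sums, divides by
the number of subjects and multiplies by 100. `peak_distances()` reports all
pairwise Euclidean distances (mm) between subjects' strongest DLPFC voxels —
the peak is the single argmax voxel, with no sub-voxel interpolation,
matching the voxel-level resolution of the analysis. Ties anywhere in
ranking are broken by ascending linear voxel index, a deterministic and
documented rule. `extract_at_coordinates()` averages a group's target maps
voxelwise and reads the value at the voxel nearest each stimulated
coordinate (nearest-voxel rather than interpolated lookup; the coordinate is
a coil-derived estimate whose error exceeds a voxel anyway).
`adjusted_outcome_correlation()` correlates per-subject connectivity
strengths with clinical outcome, plainly and partially: both variables are
residualized on an intercept plus one-hot-encoded covariates (device,
protocol, session count), residuals are correlated, and $p$ uses a $t$
distribution with $n - 2 - q$ degrees of freedom.

Midline handling: voxels at exactly $x = 0$ mm belong to neither hemisphere
and are excluded from hemisphere-specific outputs, avoiding double counting.

## The synthetic-data generator

No imaging data ship with the package; `generate_subject()` /
`generate_cohort()` create fully self-contained cohorts with exported ground
truth. The generative model is deliberately the *minimal* structure that
makes sign-reversed averaging provably beneficial: a single shared
band-limited latent signal $u(t)$ (unit variance, 0.01–0.1 Hz), voxel
series

$$x_v(t) = w_v\, u(t) + \varepsilon_{v,t}, \qquad
  \varepsilon \sim \mathcal{N}(0, 1)$$

with flat loadings $w_v = +\mathrm{snr}$ inside regulatory seeds and the
planted bilateral DLPFC clusters, $-\mathrm{snr}$ inside regulated seeds,
and 0 elsewhere. Under this model expected correlations are closed-form —
a voxel with loading $w$ against the mean of an $m$-voxel seed with loading
$w_s$ correlates at $w w_s / \sqrt{(w^2+1)(w_s^2+1/m)}$
(`expected_seed_voxel_correlation()`) — which gives every recovery test an
analytic oracle. The flat (rather than tapered) kernel is chosen precisely
so these expressions are exact.

Default conditions: a 20×24×20 voxel grid at 3 mm (small enough that a
full-pipeline subject runs in seconds; it carries its own scaled-down seed
layout because the real seed coordinates span a full-size brain), 1000
volumes at TR 1.7 s (a full story-length run; segments of 125/250/500 then
correspond to 3.5/7/14 minutes), snr 0.35 (expected in-cluster target-map
value ≈ 0.30, the magnitude of real target connectivity strengths),
per-subject target jitter SD 6 mm (interindividual target variability on
the scale of the small grid), 29 subjects, motion random walks with FD well
under 0.5 mm plus two 1 mm spike excursions per run to exercise scrubbing,
and an outcome model
$y = 100\, \rho_{\mathrm{stim}} + \mathcal{N}(0, 10)$ on a
BDI-percent-change-like scale. Each subject's RNG stream is derived from
the cohort seed by a fixed documented offset, so subject 1 is identical in
cohorts of any size and every cohort is bit-reproducible.

What the generator does *not* emulate: hemodynamic convolution, physiological
(cardiac/respiratory) noise, spatial autocorrelation of noise, scanner
drift beyond linear trends, or motion-coupled signal artifacts. Passing
recovery tests on this model therefore demonstrates correctness of the
computation and the sign logic, not robustness to every real-data nuisance;
the preprocessing steps are validated separately against their own
contracts.

## Numerical choices and degenerate inputs

* Correlations are computed on retained volumes only; fewer than 3 retained
  volumes, an empty seed, or a zero-variance seed course raise errors.
* Sphere seeds always contain the voxel nearest the peak, so a zero radius
  is a single voxel, never an empty mask.
* The rank check of the nuisance design names the collinear columns; a
  motion trace whose rotation columns exceed $2\pi$ is rejected loudly as
  suspected degrees.
* Scrubbing is strict (> threshold) and monotone in the threshold; already
  censored volumes are never un-censored.
* Fisher transforms reject $|r| \ge 1$; `variance_fold()` rejects a zero
  denominator.

## Problem sizes used in the shipped checks

The shipped test-suite and the acceptance script run entirely on generated
data at sizes chosen so a full run completes in a few minutes on one core:
repeatability curves from 1000-volume runs on 3–5 subjects, localization
over 50–100 independent 120-volume high-SNR replicates, null calibration
from 12–24 zero-SNR subjects plus $10^4$ directly simulated paired-test
nulls, and exponential-fit recovery over 100 noisy replicates. These sizes
are statements of the package's own test design, chosen once.

## Known limitations

* Seed spheres are an approximation to unpublished cluster shapes; supply
  exact masks where fidelity matters.
* The DLPFC mask construction is out of scope and must be provided.
* Partial correlation assumes linear covariate effects; no
  spatial-autocorrelation correction is applied to $r_{\mathrm{spat}}$
  inference.
* Group-level extraction uses nearest-voxel lookup; sub-voxel interpolation
  is deliberately not offered.
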