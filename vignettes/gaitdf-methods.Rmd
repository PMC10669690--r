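---
title: "Methods: step-cycle normalization, the dissimilarity factor, and the synthetic gait generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: step-cycle normalization, the dissimilarity factor, and the synthetic gait generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitdf)
```

# The analysis problem

Hindlimb kinematics of a walking rodent are captured as pixel coordinates
of manually annotated joint landmarks (metatarsus, ankle, knee; left and
right side filmed by two synchronized cameras at 240 fps). Two questions
are asked of such data. First, *where in the step cycle* does a
manipulation (here: a penetrating hippocampal lesion; more generally any
group contrast including sex or species) change a joint's displacement —
answered bin by bin along a normalized step cycle. Second, *how dissimilar
are whole step curves* between groups — answered by a scalar pairwise
statistic, the dissimilarity factor, whose group distributions are
compared non-parametrically.

This vignette documents the model each stage implements, the tunable
parameters and their defaults, what the synthetic cohort generator does
and does not emulate, and the numerical and design choices that were
genuinely open.

# Homographic camera correction

Lens distortion of the tunnel's image plane is approximated as a planar
projective transform. `estimate_homography()` solves the minimal
four-point problem: with `H[3,3]` fixed at 1, the eight incidence
equations form an 8×8 linear system solved directly, so the four
correspondences are reproduced to machine precision (verified to 1e−8 in
the tests, and against an independent SVD null-space DLT on held-out
points). Only the exactly-determined four-point solve is provided — an
over-determined least-squares fit would be a different estimator than the
procedure this pipeline standardizes. Degenerate inputs (any collinear
triple, scale-aware area test) are rejected before solving.

Coordinates follow the analysis convention *y upward*; trajectory files
recorded in image convention declare `y_axis_direction=down` in their
header and are flipped on read. Frames are 0-based and step annotations
are half-open `[start_frame, end_frame)` — the dialect is printed into
every file header to prevent drift.

# Step-cycle time normalization

Each annotated step — at least 4 frames, the support a cubic interpolant
needs — is mapped to normalized time $u = (t - t_\text{start}) /
(t_\text{end} - t_\text{start})$ and each coordinate is fit by a
**natural cubic interpolating spline**, evaluated at the 100 cycle bins
$u_i = (i-1)/99$, $i = 1\ldots100$. Bin 1 is the step's first frame and
bin 100 its last, so both endpoints are represented exactly.

Choices made here:

* *Time, not amplitude, is normalized.* The 1–100 range is read as cycle
  percentage (the abscissa on which results are reported); amplitudes stay
  in arbitrary units (AU). An optional `standardize_amplitude` flag
  (default off) additionally z-scores each coordinate across the cycle,
  for users who want shape-only comparisons.
* *Natural spline* (zero second derivative at the ends) is the
  least-assuming cubic interpolant when nothing is known about boundary
  derivatives. Interpolation, not smoothing: the curve passes through
  every sample, reproduces any affine signal exactly (tested to 1e−9),
  and is invariant to uniform rescaling of timestamps (tested to 1e−10).
* Duplicate or non-increasing timestamps and sub-minimal segments are
  errors, not warnings — silent smoothing over bad annotations would bias
  every downstream statistic.

# The dissimilarity factor

For two normalized curves $a$ and $b$ of the same joint and side,

$$\mathrm{DF}_{\langle a,b\rangle} = \frac{1}{200}\left[
\sum_{i=1}^{100}\bigl(x_a(i)-x_b(i)\bigr)^2 +
\sum_{i=1}^{100}\bigl(y_a(i)-y_b(i)\bigr)^2\right],$$

the mean of the 200 squared coordinate differences. Although such
quantities are often loosely called Euclidean distances, the defining
formula has **no square root**, and it is the formula that is
implemented (units AU²; DF = 0 iff the curves coincide; symmetric;
scales as $k^2$ under amplitude scaling — all tested, including
equivalence to an elementwise-loop oracle at 1e−12).

Pairing: DF is computed for every **unordered cross-animal pair** —
steps of one animal are never compared with each other, and since DF is
symmetric, ordered duplicates would only double each count. With animals
$u$ having $n_u$ curves the record count is $\sum_{u<v} n_u n_v$
(5 animals × 6 steps → 360 pairs). Within-group distributions built this
way are the unit of the group comparison. Whether lesioned-group analyses
should also pair lesioned against control curves is not something the
within-group definition settles; the package defaults to within-group
only and exposes `cross_condition = TRUE`, which adds the
lesioned-vs-control pair distribution per species/sex. Note a structural
property worth remembering when interpreting results: a waveform change
shared by *all* animals of a group leaves the within-group DF
distribution unchanged and appears only in cross-condition pairs.

Under a Gaussian null — both curves equal to a common template plus
i.i.d. per-bin noise of SD $\sigma$ on each axis — each squared
difference has expectation $2\sigma^2$, so $E[\mathrm{DF}] = 2\sigma^2$;
the empirical mean over $10^4$ simulated pairs is required to agree
within 5%.

# Group statistics

**Bin-wise comparison** (`binwise_compare()`): at each bin, an unpaired
two-sample *t*-test with the classic pooled-variance statistic (the
unadorned Student test, not Welch). The summary is `percent_changed`,
the count of significant bins out of 100. Defaults and their reasoning:

* `tail = "one_sided_auto"` mirrors a one-tailed test whose direction is
  chosen from the observed per-bin mean difference. This reproduces the
  field procedure as literally as possible but is **anti-conservative**
  (effective two-sided level $2\alpha$); `"two_sided"` is available and
  is what the package's own calibration tests use.
* No correction across the 100 bins by default — per-bin raw significance
  is what the reported percent-changed figures mean. Under the null this
  makes $E[\text{percent\_changed}] \approx 100\alpha$; the type-I
  calibration test requires the mean over 200 null contrasts to lie in
  [3, 7] at $\alpha = 0.05$ (two-sided). `p_adjust = "BH"` applies
  Benjamini–Hochberg across bins; the package's own
  parameter-recovery tests use it, because with raw testing an injected
  span of $K$ bins is recovered as $K + 0.05(100-K)$ bins on average —
  e.g. a 9-bin effect would read as ≈13.5% — so ±3-bin recovery of
  9/22/35/63-bin spans is only a meaningful requirement under FDR
  control (10σ effects always survive it).
* Step curves are the sampling unit (`sem = sd/√n_curves`), matching an
  analysis that averages "curves per group". Steps of one animal are not
  independent when animals differ systematically, which makes
  steps-as-units anti-conservative in the presence of animal-level
  variance; `animal_means = TRUE` averages within animal first so
  animals become the unit.
* Degenerate bins (zero variance in both groups, equal means) report
  $t = 0$, $p = 1$, not significant, rather than NaN.

**Normality**: `ks_normality()` is the one-sample KS statistic against a
normal with the *sample* mean and SD, with the Lilliefors correction of
the p-value (plain KS p-values are invalid when parameters are estimated
from the data); it wraps `nortest::lillie.test()`, and the statistic is
tested against an independent ECDF sup-distance loop.

**DF group comparison**: tie-corrected Kruskal–Wallis
(`stats::kruskal.test`) followed by Dunn's pairwise z-tests on mean ranks
with the tie-corrected variance $\left(\frac{N(N+1)}{12} -
\frac{\sum(t^3-t)}{12(N-1)}\right)\left(\frac1{n_i}+\frac1{n_j}\right)$,
Bonferroni-adjusted over the tested pairs (the GraphPad Prism
convention; `p_adjust = "none"` disables adjustment). No installed
package provides Dunn's test, so it is implemented here and checked
against the rank-sum closed form ({1,2,3} vs {4,5,6} → H = 3.857) and an
independent implementation on random instances. The all-ties corner case
(every value identical) is defined as H = 0 with unit p-values.

# The synthetic cohort generator

The generator exists so that every downstream stage can be validated
against known truth. It emulates the statistical structure the analysis
assumes, under a fixed study design: **eight groups** (control/lesioned ×
male/female × rat/mouse) of **five animals**, **six analysed steps** per
animal per limb, filmed at **240 fps**.

**Waveform templates.** Each (species, joint) has a parametric template
over the cycle: *unidirectional* — a raised-cosine bump
$\sin^2(\pi g(u))$ with a piecewise-linear warp placing its single peak —
for the rat metatarsus and ankle and the mouse knee; *pendular* — a
single-period sine under a monotone warp, giving one positive and one
negative excursion — for the mouse metatarsus and ankle and the rat knee.
These shapes are smooth, spline-interpolate cleanly, and have exactly the
one-vs-two-extrema structure that distinguishes the species' joint
kinematics. Since published displacement axes are in arbitrary units, the
default amplitudes are free parameters chosen to scale with body size
(rat ≈ 8–10 AU, mouse ≈ 2.5–4 AU) with baselines stacking the joints
vertically; they are conventions, not calibrated values.

**Noise model.** Additive Gaussian at two levels: `noise_sd_step`
(default 0.5 AU) i.i.d. per cycle bin per step, and `noise_sd_animal`
(default 0.3 AU) as one offset per animal per joint — the simplest model
that produces both sensible per-bin *t*-tests and a dispersed DF
distribution. Per-bin step noise is realised as a natural cubic curve
through the 100 noisy bin values, which is then sampled at frame times;
this construction makes the noise recoverable by the normalization stage:
at the default rat frame densities the per-bin SD after the full
generate → sample → re-normalize round trip stays within 15% of
`noise_sd_step` at every bin (tested over 500 steps).

**Step durations** are drawn uniformly per step — rats 0.65–0.85 s, mice
0.35–0.55 s, slow overground walking — so step lengths are genuinely
non-uniform and the spline normalization is exercised rather than
bypassed. At 240 fps a rat step spans ≥ 156 frames, comfortably resolving
the 100-bin noise curve; mouse steps (≥ 84 frames) under-resolve it
slightly, attenuating recovered per-bin noise by ≈ 5–10% — acceptable
because no test conditions on mouse noise recovery.

**Lesion effects** are signed vertical shifts over a bin span with an
optional raised-cosine taper (`taper = 0` is a hard step). They are the
ground-truth mechanism for "percent of step cycle changed": a 35-bin span
at 10× the step noise SD should be recovered as ≈ 35% changed. One
numerical caveat, visible in the worked example: a taper-0 effect has
discontinuous edges, and its continuous-time realization (needed to
sample frames) linearly ramps between adjacent bin centres, so the bins
immediately bordering the span carry partial shifts. At 10σ those partial
shifts are themselves significant, biasing through-the-pipeline recovery
upward by ~1–4 bins; bin-domain injection (no resampling) recovers spans
within ±3 exactly. Real lesions presumably have no razor-sharp cycle
boundary, so the smeared behaviour is, if anything, the more realistic
one.

**Determinism.** A cohort is a pure function of its configuration,
including the seed: identical configs produce byte-identical files, and
`run_pipeline()` on a fixed `run_config()` is reproducible end to end
(tested at the report and at the file level).

**What the generator does not emulate** — and therefore what passing
tests do *not* show about real recordings: annotation jitter and operator
bias in landmark placement; actual lens distortion fields (only exact
projective distortion is simulated in tests); autocorrelated or
speed-dependent within-step noise; gait-phase (stance/swing) structure;
step-to-step correlation within a bout; left–right coupling. Results on
real data additionally depend on step selection, which remains manual.

# Problem sizes in the validation suite

The packaged tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which each statistical claim is sharp: 1000 random
pairs for the DF oracle equivalence, $10^4$ pairs for the null mean,
200 simulated contrasts of 15 curves/group for type-I calibration,
30 curves/group across 4 span sizes × 5 seeds for recovery, 500 steps for
noise-SD recovery, and the full 8 × 5 × 6 default cohort for the
determinism check.

# Known limitations

* The bin-wise default (`one_sided_auto`, steps as units, no cross-bin
  correction) is deliberately the literal field procedure; all three
  ingredients are anti-conservative, and the conservative alternatives
  (`two_sided`, `animal_means`, `p_adjust = "BH"`) are one argument away.
* DF mixes horizontal and vertical displacement on the AU scale of the
  recording; curves must come from comparable calibration for DF values
  to be comparable across animals.
* The homography is the minimal 4-point solve; noisy calibration points
  propagate directly into coordinates (no redundancy to average over).
* No gait-event detection, phase splitting, speed normalization, or
  time-warping alignment (DTW): steps are compared strictly on cycle
  percentage.
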