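---
title: "How mlcqa models MLC leaf-tip errors, dose, and QA detectability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How mlcqa models MLC leaf-tip errors, dose, and QA detectability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question this package simulates

Treatment planning systems (TPS) do not ray-trace the rounded ends of
multileaf-collimator (MLC) leaves; several commercial systems describe the
leaf end with two scalar parameters — a *leaf-tip width* `w` (a region of
partial transmission at the modeled leaf end) and a *leaf-tip offset*
`delta` (a shift of the modeled tip from the nominal leaf position).  Small
errors in these parameters barely change open-field profiles, but modulated
IMRT/VMAT deliveries are built from many small, moving apertures whose dose
is dominated by leaf-end behaviour, so the same small errors can move
calculated dose by large amounts — and patient-specific QA (gamma analysis
of a diode-array measurement) may not notice.

`mlcqa` rebuilds that whole chain *in silico*: a double-step leaf-tip
transmission model, a simple planar dose engine on a virtual cylindrical
head-and-neck phantom with four TLD-like reporting ROIs, a synthetic
nine-plan IMRT/VMAT suite, a global gamma-index implementation, and
ROC/AUC analysis of whether the QA pass rate separates the correct
("clinical") beam model from perturbed ones.  No external data is used;
everything is generated by code under one master seed.

## The MLC leaf-tip model

Each leaf pair has nominal tip positions `left` and `right` along the leaf
travel axis `x`.  Under a beam model the tips retract *outward per bank* by
the offset, `left_eff = left - delta`, `right_eff = right + delta`, so a
positive offset enlarges the effective gap by `2 * delta`; if the effective
gap would be negative it is clamped to zero width at the nominal gap
midpoint.  Transmission through one leaf is a double step:

* 1 in the open field (`x` beyond the effective edge),
* `tau` in the tip region of width `w` starting at the effective edge and
  extending under the leaf,
* the intraleaf leakage `T` beyond the tip.

A pair combines its two leaves by a pointwise *minimum*: a point shadowed
by both leaves cannot transmit more than the more attenuating one, and a
product would dip unphysically below `T`.  Defaults: `T = 0.005` (typical
intraleaf leakage for a modern tungsten MLC; the commissioned value is
never printed in the source study), 40 leaf pairs at 5 mm pitch, leaf
travel ±100 mm, parked (closed) pairs at −80 mm.  Grid rows lateral of the
bank are treated as backup-jaw-blocked at transmission `T`.

**The tip transmission `tau`.**  Text descriptions of this class of model
say the tip region transmits "T", which contradicts both "partial
transmission" and the double-step picture (that would collapse the two
steps into one).  We keep `tau` configurable via `tip_rule`: the default
`"sqrt"` uses `tau = sqrt(T)` (geometric mean of open and blocked, about
0.07 for `T = 0.005`), which preserves a genuine intermediate step
`T < tau < 1`; `"literal"` sets `tau = T` for users who want the
single-step reading.  All shipped analyses use `"sqrt"`.

## The dose engine

The engine is deliberately the *simplest* model that preserves what drives
the studied effect — penumbra, scatter, and depth attenuation — not a
clone of any commercial algorithm (the source study's engine is never
named).  Per beam:

1. fluence = sum over segments of `MU x transmission map` on a 1 mm,
   256 × 256 beam's-eye-view grid;
2. planar dose = fluence convolved with a radially symmetric two-Gaussian
   kernel: primary `sigma = 1` mm (penumbra sharpness), scatter
   `sigma = 20` mm with weight 0.1 (long-range dose bath);
3. a point dose adds, over beams, `exp(-mu * depth)` times the planar dose
   at the beam's-eye projection of the point, with `mu = 0.05 /cm`
   (6-MV-like effective attenuation) and depth the ray path from the
   cylinder surface.

Inverse-square and divergence are omitted (they cancel in every reported
relative quantity), doses are per-MU arbitrary units, and all paper-facing
outputs are percent differences or gamma comparisons, which are unit-free.
The convolution is implemented separably (two 1-D Gaussian operators per
component); `planar_dose_at()` evaluates the same quadrature directly at
arbitrary points, so sampled values are exactly consistent with the
rasterized maps.  Kernels are normalized by the infinite-lattice discrete
sum, so a flat field reproduces its own level in the grid interior and
truncation at the boundary remains visible rather than being renormalized
away.

Monotonicity is the engine's load-bearing property: transmission maps are
pointwise non-decreasing in `delta`, and since MU, the kernel and the
attenuation are nonnegative, every composite dose inherits this.  The test
suite asserts the full chain.

## The virtual phantom and plan suite

The phantom is an 80 mm radius water cylinder (axis along the leaf-pair
direction) with a 25 mm radius primary target sphere (PTV1) anterior of
isocenter, a 15 mm secondary target sphere (PTV2) lateral, and a 5 mm
radius spinal-cord cylinder 10 mm posterior of the PTV1 surface.  Four
3 mm TLD-like disk ROIs report mean dose: PTV1 center and PTV2
(low-gradient), PTV1 periphery (at the posterior PTV1 edge) and the cord
(inside the blocked shadow) — the two high-gradient positions where
leaf-end errors matter most.

Nine plans mirror a typical head-and-neck credentialing suite: five
step-and-shoot IMRT plans with 7, 7, 7, 9 and 9 equally spaced beams
(6 segments per beam) and four VMAT plans with 2, 2, 2 and 3 full arcs
discretized as static control points every 4 degrees.  Total MU per plan
uses fixed clinically typical values spanning 1469–2114 MU; segment
weights are uniform with ±50% random jitter.  We deliberately do **not**
rescale plans to a nominal prescription: rescaling MU to pin a
prescription dose and independently placing total MU in a target range
are incompatible constraints, and every reported quantity is relative, so
a per-plan dose scale would cancel anyway.

Apertures are built heuristically, not inverse-optimized: each segment
conformally covers the union of the target projections while pulling one
leaf to the cord shadow's edge (2 mm margin) whenever the cord splits the
target shadow, alternating the open side between segments so the cord
sees penumbra from both banks; on top of this, seeded random sub-aperture
shrinkage (per-plan modulation strength drawn from 0.3–0.7, plus
occasional pair closures) emulates optimizer modulation and plan-to-plan
variety.  What this generator reproduces is the *structure the analysis
needs* — modulated small apertures, a ≥3%/mm falloff across the PTV–cord
gap, low-gradient target centers; what it does not reproduce is
DVH-driven optimality, realistic segment connectivity for deliverability,
heterogeneities, or collimator rotation.  Passing tests therefore
demonstrate the sensitivity-and-detectability *mechanism*, not clinical
dose accuracy.

## The virtual QA device and gamma analysis

A planar diode array in the coronal plane through isocenter (10 mm pitch,
±70 mm) stands in for a cylindrical commercial array; what the comparison
consumes — pointwise measured/calculated dose pairs at ~1 cm spacing — is
preserved without helical geometry.  "Measured" is the clinical
(truth) model's dose at the diodes plus seeded Gaussian noise of 0.5% of
the maximum (typical diode-array reproducibility; the real measurement
uncertainty is not printed in the source study, so the level is a
configurable simulation parameter).  "Calculated" is each candidate
model's noiseless dose on the same plane at 1 mm resolution.

Gamma uses global normalization (percent of the *measured* maximum — the
direction is a convention choice, stated, since QA practice normalizes to
the measurement), a 10% low-dose threshold, and presets 2%/2 mm and
3%/3 mm.  The search minimizes the generalized distance over a disk of
radius 3 × DTA: a coarse grid at 0.1 × DTA followed by local refinement at
0.05 × DTA within one coarse step of each point's best coarse offset,
clipped to the disk.  The refinement lattice coincides with the dense
0.05 × DTA lattice of `gamma_bruteforce()`, the package's explicit
reference implementation, so the fast path is an accelerated equivalent of
the reference semantics (the tests assert agreement within 0.01 in gamma
and 0.5 percentage points in pass rate on random QA-like fields).  Points
with gamma exactly 1 pass.  Two practical notes on convergence: discrete
gamma searches converge second-order at interior minima but only
first-order when the minimum sits on the search-disk boundary, which
happens once distributions disagree grossly (gamma well above 1); and the
evaluated distribution is bilinearly interpolated, so its grid must cover
every reference point plus the search radius (enforced).

## ROC analysis

Each (plan, candidate model, noise replicate, criteria) comparison yields
one pass-rate record, labeled *negative* if the candidate matches the
clinical model exactly (offset −0.5 mm, width 4.5 mm) and *positive*
otherwise.  The ROC sweeps every distinct pass rate as a threshold
(flagging records at or below it), ties move together, endpoints (0,0)
and (1,1) are always included, and the AUC is the trapezoidal area —
equal, by construction, to the tie-corrected Mann–Whitney concordance,
which the tests verify by brute-force pair counting and against pROC.
Because the simulation (unlike a single physical delivery) can replicate
measurements, each plan contributes 20 noise-replicate "deliveries" by
default so curves are non-degenerate.  Curves are built per offset
deviation magnitude (positives restricted to candidates at one
`|delta - delta_clinical|`) and pooled over all positives; the
criteria-insensitivity check (2%/2 mm vs 3%/3 mm) is made on the pooled
curves, where both criteria summarize the identical record set in one
number.

## The default study and its sizes

`run_study(study_config())` executes: 9 plans × 27 models
(offsets −2.0 … +2.0 mm in 0.5 mm steps × widths 2.5/4.5/6.0 mm) for the
ROI sensitivity table; the offset sweep at the clinical width × 20 noise
replicates × 2 criteria for detectability (4860 QA records); and a
100 × 100 mm open-field offset sweep as the insensitivity control.  These
sizes were chosen to mirror the source experiment's design while
remaining comfortable on a single CPU (minutes, not hours); the tests run
the identical configuration.  All randomness fans out from one master
seed through an affine integer hash (`split_seed()`), so reruns are
byte-identical.

## Known limitations

* The dose engine is 2-D per beam with exponential depth dose; no
  heterogeneity, 3-D scatter, spectrum, or rounded-leaf ray tracing.
* Tongue-and-groove, interleaf leakage, transmission fitting and
  leaf-position gain/curvature are out of scope by design.
* The planar QA array collapses for beams nearly edge-on to its plane
  (all diodes project near one crossplane coordinate); this affects
  "measured" and "calculated" identically, preserving the comparison, but
  it is not a geometric model of any physical array.
* Absolute doses are arbitrary; only relative quantities are meaningful.
* The heuristic planner produces modulation statistics, not clinically
  optimal plans; AUC values characterize this simulation, not any
  commercial system.
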