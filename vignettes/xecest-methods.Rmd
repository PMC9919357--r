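---
title: "Models and methods behind xecest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind xecest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xecest)
```

## The measurement this package models

Hyperpolarized ^129^Xe reversibly occupies a cryptophane-A cage tethered to
a membrane receptor. Saturating RF applied at the resonance of cage-bound
xenon depletes its polarization; exchange carries that depletion into the
large pool of freely dissolved xenon, whose signal is what is actually
read out. Stepping the saturation frequency scan by scan yields a
*z-spectrum*: free-xenon signal versus irradiation position. Each distinct
chemical environment of the cage (lipid-embedded, water-exposed, pressed
against the receptor surface or a bound peptide) produces its own dip.
`xecest` fits such z-spectra, interprets the fitted parameters through an
exchange model, and analyzes the MD-simulation side of the same problem:
where the caged xenon makes contact, and how rigid the receptor backbone
is.

## Z-spectrum model

The saturation response at irradiation position $x$ (ppm) is the
exponential-Lorentzian product over $N$ resonances

$$S(x) = A \prod_{i=1}^{N} \exp\!\left(-B_i\,
  \frac{a_i^2}{a_i^2 + (b_i - x)^2}\right),$$

with baseline $A$, position $b_i$ (ppm, converted to angular frequency
through the observe frequency), dimensionless amplitude $B_i$ (on-resonance
depth $1-e^{-B_i}$), and angular half-width $a_i$ (rad/s). Widths are
reported as $a/\pi$ in Hz everywhere outside the internal representation;
the conversion is exact, which removes a classic source of silent
$\pi$-errors. When every non-dominant $B_i \ll 1$, expanding those
exponentials to first order shows the weak signals to be plain Lorentzians
reflected at the baseline (`evaluate_zspectrum_linearized()`); the error of
that form is bounded by the quadratic Taylor remainder, which the test
suite checks at amplitude scales 1, 1/2 and 1/4.

The amplitude and width are not free-floating descriptors: under a
continuous saturation of nutation frequency $\omega_1$ applied for
$t_\mathrm{sat}$,

$$B = t_\mathrm{sat}\, k_\mathrm{on}
  \frac{\omega_1^2}{\omega_1^2 + k_\mathrm{off}^2 + k_\mathrm{off} R_2},
\qquad
a^2 = \bigl(\omega_1^2 + k_\mathrm{off}(k_\mathrm{off}+R_2)\bigr)
  \frac{k_\mathrm{off}+R_2}{k_\mathrm{off}},$$

where $k_\mathrm{on}$, $k_\mathrm{off}$ are the xenon in/out rates and
$R_2$ the transverse relaxation rate of bound xenon. The width form
expands to $a^2 = \omega_1^2 + k_\mathrm{off}^2 + R_2^2 +
(R_2/k_\mathrm{off})(\omega_1^2 + 2k_\mathrm{off}^2)$ and collapses to
$a=\omega_1$ without exchange broadening and relaxation. When
$\omega_1 \gg k_\mathrm{off}$ it simplifies to
$a^2 \approx \omega_1^2 + R_2^2 + (R_2/k_\mathrm{off})\omega_1^2$
(`width_high_power_limit()`), the regime in which relaxation rather than
exchange dominates the line width — the situation for a large
receptor–bicelle assembly tumbling slowly. Note one non-obvious
consequence of the full form: $a$ is monotone in $\omega_1$ and $R_2$ but
*not* in $k_\mathrm{off}$ once $R_2>0$; slower exchange starves the
transfer and broadens the effective line, diverging as
$k_\mathrm{off}\to 0$. The degenerate corner $k_\mathrm{off}=0$, $R_2>0$
is therefore rejected.

For slow-exchange host–guest lines the observed width essentially *is*
the off-rate. `koff_from_linewidth()` defaults to reading a width quoted
in Hz directly as a rate in s⁻¹ (the convention under which a 320 Hz
lipid-phase line corresponds to roughly twice the applied
$\omega_1 = 2\pi\cdot 99$ rad/s), with the strict Lorentzian convention
$k_\mathrm{off} = \pi\,\mathrm{FWHM}$ selectable.

## Acquisition conventions

The default `acquisition_params()` describes a weak 20 s continuous-wave
saturation at nutation frequency $2\pi\cdot 99$ rad/s with the irradiation
stepped from 5 kHz downfield to 13 kHz upfield of the free-xenon line
(196 ppm) in 200 Hz steps — 91 points. The observe frequency defaults to
83.0 MHz (^129^Xe at 7 T) and is user-overridable everywhere; it is a
conversion factor, never a hard-coded constant. Offsets in files are
stored in Hz relative to the free-xenon line and converted on load;
positions increase downfield.

## From raw scans to a z-spectrum

`integrate_scan()` integrates each absorption-mode spectrum by the
trapezoidal rule over a 7 ppm window centered on the maximum signal
amplitude, re-centered per scan by default (a fixed center is available).
Trapezoids on the native grid, without resampling, are unbiased for these
smooth single-line shapes; the test suite pins the integral of a unit-area
Lorentzian of 0.5 ppm width against the closed form
$(2/\pi)\arctan(14)$. For a constant amplitude the window centers on the
middle of the tied maxima, so a flat spectrum integrates to (amplitude ×
window) rather than clipping at the axis edge. `normalize_baseline()`
rescales by an upper quantile (default 0.9) of the intensities — a robust
baseline estimate that the fitted $A$ absorbs anyway.

## Fitting and model selection

`fit_zspectrum()` performs weighted nonlinear least squares with
Levenberg–Marquardt (via `minpack.lm`), using per-point σ when present and
unit weights otherwise. Box constraints keep positions inside the sampled
band ± 2 ppm, amplitudes in [0, 10], and widths ($a/\pi$) in
[10, 5000] Hz — spanning all plausible cryptophane hyperCEST parameters
with wide margins. Standard errors come from the covariance of the
converged fit ($\sigma^2 (J^\top J)^{-1}$ with the residual variance
estimate); a singular covariance yields `NA` with a warning rather than an
error, and non-convergence is flagged, not fatal.

Initialization deserves its own paragraph because the naive route fails.
On the 200 Hz grid the weak resonances of a realistic 5-component set are
*shoulders* of the dominant line: they never form their own local minima,
so "pick the n deepest dips" cannot find them. `initial_guess()` instead
works on the effective absorption $t(x) = -\log(S/A)$, under which the
product model becomes a *sum* of Lorentzians, and extracts components
greedily (CLEAN-style): locate the largest remaining feature with
sub-grid parabolic refinement, read its width off the interpolated
half-height span (at half height the full span in Hz equals $a/\pi$
exactly), subtract, repeat, then re-estimate each component in a few
refinement sweeps. Under visible noise the absorption is pre-smoothed with
a 5-point moving average for feature finding only. If fewer features than
requested survive the noise floor (estimated from twice-differenced
intensities, where smooth trends cancel), the remainder is placed at
residual-absorption maxima, and only as a last resort spread evenly.

`select_model()` chooses the number of resonances by the Bayesian
information criterion under a Gaussian noise model. With known per-point
σ the weighted residual sum of squares is a χ² and enters the likelihood
directly, $\mathrm{BIC} = \chi^2 + k\log n$; without σ the noise variance
is profiled out, $\mathrm{BIC} = n\log(\mathrm{rss}/n) + k\log n$. Each
candidate count is fitted with a deterministic multi-start strategy: the
greedy initial guess plus seeded jittered restarts (alternating narrow and
wide jitter), warm starts grown from the best smaller model (append a
component at the residual-absorption maximum, or split the largest
component), and structural repair moves on the winner (merge the most
overlapping pair; remove "ghost" spikes — near-bound amplitude with a
width far below the grid step, parked between grid points where they have
no spectral footprint). All randomness flows from one master seed, so
reported results are reproducible bit for bit.

A caveat the package states rather than hides: at a realistic 1% noise
level the weakest components of the 5-resonance set sit right at the BIC
detection threshold (their marginal Δχ² against the best 4-component
refit is of the same order as the 3-parameter penalty $3\ln 91 \approx
13.5$), so selection between 4 and 5 flips with the noise realization.
The 6th component of the ligand-bound set is isolated and detected
reliably. `dominant_resonance()` ranks by signal area ($B \times$ width)
rather than amplitude alone, which is robust against the ghost-spike
degeneracy described above.

## Contact analysis

A residue (receptor or ligand) or lipid molecule is *in contact* when the
minimum distance from the xenon atom to any of its heavy atoms is below
8.5 Å; hydrogens and solvent are excluded, as is the cage itself (xenon
rides inside it). Contact instances are counted per frame per residue, so
a residue contacted in $k$ frames contributes $k$ instances — the only
reading consistent with per-frame probabilities. Frames are categorized
exclusively as *just lipid*, *just protein*, *lipid and protein*, or *no
contacts*; the categories partition the retained frames exactly. The
first 100 ns are discarded as equilibration by default. Minimum-image
distances are applied when orthorhombic box vectors accompany the
trajectory; otherwise plain Euclidean distances are used with a warning
(fixture-scale toys are not periodic). Site-cluster probabilities average
the three most-contacted residues of a named cluster, ties broken by
residue index; the standard cluster definitions for the tagged Y2
receptor (N-terminus, ECL1, two ECL2 segments, ECL3, and the two NPY
segments for the ligand-bound state) ship as a YAML data file.
`normalize_counts_for_projection()` scales counts by the per-system
maximum — suitable for coloring one system's surface, explicitly not
comparable across systems.

## Order parameters

Every frame is rigid-body aligned to a reference frame on the receptor
Cα atoms (Kabsch superposition on base-R SVD, reflections excluded), which
removes overall reorientation; the ligand never enters the alignment
selection. The per-residue order parameter is then computed from the
time-averaged second moments of the Cα–H unit vector,

$$S^2 = \tfrac{3}{2}\sum_{\alpha\beta}\langle u_\alpha u_\beta\rangle^2
 - \tfrac{1}{2},$$

deliberately *not* via the $P_2$ autocorrelation plateau: the plateau
route presumes overall rotation about the membrane normal is averaged
out, which fails for a receptor–bicelle assembly on the NMR time scale.
Full-trajectory moments are used rather than windowed averages. The
estimator is validated against the wobble-in-cone closed form
$S^2 = [\cos\theta(1+\cos\theta)/2]^2$ (0.6529 at a 30° semi-angle, 0 at
90° — a uniform hemisphere has an isotropic second-moment tensor), the
static limit of 1, the isotropic limit of 0, and invariance under global
rotations. When a topology lacks hydrogens, an optional reconstruction
places an effective Cα–H direction from the N, C and CB positions
(tetrahedral geometry); it is off by default and fixtures carry explicit
hydrogens.

## Synthetic data: what it emulates and what it does not

The generators exist so that every analysis stage runs against inputs
with *known* ground truth:

* `gen_zspectrum()` evaluates the forward model for one of the bundled
  reference parameter sets (`table1_presets()`: 5-resonance apo,
  6-resonance ligand-bound, 1-resonance construct-in-bicelles control)
  on the standard grid and adds i.i.d. Gaussian noise. The default test
  noise is σ = 0.01·A — a stated assumption matching the visual scatter
  of published spectra of this kind; real noise may be correlated and
  baseline-distorted in ways this does not emulate.
* `gen_scan_set()` manufactures the per-scan layer underneath: one
  Lorentzian detection line per offset whose area tracks the model
  z-value.
* `gen_hop_trajectory()` drives a xenon atom through a discrete-state
  Markov chain over spatially isolated sites, yielding contact
  trajectories whose category and per-residue probabilities follow the
  chain's analytic stationary distribution. Real cage dynamics are
  continuous and autocorrelated; the chain's correlation is mild, and
  tests compare against 3 standard errors with a floor for it.
* `gen_cone_trajectory()` samples Cα–H vectors uniformly within
  per-residue cones about fixed axes on a rigid scaffold, optionally
  under per-frame global rigid motion, giving exact closed-form order
  parameters. Three rigid anchor residues (static bonds, $S^2=1$) keep
  the alignment well-posed.

Every generator is a pure function of (parameters, seed). Passing tests
on these fixtures demonstrates the estimators, not membrane-protein MD
realism: lipid packing, solvent structure and force-field physics are
out of scope, and the published multi-microsecond MD averages are not
reproducible at desk scale.

## Numerical choices and problem sizes

Fits run with tight tolerances (ftol = ptol = 1e-14, up to 1000
iterations) so that noiseless recovery reaches the machine-precision
residual floor; the test suite asserts rss below $10^{-10} A^2 n$. Tests
use 91-point spectra, trajectories of 500–10 000 frames and toys of under
100 atoms, sizes chosen so the whole suite runs in minutes on one CPU.
Degenerate inputs are rejected early: equal resonance positions (not
identifiable), all-zero scans (no peak to center on), reducible hop
chains without a unique stationary distribution, collinear alignment
selections. Ties are broken deterministically (middle of tied maxima for
peak centering; ascending residue index for equal contact counts).

## Known limitations

* The exchange-mechanistic mapping is per-resonance closed-form; full
  Bloch–McConnell integration, multi-pool coupling and B0/B1 maps are
  out of scope.
* Model counts between 4 and 5 are genuinely ambiguous at 1% noise on
  the standard grid (see the BIC discussion above); reporting the
  per-count score table (`$selection`) is the honest output.
* Contact analysis assumes orthorhombic boxes for minimum-image
  distances and a single xenon atom per system.
* The S² estimator uses full-trajectory moments; for strongly
  non-stationary trajectories windowed estimators would differ.
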