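---
title: "Models and methods in nmrarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in nmrarray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrarray)
```

nmrarray processes single and arrayed 1D NMR free induction decays and fits
the physical models that arrayed experiments encode: translational diffusion
(DOSY), longitudinal and transverse relaxation (ROSY), and trilinear
reaction-monitoring structure (PARAFAC). This vignette records the models,
the conventions and the numerical choices the implementation makes, so that
results can be interpreted — and reproduced — without reading the source.

## Data model and conventions

A `fid_set` holds a complex matrix with one FID per row plus the acquisition
metadata (`dwell` in s, `sfrq` in MHz, up to two increment axes). A
`spectrum_set` holds the transformed data on a **descending** frequency axis
(left = high ppm, the universal NMR display convention); every function
consumes the axis rather than assuming an index order. Frequencies are
carrier-relative Hz; the ppm calibration is `ppm = (hz - ref_offset_hz)/sfrq`,
so re-referencing (`set_reference()`) only moves `ref_offset_hz`.

Two-axis arrays are stored flattened row-major with the first axis fastest,
matching Bruker `ser` ordering. This choice is a convention of this package;
where a two-axis array must be pruned row-wise the axes are collapsed to a
generic index rather than silently mismatched.

The discrete Fourier transform halves the first FID point (the standard
DC-offset correction; without it every spectrum carries a constant baseline
offset of half the first point). `save_as_fid()` inverts the transform
exactly; in real-only mode the imaginary part is reconstructed by conjugate
symmetry, which is exact only for signals fully decayed within the first
half of the acquisition time — the documented accuracy condition.

## Apodisation

Time-domain weighting uses

$$w(t) = \exp\!\big(-\pi\,\mathrm{lw}\,t\big)\,
         \exp\!\Big[-\Big(\frac{\pi\,\mathrm{gw}\,t}{2\sqrt{\ln 2}}\Big)^2\Big],$$

where `lw` and `gw` are the **additional Lorentzian and Gaussian full widths
at half height in Hz** convolved into the spectrum. This is the unique form
for which the lw-only weighting of a non-decaying signal produces a
Lorentzian of FWHM exactly `lw` and the gw-only weighting a Gaussian of FWHM
exactly `gw`; both identities are verified by the test suite against
measured half-height widths. `lw < 0` with `gw > 0` gives the usual
Lorentz–Gauss resolution enhancement.

## Automatic phasing

The automatic phase correction minimises
$J(\phi_0,\phi_1) = \sum_{\text{signal}} \max(0, -\mathrm{Re}\,S)^2
 + 10^{-3} \sum_{\text{peaks}} |\mathrm{Re}\,S - |S||$
over a coarse grid followed by Nelder–Mead refinement, with the first-order
term normalised per full sweep width about a pivot at the tallest peak. Two
details matter. The negative-intensity penalty alone is flat wherever the
real part stays positive, so an absorption-matching tie-break is needed; and
that tie-break is evaluated **only on strong points near peak tops**, because
on the tails the magnitude retains the dispersion-mode contribution and
comparing `Re` against `|S|` there biases the estimate by several degrees.
The optimiser is seeded by a per-peak phase regression (at a resolved peak
maximum the spectral phase equals the local misphase), which makes recovery
of injected (30°, 40°) errors accurate to well under a degree on synthetic
spectra. In `"global"` mode the phases estimated on the first increment are
applied to the whole array.

## Baseline correction

Manual mode fits a polynomial of user-chosen degree to the real part over
the points outside the declared signal regions (orthogonal-polynomial basis
on a scaled abscissa for conditioning) and subtracts it. Automatic mode
iterates fit → reclassify (|residual| < 3σ is baseline) → refit until the
classification is stable, capped at 20 iterations. The operation is
idempotent to ≲1e-10 on its own output.

## Reference deconvolution

`fiddle()` removes instrumental distortions shared by all lines — lineshape
errors from poor shimming, constant phase errors, per-increment frequency
drift — using one resolved reference signal. Per increment the spectrum is
zeroed outside the reference region and inverse-transformed to the
experimental reference FID $r_\mathrm{exp}(t)$; an ideal reference
$r_\mathrm{id}(t)$ is synthesised at the reference position (taken from the
**first** increment, so that drifted increments are re-aligned to it) with
the satellite pattern of the chosen model and the target lineshape
weighting; the raw FID is multiplied by
$c(t) = r_\mathrm{id}(t)/r_\mathrm{exp}(t)$.

Numerical choices:

* **Division stabilisation** is a hard truncation: $c(t) = 0$ wherever
  $|r_\mathrm{exp}| < \varepsilon \max|r_\mathrm{exp}|$, with
  $\varepsilon = 10^{-3}$ exposed as an argument. Simple, and its effect is
  bounded by the signal level at the truncation onset.
* The ideal reference is anchored as $r_\mathrm{id}(0) = |r_\mathrm{exp}(0)|$
  — a real value, which is what removes a common phase error. A narrow
  reference window clips the reference line's dispersion tails and biases
  this single anchoring point, which rescales the corrected spectrum
  uniformly (lineshapes are unaffected); a region a few linewidths wide
  keeps the bias negligible.
* Satellite models: TMS carries ²⁹Si satellites (total fraction 0.047,
  J = 6.6 Hz) and ¹³C satellites (0.011, J = 118 Hz); TSP carries the ¹³C
  pair only. These constants are configurable because published values vary
  with isotopic abundance conventions.

## Pure shift reconstruction

Interferogram acquisitions store consecutive chunks of a homodecoupled FID
in the rows of a pseudo-2D data set. `ps_reconstruct()` concatenates
`inc1[drop+1 .. drop+first_chunk]`, then `inc_i[drop+1 .. drop+chunk_points]`
for the remaining chunks, giving exactly
`first_chunk + (chunks-1) * chunk_points` points at the original dwell.
`drop_points` is applied to **every** chunk including the first, and
`first_chunk` counts points kept after dropping — the composition rule is
stated here because acquisition schemes differ and the parameters alone do
not pin it down. No chunk-edge apodisation is applied; the residual
sidebands at multiples of the chunk rate are accepted, as in interferogram
practice.

## Diffusion analysis

The attenuation law is the Stejskal–Tanner equation
$I(g) = I_0 \exp(-\gamma^2\delta^2 g^2 D \Delta')$, generalised to the
non-uniform-gradient (NUG) form
$I = I_0\exp\big(-\sum_m c_m (\gamma^2\delta^2 g^2 \Delta' D)^m\big)$ with
$c_1 = 1$. Defaults: γ = 2.6752218744e8 rad s⁻¹ T⁻¹ (¹H), δ = 2 ms,
Δ′ = 100 ms, gradients up to 0.5 T/m over 16 increments — a routine
high-resolution DOSY setting under which D ≈ 5e-10 m²/s attenuates to
roughly e⁻³.

Per-peak (HR-DOSY) fitting takes the real-part height at the picked peak
index per increment, and fits (I₀, D) by Levenberg–Marquardt with a
two-point log-linear initial estimate and D bounded below by zero;
non-decaying data end at the bound and are flagged. The multiexponential
variant fits K, K−1, … components and keeps the largest k for which the
F-test of k versus k−1 is significant at α = 0.05 **and** every amplitude
exceeds twice its standard error; a smaller model that already fits at
machine precision is never enlarged (on noiseless data the F statistic
between two near-zero residuals is meaningless). The α = 0.05 + 2·SE rule is
this package's concretisation of "reduce until statistically significant".

DOSY maps place a Gaussian ridge per peak along a log-spaced D axis
(64 bins spanning 0.1–10× the fitted range by default), centred at the
estimate with a standard deviation equal to the fit standard error mapped to
the log axis and floored at one bin; each ridge is normalised to sum to the
peak amplitude.

## Multivariate resolution

**SCORE** minimises ‖X − C(θ)S‖² over one decay parameter per component,
with the component spectra S solved per frequency column by (optionally
non-negative) linear least squares given the decay matrix C. The outer
optimisation is a Nelder–Mead simplex on log-parameters (positivity by
construction), initialised from DECRA when the gradient grid allows it and
from a log-spaced ladder otherwise, with one restart from a perturbed start
if the relative residual stays above 1e-6. If the simplex fails to improve
on its start, the starting parameters are returned — so a SCORE fit
initialised from DECRA never ends above DECRA's residual. Integral
fractions are 100 · Σ_f S_kf / Σ_kf S_kf and sum to 100 by construction.

**OUTSCORE** uses the same parameterisation but minimises the normalised
spectral cross-talk Σ_{a<b} Σ_j |S_aj||S_bj|/(‖S_a‖‖S_b‖) — separation by
spectral difference rather than residual. The formula is this package's
normalised form of that criterion.

**DECRA** requires the Stejskal–Tanner exponent to be equally spaced
(relative tolerance 1e-6; unequal grids are refused rather than silently
interpolated). Row-shifted sub-arrays A = X[1..N−1] and B = X[2..N] share
component spectra while the decays advance by a constant factor ρ_k, so the
eigenvalues of the transfer matrix projected onto A's leading singular
subspace give D_k = −ln ρ_k/ΔX exactly for noiseless exponentials — the
algebraic oracle the iterative methods are tested against. Complex
eigenvalues are flagged as a model violation.

**ILT**: min ‖Kx − b‖² + λ²‖x‖² with K_ij = exp(−X_i D_j) on a log-spaced D
grid, solved by SVD (unconstrained) or non-negative least squares on the
augmented system. λ defaults to generalized cross-validation on the
unconstrained problem; the regularisation operator is the identity, the
simplest member of the Tikhonov family. Mass accumulating at a grid edge
triggers a warning to widen the grid.

## Relaxation

Inversion recovery uses the robust three-parameter form
I(τ) = A + B e^{−τ/T1} by default (imperfect inversion changes B, not T1);
the constrained two-parameter form B = −2A is available. Saturation
recovery fits A(1 − e^{−τ/T1}); T2 fits I₀e^{−t/T2} with t either given or
as counter × loop duration (CPMG/PROJECT loop counters, disambiguated at
import: `vclist` entries are counters, `vdlist` entries are times). ROSY
maps are built exactly like DOSY maps over T, or over the rate 1/T on
request — both are offered since conventions differ. RSCORE is the SCORE
machinery with the relaxation kernel.

## PARAFAC and PowerSlicing

PARAFAC is fitted by alternating least squares on the three unfoldings,
with row-wise non-negative least squares when a mode is constrained.
Columns of the gradient- and frequency-mode factors are unit-norm with the
scale carried in the time mode, and components are ordered by explained
variation — a convention this package fixes since none is universal. The
fit percentage 100(1 − ‖X−X̂‖²/‖X‖²) must be non-decreasing across
iterations; a decrease beyond 1e-10 aborts with diagnostics. Initialisation
is by leading singular vectors (`"svd"`), random, or best-of-n (five random
starts plus SVD, 30 burn-in iterations each, continue the best);
random draws are seeded, so results are reproducible. PowerSlicing builds
unit-shift slabs (slab s = columns s..s+L−1; default 3 slabs); for pure
exponentials on an equally spaced exponent grid the cube is exactly
trilinear with slab loadings ρ_k^s, and the rates recovered from the slab
mode agree with DECRA to machine accuracy — the cross-method identity the
tests assert.

## Arrayed-spectra diagnostics

Peak tracking reports the tallest peak per increment with parabolic
position refinement and FWHM by linear interpolation at half height.
Temperature changes are relative to the first increment,
ΔT_i = (δ_i − δ_1)/coeff, with coefficients 2.97e-4 ppm/K (HDO) and
1.14e-2 ppm/K (TSP); the sign convention (shift to higher ppm = warmer) is
fixed by the calibration slope and unit-tested. The phase-deviation
estimator shifts the phase by +90° and measures the positive/negative
excursion asymmetry ρ = (P−N)/(P+N); for a Lorentzian the closed forms
P = cos²φ/(2w(1−sin φ)) and N = cos²φ/(2w(1+sin φ)) collapse to
ρ = −sin φ, so the inverse is the exact arcsine rather than a numerical
table. The estimator assumes a near-Lorentzian line — apply broad
Lorentzian apodisation first when in doubt.

Integration multiplies region sums by the ppm step; tilt correction
subtracts the straight line through the means of the first and last
max(1, 3%) points of the region. Binning sums real intensities into
contiguous bins and conserves the total exactly. Alignment is deliberately
simple — per-interval integer-point shifts maximising cross-correlation with
the median spectrum, edges zero-filled — a reduced stand-in for interval
correlation shifting; it recovers constructed shifts exactly when the
median target represents the consensus.

## File formats

Bruker: `acqus`/`acqu2s` (JCAMP `##$KEY=` pairs), `fid`/`ser` with byte
order per `BYTORDA`, type per `DTYPA` (absent → int32, the legacy default),
integer data scaled by the power-of-two `NC` exponent, and `round(GRPDLY)`
leading complex points discarded — the simplest defensible group-delay
treatment (first-order-phase handling exists but is not the default here).
Consecutively numbered 1D directories are read as an array and must share
dwell and sfrq. Varian: big-endian `fid` with file/block headers, 16-bit
int, 32-bit int and float32 storage decoded from the status flags, arrayed
procpar parameter mapped to the increment axis. The internal format is
`meta.json` plus little-endian float64 (`data.bin`, bit-exact round trip) or
"real imag" text lines (`data.txt`); it is a fresh design, not compatible
with any vendor format. Gradient lists are written and read in T/m
throughout; converting vendor-specific units (e.g. G/cm calibration tables)
is the caller's responsibility.

## What the simulator does and does not emulate

`make_fid()` and its arrayed variants generate data directly from the
closed forms above: Lorentzian/Gaussian lines, per-component diffusion
attenuation, recovery/decay amplitude laws, trilinear cubes, common
multiplicative lineshape distortions, and interferogram raw data with an
exact reconstruction target. Noise is complex circular Gaussian with an
absolute σ per quadrature, seeded. J-multiplets are modelled as explicit
line lists; there is no spin dynamics, no radiation damping, no
temperature-drift model beyond a linear shift, and no gradient
non-uniformity beyond the NUG power series. Passing tests therefore
demonstrate correctness of the *algorithms* under their stated model
assumptions; they do not certify behaviour on real data whose distortions
violate those assumptions (e.g. lineshape errors that differ between lines,
which reference deconvolution cannot remove by construction).

Test and acceptance problem sizes — 16 gradient increments, 1–16k complex
points, 64–128 frequency bins for cubes, 200-replicate noise ensembles —
were chosen as the smallest sizes at which each method operates in its
intended regime; all complete in about a minute on one core.

## Known limitations

* FIDDLE on narrow windowed regions can rescale intensities by the
  clipped-dispersion fraction (see above); repeated application is exactly
  idempotent only when the reference window captures the full line.
* The multiexponential reduction rule and the OUTSCORE cross-talk form are
  reasonable concretisations, not published constants.
* The auto-aligner uses integer shifts against a median target and will not
  match a full interval-correlation-shifting implementation on crowded
  spectra.
* The ILT, like all regularised inversions, has resolution limited by the
  noise level; the GCV λ is a default, not an oracle.
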