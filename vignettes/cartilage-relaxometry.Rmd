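---
title: "Two-dimensional relaxometry and dispersion analysis of cartilage water"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-dimensional relaxometry and dispersion analysis of cartilage water}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartrelax)
```

## The physical picture

Articular cartilage is, from the point of view of its water, a swollen
polymer network: collagen fibers and proteoglycan aggregates fill roughly a
quarter of the tissue, and the remaining volume is occupied by a saline
water phase that diffuses almost freely between them. Proton NMR sees two
clearly distinct pools:

* a **liquid-like pool** — bulk-like water with an exponential transverse
  decay and T2 of tens of milliseconds in the hydrated tissue, shrinking to
  a few ms on drying;
* a **solid-like pool** — macromolecular protons plus strongly bound water,
  with a *Gaussian* free-induction decay (the signature of static dipolar
  coupling) and an apparent T2 of 20–40 µs that barely changes with
  hydration.

Both pools have similar longitudinal relaxation times of a few hundred ms
at 1 T. Because the solid-like pool decays within tens of microseconds it
is invisible to echo-based detection; it can only be captured in the FID
between the receiver dead time (~15 µs) and the first echo. The package
therefore simulates and analyses the combined **FID-CPMG
inversion-recovery** experiment: each recovery delay encodes T1, and the
acquisition axis concatenates a microsecond-resolved FID with one sample
per CPMG echo top.

## The 2D inverse Laplace transform

The signal matrix is modelled as

$$ S(t_{rec}, t_{acq}) = \iint F(T_1, T_2)\, k_1(t_{rec}, T_1)\,
   k_2(t_{acq}, T_2)\; d\log T_1\, d\log T_2 + \epsilon $$

with the recovery kernel $k_1 = 1 - 2 f_{inv} e^{-t_{rec}/T_1}$ (inversion)
or $1 - e^{-t_{rec}/T_1}$ (saturation), and a **mixed transverse kernel**

$$ k_2 = \begin{cases} e^{-(t_{acq}/T_2)^2} & T_2 < T_{2,b} \\
   e^{-t_{acq}/T_2} & T_2 \ge T_{2,b} \end{cases} $$

so that solid-like grid points decay as Gaussians and liquid-like points as
exponentials. The boundary $T_{2,b}$ defaults to 1 ms: the two regimes
observed in tissue sit at tens of µs and above several ms respectively, so
any boundary between ~0.1 and ~2 ms separates them; 1 ms is the geometric
middle of that gap on the default grid.

`invert()` solves the discretized, Tikhonov-regularized non-negative
problem

$$ \hat F = \arg\min_{F \ge 0} \| K_1 F K_2^T - M \|_F^2
   + \alpha \|F\|_F^2 $$

after compressing each kernel to its leading singular components (default
rank 16 per dimension — the kernels' singular values decay fast enough that
rank 16 keeps the compression error far below any realistic noise floor).
The compressed normal equations inherit the Kronecker structure
$(K_2^c{}^T K_2^c) \otimes (K_1^c{}^T K_1^c) + \alpha I$, on which a
Lawson–Hanson active-set non-negative least-squares iteration runs with a
gradient tolerance of 1e-10 (relative to the data scale) and an iteration
cap of 1500; exceeding the cap raises an error carrying the residual
gradient norm rather than returning a half-converged map.

**Choice of α.** Generalized cross-validation is the default: in the
compressed singular basis the GCV score has a closed form, and the data
components discarded by the rank truncation act as an effective noise
floor, so GCV remains well-behaved even on noiseless synthetic input. The
Butler–Reed–Dawson fixed point ($\alpha = \sqrt{N}\sigma / \|c\|$ with the
dual vector $c$ = residual/α) is available as `alpha_method = "brd"`, with
σ estimated from the part of the data orthogonal to the compressed kernel
space when not supplied. A fixed α is accepted for reproducing sweeps. The
regularization functional is plain ridge on the amplitudes; commercial
inversion codes do not disclose theirs, so results should be compared at
the level of peak positions and fractions, not map shapes.

## Peak quantification

`segment_peaks()` thresholds the map at a fraction of its maximum (default
0.05), labels 8-connected components on the log grid, and reports each
component's summed amplitude and amplitude-weighted *geometric mean*
position — the natural mean on log-spaced grids. Components below 1% of the
total intensity (the practical detection limit of regularized inversions)
are folded into a residual, and peak fractions plus the residual always sum
to one.

For *quantitative* mass accounting on low-noise data it is worth lowering
the threshold to 0.01: regularization spreads each delta-like component
into a peak with wings, and at the default 0.05 threshold those wings are
excluded from the peak integral, inflating the dominant peak's share by a
few points. The shipped analyses use 0.05 for detection and 0.01 when
comparing intensity shares against generating amplitudes.

`time_domain_fractions()` quantifies the same two pools without any
inversion, by fitting
$A_g e^{-(t/T_{2g})^2} + A_e e^{-t/T_{2e}}$ to the fully recovered decay.
The optional dead-time correction divides the Gaussian amplitude by
$1 - (1 - e^{-(t_{dead}/T_{2g})^2})$, i.e. by the fraction of the Gaussian
surviving at the dead time. It is off by default — reported intensities in
drying experiments are conventionally left uncorrected, which is also why
solid-pool fractions are systematically underestimated by 10–20%.

## Dispersion, RMTD and quadrupolar dips

Field-cycling experiments measure $R_1$ against Larmor frequency from tens
of kHz upward. The package models the dispersive part with the RMTD
mechanism (reorientations mediated by translational displacements): water
diffusing along the matrix surfaces samples a spectrum of orientation
modes $S(k) \sim k^{-\chi}$ between two wavenumber cutoffs, each mode
relaxing with $\tau(k) = 1/(Dk^2)$ for normal (Gaussian-propagator)
diffusion or $1/(ck)$ for Cauchy/Lévy statistics. The spectral density is
the mode integral

$$ I(\omega) = \int_{k_{low}}^{k_{high}} S(k)
   \frac{\tau(k)}{1 + \omega^2 \tau(k)^2}\, dk , $$

evaluated by adaptive quadrature on log k, and enters the standard rate
expressions $1/T_1 = const\,[I(\omega) + 4I(2\omega)]$,
$1/T_2 = const/2\,[3I(0) + 5I(\omega) + 2I(2\omega)]$ and the
rotating-frame analogue. Mid-band this yields the exponent relations
$\gamma = (1+\chi)/2$ (gaussian) and $\gamma = \chi$ (cauchy) for
$T_1(\omega) \sim \omega^\gamma$.

**A numerical caveat worth knowing.** For Cauchy statistics at small χ the
mode integral converges slowly towards its upper cutoff: the truncation
error scales as $(\omega/\omega_{high})^{\chi}$, so with cutoffs only four
decades apart the apparent slope at the band centre is biased by as much as
0.17 at χ = 0.1. This is a property of any truncated power-law mode
spectrum, not of the quadrature. The exponent-recovery test suite therefore
uses twelve decades of cutoff separation and fits one to three decades
above the low cutoff frequency, where all χ ∈ {0.1, …, 0.9} recover within
0.02 for both statistics. When fitting *measured* dispersions, the band
should likewise stay well below any suspected high-frequency cutoff.

Quadrupolar dips — the localized R1 enhancements near 0.6, 2.3 and 2.9 MHz
where proton Zeeman levels cross the quadrupolar levels of immobilized
amide ¹⁴N — are modelled phenomenologically as Lorentzians added to the
rate, with default HWHM 0.01 MHz. `isolate_dips()` fits the dipolar
background on all points outside the dip windows (power law in log–log by
default; a smoothing spline for curved baselines) and subtracts it;
`dip_area()` integrates the residual per window by the trapezoidal rule. A
finite window captures $\tfrac{2}{\pi}\arctan(L/w)$ of a Lorentzian's full
area πhw (L = half-window), so windows must span several tens of HWHM for
the integral to come within 5% of πhw — with the default windows and
0.01 MHz dips the capture is 96–98%. Only *relative* areas (ratios between
hydration states) are meaningful as outputs of record; absolute
normalization of measured dip areas is instrument-dependent.

## Hydration modelling

Under two-site fast exchange the observed rate is
$1/T_i = p_a/T_{i,surf} + (1-p_a)/T_{i,bulk}$, with the surface term
proportional to the surface-to-volume ratio — hence inversely proportional
to the free-water content. Both empirical parameterizations are
implemented side by side, because drying data follow the first well for T2
and only approximately for T1:

* `fit_linear_weight()` — relaxation *time* linear in sample weight (the
  way drying trajectories are usually displayed);
* `fit_fast_exchange()` — relaxation *rate* linear in inverse free water
  (weight minus dry weight), whose slope is the surface term.

The bulk relaxation time defaults to 2 s, the bulk value of the saline
water phase. Free-water measures at or below zero are refused rather than
clamped silently.

## What the synthetic-data generator does and does not emulate

`simulate_ir_fidcpmg()` reproduces the benchtop protocol for hydrated
samples: 32 log-spaced recovery delays from 1 to 5000 ms, inversion
recovery with adjustable efficiency, a 1 µs FID grid from the 15 µs dead
time to the 250 µs first echo, 2000 echo tops, and additive Gaussian noise
on a single phased channel with a seeded stream. The default two-component
composition (`cartilage_components()`: exponential 635 ms/80.8 ms/928
units; Gaussian 666 ms/30 µs/134 units) is the fully hydrated state of a
drying series. The FID sampling rate is a declared default — instrument
manuals rarely state the retained FID points, so 1 µs is chosen to resolve
a 20 µs Gaussian comfortably.

Not emulated: Rician noise (phased amplitudes are assumed), B1
inhomogeneity, off-resonance and stimulated-echo artifacts, magnetization
exchange between pools (the maps are correlation, not exchange, maps), and
ab-initio ¹H–¹⁴N cross-relaxation lineshapes. Passing tests on this
generator therefore demonstrate correctness of the *estimators* under the
stated signal model, not robustness to every instrumental artifact of real
tissue data.

`simulate_depth_profile()` emulates a single-sided depth scan of a drying
slice: per-slice saturation-recovery curves with a user-supplied T1(depth,
time) map and a shrinking sample height (e.g. 1.2 → 0.6 mm), slices outside
the sample returning noise only.

## Numerical choices and degenerate inputs

* Log-spaced default grids, T1 ∈ [1 ms, 10 s] × 64 and
  T2 ∈ [5 µs, 1 s] × 64, covering the full drying trajectory.
* SVD rank 16 per dimension; ranks are capped by the data dimensions, and
  raising the rank to the full grid size makes the compression lossless
  (used by the oracle-equivalence test).
* Peak ordering breaks intensity ties toward longer T2, so the liquid-like
  pool is "main" when shares tie.
* All-zero datasets, empty component lists, non-increasing grids, windows
  outside the profile, sub-dry-weight samples, and non-converged fits all
  raise errors with the offending quantity named; nothing returns silently
  degraded output.
* Monoexponential recovery fits require ≥4 points spanning ≥1 decade;
  power-law fits require ≥5 points in band after exclusions.

## Problem sizes used in the shipped checks

The end-to-end two-pool recovery runs the full protocol size (32 × 2234
samples onto a 64 × 64 grid, about 3 s on one CPU). Solver-equivalence and
sweep tests use 20 × 69 datasets on 16 × 16 or 32 × 32 grids, where the
dense brute-force oracle is cheap. Exponent-recovery suites use 25-point
profiles, 18 noiseless (χ, statistics) cases plus 6 stochastic cases × 8
replicates.

## Known limitations

* Peak positions are quantized by the grid (a factor 1.21 per T2 cell at
  64 points over 5.3 decades); amplitude-weighted positions interpolate
  well below one cell in practice, but reported single-cell peaks cannot
  be more accurate than the grid.
* Components closer than about a factor 2 in T2 merge at realistic SNR;
  the number of reported peaks is a lower bound on the number of pools.
* GCV can under-smooth heavy-tailed noise; for data with suspected
  correlated noise, inspect an α sweep (`alpha_method = "fixed"`) — the
  residual/solution norms in the returned map support an L-curve reading.
* The RMTD model is used as a working description of the dispersion; its
  parameters (χ, cutoffs, transport coefficient) are effective quantities
  and are not unique structural measurements of the tissue.
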