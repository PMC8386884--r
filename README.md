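# cartrelax

NMR relaxometry analysis of water in articular cartilage — and, more
generally, of any tissue or porous material whose proton signal splits into
a liquid-like pool (exponential transverse decay, T2 of milliseconds to
seconds) and a solid-like pool (Gaussian decay, T2 of tens of
microseconds). The package is aimed at relaxometry practitioners who work
with benchtop T1–T2 correlation experiments, single-sided depth profiling,
and fast field-cycling dispersion measurements, and who want an open,
tested implementation of the full analysis chain instead of opaque vendor
inversion codes.

## What it computes

**T1–T2 correlation maps.** An FID-CPMG inversion-recovery experiment
produces a signal matrix over (recovery delay × acquisition time). The
package inverts it by a Tikhonov-regularized, non-negative 2D inverse
Laplace transform,

    F̂ = argmin_{F ≥ 0} ‖K₁ F K₂ᵀ − M‖² + α‖F‖²,

with the recovery kernel K₁ = 1 − 2 f_inv exp(−t_rec/T₁) and a **mixed
transverse kernel** K₂ — Gaussian `exp(−(t/T₂)²)` for grid T₂ below a
boundary (solid-like pool), exponential above it — after SVD compression of
both kernels. α is chosen by generalized cross-validation (default),
Butler–Reed–Dawson, or fixed. Peaks are segmented and quantified as
weighted integrals; the same pools can be quantified directly in the time
domain by a Gaussian-plus-exponential fit, with an optional dead-time
correction `1 − exp(−(t_dead/T₂)²)` for the signal lost before the
receiver opens (15 µs dead time loses 43% of a T₂ = 20 µs Gaussian).

**Dispersion profiles.** R₁(ω) is modelled through the standard spectral
density expressions 1/T₁ = const·[I(ω) + 4I(2ω)],
1/T₂ = const/2·[3I(0) + 5I(ω) + 2I(2ω)], with I(ω) given by the RMTD
(reorientations mediated by translational displacements) surface-mode
integral over S(k) ~ k^(−χ). Power-law fits T₁(ω) ~ ω^γ recover
γ = (1+χ)/2 for normal surface diffusion and γ = χ for Cauchy statistics.
Quadrupolar dips near 0.6/2.3/2.9 MHz (proton–¹⁴N level crossings) are
isolated by baseline subtraction and integrated per window.

**Hydration series.** Fast-exchange (Brownstein–Tarr) modelling
1/Tᵢ = p_a/Tᵢ,surf + (1−p_a)/Tᵢ,bulk, fitted both as time-vs-weight and
rate-vs-inverse-free-water, plus drying-trend summaries and
proton-density bookkeeping (a 14% solid-pool signal fraction corresponds
to ≈ 22 wt-% of proteoglycan with densities 2/18 and 40/640).

A seeded synthetic-data module generates every input the pipeline consumes
(FID-CPMG datasets, dispersion profiles with dips, recovery curves, depth
scans), so the whole chain is testable without instrument data.

## Worked example

Simulate the fully hydrated two-pool composition (exponential main pool
T1 = 635 ms, T2 = 80.8 ms, 928 units; Gaussian solid pool T1 = 666 ms,
T2 = 30 µs, 134 units), invert, and quantify:

```r
library(cartrelax)
dataset <- simulate_ir_fidcpmg(cartilage_components(), acquisition_scheme())
dataset
#> <decay_dataset> 32 recovery times x 2234 acquisition points (inversion recovery)

map <- invert(dataset, inversion_grid())
map
#> <relaxation_map> 64 x 64 grid, alpha = 0.0116 (gcv), total intensity 1070
#>   residual norm 38.11, solution norm 740.4

segment_peaks(map, rel_threshold = 0.01)
#>      T1_ms       T2_ms intensity  fraction cell_count
#> 1 635.5054 80.85701011  923.9287 0.8637455          4
#> 2 668.1192  0.02974864  135.7371 0.1268954          6
```

The inversion returns both generating pools: the main peak at
T1 = 635.5 ms, T2 = 80.9 ms and the solid-like peak at T2 = 29.7 µs, with
intensity shares 87.2% / 12.8% against the true 87.4% / 12.6%. The same
solid fraction straight from the time domain, without any inversion:

```r
time_domain_fractions(dataset)$fraction_short
#> [1] 0.1261
```

On the dispersion side, a Cauchy-statistics RMTD model with χ = 0.27
produces a power-law dispersion whose fitted exponent returns χ:

```r
m <- rmtd_model(chi = 0.27, statistics = "cauchy",
                k_low = 1e3, k_high = 1e15, transport_coefficient = 0.1)
prof <- simulate_dispersion(m, coupling = 1, freqs = log_spaced(0.01, 10, 30))
fit_powerlaw(prof, band = c(0.05, 5))
#> <powerlaw_fit> gamma = 0.273 +/- 0.000 over 0.05-5 MHz (20 points)
```

A command-line wrapper for the full pipeline
(`simulate`/`invert`/`peaks`/`dispersion`/`exchange`/`demo`) is installed
at `system.file("scripts", "cartrelax.R", package = "cartrelax")`.

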