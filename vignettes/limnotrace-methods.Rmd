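---
title: "Models and methods behind limnotrace"
author: "limnotrace authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind limnotrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limnotrace)
```

`limnotrace` turns a per-layer sediment-core table into a pollution
history in four stages: a CRS ²¹⁰Pb chronology, element fluxes, a
three-way source apportionment, and a contamination assessment. This
vignette explains each model, its assumptions, the tunable parameters and
the numerical choices, and what the synthetic-core validation does and
does not demonstrate.

## Units

All quantities are held in fixed internal units: depths in cm below the
sediment–water interface, dry mass per area in g cm⁻², activities in
Bq kg⁻¹, inventories in Bq m⁻², mass accumulation rates (MAR) in
g m⁻² yr⁻¹, concentrations in µg g⁻¹ dry sediment and fluxes in
µg m⁻² yr⁻¹. Published summary tables conventionally print fluxes in
mg m⁻² yr⁻¹; `flux_as_mg()` / `flux_as_ug()` are pure display
conversions, so mixed-unit reports cannot arise from the computation
itself.

Layers are half-open depth intervals `[top, bottom)`; wherever one depth
or age per layer is needed the midpoint is used. Missing values are
explicit (`NA`) and never encoded as zero, because zero is a legal
concentration.

## The CRS chronology

The constant-rate-of-supply model assumes the atmospheric supply *P* of
unsupported ²¹⁰Pb to the sediment surface (Bq m⁻² yr⁻¹) is constant in
time while the mass accumulation rate may vary. Then the residual
inventory below a boundary at cumulative dry mass *m*,
*I*(*m*) = ∫ₘ A dm, decays with the age of that boundary:

$$ t(m) = \frac{1}{\lambda}\,\ln\frac{I(0)}{I(m)}, \qquad
   \mathrm{MAR}_i = \frac{\lambda\, I(m_i)}{A_i}, $$

with λ = ln 2 / 22.3 yr⁻¹ by default (configurable; the standard ²¹⁰Pb
half-life) and *A*ᵢ the layer's unsupported activity at its mass
midpoint.

Choices that matter:

* **Supported ²¹⁰Pb** defaults to the mean of the measured ²²⁶Ra
  activities; when no ²²⁶Ra exists, the mean of the deepest three total
  ²¹⁰Pb values is used instead (`estimate_supported()`), with a warning
  when that deep tail is still visibly decaying, i.e. equilibrium was not
  reached and the asymptote is rough.
* **Integration.** Activities are layer averages, so the inventory is
  integrated as the exact sum of activity × layer dry mass in the
  cumulative-mass domain (the trapezoid of the piecewise-constant step
  function). Within a layer the inventory is linear in mass, so the
  midpoint inventory is the mean of the boundary inventories.
* **Clipping.** Unsupported activities below zero (measurement noise
  around the supported level) are clipped to 0 and flagged rather than
  dropped, keeping the depth grid intact. Such layers receive an age (the
  inventory is still defined) but no MAR; they are flagged `clipped`.
* **Dated-range truncation.** The dated range ends at the deepest layer
  whose unsupported activity exceeds twice its counting uncertainty.
  Deeper activities are statistically indistinguishable from zero; the
  ratio λI/A there is dominated by noise and would produce arbitrarily
  wrong accumulation rates. Those layers fall to the extrapolation stage.
  On noise-free input (no uncertainties given) nothing is truncated.
* **Age uncertainties** are first-order propagation of the activity
  counting errors through the inventory sums; no Monte Carlo.

### Missing-inventory correction

A core that stops above radioactive equilibrium misses the inventory below
its bottom, which biases deep CRS ages old. `correct_missing_inventory()`
fits a log-linear regression of unsupported activity against cumulative
mass on the deepest `tail_k` (default 4) significantly positive layers and
adds the analytic tail integral `exp(a + b·m_bot)/(−b)` to every boundary
inventory. The tail length is configurable because the appropriate choice
depends on how far above equilibrium the core stops.

Three guards keep the correction honest, because an extrapolated integral
amplifies fit error: the correction is skipped (zero) when the deepest
activity is below 10⁻⁴ of the surface activity (the profile is effectively
complete); it refuses to fit when the slope is non-negative or within two
standard errors of zero (the tail does not resolve a decay — choose the
tail manually); and it refuses a tail integral larger than the measured
inventory. When `crs_date()` hits a refusal it continues without the
correction and warns, since a slightly biased deep chronology is more
useful than none, and the warning points at the manual override.

### Age extrapolation

Below the dated range, calendar year is extrapolated linearly in depth by
ordinary least squares on the deepest `n_anchor` (default 4) dated layers.
Extrapolated layers receive the anchor-mean MAR and are flagged; an
extrapolated year is never allowed to be younger than the deepest dated
layer. Linear extrapolation presumes a near-constant deep accumulation
rate — appropriate for records whose pre-industrial MAR is stable, which
is also what the simulator's presets encode. Whether extrapolated-age
layers enter period averages is switchable
(`compute_fluxes(use_extrapolated = )`, default yes).

## Flux apportionment

Per element, F tot,i = Cᵢ × MARᵢ. The decomposition

* F_B — background: the arithmetic mean flux over included layers older
  than the cutoff year (default 1900; `background_sensitivity()`
  recomputes F_B for 1800/1850/1900, and on stable cores the three agree
  to well under a percent);
* F_V,i = F_B (MARᵢ/MAR_ref − 1) — the part explained by erosion
  changing the accumulation rate while the sediment keeps its background
  composition, with MAR_ref the arithmetic (not inventory-weighted) mean
  of the per-layer pre-cutoff MAR;
* F_A,i = F tot,i − F_V,i − F_B — the residual attributable to
  atmospheric deposition and non-lithogenic point sources

is exactly conservative at every layer by construction, and `apportion()`
asserts this before returning. Negative F_A is retained, reported and
annotated — it diagnoses an overestimated F_B or F_V (for instance a
catchment whose soils became depleted in the element after the background
window) and must not be silently clipped.

Period shares are computed on time-integrated sums (flux × the number of
years a layer represents), so thick slow layers and thin fast layers are
weighted by the time they stand for, not by their count. Period membership
is by layer-midpoint year; the "Recent" column is the mean of the two
topmost included samples. The period summary reports pre/post means, the
post/pre Factor and Recent, for concentrations and fluxes.

### Event layers

Instantaneous deposits (flood beds, turbidites) carry catchment material
at roughly background composition and dilute the ambient ²¹⁰Pb, so the
CRS model sees them as layers of absurdly high apparent MAR. They must not
enter background means, reference MAR or period summaries.
`exclude_layers()` accepts explicit layer ids or a robust z-score rule on
per-layer MAR: `z = (MAR − median)/scale` with the MAD as scale, floored
at 25% of the median. The floor encodes a domain judgement: a two-fold
MAR regime shift (land-use change) is normal signal and must not be
flagged, while an instantaneous bed at several times the ambient rate is
not. A plain mean/sd z-score would be corrupted by the very outliers it is
meant to find; an unfloored MAD flags legitimate regime shifts whenever
more than half the record sits in one regime.

## Assessment

* **Thresholds.** The shipped table carries LEL (low effect level), ERL
  (effect range-low) and TAS (threshold for agricultural soils) per
  element, exactly as published; Hg is the documented case where
  LEL (0.2) > ERL (0.15) and is preserved as printed. "Exceeds" means
  strictly greater than the threshold; an exact tie is classed below and
  marked as a boundary case (conservative; real data never tie exactly).
* **Correlations** between element concentrations and C/N/S are Pearson,
  on concentrations (not fluxes), with raw two-sided p-values by default
  and optional Holm adjustment. Elements tied to organic matter (Hg, As)
  show strong positive correlations; the type-I error of the screen is
  validated by simulation.
* **QA/QC.** Recovery correction divides by recovery/100 and is off by
  default: a constant recovery rescales a series without changing any
  between-layer ratio or correlation, which is also asserted as a
  property. The LOD is mean + 3·sd of the procedural blanks (a
  convention; the multiplier is a parameter), and below-LOD values are
  flagged, never substituted — their treatment is left to the caller.
  Replicate RSD is 100·sd/mean per replicate set (sample sd), averaged
  across sets per element.

## The synthetic-core simulator

`build_synthetic_core()` inverts the apportionment algebra to manufacture
cores whose truth is known exactly. An annual grid carries a
piecewise-linear MAR history; erosion-derived matter has the background
concentration C_B at any MAR, and the atmospheric component adds
F_A(t)/MAR(t) on top, so C(t) = C_B + F_A(t)/MAR(t) and the generated
components satisfy F_B + F_V + F_A = F tot exactly before noise. The
atmospheric pulse is either an explicit flux trajectory or a shape scaled
so the post-1950 atmospheric share of the summed total flux hits a target
fraction exactly on the annual grid; negative targets emulate
post-background depletion (the negative-F_A diagnostic case).

Unsupported ²¹⁰Pb of matter deposited at age *a* is (P/MAR)·e^(−λa). Each
year is split into 12 sub-slabs whose inventory is the exact integral of
the supply decay, so the total inventory is P/λ to machine precision and
the inverse model's discretization bias is negligible. Slabs are cut into
layers of the configured thickness (default 0.5 cm) with mass-weighted
aggregation; the truth records each layer's mean deposition *time* (not
the integer year label — the half-year distinction matters at fine
resolution). Event beds are inserted as separate layers of background
composition with ambient activity diluted by their thickness multiplier —
the classic flood-bed signature — flagged in the truth but deliberately
not in the profile, so detection rules can be scored against truth.

Noise is multiplicative lognormal on concentrations (element-wise CV
defaulting to the 7–16% replicate-RSD range typical of ICP-MS sediment
work), Gaussian counting noise on total ²¹⁰Pb (CV 5%), and lognormal
noise on the C/N/S series. A fixed seed makes the whole core byte-for-byte
reproducible.

Two presets encode contrasting study conditions. `remote-highland`: 260
years, MAR constant at 70 g m⁻² yr⁻¹ before 1950, doubling to 140
(1950–1985), dipping to 100 by 1992 and recovering to 120 by 2014; dry
bulk density 0.15 g cm⁻³; supply 130 Bq m⁻² yr⁻¹; supported 25 Bq kg⁻¹;
background concentrations typical of Andean volcanic-soil lakes; Hg
carries a 42% post-1950 atmospheric share, As/Pb/Cu smaller ones, and the
organic-matter series co-varies with the Hg pulse. `peri-urban`: the same
shape at five-fold MAR, higher supply, strong post-1950 atmospheric
pulses for Pb (50%), Hg (40%), As (36%) and moderate ones for Cu, Zn, Cd,
plus three flood beds (1910, 1963, 1995) at eight years' worth of
material each. Magnitudes are all configurable; the presets are the
package's fixed validation conditions, not fitted quantities.

**What passing the synthetic validation shows — and what it does not.**
It shows the inverse machinery is correct: ages and MAR recover within
±0.5 yr and ±2% (noise-free, 0.5 cm, youngest 150 yr), planted source
shares are recovered within a few percentage points across seeds, the
conservation and null identities hold to machine precision, and the
missing-inventory correction restores truncated chronologies to within
2 yr. It does not validate the CRS assumption itself on a real lake
(sediment focusing, supply variability), nor compaction behaviour beyond
the linear ramp offered, nor post-depositional mobility of elements —
none of which the simulator emulates. Conclusions about a real core still
depend on those assumptions holding there.

## Validation problem sizes

The shipped tests and the acceptance script run the presets at their
default sizes: 260-year cores at 0.5 cm (≈ 29 layers remote, ≈ 90
peri-urban), convergence checks at 1.0/0.5/0.25 cm, recovery statistics
over 20 seeds, and 1000 null replicates for the correlation screen —
sizes chosen so the full validation reflects realistic record lengths
while the complete suite runs in seconds.

## Known limitations

* No sediment-focusing correction: single-core inventories are taken at
  face value, so absolute fluxes inherit any focusing bias of the coring
  site.
* No alternative chronologies (CIC, CF-CS, Bayesian) and no ¹³⁷Cs
  validation marker.
* The missing-inventory tail fit assumes exponential decay in the mass
  domain over the fitted tail, i.e. near-constant deep MAR; a strong MAR
  change inside the tail is rejected by the guards rather than modelled.
* Apportionment attributes everything non-background and non-erosional to
  "atmospheric + point sources"; it cannot separate the two, and F_B
  itself may contain a legacy anthropogenic component when the record is
  too short to reach undisturbed background.
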