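# limnotrace

Reconstructing trace-element and mercury pollution histories from
short lake-sediment cores.

Lake sediments archive the deposition of potentially toxic trace elements
(V, Cr, Co, Ni, Cu, Zn, As, Cd, Pb, Hg) over the past centuries. Working
from per-layer core measurements — dry mass, total ²¹⁰Pb and ²²⁶Ra
activities, element concentrations — `limnotrace` builds the chronology,
turns concentrations into deposition fluxes, splits each flux into its
sources, and screens the result against sediment-quality thresholds. It is
aimed at paleolimnologists and environmental geochemists who need the full
chain from a raw core table to an interpretable pollution history, with
every step testable against simulated cores of known truth.

## What it computes

**CRS chronology.** Under the constant-rate-of-supply (CRS) model the
atmospheric flux of unsupported ²¹⁰Pb is constant, so a layer boundary with
residual inventory *I(m)* (Bq m⁻², integrated over cumulative dry mass *m*)
has age

> *t*(*m*) = (1/λ) ln( *I*(0) / *I*(m) ),  λ = ln 2 / 22.3 yr⁻¹,

and layer *i* accumulates at MAR*ᵢ* = λ·*I*(mᵢ)/*A*ᵢ, with *A*ᵢ the layer's
unsupported activity. Supported ²¹⁰Pb comes from the ²²⁶Ra mean (or a
deep-asymptote fallback). Cores truncated above radioactive equilibrium get
a missing-inventory correction (log-linear fit of the deepest activities,
analytic tail integral); layers below the dated range are aged by ordinary
least squares on the deepest four dated layers ([`crs_date()`]).

**Flux apportionment.** Per element, the total flux at layer *i* is
*F*ᵢ = *C*ᵢ × MAR*ᵢ*. The background flux *F*_B is the mean pre-1900 flux;
the erosion-driven component is
*F*_V*ᵢ* = *F*_B (MAR*ᵢ*/MAR_pre-1900 − 1); the atmospheric / point-source
component is the residual *F*_A*ᵢ* = *F*ᵢ − *F*_V*ᵢ* − *F*_B. The
decomposition is exactly conservative by construction; negative *F*_A is
kept as a diagnostic ([`apportion()`]). Instantaneous event (flood) layers
are excluded by id or by a robust MAR z-score ([`exclude_layers()`]).

**Assessment.** Period summaries (pre/post-1950 means, post/pre Factor,
"Recent" mean of the two topmost samples), exceedance of LEL / ERL /
agricultural-soil thresholds, between-lake ratio tables, element vs C/N/S
correlation screening, and QA/QC helpers (recovery correction, LOD,
replicate RSD).

**Synthetic cores.** A forward simulator with known MAR history, ²¹⁰Pb
supply and per-element source composition (`build_synthetic_core()`), with
two shipped presets — a remote highland lake and a peri-urban lake — so
every stage of the pipeline can be validated against ground truth.

## Worked example

```r
library(limnotrace)

sim <- build_synthetic_core(scenario_remote_highland(), seed = 1)
fit <- crs_date(sim$profile, coring_year = 2014)
fit
#> CRS 210Pb age-depth model
#>   25 CRS-dated layer(s), 4 extrapolated; coring year 2014
#>   supported 210Pb: 25.17 Bq/kg (ra226-mean)
#>   inventory: 4185.3 Bq/m2 (missing-inventory term 0.0)
#>   years: 1729-2011; MAR 30.5-181.0 g/m2/yr (dated layers)

fp  <- compute_fluxes(sim$profile, fit)
app <- apportion(fp, fit)
subset(app$shares, element == "Hg" & window == "post-1950")
#>    element    window component share_pct
#> 29      Hg post-1950       F_B      32.3
#> 37      Hg post-1950       F_V      26.1
#> 45      Hg post-1950       F_A      41.6
```

The chronology dates 25 layers directly (supported level recovered from the
simulated ²²⁶Ra, MAR doubling after 1950 visible in its 30–181 g m⁻² yr⁻¹
range) and extrapolates four deeper layers. The share table says that 41.6%
of the post-1950 Hg deposition in this simulated remote lake is
atmospheric/point-source — the scenario planted 42%, so the pipeline
recovers the injected source structure from the noisy core. Screening the
period means against the shipped thresholds:

```r
sqg_classify(period_summary(fp))
#> Sediment-quality exceedance report: 11 of 72 checks exceed a threshold
#>  element period   conc kind threshold factor
#>       Cu    pre 23.285  LEL     16.00   1.46
#>       As   post 18.608  LEL      6.00   3.10
#>       Hg   post  0.162  ERL      0.15   1.08
#>       ...
```

Cu and As sit above their low-effect levels throughout, and post-1950 Hg
crosses the effect-range-low — the typical signature of a remote lake with
a modern atmospheric Hg overlay.

The package also ships the published period summaries and metadata of two
reference Andean lakes (`andes_reference_summaries()`,
`andes_reference_lakes()`) used in the examples and checks below.

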