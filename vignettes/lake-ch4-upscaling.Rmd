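---
title: "Upscaling lake methane emissions: model, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Upscaling lake methane emissions: model, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakech4)
```

## The model

Lake CH₄ reaches the atmosphere through four pathways: diffusion across the
water–air interface, ebullition (bubbles from the sediments), the release of
CH₄ stored under ice at spring ice-out (including spring water-column
turnover), and fall water-column turnover. `lakech4` upscales a compilation
of flux measurements to a daily, 0.25° gridded climatology of all four,
under a small set of explicit assumptions:

1. **Fluxes respond exponentially to air temperature.** For each pathway we
   fit ln F = a + b·T by ordinary least squares over the diel-corrected
   compilation (b in °C⁻¹). An exponential response in air temperature is
   the standard model for both pathways; air temperature is the single
   covariate — no water-temperature or stratification physics. ln-OLS
   rather than a nonlinear exponential fit keeps coefficients comparable
   with the broader literature. A fit is refused below 10 usable records or
   with a singular design; non-positive fluxes (diffusive uptake) cannot
   enter the log fit and are excluded with a count.
2. **Measurements are biased toward daytime and the warm season.** Daytime
   (07:00–20:00 local) fluxes exceed the 24-h mean; daytime-only records are
   multiplied by 0.7. We read the window endpoints as closed–open
   [07:00, 20:00). The correction is flagged and a second application is
   refused. Seasonal bias is removed by projecting each corrected
   measurement through its site's monthly temperature climatology,
   F(m) = F·exp(b·(Tₘ − T_anchor)), anchored so the measurement month
   returns the corrected flux exactly. Records lacking a contemporaneous
   air temperature use the site's climatological temperature of the
   measurement month (flagged `temp_imputed`).
3. **Space is organized by ecoclimatic lake type.** Seven types are
   assigned per cell by a fixed-precedence decision tree on permafrost
   category, ground ice, SOC and annual soil temperature. Measurements
   inherit the type of their cell unless they carry an explicit label
   (explicit labels win — the compilation does not say how unlocated sites
   were geolocated, so the label is the stronger evidence). The organic
   type has no measurements anywhere; its emission rates are copied from
   peat ponds via a one-entry alias table.
4. **Emissions are gated by the ice season.** Open-water emission runs from
   the climatological thaw day to the freeze day; never-freezing cells emit
   all 365 days.
5. **Episodic releases follow an accumulation–oxidation budget.** CH₄
   produced at the deep-water rate E₅ accumulates once a 60-day
   O₂-depletion lag has passed; oxidation removes 75 % (spring) or 89 %
   (fall); the remainder is emitted evenly over a short window. E₅ is the
   type's mean corrected ebullition flux rescaled along the fitted
   exponential to 5 °C (maximum-density temperature + ~1 °C metabolic
   heat): E₅ = F̄·exp(b·(5 − T̄)), with F̄ and T̄ the type's mean
   ebullition flux and mean observation temperature.
6. **Large lakes emit less per m².** Area from lakes ≥ 5,000 km² receives
   10 % of the small-lake rate (0–25 % in the uncertainty budget). The same
   factor is applied to episodic fluxes from that area, for consistency.

## Parameters that matter

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| diel factor | – | 0.7 | daytime-only → 24-h mean |
| b (per pathway) | °C⁻¹ | fitted | temperature sensitivity of ln-flux |
| t_trop | °C | 20.0 (± 2.5) | temperate / tropical soil-temperature split |
| t_bor | °C | 8.0 | boreal / temperate split (convention, see below) |
| SOC, ground-ice thresholds | kgC m⁻², % | 10, 10 | classification tree splits |
| t_deep | °C | 5 | deep-water production temperature |
| lag (spring, fall) | d | 60 (± 15) | O₂ depletion before accumulation |
| oxidation (spring, fall) | – | 0.75, 0.89 | fraction of store removed |
| emission windows | d | 14 (± 7 around thaw), 7 (before freeze) | episodic release |
| scale_large | – | 0.1 (0–0.25) | large-lake flux factor |

`t_bor` is the one classification threshold the source material does not
print; 8 °C is this package's documented convention, kept as an explicit
config value so it can be swept.

## Numerical choices

- **Calendar.** A 365-day no-leap climatological year everywhere; day
  arithmetic is modular, so Southern Hemisphere seasons that straddle the
  new year are handled by construction.
- **Climatological dates.** Per-year thaw/freeze days are averaged and
  rounded to the nearest day; when a cell's dates spread over more than 182
  days the mean is computed circularly (via mean sine/cosine), preventing
  mid-year nonsense at the date wrap.
- **Daily curves.** The twelve monthly means are anchored at month-midpoint
  days (16, 45.5, 75, …) and interpolated with a *periodic* cubic spline —
  the annual cycle has no endpoints — then ebullition is clipped at zero.
  Constants are reproduced exactly and the curve passes through every
  anchor.
- **Episodic windows.** The spring window (±7 d around thaw) emits over all
  14 days — the pre-thaw half is the ice-melt release itself. Window days
  that would cross into the opposite end of the season (a post-thaw day
  beyond freeze, or a fall-window day before thaw) are clipped and the
  stored mass renormalized over the remaining days, so mass closure
  (Σ daily = stored) holds exactly in every geometry.
- **Units.** One conversion chain, centralized:
  mg m⁻² d⁻¹ × km² → ×10³ g d⁻¹; g → ×10⁻¹² Tg. Cell areas use a spherical
  Earth (R = 6371 km) with cosine-latitude weighting; grid coordinates are
  cell centers.
- **Degenerate inputs.** Classification is total: cells matching no
  explicit branch (sporadic/isolated permafrost with SOC < 10; no
  permafrost with SOC ≥ 10) fall through to the temperature branches and
  are counted. Missing-phenology lake cells become no-freeze below 40°
  latitude and are a hard error poleward of it. Zero-lake cells are masked
  (not NaN) in per-m²-of-lake maps.

## Uncertainty conventions

The six components are combined in quadrature (they are treated as
uncorrelated). Threshold and lag components are half the absolute spread of
the global total across the two endpoint runs; the oxidation and
large-lake-factor components are the SD of totals over an 11-point evenly
spaced sweep of the stated range (the source range 0.5–0.99 for oxidation is
given once for both seasons, so a common value is swept and applied to
both). The measurement-variability term aggregates per-stratum
(type × pathway) coefficients of variation of the corrected fluxes as
ε_v = √Σ(E_s·CV_s)² — strata are independent, so their contributions add in
quadrature. A joint Monte Carlo (all parameters sampled together, flux
multipliers normal with the stratum CV truncated at zero) cross-checks the
independence approximation; on synthetic worlds the two agree within a few
percent. Scenario propagation is the default because it is deterministic
and fast; the Monte Carlo is the check, not the estimator.

## What the synthetic worlds emulate — and what they do not

The generator produces a pole-to-pole 0.25° strip with: a latitudinal
annual-mean temperature gradient and a seasonal sinusoid whose amplitude
grows poleward; permafrost bands with alternating ground-ice and SOC laid
out so all seven type signatures (including the fallback cells) occur;
thaw/freeze dates advancing ~2.5 d per degree of latitude poleward of 40°,
jittered across 13 years, from two sources (the lake-ice source holds ice
~4 days longer); a lake-area field with a small fraction of large-lake
cells; and 575 sites yielding ~880 aggregated flux records with
compilation-like type composition, lognormal scatter, a 1/0.7 daytime
excess, and planted fractions of indirect, beaver-pond, metadata-missing
and disaggregatable records. Soil annual temperature equals the annual-mean
air temperature, keeping classification and flux modeling consistent. The
default record-level parameters (σ_log = 0.3, b = 0.06 / 0.11 °C⁻¹ for
diffusion/ebullition, base fluxes 8 / 12 mg m⁻² d⁻¹ at 0 °C) are fixed
once, at magnitudes typical of the flux literature.

Passing tests on these worlds demonstrate that the *pipeline machinery* is
correct — filters count what was planted, the classifier recovers the
intended map, fitted slopes recover the generator's b, projection is
anchor-consistent, the engine conserves mass, and the quadrature matches a
joint Monte Carlo. They do not demonstrate that real lake fluxes follow a
single-covariate exponential, that the compilation is spatially
representative (tropical systems are sparse in real compilations), or that
real geography resembles a longitudinal strip: the synthetic temperate band
lies equatorward of the freeze line, so its season is 365 days where real
temperate lakes average ~289. The reference inventory table carries the
real-world magnitudes and is checked by its own closed arithmetic instead.

## Problem sizes

The shipped analysis and acceptance runs use a 2°-wide, pole-to-pole strip
(5,760 cells, ~2,900 with lakes) — large enough that every type, both
phenology sources, both size classes and the fallback branches are
exercised, while a full pipeline run takes a few seconds. Tests use a
1°-wide strip and single-cell worlds for closed-form oracles; the
Monte-Carlo cross-check uses 1,000 draws.

## Known limitations

- One pooled temperature-flux model per pathway; per-type fits would starve
  on the sparse high-latitude strata (several types have ≤ 4 ebullition
  records in real compilations).
- Episodic fluxes apply only to freezing cells: the fall model needs a
  freeze date as its stratification-end proxy, so never-freezing stratified
  tropical lakes get none.
- A cell has one season: where ≥ 50 km² and smaller lakes share a cell, the
  lake-ice source wins for the whole cell.
- Spring accumulation is not additionally capped by the emission window's
  position; the lag is the only brake.
- The grid consumes per-source area fractions; polygon rasterization and
  river/reservoir vector masking happen upstream of this package.
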