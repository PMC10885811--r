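---
title: "Estimating vineyard canopy conductance: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating vineyard canopy conductance: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyflux)
```

## Scope and scientific setting

`canopyflux` targets the drip-irrigated Mediterranean vineyard: rows of
vines about 1.7 m tall under hot, dry summers, where transpiration is
regulated almost entirely by stomata and soil evaporation is negligible
between irrigations. Under those conditions the bulk surface conductance of
the Penman–Monteith equation collapses onto the canopy conductance g_c, and
two independent routes to it become comparable:

* an **estimator** needing only leaf porometry and standard weather
  records, and
* a **reference** that inverts Penman–Monteith using eddy-covariance
  canopy transpiration.

The package implements both routes, the data conditioning between raw field
tables and analysis-ready records, the statistics used to compare the
routes, and a synthetic-data generator that stands in for a field campaign.

## The big-leaf estimator and its unit dialect

The estimator treats the canopy as one big leaf whose conductance is the
leaf-level stomatal conductance scaled by leaf area index, modulated by the
ratio of energy supply to evaporative demand:

$$ g_{c\,est} = \mathrm{LAI}\,\left(\frac{g_{sw}\,R_n}{VPD}\right)^{1/2} $$

with g_sw in m s⁻¹, R_n in MJ m⁻² h⁻¹ and VPD in **Pa**. This mixed-unit
recipe is intentional and is documented as part of the model definition:
evaluated this way, the output lands on the m s⁻¹ scale of observed canopy
conductances (roughly 5×10⁻⁴ to 3×10⁻³ m s⁻¹ over a summer day). A fully
SI-consistent variant (R_n in W m⁻², VPD in Pa) would differ by the constant
factor √(10⁶/3600) ≈ 16.7 and is deliberately **not** provided — offering
both invites silent unit mistakes, and only the recipe above corresponds to
the conductance scale the reference method produces.

One magnitude subtlety deserves a note. The square-root form means the
estimator is very sensitive to pairing predictors that never co-occur: a
morning-peak stomatal conductance (≈0.005 m s⁻¹) combined with a midday
deficit (≈2500 Pa) and midday radiation (2 MJ m⁻² h⁻¹) yields ≈0.0039
m s⁻¹, above the observed daily maximum, even though at every *actual* hour
of the diurnal course the estimator stays inside the observed band (by
10:00, when g_sw peaks, VPD is still low; by midday, when VPD is high, g_sw
has already declined). Magnitude checks should therefore use concurrent
values, as the pipeline does.

## The Penman–Monteith reference

Solving the combination equation for surface conductance gives

$$ g_{c\,obs} = \frac{\gamma\,\lambda\,E_c\,g_a}
 {\Delta R_n + k_t\,\rho\,C_p\,VPD\,g_a - \lambda(\Delta+\gamma)E_c} $$

with the FAO-56 closed forms for the psychrometric constant
γ = C_p P/(ελ), the saturation-curve slope Δ, air density ρ, and atmospheric
pressure from elevation (98.726 kPa at the default 220 m). Here VPD enters
in **kPa**, which dimensional consistency with Δ and γ (kPa °C⁻¹) requires;
the package converts explicitly at the call boundary rather than guessing.
Soil heat flux is omitted: the records this applies to are daytime hourly
means over a dry, shaded inter-row, where G is small against R_n.

Aerodynamic conductance comes from the neutral-stability logarithmic wind
profile with the standard roughness closure d = 2h/3, z_om = 0.123 h,
z_ov = 0.1 z_om. Stability corrections are out of scope; the estimator is
meant for the well-mixed daytime hours that survive filtering anyway. A
sensor below d + z_om is rejected as a configuration error. The zero-plane
displacement is named `d_disp` throughout to avoid any collision with
Cohen's d.

The forward relation (transpiration from a known conductance) is the exact
algebraic inverse of the expression above. It exists for two reasons: the
synthetic generator uses it to manufacture flux data consistent with a
known truth, and the pair is testable as an identity — the suite verifies
`invert(forward(g_c)) = g_c` to 1e-10 relative over a 10,500-point grid
spanning g_c ∈ [1e-4, 1e-2] m s⁻¹, T ∈ [15, 40] °C, RH ∈ [20, 80] %,
R_n ∈ [0.6, 3] MJ m⁻² h⁻¹ and U ∈ [0.5, 5] m s⁻¹.

The inversion's denominator vanishes when E_c reaches the energy/advection
bound for the given meteorology; beyond it the regime is physically
non-invertible and single-value calls raise an error. In batch mode
(`conductance_pipeline()`, `run_pipeline()`) precondition violations —
non-positive VPD, negative flux, the non-invertible regime — become `NA`
records with a reason code (`vpd_nonpositive`, `flux_invalid`,
`non_invertible_regime`, …) instead of exceptions: a field pipeline must
survive a bad hour, but it must also never silently drop one.

## Micrometeorological conventions

* **Hourly saturation pressure.** The period-mean form
  e_s = [e⁰(T_min)+e⁰(T_max)]/2 is supported, but hourly records rarely log
  within-hour extremes, so the default is the degenerate reduction
  T_min = T_max = T_air, i.e. e_s = e⁰(T_air).
* **Negative VPD** (supersaturation artifacts from sensor mismatch) is
  passed through with a warning, never clamped — clamping would hide data
  problems. The estimator then flags such records explicitly.
* **Canonical vapor-pressure unit** is kPa internally; the Pa values the
  estimator needs are produced by an explicit ×1000 conversion.
* **Molar density of air** for the porometry unit conversion uses the ideal
  gas law at ambient T and P (≈39.8 mol m⁻³ at 25 °C and 98.726 kPa), not a
  fixed standard value; passing fixed arguments reproduces a
  standard-condition conversion if desired.
* **Air density** evaluates P in Pa internally because R = 287 J kg⁻¹ K⁻¹
  yields kg m⁻³ only then.

## Data conditioning

The preprocessing mirrors a field campaign protocol:

* **Unit conversion and side aggregation.** Leaf samples tagged
  `mol_m2_s` are divided by the molar density of air at the concurrent air
  temperature and site pressure; east and west canopy sides are averaged
  with equal weight (a sunlit/shaded two-leaf weighting is deliberately out
  of scope — the estimator scales by total LAI). Hours with a single side
  are kept but flagged `one_side_only`.
* **Exclusion rules.** Records outside the 10:00–18:00 clock window
  (inclusive bounds) **or** with R_n < 0.60 MJ m⁻² h⁻¹ are dropped; the two
  criteria are enforced independently so every retained record satisfies
  both, and each dropped record carries its reason(s). Filtering is
  idempotent.
* **Outlier screen.** Tukey fences at 1.5×IQR, with quartiles by the
  linear-interpolation convention (`stats::quantile` type 7, configurable).
  On well-behaved campaigns this flags nothing, so the quartile convention
  is rarely discriminating — it is still pinned down and tested against a
  brute-force order-statistic oracle.
* **Alignment.** Timestamps are floored to the join cadence (hourly by
  default; minute-cadence meteorology is averaged within each bin), then
  the three tables are inner-joined; unmatched timestamps are reported, and
  a disjoint join is an error. Timestamps are local clock time without
  timezone, parsed into a fixed internal zone so results do not depend on
  the host machine.

## Agreement statistics

`evaluate_model()` populates one flat report; conventions that were
genuinely open are pinned as follows.

* **|E| is an aggregate signed-bias percentage**, |Σ(est−obs)|/Σobs × 100,
  exactly as defined — not a mean absolute percentage error. Opposite
  errors cancel in it; the suite asserts a constructed case with |E| = 0
  and MAE = 1 to keep the distinction visible. RMSE ≥ MAE always holds
  (equality iff all absolute errors are equal), and the implementation
  asserts that ordering rather than any printed value that violates it.
* **Intercept test.** Two-sided t statistic b₀/SE(b₀) with n−2 degrees of
  freedom, fit by `stats::lm`. An exact fit has no residual variance, so
  the p-value is reported `NA` with an explicit flag, never 0. The test's
  empirical type-I error is calibrated in the suite: with a true zero
  intercept, the rejection rate at α = 0.05 over 2000 seeded replicates
  must land in 0.05 ± 0.02.
* **Regression through the origin** uses slope = Σ(obs·est)/Σobs². Its
  correlation coefficient has no universal convention; the default reports
  the Pearson correlation between the estimates and the fitted values, and
  `r_method = "uncentered"` gives the square root of the uncentered R² for
  users who prefer that reading.
* **Variance conventions.** All variances, CVs and the pooled SD of
  Cohen's d use N−1 denominators.
* **U1 non-overlap.** Two modes: linear interpolation in Cohen's published
  table (default) and the exact normal expression
  U1 = (2Φ(|d|/2)−1)/Φ(|d|/2). They agree within half a percentage point
  for |d| ≤ 1 but round differently — at d = 0.217 the table gives 15.8 %,
  the closed form 15.9 % — which is why the convention is explicit and the
  table is the default. Beyond the table range the table mode falls back to
  the closed form with a warning.

## The synthetic generator

The generator emulates the *shape* of a Mediterranean summer field day so
the full pipeline is exercisable without data:

| parameter | default | meaning |
|---|---|---|
| window | 09:00–19:00 hourly | sampled clock window |
| `rn_peak` | 2.2 MJ m⁻² h⁻¹ | half-sine R_n peak at 13:00 local |
| `t_dawn`, `t_peak` | 18, 36 °C | T_air sinusoid, peaking 2 h after solar noon |
| `rh_dawn`, `rh_min` | 70, 25 % | RH mirrors T_air linearly |
| `u_mean` | 2 m s⁻¹ | lognormal wind (σ_log = 0.3) |
| `gsw_max`, `k_r`, `d0` | 0.25 mol m⁻² s⁻¹, 0.5 MJ m⁻² h⁻¹, 1.5 kPa | stomatal response |
| `noise_sd_rel` | 0 | multiplicative lognormal noise on E_c |
| `model_mismatch_rel` | 0 | controlled estimator/reference disagreement |

Stomatal conductance follows a multiplicative light × VPD limitation,
g_sw = g_max · R_n/(R_n+k_r) · 1/(1+VPD/D₀), which reproduces the
characteristic vineyard course: a mid-morning peak once light saturates,
then decline as the deficit climbs. The sun window 06:30–19:30 was chosen
so that radiation at the 09:00/19:00 shoulders falls below the 0.60
MJ m⁻² h⁻¹ threshold while every 10:00–18:00 record passes both filters —
the generated data exercise the exclusion rules exactly as a field day
would. The east/west leaf samples carry a fixed ±10 % asymmetry (east
boosted before solar noon, west after) whose mean is exact, mimicking the
sun-exposure contrast of a two-row design without modelling radiation
interception.

Crucially, transpiration is manufactured **from** the truth: the true
conductance is `(1 + model_mismatch_rel)` times the big-leaf estimate, and
E_c comes from the forward Penman–Monteith relation at that truth, with
optional multiplicative lognormal noise (flux errors scale with flux
magnitude; one seeded RNG stream per campaign). With zero noise and zero
mismatch the pipeline is therefore an algebraic round trip — r = 1 and an
origin slope of 1 to 1e-9 — and any deviation under noise is attributable
to the noise alone. This is what passing tests demonstrate: internal
consistency and correct statistics, **not** field validity. Real vineyard
data disagree with the estimator for physical reasons (canopy heterogeneity,
advection, sensor footprints) that no generator of this kind reproduces;
`model_mismatch_rel` exists precisely to exercise the statistics away from
the degenerate perfect fit.

Problem sizes used by the shipped checks — a 5-day campaign (45 retained
records), a 10,500-point round-trip grid, 1000-draw oracle comparisons and
2000 calibration replicates — were chosen as the smallest sizes at which
the properties under test are sharp.

## Degenerate inputs and numerical edges

* Quantities undefined on degenerate input (correlation of a constant
  series, CV at zero mean, |E| at Σobs = 0, Cohen's d at zero pooled
  variance, IQR screening with fewer than 4 values) raise descriptive
  errors rather than returning NaN.
* The round-trip identity is exact algebra; the 1e-10 relative tolerance
  absorbs floating-point cancellation in the denominator.
* Window bounds are inclusive; records at exactly 10:00 or 18:00 are
  retained, and a record failing both exclusion criteria carries both
  reasons.
* CSV round trips preserve numeric fields to at least 12 significant
  digits; timestamps are written second-resolution ISO-8601.

## Known limitations

* Neutral-stability aerodynamic conductance only; no stability correction,
  no two-source (canopy/soil) partitioning, no energy-balance-closure
  handling — transpiration is taken as given.
* The hourly degenerate VPD form ignores within-hour temperature extremes;
  supplying logged extremes restores the period-mean form.
* The generator's wind is uncorrelated hour to hour and its radiation is
  cloud-free; neither matters for the identities tested, but both are
  unrealistic for gap-filling studies.
* LAI is an input parameter, assumed constant over a campaign; measuring it
  is out of scope.
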