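---
title: "Projecting marine heterotrophic bacteria under climate scenarios: model, synthetic world, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting marine heterotrophic bacteria under climate scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bactclim)
```

## 1. The scientific problem

Heterotrophic bacterioplankton consume dissolved (DOC) and particulate
(POC) organic carbon, respire a large fraction of it, and thereby set
how much carbon the biological pump exports versus recycles. Explicit
bacterial schemes exist in only a handful of global biogeochemical
models, and century-scale projections made with them are archived model
output: the loss terms (grazing, mortality) are typically not saved and
the simulations cannot be re-run cheaply. This package rebuilds the
*analysis* around such projections as a self-contained, testable
pipeline: a mechanistic per-cell box model of the bacterial carbon
scheme, a seeded generator of gridded scenario forcing, composite and
change statistics, a Taylor attribution of uptake changes, and skill
scoring against (synthetic) observations.

## 2. The box model and its assumptions

Bulk biomass $B$ (mmol C m$^{-3}$) obeys
$\partial B/\partial t = BP - G - M$ with $BP = BCD - R$. The biomass is
split linearly between free-living ($B_{DOC} = \varphi_{DOC} B$) and
particle-attached ($B_{POC}$) fractions, with
$\varphi_{DOC} = DOC/(DOC+POC)$ — a deliberately simple partition that
lets the two feeding modes respond differently to climate trends.

* **Free-living uptake** is Monod-type in DOC with a cubic sigmoid
  ($DOC^3/(DOC^3+X_{DOC}^3)$: fast response under favourable conditions,
  steep shutdown under limitation) scaled by a Q10 temperature factor
  $Q10_B^{(T-10)/10}$.
* **Attached uptake** uses Contois kinetics — the half-saturation scales
  with colony biomass $X_{POC} B_{POC}$ — and a Martin-curve-like depth
  attenuation $\min(1, (z/z_0)^b)$ instead of a temperature factor.
* **Respiration** is basal ($b_B f_T B$) plus activity
  ($\gamma_a \cdot BCD$) plus an oxygen-dependent extra cost.
* **Grazing** is a Holling type-2 microzooplankton response with
  prey-capture efficiencies $e = X/(X+\mu_Z)$; **mortality** is linear
  in biomass with Q10 scaling.

Two readings of the oxygen term are implemented because the printed
formula ($+\gamma_o f_O \cdot BCD$, with $f_O$ *increasing* in oxygen)
contradicts the stated biology (extra respiration under *low* oxygen).
The default `oxygen_mode = "low_oxygen_extra"` uses $\gamma_o (1-f_O)$;
`"as_printed"` reproduces the formula literally. Neither is asserted to
be the source's intent; at the oxic default forcing (DO = 250 mmol
O$_2$ m$^{-3}$) the two differ by $\sim 10^{-4}$ relative.

**One-way forcing.** Bacteria do not deplete DOC/POC here: the package
emulates the *diagnosis* of archived Earth-system-model output, not a
coupled ecosystem. This is the single most consequential assumption (see
§4 on parameters and §7 on limitations).

## 3. Quasi-steady simulation

Bacterial turnover (days) is fast against the yearly forcing, so the
pipeline solves each year to quasi-steady state ($BP \approx G + M$).
The user-facing integrator `bact_integrate()` is plain forward Euler
(default $dt = 0.1$ d, non-negativity clip with counting, steady
tolerance $|dB/dt| < 10^{-6}\max(B, 10^{-8})$, at most $10^5$ steps;
non-convergence is flagged, not thrown). The pipeline's field solver
(`steady_state_cells()`) solves the same scalar root problem per cell
with a damped Newton iteration (numeric derivative, step capped at
halving/doubling per iteration, multiplicative escape from the unstable
low-biomass state, oscillation-triggered damping); agreement with the
Euler integrator is enforced by tests at $10^{-3}$ relative. At steady
state the oxic growth efficiency satisfies
$BGE = 1 - \gamma_a - \gamma_o(1-f_O) - b_B f_T B / BCD$, which is the
mechanism behind the persistent $BGE \approx 0.44$: the activity
fraction $\gamma_a = 0.5$ dominates, basal respiration shaves off a few
percent more.

## 4. Parameters

All rate constants are exposed via `bact_params()` and validated
(non-negativity, $\gamma_a + \gamma_o < 1$, $b \le 0$). The published
source for this scheme defers exact values to an unavailable supplement,
so the defaults are surrogates at BFM-literature magnitudes — with one
deliberate exception:

| parameter | default | unit | note |
|---|---|---|---|
| `mu_max` | 0.15 | d$^{-1}$ | realized community-scale uptake (see below) |
| `Q10_B`, `Q10_Z` | 2.95, 2.0 | — | bacteria / microzooplankton |
| `X_DOC` | 5 | mmol C m$^{-3}$ | cubic Monod half-saturation |
| `X_POC` | 1.0 | — | Contois scale on $B_{POC}$ |
| `z0`, `b_exp` | 100, −0.858 | m, — | Martin-like depth attenuation |
| `b_B`, `gamma_a`, `gamma_o` | 0.01, 0.5, 0.2 | d$^{-1}$, —, — | $\gamma_a$ is the one published value |
| `h_o` | 10 | mmol O$_2$ m$^{-3}$ | oxygen half-saturation |
| `d_B` | 0.05 | d$^{-1}$ | mortality |
| `r_Z0`, `delta_ZB/ZP`, `mu_Z`, `h_ZF` | 2.0, 1, 0.1, 2.0 | d$^{-1}$, —, mmol C m$^{-3}$ | grazing |
| `T_ref` | 10 | °C | Q10 reference |

**Why `mu_max` = 0.15 d$^{-1}$ and not a physiological maximum of
several per day.** In a coupled model a large $\mu_{max}$ is tamed by
substrate depletion: bacteria draw labile DOC down until realized uptake
matches supply. With one-way forcing that feedback is absent, and a
physiological $\mu_{max} \sim 8$ d$^{-1}$ against open-ocean DOC stocks
(where the cubic Monod factor saturates near 1) yields net specific
growth of order 3 d$^{-1}$ against linear losses of order 0.06 d$^{-1}$:
no steady state exists and the column diverges. The defensible stand-in
is the *realized* community-scale rate implied by the published
composites themselves — carbon demand over biomass is $13/47 \approx
0.28$ d$^{-1}$ at a global-mean temperature factor of $\sim$1.4, giving
$\mu_{max} \approx 0.15$ d$^{-1}$ at reference temperature. With this
value steady states exist under composite-table forcing, steady-state
BGE sits in $[0.40, 0.48]$ across 0–27 °C, and the Taylor attribution
terms computed from the composite-table fields land at the magnitudes of
the published decomposition table. The parameter is config-exposed;
users exploring the divergent regime can set any value.

## 5. The synthetic world

`scenario_spec()` + `generate_fields()` state the world the analysis
runs in. Nothing in it is tuned to test outcomes; the numbers below are
the defaults and their provenance.

* **Regional means**: baseline and per-SSP end-century targets for
  temperature, DOC and POC are the packaged composite-table values for
  the five latitudinal bands (NH, NI, LL, SI, SO). Dissolved oxygen is a
  uniform oxic 250 mmol O$_2$ m$^{-3}$. Microzooplankton and
  phytoplankton are trend-free with low-latitude minima (Z: 0.7, 0.5,
  0.25, 0.5, 0.8; P: 1.5, 1.0, 0.4, 1.0, 1.8 mmol C m$^{-3}$) —
  magnitudes a field ecologist would call ordinary for open-ocean
  surface waters.
* **Vertical shapes**: uniform for T and DO; surface-intensified
  exponential (scale 150 m) for DOC, POC, Z, P, so depth integration is
  exercised non-trivially. Stocks stated per m$^2$ over the upper layer
  are converted to surface concentrations by dividing by the
  shape-weighted thickness *computed with the package's own trapezoidal
  reduction*, which makes prescribed-moment recovery exact by
  construction.
* **Trend ramp**: zero before 2015, then linear. The ramp is normalised
  so its 2076–2099 window mean is exactly 1 (it reaches $\approx 1.16$
  by 2099). A 0-to-1-by-2099 ramp cannot satisfy the stated requirement
  that the 2076–2099 composite equal the end-century target (its window
  mean is 0.86); normalising the window mean reconciles the two and is
  the reading adopted.
* **Spatial anomaly**: a seeded smooth harmonic pattern, amplitude 5% of
  the regional baseline, demeaned with area weights inside each region —
  fields vary in space but regional composites are unaffected.
* **Interannual noise**: AR(1) per cell with lag-1 autocorrelation 0.5
  and stationary standard deviation 3% of the regional baseline —
  plausible interannual variability that does not drown the trends.
  Stocks are clipped at zero with a reported count.
* **Observations**: station generators emulate subtropical time-series
  records (monthly, seeded seasonal harmonic with zero annual mean,
  lognormal error, seeded gaps), converted to cells L$^{-1}$ or pmol
  thymidine L$^{-1}$ h$^{-1}$; the gridded generator emulates a sparse
  monthly climatology with Bernoulli cell-month coverage.

**What the generator does *not* emulate** — and hence what a green test
does not establish: real bathymetry and land masks (the all-ocean mask
means regional *area fractions* differ from the real ocean, so "global"
composites weight bands differently than the published ones); modes of
covariability such as ENSO; model drift or ensemble spread; and
observation error structure beyond lognormal-plus-gaps. Simulated
biomass *magnitudes* are an emergent property of the one-way-forced
equilibrium and are much smaller than archived-model composites; tests
assert mechanisms (convergence, BGE band, attribution signs and shares),
not stock magnitudes.

## 6. Analysis-chain decisions

* **Depth reduction**: trapezoid on level centres, linear interpolation
  to the layer boundaries, constant extension beyond the sampled range;
  integrals over 0–107 m, temperature averaged over 10–107 m. Exact for
  linear profiles (tested to $10^{-12}$).
* **Bands**: NH $\ge 50°$N, NI $[30, 50)°$N, LL $[-30, 30)°$, SI
  $[-50, -30)°$, SO $< -50°$ — the half-open interval contract, applied
  verbatim; grid centres never sit on boundaries.
* **Composite SE**: the published table's $n$ equals grid-cell counts,
  so the standard error is spatial — unweighted cell standard deviation
  over $\sqrt{n}$ — while the mean is area-weighted. Whether the
  original SE was spatial, temporal or both is not stated; the spatial
  reading is adopted and flagged here.
* **Change metrics**: difference of window means (2076–2099 minus
  1990–2013), ratio-based percent change, and an OLS trend per decade.
* **Taylor attribution**: evaluated on *period-mean* T and DOC fields
  (the estimator the source prescribes), cell-wise by default, then
  weighted by the baseline free-living biomass field, depth-integrated
  and annualised ($\times 365$) so results carry the published table's
  units (mmol C m$^{-2}$ y$^{-1}$); the biomass factor itself is not
  decomposed. The residual is computed in its analytic cross-term form
  $\mu_{max}\,\Delta f_T\,\Delta f_{DOC}$, which is exactly zero for
  single-factor changes and equals total − DOC-term − T-term to
  floating-point association. A `composite_first` order (decompose the
  regional scalars) is exposed for sensitivity checks since the original
  order of operations is unstated.
* **Reliability index**: $RI = \exp\sqrt{\overline{\ln^2(O/P)}}$ — the
  source prints no formula; this form yields the stated "68% within
  $[1/RI, RI]$" interpretation under lognormal errors and is symmetric
  in $O$ and $P$.
* **Thymidine sensitivity**: the adjusted overestimation factor scales
  *proportionally* with the alternative conversion factor, reproducing
  the printed arithmetic ($3.6 \times 4.9/3.0 \approx 5.9$,
  $3.6 \times 0.5/3.0 = 0.6$). A strict rescaling argument (obs $=
  TdR \cdot TCF \cdot CCF$, larger TCF $\Rightarrow$ larger obs
  $\Rightarrow$ *smaller* model/obs ratio) would invert the ratio; the
  printed arithmetic is reproduced and the discrepancy documented here
  rather than resolved.
* **Degenerate inputs**: $DOC + POC = 0$ gives $\varphi_{DOC} = 0$ with
  a warning; $z = 0$ gives depth factor 1; $BCD = 0$ flags BGE as
  undefined; non-positive data flag RI as undefined; constant series
  flag $r$ as undefined.
* **Gridded I/O**: the environment provides no NetCDF R library, so
  fields serialise to a CF-flavoured *text* format — a JSON header
  (coordinates, units, scenario, mask) plus long CSV at full double
  precision — with a lossless round-trip contract and the same
  error/warning semantics (missing coordinate → error; missing units →
  warning + "unknown").

## 7. Known limitations

* One-way forcing changes the equilibrium structure fundamentally
  (§4); absolute stocks and rates from `run_pipeline()` characterise
  the synthetic world, not the archived projections. The
  fixture-derived analyses (`fixture_decomposition()`, `fixture_bge()`,
  `tcf_sensitivity()`) are the quantitative bridge to the published
  numbers.
* No nutrient (N/P/Fe) quotas, no anaerobic NO$_3$ chemistry, no viral
  lysis as a distinct process, no bacterial diversity or adaptation, no
  mesopelagic (>107 m analysis layer) focus.
* Monthly dynamics exist only in the observation generators and skill
  matching; the simulation itself is yearly quasi-steady.
* The grazing closure treats microzooplankton as prescribed forcing;
  top-down pressure does not respond to the bacteria it consumes.
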