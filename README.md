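# bactclim

Climate-change projections of marine heterotrophic bacteria as a tested,
reusable R pipeline.

Marine heterotrophic bacteria respire and remineralise a large share of
the organic carbon produced in the surface ocean, yet most Earth system
models do not resolve them explicitly, and the few archived projections
that do cannot be re-run at desk scale. `bactclim` is aimed at microbial
oceanographers and biogeochemical modellers who want to study *how* such
projections behave: it re-implements the bacterial carbon scheme of a
BFM-family ocean biogeochemistry model as a per-cell box model, drives it
with a seeded synthetic emulator of historical + SSP-scenario forcing
fields, and reproduces the downstream analysis chain — regional
composites, change metrics, first-order Taylor attribution of DOC-uptake
changes into temperature versus substrate control, and model–observation
skill scoring with microbial unit conversions.

## The model

Bulk bacterial carbon biomass `B` (mmol C m⁻³) evolves as

    dB/dt = BP − G − M,      BP = BCD − R

with biomass partitioned between free-living and particle-attached
fractions by the dissolved share of substrate, φ_DOC = DOC/(DOC+POC):

    BCD_DOC = μmax · Q10_B^((T−10)/10) · DOC³/(DOC³+X_DOC³) · B_DOC
    BCD_POC = μmax · min(1, (z/z0)^b) · POC³/(POC³+(X_POC·B_POC)³) · B_POC
    R       = b_B·f_T·B + [γ_a + γ_o·(1−f_O)]·BCD,   f_O = DO³/(DO³+h_o³)
    G       = r_Z0·f_T,Z · δ_ZB·e_ZB·B/(F_c+h_ZF) · Z   (Holling type 2)
    M       = d_B·f_T·B

i.e. cubic-sigmoid Monod limitation for free-living cells, Contois
limitation with Martin-curve-like depth attenuation for attached
colonies, and Q10 temperature scaling throughout. Growth efficiency
BGE = BP/BCD emerges near 0.44 at steady state because the activity
respiration fraction γ_a = 0.5 dominates carbon losses.

Changes in the free-living specific uptake rate μ_DOC = μmax·f_T·f_DOC
between a baseline and an end-of-century period are attributed by
first-order Taylor decomposition:

    Δμ_DOC = μmax·Δf_DOC·f_T⁰  +  μmax·Δf_T·f_DOC⁰  +  μmax·Δf_T·Δf_DOC
             (DOC control)        (temperature control)   (residual)

Skill scores are the standard univariate suite (bias, AAE, RMSD with its
exact decomposition RMSD² = bias² + cRMSD², Pearson r, reliability
index), with abundance converted via fg C cell⁻¹ factors and ³H-thymidine
incorporation via cells mol⁻¹ factors.

## Worked example

```r
library(bactclim)

p <- bact_params()                        # defaults, gamma_a = 0.5
f <- env_forcing(T_c = 15, DOC = 22, POC = 5, DO = 250,
                 Z = 0.5, P = 1, z = 10)  # open-ocean mid-latitude cell
out <- bact_integrate(0.5, f, p, mode = "to_steady")
out$rates$BGE
#> [1] 0.4269822
```

The steady-state growth efficiency lands at 0.43: of every mmol of
carbon taken up, half is respired by activity (γ_a = 0.5) and a further
~7% covers basal respiration, leaving ~43% as new biomass.

```r
dec <- fixture_decomposition()            # packaged decomposition table
max(dec$residual_pct)
#> [1] 11.03896
dec$temp_share_pct[dec$region == "SO" & dec$scenario == "ssp585"]
#> [1] 18.18182
```

Across all regions and scenarios the Taylor cross-term never exceeds
~11% of the total change (first-order attribution is trustworthy), and
even in the strongly DOC-controlled Southern Ocean, temperature still
carries ~18% of the SSP5-8.5 uptake increase.

```r
skill_scores(c(1, 2, 3), c(1.5, 2, 2.5))
#> skill (n=3): bias 0 | AAE 0.3333 | RMSD 0.4082 | cRMSD 0.4082 | r 1.000 (p 0) | RI 1.293
```

A reliability index of 1.29 means ~68% of predictions fall within a
factor 1.29 of the observations.

The full pipeline (generation → quasi-steady simulation → composites →
attribution → skill) runs end to end with

```r
res <- run_pipeline(pipeline_config(scenarios = c("historical", "ssp585"),
                                    seed = 1, out_dir = "out"))
```

(~2 minutes for the default 18×36×10 grid over 1990–2099), or from the
shell via `Rscript inst/scripts/bactclim run --seed 1 --out out`.

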