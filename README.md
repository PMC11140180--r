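# decidemri

Quantitative MRI of maternal-placental-fetal haemodynamics in the
pregnant sheep.

Placental insufficiency and candidate therapies for fetal growth
restriction (e.g. phosphodiesterase-5 inhibitors such as tadalafil) act on
the maternal-placental-fetal circulation, and MRI can interrogate every
level of it in one session: cardiac output and vessel blood flow by
phase-contrast cine imaging, vessel oxygen saturation by T2-prepared
oximetry, and the internal composition of the placenta by a
multi-compartment diffusion-relaxation model. `decidemri` implements that
full analysis chain for the sheep model of human pregnancy, together with
a synthetic-data generator with known ground truth so that every stage is
testable end to end without scanner data. It is aimed at researchers in
quantitative placental/fetal MRI and at anyone reproducing or extending
repeated-measures physiology studies of this design (basal state followed
by post-treatment windows, here labelled TAD1/TAD2).

## The models

**Placentome signal model.** Each placentome is three water compartments:

    S(b, TE) = S0 [ f exp(-b d*) exp(-TE/T2fb)
                  + v exp(-TE/T2mb)
                  + (1 - f - v) exp(-b d) exp(-TE/T2ts) ]

with feto-placental blood volume fraction `f` (pseudo-diffusivity `d*`,
blood relaxation `T2fb`), maternal blood volume fraction `v` (fixed
`T2mb = 150 ms`), and a tissue fraction (diffusivity `d`, fixed
`T2ts = 42 ms`). The six parameters `(S0, f, v, d, d*, T2fb)` are fitted
per ROI and per voxel by box-constrained Levenberg-Marquardt
(`0 < f, v, d, d* < 1`, `0 < T2fb < 150 ms`).

**Oximetry.** Blood T2 from a T2-prepared series
(`S(τ) = S0 exp(-τ/T2)`, preparation times 32-192 ms) converts to oxygen
saturation through the quadratic calibration `R2 = A + B (1 - Y)²`; the
fitted placentome `T2fb` converts to a feto-placental SO2 the same way.

**Flow and oxygen transport.** Phase maps to velocity as
`v = VENC·φ/π`; ROI flow integrates velocity × pixel area per cardiac
phase. Oxygen delivery and consumption follow
`DO2 = 1.36 × Hb × Y × Q̇` (fetal: umbilical vein; uterine: uterine
arteries) and `V̇O2 = 1.36 × Hb × (Y_UV − Y_DAo) × Q̇_UV`, with the
extraction fraction `V̇O2/DO2`.

**Statistics.** Repeated-measures one-way ANOVA across the three states
with Bonferroni-corrected pairwise paired t-tests and compact letter
displays, as in a standard physiology results table.

## Worked example

Fit the placentome model to a simulated ROI at SNR 50 and convert the
fitted blood T2 to saturation:

```r
library(decidemri)

truth <- decide_params(f = 0.25, v = 0.30, d = 1.5e-3, d_star = 0.03,
                       T2fb = 90, S0 = 100)
sim <- simulate_placentome(list(truth), array(1L, c(6, 6, 1)),
                           noise = noise_spec("rician", snr = 50, seed = 42))
fit <- fit_decide_roi(sim$series)
round(unlist(fit$params), 5)
#>       S0        f        v        d   d_star     T2fb
#> 99.85303  0.24088  0.29946  0.00153  0.03099 93.78990

cal <- oximetry_calibration(preset = "sheep_3T")
as.numeric(so2_from_t2(fit$params$T2fb, cal))
#> [1] 0.667
```

The ROI fit recovers the generating parameters to a few percent at this
SNR (`f = 0.241` vs 0.25, `v = 0.299` vs 0.30), and the fitted
`T2fb = 93.8 ms` maps to a feto-placental SO2 of 0.67.

Run a whole synthetic cohort (7 ewes × 3 states, default injected
effects: `v` +0.08 at TAD2, UtA share of cardiac output −4 points at both
TAD windows, fetal oxygen endpoints null) through
simulate → fit → transport → analyse:

```r
res <- run_cohort_pipeline(pipeline_config(seed = 1))
res$summary[res$summary$variable %in%
              c("v", "Q_UtA_pct_LVCO", "fetal_DO2"),
            c("variable", "F", "p",
              "letters_basal", "letters_TAD1", "letters_TAD2")]
#>          variable      F        p letters_basal letters_TAD1 letters_TAD2
#> 2               v 52.287 1.19e-06             a            a            b
#> 9  Q_UtA_pct_LVCO 31.843 1.59e-05             a            b            b
#> 12      fetal_DO2  0.493 6.23e-01             a            a            a
```

Reading the letters: the maternal blood volume fraction `v` is distinct
at TAD2 only (letter *b*), the uterine share of cardiac output drops at
both TAD windows, and fetal oxygen delivery shows no effect — the
injected ground-truth pattern, recovered through the full measurement
chain. A thin command-line front end over the same functions is installed
at `inst/cli/decidemri.R` (`run-all`, `simulate`, `fit-decide`).

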