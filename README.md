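# picdf

Paired motor-unit estimates of persistent-inward-current (PIC) activity from
high-density surface EMG discharge data.

## What this package is for

During slow triangular isometric ramps, motoneuron discharge carries a
readable trace of intrinsic excitability. Dendritic persistent inward
currents amplify and prolong firing, so a unit that is recruited at one
torque is derecruited at a lower one. `picdf` turns decomposed motor-unit
spike trains (for example DEMUSE/convolutive-kernel decompositions of
tibialis anterior HD-EMG in ageing cohorts) into the two standard indices of
that amplification, and into cohort-level statistics:

* **ΔF** — for each higher-threshold *test* unit, the smoothed discharge
  rate of a lower-threshold *control* unit at test-unit recruitment minus at
  test-unit derecruitment (pps), averaged over all eligible controls. The
  smoothed rate is an RBF-kernel support-vector regression of the
  instantaneous rates; eligibility uses conventional recruitment-separation,
  rate-modulation and rate–rate-correlation criteria.
* **Brace height** — the maximal orthogonal deviation of the ascending
  rate-versus-torque trajectory from the straight line joining recruitment
  to peak discharge, as a percentage of the right-triangle hypotenuse
  between those points (%rTri), with deterministic exclusion rules.
* **Robust cohort models** — per recruitment-threshold bin
  (0–20 / 20–40 / 40–60 %MVT), Huber M-estimated linear mixed-effects models
  `outcome ~ group × intensity + sex + (1 | participant)`, estimated marginal
  means, and cluster (participant-level) BCa bootstrap contrasts; plus
  ΔF-versus-function association models with marginal/conditional R², and
  the SDOC sarcopenia classifier (handgrip < 20 kg F / < 35.5 kg M and gait
  speed < 0.8 m·s⁻¹).

Because raw cohort data are rarely redistributable, the package ships a
motoneuron-pool simulator with injected, analytically known hysteresis:
`simulate_cohort()` generates spike trains whose true ΔF is available in
closed form (`analytic_deltaf()`), so the whole estimation chain is testable
against ground truth.

## Worked example

```r
library(picdf)
library(dplyr)

# synthetic cohort: 3 sarcopenic, 3 control, 3 athlete participants,
# ramps at 20/40/60 %MVT
ds <- simulate_cohort(group_sizes = c(sarcopenic = 3, control = 3, athlete = 3),
                      seed = 42)
ds <- filter_pnr(ds, 30)

deltaf <- compute_deltaf(ds)
deltaf |> count(group, intensity)
#> # A tibble: 9 × 3
#>   group      intensity     n
#>   <chr>          <dbl> <int>
#> 1 athlete          0.2    38
#> 2 athlete          0.4    35
#> 3 athlete          0.6    44
#> 4 control          0.2    43
#> 5 control          0.4    42
#> 6 control          0.6    41
#> 7 sarcopenic       0.2    30
#> 8 sarcopenic       0.4    34
#> 9 sarcopenic       0.6    35

deltaf |>
  filter(bin == "rt0-20") |>
  group_by(group, intensity) |>
  summarise(mean_df = mean(delta_f_pps), .groups = "drop") |>
  tidyr::pivot_wider(names_from = intensity, values_from = mean_df)
#> # A tibble: 3 × 4
#>   group      `0.2` `0.4` `0.6`
#>   <chr>      <dbl> <dbl> <dbl>
#> 1 athlete    1.37   2.08  2.58
#> 2 control    1.26   1.70  2.30
#> 3 sarcopenic 0.923  1.01  1.01
```

The pattern is the one the simulator injects: the sarcopenic profile's ΔF is
flat across intensities (~1 pps) while control and athlete profiles
upregulate it with contraction intensity, athletes most steeply. On such a
table the robust model and bootstrap then quantify the contrasts:

```r
fit <- fit_bin_model(filter(deltaf, bin == "rt0-20"))
tidy(fit, "emmeans")           # marginal means per group x intensity
bc <- bootstrap_contrasts(filter(deltaf, bin == "rt0-20"), B = 500, seed = 1)
filter(bc, type == "group", at == "i60")
```

`run_pipeline(pipeline_config(...), out_dir)` chains all stages
(simulate/read → validate → PNR filter → metrics → ΔF → brace → stats) and
writes `units.csv`, `deltaf.csv`, `pairs.csv`, `brace.csv`, per-bin model
tables, and a `manifest.json` that accounts for every unit (decomposed =
analyzed + excluded, per reason) together with the config, seed and input
digests.

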