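# birelax

Bi-component T1rho and T2 relaxation analysis for quantitative muscle MRI.

Muscle water lives in more than one micro-environment, so the T1rho/T2
signal decay of calf muscle is often a *sum of two exponentials* — a short
component (bound/intracellular pools, a few ms) and a long one
(interstitial water, tens of ms) — rather than one. `birelax` is an R
package for researchers analysing such relaxometry series (or planning the
acquisition): it fits, voxel by voxel,

```
mono:  S(t) = S0 exp(-t/T)
bi:    S(t) = A_s exp(-t/T_s) + A_l exp(-t/T_l),   T_s <= T_l
```

with component fractions `F_s = 100 A_s/(A_s+A_l)`, `F_l = 100 - F_s`,
where `t` is the spin-lock time (T1rho) or echo time (T2) in ms. On top of
the fits it provides:

* **model selection** — nested-model F-test (mono vs bi, alpha = 0.05) with
  degeneracy guards, plus the component-separation validity rule
  `4 T_s < T_l` (voxels failing it are excluded from bi maps);
* **parameter maps** — `T_mono`, `T_short`, `T_long`, `F_short`, `F_long`,
  exclusion and detection masks as 3D volumes, NIfTI in/out with a JSON
  provenance sidecar;
* **Monte Carlo error analysis** — mean relative estimation error
  `E = |(est - true)/true|` versus SNR, number of time points, relaxation
  times and fractions (`run_mc()`, `mc_sweep()`), alongside the
  Cramér–Rao floor (`crlb_errors()`) that tells you whether the error is
  information-limited;
* **a synthetic calf phantom** — five muscle ROIs (GM, GL, SOL, PER, TA)
  with mono/bi voxel mixtures drawn from published per-muscle values, the
  10-point 2–55 ms protocol schedule and in-vivo SNR, fully seeded
  (`generate_phantom()`);
* **test–retest repeatability** — scan–rescan CV, pooled RMSCV and one-way
  random-effects ICC on tidy `(subject, session, roi, metric, value)`
  tables (`repeatability_metrics()`).

Everything user-facing takes and returns tibbles, chains with the pipe, and
has `tidy()`/`glance()`/`autoplot()` methods.

## Worked example

```r
library(birelax)
library(dplyr)

spec <- default_phantom_spec("T1rho", grid_shape = c(24, 24, 2))
ph   <- generate_phantom(spec, seed = 7)
ph
#> <phantom> grid 24x24x2, 800 tissue voxels (28.4% biexponential), seed 7

maps <- fit_volume(ph$series, spec$schedule, phantom_tissue_mask(ph))
glance(maps)
#> # A tibble: 1 x 9
#>   modality n_fitted n_failed pct_bi_detected pct_excluded T_mono_mean ...
#> 1 T1rho         800        0            21.8         40.1        28.5
```

All 800 muscle voxels fitted; a biexponential decay is detected (F-test and
separation rule) in 21.8% of them — the generator planted 28.4%, and at SNR
65 the test does not recover every weak short component. ROI summaries:

```r
roi_means(maps, ph$label_map) |>
  tidyr::pivot_wider(names_from = metric, values_from = value)
#>   roi   n_voxels T_mono T_short T_long F_short F_long ratio
#> 1 GL         160   29.3    6.42   50.5    32.2   67.8  14.4
#> 2 GM         160   28.9    6.35   43.2    32.2   67.8  20.6
#> 3 PER        160   28.5    6.07   42.7    35.3   64.7  24.4
#> 4 SOL        160   29.9    7.23   45.6    30.5   69.5  28.1
#> 5 TA         160   25.7    6.50   43.2    35.1   64.9  21.2
```

`T_mono` tracks the generating per-muscle means (e.g. GM 28 ms) closely;
the short/long columns average only detected voxels and show the expected
noise-and-selection bias of bi-component estimates at this SNR (ratio =
percent of voxels with a valid bi fit). How much error should one expect?
Ask the simulator, and compare with the information floor:

```r
truth <- decay_params(a_s = 0.25, T_s = 6.3, a_l = 0.75, T_l = 37)
run_mc(truth, protocol_schedule("T1rho"), noise_spec(snr = 65),
       n_trials = 200, seed = 7)
#>   parameter mean_error_pct mc_se_pct n_used n_failed n_trials
#> 1 T_s                26.2      1.69     200        0      200
#> 2 T_l                11.8      1.18     200        0      200
#> 3 F_s                28.1      2.06     200        0      200
#> 4 F_l                 9.37     0.686    200        0      200

crlb_errors(truth, protocol_schedule("T1rho"), snr = 65)
#>   parameter crlb_sd floor_error_pct
#> 1 T_s        2.01             25.5
#> 2 T_l        3.87              8.35
#> 3 F_s        0.0779           24.9
#> 4 F_l        0.0779            8.29
```

At this ground truth and SNR the measured ~26% error on `T_s` sits on the
Cramér–Rao floor: the fit is information-limited, and only more signal
(higher SNR, larger short fraction) — not a better optimiser — can reduce
it. `mc_sweep(list(snr = c(30, 65, 100)))` and
`autoplot()` show the trends.

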