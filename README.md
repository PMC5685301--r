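# zfcipn

Quantification of neuromuscular junction (NMJ) integrity and
stimulus-avoidance behaviour in larval zebrafish — the two readouts used
in zebrafish models of chemotherapy-induced peripheral neuropathy
(CIPN), where microtubule-targeting drugs such as vincristine impair
peripheral motor axons.

The package is for researchers running (or re-analysing) this assay
family who want the ImageJ/Excel workflow as reproducible, tested code:

* **Imaging arm** — two-channel confocal stacks (presynaptic SYT2 in
  red, postsynaptic AChR/α-bungarotoxin in green) are reduced to
  maximum-intensity Z projections, thresholded per channel with the
  Kapur maximum-entropy criterion, masked, optionally ROI-cropped (e.g.
  myoseptum excluded), and summarized as Manders and Pearson
  colocalization coefficients plus 8-connected particle metrics:

  $$M_1 = \frac{\sum_i R_i \,[G_i > 0]}{\sum_i R_i}, \qquad
    M_2 = \frac{\sum_i G_i \,[R_i > 0]}{\sum_i G_i},$$

  with the Kapur threshold $t^\* = \arg\max_t\,
  [H_{\mathrm{bg}}(t) + H_{\mathrm{fg}}(t)]$ over the 256-bin intensity
  histogram.

* **Behaviour arm** — larval position tracks from the moving-bar plate
  assay yield the avoidance statistic *percent down* (time-averaged
  percentage of larvae in the trough half away from the bar; ≈50 under
  no response, >50 under avoidance) and per-larva mean swim speed.

* **Statistics** — modified Thompson tau outlier rejection
  ($\tau = t_{\alpha/2,\,n-2}\,(n-1)/(\sqrt{n}\sqrt{n-2+t^2})$, applied
  iteratively per group) and pooled-variance Student two-sample t-tests,
  one- or two-tailed.

* **Simulators** — ground-truthed generators for both data types
  (punctate two-channel stacks with a controllable true colocalization
  fraction; reflected-random-walk trajectories with a controllable
  avoidance probability and speed), used to validate every estimator by
  parameter recovery.

## Worked example

```r
library(zfcipn)

## imaging: simulate one larva at true colocalization 0.5 and quantify it
sim <- generate_nmj_stack(synthetic_nmj_params(coloc_fraction = 0.5),
                          seed = 42)
quantify_nmj(sim$stack, larva_id = "larva_01")
#> <nmj_metrics>
#>  larva_id pct_red pct_green n_red_particles n_green_particles
#>  larva_01    5.33      13.7              39                12
#>  mean_green_particle_area_um2    M1    M2 pearson
#>                          7.49 0.516 0.221   0.311
#> thresholds: red > 57, green > 86
```

5.33% of pixels are red-positive after maximum-entropy thresholding,
the 12 green AChR clusters average 7.49 µm², and M1 = 0.516 — the
estimated fraction of SYT2 signal on AChR-positive pixels — recovers the
simulated ground truth of 0.5.

```r
## behaviour: 50 larvae, 900 s baseline then 600 s moving-bar stimulus
beh <- generate_behavior(synthetic_behavior_params(p_avoid = 0.1),
                         seed = 42)
percent_down(beh$tracks)               # 77.7  (avoidance: well above 50)
percent_down(beh$tracks, "baseline")   # 49.7  (pre-stimulus: balanced)
mean(swim_speed(beh$tracks)$mean_speed_mm_s)   # 1.45 mm/s

## group statistics
thompson_tau_outliers(c(0.61, 0.59, 0.63, 0.60, 0.22))
#> <outlier_report> alpha = 0.05: 4 kept, 1 removed (0.22)
t_test_groups(c(0.61, 0.59, 0.63, 0.60), c(0.45, 0.48, 0.43, 0.50))
#> <nmj_ttest> Student two-sample t-test, pooled variance
#>   t = 8.034, df = 6, two-tailed p = 0.0001987
```

`run_all()` chains both arms for configured treatment groups and writes
per-larva CSVs plus a JSON manifest; a command-line wrapper with
subcommands (`simulate-nmj`, `quantify-nmj`, `quantify-behavior`,
`compare`, `run-all`, ...) lives in `inst/cli/zfcipn.R`. See the
vignette `vignettes/nmj-quantification.Rmd` for the full methods
account.

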