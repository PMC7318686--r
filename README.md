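# methyldyn

Fast (ps–ns) side-chain dynamics of membrane proteins from methyl NMR
relaxation.

Methyl groups are the best dynamic probes of hydrophobic protein cores
and membrane-facing surfaces: their intra-methyl ¹H–¹H dipolar
cross-correlated relaxation rate η can be measured precisely in large,
slowly tumbling systems and converts directly into the squared order
parameter of the methyl symmetry axis, O²_axis. `methyldyn` implements
the full analysis chain:

1. **Tumbling time** — ¹⁵N R₁/R₂ backbone relaxation through the
   Lipari–Szabo model-free spectral density; per-residue root search on
   R₂/R₁ with an iterated R₁·R₂ exchange screen and a low-ratio trim
   (`predict_n15_rates`, `estimate_tau_m`, `r1r2_exchange_screen`).
2. **Methyl order parameters** — Levenberg–Marquardt fits of η build-up
   ratios, ratio(T) = ¾·η·tanh(sT)/(s − δ·tanh(sT)), with Monte-Carlo
   errors, and the exact η → O²_axis conversion
   (`fit_eta`, `eta_to_O2axis`, `fit_o2_set`).
3. **Motional classes** — error filtering, BIC-guided class-count
   selection, 1-D k-means partition into J′ (highly dynamic,
   membrane-characteristic), J and α classes, and residue-type
   composition (`filter_by_error`, `select_class_count`,
   `kmeans_classes`, `class_composition`).
4. **Conformational entropy** — diffusion-in-a-cone entropy
   S/k_B = ln[π(3 − √(1+8√O²))] per probe, ensemble totals, and paired
   temperature differences (`cone_entropy`, `ensemble_entropy`,
   `delta_entropy`, `temperature_slope`).
5. **Trajectory order parameters** — ensemble second-moment estimator and
   P₂ autocorrelation plateau for bond-vector trajectories, with a
   reflecting cone-walk generator validated against the closed form
   (`order_parameter_iso`, `p2_autocorrelation`, `make_cone_trajectory`).
6. **Structural context** — methyl coordinates from PDB files,
   distance-to-lipid correlation and spatial clustering of motional
   classes by calibrated permutation tests (`extract_methyl_probes`,
   `dynamics_distance_correlation`, `spatial_class_clustering_test`).
7. **Synthetic ground truth** — two membrane-protein presets
   (`ground_truth("pSRII")`, `ground_truth("OmpW")`) that generate
   backbone rate tables and η build-up series with known truth, used to
   validate every step end-to-end (`make_methyl_dataset`,
   `make_backbone_dataset`).

See `vignettes/methyl-dynamics.Rmd` for the underlying models,
assumptions and numerical choices.

## Worked example

Generate a membrane-protein-like dataset with known truth, fit it, and
report the ensemble analysis:

```r
library(methyldyn)

gt <- ground_truth("pSRII")          # 90 probes, tau_m 21.9/28.9 ns
md <- make_methyl_dataset(gt, seed = 1)

# fit every build-up series and convert to O2_axis at the known tau_m
mic <- fit_o2_set(md$buildup$micelle, gt$tau_m_ns[["micelle"]],
                  environment = "micelle", seed = 2)
mic$error <- md$truth_sets$micelle$error[
  match(probe_key(mic), probe_key(md$truth_sets$micelle))]
bic <- fit_o2_set(md$buildup$bicelle, gt$tau_m_ns[["bicelle"]],
                  environment = "bicelle", seed = 3)

report <- run_report(list(micelle = mic, bicelle = bic), k = 3, seed = 4)
print(report)
```

```
[micelle] n = 90, <O2_axis> = 0.357, <err> = 0.042 (filtered: 88 kept, 2 removed)
  classes: Jprime 0.200 (n=28), J 0.352 (n=36), alpha 0.546 (n=24)
  entropy: total 55.5 k_B over 90 probes
[bicelle] n = 90, <O2_axis> = 0.367, <err> = 0.015 (filtered: 90 kept, 0 removed)
  classes: Jprime 0.223 (n=37), J 0.391 (n=30), alpha 0.567 (n=23)
  entropy: total 53.1 k_B over 90 probes
Environments: R2 = 0.808, slope = 0.957 (90 pairs)
```

The recovered ensemble mean (≈0.36), the three class centres
(≈0.21/0.36/0.55) and the micelle–bicelle agreement (R² ≈ 0.81) all match
the planted truth. A single probe, at the lowest level:

```r
s <- md$buildup$micelle[[1]]
f <- fit_eta(s, n_mc = 200, seed = 5)
conv <- eta_to_O2axis(f$eta, 21.9e-9)   # tau_m in seconds
cone_entropy(conv$O2_axis)$S_kB
```

```
eta: 24.27 +/- 1.37 s^-1
O2_axis: 0.307  (truth: 0.325)
entropy S/kB: 0.743
```

## Package layout

| file | contents |
|---|---|
| `R/constants.R` | physical constants, Legendre P₂ |
| `R/modelfree.R` | spectral density, ¹⁵N rates, τ_m estimation, R₁R₂ screen |
| `R/eta.R` | η build-up model, fits, η ↔ O²_axis conversion |
| `R/classes.R` | error filter, class-count selection, k-means classes, composition |
| `R/entropy.R` | cone entropy, ensemble and paired differences |
| `R/md_order.R` | trajectory order parameters, P₂ autocorrelation |
| `R/spatial.R` | distance and clustering permutation tests |
| `R/synthetic.R` | ground-truth presets and all generators |
| `R/io.R`, `R/pdb.R`, `R/probes.R`, `R/o2set.R` | typed tables, PDB reader, probe/o2-set types |
| `R/report.R` | end-to-end report and JSON serialization |
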