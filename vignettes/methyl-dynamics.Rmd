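---
title: "Methods: methyl side-chain dynamics from NMR relaxation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methyl side-chain dynamics from NMR relaxation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methyldyn)
```

This vignette documents the models, assumptions, default parameters and
numerical choices behind `methyldyn`. The package quantifies fast (ps–ns)
side-chain dynamics of membrane proteins from methyl ^1^H–^1^H
cross-correlated relaxation, places the resulting order parameters into
motional classes, and interprets them through a conformational-entropy
layer, with synthetic generators of known ground truth for end-to-end
validation.

## 1. Model-free spectral density and backbone rates

Backbone amide relaxation is described by the Lipari–Szabo model-free
spectral density

$$J(\omega) = \frac{2}{5}\left[\frac{S^2\tau_m}{1+(\omega\tau_m)^2} +
\frac{(1-S^2)\tau}{1+(\omega\tau)^2}\right],\qquad
\frac{1}{\tau} = \frac{1}{\tau_m} + \frac{1}{\tau_e},$$

with overall tumbling time $\tau_m$, generalized order parameter $S^2$ and
internal correlation time $\tau_e$. `predict_n15_rates()` assembles the
^15^N $R_1$ and $R_2$ from the standard dipolar and CSA terms with an
optional exchange contribution $R_\mathrm{ex}$ added to $R_2$. Physical
constants are centralized in `methyl_constants()`:
$r_\mathrm{NH} = 1.02$ Å, $\Delta\sigma_N = -170$ ppm, and CODATA values
for $\gamma_H$, $\gamma_N$, $\hbar$, $\mu_0/4\pi$. The implementation was
validated against independently computed high-precision oracles (50-digit
arithmetic) before any data were fit.

**Assumptions.** Isotropic overall tumbling (appropriate for
detergent-micelle and bicelle particles), a single effective internal
motion per residue, rigid-limit geometry for the N–H bond.

## 2. Tumbling time from $R_2/R_1$

For $\tau_e = 0$ and $R_\mathrm{ex} = 0$ the ratio $R_2/R_1$ is
independent of $S^2$, so each residue gives an estimate of $\tau_m$ by a
one-dimensional root search (`stats::uniroot` on a bracket of 0.5–200 ns).
`estimate_tau_m()` reports the mean and standard deviation over retained
residues.

Residues violating the assumptions are trimmed before averaging:

* **Exchange screen** (`r1r2_exchange_screen()`): the product $R_1 R_2$ is
  nearly independent of $\tau_m$ but grows with $R_\mathrm{ex}$; residues
  with $R_1R_2 > \mathrm{median} + k\cdot\mathrm{MAD}$ (raw MAD,
  `constant = 1`, $k = 3$) are flagged. With `iterate = TRUE` the
  median/MAD are re-estimated over unflagged residues until stable, which
  markedly improves recovery of planted exchange outliers when $S^2$
  varies across the chain (the $S^2$ spread otherwise inflates the MAD
  and masks outliers). The scaled MAD (consistency constant 1.4826) is
  deliberately not used for the same reason.
* **Low-ratio trim**: residues with $R_2/R_1$ below the 10th percentile
  are dropped, removing flexible termini biased by $\tau_e$.

On synthetic data with 2% rate noise the 200-seed mean recovery bias is
below 0.3%; with 25% of residues carrying $R_\mathrm{ex} = 8$ s$^{-1}$
the iterated screen keeps the mean bias below 1%.

## 3. Methyl axis order parameters from $\eta$ build-up

Intra-methyl ^1^H–^1^H dipolar cross-correlated relaxation ($\eta$) is
measured from the intensity ratio of double-quantum-filtered and reference
experiments as a function of the relaxation delay $T$:

$$\mathrm{ratio}(T) = \frac{3}{4}\,\eta\,
\frac{\tanh(sT)}{s - \delta\tanh(sT)},\qquad s = \sqrt{\eta^2+\delta^2},$$

where $\delta$ absorbs relaxation from external protons. `fit_eta()` fits
this with Levenberg–Marquardt (`minpack.lm::nlsLM`). Numerical care: at
small $\eta T$ the $\delta$ derivative is nearly zero and the
two-parameter Jacobian is singular, so the fitter sweeps several $\delta$
starting values and falls back to the one-parameter $\delta = 0$ model
($\mathrm{ratio} = \tfrac34\tanh(\eta T)$), which is also used whenever a
series has fewer than four delays. Uncertainties come from Monte-Carlo
resampling of the residual scatter.

$\eta$ converts to the methyl symmetry-axis order parameter via

$$O^2_\mathrm{axis} = \frac{10}{9}\,
\frac{\eta\, r_\mathrm{HH}^6}
{[P_2(\cos\theta)]^2 (\mu_0/4\pi)^2 \gamma_H^4 \hbar^2 \tau_m},$$

with $r_\mathrm{HH} = 1.813$ Å and $\theta = 90^\circ$ between the H–H
vector and the methyl axis, so $[P_2(\cos\theta)]^2 = 1/4$. The
conversion is linear in $\eta$ and inverse in $\tau_m$ — an accurate
$\tau_m$ from Section 2 is therefore a prerequisite, and `o2_set` objects
carry the $\tau_m$ used as an attribute. Noiseless synthetic build-up
curves invert through `fit_o2_set()` to better than $10^{-4}$.

## 4. Motional classes

Order-parameter distributions are decomposed into discrete motional
classes:

1. **Error filter** (`filter_by_error()`): probes with uncertainty above
   0.1 (boundary-inclusive) are removed before classification.
2. **Class count** (`select_class_count()`): Gaussian-mixture BIC
   (`mclust`) over candidate $k$; scores within `tie_margin = 2` of the
   best are treated as ties resolved toward the larger $k$, reflecting
   that adjacent $k$ are often nearly equally supported for overlapping
   classes.
3. **Partition** (`kmeans_classes()`): one-dimensional k-means
   (`nstart = 50`, seeded) on values clipped to $[0, 1]$ (clipping is
   flagged, not silent). Classes are labelled low→high as J′/J/α when
   $k = 3$ and all centers are below 0.75, or J/α/ω otherwise; the J′
   label marks the distinctly membrane-associated, highly dynamic class.
4. **Composition** (`class_composition()`): fraction of
   methionine/leucine/isoleucine probes per class versus valine, with
   enrichment relative to the ensemble.

## 5. Conformational entropy

Interpreting each methyl axis as diffusing in a cone, the per-probe
entropy is

$$S/k_B = \ln\!\left[\pi\left(3 - \sqrt{1+8\sqrt{O^2_\mathrm{axis}}}\right)\right],$$

which equals $\ln 2\pi$ at $O^2 = 0$, decreases strictly with rigidity and
diverges to $-\infty$ as $O^2 \to 1$. `ensemble_entropy()` excludes
out-of-range values with a warning rather than clipping them — clipping
would silently convert a divergence into a number. `delta_entropy()`
gives paired per-probe and total differences between conditions (for
example two temperatures), and `temperature_slope()` summarizes paired
temperature series as a per-kelvin slope.

## 6. Order parameters from trajectories

For validation against molecular-dynamics-style data,
`order_parameter_iso()` computes
$O^2 = \tfrac32\sum_{ij}\langle e_ie_j\rangle^2 - \tfrac12$ from unit
bond vectors, and `p2_autocorrelation()` computes
$C(t) = \langle P_2(\mathbf{e}(\tau)\cdot\mathbf{e}(\tau+t))\rangle$ with
`plateau_estimate()` averaging the final 25% of lags. The
diffusion-in-a-cone generator (`make_cone_trajectory()`) performs a
reflecting Gaussian walk in $u = \cos\theta$ (uniform in $u$ is uniform
on the spherical cap; reflection is a triangle-wave fold) with free
azimuthal diffusion, decorrelating over ≈50 frames. Its exact target is
the closed form

$$O^2_\mathrm{cone} = \left[\frac{\cos\theta_0(1+\cos\theta_0)}{2}\right]^2,$$

e.g. 0.6529 at $\theta_0 = 30^\circ$, reproduced by both the ensemble
estimator and the correlation plateau to better than 0.02 at $10^6$
frames.

## 7. Structural context

`extract_methyl_probes()` reads methyl carbon coordinates from PDB files
(ILE CD1, LEU CD1/CD2, VAL CG1/CG2, MET CE; first altloc; selectable
chain). Two questions are addressed by permutation tests with add-one
smoothing of the p-value, $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(n_\mathrm{perm}+1)$:

* **Distance–dynamics correlation**
  (`dynamics_distance_correlation()`): $R^2$ of $O^2$ against the minimum
  distance to a reference cloud (e.g. lipid/detergent atoms, or the
  membrane-slab surrogate `zslab_pseudo_cloud()`), with significance from
  permuting $O^2$ across probes.
* **Spatial clustering of classes**
  (`spatial_class_clustering_test()`): mean within-class pairwise
  distance minus the overall mean, permuting class labels; a variant
  (`spatial_class_kmeans_test()`) compares class labels to a spatial
  k-means partition via the adjusted Rand index. Both statistics are
  calibrated (p-values uniform under the null over 100 independent
  datasets) and both detect planted segregation at $p \le 0.01$.

## 8. Synthetic ground truth

`ground_truth()` encodes two membrane-protein presets as study
conditions — they are fixed inputs, not fitting targets:

| parameter | `"pSRII"` | `"OmpW"` |
|---|---|---|
| probes | 90 | 55 |
| $\tau_m$ (ns), micelle/bicelle | 21.9 / 28.9 | 24.0 / 29.9 |
| class centers | 0.21, 0.36, 0.55 | 0.21, 0.42, 0.66 |
| class weights | 0.333, 0.404, 0.263 | 0.52, 0.28, 0.20 |
| error range | 0.010–0.066 | 0.005–0.033 |
| environment $R^2$ target | 0.81 | 0.96 |
| temperature (K) | 323.15 | 313.15 |

Both weight vectors place the mixture mean at 0.36. Per-class scatter is
0.05, values are truncated to $[0.02, 0.95]$, and 5% of probes carry
deliberately large errors to exercise the error filter.
`make_methyl_dataset()` turns a preset into build-up series with Gaussian
ratio noise (`sigma_ratio = 0.01`) for two environments; the
environment-agreement target is met by adding a bicelle-side perturbation
$s$ solving $R^2 = V^2/((V+m^2)(V+s^2+m^2))$, where the measurement
variance $m^2$ is propagated through the 2×2 Fisher information of the
$(\eta, \delta)$ fit — the $\delta$-free delta-method variance is several
times too small because freeing $\delta$ inflates the $\eta$ variance.
`make_backbone_dataset()` produces ^15^N rate tables with optional noise
and planted exchange outliers; `write_ground_truth()` writes a JSON
sidecar with all parameters and the seed. All generators take explicit
seeds and are deterministic given them (`withr::with_seed`).

## 9. End-to-end example

```{r pipeline, eval = FALSE}
gt <- ground_truth("pSRII")
md <- make_methyl_dataset(gt, seed = 1)
mic <- fit_o2_set(md$buildup$micelle, gt$tau_m_ns[["micelle"]],
                  environment = "micelle", seed = 2)
mic$error <- md$truth_sets$micelle$error[
  match(probe_key(mic), probe_key(md$truth_sets$micelle))]
bic <- fit_o2_set(md$buildup$bicelle, gt$tau_m_ns[["bicelle"]],
                  environment = "bicelle", seed = 3)
report <- run_report(list(micelle = mic, bicelle = bic), k = 3, seed = 4)
print(report)
```

`run_report()` chains the filter, classification, composition and entropy
steps, auto-detects temperature and environment pairs among the supplied
sets, and serializes to JSON via `write_report_json()`.

## 10. Reproducibility notes

* Every stochastic routine takes a seed and uses `withr::with_seed`, so
  results are independent of the caller's RNG state.
* Table I/O (`write_order_parameter_table()` etc.) round-trips doubles at
  17 significant digits.
* Problem sizes used in validation: 55–90 probes, 20 backbone residues,
  $10^5$–$10^6$ trajectory frames, 199–1999 permutations; the full test
  suite runs in a few minutes on one CPU.
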