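# bmecd

Bayesian maximum-entropy (BME) refinement of protein conformational
ensembles against circular dichroism (CD), small-angle X-ray scattering
(SAXS) and NMR chemical-shift data, with the accuracy metrics used to
assess CD prediction and secondary-structure (SS) estimation methods.

## Who this is for

Structural biologists and biophysicists modelling intrinsically
disordered proteins (IDPs): you have a large prior ensemble of
conformers (typically from molecular-dynamics simulation), per-conformer
predicted observables from external predictors (a CD basis-set
predictor, a chemical-shift predictor, a SAXS curve calculator), and
measured solution data. `bmecd` reweights the prior to fit the data with
the smallest possible perturbation, extracts compact integer-weight
sub-ensembles from the refined weights, and quantifies model accuracy.

## The model

Refined weights minimise, on the probability simplex,

    L(w) = Σ_k (M_k / 2) χ²_k(w) − θ · S_rel(w, w⁰),
    S_rel = −Σ_j w_j ln(w_j / w⁰_j)

with, per observable type k (CD, SAXS, CS),

    χ²_k = (1/M_k) Σ_i ( (O_ki − α_k Σ_j w_j O_kij^calc) / σ_ki )².

α_k is a free positive beam-intensity scale for SAXS (closed-form
weighted least squares) and fixed to 1 for CD and chemical shifts.
Uncertainty models: σ = 0.2·|O| + 0.75 kMRE for CD intensities; 0.95,
1.03, 1.13 ppm for Cα, Cβ and carbonyl-C shifts; per-point σ for SAXS.
θ is chosen by scanning {0.1, 1, 2, 5, 10, 20, 50, 100, 200} and taking
the largest θ with a significant χ² improvement over the prior. Final
models are small sub-ensembles (5–200 conformers, 5 replicas each) drawn
with replacement from the refined weights and selected by a
plateau-plus-concatenation-agreement rule.

Assessment metrics: CD RMSD with an optimal intensity scale applied to
the experimental spectrum; SS-fraction RMSD and (unscaled) χ² after
class-scheme grouping (BESTSEL↔HBSS 6-class rules, K2D3 coil
completion, editable DISICL/DSSP/HBSS reductions); SAXS χ = √χ²;
per-atom-type chemical-shift RMSD; group mean ± SEM summaries.

## Worked example

Generate a 50-conformer synthetic problem with known truth weights,
scan θ, and check recovery:

```r
library(bmecd)
p <- gen_problem(50, seed = 42)
scan <- theta_scan(p$blocks, rep(1/50, 50), thetas = c(1, 10, 100))
as.data.frame(scan)
#>           theta chi2_CD chi2_SAXS chi2_CS alpha_SAXS  s_rel loss
#> theta_100   100   0.817     0.983    1.22      0.995 -0.015 38.2
#> theta_10     10   0.690     0.915    1.07      1.009 -0.180 34.3
#> theta_1       1   0.682     0.886    0.78      1.043 -1.227 30.3

select_theta(scan)
#> [1] 10
```

θ = 10 wins: nearly all of the attainable χ² improvement is reached
while perturbing the prior far less (S_rel −0.18 vs −1.23 nats) than
θ = 1 would. The refined ensemble fits each block to about one
experimental σ (χ² ≈ 0.7–1.1, SAXS χ = 0.96), as it should when the
noise models are calibrated, and the truth observable averages are
recovered to ≈0.2–7 % relative error depending on how strongly each
block constrains the weights:

```r
res <- scan$results[["theta_10"]]
recovery_check(p, res)
#>   block mean_rel_err max_rel_err chi2_vs_truth
#> 1    CD      0.06661     0.12374       0.03702
#> 2  SAXS      0.01149     0.04739       0.00743
#> 3    CS      0.00175     0.00623       0.02039
```

Group statistics work the same way on real report tables — for example
the published SAXS deviations of the five CD-refined reference
ensembles:

```r
summarize_metrics(c(0.39, 1.94, 1.65, 0.92, 1.03), round_to = 2)
#> group_summary: 1.186 +/- 0.275 (n = 5)
```

i.e. a mean χ of 1.19 ± 0.27: within ~1.2 experimental σ of the
measured curves on average.

A command-line pipeline (`simulate`, `refine`, `subsample`, `evaluate`,
`summarize`) is available through `bmecd_cli()` or the wrapper script in
`inst/scripts/bmecd`.

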