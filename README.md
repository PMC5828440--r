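# nbclustsim

Simulation framework for asking a practical question in RNA-Seq analysis:
**which data transformation should you apply to counts before Gaussian
model-based clustering of samples?** Raw RNA-Seq counts are over-dispersed
and right-skewed — far from the Gaussian components a mixture model assumes —
so the choice of transformation (none, log2, rank-based inverse normal, or a
variance stabilizing transform) materially changes both the number of
clusters selected and how well samples are assigned.

The package implements the full study loop:

1. **Feature selection** — top-`m` genes by median absolute deviation (MAD),
   or a random panel drawn after discarding the low-MAD half
   (`select_top_mad()`, `select_random_filtered()`).
2. **Parameter estimation** — per-gene negative binomial MLEs
   (`fit_nb_mle()`, `estimate_panel_params()`) under the size
   parameterization Var = μ + μ²/k.
3. **Simulation** — clustered count datasets x_gi ~ NB(μ_g(c_i), k_g(c_i)),
   with cluster structure created by multiplying μ and k of a random subset
   of "up-expressed" genes by effect shifts Δμ₁ = e^3.375, Δμ₂ = e^5.5,
   Δk₁ = 1.01, Δk₂ = 1.03 (`build_design()`, `simulate_batch()`). Twelve
   scenarios: {TE, RE, TX, RX} parent categories × K ∈ {1, 2, 3}, N = 55
   samples, 100 genes.
4. **Transformation** — naive (identity), log2(x+1), Blom normal scores
   Φ⁻¹((r − 3/8)/(n + 1/4)), and the NB variance stabilizing transform
   (2/√α)·asinh(√(αx)) with pooled method-of-moments dispersion α
   (`apply_transform()`).
5. **Clustering** — diagonal/spherical Gaussian mixture models fit by EM
   with kmeans++ restarts; K and covariance family selected by
   BIC = 2ℓ − d·log(n), maximization convention (`gmm_fit()`,
   `select_model()`).
6. **Evaluation** — per-gene skewness/excess kurtosis
   (`summarize_normality()`); partition recovery via adjusted Rand index,
   clustering error rate (1 − Rand), and a pairwise co-membership
   concordance index (`evaluate_partition()`).

`run_simulation_study()` orchestrates all of it; `cluster_real_data()` is the
single-matrix path (transform, then cluster with K unknown).

## Worked example

```r
library(nbclustsim)

# a surrogate "tumor panel": 100 genes x 55 samples with known NB truth
sp <- generate_surrogate_panel(seed = 7)
sp$counts
#> count_matrix: 100 genes x 55 samples
#> total counts: 2,930,786

# top-MAD panel, K = 3 clusters (18/18/19 samples), naive vs log2, 10 replicates
cfg <- study_config(categories = "TE", K_set = 3,
                    transforms = c("naive", "log"), n_datasets = 10, seed = 7)
res <- run_simulation_study(cfg)
for (s in res$summaries) print(s)
#> scenario TE K=3 naive: skew 2.173, kurt 6.134; ARI 0.556, CER 0.227, CI 0.826 (mean chosen K 2.20)
#> scenario TE K=3 log:   skew -0.012, kurt -0.392; ARI 1.000, CER 0.000, CI 1.000 (mean chosen K 3.00)
```

Reading: untransformed counts are strongly right-skewed (mean per-gene
skewness 2.17) and the mixture model recovers the 3-cluster truth only
partially (mean ARI 0.56, typically under-selecting K). After log2 the data
are near-symmetric (skewness −0.01) and clustering recovers the true
partition exactly in all 10 replicates — the directional finding the
simulation study is built to expose. `write_report(res, "outdir")` writes the
normality table, the metrics table, and a run manifest as TSV.

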