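---
title: "Methods: data transformations and Gaussian model-based clustering of RNA-Seq counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: data transformations and Gaussian model-based clustering of RNA-Seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

RNA-Seq gene expression is measured as read counts, and counts from bulk
tumor panels are over-dispersed relative to Poisson: across genes, variance
grows roughly as μ + μ²/k with gene-specific dispersion k. Model-based
clustering of *samples*, however, is almost always done with Gaussian
mixture models, whose components assume symmetric, light-tailed data. This
package quantifies the mismatch: it simulates clustered negative binomial
(NB) count matrices calibrated to a real panel, applies four candidate
transformations, clusters the samples with a Gaussian mixture engine, and
measures both how Gaussian the transformed data look (skewness, excess
kurtosis) and how well the true partition is recovered (ARI, clustering
error rate, concordance index).

## The simulation model

Per gene g, counts are x_gi ~ NB(μ_g, k_g) with Var = μ_g + μ_g²/k_g (the
"size" parameterization; k → ∞ is the Poisson limit). The (μ_g, k_g) pairs
are maximum-likelihood estimates from a real or surrogate 100-gene × 55-sample
panel. With no covariates the NB MLE separates: μ̂ is the sample mean and k̂
maximizes the profile log-likelihood, which we search in log k over
[−10, 18.4] with Brent's method (tolerance 1e-8). When the sample variance
does not exceed the mean the k-likelihood is monotone increasing and the MLE
diverges; such genes are returned at the cap k = 1e8 with a `boundary` flag.
The cap value is arbitrary beyond "effectively Poisson" and the flag is what
matters downstream.

Cluster structure is created by shifting parameters for a random subset of
up-expressed genes: 10% of genes in cluster c2 (shifts Δμ₁ = e^3.375,
Δk₁ = 1.01) and a disjoint 20% in cluster c3 (Δμ₂ = e^5.5, Δk₂ = 1.03);
cluster c1 is always the unshifted baseline. Shifts are **multiplicative**
on both μ and k by default. The source material states only that shifts were
"incorporated"; we chose fold-change semantics because up-regulation in
expression analysis is conventionally multiplicative and the e^x form of the
mean shifts reads as a log-scale effect. An additive mode is available
(`build_design(..., shift_mode = "additive")`), and quantitative summaries
of K ≥ 2 scenarios should be treated as interpretation-dependent.
The c2 up-gene set is drawn from seed `base_seed − 1`, so it is identical
between K = 2 and K = 3 runs sharing a base seed; replicate d uses seed
`base_seed + d − 1`. Samples are generated in label-blocked column order —
clustering is order-invariant, and blocked order keeps truth bookkeeping
trivial.

Twelve designs cross four parent categories with K ∈ {1, 2, 3}: TE/TX use
the top-100-MAD gene panel with equal (28/27 or 18/18/19) or extremely
unequal (5/50 or 5/17/33) cluster sizes; RE/RX likewise for a random
100-gene panel drawn after discarding the lower-MAD half of genes. At K = 1
the balance distinction is vacuous, and the simulator draws identical
batches for TE/TX (and RE/RX) under shared seeds — a property the tests
assert bit-exactly.

## The transformations

* **naive** — identity; the baseline every comparison is against.
* **log2** — log2(x + 1). The pseudocount (configurable) handles zeros; the
  source is silent on it and 1 is the overwhelmingly common choice.
* **Blom** — normal scores Φ⁻¹((r − 3/8)/(n + 1/4)) with average ranks for
  ties. Applied **per sample** by default: each sample's gene profile is
  rank-normalized. The alternative per-gene axis forces every gene's
  skewness to ≈ 0 on tie-free data, which would make reported per-gene Blom
  skewness values of about −0.3 to −0.5 impossible; the per-sample axis
  reproduces systematically negative per-gene skewness, so it is the
  default. Both axes are implemented and tested.
* **VST** — u(x) = (2/√α)·asinh(√(αx)), the closed-form variance stabilizer
  for NB with Var = μ + αμ², using one pooled α per dataset estimated by
  method of moments: the median over genes of (s² − m)/m², positive values
  only, floored at 1e-8 (at the floor the transform collapses to 2√x, the
  Poisson stabilizer). A spline-fit mean–variance VST is deliberately out of
  scope; the pooled closed form is the minimal faithful version.

All four transforms are rank-preserving within their operating slices and
shape-preserving; tests check both.

## Normality summaries

Skewness g1 = m₃/m₂^{3/2} and excess kurtosis g2 = m₄/m₂² − 3 use
divisor-n central moments (bias-corrected variants behind a flag). Kurtosis
is reported in the **excess** convention (normal = 0) — reference summaries
of this design contain negative kurtosis values, which are impossible in the
non-excess convention. Aggregation is: per gene across the 55 samples, mean
over genes within a dataset, then mean and SE over the Monte-Carlo
replicates; the SE therefore measures replicate-to-replicate variation,
which is what makes the very small published-style SEs (~0.005) attainable.
Genes with zero variance in a dataset are excluded from that dataset's
average, with a count retained.

## The clustering engine

Samples (rows) are clustered in gene space (p = 100 features, n = 55
samples). The engine is a diagonal-covariance Gaussian mixture fit by EM:

* **Families**: spherical or diagonal variances, shared or varying across
  clusters (4 families). Full covariance is excluded by design — with p > n
  it is unidentifiable — mirroring the volume/shape-constrained corner of
  the standard mixture-model catalog.
* **Initialization**: kmeans++ seeding with hard initial assignments, 10
  restarts (configurable), best final log-likelihood kept. This replaces
  model-based hierarchical agglomeration with something simpler and
  seedable; behaviorally it lands in the same optima on separable data.
* **Convergence**: Δ log-likelihood < 1e-6 or 500 iterations; the trace is
  non-decreasing and is exposed for testing.
* **Degeneracy**: every fitted variance is floored at 1e-6. A component
  whose effective sample count falls below 2 would pin its variance to the
  floor and produce an unbounded likelihood spike; such fits error and the
  restart loop tries again (error only if all restarts collapse). Without
  this guard BIC reliably over-selects K on clean data — the floor turns the
  classical GMM likelihood singularity into a likelihood *bonus* unless
  degenerate components are rejected.
* **Selection**: BIC = 2ℓ − d·log(n) (maximize), d = K·p means + family-
  dependent variance count + (K − 1) weights, over K ∈ 1..5 × 4 families.
  Ties in hard assignment go to the lower cluster index.

## Evaluation metrics

Rand index and Hubert–Arabie adjusted Rand index are computed from the
contingency table. The clustering error rate is defined as exactly
1 − Rand — the definition used by this study's source, *not* the
permutation-minimized misclassification rate, which is provided separately
as `misclassification_rate()` to avoid ambiguity. The concordance index is
formalized as pairwise co-membership AUC: over all (within-truth-pair,
between-truth-pair) combinations, the fraction the estimate orders correctly
with half credit for ties. This construction is a documented choice — the
verbal description it descends from is not operational — and it meets the
stated anchors: 1 for perfect recovery, 0.5 for any constant estimate, NA
when the truth has a single cluster. K = 1 scenarios therefore carry
normality summaries but no partition metrics.

## The surrogate data world

`generate_surrogate_panel()` draws μ_g ~ LogNormal(4, 2²) and
k_g ~ LogNormal(0, 1²) for 100 genes × 55 samples. These defaults were
chosen once, a priori, to span the qualitative range of a bulk tumor panel —
low-count zero-inflated genes through 10⁴-scale counts, gene-wise
dispersion from mild to strong — and are *not* calibrated to any real
matrix. Consequently a green test on surrogate data establishes that the
machinery behaves correctly (recovery, direction of transformation effects,
determinism), not that the package reproduces any particular published
number; reproducing reference normality values requires the original
supplementary count matrices, which cannot ship with the package. The one
acceptance test that needs them fails with an explicit message when they are
absent rather than being skipped, and runs in full when tsv/xlsx conversions
are dropped into `inst/extdata/`.

## Known limitations

* No library-size variation, batch structure, or down-regulated genes in the
  simulator — the marginal per-gene NB model has none.
* The pooled-α VST is cruder than spline-based variance stabilization.
* The CER here (1 − Rand) is pessimistic for fine partitions; use
  `misclassification_rate()` when the conventional error rate is wanted.
* EM with 10 restarts is not guaranteed to find the global optimum; the BIC
  table, seeds, and restart count are all recorded so runs replay exactly.
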