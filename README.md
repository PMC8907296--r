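# scsEntropy

Shape-constrained spline normalization of Shannon clonal-diversity indices
for viral integration-site (IS) clonal-tracking data.

## The problem

In gene-therapy studies, every transduced stem-cell clone is labelled by the
genomic position where the vector integrated (its integration site), and the
Shannon entropy h = −Σ pᵢ log pᵢ of the clone relative abundances measures
how polyclonal a blood or tissue sample is. But the measured entropy also
reflects *how hard you looked*: the DNA amount used for IS retrieval, the
vector copy number (VCN), the sequencing depth (SD) and, in pooled animal
studies, the pool size (PS) all change how many clones are detected. Samples
collected under heterogeneous technical conditions are therefore not
comparable, and popular fixes — rarefaction (RAR) and scaling with ranked
subsampling (SRS) — only address depth and still leave measurable residual
confounding.

## The model

`scsEntropy` regresses the confounding away. Log-entropies follow

    log(h_i) = β₀ + Σₖ C^k_i β_c^k + Σⱼ F^j_i β_f^j + ε_i,   ε_i ~ N(0, σ²)

where each confounder enters through a quadratic B-spline C^k whose shape is
restricted to what detection mechanics allow — monotone nondecreasing,
concave, and (by default) saturating, i.e. zero slope at the right boundary
knot — and F carries unconstrained or shape-constrained factors of interest
such as lineage-by-vector entropy-decay splines over time. The restricted
least-squares estimate is the projection of log h onto a polyhedral cone,
computed by quadratic programming; the cone-face dimension d serves as the
effective parameter count (variance = RSS/(n − 1.5d), p = d in AICc/BIC),
pointwise confidence intervals come from face-probability-weighted
cone-projection covariances, and confounder subsets are compared and
averaged with BIC weights λ_l ∝ exp(−BIC_l/2). The confounder-free
diversity is the rescaled entropy

    h_res = exp(log h − C β̂_c)

with factor effects deliberately left in. RAR and SRS are included as
baselines, and residual confounding is quantified by two-sided Spearman
rank-correlation tests between (rescaled) entropies and each confounder.

## Worked example

Simulate an in-vitro-style assay (three MOI levels × three DNA amounts ×
three replicates, depth correlated with both), fit the three-confounder
model, and test residual confounding:

```r
library(scsEntropy)

ise <- simulateInVitroAssay(seed = 42)   # ISAbundanceExperiment
et  <- buildEntropyTable(ise)            # sample_id, h, log_h, dna_ng, vcn, sd

model <- scsModel(list(scsTerm("dna_ng", 1), scsTerm("vcn", 1), scsTerm("sd", 2)))
fit   <- fitScs(et, model)
fit
#> ScsFit: shape-constrained log-entropy model
#>   n = 27 samples, 8 parameters, cone-face dimension d = 5
#>   confounders: dna_ng, vcn, sd
#>   sigma^2 = 0.006939  (RSS/(n - 1.5 d)); 3 active constraints

etRes <- transform(et, h_res = unname(rescaleEntropies(fit)))
residualConfoundingReport(list(observed = et, scs = etRes),
                          c("dna_ng", "vcn", "sd"))
#>     method confounder abs_rho  p_value  n
#> 1 observed     dna_ng 0.47173 1.30e-02 27
#> 2 observed        vcn 0.83863 4.70e-08 27
#> 3 observed         sd 0.93651 7.02e-13 27
#> 4      scs     dna_ng 0.00582 9.77e-01 27
#> 5      scs        vcn 0.16889 4.00e-01 27
#> 6      scs         sd 0.07692 7.03e-01 27
```

The observed entropies correlate strongly with every technical variable
(p ≤ 0.013); after SCS rescaling all three Spearman tests are insignificant
(p ≥ 0.40), i.e. the rescaled diversities no longer depend on how the
libraries were made. `pointwiseCI()` gives cone-projection confidence bands
for each fitted effect, `modelAverage()` ranks confounder subsets by BIC
weight and reports marginal inclusion probabilities, and
`baselineRescaledEntropies()` produces the RAR/SRS comparators.

A thin command-line wrapper ships in `inst/scripts/scs-entropy`
(subcommands `simulate`, `entropy`, `run`, `normalize`, `assess`;
`run --config cfg.yaml` executes the full read → entropy → fit/average →
rescale → assess workflow and writes TSVs plus a JSON run manifest).

The methods vignette (`vignettes/scs-normalization-methods.Rmd`) documents
the model, the shape-constraint geometry, identifiability conventions,
estimation details and the synthetic-data generator.

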