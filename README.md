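# sigact

Kinase and transcription-factor (TF) activity inference for multiomics
cancer cohorts, with the downstream analyses that make the activities
useful: mutation–activity association, prior benchmarking, co-regulation
landscapes, survival models and activity-based patient stratification.

`sigact` is aimed at computational biologists working with matched
(phospho)proteomic, transcriptomic, copy-number, mutation and clinical
data — the kind of cohort assembled from CPTAC/TCGA-style studies — who
want the signalling layer (who is active, where, and with what clinical
consequence) rather than raw abundances.

## The models at the core

**Kinase activity** in a sample is a one-sample z-test comparing the mean
log2 fold-change *x* of the kinase's *N* measured substrate sites against
the background of all phosphosites measured in that sample (mean μ,
SD σ):

    z = (x − μ) / (σ / √N)

The activity score is `sign(z) · (−log10 p)` with a two-tailed normal
p-value; scores need ≥ 3 measured substrates. Phosphosites are first
residualized against host-protein abundance (and optional clinical
covariates) so the score reflects phosphorylation, not protein level.

**TF activity** is a signed regulon enrichment: per sample, gene
statistics are rank-transformed to quantiles and mapped through the
standard normal inverse Φ⁻¹; a regulon with modes wᵢ ∈ {−1, +1} over m
measured targets scores

    NES = Σ wᵢ · Φ⁻¹(qᵢ) / √m

which is approximately standard normal under random ranks (≥ 5 targets
required).

Downstream, activities are linked to somatic mutations and to each other
with study-adjusted linear models (binary mutation indicators, BH-FDR,
network-enrichment validation against a confidence-filtered edge list),
to overall survival with Kaplan–Meier/log-rank tests on activity strata
(|activity| > 1.75) and multivariate Cox models (age, gender and a
recurrent-mutation genotype panel as covariates), and to patient subtypes
through complete-linkage clustering of Spearman cross-correlation
profiles with hypergeometric clinical over-representation.

A synthetic multiomics cohort generator (`sim_config()`,
`generate_cohort()`, `generate_priors()`) plants known activity
programmes, mutation effects and survival hazards, so every stage is
validated by parameter recovery. See the vignette
(`vignettes/activity-inference.Rmd`) for the full model description and
design rationale.

## Worked example

```r
library(sigact)

sim <- sim_config(seed = 1L)          # 300 samples, 50 kinases, 40 TFs
res <- run_pipeline(sim, outdir = "sigact_run")

res$benchmark$mean_auroc
#> [1] 0.9075917

head(res$associations[order(res$associations$fdr), ], 3)
#>  predictor_id response_id  beta        p      fdr n_samples model_tag
#>         g0091         K01 3.538 1.03e-68 2.06e-66       300       eq3
#>         g0093         K03 4.330 7.63e-64 7.63e-62       300       eq3
#>         g0092         K02 3.946 1.62e-63 1.08e-61       300       eq3

table(res$clusters$clusters)
#>   1   2   3
#> 100 100 100
```

Reading the output: the benchmark line says that, over 100 balanced
negative resamples, absolute kinase activities rank truly regulated
(kinase, sample) pairs above unknown pairs with a mean AUROC of 0.91 on
this cohort. The association table recovers exactly the three planted
mutation–kinase effects (genes `g0091–g0093` driving kinases `K01–K03`,
effect sizes on the signed −log10 p activity scale) as the only hits
surviving FDR, out of 200 tested pairs. The clustering recovers the three
planted activity subtypes, 100 samples each (adjusted Rand index 1
against the planted labels). All fixtures and result tables are written
as tab-separated text under `outdir`; rerunning with the same seed
reproduces them byte-identically.

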