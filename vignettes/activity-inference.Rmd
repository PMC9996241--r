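---
title: "Inferring kinase and TF activities from multiomics cohorts: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring kinase and TF activities from multiomics cohorts: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigact)
```

## The scientific problem

Somatic alterations drive cancer largely by dysregulating the activities of
protein kinases and transcription factors (TFs), yet neither activity is
measured directly by standard multiomics assays. `sigact` estimates both
from the footprints they leave on their targets: a kinase's activity from
the phosphorylation changes of its substrate sites, a TF's activity from
the expression changes of its regulon genes. The inferred activity profiles
then serve as the substrate for every downstream question the package
answers: which mutations shift which activities, how kinases and TFs
co-regulate, which activities separate patient survival, and how samples
stratify into activity subtypes.

## The activity models

### Kinase activities: a one-sample z-test on substrate fold-changes

For kinase $K$ in sample $s$, let $x$ be the mean log2 fold-change of $K$'s
$N$ measured substrate sites, and let $\mu$ and $\sigma$ be the mean and
standard deviation of **all** phosphosites measured in $s$ (the
background). Then

$$z = \frac{x - \mu}{\sigma / \sqrt{N}},$$

a two-tailed normal p-value is computed from $z$, and the activity score is
$\mathrm{sign}(z)\,(-\log_{10} p)$: positive when the substrates are more
phosphorylated than the sample background. Scores supported by fewer than
`min_targets = 3` measured substrates are withheld — with one or two sites
the background SD is a poor yardstick and the score is dominated by single
peptides.

Two modelling choices deserve comment. First, the background includes the
kinase's own substrates; with realistically small substrate sets the
inclusion shifts $\mu$ negligibly, and an `exclude_targets` switch is
provided for sensitivity analyses. Second, the p-value is floored at
1e-300 before the log transform so that scores remain finite.

The z-test operates on *residualized* phosphosite data. Phosphosite
quantifications correlate substantially with the abundance of the host
protein, so each site is first regressed on its protein (and optional
clinical covariates such as age and gender) with ordinary least squares,
per site, on complete cases; the residuals are the phosphorylation changes
not explained by abundance. Rows with fewer than three usable samples or
without a matched protein pass through unchanged and are flagged, and the
residuals are exactly orthogonal to the fitted predictors (checked to
1e-8 in the test suite). Because residualization centres each site, a
shift planted in a fraction $f$ of samples attenuates to $(1-f)$ of its
nominal size — a point that matters when interpreting recovery
simulations (below).

A `self_sites` mode scores kinases by the phosphosites on the kinase
itself, restricted to sites with a regulatory annotation or a functional
score above 0.4; sites without a score are conservatively treated as not
passing the gate.

### TF activities: signed regulon enrichment

Per sample, the measured gene statistics (log2 fold-changes) are rank
transformed to quantiles $q_i = r_i/(n+1)$ and mapped through the standard
normal inverse $\Phi^{-1}$. A TF's normalized enrichment score over its $m$
measured regulon targets with modes $w_i \in \{-1,+1\}$ is

$$\mathrm{NES} = \frac{1}{\sqrt{m}} \sum_{i=1}^{m} w_i\, \Phi^{-1}(q_i),$$

which is approximately standard normal under random ranks — the test suite
verifies mean within $\pm 0.05$ and SD within $[0.9, 1.1]$ over 1,000
permutation draws, and agreement with the closed form for a top-ranked
regulon. Regulons with fewer than `min_regulon = 5` measured targets yield
no score. This is a deliberately transparent enrichment statistic: it is
validated by null calibration and planted-signal recovery rather than by
equality with any particular published enrichment tool, and it keeps the
activity contract (signed, roughly standard-normal scores) that the
downstream stages rely on.

## Thresholds and their defaults

All tunable thresholds live in `sigact_config()` so a single list
reconfigures a run:

* `activity_cutoff = 1.75` (absolute activity) defines "strong
  regulation" for regulation percentages, survival strata and
  tumour-versus-perturbation comparisons; `noise_cutoff = 0.15` separates
  signal from noise when splitting samples by activity sign.
* `min_gene_mut = 20`, `min_act_samples = 10`, `min_pair_mut = 5` gate the
  mutation-association models; genes must be mutated in more than 20
  samples overall, activities measured in at least 10 samples, and the
  gene mutated in at least 5 of each tested pair's samples.
* `string_min_score = 850` keeps only high-confidence edges when testing
  association pairs for network enrichment.
* `jaccard_height = 0.85` cuts the complete-linkage dendrogram on the
  1 − Jaccard substrate-overlap distance when collapsing redundant
  kinases (0.8 for the stricter correlation control).
* `n_clusters = 8` activity subtypes by default; `dereg_threshold = 2` on
  the cluster-level median/SD score calls a protein deregulated in a
  cluster.
* `bmi_cutoff = 37` and `age_cutoff = 50` binarise the clinical table for
  over-representation tests; levels with fewer than `min_level_count = 5`
  patients are excluded.
* `min_mut_genotype = 100` mutations qualify a gene for the Cox genotype
  panel; `run_pipeline()` scales this to 10 for synthetic cohorts of a few
  hundred samples, keeping the panel size comparable in spirit.

## The synthetic cohort generator

`sim_config()`/`generate_cohort()` emit a full multiomics cohort with
known ground truth, and `generate_priors()` the matching prior knowledge
(substrate lists, signed regulons, a confidence-scored edge list containing
every planted mutation–kinase pair at score ≥ 850 plus low-scoring decoys,
a gold standard of truly regulated kinase–sample pairs, and FASTA
sequences carrying each declared site and mutation residue).

The generative model mirrors the statistical structure the analyses
assume:

* Samples belong to `n_blocks = 3` activity blocks (the planted subtypes);
  studies are assigned as contiguous chunks so batch structure is
  orthogonal to biology.
* Each kinase/TF carries a sign and is active in one block. TF programmes
  span their whole block, anchoring the subtype structure; a kinase's
  programme is on in only `kinase_active_fraction = 0.15` of its block
  (about 5% of the cohort), matching the minority-sample regulation
  frequencies that motivate the 96.7th-percentile / 5%-of-samples
  "strongly regulated" filter. This choice interacts with residualization:
  centring attenuates a planted shift by the active fraction, so
  full-block kinase programmes would understate what the method faces in
  cohorts where regulation is rare.
* Phosphosite values are `slope × protein + activity + batch + noise`
  with `slope = 0.8` (reproducing the protein–phosphosite confounding),
  per-study per-feature batch offsets of SD 0.3, and site noise SD 1.
* mRNA values add `mode × TF activity` to each regulon target.
* Planted mutations add `beta = 1.5` activity units of a target kinase in
  carrier samples (15% carrier rate), and the same shift reaches the
  kinase's substrates.
* Survival is exponential with per-sample hazard
  `baseline × exp(Σ log-HR × activity)` (default log-HR = ln 2 on two
  kinases) under uniform censoring — the simplest model with an
  interpretable planted hazard ratio; batch effects are additive per
  study on every layer, matching the linear batch-removal model the
  preprocessing assumes; missingness is completely at random
  (`missingness_rate = 0.1`), as informative missingness is not part of
  any downstream model.

What the simulator does **not** emulate: peptide-level quantification and
multiply-phosphorylated peptide interference, tumour purity, copy-number
driven expression dosage, informative dropout, and correlated regulons.
Passing recovery tests on this cohort therefore demonstrates that the
statistical machinery is correct under its own assumptions — not that real
CPTAC-scale data will yield the same power.

## Numerical and design choices

* **Quantile normalization** computes ranks on observed values only and
  interpolates the target quantiles to each column's observed count
  (ties averaged); with complete data the map is exactly idempotent.
* **Missing predictors** make a residual cell missing; fitting is
  complete-case per row, and the per-row sample count is recorded. How
  missing covariates are handled is otherwise unstated in the field's
  descriptions; complete-case is the transparent choice.
* **Median-per-feature imputation** (not random-forest) fills missing
  correlation cells before clustering distances: deterministic,
  dependency-light, and logged; the clustering operates on Spearman
  correlation profiles, so the impact of single imputed cells is bounded.
* **Study covariates** enter association models as one-hot indicators
  against the first level; singleton studies are merged into the
  reference with a warning.
* **Cox ties** use the Efron approximation, the standard default and
  accurate for event times recorded in days.
* **Redundancy reduction ties** (equal substrate counts) break
  lexicographically; kinases are sorted before clustering so the result
  is independent of input order.
* **Cluster ids** are relabelled by decreasing size for stable reporting;
  "cut to obtain eight groups" is implemented as a k-groups cut of the
  dendrogram with `k` configurable.
* **Regulation-percentile pooling**: the 96.7th-percentile threshold is
  computed on the pooled absolute activity distribution (switchable to
  per-protein); pooling is the reading that makes the companion
  "in at least 5% of samples" filter bite uniformly across proteins.
* **Tumour-versus-perturbation orientation**: the regression of one
  regulation percentage on the other is orientation-ambiguous; the default
  takes the tumour percentage as the response, under which a residual
  z-score above +2 is tumour-specific, and a flag swaps the orientation
  with the labels exchanging consistently.
* **Log-rank strata**: tests run across all populated strata (not just
  active vs inactive), with the stratum count recorded per test.
* **Per-tissue association replication** subsets samples and drops the
  study term when it becomes constant, rather than adding a tissue
  covariate to the pan-cohort model.

## Validation strategy and problem sizes

The test suite works oracle-first: the z-test against an erf-based normal
CDF (1,000+ random instances, 1e-9), OLS against the normal equations,
BH against the brute-force step-up definition (10,000 vectors),
Fisher/hypergeometric tails against `choose()` enumeration (totals ≤ 30,
1e-12), the log-rank statistic against a hand-rolled observed-minus-
expected oracle, Spearman against rank-then-Pearson, and clustering
recovery against an external adjusted-Rand implementation. Parameter
recovery runs on cohorts of 200–300 samples with 10–50 kinases: planted
kinase–sample regulation is ranked with AUROC > 0.95 (complete substrate
measurement, i.e. 10 measured substrates per kinase), a planted
association effect of 1.5 is recovered within ±0.2 at n = 200, a planted
hazard ratio of 2 is recovered with ≥ 90% CI coverage over 50 replicates
at n = 300, and the three planted activity blocks are recovered exactly.
These sizes keep a complete validation run within about a minute on a
single core while leaving the statistical margins comfortable.

## Known limitations

* The NES statistic is a simplified signed enrichment; it shares the
  contract but not the implementation details (pleiotropy correction,
  two-tailed/three-tailed blending) of heavier regulon-enrichment tools.
* Activity scores are evidence scores (signed −log10 p), so they scale
  with substrate coverage: a kinase measured with 30 substrates can reach
  larger absolute scores than one with 3. Comparisons across kinases
  should use rank- or threshold-based summaries, as the pipeline does.
* Mutation records enter associations as binary gene-level indicators;
  allele-specific effects are only captured through the dedicated hotspot
  model.
* The survival stage assumes proportional hazards and uses Wald
  intervals; non-convergent fits are flagged and excluded from the FDR
  family rather than rescued.

## A minimal end-to-end run

```{r, eval = FALSE}
sim <- sim_config(seed = 1L)
res <- run_pipeline(sim, outdir = "sigact_run")
res$benchmark$mean_auroc
head(res$associations[order(res$associations$fdr), ])
```

The run writes every fixture and result table as tab-separated text under
`outdir`; repeating it with the same seed reproduces the files
byte-identically.
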