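---
title: "Interaction-aware gene selection and direction-balance auditing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction-aware gene selection and direction-balance auditing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexbalance)
```

## The problem

Differential-expression tools score each gene marginally. In two-class
transcriptomic comparisons (tumor versus normal tissue, for instance) this
has a subtle side effect: the genes a method selects can be systematically
skewed toward one coexpression direction. A selected gene sits inside a
correlation neighborhood — other genes strongly positively or negatively
correlated with it — and a method that is "directionally biased" returns
gene sets whose neighborhoods are dominated by positive correlates. The
bias propagates: gene set enrichment run on correlation-ranked lists then
over-reports activated pathways relative to suppressed ones (or the
reverse), regardless of the underlying biology.

`coexbalance` provides two things:

1. **Interaction-aware selectors** that score gene *sets* rather than
   genes — a multivariate-AUC (mvAUC) complementary forward selection with
   a high-AUC seeded variant, and an ensemble selector combining
   univariate filtering, cross-validated recursive elimination and
   stacking.
2. **A bias-auditing framework** that quantifies, for any selection
   method, whether its genes are directionally balanced: Spearman
   correlation profiles with a strong-correlate threshold, a balance
   index, repeated preranked GSEA with leading-edge accounting, super-core
   amplification analysis, and a composite gene–pathway concordance score.

Everything runs on synthetic data with exact ground truth, so every claim
the test suite makes is checkable.

## The synthetic-data model

`simulate_expression()` uses a latent single-factor design. Each anchor
gene carries the class signal,

$$a_j = \delta\, \mathbb{1}[\text{case}_j] + \varepsilon_j,\qquad
  \varepsilon_j \sim N(0, 1),$$

and block genes couple to it: a positive-block gene is
$g = \beta a + N(0, \sigma)$, a negative-block gene is
$g = -\beta a + N(0, \sigma)$, and null genes are pure $N(0, \sigma)$
noise. The defaults — $\beta = 5$, $\delta = 2$, $\sigma = 1$, equal
50-gene positive and negative blocks, 50 + 50 samples — produce anchor
correlates of $|\rho| \approx 0.9$, a designed positive-correlate
fraction of exactly 0.5, and class-separating effects large enough that
any sensible selector finds the blocks. The single-factor construction
(rather than a Cholesky factorization of an explicit correlation matrix)
was chosen because $\beta$ then controls the attained $|\rho|$
monotonically and the sign structure is guaranteed gene by gene.

An optional `baseline` offset shifts the whole matrix; every statistic in
the package is rank-based and therefore shift-invariant, but a positive
baseline keeps class means positive so the pseudocount log2 fold change
of the rank-sum baseline is defined. The benchmark uses `baseline = 15`,
about the magnitude of log-scale expression units.

What the generator does **not** emulate: negative-binomial count noise,
library-size effects, batch structure, and correlation between blocks
beyond the shared factor. Passing tests therefore demonstrate that the
algorithms behave as specified under a clean coexpression geometry — not
that any particular biological dataset is bias-free. Count simulation is
deliberately out of scope because all selection and auditing machinery
here is rank-based.

`simulate_gene_sets()` builds matched pathway collections: half the sets
draw a `purity` fraction of members from the positive block
("designed-activated"), half from the negative block
("designed-suppressed"), with the remainder from null genes. Set names
encode the design so direction recovery is assertable.

## mvAUC and complementary selection

The oriented AUC of one gene is $\max(A, 1 - A)$ where $A$ is the
fraction of (case, control) sample pairs the gene orders correctly (ties
count one half); the orientation records which direction achieved it.

The **mvAUC** of a gene set is the mean over all case × control pairs of
the *best* credit any oriented member earns on that pair — 1 if some
member strictly orders it, 0.5 if the best member ties, 0 otherwise.
This makes complementarity literal: a candidate's marginal gain is
exactly the mass of pairs it rescues. Three consequences are used as
test invariants: singletons reduce to the oriented AUC, mvAUC is monotone
under feature addition (coverage is a union), and mvAUC dominates every
member's individual AUC. Relabeling case and control flips orientations
but changes no value.

`macfc_main()` is greedy forward selection: first pick by oriented AUC,
subsequent picks by marginal mvAUC gain, stopping at `min_gain`
(default 1e-6), mvAUC = 1, or `max_features` (default 50). Ties in the
argmax break to the lexicographically smallest gene id so traces are
platform-independent. `macfc_v2()` first retains every gene whose
oriented AUC strictly exceeds `auc_threshold` (default 0.95) as
high-confidence seeds, then adds complementary genes over the seeds'
coverage; with no seeds it reduces exactly to `macfc_main()`. The
half-credit tie rule inside the per-pair credit is the package's
operational definition of mvAUC and is isolated in one internal function.

## The ensemble selector

`autofs()` unions two branches: the top-`k` genes by one-way ANOVA F
(`univariate_rank()`), and cross-validated recursive elimination
(`recursive_eliminate()`) over an ensemble of a linear maximal-margin
classifier, a decision tree and gradient-boosted trees. Elimination
drops the gene with the lowest ensemble-averaged normalized importance
(mean of per-learner importances; the fusion rule is unweighted because
nothing more specific is warranted), scores every visited subset size by
stratified CV accuracy of the probability-averaged ensemble, and keeps
the best size, preferring smaller on ties. Inputs wider than
`rfe_max_genes` (default 50) are prefiltered by F so the drop-one loop
stays quadratic in a bounded width. A randomized search
(`n_search_iterations` draws, objective = mean stratified CV accuracy)
tunes the learners, and a logistic-regression meta-learner stacks
out-of-fold base probabilities. The reported `cv_accuracy` is the
stack's accuracy on out-of-fold meta-features — slightly optimistic for
the meta-step itself, which is acceptable because the quantity is used
comparatively, never as an unbiased generalization estimate. All
randomness derives from one seed; reruns are identical to the byte.

The univariate and recursive branch widths are independent knobs; no
balancing rule between them is imposed.

## The rank-sum baseline

`wrst_de()` is the in-scope differential-expression baseline: a
two-sided Wilcoxon rank-sum test per gene (exact null when
`n_case * n_control <= 400` and the gene is tie-free, tie-corrected
normal approximation otherwise), Benjamini–Hochberg adjustment across
genes, and `log2((mean_case + 1) / (mean_control + 1))` fold changes on
the input scale as given. External DE tables (e.g. from count-model
tools) enter through `read_de_table()` with a column mapping and are
harmonized by `harmonize_de()`, whose defaults (BH `alpha = 0.05`,
`|logFC| > 1`) are the conventional count-scale gates. The benchmark
gates its rank-sum selection on adjusted significance only
(`de_lfc_min = 0`) because fold changes on the simulated continuous
scale are shift-dependent.

## Balance statistics

`profile_target()` computes Spearman correlations of a target against
the gene universe and classifies strong correlates at `rho > 0.5` /
`rho < -0.5` — strict inequalities; genes exactly at the threshold are
excluded. The `pos_fraction` is $|PCG| / (|PCG| + |NCG|)$, `NaN` when
there are no strong correlates; NaNs are reported, never silently
dropped or coerced to 0. The correlation universe defaults to the full
matrix; the restricted "selected genes only" reading is supported via
the `universe` argument, and the choice is recorded in the output. The
`balance_index()` is the mean of defined fractions — 0.5 is perfect
balance. `discrepancy_rank()` orders targets by the focal method's
strong-correlate count minus the best other method, which is how the
most extreme targets (top 3, typically) are chosen for deep auditing.

## The enrichment engine

`rank_by_target()` ranks every other gene by Spearman correlation with
the target (ties lexicographic). `enrichment_score()` is the weighted
Kolmogorov–Smirnov statistic: hits rise by $|s|^p$ normalized over hits
(default $p = 1$; $p = 0$ recovers the classical KS statistic), misses
fall by $1/(N - k)$; the ES is the signed extremum and the leading edge
("core-enriched genes" — the two terms are equivalent here) is the
members at or before it (at or after, for negative ES). Since running
maxima occur only at hits and minima just before hits, the ES is
computed in $O(k)$ from hit positions, which is what makes repeated
permutation analysis cheap. When the two extrema tie exactly in
magnitude the positive one is reported; with continuous scores this is
a measure-zero event.

Significance uses **gene permutation** — random member sets of equal
size — because phenotype permutation is undefined for a single-target
correlation ranking. NES divides the ES by the mean |ES| of same-sign
null values; the p-value is the same-sign tail fraction; the FDR q is
sign-stratified in the standard GSEA manner, pooling null NES across the
collection. A set with no same-sign null ES has an undefined NES and is
dropped with a diagnostic. The direction gate for counting activated
versus suppressed pathways defaults to `q < 0.25` (the conventional GSEA
exploratory threshold) and is configurable.

`repeat_fraction()` reruns the collection `n_repeats` times (default 20)
under derived seeds and reports per-repeat activated fractions; a repeat
in which nothing passes the gate yields `NaN`, never 0 — failed
enrichment is missing information, not evidence of suppression.
`redundancy_flag()` single-links same-direction records whose
leading-edge Jaccard reaches 0.8, because nearly identical leading edges
usually mean synonymous or nested pathways detected repeatedly rather
than independent signals.

## Core-gene accounting and the composite score

`quantify_core()` counts leading-edge genes per direction twice: the
deduplicated union and the non-deduplicated multiset total. Genes
recurring in ≥ 2 same-direction pathways are **super-core** genes (the
recurrence threshold is 2 because "recurring across multiple pathways"
starts at two). The two accountings obey a simple amplification law: if
recurrence is confined to one direction, that direction's
non-deduplicated ratio can only move further from the deduplicated one,
with equality exactly when nothing recurs. This is a property test, not
an assumption.

`composite_score()` (version `coexbalance-composite-v1`) aggregates a
method's behavior over targets and repeats: a failed repeat contributes
0; otherwise the contribution is
$c \cdot b$ with $c = 1 - |f_{\text{pathway}} - f_{\text{gene}}|$
(concordance between the pathway-level activated fraction and the
gene-level positive fraction) and
$b = 1 - 2|f_{\text{pathway}} - 0.5|$ (directional balance). The score
lies in [0, 1], equals 1 only under perfect balance and concordance with
no failures, and is monotone nonincreasing in pathway imbalance at fixed
concordance. It is this package's own scoring rule and is labeled as
such in every output so it cannot be mistaken for any external scoring
scheme.

## The benchmark pipeline

`run_benchmark()` chains everything from one config: simulate → run each
selection method → intersect the selections into the target gene set
(sorted; an empty intersection is an error that suggests relaxing
thresholds) → balance profiles → repeated GSEA per target → core
accounting → composite score, with a manifest recording the seed and
every tunable. All randomness flows from one root seed through
documented per-stage derivations, so reruns are bit-identical — this is
asserted on file hashes in the tests.

Default problem sizes are desk-scale by design: 200 permutations, 5
repeats, at most 10 GSEA targets, and an AutoFS configuration with 3
folds, 5 search draws and a 25-gene elimination cap. These are the
package's default benchmark protocol; each is a config field, and the
20-repeat / 1000-permutation protocol is available by passing a
`gsea_config()` with those values.

## Numerical choices and degenerate inputs

* Constant genes: AUC 0.5 (up-in-case by convention), Spearman `NaN`,
  ANOVA F 0 (ranked last), all propagated rather than erroring.
* Greedy and elimination tie-breaks are lexicographic on gene id.
* `min_gain = 1e-6` stops mvAUC selection below the smallest meaningful
  pair-credit increment for any realistic pair count.
* Ratios with zero denominators are `NaN` with diagnostics.
* Duplicate gene ids, ambiguous delimiters, >2 classes, non-finite
  values: hard errors at load time; silent repair is never attempted.

## Known limitations

* The generator's Gaussian, single-factor world is favorable to every
  method; it measures algorithmic balance, not robustness to count
  noise, outliers or batch effects.
* mvAUC coverage is a set-function evaluated greedily; the trace is not
  guaranteed globally optimal beyond the cases the oracle tests cover.
* The composite score is a surrogate summary, versioned and labeled;
  comparisons are meaningful only within one scoring version.
* Single-cell scale matrices (tens of thousands of cells) are out of
  scope for the drop-one elimination loop; prefilter first.
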