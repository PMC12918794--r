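---
title: "Methods: complex-level chromatin dependency analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: complex-level chromatin dependency analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, numerical
choices, and the places where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The model

### Dependency matrices and lineage filtering

Inputs are probability-of-dependency matrices D ∈ [0,1] (cell lines ×
genes), read from DepMap-dialect CSVs whose headers may be
`"SYMBOL (ENTREZID)"`; headers are reduced to bare symbols by splitting on
the first `" ("`, and symbols are then matched case-sensitively with no
alias resolution (catalog curation is an upstream concern). Genes with any
missing value are dropped rather than imputed — a dependency probability is
a model output, not a measurement with a meaningful imputation model.
Lineages with fewer than `min_lines_per_lineage` (default 5) cell lines are
removed; non-cancerous lineages are handled by an explicit
`exclude_lineages` argument rather than any heuristic, because no reliable
in-band signal distinguishes them.

### Complex scores

S<sub>i,c</sub> is the unweighted mean of D<sub>i,g</sub> over the members
of complex c that are present in the matrix after NA filtering. Members
absent from the matrix are excluded from the mean (logged once per
complex) rather than treated as zero or causing the complex to be dropped:
the score is an average activity readout, and an unmeasured subunit
carries no information. The per-complex effective member count is recorded
so downstream consumers can weight their trust accordingly. No
stoichiometry weighting is attempted.

### One-versus-rest moderated models

For every feature (gene or complex score) a no-intercept group-means OLS
model is fitted across cell lines with one indicator per lineage. For
lineage ℓ the contrast is

  logFC<sub>ℓ</sub> = mean(ℓ) − mean(rest).

"Mean of the rest" is ambiguous in the field's usual phrasing: it can be
the **unweighted mean of the other lineages' means** (the contrast implied
by a balanced one-vs-rest contrast on a group design) or the **pooled mean
over all other cell lines** (which weights large lineages more). The
package implements both behind `rest_mean = c("of_means", "pooled")`, with
`of_means` primary: it is the contrast a no-intercept design naturally
expresses, and it prevents the handful of very large lineages from
dominating every "rest" aggregate. The contrast variance multiplier is
v<sub>ℓ</sub> = 1/n<sub>ℓ</sub> + Σ<sub>ℓ′≠ℓ</sub> 1/((L−1)² n<sub>ℓ′</sub>)
for `of_means` and 1/n<sub>ℓ</sub> + 1/(n − n<sub>ℓ</sub>) for `pooled`.

Residual variances are pooled across groups with d = n − L degrees of
freedom and shrunk toward a scaled inverse-χ² prior (d₀, s₀²) estimated by
moment matching on log s²: with e = log s² − ψ(d/2) + log(d/2), solve
ψ′(d₀/2) = Var(e) − ψ′(d/2) by Newton inversion of the trigamma function,
and recover s₀² from the mean of e. When the observed spread of
log-variances is at or below the pure-sampling spread, d₀ = ∞ and all
posterior variances equal s₀² (taken as the mean observed variance). The
estimator matches the standard limma implementation choice by choice
(sample variance of e; exact zeros offset to 10⁻⁵ × median); the test
suite checks agreement with limma on shared data to ~1e-6 in the t
statistics. Moderated t = logFC / √(s̃² v) is referred to t with d + d₀ df
(normal when d₀ = ∞); BH adjustment is applied across features **within
each lineage contrast**, not jointly across lineages — each contrast asks
its own question.

Enrichment thresholds are level-specific: genes at FDR ≤ 0.05 and
logFC ≥ 0.10 (the inclusive ≥ is used where prose elsewhere wavers between
"> 0.1" and "≥ 0.10"); complexes at FDR ≤ 0.10 and logFC > 0, strict — a
complex-level call is a screen, made at a laxer FDR but demanding a
positive effect.

### Clustering

Lineage × feature logFC matrices are row z-scored (sample sd; constant
rows dropped with a warning) and clustered agglomeratively by the
Lance–Williams recurrence on squared Euclidean distances, reporting merge
heights on the distance (square-root) scale — the `ward.D2` convention.
Ties are broken by merging the pair with the smallest cluster indices, so
the tree is deterministic under permutation of input order (heights are
permutation-invariant; the test suite asserts both and checks heights
against `hclust`).

### Differentiation states and the 1-D mixture

Signature genes are z-scored across cell lines using the **sample (n−1)
standard deviation** — the field's phrasing never states the convention;
sample sd is fixed here and documented because `scale()` and most R
workflows default to it. State scores are per-state means of those
z-scores; the melanocytic aggregate averages the melanocytic,
transitory-melanocytic and transitory states, the undifferentiated
aggregate averages the neural crest-like, undifferentiated–neural
crest-like and undifferentiated states, and the intermediate neural
crest-like–transitory state is excluded from both. DiffAxis is their
difference.

The two-component Gaussian mixture is fitted by EM with **deterministic
median-split initialization** — reproducibility is worth more here than
the marginal likelihood gains of random restarts on 1-D data, and the test
suite verifies the fit reaches the same optimum as direct BFGS
maximization on representative draws. Components are ordered μ₁ < μ₂;
standard deviations are floored at √(10⁻⁶ Var(x)); convergence is a
relative log-likelihood change < 10⁻⁸ (≤ 1000 iterations). The decision
boundary solves the weighted-density equality (a quadratic); the root
between the means is canonical, with a posterior-0.5 bisection fallback
for the rare weight/variance combinations that push both quadratic roots
outside (μ₁, μ₂). Lines are assigned by posterior membership; a tie at
exactly 0.5 goes to the higher-mean (melanocytic-like) component. Posterior
and boundary-threshold assignment agree everywhere except exactly at the
boundary, and the tests assert that.

A caution the null tests made explicit: a 2-component mixture fitted to
**unimodal** data does not return two coincident components — EM converges
to split solutions with means 1.5–2 sd apart. Absence of structure must
therefore be judged from the generator truth (planted classes carrying no
DiffAxis signal), never from component-mean proximity.

### PLS-DA

Class imbalance is handled by conditional down-sampling to at most a 3:1
ratio (majority members sampled without replacement under a derived seed);
iterations (default 100) repeat the whole procedure. Within an iteration:
zero-variance features are dropped, features are standardized **on the
retained lines only**, the number of latent variables is chosen by 5-fold
stratified cross-validated ROC AUC (fold standardization statistics come
from the training folds only; smallest k within 1e-12 of the maximum wins),
and the final NIPALS PLS1 model is fitted on all retained lines. VIP is
computed over min(2, chosen k) latent variables —
VIP<sub>j</sub> = √(p Σ<sub>a</sub> SSY<sub>a</sub> (w<sub>ja</sub>/‖w<sub>a</sub>‖)² / Σ<sub>a</sub> SSY<sub>a</sub>) —
and satisfies Σ VIP² = p per model (asserted at 1e-6). Signs come from a
ridge-penalized logistic regression (fixed λ = 10⁻³, intercept
unpenalized) on the same standardized matrix: the penalty guarantees the
coefficients exist under complete separation, which unpenalized logistic
regression does not. Signed VIPs are aggregated across iterations by
**mean** (the aggregation is not specified anywhere authoritative; mean is
primary, with sd and the frequency of passing the stringent cutoff also
reported). Cutoffs |VIP| ≥ 1 (stringent) and ≥ 0.6 (permissive) are both
inclusive. CV AUC is reported per iteration and summarized as mean ± sd
across iterations.

### Enrichment

Phenotype ranking is per-gene Spearman correlation (average ranks on
ties), ordered descending with gene-name tie-breaks for determinism. The
enrichment score is the classic weighted running-sum statistic with weight
exponent 1 (configurable); the null is **gene-sampling**: random same-size
sets drawn from the ranked genes (10,000 draws by default in pipeline use;
tests use fewer where the assertion allows), with NES = ES / mean |null ES
of matching sign| and one-sided p within sign, BH across tested sets. Set
sizes are computed on the genes present in the ranking and bounded at
15–500. Over-representation uses the one-sided upper-tail hypergeometric
test against an explicit universe; query genes outside the universe are
dropped with a warning. No attempt is made to reproduce any web service's
combined score; the adjusted hypergeometric p is the comparison surface.

### Single-cell gating

Per (cell line, marker), intensities are log-transformed — base 10, a
documented choice where "log-transformed" is all the field usually states,
recorded in the gate object — pooled across conditions and replicates, and
gated at the mixture decision boundary. Pooling across conditions is what
makes the threshold comparable between control and knockdown. Cells with
nonpositive intensity (background-subtraction artifacts) are dropped with
a logged count; a cell exactly at the threshold is **low** (strict `>` for
high). Fraction-high is reported per replicate and pooled (the pooled
value equals the cell-count-weighted replicate mean; asserted). Quadrant
fractions are computed on all cells — any down-sampling is display-only —
and sum to exactly 100 per condition. Replicate-level comparisons use
Welch's t with Welch–Satterthwaite df; when both within-group variances
are zero the standard error gets an epsilon proportional to the squared
mean scale and df falls back to n₁+n₂−2, so degenerate replicate triplets
give a finite, extreme statistic instead of NaN. Normalized cell counts
divide each replicate's count by the mean control count within the cell
line. Δ%–Δ% relationships use OLS with R² = 1 − SSres/SStot.

### Consensus differential expression

The package consumes per-line DE statistic tables (gene, log2FC, Wald
statistic, p, FDR) rather than fitting count GLMs — the negative-binomial
machinery is mature external tooling, and the contribution here is the
consensus logic. Per line, genes are flagged up/down at FDR ≤ 0.05 with a
strict sign (log2FC exactly 0 is never significant). The consensus up
(down) set contains genes flagged in that direction in **every** sensitive
line and **not** flagged in the same direction in the insensitive
reference — reference-non-significant and reference-opposite genes are
both retained; the reference uses the same FDR + sign rule as sensitive
lines. Genes absent from any sensitive table are excluded (the
intersection rule, which also subsumes per-line low-count filtering). The
merged ranking is the unweighted mean Wald statistic over the gene
intersection, descending, gene-name tie-breaks. Sample-level PCA z-scores
genes across samples and runs SVD on the transposed matrix with no further
centering or scaling (z-scoring already centers every gene); percent
variance comes from the squared singular values, and each component's sign
is fixed by making its largest-magnitude loading positive.

## The synthetic world

The generators emulate the structure the pipeline consumes, not the full
covariance of real screens:

- **Dependency**: per-gene Beta(2, 8) baselines (most genes non-essential,
  matching the right-skew of probability-of-dependency data), planted gene
  or complex effects δ added within a target lineage, Gaussian noise
  (default sd 0.1), clipping to [0, 1] with the clip rate recorded.
  Defaults — 5-ish lineages × 10 lines, δ = 0.3 — mirror the scale at
  which the acceptance criteria are stated. Not emulated: co-essentiality
  covariance between genes, batch structure, screen quality variation.
- **Expression**: signature genes of the melanocytic-side (resp.
  undifferentiated-side) states shifted ±separation/2 by class
  (default separation 3 noise-sd — clearly separated classes, the regime
  the binary classification targets), intermediate-state and non-signature
  genes pure noise.
- **Single cell**: latent high/low states per cell (condition-specific
  high fractions, default 0.85 control vs 0.25 knockdown — the magnitude
  of change seen in strong knockdown responses), lognormal emission
  (log-means 1 and 2, sd 0.15), optional cross-marker coupling, jittered
  replicate counts.
- **DE tables**: null Wald statistics standard normal, planted genes at
  |Wald| = 8 ± 1 with consistent signs in sensitive lines and null
  behavior in the reference.

A green test on this world establishes that the implementations compute
their definitions correctly and recover planted structure at realistic
effect sizes; it does not establish robustness to the correlation
structure, outliers, or annotation noise of real DepMap/CCLE data.

## Determinism

One global seed lives in the config; every stochastic stage derives a
child seed as a hash of (global seed, stage name), so adding or reordering
stages never perturbs another stage's stream, and all generators
save/restore the caller's RNG state. The full pipeline is byte-identical
across reruns under a fixed seed (asserted on every output file).

## Known limitations

- Complexes with absent members are averaged over the present ones; no
  rescaling or minimum-coverage rule is enforced beyond the recorded
  effective member count.
- The PLS-DA latent-variable count is chosen per iteration; VIP is always
  computed on min(2, k), so iterations that select k = 1 contribute
  single-LV VIPs to the aggregate.
- The gene-sampling GSEA null treats genes as exchangeable; correlated
  gene sets (co-essential modules) will appear anti-conservative relative
  to a sample-permutation null, which pre-ranked input cannot support.
- The single-cell machinery assumes two-component log-intensity mixtures;
  markers with genuinely trimodal distributions (e.g. DNA content across
  S phase) are approximated by the two-component boundary plus the
  documented inter-boundary band convention.
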