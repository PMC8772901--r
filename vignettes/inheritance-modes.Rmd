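---
title: "Classifying gene-expression inheritance in reciprocal F1 hybrids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying gene-expression inheritance in reciprocal F1 hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridexpr)
```

## The problem

When two related species are crossed, most genes in the F1 hybrid are
expressed near the mid-parent value (additive inheritance) or near one
parent's level (dominance). A minority are *transgressive*: expressed beyond
the range spanned by both parents, in either direction. Transgressive
expression is the transcriptomic signature of overdominance and of hybrid
misregulation, and its direction and consistency across the two *reciprocal*
F1 crosses (maternal and paternal species swapped) distinguishes stable
hybrid effects from cross-direction-dependent ones.

`hybridexpr` implements this analysis for the standard four-group design:
two parental lines (`PC`, `PB`) and the two reciprocal hybrids (`F1BC`,
`F1CB`), each profiled by bulk RNA-seq with a small number of biological
replicates, plus matched phenotype tables for heterosis statistics. The
motivating system is the reciprocal channel catfish x blue catfish cross,
where hybrid superiority is environment-dependent, but nothing in the code
is specific to catfish.

## Pipeline model

1. **RPKM normalization.** `compute_rpkm()` computes
   `count * 1e9 / (length_bp * library_size)`. Library sizes default to
   column sums of the count matrix because the true total-mapped-reads
   denominator is not recoverable from a count matrix; an explicit vector
   overrides this.
2. **Expressed universe.** `filter_expressed()` keeps genes whose *type-mean*
   RPKM strictly exceeds 1.0 in at least one genetic type. Operating on type
   means rather than individual samples is a deliberate choice: with two
   replicates per type, a single noisy sample should neither admit nor
   exclude a gene. Both the threshold and the strict inequality are
   configurable only through the run configuration, so they appear exactly
   once.
3. **Differential expression.** `de_pairwise()` contrasts two genetic types
   with a negative-binomial exact test (below); all six pairs of the four
   types are run by `run_pipeline()`. A gene is a DEG when
   `|log2FC| > 1.5` (strict) and the Benjamini-Hochberg adjusted p-value is
   `< 0.05` (strict). The fold change is computed on type-mean RPKM with a
   pseudocount of 1.0 (configurable), since zero means are otherwise
   undefined.
4. **Inheritance classification.** `classify_all()` applies the transgressive
   margin rule per hybrid and the concordant/discordant truth table (below).
5. **Phenotype statistics.** `pheno_statistics()` computes mid-parent
   heterosis, heterobeltiosis, and exact Mann-Whitney U tests for the six
   pairwise type comparisons per trait.

## The negative-binomial exact test

Counts are modelled NB with variance `mu + phi * mu^2`. For one gene and two
groups with `n_a` and `n_b` library-size-equalized replicates, the group sums
are NB with means `n_g * mu` and sizes `n_g / phi`. Conditioning on the total
removes `mu` from the comparison: the two-sided p-value is the summed
probability of every split of the total that is no more likely than the
observed one. Probability ties are included in the rejection mass, which is
conservative. At `phi = 0` the conditional law is exactly
binomial(total, `n_a / (n_a + n_b)`), so the Poisson limit needs no special
casing beyond the density switch.

Numerical choices: split probabilities are computed on the log scale and
normalized before summation, so totals in the tens of thousands are stable;
the tie comparison uses a relative tolerance of `1e-12`; a zero total returns
p = 1 (no information). Library-size equalization rescales each sample to
the geometric-mean library size and rounds to the nearest integer — a simple,
transparent stand-in for quantile-based adjustment that keeps the
conditioning argument valid at the scale of a two-to-three-replicate design.

The dispersion is a single *common* `phi` estimated by conditional maximum
likelihood: given a gene's within-group sum, the conditional likelihood no
longer involves the gene's mean, so one parameter is fit by `optimize()` on
the log scale over all genes and both groups, floored at zero. Tagwise
(per-gene) shrinkage estimators are deliberately omitted: with two
replicates per type they are unstable, and a common value keeps the exact
test's assumptions explicit. In tests the estimator and the exact test are
cross-checked against an independent implementation of the same qCML/exact
approach and against enumeration oracles.

## The transgressive margin rule

For each hybrid, with parental type means `p1`, `p2` and hybrid type mean
`f1` and margin `m` (default 0.2):

* **up** if `f1 >= (1 + m) * max(p1, p2)`,
* **down** if `f1 <= (1 - m) * min(p1, p2)`,
* otherwise **none**.

Both boundaries are inclusive ("at least 20%"). The rule is formalized
against the parental *envelope* (`max`/`min`); the alternative reading —
20% beyond each parent separately — coincides with it for the upward call and
for the downward call under any parent ordering, so the two readings are
identical under this formalization. When a parental bound is zero the margin
degenerates (`1.2 * 0 = 0`), so an up call additionally requires
`f1 > max(p1, p2)` and a down call `f1 < min(p1, p2)`; for positive parents
these extra conditions are implied by the margin. Consequences: with both
parents at zero, any positive hybrid expression is transgressive-up and a
down call is impossible.

The two hybrid calls combine into five classes:

| F1BC \\ F1CB | up            | down          | none          |
|--------------|---------------|---------------|---------------|
| **up**       | concordant_up | discordant_II | discordant_I  |
| **down**     | discordant_II | concordant_down | discordant_I |
| **none**     | discordant_I  | discordant_I  | non_transgressive |

Classification is restricted to the expressed universe, because the headline
fraction ("transgressive share of expressed genes") is defined on it. The
rule is applied to type-mean point estimates, exactly as in the field's
practice with two replicates; no significance test is attached to the 20%
margin. This is the rule's main statistical weakness — see *Limitations*.

Invariant properties (all tested): the five classes partition the universe;
calls are invariant to a common positive rescaling of a gene's four means
and to swapping the parental labels; raising the margin only shrinks the
transgressive set.

## Heterosis statistics

For a trait with type means `PC`, `PB`, `F1BC`, `F1CB`:

* mid-parent heterosis: `100 * (f1_mean - midparent) / midparent`, with
  `midparent = (PC + PB) / 2` and `f1_mean = (F1BC + F1CB) / 2`;
* heterobeltiosis: `100 * (f1_mean - best_parent) / best_parent`, where the
  best parent is the larger parental mean by default. The superiority
  direction is an analytic choice per trait (`larger_is_better`), not
  hard-coded biology — for a plasma stress marker, lower may be superior.

`standardize_by_length()` divides shape and weight traits by each
individual's total length before comparison, removing overall size.

The Mann-Whitney U test uses mid-ranks and, whenever
`choose(n1 + n2, n1) <= 200000`, an *exact* p-value by complete enumeration
of all group assignments; tied statistics contribute their full probability
to the tail (conservative), and the two-sided p is twice the smaller tail,
capped at 1. The cap covers the design's n = 6 vs 6 (924 assignments) with
enormous headroom; beyond it a normal approximation with tie correction is
used and labelled in the result. Exactness matters here: at n = 6 vs 6 the
smallest achievable two-sided p is 2/924, and asymptotic approximations are
unreliable at these sizes.

## The synthetic-data generator

`generate_counts()` plants one of eight inheritance modes per gene and draws
NB counts with expected count
`expression * (length_bp / 1000) * (library_size / 1e6)` — chosen so that
RPKM normalization inverts the construction in expectation, making the
generator self-verifying (a property the tests exploit). Parental separation
is geometric around a per-gene baseline; transgressive modes place hybrids
an `effect_size` factor beyond the parental envelope, with a milder
`effect_size^(1/4)` parental separation so that parental DE and
transgression are not conflated. `discordant_I` is planted transgressive-up
in F1BC only (the choice of hybrid is arbitrary but fixed and recorded in
the truth table); `discordant_II` up in F1BC and down in F1CB.

Defaults, chosen once as realistic for a liver bulk-RNA-seq design of this
kind: median baseline 30 RPKM with log-normal gene-to-gene spread
(sdlog 0.5), gene lengths uniform on 500-5000 bp, 5 million reads per
sample, 2 replicates per type, NB dispersion 0.1 (a biological-replicate
scale value; `phi = 0` gives exact Poisson sampling), effect size 2. The
default mode mix mirrors the class composition reported for the catfish
system (10,000 null; 800 additive; 400 + 400 dominant; 60 concordant-up;
925 concordant-down; 106 discordant I; 49 discordant II).

What the generator emulates: the four-type replicate structure, NB counting
noise on a realistic dynamic range, length/depth confounding of counts, and
every inheritance mode the classifier must distinguish. What it does not:
maternal and allele-specific effects, GC/length bias, batch structure,
correlated genes, or alignment artifacts. Passing the recovery tests
therefore demonstrates that the *pipeline logic* is correct under its own
model, not that real tissue data meet that model.

`generate_phenotypes()` draws individuals from normals truncated at zero
(morphometric and plasma values are physically non-negative) via rejection
sampling; `sd = 0` reproduces the group means exactly, which the tests use
to verify the heterosis arithmetic against hand-computed values.

## Validation strategy and problem sizes

Every statistical primitive is checked against an independent oracle:
complete enumeration for the Mann-Whitney and NB exact tests (totals up to
30, all splits, dispersions 0, 0.1, 0.5), a hand-written step-up rule for
BH, rank-then-Pearson for Spearman, and simulation with known truth for the
dispersion estimator and the planted-mode recovery (5,000 genes, effect 2,
dispersion 0.01, 3 replicates — conditions under which the margin rule on
type means is reliably separable). Null calibration uses 5,000 simulated
null genes at dispersion 0.1 (Kolmogorov-Smirnov distance from uniform) and
a 20-seed all-null sweep of the adjusted-p call rate. These sizes were
picked so the full suite exercises each property at meaningful resolution
while remaining quick to run.

## Limitations

* The 20% margin rule tests point estimates, not hypotheses. With two
  replicates and biological-scale dispersion, type means are noisy and the
  rule over-calls — disproportionately in the discordant I class, which
  requires only one hybrid to cross the envelope. The planted-mode recovery
  guarantees hold at low dispersion or more replicates; on noisy designs the
  discordant I count should be read as an upper bound. An optional remedy
  (replicate-level bootstrap of the calls) would change the definition and
  is intentionally not the default.
* The common-dispersion exact test does not model gene-specific dispersion;
  genes with unusually high biological variability can yield optimistic
  p-values.
* Geometric-mean library equalization with rounding is adequate at desk
  scale but is not a quantile adjustment; DEG counts on real data will not
  be bit-identical to other toolchains.
* Heterosis statistics summarize group means; they inherit whatever
  imbalance or outliers the phenotype table contains. The exact
  Mann-Whitney tests are the intended guard at these sample sizes.
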