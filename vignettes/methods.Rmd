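---
title: "Methods: Monte Carlo feature selection and rough-set rule induction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo feature selection and rough-set rule induction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery behind `allergyrules`
and the reasoning behind its default parameters.

## Decision tables

All analyses operate on a *decision table*: children (objects) in rows,
categorical attributes in columns, and a binary decision
(`affected` / `unaffected`, with `EXCLUDED` children removed from the
classified view). SNP genotypes are coded `0`/`1`/`2` as the number of
minor alleles — `2` therefore means "homozygous for the minor allele"
when the major allele is the reference. Environment and lifestyle
factors keep their natural categories (`yes`/`no`, dose bands, ...).
Missing cells are allowed everywhere and are excluded pair-wise from
discernibility and rule matching.

## Phenotype derivation with restricted reference groups

Eleven phenotypes are derived from six raw record columns (doctor's
asthma diagnosis, wheeze in the last 12 months, eczema diagnosis,
rhinoconjunctivitis symptoms, inhalant and food IgE). The subtype
phenotypes use *restricted* reference groups rather than "everyone
else": allergic asthma contrasts asthmatic-and-sensitised children
against children who are neither asthmatic nor sensitised; children
fitting neither profile are `EXCLUDED`. This keeps the contrast
interpretable at the cost of sample size — `derive_phenotypes()`
reports the per-phenotype class counts via `phenotype_counts()`.
`current_asthma_reference` controls whether current asthma is
contrasted against never-asthmatics (`"non_asthma"`, the default) or
against all children without current symptoms (`"non_current"`).

## Monte Carlo feature selection

`mcfs_ri()` builds `s` random projections of `m` attributes
(default `m = ceiling(sqrt(d))`, `s = ceiling(30 * d / m)` so that
every attribute is expected to appear about 30 times), splits each
projection `t` times into a training and test part, and grows an
information-gain decision tree on each training part. The relative
importance of attribute *a* accumulates, over every tree node ν that
splits on *a*:

wAcc^u * IG(ν) * (n(ν) / n)^v

where wAcc is the tree's class-weighted test accuracy (mean of
per-class recalls), IG(ν) the information gain of the split, and
n(ν)/n the fraction of training objects routed through the node.
Exponents `u` and `v` (default 1) sharpen or flatten the respective
contributions; raising `u` can only down-weight trees with imperfect
accuracy, never increase RI.

### Tree depth

`max_depth` defaults to 5. Deeper trees let an attribute score in many
nodes of the same tree, which inflates the null RI variance and
*raises* the significance threshold: on pure-noise tables the
familywise error stays within the nominal level at depth 5, while the
power loss relative to shallow trees is modest. Depth 3 is a good
choice when runtime matters (the planted-effect recovery analyses use
it); depth 1 (stumps) discards all interaction signal and is only
useful for debugging.

### Significance: the predictive-*t* tail

`mcfs_significance()` re-runs the whole procedure on `B ≥ 10`
label-permuted copies of the table (default `B = 50`). For each
attribute the observed RI is compared to its permutation distribution
with a *predictive* t statistic:

p = P( T_{B-1} > (RI − m̂) / (ŝ · sqrt(1 + 1/B)) )

where m̂ and ŝ are the permutation mean and standard deviation. The
`sqrt(1 + 1/B)` factor accounts for the fact that a *new* null draw,
not the null mean, is the reference — without it the test is
anti-conservative at small `B`. P-values are Bonferroni-adjusted
across the `d` attributes and compared to `alpha` (default 0.05).
Setting `alpha >= 1` turns the threshold off and reports every
attribute as significant; since adjusted p-values saturate at exactly
1, a strict cut at 1 could never do that.

`mcfs_null_validation()` offers a second guard: it appends a
label-shuffled copy of every attribute and checks that the original
attributes, not their shuffled twins, carry the significance.

## Rough-set rule induction

`induce_rules()` groups classified objects by identical attribute
profiles. A profile is *consistent* when all its objects share one
class; inconsistent profiles are counted and skipped. For each
consistent profile, the discernibility clauses against all
opposite-class profiles (the sets of attributes on which they differ)
are reduced by the Johnson greedy set-cover heuristic: repeatedly pick
the attribute covering most uncovered clauses. The reduct's attribute
values at that profile become one IF-THEN rule.

`johnson_fraction` (pipeline default 0.9) stops the greedy cover once
that fraction of clauses is covered. An exact cover (1.0) yields long,
brittle rules that memorise rare contrasts; 0.9 trades a little
discernibility for substantially shorter, better-supported rules.

Duplicate rules arising from different generator profiles are merged.
Rule statistics (support, left-hand-side matches, accuracy, class
coverage) are computed on the full table, then the `min_support` and
`min_accuracy` filters apply. Note a structural property of the
object-related approach: with few, coarse attributes and a rare
affected class, almost every profile mixes both classes and the
affected side of the model can legitimately be empty — the affected
class is then captured by rule *statistics* on candidate combinations
(below) rather than by induced classifiers.

`classify()` lets all matching rules vote with support-weighted votes
(ties broken toward the larger class prior; no matching rule means
`ABSTAIN`), and `cross_validate()` reports stratified k-fold coverage
(fraction of test children receiving a vote) and class-weighted
accuracy among covered children.

## Rule statistics and validation

- `rule_pvalue()`: hypergeometric enrichment of the rule's match set
  in the affected class, exact upper tail.
- `bonferroni()` / `bonferroni_threshold()`: family-size-controlled
  significance; a family of 220 rules at α = 0.05 gives the threshold
  2.3e-4.
- `rule_or()`: odds ratio of fulfilling the rule, from a logistic
  model (Wald CI) with a Woolf/Haldane 2×2 fallback under separation.
- `validate_rule_external()`: does the rule point in the same
  direction (OR above/below 1) in the second cohort?
- `dose_response()`: OR by number of fulfilled rule conditions,
  relative to children fulfilling none.
- `summary_report()`: averages the per-phenotype model reports into
  headline numbers (significant factors, rules, cross-validated
  coverage/accuracy per model).

## The synthetic cohort generator

`cohort_spec()` declares a cohort: size, SNP major-allele frequencies
(genotypes drawn in Hardy–Weinberg proportions), categorical
environment factors, baseline prevalences for five raw ingredients
(asthma, wheeze, eczema, rhinoconjunctivitis, sensitisation), planted
effects, and a missingness rate. Effects are expressed on the odds
scale and applied multiplicatively to the baseline odds of their
target ingredient when the child matches all effect conditions —
`main`, `gene_gene` and `gene_environment` effects differ only in
which attributes they condition on. IgE titres are generated
consistently with the sensitisation indicator so that the derived
IgE-based phenotypes agree with the planted prevalence.

Planted odds-ratio effects are one-directional, so realized
ingredient prevalence exceeds baseline in their presence;
effect-free ingredients stay within sampling noise of baseline.

`default_cohort_specs()` encodes the study design: cohort A with 2033
children and 110 SNPs, cohort B with 3113 children, 188 SNPs (the 110
shared ones plus 78) and 33 environment/lifestyle factors, eleven
derived phenotypes, and planted gene–gene and gene–environment pairs.

## Reduced problem sizes in the tests

The test suite must establish statistical behaviour (familywise error,
power, CI coverage, dose response) quickly. Where the full-scale
configuration would take hours, the tests use reduced but *measured*
configurations — e.g. OR-3 main-effect power at n = 2000 with
s = 60, B = 16 (10/10 seeds), or the planted-pair recovery chain at
n = 3000, B = 20 over 20 seeds (each component ≥ 80 % of seeds).
Tolerances were fixed from those measurements before being encoded in
the tests, not adjusted afterwards.
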