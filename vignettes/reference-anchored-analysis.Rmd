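---
title: "Reference-anchored classification of proteome regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-anchored classification of proteome regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletdep)
```

## The question the package answers

Protocols that differentiate human induced pluripotent stem cells (hiPSC)
toward pancreatic islet cells are judged by how closely the resulting cells
resemble native islets. A plain two-group comparison — encapsulated cells vs
their 2D-culture counterparts — says which proteins respond to
encapsulation, but not whether those responses are *useful*. `isletdep`
therefore anchors every comparison to the islet reference. For a protein
$p$ and condition $c$, write

$$r_{pc} = \log_2 \bar{x}_{pc} - \log_2 \bar{x}_{p,\mathrm{ISLET}}$$

for its log2 deviation from the islet level (group means are arithmetic
means of log2 abundances, i.e. geometric means of ratios). The analysis
proceeds in two steps:

1. **Baseline DEPs.** Against the islet reference, a baseline condition
   (`S5`, the endocrine-progenitor stage, or `S7`, the maturing beta-like
   stage) yields differentially expressed proteins: those with fold change
   $|r| \ge \log_2 1.5$ and an unpaired two-tailed Student's (pooled
   variance) t-test at $p \le 0.05$ on the log2 values. Both thresholds are
   inclusive; a strict-p variant is selectable because usage varies.
2. **Effect classification.** For each *effect* — a (baseline, effect
   condition) pair — each baseline DEP's movement is
   $\Delta = r_{\mathrm{effect}} - r_{\mathrm{baseline}}$. If
   $|\Delta| \ge \log_2 1.5$ and the movement points toward the islet level
   ($\operatorname{sign}\Delta = -\operatorname{sign} r_{\mathrm{baseline}}$)
   the protein is **islet-promoting**; the same magnitude away from the
   islet level is **islet-antagonizing**; smaller movements are
   **unchanged**. Independently, a protein **attains** islet-like abundance
   when its effect-condition deviation sits strictly inside the band,
   $|r_{\mathrm{effect}}| < \log_2 1.5$ — the exact complement of the DEP
   fold criterion.

The four canonical effects are `differentiation_cocktail` (S5 → S7),
`early_encapsulation` (S5 → S5_bead), `confounding` (S5 → S7_bead) and
`late_encapsulation` (S7 → S7_bead). The last two share the measured
`S7_bead` profile and differ only in the baseline against which the
movement is read; the late-encapsulation effect is assessed on the
S7-baseline DEP list, the other three on the S5-baseline list.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `fc_threshold` | 1.5 | linear fold | one threshold for DEP calling, movement and attainment alike |
| `p_threshold` | 0.05 | probability | t-test significance for DEP calling |
| `p_inclusive` | `TRUE` | — | `<=` vs `<` on the p-value |
| `adjust_p` | `FALSE` | — | optional Benjamini–Hochberg before DEP calling |
| `require_nonsignificant_attainment` | `FALSE` | — | attainment may additionally demand a non-significant islet contrast |
| `zero_var_p` | `"zero"` | — | convention for zero pooled variance (below) |

A single `fc_threshold` drives all three rules deliberately: the
classification is a geometry on the log2-vs-islet axis, and using one band
keeps "attains islet level" the complement of "is a DEP vs islets".

Attainment is fold-change-only by default. At $n = 2$–3 replicates a
non-significance requirement mostly measures power, not proximity; both
readings are exposed and the summary reports attainment against both the
DEP-set and the promoting-set denominators, since either can be of
interest.

The movement criterion is fold-change-only as well (no second t-test of
effect vs baseline); `require_movement_significance` adds one for users who
want it. A promoting protein that *overshoots* — crossing the islet level
and ending at least `fc_threshold`-fold on the far side — stays
islet-promoting but carries an `overshoot` flag, since "moved toward and
past" and "moved toward" are different biological statements.

## Numerical and degenerate-input choices

**Zero pooled variance.** With tiny replicate groups, both groups can be
exactly constant. Equal constants give $p = 1$ (no signal). Constant but
*different* groups are the limit $t \to \pm\infty$, so the default reports
$p = 0$: in noise-free data the difference is certain, and under any
continuous noise model the event has probability zero, so real data are
unaffected. The conservative alternative — an undefined p that excludes the
protein from DEP calling — is available as `zero_var_p = "undefined"`.
The default also makes noise-free synthetic studies behave sensibly:
a pipeline run on exact group means recovers exactly the planted classes.

**Missing values** are explicit `NA`s, never zeros (zeros would corrupt the
single log2 transform). Group statistics use available values only, with
`n_a`/`n_b` recording actual usage; a p-value requires at least two values
per group. The expressed-protein universe keeps proteins quantified in at
least one sample of every condition. DEPs unquantified in an effect
condition are dropped from that effect with a logged count, not imputed.

**Clustering** uses squared-Euclidean distances on complete-case proteins
(no imputation) after one log2 transform; per-protein median centering is
optional and off by default, since normalized ratio data are assumed
comparable across channels. Ward agglomeration follows the Lance–Williams
recurrence on squared-Euclidean input; merge heights are on that input
scale, i.e. twice the within-cluster sum-of-squares increase of the merge,
and are inversion-free. Ties break toward the lowest-index pair so trees
are reproducible across platforms. The condition-proximity summary
compares condition centroids to the islet centroid, with ties ordered by
condition name.

**Venn shares** are reported against each contributing set's own total
("x% of the respective protein set"), and over-representation uses the
upper-tail hypergeometric test against a caller-supplied universe and GMT
annotation sets — the package bundles no pathway database, because
knowledge-base content is neither stable nor freely redistributable.
Protein↔transcript concordance matches identifiers verbatim; mapping is
the caller's responsibility.

## What the synthetic generator emulates

`generate_study()` draws, per protein, an islet log2 mean from
$\mathcal{N}(0, 1)$, plants a baseline class (40% null, 30% up, 30% down by
default) with offsets $|r_{S5}|$ uniform on 1.2–2.5 log2 units, and plants
response classes (45% promoting / 35% antagonizing / 20% unchanged, half of
promoting attaining) for the three S5-baseline effects. Replicates default
to the (2, 2, 2, 2, 3) design across S5, S7, S5_bead, S7_bead and islets.
Observations are true mean plus $\mathcal{N}(0, \sigma)$ in log2 space
(log-normal noise, the standard model for ratio data), with
$\sigma = 0.15$ by default — a realistic replicate CV for labelled
quantitative proteomics.

Two structural points deserve emphasis:

* Because the confounding and late-encapsulation effects share the
  `S7_bead` condition, only three response classes can be planted freely;
  the late-encapsulation response is implied by the generated means. The
  truth table therefore records, for *every* effect, the label derived from
  the true means by the classification rule itself — planted labels are
  consistent with the generating means by construction — and a rejection
  step redraws the `S7_bead` deviation within its planted class until the
  implied late-encapsulation movement also clears the safety margin, where
  the class geometry permits.
* Every generating quantity keeps a configurable safety `margin` (default
  0.5 log2 units) away from $\log_2 1.5$. Identifiability is carried by
  the margin, not by classifier tuning: at zero noise recovery is exact,
  and at $\sigma = 0.15$ the nearest planted quantity sits roughly
  $3\sigma$ from the nearest decision boundary.

`generate_gradient_study()` is a separate, simpler generator for the
clustering picture: every protein is a DEP and each condition moves a fixed
fraction of the way toward the islet level (defaults 0, 0.25, 0.65, 0.9 for
S5, S7, S5_bead, S7_bead). The spacing is deliberately uneven — even
spacing would place the middle condition exactly equidistant between its
neighbours and leave its side of the dendrogram to floating-point ties.

What the generator does **not** emulate: peptide-level variation and
roll-up, isobaric-label ratio compression and channel interference, batch
effects, intensity-dependent missingness (its missingness is uniform, or
whole-condition knockouts via `inject_missingness()`), and correlated
proteins. Passing recovery tests therefore demonstrates that the analysis
chain is correct and well-calibrated under its own assumptions — not that
those assumptions hold in any particular real dataset.

## Verification strategy and problem sizes

The test suite checks every statistic against an independent route: the
pooled-variance t-test against `stats::t.test(var.equal = TRUE)` on 1 000
random group pairs; Ward merge heights against direct recomputation of the
within-cluster sum-of-squares increase from coordinates (and against
`stats::hclust(method = "ward.D")`); hypergeometric tails against
exhaustive enumeration on universes of at most 20; Venn regions against a
per-protein membership tally. End-to-end, studies of 5 000 proteins are
used for recovery (exact at zero noise; per-class recall and precision at
the default noise), 2 000-protein all-null studies over 20 seeds for false
positive calibration, and 100 small randomized studies for structural
invariants (category partition, mirror symmetry under abundance inversion,
threshold monotonicity). These sizes give stable estimates while keeping
the whole suite fast; they are knobs, not limits.

## Worked example

```{r example, eval = FALSE}
st <- generate_study(simulation_config(n_proteins = 2000, seed = 7))
bundle <- run_full_pipeline(st$matrix, st$annotation)
bundle$summaries[, c("effect", "n_deps", "n_promoting", "n_reaching_islet")]
evaluate_recovery(bundle, st$truth)$effects
cat(render_summary_report(bundle), sep = "\n")
```

## Known limitations

* No moderated-variance (empirical-Bayes) testing; at $n = 2$ the Student
  t-test is exactly what it is. The pipeline applies no multiple-testing
  correction by default, mirroring common practice for this kind of
  threshold filter; BH is one flag away.
* The classification is marginal per protein; no joint or correlated
  structure is modelled.
* Attainment and movement use point estimates of group means; no
  uncertainty is propagated into the category calls.
* The Venn partition operates on whichever promoting sets it is given;
  proteins present in only one baseline universe simply appear in that
  universe's sets.
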