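# isletdep

Reference-anchored differential proteome analysis for stem-cell-derived
islet cells.

## The problem

Quantitative (TMT-style) proteomics is routinely used to judge how far
human iPSC-derived cells have progressed toward a target cell type — here,
pancreatic islet cells differentiated in 2D culture or inside alginate
microcapsules. A direct comparison of two culture conditions tells you
which proteins respond to the intervention, but not whether those responses
move the cells *toward* the target. `isletdep` implements the
reference-anchored alternative: every contrast is normalized to native
human islets, and each differentially expressed protein (DEP) is classified
by whether a given culture "effect" pushes it toward or away from the islet
abundance level.

For protein *p* in condition *c*, let *r* = log2(mean abundance in *c*) −
log2(mean abundance in islets). The pipeline:

1. keeps proteins quantified in at least one sample of every condition;
2. calls baseline DEPs vs islets at |*r*| ≥ log2 1.5 and unpaired
   two-tailed Student's (pooled-variance) t-test p ≤ 0.05;
3. for each effect — `differentiation_cocktail` (S5→S7),
   `early_encapsulation` (S5→S5_bead), `confounding` (S5→S7_bead),
   `late_encapsulation` (S7→S7_bead) — computes the movement
   Δ = *r*(effect) − *r*(baseline) and classifies each baseline DEP as
   **islet-promoting** (|Δ| ≥ log2 1.5, toward the islet level),
   **islet-antagonizing** (same magnitude, away) or **unchanged**, flagging
   proteins that **attain** islet-like abundance (|*r*(effect)| < log2 1.5);
4. partitions islet-promoting sets across effects (Venn), runs
   hypergeometric over-representation tests against user-supplied GMT
   annotation sets, checks protein/transcript fold-change direction
   concordance, and clusters samples with Ward linkage on squared-Euclidean
   distances, summarizing each condition's centroid proximity to the islet
   reference.

A synthetic-data generator plants known baseline classes, per-effect
responses and attainment flags (with configurable safety margins around the
thresholds), so the entire chain is verifiable by parameter recovery
without any deposited dataset.

## Worked example

```r
library(isletdep)

st <- generate_study(simulation_config(n_proteins = 2000, seed = 7))
bundle <- run_full_pipeline(st$matrix, st$annotation)
bundle$summaries[, c("effect", "n_deps", "n_promoting", "n_antagonizing",
                     "n_unchanged", "n_reaching_islet")]
#>                    effect n_deps n_promoting n_antagonizing n_unchanged n_reaching_islet
#>  differentiation_cocktail   1209         547            419         243              265
#>       early_encapsulation   1209         552            425         232              277
#>               confounding   1209         516            446         247              278
#>        late_encapsulation    944         582            105         257              220
```

Of the 2 000 simulated proteins, 1 209 are DEPs between S5 cells and
islets (944 between S7 cells and islets); each row counts how that DEP set
responded to one effect — e.g. under the late-encapsulation effect 582
proteins moved ≥ 1.5-fold toward the islet level and 220 ended
indistinguishable from it. Recovery against the generator's planted truth
is exact here (noise sd 0.15, margins 0.5):

```r
evaluate_recovery(bundle, st$truth)$effects[10:12, ]
#>              effect              class n_truth n_pred recall precision
#>  late_encapsulation    islet_promoting     582    582      1         1
#>  late_encapsulation islet_antagonizing     105    105      1         1
#>  late_encapsulation          unchanged     257    257      1         1
```

Reading real data instead:

```r
mat <- read_abundance_matrix("abundance.tsv")   # proteins x samples, positive
ann <- read_sample_annotation("annotation.tsv") # sample_id, condition, replicate
bundle <- run_full_pipeline(mat, ann, output_dir = "results")
cat(render_summary_report(bundle), sep = "\n")
```

`run_full_pipeline(output_dir =)` writes every intermediate table
(contrasts, DEP lists, per-effect regulation calls, summaries, Venn
partition, dendrogram as Newick/JSON, condition proximity) plus a JSON
manifest with the thresholds and per-stage counts. The same stages are
available from a shell via `inst/scripts/isletdep.R`
(`simulate`, `filter`, `contrast`, `classify`, `venn`, `cluster`, `enrich`,
`concordance`, `all`, `report`).

See `vignettes/reference-anchored-analysis.Rmd` for the model, parameter
meanings, degenerate-input conventions and the generator's assumptions.

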