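#' The four canonical study effects
#'
#' Each effect compares an effect condition against the islet reference and
#' asks how the baseline DEP set responded. Baselines: `S5` for the
#' differentiation-cocktail, early-encapsulation and confounding effects;
#' `S7` for the late-encapsulation effect. The confounding and
#' late-encapsulation effects share the `S7_bead` effect condition but
#' differ in baseline, so the same measured profile is read against two
#' different starting points.
#'
#' @return A data.frame with columns `effect`, `baseline_condition`,
#'   `effect_condition`; one row per effect.
#' @export
canonical_effects <- function() {
  data.frame(
    effect = c("differentiation_cocktail", "early_encapsulation",
               "confounding", "late_encapsulation"),
    baseline_condition = c("S5", "S5", "S5", "S7"),
    effect_condition = c("S7", "S5_bead", "S7_bead", "S7_bead"),
    stringsAsFactors = FALSE)
}

#' Islet-level attainment
#'
#' A protein attains islet-like abundance under an effect when its
#' effect-condition abundance sits strictly inside the fold-change band
#' around the islet level: `|log2_fc| < log2(fc_threshold)` — the complement
#' of the DEP fold criterion. Optionally the t-test against islets must also
#' be non-significant (`p > p_threshold` or undefined).
#'
#' @param effect_contrast A `ContrastTable` of the effect condition vs
#'   `ISLET` (or any data.frame with `log2_fc` and `p_value`).
#' @param fc_threshold Linear fold-change threshold (default 1.5).
#' @param require_nonsignificance Also require a non-significant p-value.
#' @param p_threshold Used only when `require_nonsignificance` is `TRUE`.
#' @return Logical vector, one entry per row of `effect_contrast`.
#' @export
reaches_islet_level <- function(effect_contrast, fc_threshold = 1.5,
                                require_nonsignificance = FALSE,
                                p_threshold = 0.05) {
  within <- abs(effect_contrast$log2_fc) < log2(fc_threshold)
  if (require_nonsignificance) {
    p <- effect_contrast$p_value
    within <- within & (is.na(p) | p > p_threshold)
  }
  within
}

#' Classify a baseline DEP set's response to one effect
#'
#' For each baseline DEP the movement under the effect is
#' `delta_log2 = effect_log2_vs_islet - baseline_log2_vs_islet`. A movement
#' of at least `log2(fc_threshold)` toward the islet level (sign opposite
#' the baseline deviation) is islet-promoting; the same magnitude away from
#' it is islet-antagonizing; anything smaller is unchanged. The movement
#' criterion is fold-change only, mirroring the single stated threshold of
#' the workflow; `require_movement_significance` adds an effect-vs-baseline
#' t-test on top (needs `matrix`/`annotation`).
#'
#' Promoting proteins that overshoot — ending at least `fc_threshold`-fold
#' on the far side of the islet level — stay islet-promoting but are
#' flagged. DEPs unquantified in the effect condition are dropped with
#' their count recorded in attribute `n_dropped`.
#'
#' @param deps A `DepTable` from [call_deps()] on the baseline contrast.
#' @param baseline_contrast `ContrastTable` of the baseline condition vs
#'   `ISLET` (source of the DEP list).
#' @param effect_contrast `ContrastTable` of the effect condition vs `ISLET`.
#' @param effect Effect name (a row of [canonical_effects()]), stored in the
#'   output.
#' @param fc_threshold Linear fold-change threshold used for movement and
#'   attainment alike (default 1.5).
#' @param require_nonsignificant_attainment Passed to
#'   [reaches_islet_level()].
#' @param p_threshold Significance level for the optional significance
#'   checks.
#' @param require_movement_significance If `TRUE`, movement must also pass a
#'   Student's t-test of effect vs baseline condition.
#' @param matrix,annotation Needed only when
#'   `require_movement_significance = TRUE`.
#' @return A data.frame (class `RegulationTable`): `protein_id`, `effect`,
#'   `category` (`islet_promoting`/`islet_antagonizing`/`unchanged`),
#'   `subtype` (`from_up`/`from_down`), `baseline_log2_vs_islet`,
#'   `effect_log2_vs_islet`, `delta_log2`, `reaches_islet`, `overshoot`.
#' @export
classify_effect <- function(deps, baseline_contrast, effect_contrast,
                            effect = "effect", fc_threshold = 1.5,
                            require_nonsignificant_attainment = FALSE,
                            p_threshold = 0.05,
                            require_movement_significance = FALSE,
                            matrix = NULL, annotation = NULL) {
  if (length(effect) > 1 || is.data.frame(effect)) {
    effect <- as.data.frame(effect)$effect[1]
  }
  ids <- deps$protein_id
  if (!all(ids %in% baseline_contrast$protein_id)) {
    stop("DEP protein(s) missing from the baseline contrast", call. = FALSE)
  }
  eff_idx <- match(ids, effect_contrast$protein_id)
  quantified <- !is.na(eff_idx) & !is.na(effect_contrast$log2_fc[eff_idx])
  n_dropped <- sum(!quantified)
  if (n_dropped) {
    message(sprintf("classify_effect(%s): %d DEP(s) unquantified in the effect condition, dropped",
                    effect, n_dropped))
  }
  ids <- ids[quantified]
  base <- baseline_contrast$log2_fc[match(ids, baseline_contrast$protein_id)]
  eff <- effect_contrast$log2_fc[eff_idx[quantified]]

  lt <- log2(fc_threshold)
  delta <- eff - base
  moved <- abs(delta) >= lt
  toward <- sign(delta) == -sign(base)
  if (require_movement_significance) {
    if (is.null(matrix) || is.null(annotation)) {
      stop("movement significance needs `matrix` and `annotation`", call. = FALSE)
    }
    mv <- compute_contrast(matrix, annotation,
                           attr(effect_contrast, "cond_a"),
                           attr(baseline_contrast, "cond_a"), proteins = NULL)
    mvp <- mv$p_value[match(ids, mv$protein_id)]
    moved <- moved & !is.na(mvp) & mvp <= p_threshold
  }
  category <- ifelse(!moved, "unchanged",
                     ifelse(toward, "islet_promoting", "islet_antagonizing"))
  reaches <- reaches_islet_level(
    data.frame(log2_fc = eff,
               p_value = effect_contrast$p_value[eff_idx[quantified]]),
    fc_threshold, require_nonsignificant_attainment, p_threshold)
  overshoot <- category == "islet_promoting" &
    sign(eff) == -sign(base) & abs(eff) >= lt

  out <- data.frame(
    protein_id = ids, effect = rep_len(effect, length(ids)),
    category = category,
    subtype = ifelse(base > 0, "from_up", "from_down"),
    baseline_log2_vs_islet = base, effect_log2_vs_islet = eff,
    delta_log2 = delta, reaches_islet = reaches, overshoot = overshoot,
    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("RegulationTable", class(out))
  out
}

#' Tally one effect's regulation calls
#'
#' Counts per category, attainment, and the two headline fractions: the
#' share of islet-promoting proteins that started above islet level
#' (`fraction_promoting_from_up`) and attainment as a share of the DEP set
#' (`fraction_reaching_islet_of_deps`). Because the natural denominator of
#' attainment is debatable, the promoting-set share is reported too.
#'
#' @param calls A `RegulationTable` from [classify_effect()] (single effect).
#' @return One-row data.frame: `effect`, `n_deps`, `n_promoting`,
#'   `n_promoting_from_up`, `n_promoting_from_down`, `n_antagonizing`,
#'   `n_unchanged`, `n_reaching_islet`, `fraction_promoting_from_up`,
#'   `fraction_reaching_islet_of_deps`,
#'   `fraction_reaching_islet_of_promoting`.
#' @export
summarize_effect <- function(calls) {
  eff <- unique(calls$effect)
  if (length(eff) > 1) {
    stop("mixed effect names in one summary: ", paste(eff, collapse = ", "),
         call. = FALSE)
  }
  if (length(eff) == 0) eff <- NA_character_
  n <- nrow(calls)
  promoting <- calls$category == "islet_promoting"
  n_pro <- sum(promoting)
  n_pro_up <- sum(promoting & calls$subtype == "from_up")
  n_reach <- sum(calls$reaches_islet)
  data.frame(
    effect = eff, n_deps = n,
    n_promoting = n_pro, n_promoting_from_up = n_pro_up,
    n_promoting_from_down = n_pro - n_pro_up,
    n_antagonizing = sum(calls$category == "islet_antagonizing"),
    n_unchanged = sum(calls$category == "unchanged"),
    n_reaching_islet = n_reach,
    fraction_promoting_from_up = if (n_pro) n_pro_up / n_pro else 0,
    fraction_reaching_islet_of_deps = if (n) n_reach / n else 0,
    fraction_reaching_islet_of_promoting =
      if (n_pro) sum(calls$reaches_islet & promoting) / n_pro else 0,
    stringsAsFactors = FALSE)
}
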