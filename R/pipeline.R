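#' Run the full reference-anchored analysis
#'
#' Executes the whole chain on an abundance matrix and its annotation:
#' expressed-protein universe filter, contrasts of every cell condition
#' against the islet reference, DEP calling on the baselines (`S5`, `S7`),
#' classification of each selected effect, per-effect summaries, Venn
#' partition of the islet-promoting sets, sample clustering (squared
#' Euclidean + Ward) with condition-to-islet proximity, and optional
#' over-representation and transcript-concordance analyses. When
#' `output_dir` is given every intermediate table is written along with a
#' JSON manifest recording inputs, thresholds and row counts per stage.
#'
#' @param matrix An [abundance_matrix()].
#' @param annotation A [sample_annotation()]; must include `ISLET`.
#' @param fc_threshold,p_threshold,p_inclusive,adjust_p,zero_var_p Passed to
#'   [compute_contrast()] / [call_deps()].
#' @param effects Character vector of effect names to classify (default all
#'   four of [canonical_effects()]).
#' @param require_nonsignificant_attainment Passed to [classify_effect()].
#' @param annotation_sets Optional named list (or GMT path) of protein sets
#'   for [enrichment_test()] on each islet-promoting set.
#' @param concordance_contrast Optional second contrast table (e.g.
#'   transcripts) for [direction_concordance()] against each baseline
#'   contrast.
#' @param concordance_min_abs_log2_fc Threshold for the concordance
#'   comparison.
#' @param cluster_transform,cluster_centering Passed to
#'   [sample_distance_matrix()].
#' @param output_dir Optional directory for all result files.
#' @param seed Optional integer recorded in the manifest (the pipeline
#'   itself is deterministic).
#' @return A list of class `PipelineBundle`: `universe`, `contrasts` (per
#'   condition vs ISLET), `deps` (per baseline), `calls` (per effect),
#'   `summaries`, `venn`, `distances`, `tree`, `proximity`, optional
#'   `enrichment`/`concordance`, `manifest`.
#' @export
run_full_pipeline <- function(matrix, annotation,
                              fc_threshold = 1.5, p_threshold = 0.05,
                              p_inclusive = TRUE, adjust_p = FALSE,
                              zero_var_p = "zero",
                              effects = canonical_effects()$effect,
                              require_nonsignificant_attainment = FALSE,
                              annotation_sets = NULL,
                              concordance_contrast = NULL,
                              concordance_min_abs_log2_fc = 0,
                              cluster_transform = "log2",
                              cluster_centering = "none",
                              output_dir = NULL, seed = NULL) {
  stage <- "input validation"
  bundle <- tryCatch({
    check_matrix_annotation(matrix, annotation)
    if (!"ISLET" %in% annotation$condition) {
      stop("annotation lacks the ISLET reference condition", call. = FALSE)
    }
    eff_def <- canonical_effects()
    unknown <- setdiff(effects, eff_def$effect)
    if (length(unknown)) {
      stop("unknown effect(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    eff_def <- eff_def[eff_def$effect %in% effects, , drop = FALSE]
    if (is.character(annotation_sets) && length(annotation_sets) == 1) {
      annotation_sets <- read_gmt(annotation_sets)
    }

    stage <- "universe filter"
    universe <- filter_expressed(matrix, annotation)
    mat_u <- matrix[universe, , drop = FALSE]
    class(mat_u) <- class(matrix)

    stage <- "contrasts vs ISLET"
    cell_conds <- intersect(
      unique(c(eff_def$baseline_condition, eff_def$effect_condition)),
      annotation$condition)
    contrasts <- lapply(cell_conds, function(cc) {
      compute_contrast(mat_u, annotation, cc, "ISLET",
                       zero_var_p = zero_var_p)
    })
    names(contrasts) <- cell_conds

    stage <- "DEP calling"
    baselines <- unique(eff_def$baseline_condition)
    deps <- lapply(baselines, function(bc) {
      call_deps(contrasts[[bc]], fc_threshold, p_threshold,
                p_inclusive = p_inclusive, adjust_p = adjust_p)
    })
    names(deps) <- baselines

    stage <- "effect classification"
    calls <- lapply(seq_len(nrow(eff_def)), function(i) {
      classify_effect(deps[[eff_def$baseline_condition[i]]],
                      contrasts[[eff_def$baseline_condition[i]]],
                      contrasts[[eff_def$effect_condition[i]]],
                      effect = eff_def$effect[i],
                      fc_threshold = fc_threshold,
                      require_nonsignificant_attainment =
                        require_nonsignificant_attainment,
                      p_threshold = p_threshold)
    })
    names(calls) <- eff_def$effect
    summaries <- do.call(rbind, lapply(calls, summarize_effect))
    rownames(summaries) <- NULL

    stage <- "Venn partition"
    promoting <- lapply(calls, function(cl)
      cl$protein_id[cl$category == "islet_promoting"])
    venn <- if (length(promoting) >= 2) venn_partition(promoting) else NULL

    stage <- "clustering"
    distances <- sample_distance_matrix(mat_u, cluster_transform,
                                        cluster_centering)
    tree <- ward_linkage(distances)
    proximity <- condition_proximity_to_reference(mat_u, annotation, "ISLET",
                                                  cluster_transform,
                                                  cluster_centering)

    enrichment <- NULL
    if (!is.null(annotation_sets)) {
      stage <- "enrichment"
      enrichment <- lapply(promoting, function(q) {
        enrichment_test(intersect(q, universe), universe, annotation_sets)
      })
    }
    concordance <- NULL
    if (!is.null(concordance_contrast)) {
      stage <- "concordance"
      concordance <- lapply(contrasts[baselines], direction_concordance,
                            contrast_b = concordance_contrast,
                            min_abs_log2_fc = concordance_min_abs_log2_fc)
    }

    manifest <- list(
      package_version = as.character(utils::packageVersion("isletdep")),
      seed = seed,
      thresholds = list(fc_threshold = fc_threshold,
                        p_threshold = p_threshold,
                        p_inclusive = p_inclusive, adjust_p = adjust_p,
                        zero_var_p = zero_var_p,
                        require_nonsignificant_attainment =
                          require_nonsignificant_attainment),
      effects = eff_def$effect,
      counts = list(
        n_proteins_input = nrow(matrix),
        n_samples = ncol(matrix),
        n_universe = length(universe),
        n_deps = lapply(deps, nrow),
        n_calls = lapply(calls, nrow),
        n_dropped_in_effect = lapply(calls, attr, "n_dropped"),
        n_promoting = lapply(calls, function(cl)
          sum(cl$category == "islet_promoting"))),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

    structure(list(universe = universe, contrasts = contrasts, deps = deps,
                   calls = calls, summaries = summaries, venn = venn,
                   distances = distances, tree = tree, proximity = proximity,
                   enrichment = enrichment, concordance = concordance,
                   manifest = manifest),
              class = "PipelineBundle")
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  if (!is.null(output_dir)) write_bundle(bundle, output_dir)
  bundle
}

#' Write a pipeline bundle to disk
#'
#' @param bundle A `PipelineBundle`.
#' @param output_dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_bundle <- function(bundle, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(bundle$universe, file.path(output_dir, "universe.txt"))
  for (cc in names(bundle$contrasts)) {
    write_results(bundle$contrasts[[cc]],
                  file.path(output_dir, sprintf("contrast_%s_vs_ISLET.tsv", cc)))
  }
  for (bc in names(bundle$deps)) {
    write_results(bundle$deps[[bc]],
                  file.path(output_dir, sprintf("deps_%s.tsv", bc)))
  }
  for (ef in names(bundle$calls)) {
    write_results(bundle$calls[[ef]],
                  file.path(output_dir, sprintf("regulation_%s.tsv", ef)))
  }
  write_results(bundle$summaries,
                file.path(output_dir, "effect_summaries.tsv"))
  write_results(bundle$summaries,
                file.path(output_dir, "effect_summaries.json"), "json")
  if (!is.null(bundle$venn)) {
    jsonlite::write_json(
      list(counts = as.list(bundle$venn$counts),
           per_set_totals = as.list(bundle$venn$per_set_totals),
           regions = bundle$venn$regions, shares = bundle$venn$shares),
      file.path(output_dir, "venn.json"),
      dataframe = "rows", digits = NA, auto_unbox = TRUE)
  }
  writeLines(linkage_newick(bundle$tree),
             file.path(output_dir, "dendrogram.nwk"))
  linkage_json(bundle$tree, file.path(output_dir, "dendrogram.json"))
  write_results(bundle$proximity,
                file.path(output_dir, "condition_proximity.tsv"))
  for (ef in names(bundle$enrichment)) {
    write_results(bundle$enrichment[[ef]],
                  file.path(output_dir, sprintf("enrichment_%s.tsv", ef)))
  }
  if (!is.null(bundle$concordance)) {
    jsonlite::write_json(bundle$concordance,
                         file.path(output_dir, "concordance.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  jsonlite::write_json(bundle$manifest, file.path(output_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(output_dir)
}

#' Render a human-readable summary report
#'
#' Markdown report of the per-effect tallies with percentages recomputed
#' from the counts in the bundle (nothing is report-only arithmetic), plus
#' the condition-to-islet proximity ordering and Venn counts when present.
#'
#' @param bundle A `PipelineBundle` from [run_full_pipeline()].
#' @param path Optional file to write the report to.
#' @return Character vector of markdown lines (invisibly when written).
#' @export
render_summary_report <- function(bundle, path = NULL) {
  missing <- setdiff(c("summaries", "proximity", "manifest"),
                     names(Filter(Negate(is.null), bundle)))
  if (length(missing)) {
    stop("incomplete bundle; missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pct <- function(num, den) if (den > 0) sprintf("%.1f%%", 100 * num / den) else "-"
  lines <- c("# Reference-anchored proteome analysis report", "",
             sprintf("Universe: %d proteins across %d samples.",
                     bundle$manifest$counts$n_universe,
                     bundle$manifest$counts$n_samples), "",
             "## Effect summaries", "",
             paste("| effect | DEPs | promoting (from up / from down) |",
                   "antagonizing | unchanged | reaching islet level |"),
             "|---|---|---|---|---|---|")
  s <- bundle$summaries
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, sprintf(
      "| %s | %d | %d = %s (%d / %d) | %d = %s | %d = %s | %d = %s of DEPs |",
      s$effect[i], s$n_deps[i],
      s$n_promoting[i], pct(s$n_promoting[i], s$n_deps[i]),
      s$n_promoting_from_up[i], s$n_promoting_from_down[i],
      s$n_antagonizing[i], pct(s$n_antagonizing[i], s$n_deps[i]),
      s$n_unchanged[i], pct(s$n_unchanged[i], s$n_deps[i]),
      s$n_reaching_islet[i], pct(s$n_reaching_islet[i], s$n_deps[i])))
  }
  lines <- c(lines, "", "## Condition proximity to the islet reference", "",
             "| condition | squared distance of centroids |", "|---|---|",
             sprintf("| %s | %.4g |", bundle$proximity$condition,
                     bundle$proximity$distance))
  if (!is.null(bundle$venn)) {
    lines <- c(lines, "", "## Venn partition of islet-promoting sets", "",
               "| region | proteins |", "|---|---|",
               sprintf("| %s | %d |", names(bundle$venn$counts),
                       bundle$venn$counts))
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Score pipeline output against planted truth
#'
#' Per-class recall and precision of the recovered baseline DEP classes,
#' per-effect response classes and attainment flags, measured against the
#' truth table of [generate_study()]. A protein whose truth label for an
#' effect is defined but which the pipeline did not call counts against
#' recall of its class; a call on a truth-undefined protein counts against
#' precision.
#'
#' @param bundle A `PipelineBundle` from [run_full_pipeline()].
#' @param truth The `truth` data.frame of a `SyntheticStudy`.
#' @return List: `baseline` (per baseline condition and class), `effects`
#'   (per effect and class), `attainment` (per effect: agreement and flag
#'   recall/precision over proteins labelled by both).
#' @export
evaluate_recovery <- function(bundle, truth) {
  prf <- function(truth_lab, pred_lab, classes) {
    do.call(rbind, lapply(classes, function(cl) {
      tp <- sum(truth_lab == cl & pred_lab == cl, na.rm = TRUE)
      nt <- sum(truth_lab == cl, na.rm = TRUE)
      np <- sum(pred_lab == cl, na.rm = TRUE)
      data.frame(class = cl, n_truth = nt, n_pred = np,
                 recall = if (nt) tp / nt else NA_real_,
                 precision = if (np) tp / np else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  ids <- truth$protein_id

  baseline <- do.call(rbind, lapply(names(bundle$deps), function(bc) {
    dep <- bundle$deps[[bc]]
    pred <- rep("null", length(ids))
    pred[match(dep$protein_id, ids)] <- dep$direction
    pred[pred == "up"] <- "dep_up"; pred[pred == "down"] <- "dep_down"
    truth_cl <- truth[[paste0("class_", tolower(bc))]]
    cbind(baseline = bc, prf(truth_cl, pred, c("dep_up", "dep_down", "null")))
  }))

  effects <- NULL; attainment <- NULL
  for (ef in names(bundle$calls)) {
    calls <- bundle$calls[[ef]]
    pred <- rep(NA_character_, length(ids))
    pred[match(calls$protein_id, ids)] <- calls$category
    truth_cl <- truth[[paste0("response_", ef)]]
    effects <- rbind(effects,
                     cbind(effect = ef,
                           prf(truth_cl, pred,
                               c("islet_promoting", "islet_antagonizing",
                                 "unchanged"))))
    pred_fl <- rep(NA, length(ids))
    pred_fl[match(calls$protein_id, ids)] <- calls$reaches_islet
    truth_fl <- truth[[paste0("attain_", ef)]]
    both <- !is.na(pred_fl) & !is.na(truth_fl)
    tp <- sum(both & pred_fl & truth_fl)
    attainment <- rbind(attainment, data.frame(
      effect = ef, n_compared = sum(both),
      agreement = if (any(both)) mean(pred_fl[both] == truth_fl[both]) else NA_real_,
      recall = if (sum(both & truth_fl)) tp / sum(both & truth_fl) else NA_real_,
      precision = if (sum(both & pred_fl)) tp / sum(both & pred_fl) else NA_real_,
      stringsAsFactors = FALSE))
  }
  rownames(baseline) <- rownames(effects) <- rownames(attainment) <- NULL
  list(baseline = baseline, effects = effects, attainment = attainment)
}
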