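#' Configuration for the synthetic study generator
#'
#' Defaults mirror the study design the analysis assumes: five condition
#' groups with replicates (2, 2, 2, 2, 3), log-normal abundances (Normal in
#' log2 space), and planted regulation classes whose generating deviations
#' keep a safety `margin` (in log2 units) clear of every threshold the
#' classifier uses, so zero-noise recovery is exact by construction — the
#' margin, not the classifier, carries the identifiability burden.
#'
#' @param n_proteins Number of proteins.
#' @param replicates Named integer vector of replicates per condition.
#' @param class_proportions Proportions of baseline classes
#'   `null`/`dep_up`/`dep_down` (vs islet, at `S5`); must sum to 1.
#' @param effect_class_proportions Proportions of planted per-effect
#'   responses `islet_promoting`/`islet_antagonizing`/`unchanged`.
#' @param attainment_fraction Fraction of islet-promoting responses planted
#'   to land inside the islet-attainment band.
#' @param baseline_islet_log2_mean,baseline_islet_log2_sd Distribution of
#'   per-protein islet log2 abundance.
#' @param dep_log2_offset_range Range of baseline |log2| deviations from the
#'   islet level for DEP proteins; lower bound must clear
#'   `log2(fc_threshold) + margin`.
#' @param effect_shift_log2_range Range of planted away-from-islet shift
#'   magnitudes (log2).
#' @param margin Safety margin (log2 units) kept between every generating
#'   quantity and `log2(fc_threshold)`.
#' @param fc_threshold The fold-change threshold geometry the margins refer
#'   to (default 1.5).
#' @param noise_sd_log2 Replicate noise sd in log2 space.
#' @param missing_rate Uniform missingness rate in [0, 1); each protein is
#'   guaranteed to keep at least one value per condition (condition
#'   knockouts are produced only by [inject_missingness()]).
#' @param seed Integer seed; identical seeds give identical studies.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_proteins = 5000,
                              replicates = c(S5 = 2, S7 = 2, S5_bead = 2,
                                             S7_bead = 2, ISLET = 3),
                              class_proportions = c(null = 0.4, dep_up = 0.3,
                                                    dep_down = 0.3),
                              effect_class_proportions =
                                c(islet_promoting = 0.45,
                                  islet_antagonizing = 0.35,
                                  unchanged = 0.20),
                              attainment_fraction = 0.5,
                              baseline_islet_log2_mean = 0,
                              baseline_islet_log2_sd = 1,
                              dep_log2_offset_range = c(1.2, 2.5),
                              effect_shift_log2_range = c(1.2, 2.2),
                              margin = 0.5,
                              fc_threshold = 1.5,
                              noise_sd_log2 = 0.15,
                              missing_rate = 0,
                              seed = 1L) {
  stopifnot(n_proteins >= 1, noise_sd_log2 >= 0,
            missing_rate >= 0, missing_rate < 1,
            margin >= 0, fc_threshold > 1,
            attainment_fraction >= 0, attainment_fraction <= 1)
  if (!all(names(replicates) %in% islet_conditions()) ||
      !"ISLET" %in% names(replicates) || any(replicates < 2)) {
    stop("replicates must cover ISLET and use >= 2 per condition", call. = FALSE)
  }
  if (abs(sum(class_proportions) - 1) > 1e-9 ||
      !setequal(names(class_proportions), c("null", "dep_up", "dep_down"))) {
    stop("class_proportions must be named null/dep_up/dep_down and sum to 1",
         call. = FALSE)
  }
  if (abs(sum(effect_class_proportions) - 1) > 1e-9 ||
      !setequal(names(effect_class_proportions),
                c("islet_promoting", "islet_antagonizing", "unchanged"))) {
    stop("effect_class_proportions must be named islet_promoting/islet_antagonizing/unchanged and sum to 1",
         call. = FALSE)
  }
  lt <- log2(fc_threshold)
  if (diff(dep_log2_offset_range) < 0 || diff(effect_shift_log2_range) < 0) {
    stop("interval bounds must be ordered", call. = FALSE)
  }
  if (dep_log2_offset_range[1] <= lt + margin ||
      effect_shift_log2_range[1] <= lt + margin) {
    stop(sprintf("offset/shift lower bounds must exceed log2(fc_threshold) + margin = %.3f",
                 lt + margin), call. = FALSE)
  }
  if (attainment_fraction > 0 && dep_log2_offset_range[1] < 2 * lt) {
    stop("attainment band incompatible with offsets: need dep offsets >= 2*log2(fc_threshold)",
         call. = FALSE)
  }
  structure(list(n_proteins = as.integer(n_proteins), replicates = replicates,
                 class_proportions = class_proportions,
                 effect_class_proportions = effect_class_proportions,
                 attainment_fraction = attainment_fraction,
                 baseline_islet_log2_mean = baseline_islet_log2_mean,
                 baseline_islet_log2_sd = baseline_islet_log2_sd,
                 dep_log2_offset_range = dep_log2_offset_range,
                 effect_shift_log2_range = effect_shift_log2_range,
                 margin = margin, fc_threshold = fc_threshold,
                 noise_sd_log2 = noise_sd_log2, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

set_generator_seed <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
}

runif_sign <- function(n) sample(c(-1, 1), n, replace = TRUE)

# Deviation (log2 vs islet) of an effect condition, given the baseline
# deviation b and the planted response class, honoring the safety margins.
draw_effect_dev <- function(b, cls, attain, cfg) {
  lt <- log2(cfg$fc_threshold); m <- cfg$margin
  n <- length(b)
  e <- numeric(n)
  pro_a <- cls == "islet_promoting" & attain
  pro_n <- cls == "islet_promoting" & !attain
  ant <- cls == "islet_antagonizing"
  unc <- cls == "unchanged"
  e[pro_a] <- stats::runif(sum(pro_a), -(lt - m), lt - m)
  if (any(pro_n)) {
    bb <- b[pro_n]
    # same-side landing is only feasible when the baseline deviation leaves
    # room for both the movement and the attainment margins; otherwise the
    # protein overshoots to the far side of the islet level
    feasible <- abs(bb) >= 2 * (lt + m)
    same <- feasible & stats::runif(sum(pro_n)) < 0.5
    ee <- -sign(bb) * stats::runif(sum(pro_n), lt + m, lt + m + 0.5)
    if (any(same)) {
      ee[same] <- sign(bb[same]) *
        stats::runif(sum(same), lt + m, abs(bb[same]) - (lt + m))
    }
    e[pro_n] <- ee
  }
  e[ant] <- b[ant] + sign(b[ant]) *
    stats::runif(sum(ant), cfg$effect_shift_log2_range[1],
                 cfg$effect_shift_log2_range[2])
  e[unc] <- b[unc] + stats::runif(sum(unc), -(lt - m), lt - m)
  e
}

# Classification rule applied to true means: the truth labels the generator
# emits are exactly what a noise-free analysis must recover.
derive_response <- function(baseline_dev, effect_dev, fc_threshold) {
  lt <- log2(fc_threshold)
  delta <- effect_dev - baseline_dev
  out <- rep(NA_character_, length(baseline_dev))
  is_dep <- abs(baseline_dev) >= lt
  moved <- abs(delta) >= lt
  toward <- sign(delta) == -sign(baseline_dev)
  out[is_dep & !moved] <- "unchanged"
  out[is_dep & moved & toward] <- "islet_promoting"
  out[is_dep & moved & !toward] <- "islet_antagonizing"
  out
}

derive_baseline_class <- function(dev, fc_threshold) {
  lt <- log2(fc_threshold)
  ifelse(abs(dev) < lt, "null", ifelse(dev > 0, "dep_up", "dep_down"))
}

#' Generate a synthetic abundance study with planted truth
#'
#' Draws per-protein islet log2 means, plants baseline DEP classes (the S5
#' deviation from islet), plants response classes for the three S5-baseline
#' effects (differentiation cocktail, early encapsulation, confounding), and
#' derives the condition means. Because the confounding and
#' late-encapsulation effects share the `S7_bead` condition, the
#' late-encapsulation response is implied by the generated means rather than
#' planted freely; a rejection step redraws the `S7_bead` deviation (within
#' its planted confounding class) until the implied late-encapsulation
#' movement also respects the safety margin, where feasible.
#'
#' The emitted truth table records, for every effect, the label derived from
#' the true means by the classification rule itself (`NA` for proteins that
#' are not baseline DEPs of that effect), so planted classes are consistent
#' with the generating means by construction.
#'
#' Observations are true log2 mean + Normal(0, `noise_sd_log2`),
#' exponentiated to linear scale. With `missing_rate > 0` cells are dropped
#' uniformly, always keeping at least one value per protein and condition.
#'
#' @param config A [simulation_config()].
#' @return List of class `SyntheticStudy`: `matrix`
#'   ([abundance_matrix()]), `annotation` ([sample_annotation()]), `truth`
#'   (data.frame), `config`.
#' @export
generate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  set_generator_seed(cfg$seed)
  n <- cfg$n_proteins
  lt <- log2(cfg$fc_threshold); m <- cfg$margin
  pid <- sprintf("P%05d", seq_len(n))

  mu_islet <- stats::rnorm(n, cfg$baseline_islet_log2_mean,
                           cfg$baseline_islet_log2_sd)
  cls5 <- sample(names(cfg$class_proportions), n, replace = TRUE,
                 prob = cfg$class_proportions)
  b5 <- stats::runif(n, -(lt - m), lt - m)
  is_dep <- cls5 != "null"
  nd <- sum(is_dep)
  if (nd) {
    off <- stats::runif(nd, cfg$dep_log2_offset_range[1],
                        cfg$dep_log2_offset_range[2])
    b5[is_dep] <- ifelse(cls5[is_dep] == "dep_up", off, -off)
  }

  plant <- function(nn) {
    cls <- sample(names(cfg$effect_class_proportions), nn, replace = TRUE,
                  prob = cfg$effect_class_proportions)
    attain <- cls == "islet_promoting" &
      stats::runif(nn) < cfg$attainment_fraction
    list(cls = cls, attain = attain)
  }
  # condition deviations start at the baseline (null proteins stay there)
  dev <- list(S5 = b5, S7 = b5, S5_bead = b5, S7_bead = b5)
  cf_plan <- NULL
  if (nd) {
    bb <- b5[is_dep]
    dc <- plant(nd); ee <- plant(nd); cf <- plant(nd)
    dev$S7[is_dep] <- draw_effect_dev(bb, dc$cls, dc$attain, cfg)
    dev$S5_bead[is_dep] <- draw_effect_dev(bb, ee$cls, ee$attain, cfg)
    dev$S7_bead[is_dep] <- draw_effect_dev(bb, cf$cls, cf$attain, cfg)
    # keep the implied late-encapsulation movement clear of the threshold
    # band for proteins that are S7-baseline DEPs
    for (iter in seq_len(100)) {
      b7 <- dev$S7[is_dep]
      dl <- abs(dev$S7_bead[is_dep] - b7)
      bad <- abs(b7) >= lt & dl > lt - m & dl < lt + m
      if (!any(bad)) break
      redraw <- draw_effect_dev(bb[bad], cf$cls[bad], cf$attain[bad], cfg)
      dev$S7_bead[is_dep][bad] <- redraw
    }
    cf_plan <- cf
  }

  truth <- data.frame(
    protein_id = pid,
    class_s5 = derive_baseline_class(dev$S5, cfg$fc_threshold),
    class_s7 = derive_baseline_class(dev$S7, cfg$fc_threshold),
    true_islet_log2_mean = mu_islet,
    dev_S5 = dev$S5, dev_S7 = dev$S7,
    dev_S5_bead = dev$S5_bead, dev_S7_bead = dev$S7_bead,
    stringsAsFactors = FALSE)
  eff_def <- canonical_effects()
  for (i in seq_len(nrow(eff_def))) {
    bdev <- dev[[eff_def$baseline_condition[i]]]
    edev <- dev[[eff_def$effect_condition[i]]]
    resp <- derive_response(bdev, edev, cfg$fc_threshold)
    attain <- ifelse(is.na(resp), NA, abs(edev) < lt)
    truth[[paste0("response_", eff_def$effect[i])]] <- resp
    truth[[paste0("attain_", eff_def$effect[i])]] <- attain
  }

  conds <- names(cfg$replicates)
  sample_id <- unlist(lapply(conds, function(cc)
    paste0(cc, "_", seq_len(cfg$replicates[[cc]]))))
  condition <- rep(conds, times = cfg$replicates)
  replicate <- unlist(lapply(cfg$replicates, seq_len), use.names = FALSE)
  annotation <- sample_annotation(sample_id, condition, replicate)

  dev$ISLET <- rep(0, n)
  logmat <- matrix(NA_real_, n, length(sample_id),
                   dimnames = list(pid, sample_id))
  for (j in seq_along(sample_id)) {
    mu <- mu_islet + dev[[condition[j]]]
    logmat[, j] <- mu + stats::rnorm(n, 0, cfg$noise_sd_log2)
  }
  values <- 2^logmat

  if (cfg$missing_rate > 0) {
    drop <- matrix(stats::runif(length(values)) < cfg$missing_rate,
                   n, ncol(values))
    for (cc in conds) {
      cols <- which(condition == cc)
      allgone <- rowSums(!drop[, cols, drop = FALSE]) == 0
      if (any(allgone)) {
        keep_col <- cols[sample.int(length(cols), sum(allgone), replace = TRUE)]
        drop[cbind(which(allgone), keep_col)] <- FALSE
      }
    }
    values[drop] <- NA_real_
  }

  structure(list(matrix = abundance_matrix(values), annotation = annotation,
                 truth = truth, config = cfg),
            class = "SyntheticStudy")
}

#' Inject missing values into an abundance matrix
#'
#' `uniform` mode drops cells independently at `rate`. `condition_knockout`
#' removes every value of one (randomly chosen) condition for a `rate`
#' fraction of proteins, creating proteins the expressed-universe filter
#' must exclude; it requires the sample annotation.
#'
#' @param matrix An [abundance_matrix()].
#' @param rate Missingness rate (uniform) or knocked-out protein fraction
#'   (condition_knockout); in [0, 1).
#' @param mode `"uniform"` or `"condition_knockout"`.
#' @param seed Integer seed.
#' @param annotation Required for `condition_knockout`.
#' @return List: `matrix` (with injected `NA`s) and `log` — the dropped
#'   (protein, sample) pairs for uniform mode, or the (protein, condition)
#'   knockouts.
#' @export
inject_missingness <- function(matrix, rate,
                               mode = c("uniform", "condition_knockout"),
                               seed = 1L, annotation = NULL) {
  mode <- match.arg(mode)
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)", call. = FALSE)
  set_generator_seed(seed)
  values <- unclass(matrix)
  if (mode == "uniform") {
    drop <- matrix(stats::runif(length(values)) < rate,
                   nrow(values), ncol(values))
    idx <- which(drop & !is.na(values), arr.ind = TRUE)
    values[drop] <- NA_real_
    log <- data.frame(protein_id = rownames(values)[idx[, 1]],
                      sample_id = colnames(values)[idx[, 2]],
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(annotation)) {
      stop("condition_knockout needs `annotation`", call. = FALSE)
    }
    check_matrix_annotation(matrix, annotation)
    hit <- which(stats::runif(nrow(values)) < rate)
    conds <- unique(annotation$condition)
    ko_cond <- if (length(hit)) conds[sample.int(length(conds), length(hit),
                                                 replace = TRUE)] else character(0)
    for (k in seq_along(hit)) {
      cols <- annotation$sample_id[annotation$condition == ko_cond[k]]
      values[hit[k], cols] <- NA_real_
    }
    log <- data.frame(protein_id = rownames(values)[hit],
                      condition = ko_cond, stringsAsFactors = FALSE)
  }
  list(matrix = abundance_matrix(values), log = log)
}

#' Generate a planted-gradient study for clustering checks
#'
#' Every protein is a DEP at baseline; each condition moves a fixed fraction
#' of the way from the baseline deviation toward the islet level
#' (`dev_c = b * (1 - fraction_c)`). With the default fractions the planted
#' order of proximity to islets is `S7_bead < S5_bead < S7 < S5`, emulating
#' a design in which encapsulated populations sit nearest the reference.
#' The default spacing is deliberately uneven so no condition centroid is
#' equidistant between two others (even spacing would leave the middle
#' condition's cluster side to floating-point ties).
#'
#' @param n_proteins Number of proteins.
#' @param shift_fractions Named toward-islet fractions in [0, 1] for the
#'   four cell conditions.
#' @param replicates Replicates per condition.
#' @param noise_sd_log2 Replicate noise sd (log2).
#' @param baseline_islet_log2_mean,baseline_islet_log2_sd,dep_log2_offset_range
#'   As in [simulation_config()].
#' @param seed Integer seed.
#' @return List of class `SyntheticStudy`: `matrix`, `annotation`,
#'   `shift_fractions`.
#' @export
generate_gradient_study <- function(n_proteins = 1000,
                                    shift_fractions = c(S5 = 0, S7 = 0.25,
                                                        S5_bead = 0.65,
                                                        S7_bead = 0.9),
                                    replicates = c(S5 = 2, S7 = 2,
                                                   S5_bead = 2, S7_bead = 2,
                                                   ISLET = 3),
                                    noise_sd_log2 = 0.15,
                                    baseline_islet_log2_mean = 0,
                                    baseline_islet_log2_sd = 1,
                                    dep_log2_offset_range = c(1.2, 2.5),
                                    seed = 1L) {
  stopifnot(all(shift_fractions >= 0), all(shift_fractions <= 1),
            all(names(shift_fractions) %in% islet_conditions()))
  set_generator_seed(seed)
  pid <- sprintf("P%05d", seq_len(n_proteins))
  mu <- stats::rnorm(n_proteins, baseline_islet_log2_mean,
                     baseline_islet_log2_sd)
  b <- runif_sign(n_proteins) * stats::runif(n_proteins,
                                             dep_log2_offset_range[1],
                                             dep_log2_offset_range[2])
  conds <- names(replicates)
  sample_id <- unlist(lapply(conds, function(cc)
    paste0(cc, "_", seq_len(replicates[[cc]]))))
  condition <- rep(conds, times = replicates)
  annotation <- sample_annotation(sample_id, condition,
                                  unlist(lapply(replicates, seq_len),
                                         use.names = FALSE))
  values <- matrix(NA_real_, n_proteins, length(sample_id),
                   dimnames = list(pid, sample_id))
  for (j in seq_along(sample_id)) {
    cc <- condition[j]
    devj <- if (cc == "ISLET") 0 else b * (1 - shift_fractions[[cc]])
    values[, j] <- 2^(mu + devj + stats::rnorm(n_proteins, 0, noise_sd_log2))
  }
  structure(list(matrix = abundance_matrix(values), annotation = annotation,
                 shift_fractions = shift_fractions, seed = as.integer(seed)),
            class = "SyntheticStudy")
}

#' Write a synthetic study to the standard file formats
#'
#' Emits the abundance TSV, annotation TSV and (when present) truth TSV.
#'
#' @param study A `SyntheticStudy` from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "abundance.tsv"),
             annotation = file.path(dir, "annotation.tsv"))
  write_abundance_matrix(study$matrix, paths[["matrix"]])
  write_sample_annotation(study$annotation, paths[["annotation"]])
  if (!is.null(study$truth)) {
    paths[["truth"]] <- file.path(dir, "truth.tsv")
    write_results(study$truth, paths[["truth"]], "tsv")
  }
  invisible(paths)
}
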