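#' Restrict to the expressed-protein universe
#'
#' Keeps the proteins quantified (non-missing) in at least one sample of
#' every condition present in the annotation. This is the protein-universe
#' filter applied before any contrast; proteins failing it cannot be
#' compared against every group.
#'
#' @param matrix An [abundance_matrix()].
#' @param annotation A [sample_annotation()] covering all matrix samples.
#' @return Character vector of retained protein ids, in matrix order.
#' @export
filter_expressed <- function(matrix, annotation) {
  check_matrix_annotation(matrix, annotation)
  keep <- rep(TRUE, nrow(matrix))
  for (cond in unique(annotation$condition)) {
    cols <- condition_samples(annotation, cond)
    keep <- keep & rowSums(!is.na(matrix[, cols, drop = FALSE])) >= 1
  }
  rownames(matrix)[keep]
}

#' Per-protein contrast between two conditions
#'
#' Log2-transforms the abundances once, then per protein computes group
#' means, the log2 fold change `mean_a - mean_b`, and an unpaired two-tailed
#' Student's t-test (pooled variance) on the log2 values. Missing values are
#' simply dropped; `n_a`/`n_b` record the values actually used. A p-value is
#' defined only when both groups retain at least two values.
#'
#' Degenerate variance: when the pooled variance is exactly zero the t
#' statistic is not finite. With `zero_var_p = "zero"` (default) a zero
#' difference gives p = 1 and a nonzero difference gives p = 0 (the limit of
#' the statistic); `"undefined"` instead marks the nonzero-difference case
#' as `NA`, which excludes it from DEP calling.
#'
#' @param matrix An [abundance_matrix()].
#' @param annotation A [sample_annotation()].
#' @param cond_a,cond_b Condition labels from [islet_conditions()].
#' @param proteins Optional protein-id subset (e.g. the expressed universe).
#' @param zero_var_p Convention for zero pooled variance with a nonzero
#'   mean difference: `"zero"` or `"undefined"`.
#' @return A data.frame (class `ContrastTable`) with columns `protein_id`,
#'   `mean_log2_a`, `mean_log2_b`, `log2_fc`, `t_statistic`, `p_value`,
#'   `n_a`, `n_b`; attributes `cond_a`, `cond_b`.
#' @export
compute_contrast <- function(matrix, annotation, cond_a, cond_b,
                             proteins = NULL,
                             zero_var_p = c("zero", "undefined")) {
  zero_var_p <- match.arg(zero_var_p)
  check_matrix_annotation(matrix, annotation)
  if (!is.null(proteins)) {
    missing_ids <- setdiff(proteins, rownames(matrix))
    if (length(missing_ids)) {
      stop("proteins absent from matrix: ",
           paste(utils::head(missing_ids, 3), collapse = ", "), call. = FALSE)
    }
    matrix <- matrix[proteins, , drop = FALSE]
  }
  la <- log2(matrix[, condition_samples(annotation, cond_a), drop = FALSE])
  lb <- log2(matrix[, condition_samples(annotation, cond_b), drop = FALSE])

  stat <- function(x) {
    n <- as.integer(rowSums(!is.na(x)))
    m <- rowMeans(x, na.rm = TRUE)
    m[n == 0] <- NA_real_
    ss <- rowSums((x - m)^2, na.rm = TRUE)
    list(n = n, mean = m, ss = ss)
  }
  a <- stat(la)
  b <- stat(lb)

  fc <- a$mean - b$mean
  df <- a$n + b$n - 2L
  ok <- a$n >= 2L & b$n >= 2L
  pooled <- ifelse(ok, (a$ss + b$ss) / pmax(df, 1L), NA_real_)
  se <- sqrt(pooled * (1 / a$n + 1 / b$n))
  tstat <- fc / se
  p <- 2 * stats::pt(-abs(tstat), df)
  zerovar <- ok & pooled == 0
  p[zerovar & fc == 0] <- 1
  p[zerovar & fc != 0] <- if (zero_var_p == "zero") 0 else NA_real_
  p[!ok] <- NA_real_

  tstat[!ok] <- NA_real_
  out <- data.frame(protein_id = rownames(matrix),
                    mean_log2_a = unname(a$mean), mean_log2_b = unname(b$mean),
                    log2_fc = unname(fc), t_statistic = unname(tstat),
                    p_value = unname(p),
                    n_a = unname(a$n), n_b = unname(b$n),
                    stringsAsFactors = FALSE)
  attr(out, "cond_a") <- cond_a
  attr(out, "cond_b") <- cond_b
  class(out) <- c("ContrastTable", class(out))
  out
}

#' Call differentially expressed proteins (DEPs)
#'
#' Selects proteins with `|log2_fc| >= log2(fc_threshold)` and a defined
#' p-value passing `p_threshold`. Both thresholds are inclusive by default
#' (`FC >= 1.5`, `p <= 0.05`); a strict-p variant is selectable. Direction
#' follows the sign of the fold change.
#'
#' @param contrasts A `ContrastTable` from [compute_contrast()].
#' @param fc_threshold Linear fold-change threshold, `>= 1`.
#' @param p_threshold Significance threshold in (0, 1].
#' @param p_inclusive If `TRUE` (default) use `p <= p_threshold`, else `<`.
#' @param adjust_p If `TRUE`, apply Benjamini-Hochberg to the defined
#'   p-values first (off by default).
#' @return A data.frame (class `DepTable`) with columns `protein_id`,
#'   `direction` (`"up"`/`"down"`), `baseline_log2_fc`, `baseline_p`.
#' @export
call_deps <- function(contrasts, fc_threshold = 1.5, p_threshold = 0.05,
                      p_inclusive = TRUE, adjust_p = FALSE) {
  stopifnot(fc_threshold >= 1, p_threshold > 0, p_threshold <= 1)
  p <- contrasts$p_value
  if (adjust_p) p <- stats::p.adjust(p, method = "BH")
  pass_p <- !is.na(p) & if (p_inclusive) p <= p_threshold else p < p_threshold
  pass_fc <- abs(contrasts$log2_fc) >= log2(fc_threshold)
  sel <- which(pass_p & pass_fc)
  out <- data.frame(
    protein_id = contrasts$protein_id[sel],
    direction = ifelse(contrasts$log2_fc[sel] > 0, "up", "down"),
    baseline_log2_fc = contrasts$log2_fc[sel],
    baseline_p = p[sel],
    stringsAsFactors = FALSE)
  class(out) <- c("DepTable", class(out))
  out
}
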