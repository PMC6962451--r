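# Build an abundance matrix + annotation from log2 group values.
# `groups`: named list condition -> matrix (proteins x replicates) of log2
# abundances; all matrices share protein count (and optional rownames).
study_from_log2 <- function(groups) {
  n <- nrow(groups[[1]])
  pid <- rownames(groups[[1]])
  if (is.null(pid)) pid <- sprintf("P%03d", seq_len(n))
  cols <- list(); sample_id <- character(0)
  condition <- character(0); replicate <- integer(0)
  for (cc in names(groups)) {
    g <- groups[[cc]]
    for (r in seq_len(ncol(g))) {
      sample_id <- c(sample_id, paste0(cc, "_", r))
      condition <- c(condition, cc)
      replicate <- c(replicate, r)
      cols[[length(cols) + 1]] <- 2^g[, r]
    }
  }
  values <- do.call(cbind, cols)
  dimnames(values) <- list(pid, sample_id)
  list(matrix = abundance_matrix(values),
       annotation = sample_annotation(sample_id, condition, replicate))
}

# A contrast table vs ISLET built directly from stated log2 deviations.
contrast_from_dev <- function(dev, p = rep(0.01, length(dev)),
                              cond_a = "S5") {
  ids <- names(dev)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_along(dev))
  n <- length(dev)
  out <- data.frame(protein_id = ids, mean_log2_a = unname(dev),
                    mean_log2_b = rep(0, n),
                    log2_fc = unname(dev), p_value = p,
                    n_a = rep(2L, n), n_b = rep(3L, n),
                    stringsAsFactors = FALSE)
  attr(out, "cond_a") <- cond_a
  attr(out, "cond_b") <- "ISLET"
  out
}

dep_table_from_dev <- function(dev, p = rep(0.01, length(dev))) {
  ids <- names(dev)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_along(dev))
  data.frame(protein_id = ids,
             direction = as.character(ifelse(dev > 0, "up", "down")),
             baseline_log2_fc = unname(dev), baseline_p = p,
             stringsAsFactors = FALSE)
}

# Direct recomputation of Ward merge costs from sample coordinates: at each
# step the pair minimizing the increase in within-cluster sum of squares is
# merged; the recorded height is twice that increase (the squared-Euclidean
# Lance-Williams scale).
ward_heights_from_coords <- function(coords) {
  ess <- function(rows) {
    x <- coords[rows, , drop = FALSE]
    sum(sweep(x, 2, colMeans(x))^2)
  }
  clusters <- as.list(seq_len(nrow(coords)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        inc <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (inc < best - 1e-12) { best <- inc; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, 2 * best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}
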