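#' Exclusive Venn partition of named protein sets
#'
#' Decomposes 2-4 named sets into their exclusive regions. Each region is
#' labelled by the sets containing it, joined with `&` in the input order.
#' For each region the share of every contributing set's total is reported
#' (a region's size divided by that set's full size).
#'
#' @param sets Named list of 2-4 character vectors of protein ids.
#' @return A list of class `VennPartition`: `regions` (named list,
#'   region label -> id vector), `counts` (named integer vector),
#'   `per_set_totals`, and `shares` (data.frame: region, set, share).
#' @export
venn_partition <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("`sets` must be a named list", call. = FALSE)
  }
  if (length(sets) < 2 || length(sets) > 4) {
    stop("venn_partition takes 2-4 sets", call. = FALSE)
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets, use.names = FALSE))
  if (!length(universe)) {
    out <- list(regions = stats::setNames(list(), character(0)),
                counts = stats::setNames(integer(0), character(0)),
                per_set_totals = vapply(sets, length, integer(1)),
                shares = data.frame(region = character(0), set = character(0),
                                    share = numeric(0)))
    class(out) <- "VennPartition"
    return(out)
  }
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  regions <- split(universe, pattern)
  # stable order: by number of contributing sets, then input set order
  key <- vapply(names(regions), function(lab) {
    idx <- match(strsplit(lab, "&", fixed = TRUE)[[1]], names(sets))
    sum(10^(length(sets) - idx))
  }, numeric(1))
  regions <- regions[order(lengths(strsplit(names(regions), "&", fixed = TRUE)),
                           -key)]
  counts <- vapply(regions, length, integer(1))
  totals <- vapply(sets, length, integer(1))
  shares <- do.call(rbind, lapply(names(regions), function(lab) {
    inset <- strsplit(lab, "&", fixed = TRUE)[[1]]
    data.frame(region = lab, set = inset,
               share = counts[[lab]] / totals[inset],
               stringsAsFactors = FALSE)
  }))
  rownames(shares) <- NULL
  out <- list(regions = regions, counts = counts,
              per_set_totals = totals, shares = shares)
  class(out) <- "VennPartition"
  out
}

#' @export
print.VennPartition <- function(x, ...) {
  cat("VennPartition over", length(x$per_set_totals), "sets:\n")
  for (lab in names(x$counts)) cat(sprintf("  %s: %d\n", lab, x$counts[[lab]]))
  invisible(x)
}

#' Hypergeometric over-representation test
#'
#' For each annotation set (term), tests whether the query set overlaps it
#' more than expected by chance inside the universe: upper-tail
#' hypergeometric `P(X >= overlap)` with population `|universe|`, successes
#' `|term ∩ universe|`, draws `|query|`. A neutral stand-in for pathway
#' summarization against any user-supplied collection (e.g. a GMT file,
#' [read_gmt()]).
#'
#' @param query Character vector of ids, a subset of `universe`.
#' @param universe Character vector of background ids.
#' @param annotation_sets Named list of character vectors (term -> members);
#'   members are intersected with the universe.
#' @param adjust If `TRUE` (default) adds Benjamini-Hochberg `q` values.
#' @return A data.frame: `term`, `overlap`, `term_size`, `query_size`,
#'   `universe_size`, `expected`, `p` (and `q`).
#' @export
enrichment_test <- function(query, universe, annotation_sets, adjust = TRUE) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (!all(query %in% universe)) {
    stop("query contains ids outside the universe", call. = FALSE)
  }
  if (!length(annotation_sets) || is.null(names(annotation_sets))) {
    stop("`annotation_sets` must be a non-empty named list", call. = FALSE)
  }
  N <- length(universe)
  k <- length(query)
  rows <- lapply(names(annotation_sets), function(term) {
    m <- sum(unique(annotation_sets[[term]]) %in% universe)
    ov <- sum(query %in% annotation_sets[[term]])
    p <- if (m == 0) 1 else stats::phyper(ov - 1, m, N - m, k, lower.tail = FALSE)
    data.frame(term = term, overlap = ov, term_size = m, query_size = k,
               universe_size = N, expected = k * m / N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}

#' Read annotation sets from a GMT file
#'
#' GMT: one set per line, tab-separated — term, description, member ids.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors; descriptions in attribute
#'   `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3
  if (any(short)) stop("GMT line(s) with fewer than 3 fields", call. = FALSE)
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "descriptions") <- vapply(parts, `[`, character(1), 2)
  sets
}

#' Direction concordance between two contrasts
#'
#' Compares fold-change signs over the shared identifiers — e.g. a protein
#' contrast vs the matching transcript contrast — after restricting to ids
#' with `|log2_fc| >= min_abs_log2_fc` in both. Identifier mapping is the
#' caller's job: ids are matched verbatim.
#'
#' @param contrast_a,contrast_b Data frames with `protein_id` and `log2_fc`.
#' @param min_abs_log2_fc Minimum absolute log2 fold change in both
#'   collections (default 0).
#' @return List: `n_shared`, `n_concordant`, `fraction` (`NA` when no ids
#'   qualify).
#' @export
direction_concordance <- function(contrast_a, contrast_b,
                                  min_abs_log2_fc = 0) {
  a <- contrast_a[!is.na(contrast_a$log2_fc) &
                    abs(contrast_a$log2_fc) >= min_abs_log2_fc, ]
  b <- contrast_b[!is.na(contrast_b$log2_fc) &
                    abs(contrast_b$log2_fc) >= min_abs_log2_fc, ]
  shared <- intersect(a$protein_id, b$protein_id)
  fa <- a$log2_fc[match(shared, a$protein_id)]
  fb <- b$log2_fc[match(shared, b$protein_id)]
  n_conc <- sum(sign(fa) == sign(fb))
  list(n_shared = length(shared), n_concordant = n_conc,
       fraction = if (length(shared)) n_conc / length(shared) else NA_real_)
}
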