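# Shared preprocessing for the clustering operations: complete-case
# restriction (no imputation), one log2 transform, optional per-protein
# median centering.
cluster_input <- function(matrix, transform = c("log2", "none"),
                          centering = c("none", "protein_median")) {
  transform <- match.arg(transform)
  centering <- match.arg(centering)
  x <- unclass(matrix)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 2) {
    stop("fewer than 2 complete-case proteins; cannot compute distances",
         call. = FALSE)
  }
  if (transform == "log2") x <- log2(x)
  if (centering == "protein_median") {
    x <- sweep(x, 1, apply(x, 1, stats::median))
  }
  x
}

#' Squared-Euclidean sample distance matrix
#'
#' Distances between sample profiles over the complete-case proteins
#' (proteins quantified in every sample): `d(i, j) = sum_p (x_pi - x_pj)^2`.
#'
#' @param matrix An [abundance_matrix()].
#' @param transform `"log2"` (default) or `"none"`.
#' @param centering `"none"` (default) or `"protein_median"` (subtract each
#'   protein's median profile before distances).
#' @return Symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
sample_distance_matrix <- function(matrix, transform = c("log2", "none"),
                                   centering = c("none", "protein_median")) {
  x <- cluster_input(matrix, transform, centering)
  as.matrix(stats::dist(t(x), method = "euclidean"))^2
}

#' Ward agglomeration on a squared-Euclidean distance matrix
#'
#' Greedy agglomerative clustering minimizing the Ward criterion, updated
#' with the Lance-Williams recurrence for Ward's method on squared-Euclidean
#' input. Merge heights are on the input (squared-distance) scale, i.e.
#' twice the increase in within-cluster sum of squares at each merge; on
#' this input Ward has no inversions, so heights are non-decreasing. Ties
#' are broken toward the lowest-index pair, making the tree deterministic.
#'
#' @param distances Symmetric matrix of squared-Euclidean distances, e.g.
#'   from [sample_distance_matrix()].
#' @return A list of class `LinkageTree`: `merge` (hclust-style matrix,
#'   negative entries are leaves), `height` (merge heights), `labels`
#'   (leaf ids).
#' @export
ward_linkage <- function(distances) {
  d <- as.matrix(distances)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
    stop("`distances` must be a symmetric matrix", call. = FALSE)
  }
  n <- nrow(d)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  size <- rep(1, n)
  id <- -seq_len(n)            # hclust convention: negative = leaf
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  diag(d) <- Inf
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- d[idx, idx, drop = FALSE]
    best <- Inf; bi <- bj <- NA_integer_
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (b <= a) next
        if (sub[a, b] < best - 1e-15) { best <- sub[a, b]; bi <- idx[a]; bj <- idx[b] }
      }
    }
    merge[step, ] <- sort(c(id[bi], id[bj]))
    height[step] <- d[bi, bj]
    # Lance-Williams Ward update into slot bi; retire bj
    ni <- size[bi]; nj <- size[bj]
    others <- setdiff(idx, c(bi, bj))
    if (length(others)) {
      nk <- size[others]
      d[bi, others] <- ((ni + nk) * d[bi, others] + (nj + nk) * d[bj, others] -
                          nk * d[bi, bj]) / (ni + nj + nk)
      d[others, bi] <- d[bi, others]
    }
    size[bi] <- ni + nj
    id[bi] <- step
    active[bj] <- FALSE
  }
  out <- list(merge = merge, height = height, labels = labels)
  class(out) <- "LinkageTree"
  out
}

#' Convert a LinkageTree to a stats::hclust object
#'
#' @param tree A `LinkageTree` from [ward_linkage()].
#' @return An object of class `hclust` (usable with [stats::cophenetic()],
#'   [stats::cutree()], plotting).
#' @export
as_hclust <- function(tree) {
  leaf_order <- function(node) {
    if (node < 0) return(-node)
    c(leaf_order(tree$merge[node, 1]), leaf_order(tree$merge[node, 2]))
  }
  structure(list(merge = tree$merge, height = tree$height,
                 order = leaf_order(nrow(tree$merge)),
                 labels = tree$labels, method = "ward",
                 call = match.call(), dist.method = "squared euclidean"),
            class = "hclust")
}

#' @export
print.LinkageTree <- function(x, ...) {
  cat(sprintf("LinkageTree: %d leaves, %d merges, heights [%.4g, %.4g]\n",
              length(x$labels), length(x$height),
              min(x$height), max(x$height)))
  invisible(x)
}

#' Serialize a LinkageTree as Newick
#'
#' Branch lengths are height differences between a node and its parent
#' (leaves sit at height 0).
#'
#' @param tree A `LinkageTree`.
#' @return A single Newick string, semicolon-terminated.
#' @export
linkage_newick <- function(tree) {
  node_str <- function(node, parent_h) {
    if (node < 0) {
      return(sprintf("%s:%.10g", tree$labels[-node], parent_h))
    }
    h <- tree$height[node]
    sprintf("(%s,%s):%.10g",
            node_str(tree$merge[node, 1], h),
            node_str(tree$merge[node, 2], h),
            parent_h - h)
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  sprintf("(%s,%s);", node_str(tree$merge[root, 1], h),
          node_str(tree$merge[root, 2], h))
}

#' Serialize a LinkageTree as a JSON merge list
#'
#' @param tree A `LinkageTree`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
linkage_json <- function(tree, path = NULL) {
  obj <- list(labels = tree$labels,
              merges = data.frame(node_a = tree$merge[, 1],
                                  node_b = tree$merge[, 2],
                                  height = tree$height))
  if (is.null(path)) {
    jsonlite::toJSON(obj, dataframe = "rows", digits = NA, auto_unbox = TRUE)
  } else {
    jsonlite::write_json(obj, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE)
    invisible(path)
  }
}

#' Condition centroid proximity to the reference
#'
#' For every non-reference condition, the squared-Euclidean distance between
#' its centroid (mean log2 profile over the condition's samples) and the
#' reference centroid, in ascending order (ties broken by condition name).
#' Mirrors the dendrogram question "which conditions sit closest to the
#' islets" as a single number per condition.
#'
#' @param matrix An [abundance_matrix()].
#' @param annotation A [sample_annotation()].
#' @param reference Reference condition (default `"ISLET"`).
#' @param transform,centering As in [sample_distance_matrix()].
#' @return Data frame with columns `condition`, `distance`, ascending.
#' @export
condition_proximity_to_reference <- function(matrix, annotation,
                                             reference = "ISLET",
                                             transform = c("log2", "none"),
                                             centering = c("none", "protein_median")) {
  check_matrix_annotation(matrix, annotation)
  if (!reference %in% annotation$condition) {
    stop("reference condition '", reference, "' not present", call. = FALSE)
  }
  x <- cluster_input(matrix, transform, centering)
  centroid <- function(cond) {
    rowMeans(x[, annotation$sample_id[annotation$condition == cond],
               drop = FALSE])
  }
  ref <- centroid(reference)
  conds <- setdiff(sort(unique(annotation$condition)), reference)
  dist_to_ref <- vapply(conds, function(cc) sum((centroid(cc) - ref)^2),
                        numeric(1))
  out <- data.frame(condition = conds, distance = unname(dist_to_ref),
                    stringsAsFactors = FALSE)
  out[order(out$distance, out$condition), , drop = FALSE]
}
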