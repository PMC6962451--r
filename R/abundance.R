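#' Condition vocabulary
#'
#' The five condition labels of the study design: pancreatic endocrine
#' progenitors (`S5`), maturing beta-like cells (`S7`), their counterparts
#' differentiated inside alginate microcapsules during the early
#' (`S5_bead`) or late (`S7_bead`) protocol stages, and native human
#' pancreatic islets (`ISLET`), the reference all contrasts are anchored to.
#'
#' @return Character vector of the five condition labels.
#' @export
islet_conditions <- function() {
  c("S5", "S7", "S5_bead", "S7_bead", "ISLET")
}

#' Construct a validated abundance matrix
#'
#' An `AbundanceMatrix` is a numeric matrix of strictly positive,
#' linear-scale protein abundances (the normalized TMT-ratio analog) with
#' proteins in rows and samples in columns. Missing values (non-detections)
#' are stored as `NA`, never as zero: zeros would corrupt the single
#' downstream log2 transform.
#'
#' @param values Numeric matrix with unique, non-empty rownames (protein
#'   ids) and colnames (sample ids). `NA` marks a missing cell.
#' @return The matrix with class `AbundanceMatrix` prepended.
#' @export
abundance_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  pid <- rownames(values)
  sid <- colnames(values)
  if (is.null(pid) || is.null(sid) || any(!nzchar(pid)) || any(!nzchar(sid))) {
    stop("abundance matrix needs non-empty protein (row) and sample (column) ids",
         call. = FALSE)
  }
  dup <- c(pid[duplicated(pid)], sid[duplicated(sid)])
  if (length(dup)) {
    stop("duplicate identifier(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  present <- !is.na(values)
  if (any(!is.finite(values[present]))) {
    stop("abundance values must be finite where present", call. = FALSE)
  }
  if (any(values[present] <= 0)) {
    bad <- which(values <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("abundance values must be > 0; offending cell %s / %s",
                 pid[bad[1]], sid[bad[2]]), call. = FALSE)
  }
  class(values) <- c("AbundanceMatrix", class(values))
  values
}

#' @export
print.AbundanceMatrix <- function(x, ...) {
  cat(sprintf("AbundanceMatrix: %d proteins x %d samples (%d missing cells)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' Construct a validated sample annotation
#'
#' Maps each sample to one of the five study conditions (see
#' [islet_conditions()]) and a replicate index. The `ISLET` reference must
#' be present for any reference-anchored analysis, and every condition used
#' needs at least two samples so a t-test is defined.
#'
#' @param sample_id Character vector of unique sample ids.
#' @param condition Character vector of condition labels drawn from
#'   [islet_conditions()].
#' @param replicate Positive integer replicate indices.
#' @return A `data.frame` with class `SampleAnnotation`.
#' @export
sample_annotation <- function(sample_id, condition, replicate) {
  sample_id <- as.character(sample_id)
  condition <- as.character(condition)
  replicate <- as.integer(replicate)
  if (length(sample_id) != length(condition) ||
      length(sample_id) != length(replicate)) {
    stop("sample_id, condition and replicate must have equal length", call. = FALSE)
  }
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(condition), islet_conditions())
  if (length(unknown)) {
    stop("unknown condition label(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(islet_conditions(), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(replicate)) || any(replicate < 1)) {
    stop("replicate indices must be positive integers", call. = FALSE)
  }
  tab <- table(condition)
  if (any(tab < 2)) {
    stop("every condition used needs >= 2 samples; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  ann <- data.frame(sample_id = sample_id, condition = condition,
                    replicate = replicate, stringsAsFactors = FALSE)
  class(ann) <- c("SampleAnnotation", class(ann))
  ann
}

delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, tsv = "\t", txt = "\t", csv = ",",
         stop("cannot infer delimiter from extension '.", ext,
              "'; use .tsv or .csv", call. = FALSE))
}

#' Read an abundance matrix from delimited text
#'
#' Expects a header row of sample ids, a first column of protein ids, and
#' one numeric (or missing) cell per protein/sample. The delimiter is taken
#' from the file extension (`.tsv`/`.txt` tab, `.csv` comma); no sniffing.
#' Column order is preserved as in the file.
#'
#' @param path Path to the TSV/CSV file.
#' @param missing_token Text marking a missing cell; empty cells are always
#'   treated as missing.
#' @return An [abundance_matrix()].
#' @export
read_abundance_matrix <- function(path, missing_token = "NA") {
  raw <- utils::read.table(path, sep = delim_for(path), header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", row.names = NULL)
  if (ncol(raw) < 2) stop("abundance file needs a protein-id column and >= 1 sample",
                          call. = FALSE)
  pid <- raw[[1]]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  miss <- cells == "" | cells == missing_token
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(!miss & is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell '%s' at protein %s, sample %s",
                 cells[bad[1, 1], bad[1, 2]], pid[bad[1, 1]],
                 colnames(cells)[bad[1, 2]]), call. = FALSE)
  }
  num[miss] <- NA_real_
  rownames(num) <- pid
  colnames(num) <- colnames(cells)
  abundance_matrix(num)
}

#' Read a sample annotation table
#'
#' Delimited text with columns `sample_id`, `condition`, `replicate`
#' (delimiter by extension, as for [read_abundance_matrix()]).
#'
#' @param path Path to the TSV/CSV file.
#' @return A [sample_annotation()].
#' @export
read_sample_annotation <- function(path) {
  raw <- utils::read.table(path, sep = delim_for(path), header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  need <- c("sample_id", "condition", "replicate")
  if (!all(need %in% names(raw))) {
    stop("annotation file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  sample_annotation(raw$sample_id, raw$condition, as.integer(raw$replicate))
}

#' Write an abundance matrix to delimited text
#'
#' @param matrix An [abundance_matrix()].
#' @param path Output path; delimiter by extension.
#' @param missing_token Text written for missing cells.
#' @export
write_abundance_matrix <- function(matrix, path, missing_token = "NA") {
  df <- data.frame(protein_id = rownames(matrix),
                   format_num(unclass(matrix)), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE, na = missing_token)
}

#' Write a sample annotation to delimited text
#'
#' @param annotation A [sample_annotation()].
#' @param path Output path; delimiter by extension.
#' @export
write_sample_annotation <- function(annotation, path) {
  utils::write.table(as.data.frame(annotation), path, sep = delim_for(path),
                     quote = FALSE, row.names = FALSE)
}

# Numbers serialized at full double precision so round-trips are faithful
# to well under 12 significant digits.
format_num <- function(x) {
  if (is.matrix(x)) {
    out <- apply(x, 2, function(col) {
      ifelse(is.na(col), NA_character_, formatC(col, digits = 17, format = "g"))
    })
    rownames(out) <- rownames(x)
    return(out)
  }
  x
}

#' Write a result table to TSV or JSON
#'
#' Any of the package's result collections (contrast tables, DEP calls,
#' regulation calls, summaries) can be written and re-read without loss:
#' `read_results(write_results(x))` reproduces `x` up to floating-point
#' formatting precision. JSON output is an array of objects with stable
#' key names.
#'
#' @param records A data.frame of results (may have zero rows).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_results <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  records <- as.data.frame(records)
  if (format == "tsv") {
    out <- records
    for (j in seq_along(out)) {
      if (is.double(out[[j]])) {
        out[[j]] <- ifelse(is.na(out[[j]]), NA_character_,
                           formatC(out[[j]], digits = 17, format = "g"))
      }
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE)
  }
  invisible(NULL)
}

#' Read back a result table written by [write_results()]
#'
#' @param path Input path.
#' @param format `"tsv"` or `"json"`.
#' @return A data.frame.
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::read.table(path, sep = "\t", header = TRUE, na.strings = "NA",
                      check.names = FALSE, quote = "", comment.char = "",
                      stringsAsFactors = FALSE, colClasses = NA)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}

# Consistency check used by every operation pairing a matrix with its
# annotation.
check_matrix_annotation <- function(matrix, annotation) {
  miss <- setdiff(colnames(matrix), annotation$sample_id)
  extra <- setdiff(annotation$sample_id, colnames(matrix))
  if (length(miss) || length(extra)) {
    stop("matrix/annotation sample mismatch; unannotated: [",
         paste(miss, collapse = ", "), "], absent from matrix: [",
         paste(extra, collapse = ", "), "]", call. = FALSE)
  }
  invisible(TRUE)
}

condition_samples <- function(annotation, condition) {
  if (!condition %in% islet_conditions()) {
    stop("unknown condition label: ", condition, call. = FALSE)
  }
  annotation$sample_id[annotation$condition == condition]
}
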