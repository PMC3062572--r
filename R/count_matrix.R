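#' Construct a count matrix
#'
#' The central container of the pipeline: a probes x samples matrix of
#' nonnegative counts, tied to the [codeset] describing its rows and a
#' sample-metadata table describing its columns, plus a normalization state.
#' Raw counts are integers from the instrument; normalized counts are reals.
#' The normalization state machine only moves forward:
#' `raw -> positive_normalized -> target_sum_normalized`.
#'
#' @param counts numeric matrix, probes x samples; rownames must match
#'   `codeset$gene_id` (order taken from the code set), colnames must match
#'   `samples$sample_id`.
#' @param codeset a [codeset].
#' @param samples data frame of per-sample metadata with columns
#'   `sample_id` (unique), and optionally `rna_mass` (micrograms of total
#'   RNA hybridized; 0 encodes the no-RNA control), `condition`
#'   (stage/strain/treatment label), `replicate`, `strain`.
#' @param norm_state one of `"raw"`, `"positive_normalized"`,
#'   `"target_sum_normalized"`.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, codeset, samples,
                         norm_state = c("raw", "positive_normalized",
                                        "target_sum_normalized")) {
  norm_state <- match.arg(norm_state)
  stopifnot(inherits(codeset, "codeset"))
  counts <- as.matrix(counts)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(samples)) {
    abort("sample metadata must have a sample_id column", "format_error")
  }
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) {
    abort("sample_id must be unique within an experiment", "validation_error")
  }
  for (col in c("rna_mass", "condition", "replicate", "strain")) {
    if (!col %in% names(samples)) samples[[col]] <- rep(NA, nrow(samples))
  }
  if (any(!is.na(samples$rna_mass) & samples$rna_mass < 0)) {
    abort("rna_mass must be >= 0", "validation_error")
  }
  if (is.null(rownames(counts))) {
    if (nrow(counts) != nrow(codeset)) {
      abort("counts rows do not match the code set", "validation_error")
    }
    rownames(counts) <- codeset$gene_id
  }
  if (is.null(colnames(counts))) {
    if (ncol(counts) != nrow(samples)) {
      abort("counts columns do not match the sample metadata", "validation_error")
    }
    colnames(counts) <- samples$sample_id
  }
  unknown <- setdiff(rownames(counts), codeset$gene_id)
  if (length(unknown) > 0) {
    abort(sprintf("probe id(s) not in code set: %s",
                  paste(unknown, collapse = ", ")), "validation_error")
  }
  missing_probes <- setdiff(codeset$gene_id, rownames(counts))
  if (length(missing_probes) > 0) {
    abort(sprintf("code-set probe(s) absent from counts: %s",
                  paste(missing_probes, collapse = ", ")), "validation_error")
  }
  missing_samples <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing_samples) > 0) {
    abort(sprintf("sample(s) missing metadata: %s",
                  paste(missing_samples, collapse = ", ")), "validation_error")
  }
  counts <- counts[codeset$gene_id, samples$sample_id, drop = FALSE]
  if (any(is.na(counts))) {
    abort("missing values are not allowed in counts", "validation_error")
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative count at probe '%s', sample '%s'",
                  rownames(counts)[bad[1]], colnames(counts)[bad[2]]),
          "format_error")
  }
  rownames(samples) <- NULL
  structure(list(counts = counts, codeset = codeset, samples = samples,
                 norm_state = norm_state),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d probes x %d samples [%s]\n",
              nrow(x$counts), ncol(x$counts), x$norm_state))
  invisible(x)
}

#' Subset a count matrix by sample
#'
#' @param x a [count_matrix].
#' @param samples character vector of sample ids or a logical/integer index
#'   into the sample table.
#' @return a [count_matrix] restricted to the selected samples.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.character(samples)) {
    idx <- match(samples, x$samples$sample_id)
    if (anyNA(idx)) {
      abort(sprintf("unknown sample id(s): %s",
                    paste(samples[is.na(idx)], collapse = ", ")),
            "validation_error")
    }
  } else {
    idx <- seq_len(nrow(x$samples))[samples]
  }
  count_matrix(x$counts[, idx, drop = FALSE], x$codeset,
               x$samples[idx, , drop = FALSE], x$norm_state)
}

#' Column-bind count matrices sharing one code set
#'
#' @param ... count matrices with identical code sets and norm_state.
#' @return a combined [count_matrix].
#' @export
combine_counts <- function(...) {
  mats <- list(...)
  stopifnot(length(mats) >= 1, all(vapply(mats, inherits, TRUE, "count_matrix")))
  states <- unique(vapply(mats, `[[`, "", "norm_state"))
  if (length(states) != 1) {
    abort("cannot combine count matrices with different norm_state",
          "validation_error")
  }
  cs <- mats[[1]]$codeset
  for (m in mats[-1]) {
    if (!identical(m$codeset$gene_id, cs$gene_id)) {
      abort("cannot combine count matrices with different code sets",
            "validation_error")
    }
  }
  counts <- do.call(cbind, lapply(mats, `[[`, "counts"))
  samples <- do.call(rbind, lapply(mats, `[[`, "samples"))
  count_matrix(counts, cs, samples, states)
}

#' Read a raw count table
#'
#' Reads a delimited table with probes as rows (first column `gene_id`) and
#' samples as columns, resolving probe ids against a code set.
#'
#' @param path path to the counts file.
#' @param codeset a [codeset]; every probe in the file must be present in it
#'   and, unless `allow_missing = TRUE`, vice versa.
#' @param samples optional sample metadata data frame; defaults to bare
#'   metadata built from the column names.
#' @param norm_state the normalization state to stamp on the result
#'   (default `"raw"`); a reader of pre-normalized supplementary tables can
#'   declare the state explicitly.
#' @param allow_missing if TRUE, probes present in the code set but absent
#'   from the file are tolerated by shrinking the code set to the file.
#' @param delim optional delimiter; sniffed from the header by default.
#' @return a [count_matrix].
#' @export
read_counts <- function(path, codeset, samples = NULL, norm_state = "raw",
                        allow_missing = FALSE, delim = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("counts file '%s' does not exist", path), "io_error")
  }
  delim <- delim %||% sniff_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  if (!"gene_id" %in% names(df)) {
    abort("counts file must have a gene_id column", "format_error")
  }
  ids <- as.character(df$gene_id)
  mat <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(mat, 2, as.numeric))), arr.ind = TRUE)
    coord <- if (length(bad) > 0) {
      sprintf(" (row %d, column '%s')", bad[1, 1], colnames(mat)[bad[1, 2]])
    } else ""
    abort(sprintf("non-numeric count in '%s'%s", path, coord), "format_error")
  }
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(sprintf("negative count at row %d (probe '%s'), column '%s'",
                  neg[1, 1], ids[neg[1, 1]], colnames(mat)[neg[1, 2]]),
          "format_error")
  }
  rownames(mat) <- ids
  unknown <- setdiff(ids, codeset$gene_id)
  if (length(unknown) > 0) {
    abort(sprintf("probe id(s) not in code set: %s",
                  paste(unknown, collapse = ", ")), "validation_error")
  }
  absent <- setdiff(codeset$gene_id, ids)
  if (length(absent) > 0) {
    if (!allow_missing) {
      abort(sprintf("probe(s) in code set but not in file: %s",
                    paste(absent, collapse = ", ")), "validation_error")
    }
    codeset <- codeset(as.data.frame(codeset)[codeset$gene_id %in% ids, ])
  }
  if (is.null(samples)) {
    samples <- data.frame(sample_id = colnames(mat), stringsAsFactors = FALSE)
  }
  count_matrix(mat, codeset, samples, norm_state)
}

#' Read a sample-metadata table
#'
#' @param path delimited file with a `sample_id` column and any of
#'   `rna_mass`, `condition`, `replicate`, `strain`.
#' @param delim optional delimiter; sniffed by default.
#' @return a data frame of sample metadata.
#' @export
read_sample_meta <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("metadata file '%s' does not exist", path), "io_error")
  }
  delim <- delim %||% sniff_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) {
    abort("metadata file must have a sample_id column", "format_error")
  }
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Write a result object to delimited text
#'
#' Writes count matrices, expression profiles and plain tables as delimited
#' text with a header row. Numeric cells are formatted to 15 significant
#' digits so that a write/read round trip reproduces values (the contract is
#' >= 12 significant digits) and a write/read/write cycle is byte-identical.
#'
#' @param object a [count_matrix], [expression_profile] or data frame.
#' @param path output path.
#' @param delim field delimiter (default tab).
#' @export
write_table <- function(object, path, delim = "\t") {
  UseMethod("write_table")
}

#' @noRd
write_formatted <- function(df, path, delim) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  cells <- lapply(df, function(col) {
    if (is.numeric(col)) format_num(col) else as.character(col)
  })
  writeLines(paste(names(df), collapse = delim), con)
  if (nrow(df) > 0) {
    body <- do.call(paste, c(cells, sep = delim))
    writeLines(body, con)
  }
  invisible(path)
}

#' @export
write_table.count_matrix <- function(object, path, delim = "\t") {
  df <- data.frame(gene_id = rownames(object$counts),
                   as.data.frame(object$counts, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_formatted(df, path, delim)
}

#' @export
write_table.data.frame <- function(object, path, delim = "\t") {
  write_formatted(object, path, delim)
}

#' @export
write_table.expression_profile <- function(object, path, delim = "\t") {
  long <- profile_to_table(object)
  write_formatted(long, path, delim)
}
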