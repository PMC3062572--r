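#' Construct a code set
#'
#' A code set is the static design of a barcode-count assay: one probe per
#' gene, each probe belonging to exactly one class. `target` probes measure
#' transcripts of the organism under study; `positive` probes match synthetic
#' transcripts spiked into the code set at known femtomole amounts and anchor
#' between-sample normalization and the standard curve; `negative` probes
#' match foreign sequences with no spiked transcript and estimate nonspecific
#' background.
#'
#' @param probes a data frame with columns `gene_id` (character, unique,
#'   nonempty), `probe_class` (one of `"target"`, `"positive"`,
#'   `"negative"`; parsed case-insensitively), and optionally
#'   `target_region` (free text), `spike_fmol` (required, positive, for
#'   positive controls; must be absent/NA otherwise) and `specificity_flag`
#'   (free text noting known cross-hybridization).
#'
#' @return an object of class `codeset` (a validated data frame).
#' @examples
#' cs <- codeset(data.frame(
#'   gene_id = c("ins-1", "POS_A", "NEG_A"),
#'   probe_class = c("target", "positive", "negative"),
#'   spike_fmol = c(NA, 0.1, NA)
#' ))
#' table(cs$probe_class)
#' @export
codeset <- function(probes) {
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  required <- c("gene_id", "probe_class")
  missing_cols <- setdiff(required, names(probes))
  if (length(missing_cols) > 0) {
    abort(sprintf("code set is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          "format_error", columns = missing_cols)
  }
  probes$gene_id <- as.character(probes$gene_id)
  probes$probe_class <- tolower(trimws(as.character(probes$probe_class)))
  if (!"target_region" %in% names(probes)) probes$target_region <- NA_character_
  if (!"spike_fmol" %in% names(probes)) probes$spike_fmol <- NA_real_
  if (!"specificity_flag" %in% names(probes)) probes$specificity_flag <- NA_character_
  probes$spike_fmol <- suppressWarnings(as.numeric(probes$spike_fmol))

  bad_class <- setdiff(unique(probes$probe_class), c("target", "positive", "negative"))
  if (length(bad_class) > 0) {
    abort(sprintf("unknown probe class(es): %s", paste(bad_class, collapse = ", ")),
          "validation_error")
  }
  if (any(!nzchar(probes$gene_id) | is.na(probes$gene_id))) {
    abort("gene_id must be nonempty for every probe", "validation_error")
  }
  dups <- unique(probes$gene_id[duplicated(probes$gene_id)])
  if (length(dups) > 0) {
    abort(sprintf("duplicate gene_id(s): %s", paste(dups, collapse = ", ")),
          "validation_error", duplicates = dups)
  }
  pos <- probes$probe_class == "positive"
  bad_pos <- pos & (is.na(probes$spike_fmol) | probes$spike_fmol <= 0)
  if (any(bad_pos)) {
    abort(sprintf(
      "positive-control probe(s) without a positive spike_fmol: %s",
      paste(probes$gene_id[bad_pos], collapse = ", ")),
      "validation_error", probes = probes$gene_id[bad_pos])
  }
  bad_nonpos <- !pos & !is.na(probes$spike_fmol)
  if (any(bad_nonpos)) {
    abort(sprintf(
      "spike_fmol set for non-positive probe(s): %s",
      paste(probes$gene_id[bad_nonpos], collapse = ", ")),
      "validation_error", probes = probes$gene_id[bad_nonpos])
  }
  rownames(probes) <- NULL
  structure(probes[, c("gene_id", "probe_class", "target_region",
                       "spike_fmol", "specificity_flag")],
            class = c("codeset", "data.frame"))
}

#' Read a code-set definition table
#'
#' Reads a delimited (comma- or tab-separated, auto-detected from the header
#' line) probe definition file with columns `gene_id`, `probe_class` and
#' optionally `target_region`, `spike_fmol`, `specificity_flag`.
#'
#' @param path path to the file.
#' @param delim optional delimiter; by default sniffed from the header.
#' @return a [codeset].
#' @export
read_codeset <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("code-set file '%s' does not exist", path), "io_error")
  }
  delim <- delim %||% sniff_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  codeset(df)
}

#' Write a code set to delimited text
#'
#' @param x a [codeset].
#' @param path output path.
#' @param delim field delimiter (default tab).
#' @export
write_codeset <- function(x, path, delim = "\t") {
  stopifnot(inherits(x, "codeset"))
  utils::write.table(as.data.frame(x), path, sep = delim, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Probe ids belonging to one class
#'
#' @param codeset a [codeset].
#' @param class one of `"target"`, `"positive"`, `"negative"`.
#' @return character vector of gene ids.
#' @export
class_probes <- function(codeset, class) {
  stopifnot(inherits(codeset, "codeset"))
  class <- match.arg(class, c("target", "positive", "negative"))
  codeset$gene_id[codeset$probe_class == class]
}

#' @export
print.codeset <- function(x, ...) {
  counts <- table(factor(x$probe_class, c("target", "positive", "negative")))
  cat(sprintf("<codeset> %d probes (%d targets, %d positives, %d negatives)\n",
              nrow(x), counts[["target"]], counts[["positive"]],
              counts[["negative"]]))
  invisible(x)
}
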