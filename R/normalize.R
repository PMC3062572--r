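#' Between-sample normalization for barcode-count data
#'
#' The pipeline uses a two-step normalization. Step one rescales every count
#' in each sample so that the per-sample sums of positive-control (spike-in)
#' counts are equal across samples; because the spike-ins are added to the
#' code set at fixed amounts independent of the RNA input, this removes
#' sample-to-sample differences in hybridization, binding and imaging
#' efficiency. Step two (optional, used for biological comparisons such as
#' the life-cycle experiment) additionally rescales the target-probe rows so
#' the per-sample sums of target counts are equal, a total-content
#' normalization under the assumption that overall target mRNA content is
#' comparable across samples. Control rows are untouched by step two.
#'
#' The common post-scaling reference is the arithmetic mean over samples of
#' the per-sample sums, so normalization leaves the overall count scale
#' unchanged on average.
#'
#' @param counts a [count_matrix] with `norm_state = "raw"` (step one) or
#'   `"positive_normalized"` (step two).
#' @return a list with components `counts` (the rescaled [count_matrix],
#'   with `norm_state` advanced) and `normalization` (a
#'   `normalization_result` with per-sample `factors`, the common
#'   `reference_value`, and the `method`).
#' @seealso [normalize_target_sum()]
#' @examples
#' cs <- simulate_codeset(synthetic_config(seed = 1))
#' cm <- simulate_hybridization(synthetic_config(seed = 1), mass = 1,
#'                              n_replicates = 3)
#' norm <- normalize_positive_controls(cm)
#' norm$normalization$factors
#' @export
normalize_positive_controls <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  if (counts$norm_state != "raw") {
    abort(sprintf(
      "positive-control normalization requires raw counts (norm_state is '%s')",
      counts$norm_state), "state_error")
  }
  pos <- class_probes(counts$codeset, "positive")
  if (length(pos) == 0) {
    abort("code set has no positive-control probes", "normalization_error")
  }
  sums <- colSums(counts$counts[pos, , drop = FALSE])
  zero <- names(sums)[sums <= 0]
  if (length(zero) > 0) {
    abort(sprintf("sample(s) with zero positive-control counts: %s",
                  paste(zero, collapse = ", ")),
          "normalization_error", samples = zero)
  }
  reference <- mean(sums)
  factors <- reference / sums
  scaled <- sweep(counts$counts, 2, factors, `*`)
  out <- count_matrix(scaled, counts$codeset, counts$samples,
                      "positive_normalized")
  list(counts = out,
       normalization = normalization_result(factors, reference,
                                            "positive_controls"))
}

#' Target-sum (total-content) normalization
#'
#' Second normalization step: rescales only the target-probe rows of a
#' positive-control-normalized matrix so that per-sample target sums are
#' equal to the mean pre-scaling target sum. Positive- and negative-control
#' rows are returned bit-identical.
#'
#' @inheritParams normalize_positive_controls
#' @return same structure as [normalize_positive_controls()], with
#'   `method = "target_sum"` and `norm_state = "target_sum_normalized"`.
#' @export
normalize_target_sum <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  if (counts$norm_state != "positive_normalized") {
    abort(sprintf(
      "target-sum normalization requires positive-normalized counts (norm_state is '%s')",
      counts$norm_state), "state_error")
  }
  targets <- class_probes(counts$codeset, "target")
  if (length(targets) == 0) {
    abort("code set has no target probes", "normalization_error")
  }
  sums <- colSums(counts$counts[targets, , drop = FALSE])
  zero <- names(sums)[sums <= 0]
  if (length(zero) > 0) {
    abort(sprintf("sample(s) with zero target counts: %s",
                  paste(zero, collapse = ", ")),
          "normalization_error", samples = zero)
  }
  reference <- mean(sums)
  factors <- reference / sums
  scaled <- counts$counts
  scaled[targets, ] <- sweep(scaled[targets, , drop = FALSE], 2, factors, `*`)
  out <- count_matrix(scaled, counts$codeset, counts$samples,
                      "target_sum_normalized")
  list(counts = out,
       normalization = normalization_result(factors, reference, "target_sum"))
}

#' @noRd
normalization_result <- function(factors, reference_value, method) {
  structure(list(factors = factors, reference_value = reference_value,
                 method = method),
            class = "normalization_result")
}

#' @export
print.normalization_result <- function(x, ...) {
  cat(sprintf("<normalization_result> method=%s reference=%.6g\n",
              x$method, x$reference_value))
  print(round(x$factors, 4))
  invisible(x)
}

#' Housekeeping-gene normalization (not implemented)
#'
#' Normalization against designated invariant ("housekeeping") genes is a
#' standard alternative to target-sum normalization, but the insulin-like
#' code set this pipeline was built around contains no invariant genes, so
#' the method is exposed only as a stub.
#'
#' @param counts a [count_matrix].
#' @param genes character vector of housekeeping gene ids.
#' @export
normalize_housekeeping <- function(counts, genes) {
  abort("housekeeping normalization is not implemented: the code set contains no invariant genes",
        "not_implemented_error")
}
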