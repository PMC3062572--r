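#' Background model from negative-control probes
#'
#' Models nonspecific background for a group of samples ("scope") as the
#' mean of the negative-control counts plus `k` standard deviations. All
#' negative-control values in the scope are pooled (probes x samples) and
#' the SD is the sample SD (n - 1 denominator): with typically 8 negative
#' probes and 3 replicates, per-probe SDs are too unstable to use, and the
#' assay reports one cutoff per condition.
#'
#' @param counts a [count_matrix], positive-control normalized.
#' @param samples sample ids (or index) defining the scope; `NULL` means all
#'   samples.
#' @param k SD multiplier (default 3).
#' @param scope label recorded on the model (defaults to a sensible name).
#' @return a `background_model` with fields `threshold`, `method`
#'   (`"negctrl_mean_sd"`), `k`, `scope`, `neg_mean`, `neg_sd`, `n_values`.
#' @examples
#' # pooled negative counts {17, 25, 33}: mean 25, SD 8, k = 3 -> 49
#' @export
negative_control_threshold <- function(counts, samples = NULL, k = 3,
                                       scope = NULL) {
  stopifnot(inherits(counts, "count_matrix"), k >= 0)
  if (counts$norm_state == "raw") {
    abort("background modeling requires positive-normalized counts",
          "state_error")
  }
  if (!is.null(samples)) counts <- subset_samples(counts, samples)
  neg <- class_probes(counts$codeset, "negative")
  if (length(neg) == 0) {
    abort("code set has no negative-control probes", "model_error")
  }
  values <- as.vector(counts$counts[neg, , drop = FALSE])
  if (length(values) < 2) {
    abort("a single negative-control value leaves the SD undefined",
          "model_error")
  }
  m <- mean(values)
  s <- stats::sd(values)
  background_model(threshold = m + k * s, method = "negctrl_mean_sd", k = k,
                   scope = scope %||% paste(counts$samples$sample_id,
                                            collapse = "+"),
                   neg_mean = m, neg_sd = s, n_values = length(values))
}

#' Deletion-calibrated background threshold
#'
#' Cross-hybridization among related targets can exceed the background seen
#' by foreign-sequence negative controls. Residual counts measured for
#' probes whose target gene has been deleted bound that cross-hybridization
#' empirically. The threshold is the maximum residual (deletion-strain) mean
#' across the assayed deletions, plus `k` times the SD of the summary
#' attaining that maximum, optionally rounded up to the next multiple of 50
#' or 100 for a conservative operating cutoff.
#'
#' @param summaries data frame with columns `gene_id`, `deletion_mean`,
#'   `deletion_sd` (and optionally `wildtype_mean`, `n_replicates`).
#' @param k SD multiplier (default 4).
#' @param rounding `"none"` (default), `"ceil_to_50"` or `"ceil_to_100"`.
#' @param scope label recorded on the model.
#' @return a `background_model` with `method = "deletion_calibrated"`.
#' @examples
#' fig_summaries <- data.frame(
#'   gene_id = c("ins-4", "ins-5", "ins-6"),
#'   deletion_mean = c(31, 124, 137),
#'   deletion_sd = c(2, 55, 53))
#' deletion_threshold(fig_summaries)$threshold                       # 349
#' deletion_threshold(fig_summaries, rounding = "ceil_to_100")$threshold  # 400
#' @export
deletion_threshold <- function(summaries, k = 4,
                               rounding = c("none", "ceil_to_50",
                                            "ceil_to_100"),
                               scope = "deletion_panel") {
  rounding <- match.arg(rounding)
  summaries <- as.data.frame(summaries)
  if (nrow(summaries) == 0) {
    abort("at least one deletion summary is required", "model_error")
  }
  needed <- c("gene_id", "deletion_mean", "deletion_sd")
  missing_cols <- setdiff(needed, names(summaries))
  if (length(missing_cols) > 0) {
    abort(sprintf("deletion summaries missing column(s): %s",
                  paste(missing_cols, collapse = ", ")), "format_error")
  }
  if (any(summaries$deletion_sd < 0)) {
    abort("deletion_sd must be >= 0", "validation_error")
  }
  i <- which.max(summaries$deletion_mean)
  threshold <- summaries$deletion_mean[i] + k * summaries$deletion_sd[i]
  threshold <- switch(rounding,
                      none = threshold,
                      ceil_to_50 = 50 * ceiling(threshold / 50),
                      ceil_to_100 = 100 * ceiling(threshold / 100))
  background_model(threshold = threshold, method = "deletion_calibrated",
                   k = k, scope = scope, rounding = rounding,
                   calibrating_gene = summaries$gene_id[i])
}

#' Fixed background threshold
#'
#' @param threshold nonnegative count threshold.
#' @param scope label recorded on the model.
#' @return a `background_model` with `method = "fixed"`.
#' @export
fixed_threshold <- function(threshold, scope = "fixed") {
  background_model(threshold = threshold, method = "fixed", k = NA_real_,
                   scope = scope)
}

#' @noRd
background_model <- function(threshold, method, k, scope, ...) {
  if (threshold < 0) abort("threshold must be >= 0", "model_error")
  structure(list(threshold = threshold, method = method, k = k,
                 scope = scope, ...),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> %s: threshold %.4g counts (k=%s, scope=%s)\n",
              x$method, x$threshold, format(x$k), x$scope))
  invisible(x)
}

#' Call detection of probes above background
#'
#' A probe is called detected when its tested statistic strictly exceeds the
#' model threshold ("detected above background"): a count exactly equal to
#' the threshold is conservatively not detected. The default statistic is
#' the mean over the replicates in scope; `per_sample` tests each sample
#' individually.
#'
#' @param counts a [count_matrix].
#' @param model a `background_model` (or, for multiple scopes, a named list
#'   of models matched by name to `groups`).
#' @param samples sample ids defining the scope for a single model; ignored
#'   when `groups` is given.
#' @param statistic `"group_mean"` (default) or `"per_sample"`.
#' @param groups optional named list of sample-id vectors, one scope per
#'   element, evaluated against the matching element of `model`.
#' @return a `detection_calls` object: logical `calls` matrix
#'   (probes x scopes), numeric `thresholds` per scope, the statistic used.
#' @export
call_detection <- function(counts, model, samples = NULL,
                           statistic = c("group_mean", "per_sample"),
                           groups = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(counts, "count_matrix"))
  if (!is.null(groups)) {
    stopifnot(is.list(model), identical(sort(names(model)), sort(names(groups))))
    parts <- lapply(names(groups), function(g) {
      call_detection(counts, model[[g]], samples = groups[[g]],
                     statistic = statistic)
    })
    calls <- do.call(cbind, lapply(parts, `[[`, "calls"))
    if (statistic == "group_mean") colnames(calls) <- names(groups)
    thresholds <- unlist(lapply(parts, `[[`, "thresholds"))
    if (statistic == "group_mean") names(thresholds) <- names(groups)
    return(structure(list(calls = calls, thresholds = thresholds,
                          statistic = statistic),
                     class = "detection_calls"))
  }
  stopifnot(inherits(model, "background_model"))
  scoped <- if (is.null(samples)) counts else subset_samples(counts, samples)
  if (ncol(scoped$counts) == 0) {
    abort("detection scope contains no samples", "validation_error")
  }
  if (statistic == "group_mean") {
    stat <- rowMeans(scoped$counts)
    calls <- matrix(stat > model$threshold, ncol = 1,
                    dimnames = list(rownames(scoped$counts), model$scope))
    thresholds <- stats::setNames(model$threshold, model$scope)
  } else {
    calls <- scoped$counts > model$threshold
    thresholds <- stats::setNames(rep(model$threshold, ncol(scoped$counts)),
                                  colnames(scoped$counts))
  }
  structure(list(calls = calls, thresholds = thresholds,
                 statistic = statistic),
            class = "detection_calls")
}

#' Tabulate detected genes per probe class and scope
#'
#' Reproduces the detection table of a titration experiment: one row per
#' probe class, one column per scope, each cell the number of probes of that
#' class called detected, with class totals annotated.
#'
#' @param calls a `detection_calls` object.
#' @param codeset the [codeset] the calls were made against.
#' @return data frame with columns `probe_class`, `n_probes`, then one
#'   column of detected counts per scope.
#' @export
detection_summary <- function(calls, codeset) {
  stopifnot(inherits(calls, "detection_calls"), inherits(codeset, "codeset"))
  classes <- c("positive", "negative", "target")
  cls <- codeset$probe_class[match(rownames(calls$calls), codeset$gene_id)]
  if (anyNA(cls)) {
    abort("detection calls contain probes not in the code set",
          "validation_error")
  }
  out <- data.frame(probe_class = classes,
                    n_probes = vapply(classes, function(cc) sum(cls == cc), 0L),
                    stringsAsFactors = FALSE)
  for (scope in colnames(calls$calls)) {
    out[[scope]] <- vapply(classes, function(cc) {
      sum(calls$calls[cls == cc, scope])
    }, 0L)
  }
  out
}
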