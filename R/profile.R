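#' Canonical life-cycle stage order
#'
#' The developmental series used for stage profiling: mid-gastrulation
#' embryos, starvation-induced L1 arrest, fed larval time points at 12-48 h
#' (roughly the ends of the four larval stages), 60 h (adults plus their
#' early embryos), and dauer arrest.
#'
#' @return character vector of the eight ordered stage labels.
#' @export
life_cycle_stages <- function() {
  c("embryo", "L1_arrest", "12h", "24h", "36h", "48h", "60h", "dauer")
}

#' @noRd
larval_stages <- function() c("12h", "24h", "36h", "48h")

#' Construct an expression profile
#'
#' Replicate mean, sample SD and replicate count per gene x group, the unit
#' of biological interpretation. Optionally carries the background
#' threshold used to interpret it and the [codeset] for specificity flags.
#'
#' @param mean,sd genes x groups numeric matrices with matching dimnames.
#' @param n named integer vector of replicates per group.
#' @param stage_order optional ordering imposed on the columns.
#' @param threshold optional background threshold attached for
#'   interpretation.
#' @param codeset optional [codeset].
#' @return an object of class `expression_profile`.
#' @export
expression_profile <- function(mean, sd, n, stage_order = NULL,
                               threshold = NULL, codeset = NULL) {
  stopifnot(identical(dim(mean), dim(sd)),
            identical(dimnames(mean), dimnames(sd)))
  if (any(sd < 0)) abort("SD must be >= 0", "validation_error")
  if (any(n < 1)) abort("each group needs n >= 1", "validation_error")
  if (!is.null(stage_order)) {
    if (!setequal(colnames(mean), stage_order)) {
      abort(sprintf("unknown or missing stage label(s): %s",
                    paste(symdiff_chr(colnames(mean), stage_order),
                          collapse = ", ")), "validation_error")
    }
    mean <- mean[, stage_order, drop = FALSE]
    sd <- sd[, stage_order, drop = FALSE]
    n <- n[stage_order]
  }
  structure(list(mean = mean, sd = sd, n = n, threshold = threshold,
                 codeset = codeset),
            class = "expression_profile")
}

#' @noRd
symdiff_chr <- function(a, b) union(setdiff(a, b), setdiff(b, a))

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("<expression_profile> %d genes x %d groups (n: %s)\n",
              nrow(x$mean), ncol(x$mean), paste(x$n, collapse = ",")))
  invisible(x)
}

#' Long-format table of an expression profile
#'
#' @param profile an [expression_profile].
#' @return data frame with columns gene_id, group, mean, sd, n.
#' @export
profile_to_table <- function(profile) {
  stopifnot(inherits(profile, "expression_profile"))
  groups <- colnames(profile$mean)
  data.frame(
    gene_id = rep(rownames(profile$mean), times = length(groups)),
    group = rep(groups, each = nrow(profile$mean)),
    mean = as.vector(profile$mean),
    sd = as.vector(profile$sd),
    n = rep(as.integer(profile$n), each = nrow(profile$mean)),
    stringsAsFactors = FALSE)
}

#' Stage-structured expression profile
#'
#' Replicate mean, SD and n per gene and life-cycle stage, with stages in
#' canonical developmental order. Counts are expected to be fully
#' normalized (positive-control then target-sum).
#'
#' @param counts a [count_matrix].
#' @param stages stage assignment of samples: vector/factor or the name of
#'   a sample-metadata column (default `"condition"`).
#' @param stage_order stage ordering (default [life_cycle_stages()],
#'   restricted to the stages present).
#' @param threshold optional background threshold attached to the profile.
#' @return an [expression_profile] with ordered stage columns.
#' @export
stage_profile <- function(counts, stages = "condition", stage_order = NULL,
                          threshold = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  stages <- resolve_groups(counts, stages)
  if (is.null(stage_order)) {
    canonical <- life_cycle_stages()
    known <- unique(stages)
    if (all(known %in% canonical)) {
      stage_order <- canonical[canonical %in% known]
    } else {
      abort(sprintf("unknown stage label(s): %s; pass stage_order explicitly",
                    paste(setdiff(known, canonical), collapse = ", ")),
            "validation_error")
    }
  } else if (!all(unique(stages) %in% stage_order)) {
    abort(sprintf("stage label(s) not in stage_order: %s",
                  paste(setdiff(unique(stages), stage_order), collapse = ", ")),
          "validation_error")
  }
  prof <- group_average(counts, stages)
  expression_profile(prof$mean, prof$sd, prof$n, stage_order = stage_order,
                     threshold = threshold, codeset = counts$codeset)
}

#' Fold-change between stage sets
#'
#' Ratio of means of stage means: the numerator is the mean over the
#' numerator stages of the gene's stage means, likewise the denominator
#' (ratio-of-means, matching plotted replicate means, not mean-of-ratios).
#'
#' @param profile an [expression_profile].
#' @param gene gene id.
#' @param numerator,denominator character vectors of stage labels.
#' @return positive fold-change F; `fold_change(g, A, B) * fold_change(g, B, A) = 1`.
#' @export
fold_change <- function(profile, gene, numerator, denominator) {
  stopifnot(inherits(profile, "expression_profile"))
  if (!gene %in% rownames(profile$mean)) {
    abort(sprintf("unknown gene '%s'", gene), "validation_error")
  }
  for (s in c(numerator, denominator)) {
    if (!s %in% colnames(profile$mean)) {
      abort(sprintf("unknown stage '%s'", s), "validation_error")
    }
  }
  num <- mean(profile$mean[gene, numerator])
  den <- mean(profile$mean[gene, denominator])
  if (den <= 0) {
    abort(sprintf("denominator mean for '%s' is not positive; fold undefined",
                  gene), "fold_error")
  }
  num / den
}

#' Classify life-cycle expression patterns
#'
#' Assigns each gene exactly one pattern label from its stage profile, a
#' background threshold `T` and a minimum fold separation `F_min`:
#'
#' * `below_background` — no stage mean exceeds `T`;
#' * `embryo_specific` — embryo mean > `T` and >= `F_min` x every other
#'   stage mean;
#' * `adult_enriched` — 60 h mean > `T` and >= `F_min` x every other stage
#'   mean;
#' * `arrest_enriched` — mean over L1 arrest and dauer > `T` and >=
#'   `F_min` x the mean over the developing-larval stages (12-48 h);
#' * `larval_peaking` — the maximum stage mean falls at 12-48 h, exceeds
#'   `T`, and is >= `F_min` x both the embryo and 60 h means;
#' * `broadly_expressed` — otherwise.
#'
#' Rules are applied in that precedence order; ties for the peak stage are
#' broken toward the earlier stage. Labels are invariant to rescaling all
#' counts and `T` by a common positive constant. Probes with a
#' specificity flag in the code set carry it into the output.
#'
#' @param profile an [expression_profile] over the [life_cycle_stages()]
#'   (all eight stages required).
#' @param threshold background threshold `T` in counts (defaults to the one
#'   attached to the profile).
#' @param min_fold minimum fold separation `F_min` (default 3).
#' @return data frame with columns `gene_id`, `label`, `peak_stage`,
#'   `peak_fold` (peak stage mean over the mean of the other stages),
#'   `specificity_flag`.
#' @export
classify_patterns <- function(profile, threshold = NULL, min_fold = 3) {
  stopifnot(inherits(profile, "expression_profile"))
  threshold <- threshold %||% profile$threshold
  if (is.null(threshold) || threshold < 0) {
    abort("a nonnegative background threshold is required", "validation_error")
  }
  stages <- life_cycle_stages()
  if (!all(stages %in% colnames(profile$mean))) {
    abort(sprintf("profile is missing stage(s): %s",
                  paste(setdiff(stages, colnames(profile$mean)),
                        collapse = ", ")), "validation_error")
  }
  m <- profile$mean[, stages, drop = FALSE]
  # only target probes carry biological patterns; controls are excluded
  # when the profile knows its code set
  if (!is.null(profile$codeset)) {
    m <- m[rownames(m) %in% class_probes(profile$codeset, "target"), ,
           drop = FALSE]
  }
  larv <- larval_stages()
  labels <- character(nrow(m))
  peak_stage <- character(nrow(m))
  peak_fold <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    pk <- which.max(v)  # earliest stage wins ties
    peak_stage[i] <- stages[pk]
    rest <- mean(v[-pk])
    peak_fold[i] <- if (rest > 0) v[pk] / rest else Inf
    arrest_mean <- mean(v[c("L1_arrest", "dauer")])
    larval_mean <- mean(v[larv])
    labels[i] <-
      if (all(v <= threshold)) {
        "below_background"
      } else if (v[["embryo"]] > threshold &&
                 all(v[["embryo"]] >= min_fold * v[setdiff(stages, "embryo")])) {
        "embryo_specific"
      } else if (v[["60h"]] > threshold &&
                 all(v[["60h"]] >= min_fold * v[setdiff(stages, "60h")])) {
        "adult_enriched"
      } else if (arrest_mean > threshold &&
                 arrest_mean >= min_fold * larval_mean) {
        "arrest_enriched"
      } else if (stages[pk] %in% larv && v[pk] > threshold &&
                 v[pk] >= min_fold * v[["embryo"]] &&
                 v[pk] >= min_fold * v[["60h"]]) {
        "larval_peaking"
      } else {
        "broadly_expressed"
      }
  }
  flags <- rep(NA_character_, nrow(m))
  if (!is.null(profile$codeset)) {
    flags <- profile$codeset$specificity_flag[
      match(rownames(m), profile$codeset$gene_id)]
  }
  data.frame(gene_id = rownames(m), label = labels, peak_stage = peak_stage,
             peak_fold = peak_fold, specificity_flag = flags,
             stringsAsFactors = FALSE)
}

#' Pattern labels recognized by the classifier
#' @return character vector of the six labels.
#' @export
pattern_labels <- function() {
  c("below_background", "embryo_specific", "adult_enriched",
    "arrest_enriched", "larval_peaking", "broadly_expressed")
}
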