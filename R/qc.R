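#' Fit a spike-in standard curve
#'
#' Ordinary least squares of log10(count) on log10(spiked amount) across the
#' positive-control probes. Because spike-ins are present at fixed femtomole
#' amounts regardless of the RNA input, the curve characterizes assay
#' response (slope ~ 1 for ideal proportionality; intercept = log10 counts
#' at 1 fmol) and should be unaffected by RNA mass.
#'
#' @param counts numeric vector of counts, one per positive-control probe
#'   (typically replicate means).
#' @param amounts matching spiked amounts in fmol.
#' @return a `standard_curve` with `slope`, `intercept`, `r_squared`,
#'   `n_points`, and the fitted `lm` object.
#' @examples
#' fit_standard_curve(c(10, 100, 1000), c(0.1, 1, 10))  # slope 1, intercept 2
#' @export
fit_standard_curve <- function(counts, amounts) {
  stopifnot(length(counts) == length(amounts))
  usable <- counts > 0 & amounts > 0
  if (any(!usable)) {
    warning(sprintf("%d point(s) with nonpositive count excluded from the standard curve",
                    sum(!usable)))
  }
  counts <- counts[usable]
  amounts <- amounts[usable]
  if (length(unique(amounts)) < 2) {
    abort("standard curve requires >= 2 distinct spike amounts", "fit_error")
  }
  if (length(counts) < 2) {
    abort("standard curve requires >= 2 usable points", "fit_error")
  }
  fit <- stats::lm(log10(counts) ~ log10(amounts))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r_squared(fit, log10(counts)),
                 n_points = length(counts),
                 fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> slope %.4f, intercept %.4f, R^2 %.4f (n=%d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Replicate coefficient of variation per gene and group
#'
#' For each gene and replicate group, CV%% = 100 x sample SD / mean over the
#' replicates (sample SD, n - 1 denominator). Genes with mean zero in a
#' group have an undefined CV: they are flagged and excluded from the
#' per-group median, never reported as zero.
#'
#' @param counts a [count_matrix].
#' @param groups grouping of samples: a vector/factor of length
#'   n-samples, or the name of a sample-metadata column.
#' @param probe_filter probe class(es) retained for the median (default
#'   `"target"`); per-gene CVs are reported for the same filter.
#' @return a `cv_summary`: `per_gene_cv` (gene x group matrix, %%),
#'   `median_cv` (named vector, %%), `group_sizes`, and `undefined`
#'   (logical gene x group matrix flagging mean-zero cells).
#' @export
replicate_cv <- function(counts, groups, probe_filter = "target") {
  stopifnot(inherits(counts, "count_matrix"))
  groups <- resolve_groups(counts, groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    abort(sprintf("replicate group(s) with fewer than 2 samples: %s",
                  paste(small, collapse = ", ")),
          "validation_error", groups = small)
  }
  keep <- counts$codeset$gene_id[counts$codeset$probe_class %in% probe_filter]
  mat <- counts$counts[keep, , drop = FALSE]
  levels_ <- unique(as.character(groups))
  per_gene <- matrix(NA_real_, nrow(mat), length(levels_),
                     dimnames = list(rownames(mat), levels_))
  undefined <- matrix(FALSE, nrow(mat), length(levels_),
                      dimnames = list(rownames(mat), levels_))
  for (g in levels_) {
    sub <- mat[, groups == g, drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1, stats::sd)
    cv <- ifelse(mu > 0, 100 * sdv / mu, NA_real_)
    per_gene[, g] <- cv
    undefined[, g] <- mu == 0
  }
  median_cv <- apply(per_gene, 2, stats::median, na.rm = TRUE)
  structure(list(per_gene_cv = per_gene, median_cv = median_cv,
                 group_sizes = as.integer(sizes[levels_]),
                 undefined = undefined),
            class = "cv_summary")
}

#' @noRd
resolve_groups <- function(counts, groups) {
  if (is.character(groups) && length(groups) == 1 &&
      groups %in% names(counts$samples)) {
    groups <- counts$samples[[groups]]
  }
  if (length(groups) != ncol(counts$counts)) {
    abort("grouping length does not match the number of samples",
          "validation_error")
  }
  as.character(groups)
}

#' Summarize an RNA input-mass titration
#'
#' For each RNA mass level, reports the mean count over probes x replicates
#' within each probe class plus the grand total of all counts, and the
#' fold-ratios of target and negative-control means between mass levels.
#' Counts should be positive-control normalized so that comparisons across
#' masses are on a common scale.
#'
#' @param counts a [count_matrix]; `rna_mass` must be set in the sample
#'   metadata.
#' @return a `titration_summary`: `table` (rows: average positive /
#'   negative / target counts and summed counts; one column per mass, in
#'   increasing order) and `fold` — a function
#'   `fold(class, numerator_mass, denominator_mass)` returning the ratio of
#'   class means.
#' @export
titration_summary <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  mass <- counts$samples$rna_mass
  if (any(is.na(mass))) {
    abort("titration summary requires rna_mass for every sample",
          "validation_error")
  }
  levels_ <- sort(unique(mass))
  if (length(levels_) < 2) {
    abort("titration summary requires >= 2 mass levels", "validation_error")
  }
  classes <- c("positive", "negative", "target")
  means <- matrix(NA_real_, 3, length(levels_),
                  dimnames = list(classes, as.character(levels_)))
  totals <- numeric(length(levels_))
  for (j in seq_along(levels_)) {
    sel <- mass == levels_[j]
    sub <- counts$counts[, sel, drop = FALSE]
    cls <- counts$codeset$probe_class
    for (cc in classes) {
      means[cc, j] <- mean(sub[cls == cc, , drop = FALSE])
    }
    totals[j] <- sum(sub) / sum(sel)  # summed counts per hybridization
  }
  tab <- rbind(means, sum_counts = totals)
  fold <- function(class, numerator_mass, denominator_mass) {
    class <- match.arg(class, classes)
    means[class, as.character(numerator_mass)] /
      means[class, as.character(denominator_mass)]
  }
  structure(list(table = tab, masses = levels_, fold = fold),
            class = "titration_summary")
}

#' @export
print.titration_summary <- function(x, ...) {
  cat("<titration_summary> mean counts per probe class by RNA mass (ug):\n")
  print(round(x$table, 1))
  invisible(x)
}

#' Average replicate groups of a count matrix
#'
#' Per-gene arithmetic mean and sample SD within each replicate group, with
#' group sizes recorded: the unit of biological interpretation and the
#' input to cross-platform concordance.
#'
#' @param counts a [count_matrix].
#' @param groups grouping of samples (vector/factor or metadata column
#'   name); groups must partition the samples and be nonempty.
#' @return an [expression_profile] whose columns are the groups in order of
#'   first appearance.
#' @export
group_average <- function(counts, groups) {
  stopifnot(inherits(counts, "count_matrix"))
  groups <- resolve_groups(counts, groups)
  if (any(is.na(groups) | !nzchar(groups))) {
    abort("every sample must belong to a named group", "validation_error")
  }
  levels_ <- unique(groups)
  mat <- counts$counts
  mean_m <- matrix(NA_real_, nrow(mat), length(levels_),
                   dimnames = list(rownames(mat), levels_))
  sd_m <- mean_m
  n <- integer(length(levels_))
  for (j in seq_along(levels_)) {
    sub <- mat[, groups == levels_[j], drop = FALSE]
    mean_m[, j] <- rowMeans(sub)
    sd_m[, j] <- if (ncol(sub) >= 2) apply(sub, 1, stats::sd) else 0
    n[j] <- ncol(sub)
  }
  expression_profile(mean_m, sd_m, stats::setNames(n, levels_),
                     codeset = counts$codeset)
}

#' Cross-platform concordance of averaged profiles
#'
#' Correlates two genes x groups mean matrices (e.g., barcode counts vs
#' microarray intensities for the same biological groups) after aligning
#' shared genes and groups, excluding listed genes, and flattening all
#' gene x group pairs into one scatter. On the default log10 scale, pairs
#' where either platform has a nonpositive value are excluded with a
#' warning rather than pseudocounted, since pseudocounts distort exactly
#' the near-background low end.
#'
#' @param profile_a,profile_b [expression_profile] objects or plain numeric
#'   matrices (genes x groups) with dimnames.
#' @param exclude gene ids dropped before correlating (e.g., genes whose
#'   probes target different transcript regions on the two platforms).
#' @param scale `"log10"` (default) or `"linear"`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return a `concordance` object: correlation `r`, `n_pairs`, number of
#'   `dropped_nonpositive` pairs, the per-pair `table`
#'   (gene, group, value_a, value_b on the analysis scale), and the scale
#'   and method used.
#' @export
platform_concordance <- function(profile_a, profile_b, exclude = NULL,
                                 scale = c("log10", "linear"),
                                 method = c("pearson", "spearman")) {
  scale <- match.arg(scale)
  method <- match.arg(method)
  a <- profile_means(profile_a)
  b <- profile_means(profile_b)
  genes <- setdiff(intersect(rownames(a), rownames(b)), exclude)
  shared_groups <- intersect(colnames(a), colnames(b))
  if (length(shared_groups) < 1) {
    abort("no shared group labels between the profiles", "alignment_error")
  }
  if (ncol(a) != ncol(b) || !setequal(colnames(a), colnames(b))) {
    abort("group labels differ between the profiles", "alignment_error")
  }
  a <- a[genes, shared_groups, drop = FALSE]
  b <- b[genes, shared_groups, drop = FALSE]
  tab <- data.frame(gene = rep(genes, times = length(shared_groups)),
                    group = rep(shared_groups, each = length(genes)),
                    value_a = as.vector(a), value_b = as.vector(b),
                    stringsAsFactors = FALSE)
  dropped <- 0L
  if (scale == "log10") {
    ok <- tab$value_a > 0 & tab$value_b > 0
    dropped <- sum(!ok)
    if (dropped > 0) {
      warning(sprintf("%d gene-group pair(s) with nonpositive values excluded on log scale",
                      dropped))
    }
    tab <- tab[ok, , drop = FALSE]
    tab$value_a <- log10(tab$value_a)
    tab$value_b <- log10(tab$value_b)
  }
  if (nrow(tab) < 3) {
    abort("fewer than 3 shared gene-group pairs after exclusions",
          "validation_error")
  }
  r <- stats::cor(tab$value_a, tab$value_b, method = method)
  structure(list(r = r, n_pairs = nrow(tab),
                 dropped_nonpositive = dropped, table = tab,
                 scale = scale, method = method),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("<concordance> r = %.4f (%s, %s scale, %d pairs, %d dropped)\n",
              x$r, x$method, x$scale, x$n_pairs, x$dropped_nonpositive))
  invisible(x)
}

#' @noRd
profile_means <- function(x) {
  if (inherits(x, "expression_profile")) return(x$mean)
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("plain profile matrices need gene rownames and group colnames",
          "format_error")
  }
  x
}
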