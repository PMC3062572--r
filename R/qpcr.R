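#' Fit a qPCR standard curve
#'
#' Ordinary least squares of cycle threshold (Ct) on log10 template copy
#' number from a genomic-DNA dilution series. A valid curve has negative
#' slope; amplification efficiency is `E = 10^(-1/slope)` (E = 2 for perfect
#' doubling, i.e. slope -1/log10(2) = -3.3219). Efficiencies outside
#' (1, 2.2] are flagged with a warning but returned.
#'
#' @param cts numeric Ct values.
#' @param copies matching known template copy numbers (> 0).
#' @return a `qpcr_curve` with `slope`, `intercept` (Ct at 1 copy),
#'   `efficiency`, `r_squared`, `n_points`, and the fitted copy range.
#' @examples
#' fit_qpcr_curve(c(30, 26.68, 23.36), c(1e2, 1e3, 1e4))  # E ~ 2
#' @export
fit_qpcr_curve <- function(cts, copies) {
  stopifnot(length(cts) == length(copies), all(copies > 0))
  if (length(cts) < 3) {
    abort("qPCR standard curve requires >= 3 dilution points", "fit_error")
  }
  span <- log10(max(copies)) - log10(min(copies))
  if (span < 2) {
    abort("dilution series must span >= 2 log10 in copy number", "fit_error")
  }
  fit <- stats::lm(cts ~ log10(copies))
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) {
    abort("fitted slope is nonnegative: Ct must decrease with template copies",
          "curve_quality_error")
  }
  efficiency <- 10^(-1 / slope)
  if (efficiency <= 1 || efficiency > 2.2) {
    warning(sprintf("amplification efficiency %.3f outside the plausible range (1, 2.2]",
                    efficiency))
  }
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 efficiency = efficiency,
                 r_squared = r_squared(fit, cts),
                 n_points = length(cts),
                 copy_range = range(copies)),
            class = "qpcr_curve")
}

#' @export
print.qpcr_curve <- function(x, ...) {
  cat(sprintf("<qpcr_curve> slope %.4f, intercept %.2f, E %.3f, R^2 %.4f\n",
              x$slope, x$intercept, x$efficiency, x$r_squared))
  invisible(x)
}

#' Predict Ct from copy number on a fitted curve
#'
#' @param curve a `qpcr_curve`.
#' @param copies template copy number (> 0).
#' @return predicted Ct.
#' @export
qpcr_predict_ct <- function(curve, copies) {
  stopifnot(inherits(curve, "qpcr_curve"), all(copies > 0))
  curve$intercept + curve$slope * log10(copies)
}

#' Convert cycle thresholds to copy numbers
#'
#' Inverts the standard curve: `copies = 10^((ct - intercept)/slope)`.
#' Values outside the fitted dilution range are extrapolations and trigger
#' a warning, not an error.
#'
#' @param ct numeric Ct value(s).
#' @param curve a `qpcr_curve`.
#' @return positive copy number(s).
#' @export
ct_to_copies <- function(ct, curve) {
  stopifnot(inherits(curve, "qpcr_curve"))
  copies <- 10^((ct - curve$intercept) / curve$slope)
  out_of_range <- copies < curve$copy_range[1] | copies > curve$copy_range[2]
  if (any(out_of_range)) {
    warning(sprintf("%d Ct value(s) fall outside the fitted dilution range (extrapolation)",
                    sum(out_of_range)))
  }
  copies
}

#' Reference-gene normalization of qPCR copy numbers
#'
#' Divides each measurement's copy number by that sample's reference
#' factor: the geometric mean of the reference-gene copy numbers in the
#' same sample, rescaled so the across-sample mean reference factor is 1.
#' The geometric mean is the standard scale-symmetric aggregate for
#' multiple reference genes; the rescaling keeps normalized abundances on
#' the original copy scale. Doubling every copy number of one sample
#' (a global cDNA-input effect) leaves its normalized abundances unchanged.
#'
#' @param measurements data frame with columns `gene_id`, `sample_id`,
#'   `copies`.
#' @param reference_genes character vector of reference gene ids (each must
#'   have positive copies in every sample).
#' @return the input data frame with a `normalized_abundance` column added
#'   and reference rows retained; attribute `reference_factors` holds the
#'   per-sample divisors.
#' @export
reference_normalize <- function(measurements, reference_genes) {
  measurements <- as.data.frame(measurements)
  needed <- c("gene_id", "sample_id", "copies")
  if (!all(needed %in% names(measurements))) {
    abort(sprintf("measurements need columns: %s", paste(needed, collapse = ", ")),
          "format_error")
  }
  samples <- unique(measurements$sample_id)
  geo <- vapply(samples, function(s) {
    ref <- measurements$copies[measurements$sample_id == s &
                                 measurements$gene_id %in% reference_genes]
    if (length(ref) != length(reference_genes)) {
      abort(sprintf("sample '%s' lacks copies for all reference genes", s),
            "normalization_error")
    }
    if (any(ref <= 0)) {
      abort(sprintf("sample '%s' has nonpositive reference copies", s),
            "normalization_error")
    }
    geometric_mean(ref)
  }, numeric(1))
  factors <- geo / mean(geo)  # mean reference factor across samples = 1
  measurements$normalized_abundance <-
    measurements$copies / factors[match(measurements$sample_id, samples)]
  attr(measurements, "reference_factors") <- stats::setNames(factors, samples)
  measurements
}

#' Compare qPCR and barcode-count stage profiles per gene
#'
#' Copy numbers and barcode counts are in incommensurate units, so each
#' platform's per-gene profile is first scaled to its own across-stage
#' mean; only profile shape is then compared. Reports the per-gene Pearson
#' correlation of log-scaled shapes across shared stages, and flags stages
#' where one platform shows a >= 2-fold departure from its mean while the
#' other shows < 1.3-fold — apparent differential expression on one
#' platform not captured by the other. Genes with zero variance on either
#' platform get an NA correlation and a flag rather than a number.
#'
#' @param qpcr_profile genes x stages matrix of qPCR means (or an
#'   [expression_profile]).
#' @param count_profile genes x stages matrix of count means (or an
#'   [expression_profile]).
#' @param genes genes to compare (default: all shared).
#' @return data frame per gene: `gene_id`, `n_stages`, `correlation`,
#'   `zero_variance` flag, `discordant_stages` (comma-joined labels, ""
#'   when none).
#' @export
platform_profile_compare <- function(qpcr_profile, count_profile,
                                     genes = NULL) {
  a <- profile_means(qpcr_profile)
  b <- profile_means(count_profile)
  genes <- genes %||% intersect(rownames(a), rownames(b))
  stages <- intersect(colnames(a), colnames(b))
  if (length(stages) < 3) {
    abort("fewer than 3 shared stages between the platforms",
          "validation_error")
  }
  out <- lapply(genes, function(g) {
    if (!g %in% rownames(a) || !g %in% rownames(b)) {
      abort(sprintf("gene '%s' missing from one platform", g),
            "validation_error")
    }
    va <- a[g, stages]
    vb <- b[g, stages]
    if (any(va <= 0) || any(vb <= 0)) {
      keep <- va > 0 & vb > 0
      va <- va[keep]; vb <- vb[keep]
    }
    if (length(va) < 3) {
      return(data.frame(gene_id = g, n_stages = length(va),
                        correlation = NA_real_, zero_variance = NA,
                        discordant_stages = NA_character_))
    }
    fa <- va / mean(va)  # fold vs the gene's own mean on platform a
    fb <- vb / mean(vb)
    zero_var <- stats::sd(log10(fa)) == 0 || stats::sd(log10(fb)) == 0
    r <- if (zero_var) NA_real_ else stats::cor(log10(fa), log10(fb))
    disc <- names(fa)[(pmax(fa, 1 / fa) >= 2 & pmax(fb, 1 / fb) < 1.3) |
                        (pmax(fb, 1 / fb) >= 2 & pmax(fa, 1 / fa) < 1.3)]
    data.frame(gene_id = g, n_stages = length(va), correlation = r,
               zero_variance = zero_var,
               discordant_stages = paste(disc, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
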