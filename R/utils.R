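# Internal helpers shared across modules.

#' Stop with a classed condition
#'
#' All user-facing errors in the package carry a condition class so callers
#' (and tests) can distinguish validation, format, normalization, model and
#' I/O failures without matching message text.
#'
#' @param message error message.
#' @param class condition class suffix, e.g. "validation_error".
#' @param ... fields stored on the condition object.
#' @noRd
abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "inscount_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Geometric mean of strictly positive values
#' @noRd
geometric_mean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

#' Coefficient of variation in percent (sample SD, n - 1)
#' @noRd
cv_percent <- function(x) 100 * stats::sd(x) / mean(x)

#' Coefficient of determination computed from a fit's residuals
#'
#' Avoids summary.lm, which warns on exactly collinear (noise-free) input.
#' @noRd
r_squared <- function(fit, y) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum(stats::residuals(fit)^2) / ss_tot
}

#' Sniff the delimiter of a delimited text file
#'
#' Inspects the header line: a tab anywhere wins, otherwise comma.
#' @noRd
sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) {
    abort(sprintf("file '%s' is empty", path), "format_error")
  }
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Format numerics so delimited output round-trips
#'
#' 15 significant digits reproduce doubles to well beyond the 12 digits the
#' table contract guarantees, while keeping integers printed as integers.
#' @noRd
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- sprintf("%.15g", v)
    s
  }, character(1))
  out
}

#' Derive a child RNG seed from a base seed and a stream index
#'
#' Keeps every derived seed a valid 32-bit integer.
#' @noRd
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483647)
}

#' Draw per-replicate lognormal efficiency factors with mean 1 and CV tau
#' @noRd
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
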