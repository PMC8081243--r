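# Signal-comparison metrics: per-lead Pearson correlation (CC), per-lead
# range-normalized RMS deviation (NRMSD, %), the integrative relative
# Euclidean distance (RED, %) over all leads and times, max-RED sensitivity
# over a parameter sweep, and relative biomarker spans.
#
# Signal sets are numeric matrices with one row per lead/node and one column
# per time sample; compared sets must share both dimensions.

check_match <- function(a, b) {
  if (!is.matrix(a)) a <- matrix(a, nrow = 1)
  if (!is.matrix(b)) b <- matrix(b, nrow = 1)
  if (!all(dim(a) == dim(b)))
    stop("signal sets must share lead set and time grid")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("signal sets must be finite")
  list(a = a, b = b)
}

#' Per-lead correlation coefficient
#'
#' Pearson correlation between matched leads of two signal sets. Leads where
#' either trace is constant have undefined correlation and are returned as
#' NA (excluded, not zero); the number of excluded leads is attached as
#' attribute \code{n_excluded}.
#'
#' @param a,b signal sets (leads x time matrices).
#' @return numeric vector of per-lead CC in [-1, 1] (NA where undefined).
#' @export
cc <- function(a, b) {
  m <- check_match(a, b)
  ac <- m$a - rowMeans(m$a)
  bc <- m$b - rowMeans(m$b)
  sa <- sqrt(rowSums(ac^2))
  sb <- sqrt(rowSums(bc^2))
  out <- rep(NA_real_, nrow(m$a))
  okk <- sa > 0 & sb > 0
  out[okk] <- rowSums(ac * bc)[okk] / (sa * sb)[okk]
  attr(out, "n_excluded") <- sum(!okk)
  out
}

#' Per-lead normalized root-mean-square deviation (percent)
#'
#' RMS of the per-lead difference over time, normalized by the range of the
#' corresponding lead of \code{b} (the patient-like/normalizing set), times
#' 100. Zero-range leads are NA with \code{n_excluded} attached.
#'
#' @param a,b signal sets; \code{b} provides the normalizing ranges.
#' @return per-lead NRMSD in percent.
#' @export
nrmsd <- function(a, b) {
  m <- check_match(a, b)
  rng <- apply(m$b, 1, function(r) diff(range(r)))
  rms <- sqrt(rowMeans((m$a - m$b)^2))
  out <- rep(NA_real_, nrow(m$a))
  okk <- rng > 0
  out[okk] <- rms[okk] / rng[okk] * 100
  attr(out, "n_excluded") <- sum(!okk)
  out
}

#' Integrative relative Euclidean distance (percent)
#'
#' \code{sqrt(sum((a - b)^2)) / sqrt(sum(b^2)) * 100} over all leads and
#' samples of the set.
#'
#' @param a,b signal sets; \code{b} is the reference in the denominator.
#' @return scalar RED in percent.
#' @export
red <- function(a, b) {
  m <- check_match(a, b)
  den <- sqrt(sum(m$b^2))
  if (den == 0) stop("RED undefined: reference set is identically zero")
  sqrt(sum((m$a - m$b)^2)) / den * 100
}

#' Max-RED sensitivity over a set of varied runs
#'
#' @param varied named list of signal sets, one per tested parameter value
#'   (names are the parameter values).
#' @param reference the reference signal set.
#' @return list with \code{max_red} (percent), \code{argmax} (parameter
#'   value attaining it), and the per-value \code{red} vector.
#' @export
max_red_sensitivity <- function(varied, reference) {
  if (!length(varied)) stop("empty list of varied signal sets")
  reds <- vapply(varied, red, numeric(1), b = reference)
  k <- which.max(reds)
  list(max_red = reds[[k]],
       argmax = if (!is.null(names(varied))) as.numeric(names(varied)[k]) else k,
       red = reds)
}

#' Relative biomarker span (percent of reference)
#'
#' Minimal and maximal value of a scalar biomarker across a parameter sweep,
#' relative to its reference-model value, in percent.
#'
#' @param varied_biomarkers numeric vector over tested parameter values.
#' @param reference_biomarker scalar reference value (non-zero).
#' @return named vector \code{c(U_min, U_max)} in percent.
#' @export
biomarker_span <- function(varied_biomarkers, reference_biomarker) {
  if (!is.finite(reference_biomarker) || reference_biomarker == 0)
    stop("biomarker span undefined: zero or non-finite reference")
  v <- varied_biomarkers[is.finite(varied_biomarkers)]
  if (!length(v)) return(c(U_min = NA_real_, U_max = NA_real_))
  c(U_min = min(v) / reference_biomarker * 100,
    U_max = max(v) / reference_biomarker * 100)
}

# mean / quartiles / sd summary used in metric reports ("sd" is the spread
# column; quartiles are type-7)
metric_summary <- function(x) {
  x <- x[is.finite(x)]
  c(mean = mean(x), p25 = unname(quantile(x, 0.25)),
    p75 = unname(quantile(x, 0.75)), sd = sd(x), n = length(x))
}
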