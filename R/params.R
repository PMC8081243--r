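# Model parameters: the fixed bidomain constants, the seven varied
# tissue/organ parameters with their reference values and ranges, the Roth
# conductivity framework, and the two cellular heterogeneity rules.

#' Reference model parameters
#'
#' Builds the full parameter set of the heart-torso bidomain model: membrane
#' capacitance \code{C_m} (uF/cm^2), surface-to-volume ratio \code{beta}
#' (1/cm), basic myocardial conductivity \code{sigma} (mS/cm), Roth framework
#' coefficients \code{alpha} and \code{epsilon}, bulk torso conductivity
#' \code{sigma_b} (mS/cm), plus the seven parameters varied in sensitivity
#' analyses: transmural heterogeneity \code{H_TR}, apicobasal heterogeneity
#' \code{H_AB}, anisotropy ratio \code{anisotropy_ratio}, and the lungs,
#' blood, spine and liver conductivities (mS/cm).
#'
#' @param ... named overrides of individual parameters.
#' @return an object of class \code{parameter_set} (a named list).
#' @export
#' @examples
#' p <- parameter_set()
#' p$sigma_blood
#' parameter_set(H_AB = 0.8)$H_AB
parameter_set <- function(...) {
  p <- list(
    C_m = 1, beta = 400, sigma = 3.0, alpha = 1, epsilon = 0.75,
    sigma_b = 2.0, anisotropy_ratio = 2.5, H_TR = 0.5, H_AB = 1,
    sigma_lungs = 0.39, sigma_blood = 7, sigma_spine = 0.2,
    sigma_liver = 0.28
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  conds <- c("sigma", "sigma_b", "sigma_lungs", "sigma_blood", "sigma_spine",
             "sigma_liver")
  if (any(unlist(p[conds]) <= 0) && p$sigma < 0)
    stop("conductivities must be positive")
  stopifnot(p$C_m > 0, p$beta > 0, p$alpha > 0,
            p$epsilon >= 0, p$epsilon < 1,
            p$H_TR >= 0, p$H_TR <= 1, p$H_AB >= 0, p$H_AB <= 1,
            p$anisotropy_ratio >= 1)
  structure(p, class = "parameter_set")
}

#' Variation ranges of the seven varied parameters
#'
#' @param which \code{"study"} or \code{"physiological"}.
#' @return named list of length-2 numeric ranges.
#' @export
param_ranges <- function(which = c("physiological", "study")) {
  which <- match.arg(which)
  study <- list(
    H_TR = c(0, 1), H_AB = c(0, 1), anisotropy_ratio = c(1.6, 6.0),
    sigma_lungs = c(0.39, 1.34), sigma_blood = c(4.35, 10),
    sigma_spine = c(0.05, 0.6), sigma_liver = c(0.28, 2.0)
  )
  phys <- list(
    H_TR = c(0.2, 0.6), H_AB = c(0.7, 1.0), anisotropy_ratio = c(2.0, 3.0),
    sigma_lungs = c(0.39, 1.34), sigma_blood = c(4.35, 10),
    sigma_spine = c(0.05, 0.6), sigma_liver = c(0.28, 2.0)
  )
  if (which == "study") study else phys
}

# The narrower apicobasal range quoted alongside the rule in the model
# description; exposed because both conventions appear in the literature.
#' @rdname param_ranges
#' @export
hab_range_alternative <- function() c(0.75, 1.0)

#' Roth-framework myocardial conductivities
#'
#' Computes the four bidomain conductivities from the basic myocardial
#' conductivity \code{sigma}, the intra/extracellular ratio
#' \code{alpha = sigma_li/sigma_le}, the imbalance coefficient
#' \code{epsilon = 1 - (sigma_le/sigma_te)/(sigma_li/sigma_ti)} and the
#' anisotropy ratio \code{lambda_L/lambda_T}:
#' \deqn{\sigma_{li} = \sigma,\quad
#'       \sigma_{ti} = \sigma\,(1/\lambda)^2 (1+\alpha(1-\epsilon))/(1+\alpha),\quad
#'       \sigma_{le} = \sigma/\alpha,\quad
#'       \sigma_{te} = \sigma_{ti}/(\alpha(1-\epsilon)).}
#'
#' @param sigma basic myocardial conductivity, mS/cm.
#' @param alpha intra/extracellular longitudinal conductivity ratio.
#' @param epsilon anisotropy imbalance, in [0, 1).
#' @param anisotropy_ratio longitudinal-to-transverse scaling ratio, >= 1.
#' @return named numeric vector \code{(sigma_li, sigma_ti, sigma_le, sigma_te)}
#'   in mS/cm.
#' @export
#' @examples
#' roth_conductivities(3, 1, 0.75, 2.5)  # reference: (3, 0.3, 3, 1.2)
roth_conductivities <- function(sigma = 3, alpha = 1, epsilon = 0.75,
                                anisotropy_ratio = 2.5) {
  stopifnot(sigma >= 0, alpha > 0, anisotropy_ratio >= 1)
  if (epsilon < 0 || epsilon >= 1)
    stop("epsilon must lie in [0, 1): epsilon = 1 makes sigma_te divide by zero")
  sigma_li <- sigma
  sigma_ti <- sigma * (1 / anisotropy_ratio)^2 *
    (1 + alpha * (1 - epsilon)) / (1 + alpha)
  sigma_le <- sigma / alpha
  sigma_te <- sigma_ti / (alpha * (1 - epsilon))
  c(sigma_li = sigma_li, sigma_ti = sigma_ti,
    sigma_le = sigma_le, sigma_te = sigma_te)
}

#' Apicobasal slow-potassium conductance rule
#'
#' Linear apex-to-base reduction of the slow delayed-rectifier conductance:
#' \code{g_Ks(z) = 0.392 - 0.294 * H_AB * z}, so the apex (z = 0) keeps the
#' nominal 0.392 nS/pF and the base is maximally reduced (longer basal action
#' potentials). \code{H_AB = 0} is the homogeneous limit.
#'
#' @param z apicobasal coordinate(s) in [0, 1] (0 apex, 1 base).
#' @param H_AB heterogeneity coefficient in [0, 1].
#' @return g_Ks value(s), nS/pF.
#' @export
gks_apicobasal <- function(z, H_AB) {
  if (any(!is.finite(z)) || any(z < 0 | z > 1))
    stop("z must lie in [0, 1]")
  if (length(H_AB) != 1 || !is.finite(H_AB) || H_AB < 0 || H_AB > 1)
    stop("H_AB must lie in [0, 1]")
  0.392 - 0.294 * H_AB * z
}

#' Transmural cell-type rule
#'
#' Assigns the epicardial cell variant to the outer fraction \code{H_TR} of
#' the wall depth and the endocardial variant to the rest: a node at
#' transmural depth \code{d} (0 endo, 1 epi) is \code{"epi"} iff
#' \code{d > 1 - H_TR}.
#'
#' @param d transmural coordinate(s) in [0, 1].
#' @param H_TR epicardial layer fraction in [0, 1].
#' @return character vector of \code{"epi"} / \code{"endo"}.
#' @export
cell_type_transmural <- function(d, H_TR) {
  if (any(!is.finite(d)) || any(d < 0 | d > 1)) stop("d must lie in [0, 1]")
  if (length(H_TR) != 1 || !is.finite(H_TR) || H_TR < 0 || H_TR > 1)
    stop("H_TR must lie in [0, 1]")
  ifelse(d > 1 - H_TR, "epi", "endo")
}
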