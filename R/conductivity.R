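# Conductivity tensor fields: Roth myocardial tensors rotated onto the local
# fiber, scalar organ conductivities elsewhere.

#' Assemble the conductivity tensor field
#'
#' Myocardial tets receive the intracellular and extracellular tensors
#' \code{Sigma = M diag(sigma_l, sigma_t, sigma_t) M'} built from the Roth
#' conductivities and the local fiber direction; every other tet receives its
#' organ's scalar conductivity (blood, lungs, liver, spine, torso bulk).
#'
#' @param anatomy an \code{anatomy_model}.
#' @param fibers a \code{fiber_field} covering all myocardial tets.
#' @param params a \code{parameter_set}.
#' @return object of class \code{conductivity_field}: \code{Sigma_i} and
#'   \code{Sigma_e} as m x 6 matrices (xx, yy, zz, xy, xz, yz; mS/cm) over
#'   myocardial tets, and \code{sigma_region} per non-myocardial tet.
#' @export
build_tensor_field <- function(anatomy, fibers, params) {
  myo_tets <- which(anatomy$region == "myocardium")
  if (!identical(myo_tets, fibers$myo_tets) &&
      !setequal(myo_tets, fibers$myo_tets))
    stop("fiber field does not cover the myocardial tets: missing ",
         length(setdiff(myo_tets, fibers$myo_tets)), " element(s)")
  rc <- roth_conductivities(params$sigma, params$alpha, params$epsilon,
                            params$anisotropy_ratio)
  f <- fibers$fiber[match(myo_tets, fibers$myo_tets), , drop = FALSE]
  tensor6 <- function(sl, st) {
    cbind(xx = (sl - st) * f[, 1]^2 + st,
          yy = (sl - st) * f[, 2]^2 + st,
          zz = (sl - st) * f[, 3]^2 + st,
          xy = (sl - st) * f[, 1] * f[, 2],
          xz = (sl - st) * f[, 1] * f[, 3],
          yz = (sl - st) * f[, 2] * f[, 3])
  }
  organ <- c(blood = params$sigma_blood, lungs = params$sigma_lungs,
             liver = params$sigma_liver, spine = params$sigma_spine,
             torso_bulk = params$sigma_b)
  nonmyo <- which(anatomy$region != "myocardium")
  structure(list(
    Sigma_i = tensor6(rc["sigma_li"], rc["sigma_ti"]),
    Sigma_e = tensor6(rc["sigma_le"], rc["sigma_te"]),
    sigma_region = unname(organ[anatomy$region[nonmyo]]),
    myo_tets = myo_tets, nonmyo_tets = nonmyo,
    roth = rc, params = params
  ), class = "conductivity_field")
}
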