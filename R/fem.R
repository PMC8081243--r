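# Discretization of the bidomain-with-bath system: P1 tetrahedral stiffness
# operators for Sigma_i and Sigma_i + Sigma_e on the myocardium and Sigma_b
# on the bath, plus the lumped myocardial mass. Extracellular and bath
# potentials live in one global nodal field, so the phi_e = phi_b continuity
# and flux matching across the heart surface are enforced by shared-node
# assembly.

#' Assemble the discrete bidomain operators
#'
#' @param anatomy an \code{anatomy_model}.
#' @param tensor_field a \code{conductivity_field}.
#' @param params a \code{parameter_set}.
#' @return object of class \code{discrete_system} with sparse symmetric
#'   operators \code{K_i} (myocardial intracellular stiffness, reduced to
#'   myocardial nodes), \code{K_ell} (global \code{Sigma_i + Sigma_e} plus
#'   bath stiffness; pure-Neumann, nullspace = constants), lumped myocardial
#'   mass \code{M} (cm^3 per myocardial node), and index maps.
#' @export
assemble_system <- function(anatomy, tensor_field, params) {
  n <- nrow(anatomy$nodes)
  m <- nrow(anatomy$tets)
  myo_mask <- anatomy$region == "myocardium"
  tens_i <- matrix(0, m, 6)
  tens_i[tensor_field$myo_tets, ] <- tensor_field$Sigma_i
  tens_ie <- matrix(0, m, 6)
  tens_ie[tensor_field$myo_tets, ] <- tensor_field$Sigma_i + tensor_field$Sigma_e
  tens_b <- matrix(0, m, 6)
  tens_b[tensor_field$nonmyo_tets, 1:3] <- tensor_field$sigma_region
  spmat <- function(asm) Matrix::forceSymmetric(Matrix::sparseMatrix(
    i = asm$i, j = asm$j, x = asm$x, dims = c(n, n)))
  asm_i <- fem_assemble_cpp(anatomy$nodes, anatomy$tets, tens_i, myo_mask)
  K_i_full <- spmat(asm_i)
  asm_ie <- fem_assemble_cpp(anatomy$nodes, anatomy$tets, tens_ie, myo_mask)
  K_ell <- spmat(asm_ie)
  has_bath <- any(!myo_mask)
  if (has_bath) {
    asm_b <- fem_assemble_cpp(anatomy$nodes, anatomy$tets, tens_b, !myo_mask)
    K_ell <- K_ell + spmat(asm_b)
  }
  mn <- anatomy$myo_nodes
  structure(list(
    K_i = K_i_full[mn, mn, drop = FALSE],
    K_ell = K_ell,
    M = asm_i$lump[mn],
    myo_nodes = mn, n_nodes = n, has_bath = has_bath,
    anatomy = anatomy, tensor_field = tensor_field, params = params
  ), class = "discrete_system")
}

#' Focal stimulation region
#'
#' @param center 3-vector, cm (on or in the myocardium).
#' @param radius stimulated sphere radius, cm.
#' @param onset,duration stimulus timing, ms.
#' @param amplitude transmembrane current density, pA/pF (positive
#'   depolarizes); the default (24) is about twice the capture threshold
#'   found by bisection on the calibration bar and reference anatomy meshes
#'   (9.8 and 11.7 pA/pF; see \code{\link{capture_threshold}}).
#' @return object of class \code{stimulus_region}.
#' @export
stimulus_region <- function(center, radius = 0.3, onset = 0, duration = 3,
                            amplitude = 24) {
  stopifnot(length(center) == 3, radius > 0, duration > 0, onset >= 0)
  structure(list(center = as.numeric(center), radius = radius, onset = onset,
                 duration = duration, amplitude = amplitude),
            class = "stimulus_region")
}

stimulus_nodes <- function(system, stim) {
  an <- system$anatomy
  mn <- system$myo_nodes
  p <- an$nodes[mn, , drop = FALSE]
  d2 <- (p[, 1] - stim$center[1])^2 + (p[, 2] - stim$center[2])^2 +
    (p[, 3] - stim$center[3])^2
  idx <- which(d2 <= stim$radius^2)
  if (!length(idx)) stop("stimulus region contains no myocardial node ",
                         "(center outside the myocardium?)")
  idx
}
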