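# Cellular electrophysiology: the ten Tusscher-Panfilov 2006 epicardial and
# endocardial human ventricular myocyte variants (compiled), with per-node
# g_Ks override, plus a fast two-variable test cell for solver unit tests.

TP06_STATE_NAMES <- c("V", "m", "h", "j", "Xr1", "Xr2", "Xs", "r", "s",
                      "d", "f", "f2", "fCass", "Rbar", "Cai", "CaSR",
                      "CaSS", "Nai", "Ki")
GKS_NOMINAL <- 0.392

#' Resting state of a cell variant
#'
#' Integrates the unstimulated cell from the published initial values until
#' quiescent and returns the settled state (cached per variant/g_Ks).
#'
#' @param variant \code{"epi"} or \code{"endo"}.
#' @param gks slow-potassium conductance, nS/pF.
#' @param settle_ms quiescent settling time.
#' @return named state vector (19 components).
#' @export
resting_state <- function(variant = c("epi", "endo"), gks = GKS_NOMINAL,
                          settle_ms = 3000, dt = 0.02) {
  variant <- match.arg(variant)
  key <- sprintf("rest_%s_%.6f_%g", variant, gks, settle_ms)
  if (!is.null(.fecgsim_cache[[key]])) return(.fecgsim_cache[[key]])
  r <- tp06_single_cpp(variant == "epi", gks, dt, settle_ms,
                       numeric(0), 0, 0, settle_ms, tp06_init_state_cpp())
  st <- stats::setNames(r$state, TP06_STATE_NAMES)
  .fecgsim_cache[[key]] <- st
  st
}

#' Advance one cell state
#'
#' Single explicit step of the ionic model: Rush-Larsen exponential updates
#' for the 12 gates, forward Euler for voltage and the ionic concentrations.
#'
#' @param state named 19-vector (see \code{resting_state}).
#' @param dt time step, ms; must lie in (0, 0.05] for stability.
#' @param I_ext external transmembrane current density, pA/pF (positive
#'   depolarizes).
#' @param variant \code{"epi"} or \code{"endo"}.
#' @param gks optional g_Ks override.
#' @return the advanced named state vector.
#' @export
cell_step <- function(state, dt, I_ext = 0, variant = c("epi", "endo"),
                      gks = GKS_NOMINAL) {
  variant <- match.arg(variant)
  if (dt <= 0 || dt > 0.05) stop("dt must lie in (0, 0.05] ms")
  m <- matrix(unname(state), 1, 19)
  tp06_advance_cpp(m, as.integer(variant == "epi"), gks, dt, 1L, I_ext)
  stats::setNames(as.vector(m), TP06_STATE_NAMES)
}

#' Paced single-cell action-potential trace
#'
#' Applies a train of rectangular 1-ms stimuli at the given cycle length and
#' returns the final beat, sampled at 1 kHz, with earlier beats discarded as
#' pre-pacing.
#'
#' @param variant \code{"epi"} or \code{"endo"}.
#' @param pacing_cl_ms cycle length, >= 300 ms.
#' @param n_beats number of paced beats, >= 1.
#' @param gks_override optional g_Ks value (default nominal 0.392 nS/pF).
#' @param dt integration step, ms.
#' @param stim_amp stimulus amplitude, pA/pF.
#' @return data.frame \code{(t_ms, V_mV)} covering the last beat (t_ms
#'   restarts at 0 at the last stimulus); attribute \code{captured} reports
#'   whether the beat produced an upstroke above 0 mV.
#' @export
simulate_single_cell <- function(variant = c("epi", "endo"),
                                 pacing_cl_ms = 1000, n_beats = 1,
                                 gks_override = NULL, dt = 0.02,
                                 stim_amp = 52) {
  variant <- match.arg(variant)
  if (pacing_cl_ms < 300) stop("pacing cycle length must be >= 300 ms")
  if (n_beats < 1) stop("n_beats must be >= 1")
  gks <- if (is.null(gks_override)) GKS_NOMINAL else gks_override
  st <- resting_state(variant)
  onsets <- seq(0, by = pacing_cl_ms, length.out = n_beats)
  r <- tp06_single_cpp(variant == "epi", gks, dt, n_beats * pacing_cl_ms,
                       onsets, 1, stim_amp, 1, unname(st))
  keep <- r$t >= (n_beats - 1) * pacing_cl_ms
  out <- data.frame(t_ms = r$t[keep] - (n_beats - 1) * pacing_cl_ms,
                    V_mV = r$V[keep])
  attr(out, "captured") <- max(out$V_mV) > 0
  if (!attr(out, "captured"))
    warning("stimulus failed to capture (no upstroke above 0 mV)")
  out
}

#' APD at 90 percent repolarization from a single-beat trace
#' @param t,V time (ms) and voltage (mV) vectors of one beat.
#' @return APD90 in ms (NA when the beat does not repolarize in the trace).
#' @export
apd90 <- function(t, V) {
  vr <- V[1]; vp <- max(V)
  thr <- vr + 0.1 * (vp - vr)
  up <- which(V > thr)[1]
  if (is.na(up)) return(NA_real_)
  pk <- which.max(V)
  dn <- which(t > t[pk] & V < thr)[1]
  if (is.na(dn)) return(NA_real_)
  # linear interpolation at both crossings
  tu <- t[up - 1] + (thr - V[up - 1]) / (V[up] - V[up - 1]) * (t[up] - t[up - 1])
  td <- t[dn - 1] + (thr - V[dn - 1]) / (V[dn] - V[dn - 1]) * (t[dn] - t[dn - 1])
  td - tu
}

#' Nodewise ionic assignment from anatomical coordinates
#'
#' Combines the transmural cell-type rule (epi layer fraction \code{H_TR})
#' and the apicobasal g_Ks rule (\code{H_AB}) into per-node variant flags and
#' g_Ks values for the tissue solver.
#'
#' @param anatomy an \code{anatomy_model}.
#' @param coords matching \code{anatomical_coords}.
#' @param params a \code{parameter_set}.
#' @return list with \code{epi} (0/1 per myocardial node), \code{gks},
#'   \code{model = "tp06"}.
#' @export
ionic_assignment <- function(anatomy, coords, params) {
  variant <- cell_type_transmural(coords$d_transmural, params$H_TR)
  gks <- gks_apicobasal(coords$z_apicobasal, params$H_AB)
  list(model = "tp06", epi = as.integer(variant == "epi"), gks = gks,
       variant = variant)
}

#' Uniform ionic assignment (bars / verification meshes)
#' @param n number of myocardial nodes.
#' @param variant cell variant for all nodes.
#' @param gks g_Ks for all nodes.
#' @return assignment list as from \code{\link{ionic_assignment}}.
#' @export
uniform_ionic_assignment <- function(n, variant = "epi", gks = GKS_NOMINAL) {
  list(model = "tp06", epi = rep(as.integer(variant == "epi"), n),
       gks = rep(gks, n), variant = rep(variant, n))
}

# Aliev-Panfilov style test cell behind the same interface (2 states)
fhn_initial_state <- function(n) cbind(V = rep(-85, n), w = rep(0, n))

#' Two-variable test-cell assignment (solver unit tests)
#'
#' Assigns the fast Aliev-Panfilov-style excitable cell to every myocardial
#' node; used to exercise the PDE machinery in seconds. Never used for
#' physiological results.
#'
#' @param n number of myocardial nodes.
#' @return assignment list with \code{model = "fhn"}.
#' @export
fhn_ionic_assignment <- function(n)
  list(model = "fhn", epi = rep(0L, n), gks = rep(0, n),
       variant = rep("fhn", n))
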