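# Lead derivation (body-surface map + standard 12-lead) and the
# depolarization/repolarization biomarkers.

#' Derive BSM and 12-lead ECGs from a simulation result
#'
#' Unipolar body-surface leads are the torso potentials at the vest nodes,
#' referenced to the Wilson central terminal (mean of RA, LA, LL, forced to
#' zero). Limb leads follow Einthoven (I = LA-RA, II = LL-RA, III = LL-LA),
#' augmented leads follow Goldberger, and V1-V6 are the WCT-referenced
#' precordial potentials.
#'
#' @param result a \code{simulation_result}.
#' @param electrodes an \code{electrode_array}.
#' @return object of class \code{lead_signals}: \code{times} (ms),
#'   \code{bsm} (N x T, mV), \code{leads12} (12 x T, mV, rows I, II, III,
#'   aVR, aVL, aVF, V1..V6).
#' @export
derive_leads <- function(result, electrodes) {
  need <- c(electrodes$bsm_nodes, unlist(electrodes$limb_nodes),
            electrodes$precordial_nodes)
  miss <- need[need > nrow(result$phi_b) | need < 1]
  if (length(miss))
    stop("electrode node(s) missing from the simulation result: ",
         paste(names(miss), collapse = ", "))
  limb <- unlist(electrodes$limb_nodes)
  phi <- enforce_wct(result$phi_b, limb)
  bsm <- phi[electrodes$bsm_nodes, , drop = FALSE]
  rownames(bsm) <- names(electrodes$bsm_nodes)
  ra <- phi[limb[1], ]; la <- phi[limb[2], ]; ll <- phi[limb[3], ]
  leads12 <- rbind(
    I = la - ra, II = ll - ra, III = ll - la,
    aVR = ra - (la + ll) / 2, aVL = la - (ra + ll) / 2,
    aVF = ll - (ra + la) / 2,
    phi[electrodes$precordial_nodes, , drop = FALSE])
  rownames(leads12) <- c("I", "II", "III", "aVR", "aVL", "aVF",
                         paste0("V", 1:6))
  structure(list(times = result$times, bsm = bsm, leads12 = leads12,
                 electrodes = electrodes),
            class = "lead_signals")
}

#' Per-node activation times
#'
#' First upward crossing of the threshold (default 0 mV), linearly
#' interpolated between samples; nodes that never cross are NA.
#'
#' @param Vm_series nodes x samples voltage matrix, mV.
#' @param times sample times, ms.
#' @param threshold crossing threshold, mV.
#' @return numeric vector of activation times (ms), NA where not activated.
#' @export
activation_times <- function(Vm_series, times, threshold = 0) {
  above <- Vm_series > threshold
  idx <- apply(above, 1, function(r) which(r)[1])
  out <- rep(NA_real_, nrow(Vm_series))
  ok <- !is.na(idx) & idx > 1
  i <- idx[ok]
  rows <- which(ok)
  v1 <- Vm_series[cbind(rows, i - 1)]
  v2 <- Vm_series[cbind(rows, i)]
  out[rows] <- times[i - 1] + (threshold - v1) / (v2 - v1) *
    (times[i] - times[i - 1])
  out[!is.na(idx) & idx == 1] <- times[1]
  out
}

#' Per-node repolarization time and APD
#'
#' Repolarization is the first downward crossing, after the action-potential
#' peak, of V_rest + 0.1 (V_peak - V_rest) (APD90 convention); APD is
#' repolarization minus activation. Nodes that do not repolarize within the
#' simulated window are flagged and excluded from dispersions.
#'
#' @param Vm_series nodes x samples voltage matrix, mV.
#' @param times sample times, ms.
#' @param activation from \code{\link{activation_times}}.
#' @return data.frame with \code{repol}, \code{apd}, logical
#'   \code{incomplete}.
#' @export
repolarization_and_apd <- function(Vm_series, times, activation) {
  n <- nrow(Vm_series)
  repol <- rep(NA_real_, n)
  vrest <- Vm_series[, 1]
  for (r in seq_len(n)) {
    if (is.na(activation[r])) next
    V <- Vm_series[r, ]
    pk <- which.max(V)
    thr <- vrest[r] + 0.1 * (V[pk] - vrest[r])
    post <- seq(pk, length(V))
    below <- which(V[post] < thr)
    if (!length(below) || below[1] == 1) next
    i <- post[below[1]]
    repol[r] <- times[i - 1] + (thr - V[i - 1]) / (V[i] - V[i - 1]) *
      (times[i] - times[i - 1])
  }
  data.frame(repol = repol, apd = repol - activation,
             incomplete = !is.na(activation) & is.na(repol))
}

# QRS onset/offset and QT from the RMS-across-leads curve: crossings of 5%
# of the QRS peak, runs merged when separated by < merge_ms.
find_qrs_windows <- function(rms, times, frac = 0.05, merge_ms = 10) {
  thr <- frac * max(rms)
  above <- rms >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  segs <- cbind(starts[r$values], ends[r$values])
  if (nrow(segs) == 0) return(NULL)
  merged <- segs[1, , drop = FALSE]
  if (nrow(segs) > 1) for (k in 2:nrow(segs)) {
    gap <- times[segs[k, 1]] - times[merged[nrow(merged), 2]]
    if (gap < merge_ms) merged[nrow(merged), 2] <- segs[k, 2]
    else merged <- rbind(merged, segs[k, ])
  }
  pk <- which.max(rms)
  qrs <- merged[merged[, 1] <= pk & merged[, 2] >= pk, , drop = FALSE][1, ]
  list(qrs_onset = times[qrs[1]], qrs_offset = times[qrs[2]],
       qt_end = times[merged[nrow(merged), 2]],
       peak_time = times[pk])
}

#' Depolarization/repolarization biomarkers of one simulation
#'
#' Computes the reference-model biomarkers: late activation time (relative
#' to stimulus onset), APD and repolarization-time dispersions (max - min
#' over myocardial nodes), maximal absolute extracellular potential on the
#' heart surface in the depolarization and repolarization windows, maximal
#' absolute torso-surface potential in the QRS and T windows (the surface
#' potential itself, not bipolar leads), and QRS width / QT duration from
#' the RMS of the 12 standard leads (5% rule).
#'
#' @param result a \code{simulation_result}.
#' @param leads a \code{lead_signals} derived from it.
#' @return object of class \code{biomarker_table} (named list; ms and mV).
#' @export
biomarker_table <- function(result, leads) {
  times <- result$times
  onset <- min(vapply(result$stimuli, function(s) s$onset, numeric(1)))
  act <- activation_times(result$Vm, times)
  rep_apd <- repolarization_and_apd(result$Vm, times, act)
  ok <- !is.na(rep_apd$apd)
  rms <- sqrt(colMeans(leads$leads12^2))
  win <- find_qrs_windows(rms, times)
  if (is.null(win)) stop("no QRS complex detected in the 12-lead RMS curve")
  hrow <- heart_surface_rows(result)
  depol_cols <- which(times >= onset & times <= win$qrs_offset)
  repol_cols <- which(times > win$qrs_offset)
  amp <- function(m, cols) if (length(cols)) max(abs(m[, cols])) else NA_real_
  tsn <- result$torso_surface_nodes
  surf_phi <- if (!is.null(tsn) && length(tsn))
    result$phi_b[tsn, , drop = FALSE] else result$phi_b
  out <- list(
    late_activation_time = max(act, na.rm = TRUE) - onset,
    apd_dispersion = if (any(ok)) diff(range(rep_apd$apd[ok])) else NA_real_,
    repolarization_dispersion =
      if (any(ok)) diff(range(rep_apd$repol[ok])) else NA_real_,
    max_phi_e_depol = amp(result$phi_e[hrow, , drop = FALSE], depol_cols),
    max_phi_e_repol = amp(result$phi_e[hrow, , drop = FALSE], repol_cols),
    max_qrs_amplitude_torso = amp(surf_phi, depol_cols),
    max_twave_amplitude_torso = amp(surf_phi, repol_cols),
    qrs_width = win$qrs_offset - win$qrs_onset,
    qt_duration = win$qt_end - win$qrs_onset,
    qrs_onset = win$qrs_onset, qrs_offset = win$qrs_offset,
    n_not_repolarized = sum(rep_apd$incomplete),
    n_not_activated = sum(is.na(act))
  )
  structure(out, class = "biomarker_table")
}

# rows of phi_e/Vm lying on the heart surface (all myocardial nodes for
# all-myocardium meshes such as bars)
heart_surface_rows <- function(result) {
  hs <- result$heart_surface_nodes
  if (is.null(hs) || !length(hs)) return(seq_along(result$myo_nodes))
  r <- match(hs, result$myo_nodes)
  r[!is.na(r)]
}
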