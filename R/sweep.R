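# One-at-a-time sensitivity pipeline: forward simulations over a parameter
# range against a cached reference run, RED per signal class, natural cubic
# spline interpolation of the sensitivity curve, biomarker spans, regional
# RED maps and parameter rankings.

SIGNAL_CLASSES <- c("Vm_volume", "Vm_surface", "phie_volume", "phie_surface",
                    "phib_surface", "bsm")

extract_class <- function(result, leads, class) {
  hrow <- heart_surface_rows(result)
  switch(class,
    Vm_volume = result$Vm,
    Vm_surface = result$Vm[hrow, , drop = FALSE],
    phie_volume = result$phi_e,
    phie_surface = result$phi_e[hrow, , drop = FALSE],
    phib_surface = result$phi_b[result$torso_surface_nodes, , drop = FALSE],
    bsm = leads$bsm,
    stop("unknown signal class: ", class))
}

simulate_case <- function(anatomy, coords, fibers, placement, params,
                          duration_ms, dt_pde, dt_ode, phi_update_every = 1L) {
  tf <- build_tensor_field(anatomy, fibers, params)
  sys <- assemble_system(anatomy, tf, params)
  ion <- ionic_assignment(anatomy, coords, params)
  res <- run_simulation(sys, ion, placement$stimuli, duration_ms,
                        dt_pde = dt_pde, dt_ode = dt_ode,
                        electrodes = placement$electrodes,
                        phi_update_every = phi_update_every)
  leads <- derive_leads(res, placement$electrodes)
  list(result = res, leads = leads)
}

#' One-at-a-time parameter sweep
#'
#' Runs the full forward simulation at the range endpoints, the reference
#' value and evenly spaced interior points of one parameter (all others at
#' reference), computes the RED of each signal class against the reference
#' run, fits a natural cubic spline through the tested points, and extracts
#' the max-RED sensitivity and relative biomarker spans.
#'
#' @param anatomy an \code{anatomy_model}.
#' @param reference_params a \code{parameter_set}.
#' @param parameter_name one of H_TR, H_AB, anisotropy_ratio, sigma_lungs,
#'   sigma_blood, sigma_spine, sigma_liver.
#' @param range_kind \code{"physiological"} or \code{"study"}.
#' @param n_points number of evenly spaced tested values (>= 3; the
#'   reference value is inserted if not already tested).
#' @param pacing_site pacing site name (see
#'   \code{\link{place_electrodes_and_pacing}}).
#' @param duration_ms simulated time per run.
#' @param dt_pde,dt_ode solver steps.
#' @param layout electrode layout.
#' @param keep_results keep the full simulation results (needed for regional
#'   maps).
#' @param phi_update_every see \code{\link{run_simulation}}.
#' @return object of class \code{sweep_result}.
#' @export
run_oat_sweep <- function(anatomy, reference_params, parameter_name,
                          range_kind = c("physiological", "study"),
                          n_points = 5, pacing_site = "rv_apex",
                          duration_ms = 450, dt_pde = 0.1, dt_ode = 0.02,
                          layout = electrode_layout(sites = pacing_site),
                          keep_results = TRUE, phi_update_every = 1L) {
  range_kind <- match.arg(range_kind)
  rng <- param_ranges(range_kind)[[parameter_name]]
  if (is.null(rng)) stop("parameter ", parameter_name, " is not in the ",
                         "varied set")
  if (n_points < 3) stop("n_points must be >= 3")
  ref_val <- reference_params[[parameter_name]]
  vals <- sort(unique(c(seq(rng[1], rng[2], length.out = n_points), ref_val)))
  coords <- compute_anatomical_coords(anatomy)
  fibers <- assign_fibers(anatomy, coords)
  placement <- place_electrodes_and_pacing(anatomy, layout, coords)
  run_one <- function(p) simulate_case(anatomy, coords, fibers, placement, p,
                                       duration_ms, dt_pde, dt_ode,
                                       phi_update_every)
  ref <- reference_run(anatomy, reference_params, run_one)
  cases <- vector("list", length(vals))
  delta <- matrix(NA_real_, length(SIGNAL_CLASSES), length(vals),
                  dimnames = list(SIGNAL_CLASSES, signif(vals, 10)))
  biom <- vector("list", length(vals))
  status <- "complete"
  for (k in seq_along(vals)) {
    cs <- if (vals[k] == ref_val) ref else {
      pk <- reference_params
      pk[[parameter_name]] <- vals[k]
      tryCatch(run_one(pk), error = function(e) e)
    }
    if (inherits(cs, "error")) {
      status <- paste0("incomplete: simulation failed at ", parameter_name,
                       " = ", vals[k], " (", conditionMessage(cs), ")")
      break
    }
    cases[[k]] <- cs
    for (cl in SIGNAL_CLASSES) {
      a <- extract_class(cs$result, cs$leads, cl)
      b <- extract_class(ref$result, ref$leads, cl)
      delta[cl, k] <- if (vals[k] == ref_val) 0 else red(a, b)
    }
    biom[[k]] <- biomarker_table(cs$result, cs$leads)
  }
  done <- !vapply(cases, is.null, logical(1))
  splines <- apply(delta[, done, drop = FALSE], 1, function(y)
    splinefun(vals[done], y, method = "natural"))
  max_red <- apply(delta[, done, drop = FALSE], 1, max)
  argmax <- vals[done][apply(delta[, done, drop = FALSE], 1, which.max)]
  ref_biom <- biom[[which(vals == ref_val)]]
  span_names <- c("late_activation_time", "apd_dispersion",
                  "repolarization_dispersion", "max_phi_e_depol",
                  "max_phi_e_repol", "max_qrs_amplitude_torso",
                  "max_twave_amplitude_torso", "qrs_width", "qt_duration")
  spans <- sapply(span_names, function(nm) {
    vv <- vapply(biom[done], function(b) b[[nm]], numeric(1))
    if (!is.finite(ref_biom[[nm]]) || ref_biom[[nm]] == 0)
      c(U_min = NA_real_, U_max = NA_real_)
    else biomarker_span(vv, ref_biom[[nm]])
  })
  structure(list(
    parameter = parameter_name, range_kind = range_kind, range = rng,
    values = vals[done], delta = delta[, done, drop = FALSE],
    splines = splines, max_red = max_red, argmax = argmax,
    biomarkers = biom[done], reference_biomarkers = ref_biom,
    spans = spans, status = status,
    mesh_hash = anatomy$mesh_hash, pacing_site = pacing_site,
    duration_ms = duration_ms, dt_pde = dt_pde, dt_ode = dt_ode,
    results = if (keep_results) c(list(reference = ref), stats::setNames(
      cases[done], paste0("x", signif(vals[done], 10)))) else NULL
  ), class = "sweep_result")
}

# reference simulation cache keyed by mesh, parameters and protocol
reference_run <- function(anatomy, params, run_one) {
  key <- paste0("ref_", anatomy$mesh_hash, "_",
                paste(unlist(params), collapse = "_"))
  hit <- .fecgsim_cache[[key]]
  if (!is.null(hit)) return(hit)
  ref <- run_one(params)
  .fecgsim_cache[[key]] <- ref
  ref
}

#' Regional RED (sensitivity) map on a surface
#'
#' Per-node RED between the local time traces of the reference and
#' worst-case (max overall RED) simulations, on the heart surface
#' (extracellular potential) or the torso surface (body-surface potential),
#' with min-max scaling for display.
#'
#' @param reference_result,worst_case_result \code{simulation_result}s on
#'   the same mesh.
#' @param surface_id \code{"heart"} or \code{"torso"}.
#' @return object of class \code{regional_map}: global node ids, local RED
#'   (percent, NA where the reference trace is identically zero) and
#'   display values scaled to [0, 1].
#' @export
regional_red_map <- function(reference_result, worst_case_result,
                             surface_id = c("heart", "torso")) {
  surface_id <- match.arg(surface_id)
  if (!identical(reference_result$mesh_hash, worst_case_result$mesh_hash))
    stop("results live on different meshes")
  if (surface_id == "heart") {
    rows <- heart_surface_rows(reference_result)
    a <- worst_case_result$phi_e[rows, , drop = FALSE]
    b <- reference_result$phi_e[rows, , drop = FALSE]
    nodes <- reference_result$myo_nodes[rows]
  } else {
    nodes <- reference_result$torso_surface_nodes
    a <- worst_case_result$phi_b[nodes, , drop = FALSE]
    b <- reference_result$phi_b[nodes, , drop = FALSE]
  }
  den <- sqrt(rowSums(b^2))
  num <- sqrt(rowSums((a - b)^2))
  local_red <- ifelse(den > 0, num / den * 100, NA_real_)
  fin <- is.finite(local_red)
  disp <- rep(NA_real_, length(local_red))
  if (any(fin)) {
    lo <- min(local_red[fin]); hi <- max(local_red[fin])
    disp[fin] <- if (hi > lo) (local_red[fin] - lo) / (hi - lo)
                 else rep(0, sum(fin))
  }
  structure(list(surface = surface_id, nodes = nodes, local_red = local_red,
                 display = disp),
            class = "regional_map")
}

#' Rank parameters by max-RED sensitivity
#'
#' @param sweeps list of \code{sweep_result}s sharing a signal class.
#' @param signal_class one of Vm_volume, Vm_surface, phie_volume,
#'   phie_surface, phib_surface, bsm.
#' @return data.frame ordered by descending max-RED, with per-class values.
#' @export
rank_parameters <- function(sweeps, signal_class = "bsm") {
  if (!length(sweeps)) stop("no sweeps to rank")
  if (!signal_class %in% SIGNAL_CLASSES)
    stop("unknown signal class: ", signal_class)
  tab <- do.call(rbind, lapply(sweeps, function(s) {
    data.frame(parameter = s$parameter,
               max_red = unname(s$max_red[signal_class]),
               argmax = unname(s$argmax[match(signal_class, SIGNAL_CLASSES)]),
               t(s$max_red))
  }))
  tab[order(-tab$max_red), , drop = FALSE]
}
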