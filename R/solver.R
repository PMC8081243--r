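# Time integration of the bidomain-with-bath system by Godunov operator
# splitting: the ionic ODEs advance with Rush-Larsen/forward-Euler substeps,
# the parabolic update is implicit in V_m (lumped mass), and the elliptic
# extracellular/bath solve closes each step. Potentials are gauged to zero
# mean and re-referenced to the Wilson central terminal when limb electrodes
# are available.

#' Run a bidomain simulation
#'
#' @param system a \code{discrete_system} from \code{\link{assemble_system}}.
#' @param ionic nodewise assignment from \code{\link{ionic_assignment}} (or
#'   \code{uniform_ionic_assignment}).
#' @param stimuli list of \code{\link{stimulus_region}} objects.
#' @param duration_ms simulated time; sampled every \code{sample_dt} ms
#'   (default 1 ms, i.e. 1 kHz), giving exactly
#'   \code{duration_ms / sample_dt} samples at t = 0, 1, ..., duration-1.
#' @param dt_pde,dt_ode PDE and ODE substep lengths, ms.
#' @param electrodes optional \code{electrode_array}; when given, every
#'   sample is re-referenced so the Wilson central terminal is exactly zero.
#' @param phi_update_every solve the elliptic problem every k-th PDE step
#'   (1 = every step).
#' @return object of class \code{simulation_result}: \code{times} (ms),
#'   \code{Vm}, \code{phi_e} (myocardial nodes x samples, mV), \code{phi_b}
#'   (all torso nodes x samples, mV), and protocol metadata.
#' @export
run_simulation <- function(system, ionic, stimuli, duration_ms,
                           dt_pde = 0.1, dt_ode = 0.02, electrodes = NULL,
                           sample_dt = 1, phi_update_every = 1L) {
  stopifnot(inherits(system, "discrete_system"), duration_ms >= 1)
  p <- system$params
  mn <- system$myo_nodes
  nm <- length(mn)
  n <- system$n_nodes
  if (length(ionic$epi) != nm || length(ionic$gks) != nm)
    stop("ionic assignment must cover every myocardial node")
  nsub <- max(1L, round(dt_pde / dt_ode))
  nstep_per_sample <- round(sample_dt / dt_pde)
  if (abs(nstep_per_sample * dt_pde - sample_dt) > 1e-9)
    stop("dt_pde must divide sample_dt")
  nsamp <- floor(duration_ms / sample_dt)
  nstep <- nsamp * nstep_per_sample

  model <- ionic$model %||% "tp06"
  if (model == "tp06") {
    # initial states: variant-wise resting states (g_Ks has negligible
    # effect on the resting point, so per-variant caching suffices)
    states <- matrix(0, nm, 19)
    for (v in c(1L, 0L)) {
      sel <- ionic$epi == v
      if (any(sel))
        states[sel, ] <- matrix(unname(resting_state(if (v) "epi" else "endo")),
                                sum(sel), 19, byrow = TRUE)
    }
  } else if (model == "fhn") {
    states <- fhn_initial_state(nm)
  } else stop("unknown ionic model: ", model)

  scale <- p$beta * p$C_m / dt_pde
  A_par <- Matrix::forceSymmetric(
    Matrix::Diagonal(nm, system$M * scale) + system$K_i)
  ch_par <- Matrix::Cholesky(A_par, LDL = FALSE, perm = TRUE, super = TRUE)
  # elliptic operator is pure Neumann; pin one node, restore gauge afterwards
  pin <- 1L
  free <- setdiff(seq_len(n), pin)
  ch_ell <- Matrix::Cholesky(Matrix::forceSymmetric(
    system$K_ell[free, free, drop = FALSE]), LDL = FALSE, perm = TRUE, super = TRUE)

  stim_nodes <- lapply(stimuli, function(s) stimulus_nodes(system, s))
  limb <- NULL
  if (!is.null(electrodes)) limb <- c(electrodes$limb_nodes$RA,
                                      electrodes$limb_nodes$LA,
                                      electrodes$limb_nodes$LL)

  Vm_out <- matrix(NA_real_, nm, nsamp)
  phie_out <- matrix(NA_real_, nm, nsamp)
  phib_out <- matrix(NA_real_, n, nsamp)
  times <- (seq_len(nsamp) - 1) * sample_dt

  phi <- numeric(n)
  V <- states[, 1]
  Mw <- system$M * scale
  record <- function(k, V, phi) {
    off <- if (is.null(limb)) mean(phi) else mean(phi[limb])
    phi <- phi - off
    Vm_out[, k] <<- V
    phie_out[, k] <<- phi[mn]
    phib_out[, k] <<- phi
  }
  record(1L, V, phi)
  ell_rhs <- numeric(n)
  for (step in seq_len(nstep)) {
    t0 <- (step - 1) * dt_pde
    istim <- numeric(nm)
    for (q in seq_along(stimuli)) {
      s <- stimuli[[q]]
      if (t0 >= s$onset && t0 < s$onset + s$duration)
        istim[stim_nodes[[q]]] <- istim[stim_nodes[[q]]] + s$amplitude
    }
    # ionic substeps (advance V and cell states)
    if (model == "tp06")
      tp06_advance_cpp(states, ionic$epi, ionic$gks, dt_ode, nsub, istim)
    else fhn_advance_cpp(states, dt_ode, nsub, istim)
    Vstar <- states[, 1]
    # parabolic half: (M beta C_m/dt + K_i) V = M beta C_m/dt V* - K_i phi_e
    rhs <- Mw * Vstar - as.vector(system$K_i %*% phi[mn])
    V <- as.vector(Matrix::solve(ch_par, rhs, system = "A"))
    states[, 1] <- V
    # instability guard (suspended while a stimulus drives V_m directly)
    stim_active <- any(vapply(stimuli, function(s)
      t0 >= s$onset && t0 < s$onset + s$duration + 5, logical(1)))
    if (!stim_active && max(abs(V)) > 100)
      stop("instability detected: |V_m| exceeded 100 mV at t = ", t0, " ms")
    # elliptic: K_ell phi = -K_i V (scattered to global nodes)
    if (step %% phi_update_every == 0L || step == nstep) {
      ell_rhs[] <- 0
      ell_rhs[mn] <- -as.vector(system$K_i %*% V)
      sol <- as.vector(Matrix::solve(ch_ell, ell_rhs[free], system = "A"))
      phi[free] <- sol
      phi[pin] <- 0
      phi <- phi - mean(phi)
    }
    if (step %% nstep_per_sample == 0L && step < nstep)
      record(step %/% nstep_per_sample + 1L, V, phi)
  }
  structure(list(
    times = times, Vm = Vm_out, phi_e = phie_out, phi_b = phib_out,
    myo_nodes = mn, stimuli = stimuli, dt_pde = dt_pde, dt_ode = dt_ode,
    params = p, mesh_hash = system$anatomy$mesh_hash,
    heart_surface_nodes = sort(unique(as.vector(system$anatomy$surfaces$heart))),
    torso_surface_nodes = sort(unique(as.vector(system$anatomy$surfaces$torso))),
    wct_applied = !is.null(limb), ionic_model = ionic$model
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("simulation_result:", length(x$times), "samples at",
      diff(x$times[1:2]), "ms;", nrow(x$Vm), "myocardial nodes,",
      nrow(x$phi_b), "torso nodes\n")
  invisible(x)
}

#' Wilson-central-terminal normalization of one potential sample
#'
#' Subtracts the mean of the three limb-electrode potentials from all values,
#' making the Wilson central terminal exactly zero. Idempotent, and
#' invariant to any constant shift of the input.
#'
#' @param phi numeric vector (one sample over nodes) or matrix
#'   (nodes x samples).
#' @param limb_nodes indices of RA, LA, LL within \code{phi}'s rows.
#' @return adjusted \code{phi}.
#' @export
enforce_wct <- function(phi, limb_nodes) {
  stopifnot(length(limb_nodes) == 3)
  if (is.matrix(phi)) {
    off <- colMeans(phi[limb_nodes, , drop = FALSE])
    sweep(phi, 2, off)
  } else phi - mean(phi[limb_nodes])
}

#' Monodomain reference solver
#'
#' Independent reduction used as a verification oracle: a single parabolic
#' reaction-diffusion equation with an effective conductivity tensor,
#' integrated with the same splitting but no extracellular/bath solve.
#'
#' @param anatomy bar-like \code{anatomy_model} (all myocardium).
#' @param fibers a \code{fiber_field}.
#' @param sigma_l,sigma_t effective longitudinal/transverse conductivities
#'   (mS/cm).
#' @param params a \code{parameter_set} (uses beta, C_m).
#' @param ionic nodewise assignment.
#' @param stimuli list of \code{stimulus_region}.
#' @param duration_ms,dt_pde,dt_ode as in \code{\link{run_simulation}}.
#' @return list with \code{times} and \code{Vm}.
#' @export
run_monodomain <- function(anatomy, fibers, sigma_l, sigma_t, params, ionic,
                           stimuli, duration_ms, dt_pde = 0.1, dt_ode = 0.02) {
  stopifnot(all(anatomy$region == "myocardium"))
  n <- nrow(anatomy$nodes)
  f <- fibers$fiber
  tens <- cbind((sigma_l - sigma_t) * f[, 1]^2 + sigma_t,
                (sigma_l - sigma_t) * f[, 2]^2 + sigma_t,
                (sigma_l - sigma_t) * f[, 3]^2 + sigma_t,
                (sigma_l - sigma_t) * f[, 1] * f[, 2],
                (sigma_l - sigma_t) * f[, 1] * f[, 3],
                (sigma_l - sigma_t) * f[, 2] * f[, 3])
  asm <- fem_assemble_cpp(anatomy$nodes, anatomy$tets, tens,
                          rep(TRUE, nrow(anatomy$tets)))
  K <- Matrix::forceSymmetric(Matrix::sparseMatrix(
    i = asm$i, j = asm$j, x = asm$x, dims = c(n, n)))
  scale <- params$beta * params$C_m / dt_pde
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(
    Matrix::Diagonal(n, asm$lump * scale) + K), LDL = FALSE, perm = TRUE, super = TRUE)
  states <- matrix(unname(resting_state(ionic$variant[1])), n, 19, byrow = TRUE)
  nsub <- max(1L, round(dt_pde / dt_ode))
  nsamp <- floor(duration_ms)
  nper <- round(1 / dt_pde)
  Vm <- matrix(NA_real_, n, nsamp)
  Vm[, 1] <- states[, 1]
  p <- anatomy$nodes
  stim_idx <- lapply(stimuli, function(s) {
    d2 <- (p[, 1] - s$center[1])^2 + (p[, 2] - s$center[2])^2 +
      (p[, 3] - s$center[3])^2
    which(d2 <= s$radius^2)
  })
  Mw <- asm$lump * scale
  for (step in seq_len(nsamp * nper)) {
    t0 <- (step - 1) * dt_pde
    istim <- numeric(n)
    for (q in seq_along(stimuli)) {
      s <- stimuli[[q]]
      if (t0 >= s$onset && t0 < s$onset + s$duration)
        istim[stim_idx[[q]]] <- istim[stim_idx[[q]]] + s$amplitude
    }
    tp06_advance_cpp(states, ionic$epi, ionic$gks, dt_ode, nsub, istim)
    V <- as.vector(Matrix::solve(ch, Mw * states[, 1], system = "A"))
    states[, 1] <- V
    if (step %% nper == 0L && step < nsamp * nper)
      Vm[, step %/% nper + 1L] <- V
  }
  list(times = seq_len(nsamp) - 1, Vm = Vm)
}

#' Capture threshold of a focal stimulus by bisection
#'
#' Finds the smallest stimulus amplitude (pA/pF) that elicits a propagated
#' upstroke (V_m > 0 mV anywhere outside the stimulated region) within
#' \code{probe_ms}.
#'
#' @param system a \code{discrete_system}.
#' @param ionic nodewise assignment.
#' @param stim template \code{stimulus_region} (its amplitude is ignored).
#' @param probe_ms trial duration per bisection step.
#' @param lo,hi initial bracket, pA/pF.
#' @param tol bracket width at which to stop, pA/pF.
#' @return threshold amplitude, pA/pF.
#' @export
capture_threshold <- function(system, ionic, stim, probe_ms = 20,
                              lo = 2, hi = 64, tol = 2) {
  captured <- function(amp) {
    s <- stim
    s$amplitude <- amp
    res <- run_simulation(system, ionic, list(s), probe_ms)
    outside <- setdiff(seq_along(system$myo_nodes), stimulus_nodes(system, s))
    max(res$Vm[outside, ]) > 0
  }
  if (!captured(hi)) stop("no capture at the upper bracket of ", hi, " pA/pF")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (captured(mid)) hi <- mid else lo <- mid
  }
  hi
}
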