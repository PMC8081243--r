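# Shared fixtures, built once per test session and cached.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# compact heart-torso geometry used for desk-scale pipeline tests
mini_geometry <- function(...) geometry_params(
  torso_rx = 5.2, torso_ry = 4.2, torso_zlo = -6, torso_zhi = 4.5,
  heart_center = c(0.8, -0.4), base_z = 0.8,
  lv_semi = c(1.8, 1.8, 3.2), lv_wall = 0.9,
  rv_offset = -0.7, rv_semi = c(2.4, 1.6, 3.0), rv_wall = 0.55,
  lung_left_center = c(3.1, 0.2, 0.4), lung_left_semi = c(1.9, 2.4, 4.2),
  lung_right_center = c(-2.9, 0.2, 0.6), lung_right_semi = c(2.0, 2.5, 4.0),
  liver_center = c(-1.6, 0.2, -3.9), liver_semi = c(2.9, 2.5, 2.2),
  spine_center = c(0, 3.2), spine_radius = 0.9,
  h_fine = 0.2, h_coarse = 1.0, ...)

mini_anatomy <- function() fixture("mini_anatomy", function()
  build_anatomy(mini_geometry(), seed = 0))

mini_coords <- function() fixture("mini_coords", function()
  compute_anatomical_coords(mini_anatomy()))

mini_placement <- function() fixture("mini_placement", function()
  place_electrodes_and_pacing(mini_anatomy(),
                              electrode_layout(sites = "rv_apex"),
                              mini_coords()))

# short bar (1 cm) for fast solver checks
short_bar <- function() fixture("short_bar", function()
  build_bar_anatomy(1, 0.08, 0.08, 0.02))

bar_stimulus <- function(width = 0.08, amplitude = 24)
  stimulus_region(center = c(0, width / 2, width / 2), radius = 0.3,
                  duration = 3, amplitude = amplitude)

run_bar_simulation <- function(bar, direction = c(1, 0, 0), duration = 30,
                               params = parameter_set(), ...) {
  fib <- uniform_fiber_field(bar, direction)
  sys <- assemble_system(bar, build_tensor_field(bar, fib, params), params)
  ion <- uniform_ionic_assignment(length(bar$myo_nodes), "epi")
  run_simulation(sys, ion, list(bar_stimulus(bar$geometry$bar[2])),
                 duration, ...)
}

# cached 30-ms planar-wave run on the short bar (reused by several files)
short_bar_run <- function() fixture("short_bar_run", function()
  run_bar_simulation(short_bar()))

# conduction velocity between two probe planes (m/s)
bar_cv <- function(bar, result, x1 = NULL, x2 = NULL) {
  L <- bar$geometry$bar[1]
  if (is.null(x1)) x1 <- 0.25 * L
  if (is.null(x2)) x2 <- 0.75 * L
  act <- activation_times(result$Vm, result$times)
  x <- bar$nodes[bar$myo_nodes, 1]
  x1 <- x[which.min(abs(x - x1))]  # snap probes to grid planes
  x2 <- x[which.min(abs(x - x2))]
  t1 <- mean(act[abs(x - x1) < 1e-9], na.rm = TRUE)
  t2 <- mean(act[abs(x - x2) < 1e-9], na.rm = TRUE)
  (x2 - x1) / (t2 - t1) * 10
}

# brute-force double-loop metric oracles (deliberately naive)
oracle_cc <- function(a, b) {
  out <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    am <- mean(a[i, ]); bm <- mean(b[i, ])
    num <- 0; da <- 0; db <- 0
    for (t in seq_len(ncol(a))) {
      num <- num + (a[i, t] - am) * (b[i, t] - bm)
      da <- da + (a[i, t] - am)^2
      db <- db + (b[i, t] - bm)^2
    }
    out[i] <- num / sqrt(da * db)
  }
  out
}

oracle_nrmsd <- function(a, b) {
  out <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    ss <- 0
    for (t in seq_len(ncol(a))) ss <- ss + (a[i, t] - b[i, t])^2
    out[i] <- sqrt(ss / ncol(a)) / (max(b[i, ]) - min(b[i, ])) * 100
  }
  out
}

oracle_red <- function(a, b) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(a))) for (t in seq_len(ncol(a))) {
    num <- num + (a[i, t] - b[i, t])^2
    den <- den + b[i, t]^2
  }
  sqrt(num) / sqrt(den) * 100
}

# 100-ms unstimulated bar run (resting stationarity checks)
bar_rest_run <- function() fixture("bar_rest", function() {
  bar <- short_bar()
  fib <- uniform_fiber_field(bar, c(1, 0, 0))
  p <- parameter_set()
  sys <- assemble_system(bar, build_tensor_field(bar, fib, p), p)
  run_simulation(sys, uniform_ionic_assignment(length(bar$myo_nodes), "epi"),
                 list(), 100)
})

# matched bidomain / monodomain pair on the short bar (reduction oracle)
monodomain_pair <- function() fixture("mono_pair", function() {
  bar <- short_bar()
  fib <- uniform_fiber_field(bar, c(1, 0, 0))
  p <- parameter_set()
  k <- 2
  rc <- roth_conductivities(p$sigma, p$alpha, p$epsilon, p$anisotropy_ratio)
  tf <- build_tensor_field(bar, fib, p)
  tf$Sigma_e <- k * tf$Sigma_i
  sys <- assemble_system(bar, tf, p)
  ion <- uniform_ionic_assignment(length(bar$myo_nodes), "epi")
  stim <- bar_stimulus()
  # small dt so the lagged-phi splitting error does not mask the identity
  list(bar = bar,
       bidomain = run_simulation(sys, ion, list(stim), 25, dt_pde = 0.02),
       mono = run_monodomain(bar, fib,
                             sigma_l = unname(rc["sigma_li"]) * k / (1 + k),
                             sigma_t = unname(rc["sigma_ti"]) * k / (1 + k),
                             p, ion, list(stim), 25, dt_pde = 0.02))
})
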