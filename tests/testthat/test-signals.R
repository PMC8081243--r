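test_that("lead algebra: Einthoven, Goldberger, zero field, missing nodes", {
  # synthetic result over a fabricated 10-node torso
  nt <- 60
  phi <- matrix(rnorm(10 * nt), 10)
  res <- structure(list(times = 0:(nt - 1), phi_b = phi,
                        myo_nodes = 1:2, mesh_hash = "toy"),
                   class = "simulation_result")
  el <- structure(list(
    bsm_nodes = stats::setNames(1:4, paste0("e", 1:4)),
    limb_nodes = list(RA = 5L, LA = 6L, LL = 7L),
    precordial_nodes = stats::setNames(c(8L, 9L, 10L, 1L, 2L, 3L),
                                       paste0("V", 1:6)),
    layout = "toy"), class = "electrode_array")
  ld <- derive_leads(res, el)
  expect_lt(max(abs(ld$leads12["I", ] + ld$leads12["III", ] -
                      ld$leads12["II", ])), 1e-9)
  expect_lt(max(abs(colSums(ld$leads12[c("aVR", "aVL", "aVF"), ]))), 1e-9)
  # WCT of the unipolar reference is exactly zero
  wct <- (ld$bsm[1, ] * 0 +
            colMeans(enforce_wct(phi, 5:7)[5:7, , drop = FALSE]))
  expect_lt(max(abs(wct)), 1e-12)
  res0 <- res; res0$phi_b <- phi * 0
  ld0 <- derive_leads(res0, el)
  expect_true(all(ld0$bsm == 0) && all(ld0$leads12 == 0))
  el_bad <- el; el_bad$precordial_nodes[2] <- 99L
  expect_error(derive_leads(res, el_bad), "missing")
})

test_that("a midline source with mirrored arm electrodes nulls lead I", {
  # mirror-symmetric toy torso: nodes at (+/-x, y, z) pairs with a field
  # even in x; LA/RA mirrored -> lead I identically zero
  xs <- c(-2, -1, 1, 2)
  grid <- expand.grid(x = xs, y = 0:1, z = 0:1)
  phi_fun <- function(x, y, z, t) cos(x) * (1 + y) * sin(0.1 * t + z)
  nt <- 40
  phi <- t(sapply(seq_len(nrow(grid)), function(i)
    phi_fun(grid$x[i], grid$y[i], grid$z[i], 1:nt)))
  ra <- which(grid$x == -2 & grid$y == 0 & grid$z == 1)[1]
  la <- which(grid$x == 2 & grid$y == 0 & grid$z == 1)[1]
  ll <- which(grid$x == 1 & grid$y == 1 & grid$z == 0)[1]
  res <- structure(list(times = 1:nt, phi_b = phi, myo_nodes = 1:2,
                        mesh_hash = "mirror"), class = "simulation_result")
  el <- structure(list(
    bsm_nodes = stats::setNames(1:2, c("e1", "e2")),
    limb_nodes = list(RA = ra, LA = la, LL = ll),
    precordial_nodes = stats::setNames(rep(1L, 6), paste0("V", 1:6)),
    layout = "toy"), class = "electrode_array")
  ld <- derive_leads(res, el)
  expect_lt(max(abs(ld$leads12["I", ])), 1e-6)
})

test_that("activation detection: bracketing, interpolation, flat traces", {
  tm <- 0:20
  v <- rep(-86, 21); v[11:21] <- 20  # steps between samples 9 and 10 ms
  act <- activation_times(rbind(v, rep(-86, 21)), tm)
  expect_gt(act[1], 9); expect_lt(act[1], 10)
  expect_true(is.na(act[2]))
  # linear interpolation is exact for a ramp
  ramp <- seq(-50, 50, length.out = 21)
  expect_equal(activation_times(matrix(ramp, 1), tm), 10)
})

test_that("activation time is linear in distance for a planar bar wave", {
  bar <- short_bar()
  res <- short_bar_run()
  act <- activation_times(res$Vm, res$times)
  x <- bar$nodes[bar$myo_nodes, 1]
  sel <- x > 0.3 & x < 0.9 & !is.na(act)  # beyond the stimulated slab
  fit <- lm(act[sel] ~ x[sel])
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("repolarization and APD: constructed traces and dispersion", {
  tm <- 0:400
  sq <- function(apd) { v <- rep(-86, 401); v[6:(6 + apd)] <- 14; v }
  out <- repolarization_and_apd(rbind(sq(300), sq(250)), tm,
                                activation_times(rbind(sq(300), sq(250)), tm))
  expect_equal(out$apd[1], 300, tolerance = 1)
  expect_equal(out$apd[2], 250, tolerance = 1)
  expect_equal(diff(range(out$apd)), 50, tolerance = 1.5)
  # unfinished repolarization flagged
  v <- rep(-86, 401); v[6:401] <- 14
  out2 <- repolarization_and_apd(matrix(v, 1), tm, 5.5)
  expect_true(out2$incomplete[1])
})

test_that("electrotonic coupling keeps APD dispersion small on a uniform bar", {
  res <- fixture("bm_run", function()
    run_bar_simulation(short_bar(), duration = 350))
  act <- activation_times(res$Vm, res$times)
  ra <- repolarization_and_apd(res$Vm, res$times, act)
  bar <- short_bar()
  x <- bar$nodes[bar$myo_nodes, 1]
  ok <- !is.na(ra$apd) & x > 0.3   # outside the stimulated slab
  expect_gt(mean(!is.na(ra$apd)), 0.95)
  expect_lt(diff(range(ra$apd[ok])), 5)
})

test_that("biomarker homogeneity: amplitudes scale, times do not", {
  res <- fixture("bm_run", function()
    run_bar_simulation(short_bar(), duration = 350))
  el <- structure(list(
    bsm_nodes = stats::setNames(res$torso_surface_nodes[1:6],
                                paste0("e", 1:6)),
    limb_nodes = list(RA = res$torso_surface_nodes[7],
                      LA = res$torso_surface_nodes[8],
                      LL = res$torso_surface_nodes[9]),
    precordial_nodes = stats::setNames(res$torso_surface_nodes[10:15],
                                       paste0("V", 1:6)),
    layout = "toy"), class = "electrode_array")
  ld <- derive_leads(res, el)
  bm <- biomarker_table(res, ld)
  res2 <- res
  res2$Vm <- res$Vm            # V_m is not a potential we rescale
  res2$phi_e <- 2 * res$phi_e
  res2$phi_b <- 2 * res$phi_b
  ld2 <- derive_leads(res2, el)
  bm2 <- biomarker_table(res2, ld2)
  for (nm in c("max_phi_e_depol", "max_phi_e_repol",
               "max_qrs_amplitude_torso", "max_twave_amplitude_torso"))
    expect_equal(bm2[[nm]], 2 * bm[[nm]], tolerance = 1e-9)
  for (nm in c("late_activation_time", "qrs_width", "qt_duration"))
    expect_equal(bm2[[nm]], bm[[nm]])
  expect_gte(bm$late_activation_time, 0)
  # no discernible T wave on the bar's surface leads: QT >= QRS
  expect_gte(bm$qt_duration, bm$qrs_width)
})
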