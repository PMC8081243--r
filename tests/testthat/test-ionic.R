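test_that("resting state is stationary and within the physiological window", {
  for (v in c("epi", "endo")) {
    st <- resting_state(v)
    expect_gt(st["V"], -88); expect_lt(st["V"], -84)
    # 1000 unstimulated steps drift < 0.01 mV
    s <- st
    m <- matrix(unname(s), 1, 19)
    fecgsim:::tp06_advance_cpp(m, as.integer(v == "epi"), 0.392, 0.02,
                               1000L, 0)
    expect_lt(abs(m[1, 1] - st["V"]), 0.01)
  }
})

test_that("gates remain in [0,1] through a paced beat", {
  st <- resting_state("epi")
  gates <- c("m", "h", "j", "Xr1", "Xr2", "Xs", "r", "s", "d", "f", "f2",
             "fCass", "Rbar")
  s <- st
  for (k in 1:400) {  # 8 ms covering stimulus and upstroke
    s <- cell_step(s, 0.02, I_ext = if (k <= 100) 40 else 0, variant = "epi")
    expect_true(all(s[gates] >= 0 & s[gates] <= 1))
  }
  expect_gt(s["V"], 0)  # captured
  expect_error(cell_step(st, 0.2), "dt")
})

test_that("single-cell protocol: APD windows, variants, g_Ks monotonicity", {
  tr_epi <- simulate_single_cell("epi", 1000, 1)
  tr_endo <- simulate_single_cell("endo", 1000, 1)
  a_epi <- apd90(tr_epi$t_ms, tr_epi$V_mV)
  a_endo <- apd90(tr_endo$t_ms, tr_endo$V_mV)
  expect_true(attr(tr_epi, "captured") && attr(tr_endo, "captured"))
  # published-model characteristics: both variants near 300 ms at 1 Hz and
  # close to each other (the two variants differ mainly in I_to / notch)
  expect_gt(a_epi, 260); expect_lt(a_epi, 330)
  expect_gt(a_endo, 260); expect_lt(a_endo, 330)
  expect_lt(abs(a_epi - a_endo), 15)
  # epicardial notch: epi has the large transient-outward current
  notch <- function(tr) {
    pk <- which.max(tr$V_mV)
    max(tr$V_mV) - min(tr$V_mV[pk:(pk + 40)])
  }
  expect_gt(notch(tr_epi), notch(tr_endo) + 3)
  # APD90 strictly increases when g_Ks drops from 0.392 to 0.098
  gvals <- c(0.392, 0.245, 0.098)
  apds <- vapply(gvals, function(g) {
    tr <- simulate_single_cell("epi", 1000, 1, gks_override = g)
    apd90(tr$t_ms, tr$V_mV)
  }, numeric(1))
  expect_true(all(diff(apds) > 0))
  # n_beats = 1 equals the last beat of n_beats = 1 (identity)
  tr2 <- simulate_single_cell("epi", 1000, 1)
  expect_equal(tr2$V_mV, tr_epi$V_mV)
  expect_error(simulate_single_cell("epi", 200), "cycle length")
})

apd90_of <- function(tr) apd90(tr$t_ms, tr$V_mV)

test_that("halving dt changes APD90 by less than 1 ms", {
  a1 <- apd90_of(simulate_single_cell("epi", 1000, 1, dt = 0.02))
  a2 <- apd90_of(simulate_single_cell("epi", 1000, 1, dt = 0.01))
  expect_lt(abs(a1 - a2), 1)
})

test_that("ionic assignment combines the heterogeneity rules nodewise", {
  an <- mini_anatomy(); co <- mini_coords()
  p <- parameter_set(H_TR = 0.3, H_AB = 0.8)
  ion <- ionic_assignment(an, co, p)
  expect_length(ion$epi, length(an$myo_nodes))
  expect_identical(ion$epi == 1L, co$d_transmural > 0.7)
  expect_equal(ion$gks, 0.392 - 0.294 * 0.8 * co$z_apicobasal)
})
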