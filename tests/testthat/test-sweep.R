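# short-protocol sweep on the mini anatomy (sweep machinery, not physiology)

sweep_fixture <- function() fixture("spine_sweep", function()
  run_oat_sweep(mini_anatomy(), parameter_set(), "sigma_spine",
                range_kind = "physiological", n_points = 3,
                duration_ms = 100, dt_pde = 0.2, phi_update_every = 2L))

test_that("OAT sweep: reference distance is exactly zero, endpoints move", {
  sw <- sweep_fixture()
  expect_equal(sw$status, "complete")
  ref_col <- which(sw$values == parameter_set()$sigma_spine)
  expect_true(all(sw$delta[, ref_col] == 0))
  ends <- match(range(sw$values), sw$values)
  # any conductivity change perturbs the body-surface potentials
  expect_true(all(sw$delta["phib_surface", ends] > 0))
  expect_true(all(sw$delta["bsm", ends] > 0))
  expect_true(all(sw$values >= sw$range[1] & sw$values <= sw$range[2]))
})

test_that("sweep splines interpolate the tested points", {
  sw <- sweep_fixture()
  for (cl in rownames(sw$delta))
    expect_equal(sw$splines[[cl]](sw$values), unname(sw$delta[cl, ]),
                 tolerance = 1e-9)
})

test_that("max-RED bookkeeping and ranking order", {
  sw <- sweep_fixture()
  expect_equal(unname(sw$max_red), unname(apply(sw$delta, 1, max)))
  fake <- sw
  fake$parameter <- "sigma_liver"
  fake$max_red <- sw$max_red * 3
  tab <- rank_parameters(list(sw, fake), "bsm")
  expect_equal(tab$parameter[1], "sigma_liver")
  expect_true(all(diff(tab$max_red) <= 0))
  expect_error(rank_parameters(list(), "bsm"), "no sweeps")
  expect_error(rank_parameters(list(sw), "nope"), "unknown signal class")
})

test_that("regional maps: zero against itself, argmax scaling, surfaces", {
  sw <- sweep_fixture()
  ref <- sw$results$reference$result
  worst_val <- sw$argmax[match("phie_surface", fecgsim:::SIGNAL_CLASSES)]
  worst <- sw$results[[paste0("x", signif(worst_val, 10))]]$result
  self_map <- regional_red_map(ref, ref, "heart")
  expect_true(all(self_map$local_red[is.finite(self_map$local_red)] == 0))
  map <- regional_red_map(ref, worst, "torso")
  fin <- is.finite(map$local_red)
  expect_true(any(fin))
  expect_true(all(map$local_red[fin] >= 0))
  expect_equal(max(map$display[fin]), 1)
  expect_equal(map$nodes[which.max(map$display)],
               map$nodes[which.max(map$local_red)])
})

test_that("sweep rejects bad requests", {
  expect_error(run_oat_sweep(mini_anatomy(), parameter_set(), "C_m"),
               "not in the")
  expect_error(run_oat_sweep(mini_anatomy(), parameter_set(), "H_AB",
                             n_points = 2), "n_points")
})
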