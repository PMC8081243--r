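test_that("Roth conductivities evaluate the published formulas", {
  # direct evaluation at the reference parameter set
  rc <- roth_conductivities(3, 1, 0.75, 2.5)
  expect_equal(unname(rc), c(3, 0.3, 3, 1.2), tolerance = 1e-12)
  # full isotropy limit
  expect_equal(unname(roth_conductivities(2.4, 1, 0, 1)), rep(2.4, 4))
  # zero basic conductivity
  expect_equal(unname(roth_conductivities(0, 1, 0.75, 2.5)), rep(0, 4))
  expect_error(roth_conductivities(3, 1, 1, 2.5), "epsilon")
})

test_that("Roth round-trip recovers alpha and epsilon", {
  set.seed(11)
  for (k in 1:25) {
    sg <- runif(1, 0.5, 6); al <- runif(1, 0.3, 3)
    ep <- runif(1, 0, 0.95); lam <- runif(1, 1, 6)
    rc <- roth_conductivities(sg, al, ep, lam)
    alpha_rec <- rc["sigma_li"] / rc["sigma_le"]
    eps_rec <- 1 - (rc["sigma_le"] / rc["sigma_te"]) /
      (rc["sigma_li"] / rc["sigma_ti"])
    expect_equal(unname(alpha_rec), al, tolerance = 1e-10)
    expect_equal(unname(eps_rec), ep, tolerance = 1e-10)
  }
})

test_that("apicobasal g_Ks rule: homogeneous limit, endpoints, monotonicity", {
  zs <- c(0, 0.25, 0.5, 0.77, 1)
  expect_equal(gks_apicobasal(zs, 0), rep(0.392, 5))
  expect_equal(gks_apicobasal(1, 1), 0.098)
  expect_equal(gks_apicobasal(0.5, 1), 0.245)
  # monotone non-increasing in both arguments
  g1 <- gks_apicobasal(seq(0, 1, 0.1), 0.8)
  expect_true(all(diff(g1) <= 0))
  for (z in zs) {
    gh <- vapply(seq(0, 1, 0.2), function(h) gks_apicobasal(z, h), numeric(1))
    expect_true(all(diff(gh) <= 0))
  }
  expect_error(gks_apicobasal(1.2, 0.5), "z must")
  expect_error(gks_apicobasal(0.5, -0.1), "H_AB")
})

test_that("transmural cell-type rule and layer fractions", {
  d <- seq(0, 1, length.out = 101)
  expect_true(all(cell_type_transmural(d, 0) == "endo"))
  expect_true(all(cell_type_transmural(d[d > 0], 1) == "epi"))
  expect_identical(cell_type_transmural(0.75, 0.5), "epi")
  # epi fraction tracks H_TR on a uniform transmural sample
  for (h in c(0.2, 0.5, 0.8)) {
    frac <- mean(cell_type_transmural(d, h) == "epi")
    expect_equal(frac, h, tolerance = 0.02)
  }
})

test_that("parameter set defaults match the fixed/varied tables", {
  p <- parameter_set()
  expect_equal(p$C_m, 1); expect_equal(p$beta, 400)
  expect_equal(p$sigma, 3.0); expect_equal(p$alpha, 1)
  expect_equal(p$epsilon, 0.75); expect_equal(p$sigma_b, 2.0)
  expect_equal(p$anisotropy_ratio, 2.5)
  expect_equal(p$H_TR, 0.5); expect_equal(p$H_AB, 1)
  expect_equal(p$sigma_lungs, 0.39); expect_equal(p$sigma_blood, 7)
  expect_equal(p$sigma_spine, 0.2); expect_equal(p$sigma_liver, 0.28)
  expect_error(parameter_set(nonsense = 1), "unknown parameter")
  rngs <- param_ranges("study")
  expect_equal(rngs$anisotropy_ratio, c(1.6, 6.0))
  expect_equal(param_ranges("physiological")$H_AB, c(0.7, 1.0))
  expect_equal(hab_range_alternative(), c(0.75, 1.0))
})
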