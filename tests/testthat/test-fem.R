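test_that("stiffness operators: Neumann nullspace, symmetry, energy", {
  bar <- short_bar()
  fib <- uniform_fiber_field(bar, c(1, 0, 0))
  p <- parameter_set()
  sys <- assemble_system(bar, build_tensor_field(bar, fib, p), p)
  n <- length(bar$myo_nodes)
  ones <- rep(1, n)
  expect_lt(max(abs(sys$K_i %*% ones)), 1e-10)
  expect_lt(max(abs(sys$K_ell %*% ones)), 1e-10)
  expect_lt(max(abs(sys$K_i - Matrix::t(sys$K_i))) /
              max(abs(sys$K_i)), 1e-12)
  # energy identity: u linear with gradient g -> u'Ku = V_total * g'Sg
  rc <- roth_conductivities(p$sigma, p$alpha, p$epsilon, p$anisotropy_ratio)
  vol_total <- prod(bar$geometry$bar)
  set.seed(5)
  for (k in 1:5) {
    g <- rnorm(3)
    u <- as.vector(bar$nodes %*% g)
    e_fem <- as.numeric(t(u) %*% (sys$K_i %*% u))
    S <- diag(c(rc["sigma_li"], rc["sigma_ti"], rc["sigma_ti"]))
    e_exact <- vol_total * as.numeric(t(g) %*% S %*% g)
    expect_equal(e_fem, e_exact, tolerance = 1e-10)
  }
  # lumped mass sums to the bar volume
  expect_equal(sum(sys$M), vol_total, tolerance = 1e-12)
})

test_that("tensor field: spectrum, principal axis, organ scalars", {
  rc <- roth_conductivities(3, 1, 0.75, 2.5)
  an <- mini_anatomy()
  co <- mini_coords()
  fib <- assign_fibers(an, co)
  p <- parameter_set()
  tf <- build_tensor_field(an, fib, p)
  to_mat <- function(r) matrix(c(r[1], r[4], r[5],
                                 r[4], r[2], r[6],
                                 r[5], r[6], r[3]), 3, 3)
  set.seed(3)
  for (k in sample(nrow(tf$Sigma_i), 20)) {
    Si <- to_mat(tf$Sigma_i[k, ])
    ev <- eigen(Si, symmetric = TRUE)
    expect_equal(sort(ev$values),
                 sort(unname(c(rc["sigma_li"], rc["sigma_ti"],
                               rc["sigma_ti"]))),
                 tolerance = 1e-10)
    f <- fib$fiber[k, ]
    vmax <- ev$vectors[, which.max(ev$values)]
    expect_equal(abs(sum(vmax * f)), 1, tolerance = 1e-8)
    Se <- to_mat(tf$Sigma_e[k, ])
    expect_equal(sort(eigen(Se, symmetric = TRUE)$values),
                 unname(sort(c(rc["sigma_le"], rc["sigma_te"], rc["sigma_te"]))),
                 tolerance = 1e-10)
  }
  # organ conductivities by region
  reg <- an$region[tf$nonmyo_tets]
  expect_true(all(tf$sigma_region[reg == "lungs"] == 0.39))
  expect_true(all(tf$sigma_region[reg == "blood"] == 7))
  expect_true(all(tf$sigma_region[reg == "liver"] == 0.28))
  expect_true(all(tf$sigma_region[reg == "spine"] == 0.2))
  expect_true(all(tf$sigma_region[reg == "torso_bulk"] == 2.0))
  # missing fibers rejected
  fib2 <- fib; fib2$myo_tets <- fib2$myo_tets[-1]
  expect_error(build_tensor_field(an, fib2, p), "fiber")
})
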