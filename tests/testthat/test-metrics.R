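test_that("metric identities on constructed signals", {
  t <- seq(0, 2 * pi, length.out = 400)[-400]
  a <- rbind(sin(t), cos(2 * t) + 1)
  expect_equal(as.vector(cc(a, a)), c(1, 1))
  expect_equal(as.vector(cc(a, -a)), c(-1, -1))
  # orthogonal sin/cos over whole periods
  expect_lt(abs(cc(matrix(sin(t), 1), matrix(cos(t), 1))), 1e-6)
  expect_equal(as.vector(nrmsd(a, a)), c(0, 0))
  # offset ramp: range 1, constant offset 0.5 -> 50%
  ramp <- matrix(seq(0, 1, length.out = 200), 1)
  expect_equal(as.vector(nrmsd(ramp + 0.5, ramp)), 50)
  # scale covariance: both scaled by the same constant
  expect_equal(nrmsd(3 * (ramp + 0.5), 3 * ramp), nrmsd(ramp + 0.5, ramp))
  expect_equal(red(a, a), 0)
  expect_equal(red(matrix(0, 2, ncol(a)), a), 100)
  expect_equal(red(2 * a, a), 100)
  expect_error(red(a, 0 * a), "identically zero")
})

test_that("metrics agree with naive double-loop oracles", {
  set.seed(42)
  for (k in 1:5) {
    a <- matrix(rnorm(8 * 30), 8)
    b <- matrix(rnorm(8 * 30), 8)
    expect_equal(as.vector(cc(a, b)), oracle_cc(a, b), tolerance = 1e-10)
    expect_equal(as.vector(nrmsd(a, b)), oracle_nrmsd(a, b), tolerance = 1e-10)
    expect_equal(red(a, b), oracle_red(a, b), tolerance = 1e-10)
  }
})

test_that("cc is affine-invariant per lead; red and nrmsd are not", {
  set.seed(7)
  a <- matrix(rnorm(5 * 40), 5)
  b <- matrix(rnorm(5 * 40), 5)
  sc <- runif(5, 0.5, 3); off <- rnorm(5)
  a2 <- a * sc + off
  expect_equal(as.vector(cc(a2, b)), as.vector(cc(a, b)), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(red(a2, b), red(a, b))))
  expect_false(isTRUE(all.equal(as.vector(nrmsd(a2, b)), as.vector(nrmsd(a, b)))))
})

test_that("red vanishes iff equal and satisfies the scaled triangle bound", {
  set.seed(13)
  for (k in 1:10) {
    a <- matrix(rnorm(60), 4); b <- matrix(rnorm(60), 4)
    c_ <- matrix(rnorm(60), 4)
    expect_gt(red(a, b), 0)
    expect_equal(red(b, b), 0)
    lhs <- red(a, c_)
    rhs <- red(a, b) * sqrt(sum(b^2)) / sqrt(sum(c_^2)) + red(b, c_)
    expect_lte(lhs, rhs + 1e-9)
  }
})

test_that("constant leads are excluded, not zeroed", {
  a <- rbind(rep(1, 10), 1:10)
  b <- rbind(2:11, rep(3, 10))
  r <- cc(a, b)
  expect_true(is.na(r[1]) && is.na(r[2]))
  expect_equal(attr(r, "n_excluded"), 2)
  n <- nrmsd(a, b)
  expect_false(is.na(n[1]))
  expect_true(is.na(n[2]))
})

test_that("max-RED sensitivity and biomarker spans", {
  ref <- matrix(rnorm(50), 5)
  v1 <- ref * 1.1; v2 <- ref * 1.3
  m <- max_red_sensitivity(list("0.1" = v1, "0.3" = v2), ref)
  expect_equal(m$max_red, 30, tolerance = 1e-9)
  expect_equal(m$argmax, 0.3)
  expect_true(all(m$max_red >= m$red))
  expect_equal(max_red_sensitivity(list("1" = ref), ref)$max_red, 0)
  expect_error(max_red_sensitivity(list(), ref), "empty")
  expect_equal(unname(biomarker_span(100, 100)), c(100, 100))
  expect_equal(unname(biomarker_span(c(90, 110), 100)), c(90, 110))
  expect_equal(biomarker_span(3 * c(90, 110), 3 * 100),
               biomarker_span(c(90, 110), 100))
  expect_error(biomarker_span(c(1, 2), 0), "zero")
})
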