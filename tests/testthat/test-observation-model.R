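test_that("mixture construction weights centers by occurrence counts", {
  trials <- data.frame(
    trial_type = c("lead", "test", "test", "test", "trail"),
    frequency_hz = c(217.4, 50, 50, 100, 10),
    price_s = c(1, 2, 2, 5, 1))
  mix <- kernel_mixture(trials, 0.2)
  expect_equal(nrow(mix$components$lead$centers), 1L)
  expect_equal(mix$components$lead$weights, 1)
  # a condition seen twice vs once -> weights 2/3, 1/3
  expect_equal(sort(mix$components$test$weights), c(1 / 3, 2 / 3))
  expect_error(kernel_mixture(trials, 0), "positive")
  expect_error(kernel_mixture(trials, -0.1), "positive")
})

test_that("2-D likelihood matches the Gaussian peak and a brute-force kernel sum", {
  # single-centre type at its own centre: peak 1 / (2 pi sigma^2)
  trials <- data.frame(trial_type = c("lead", "test", "trail"),
                       frequency_hz = c(217.4, 50, 10), price_s = c(1, 2, 1))
  mix <- kernel_mixture(trials, 0.2)
  peak <- observation_likelihood(mix, c(log10(217.4), 0), "lead")
  expect_equal(peak, 1 / (2 * pi * 0.04), tolerance = 1e-12)

  # 126-centre test mixture vs direct summation oracle
  log <- fix_log
  mix2 <- kernel_mixture(log, 0.17)
  obs <- c(1.3, 0.4)
  cmp <- mix2$components$test
  oracle <- 0
  for (k in seq_along(cmp$weights)) {
    d2 <- (obs[1] - cmp$centers[k, "log_f"])^2 +
      (obs[2] - cmp$centers[k, "log_P"])^2
    oracle <- oracle + cmp$weights[k] *
      exp(-d2 / (2 * 0.17^2)) / (2 * pi * 0.17^2)
  }
  expect_equal(observation_likelihood(mix2, obs, "test"), unname(oracle),
               tolerance = 1e-12)

  # two equal-weight centres symmetric about the observation
  tr <- data.frame(trial_type = c("lead", "trail", "test", "test"),
                   frequency_hz = c(100, 10, 10^1.2, 10^1.8),
                   price_s = c(1, 1, 1, 1))
  mx <- kernel_mixture(tr, 0.25)
  mid <- c(1.5, 0)
  one <- exp(-(0.3^2) / (2 * 0.25^2)) / (2 * pi * 0.25^2)
  expect_equal(observation_likelihood(mx, mid, "test"), one, tolerance = 1e-12)
})

test_that("each per-type mixture integrates to one over the plane", {
  mix <- kernel_mixture(fix_log, 0.2)
  gx <- seq(-1.5, 4.5, length.out = 241L)
  gy <- seq(-3, 4, length.out = 241L)
  dx <- diff(gx)[1]; dy <- diff(gy)[1]
  for (tt in c("lead", "test", "trail")) {
    dens <- observation_likelihood(
      mix, cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx))), tt)
    expect_equal(sum(dens) * dx * dy, 1, tolerance = 1e-3)
  }
})

test_that("1-D marginal likelihood matches its peak, ignores the dropped axis and equals the numeric marginal", {
  trials <- data.frame(trial_type = c("lead", "test", "trail"),
                       frequency_hz = c(217.4, 50, 10), price_s = c(1, 2, 1))
  mix <- kernel_mixture(trials, 0.2)
  peak <- observation_likelihood_1d(mix, log10(217.4), "lead", "frequency")
  expect_equal(peak, 1 / (0.2 * sqrt(2 * pi)), tolerance = 1e-12)

  # price-only likelihood is invariant to frequency
  mix2 <- kernel_mixture(fix_log, 0.2)
  o1 <- matrix(c(0.5, 0.3), 1); o2 <- matrix(c(2.5, 0.3), 1)
  expect_equal(observation_likelihood_1d(mix2, o1, "test", "price"),
               observation_likelihood_1d(mix2, o2, "test", "price"))

  # equals the 2-D mixture marginalised numerically over the dropped axis
  target <- observation_likelihood_1d(mix2, 1.4, "test", "frequency")
  num <- stats::integrate(function(p) {
    observation_likelihood(mix2, cbind(1.4, p), "test")
  }, -6, 6, rel.tol = 1e-10)$value
  expect_equal(target, num, tolerance = 1e-7)
})

test_that("likelihoods are invariant to duplicate-centre consolidation", {
  dup <- data.frame(trial_type = c("lead", "trail", rep("test", 4)),
                    frequency_hz = c(100, 10, 50, 50, 80, 80),
                    price_s = c(1, 1, 2, 2, 3, 3))
  con <- data.frame(trial_type = c("lead", "trail", "test", "test"),
                    frequency_hz = c(100, 10, 50, 80),
                    price_s = c(1, 1, 2, 3))
  m1 <- kernel_mixture(dup, 0.2)
  m2 <- kernel_mixture(con, 0.2)
  obs <- cbind(runif(20, 0.5, 2.5), runif(20, -0.5, 1))
  expect_equal(observation_likelihood(m1, obs, "test"),
               observation_likelihood(m2, obs, "test"), tolerance = 1e-12)
})

test_that("discriminability vanishes as sigma grows and sharpens as it shrinks", {
  obs <- c(log10(217.4), 0)  # the lead centre
  wide <- kernel_mixture(fix_log, 25)
  ratio <- observation_likelihood(wide, obs, "lead") /
    observation_likelihood(wide, obs, "trail")
  expect_equal(ratio, 1, tolerance = 0.05)
  narrow <- kernel_mixture(fix_log, 0.05)
  expect_gt(observation_likelihood(narrow, obs, "lead"),
            1e6 * observation_likelihood(narrow, obs, "trail"))
})
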