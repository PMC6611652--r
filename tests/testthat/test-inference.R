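test_that("belief-transition matrix B interpolates identity to uniform", {
  expect_equal(matrix_B(0), diag(3), ignore_attr = TRUE)
  expect_equal(matrix_B(1), matrix(1 / 3, 3, 3), ignore_attr = TRUE)
  B <- matrix_B(0.5)
  expect_equal(unname(diag(B)), rep(2 / 3, 3))
  expect_equal(unname(B[1, 2]), 1 / 6)
  expect_equal(rowSums(B), rep(1, 3), ignore_attr = TRUE)
  expect_error(matrix_B(-0.01), "\\[0, 1\\]")
  expect_error(matrix_B(1.01), "\\[0, 1\\]")
})

test_that("asymmetric B nests the symmetric form and splits directions", {
  expect_equal(matrix_B_asym(0.6, 0.6), matrix_B(0.6))
  expect_equal(matrix_B_asym(0, 0), diag(3), ignore_attr = TRUE)
  B <- matrix_B_asym(0.9, 0)
  expect_equal(unname(B["test", ]), c(0, 0.7, 0.3))
  expect_equal(rowSums(B), rep(1, 3), ignore_attr = TRUE)
  expect_error(matrix_B_asym(1.2, 0), "\\[0, 1\\]")
})

test_that("task matrix A advances beliefs around the cycle", {
  A <- transition_matrix_A()
  expect_equal(belief_next_trial(c(1, 0, 0), A),
               c(lead = 0, test = 1, trail = 0))
  expect_equal(belief_next_trial(c(0, 0, 1), A),
               c(lead = 1, test = 0, trail = 0))
  expect_equal(belief_next_trial(c(0.2, 0.5, 0.3), A),
               c(lead = 0.3, test = 0.2, trail = 0.5))
})

test_that("end-of-test posterior multiplies likelihood and propagated prior", {
  mix <- kernel_mixture(fix_log, 0.2)
  obs <- c(log10(150), 0.1)

  # gamma = 0: identity B forces the prior through, whatever the evidence
  expect_equal(posterior_end_of_test(obs, matrix_B(0), mix),
               c(lead = 0, test = 1, trail = 0))

  # gamma = 1: uniform prior, posterior proportional to the likelihood
  lik <- vapply(c("lead", "test", "trail"), function(tt) {
    observation_likelihood(mix, obs, tt)
  }, numeric(1))
  expect_equal(unname(posterior_end_of_test(obs, matrix_B(1), mix)),
               unname(lik / sum(lik)), tolerance = 1e-12)

  # generic gamma: three-term enumeration oracle
  B <- matrix_B(0.3)
  oracle <- lik * B["test", ]
  oracle <- oracle / sum(oracle)
  expect_equal(unname(posterior_end_of_test(obs, B, mix)), unname(oracle),
               tolerance = 1e-12)
})

test_that("posteriors are normalised, nonnegative and match enumeration on random instances", {
  mix <- kernel_mixture(fix_log, 0.15)
  set.seed(42)
  for (i in 1:50) {
    obs <- c(runif(1, 0.5, 2.5), runif(1, -0.6, 1.4))
    g <- runif(1)
    post <- posterior_end_of_test(obs, matrix_B(g), mix)
    expect_true(all(post >= 0))
    expect_equal(sum(post), 1, tolerance = 1e-12)
    lik <- vapply(c("lead", "test", "trail"), function(tt) {
      observation_likelihood(mix, obs, tt)
    }, numeric(1))
    oracle <- lik * c(g / 3, 1 - 2 * g / 3, g / 3)
    expect_equal(unname(post), unname(oracle / sum(oracle)),
                 tolerance = 1e-12)
  }
})

test_that("posterior lead mass at the lead centre is non-decreasing in gamma", {
  mix <- kernel_mixture(fix_log, 0.2)
  obs <- c(log10(fix_cfg$f_lead), log10(fix_cfg$P_lead))
  mass <- vapply(seq(0, 1, by = 0.1), function(g) {
    posterior_end_of_test(obs, matrix_B(g), mix)[["lead"]]
  }, numeric(1))
  expect_true(all(diff(mass) >= -1e-12))
})

test_that("the gamma = 0 pipeline reproduces the pure task chain end to end", {
  mix <- kernel_mixture(fix_log, 0.2)
  set.seed(11)
  for (i in 1:10) {
    obs <- c(runif(1, 0.5, 2.5), runif(1, -0.6, 1.4))
    s4 <- belief_next_trial(posterior_end_of_test(obs, matrix_B(0), mix))
    expect_equal(s4, c(lead = 0, test = 0, trail = 1))
  }
})

test_that("the response mixture conserves probability", {
  resp <- fix_param_resp
  # a certain trail belief: no-engagement mass is 1 - EP_trail
  rd <- response_distribution(c(0, 0, 1), resp)
  expect_equal(rd$p_no_engagement, 0.75)

  # uniform belief with all EP = 1: density is the average of the three
  all_in <- response_model(ep = c(lead = 1, test = 1, trail = 1),
                           irt = list(lead = irt_lnorm(log(1), 0.4),
                                      test = irt_lnorm(log(2.5), 0.5),
                                      trail = irt_lnorm(log(10), 0.5)))
  rd2 <- response_distribution(rep(1 / 3, 3), all_in)
  x <- c(0.5, 2, 8, 20)
  avg <- (irt_density(all_in$lead$irt, x) + irt_density(all_in$test$irt, x) +
            irt_density(all_in$trail$irt, x)) / 3
  expect_equal(rd2$density(x), avg, tolerance = 1e-12)

  # generic belief: no-engagement mass + engaged density integral = 1
  s4 <- c(0.2, 0.5, 0.3)
  rd3 <- response_distribution(s4, resp)
  mass <- stats::integrate(rd3$density, 0, 24, rel.tol = 1e-9,
                           subdivisions = 500L)$value
  expect_equal(rd3$p_no_engagement + mass, 1, tolerance = 1e-6)
})
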