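test_that("tertile splits are contiguous, ordered and near-equal", {
  expect_equal(split_tertiles(1:9), list(1:3, 4:6, 7:9))
  expect_equal(split_tertiles(1:10), list(1:4, 5:7, 8:10))
  expect_equal(split_tertiles(1:11), list(1:4, 5:8, 9:11))
  expect_error(split_tertiles(1:2), "at least 3")
  s <- split_tertiles(letters[1:10])
  expect_equal(unlist(s), letters[1:10])
})

test_that("the likelihood of a single unengaged trail response is the no-engagement mass", {
  tiny <- data.frame(
    triad_index = rep(1L, 3L), survey_index = 1L,
    trial_type = c("lead", "test", "trail"),
    frequency_hz = c(217.4, 50, 10), price_s = c(1, 2, 1),
    duration_s = c(25, 50, 25),
    engaged = c(TRUE, TRUE, FALSE), irt_s = c(1, 2, NA))
  resp <- response_model(ep = c(lead = 0.99, test = 0.98, trail = 0.1),
                         irt = fix_param_resp_irts())
  # gamma = 0 forces the trail belief; P(no engagement) = 1 - EP_trail
  nll <- negative_log_likelihood(tiny, c(gamma = 0, sigma = 0.2), "full",
                                 config = fix_cfg, resp = resp)
  expect_equal(nll, -log(0.9), tolerance = 1e-12)
})

test_that("the summed likelihood matches brute-force enumeration and ignores triad order", {
  keep <- unique(fix_log$triad_index)[1:10]
  small <- fix_log[fix_log$triad_index %in% keep, , drop = FALSE]
  attr(small, "config") <- fix_cfg
  class(small) <- class(fix_log)
  params <- c(gamma = 0.25, sigma = 0.18)
  nll <- negative_log_likelihood(small, params, "full", resp = fix_param_resp)

  # independent oracle: per-triad three-state enumeration through the
  # posterior / belief-propagation / response-mixture functions
  mix <- kernel_mixture(small, params[["sigma"]])
  B <- matrix_B(params[["gamma"]])
  total <- 0
  for (ti in keep) {
    tr <- small[small$triad_index == ti, ]
    obs <- c(log10(tr$frequency_hz[tr$trial_type == "test"]),
             log10(tr$price_s[tr$trial_type == "test"]))
    s4 <- belief_next_trial(posterior_end_of_test(obs, B, mix))
    rd <- response_distribution(s4, fix_param_resp)
    eng <- tr$engaged[tr$trial_type == "trail"]
    p <- if (eng) rd$density(tr$irt_s[tr$trial_type == "trail"])
         else rd$p_no_engagement
    total <- total - log(p)
  }
  expect_equal(nll, total, tolerance = 1e-12)

  shuffled <- small[rev(seq_len(nrow(small))), ]
  attr(shuffled, "config") <- fix_cfg
  class(shuffled) <- class(fix_log)
  expect_equal(negative_log_likelihood(shuffled, params, "full",
                                       resp = fix_param_resp),
               nll, tolerance = 1e-12)
})

test_that("BIC follows -2 logL + k log n and adds over tertiles", {
  expect_equal(bic(-100, 2, 100), 209.2103, tolerance = 1e-4)
  expect_equal(bic(-50, 0, 10), 100)
  parts <- c(bic(-40, 2, 30), bic(-45, 2, 30), bic(-38, 2, 31))
  expect_equal(sum(parts), -2 * (-40 - 45 - 38) + 2 * (2 * log(30) + log(31)))
})

test_that("Hessian standard errors match closed-form Gaussian curvature", {
  ll1 <- function(th) -(th[[1]] - 1)^2 / (2 * 0.01)
  h <- hessian_se_and_correlation(ll1, c(theta = 1))
  expect_equal(unname(h$se), 0.1, tolerance = 1e-6)

  ll2 <- function(th) {
    -(th[[1]] - 1)^2 / (2 * 0.01) - (th[[2]] + 2)^2 / (2 * 0.04)
  }
  h2 <- hessian_se_and_correlation(ll2, c(a = 1, b = -2))
  expect_equal(unname(h2$se), c(0.1, 0.2), tolerance = 1e-6)
  expect_equal(h2$rho[1, 2], 0, tolerance = 1e-8)

  flat <- function(th) 0
  expect_error(hessian_se_and_correlation(flat, c(a = 0.5)),
               "not invertible")
})

test_that("nested variants never beat the full model in likelihood and the asymmetric model nests the full one", {
  f_full <- fit_mle(fix_ctx, "full", se = FALSE)
  f_g0 <- fit_mle(fix_ctx, "gamma0", se = FALSE)
  f_g1 <- fit_mle(fix_ctx, "gamma1", se = FALSE)
  expect_gte(f_full$log_likelihood, f_g0$log_likelihood)
  expect_gte(f_full$log_likelihood, f_g1$log_likelihood)

  p_full <- c(gamma = 0.3, sigma = 0.2)
  p_asym <- c(gamma_f = 0.3, gamma_b = 0.3, sigma = 0.2)
  expect_equal(negative_log_likelihood(fix_ctx, p_asym, "asym"),
               negative_log_likelihood(fix_ctx, p_full, "full"),
               tolerance = 1e-10)
})

test_that("fitting is deterministic and recovers a boundary truth", {
  f1 <- fit_mle(fix_ctx, "full")
  f2 <- fit_mle(fix_ctx, "full")
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$log_likelihood, f2$log_likelihood)

  agent0 <- agent_params(gamma = 0, sigma = 0.2)
  log0 <- simulate_trial_log(fix_cfg, agent0, n_surveys = 6L, seed = 77L)
  suppressWarnings(
    f0 <- fit_mle(log0, "full", config = fix_cfg, resp = fix_param_resp))
  expect_lte(f0$theta[["gamma"]], 0.05)
})

test_that("model fits report plausible uncertainty on the recovery fixture", {
  f <- fit_mle(fix_ctx, "full")
  expect_true(all(is.finite(f$se)))
  expect_true(all(f$se > 0))
  # gamma and sigma trade off: their estimates anticorrelate
  expect_lt(f$rho["gamma", "sigma"], 0)
  expect_gte(f$rho["gamma", "sigma"], -1)
  expect_equal(f$bic, -2 * f$log_likelihood + 2 * log(f$n_data))
})
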