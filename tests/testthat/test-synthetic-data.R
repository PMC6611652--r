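test_that("survey grid is the Cartesian product of the config lists", {
  expect_equal(nrow(build_survey_grid(fix_cfg)), 126L)
  cfg <- one_condition_config(c(20, 50), c(1, 2, 5))
  expect_equal(nrow(build_survey_grid(cfg)), 6L)
  # duplicates repeat; the size is still |F| x |P|
  cfg2 <- one_condition_config(c(20, 20), c(1, 2))
  expect_equal(nrow(build_survey_grid(cfg2)), 4L)
  cfg3 <- fix_cfg; cfg3$survey_frequencies <- numeric(0)
  expect_error(build_survey_grid(cfg3), "non-empty")
})

test_that("sessions are triads of lead, test, trail visiting each condition once per survey", {
  sess <- simulate_session(fix_cfg, n_surveys = 3L, seed = 0L)
  expect_equal(length(unique(sess$triad_index)), 378L)
  expect_equal(nrow(sess), 1134L)
  # order within each triad
  types <- matrix(sess$trial_type, ncol = 3L, byrow = TRUE)
  expect_true(all(types[, 1] == "lead" & types[, 2] == "test" &
                    types[, 3] == "trail"))
  # lead/trail constants, duration rule
  expect_true(all(sess$frequency_hz[sess$trial_type == "lead"] == fix_cfg$f_lead))
  expect_true(all(sess$price_s[sess$trial_type == "trail"] == fix_cfg$P_trail))
  expect_equal(sess$duration_s, trial_duration(sess$price_s, fix_cfg))
  # conservation: per-survey multiset of test conditions equals the grid
  grid <- build_survey_grid(fix_cfg)
  grid_key <- sort(paste(grid$frequency_hz, grid$price_s))
  for (s in 0:2) {
    tests <- sess[sess$trial_type == "test" & sess$survey_index == s, ]
    expect_equal(sort(paste(tests$frequency_hz, tests$price_s)), grid_key)
  }
})

test_that("schedule and behaviour are seed-deterministic", {
  a <- simulate_trial_log(fix_cfg, fix_agent, n_surveys = 2L, seed = 5L)
  b <- simulate_trial_log(fix_cfg, fix_agent, n_surveys = 2L, seed = 5L)
  expect_identical(a, b)
  c <- simulate_trial_log(fix_cfg, fix_agent, n_surveys = 2L, seed = 6L)
  expect_false(identical(a$frequency_hz, c$frequency_hz))
})

test_that("trail engagement matches the analytic response mixture", {
  # single repeated test condition: the analytic engagement probability is
  # sum_i s4_i EP_i with s4 from the posterior at that observation
  cfg <- one_condition_config(50, 10)
  agent <- agent_params(gamma = 0.4, sigma = 0.2,
                        ep = c(lead = 0.99, test = 0.98, trail = 0.25))
  sess <- simulate_session(cfg, n_surveys = 2000L, seed = 3L)
  resp <- simulate_responses(sess, agent, seed = 4L, trials = "trail")
  mix <- kernel_mixture(sess, agent$sigma)
  post <- posterior_end_of_test(c(log10(50), log10(10)),
                                matrix_B(agent$gamma), mix)
  s4 <- belief_next_trial(post)
  p_eng <- sum(s4 * agent$ep)
  se <- sqrt(p_eng * (1 - p_eng) / nrow(resp))
  expect_lt(abs(mean(resp$engaged) - p_eng), 3 * se)
})

test_that("a certain agent (gamma = 0) responds as the pure trail model", {
  cfg <- one_condition_config(217.4, 1)  # maximally misleading observation
  agent <- agent_params(gamma = 0, sigma = 0.2)
  sess <- simulate_session(cfg, n_surveys = 1500L, seed = 8L)
  resp <- simulate_responses(sess, agent, seed = 9L, trials = "trail")
  p <- agent$ep[["trail"]]
  se <- sqrt(p * (1 - p) / nrow(resp))
  expect_lt(abs(mean(resp$engaged) - p), 3 * se)
  # engaged IRTs come from the trail component only: long-IRT distribution
  irts <- resp$irt_s[resp$engaged]
  expect_gt(min(irts), 0)
  expect_lte(max(irts), 24)
  expect_gt(median(irts), 5)  # trail component is slow; test/lead are fast
})

test_that("a past-blind agent (gamma = 1) at the lead point responds mostly test-like", {
  # enumeration oracle: with the observation at the lead centre the
  # posterior splits between lead and the (identically placed) test kernel,
  # so the trail-trial belief loads on test and trail; the response mixture
  # is then dominated by the fast, high-engagement test component
  cfg <- one_condition_config(217.4, 1)
  agent <- agent_params(gamma = 1, sigma = 0.2)
  sess <- simulate_session(cfg, n_surveys = 1000L, seed = 10L)
  mix <- kernel_mixture(sess, agent$sigma)
  post <- posterior_end_of_test(c(log10(217.4), 0), matrix_B(1), mix)
  s4 <- belief_next_trial(post)
  expect_gt(s4[["test"]], 0.45)

  rm <- response_model(ep = agent$ep, irt = agent$irt)
  rd <- response_distribution(s4, rm)
  p_short <- stats::integrate(rd$density, 0, 6)$value
  p_long <- stats::integrate(rd$density, 6, 24)$value
  expect_gt(p_short, p_long)  # test-like responses dominate

  resp <- simulate_responses(sess, agent, seed = 11L, trials = "trail")
  n <- nrow(resp)
  p_eng <- rd$p_engagement
  expect_lt(abs(mean(resp$engaged) - p_eng),
            3 * sqrt(p_eng * (1 - p_eng) / n))
  frac_short <- p_short / p_eng
  obs_short <- mean(resp$irt_s[resp$engaged] < 6)
  expect_lt(abs(obs_short - frac_short),
            3 * sqrt(frac_short * (1 - frac_short) / sum(resp$engaged)))
})

test_that("first-survey exclusion removes exactly one survey of triads", {
  log <- simulate_trial_log(fix_cfg, fix_agent, n_surveys = 3L, seed = 2L)
  out <- exclude_first_survey(log)
  expect_equal(length(unique(out$triad_index)), 252L)
  expect_equal(length(unique(log$triad_index)) -
                 length(unique(out$triad_index)), 126L)
  expect_false(0L %in% out$survey_index)
  cfg <- one_condition_config(c(20, 50), c(1, 2, 5))
  log6 <- simulate_trial_log(cfg, fix_agent, n_surveys = 2L, seed = 2L)
  expect_equal(length(unique(exclude_first_survey(log6)$triad_index)), 6L)
  one <- simulate_trial_log(cfg, fix_agent, n_surveys = 1L, seed = 2L)
  expect_warning(empty <- exclude_first_survey(one), "no triads remain")
  expect_equal(nrow(empty), 0L)
})

test_that("trial logs round-trip through the CSV dialect", {
  log <- simulate_trial_log(fix_cfg, fix_agent, n_surveys = 2L, seed = 12L)
  path <- tempfile(fileext = ".csv")
  write_trial_log(log, path)
  back <- read_trial_log(path, config = fix_cfg)
  expect_equal(as.data.frame(back), as.data.frame(log), tolerance = 1e-12)
  header <- readLines(path, n = 1L)
  expect_match(header, "triad_index.*survey_index.*trial_type.*frequency_hz")
})
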