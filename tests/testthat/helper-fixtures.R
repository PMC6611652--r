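# Shared fixtures, built once per test run. Sizes are chosen so the whole
# suite stays well inside a desktop-minutes budget; acceptance tests that
# need larger simulations build their own data.

fix_cfg <- task_config(1)

# a moderately trained synthetic subject: 8 surveys, first excluded
fix_agent <- agent_params(gamma = 0.3, sigma = 0.2)
fix_log <- exclude_first_survey(
  simulate_trial_log(fix_cfg, fix_agent, n_surveys = 8L, seed = 101L))
fix_resp <- fit_response_model(fix_log, fix_cfg)
fix_ctx <- fit_context(fix_log, fix_cfg, fix_resp)

# a tiny config with a single test condition, for analytic response checks
one_condition_config <- function(f, P, base = fix_cfg) {
  cfg <- base
  cfg$survey_frequencies <- f
  cfg$survey_prices <- P
  cfg
}

# parametric response model with known components (no KDE estimation noise)
fix_param_resp_irts <- function() {
  list(lead = irt_lnorm(log(1.0), 0.4),
       test = irt_lnorm(log(2.5), 0.5),
       trail = irt_lnorm(log(12), 0.4))
}
fix_param_resp <- response_model(
  ep = c(lead = 0.99, test = 0.98, trail = 0.25),
  irt = fix_param_resp_irts())
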