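#' Sort trail responses by the region of the preceding test trial
#'
#' Each trail trial is assigned the frequency-price region (alpha, beta,
#' lambda, other) of its own triad's test trial; groups are disjoint and
#' exhaustive over the trail trials.
#'
#' @param trial_log a trial log.
#' @param config a \code{\link{task_config}}.
#' @return named list of data.frames (\code{alpha}, \code{beta},
#'   \code{lambda}, \code{other}) of trail responses with columns
#'   \code{triad_index}, \code{engaged}, \code{irt_s}.
#' @export
sort_trail_by_preceding_region <- function(trial_log,
                                           config = attr(trial_log, "config")) {
  stopifnot(inherits(config, "task_config"))
  resp <- extract_responses(trial_log)
  tests <- trial_log[trial_log$trial_type == "test", , drop = FALSE]
  trails <- resp[resp$trial_type == "trail", , drop = FALSE]
  pos <- match(trails$triad_index, tests$triad_index)
  if (any(is.na(pos))) {
    stop("sort_trail_by_preceding_region: trail trial(s) without a test ",
         "trial in triad(s) ",
         paste(utils::head(trails$triad_index[is.na(pos)], 5L),
               collapse = ", "), call. = FALSE)
  }
  region <- classify_region(tests$frequency_hz[pos], tests$price_s[pos], config)
  lapply(stats::setNames(nm = c("alpha", "beta", "lambda", "other")),
         function(rg) {
           trails[region == rg, c("triad_index", "engaged", "irt_s"),
                  drop = FALSE]
         })
}

# trail responses whose preceding test trial satisfies a predicate on (f, P)
trail_after <- function(trial_log, pred) {
  resp <- extract_responses(trial_log)
  tests <- trial_log[trial_log$trial_type == "test", , drop = FALSE]
  trails <- resp[resp$trial_type == "trail", , drop = FALSE]
  pos <- match(trails$triad_index, tests$triad_index)
  keep <- pred(tests$frequency_hz[pos], tests$price_s[pos])
  trails[keep & !is.na(keep), , drop = FALSE]
}

#' Short-IRT fractions by frequency and price category
#'
#' Computes the fraction of short trail-trial IRTs (confusion rate per
#' trail-trial opportunity) grouped by properties of the preceding test
#' trial:
#' \describe{
#'   \item{frequency}{low / intermediate / high frequency, restricted to a
#'     short-price band around the 1 s lead/trail price (default
#'     [0.5, 2] s, the grid prices closest to 1 s).}
#'   \item{price_high_f}{at high (lead-like) frequency: short-price band
#'     versus long prices (> 7 s).}
#'   \item{price_sensitivity}{sub-0.3 s prices (duration pinned at 25 s)
#'     split by low versus high frequency; reported as a contrast only,
#'     with no model prediction attached.}
#' }
#' Empty categories are reported with \code{n = 0} and an NA fraction.
#'
#' @param trial_log a trial log.
#' @param config a \code{\link{task_config}}.
#' @param threshold short-IRT threshold; default the 95th percentile of the
#'   log's engaged test-trial IRTs.
#' @param price_band_1s numeric length-2: the price band treated as
#'   "P = 1 s".
#' @return data.frame with columns \code{analysis}, \code{category},
#'   \code{n_trail}, \code{n_short}, \code{fraction}.
#' @export
category_breakdown <- function(trial_log, config = attr(trial_log, "config"),
                               threshold = NULL,
                               price_band_1s = c(0.5, 2)) {
  stopifnot(inherits(config, "task_config"))
  resp <- extract_responses(trial_log)
  if (is.null(threshold)) {
    test_irts <- resp$irt_s[resp$trial_type == "test" & resp$engaged]
    threshold <- short_irt_threshold(test_irts)
  }
  in_band <- function(P) P >= price_band_1s[1] & P <= price_band_1s[2]
  groups <- list(
    list("frequency", "low_f",
         function(f, P) in_band(P) & frequency_category(f, config) == "low"),
    list("frequency", "intermediate_f",
         function(f, P) in_band(P) &
           frequency_category(f, config) == "intermediate"),
    list("frequency", "high_f",
         function(f, P) in_band(P) & frequency_category(f, config) == "high"),
    list("price_high_f", "P_1s",
         function(f, P) in_band(P) & frequency_category(f, config) == "high"),
    list("price_high_f", "P_gt_7s",
         function(f, P) P > 7 & frequency_category(f, config) == "high"),
    list("price_sensitivity", "low_f_P_lt_0.3s",
         function(f, P) P < 0.3 & frequency_category(f, config) == "low"),
    list("price_sensitivity", "high_f_P_lt_0.3s",
         function(f, P) P < 0.3 & frequency_category(f, config) == "high")
  )
  rows <- lapply(groups, function(g) {
    tr <- trail_after(trial_log, g[[3L]])
    n <- nrow(tr)
    if (n == 0L) {
      data.frame(analysis = g[[1L]], category = g[[2L]], n_trail = 0L,
                 n_short = NA_integer_, fraction = NA_real_)
    } else {
      short <- sum(tr$engaged & is.finite(tr$irt_s) & tr$irt_s <= threshold)
      data.frame(analysis = g[[1L]], category = g[[2L]], n_trail = n,
                 n_short = short, fraction = short / n)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  out
}

#' Per-tertile fits and learning tests
#'
#' Divides the triads into three sequential tertiles, fits the model
#' independently to each, computes the tertile short-IRT fractions, and runs
#' the first-versus-last learning tests: a binomial proportion test on the
#' short-IRT fractions and a label-permutation test on the change in each
#' MLE parameter.
#'
#' @param trial_log a trial log.
#' @param variant model variant to fit (default \code{"full"}).
#' @param config a \code{\link{task_config}}.
#' @param resp optional \code{\link{response_model}}; fitted from the log
#'   when NULL.
#' @param n_perm permutations for the MLE-change test.
#' @param seed integer seed.
#' @return list of class \code{tertile_analysis} with \code{fits} (one
#'   \code{fit_result} per tertile), \code{short_irt} (per-tertile counts
#'   and fractions), \code{threshold}, \code{test_fraction_change} (binomial
#'   proportion test first vs last), \code{test_mle_change} (per-parameter
#'   permutation test).
#' @export
tertile_analysis <- function(trial_log, variant = "full",
                             config = attr(trial_log, "config"), resp = NULL,
                             n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(config, "task_config"))
  if (is.null(resp)) resp <- fit_response_model(trial_log, config)
  ctx <- fit_context(trial_log, config, resp)
  blocks <- split_tertiles(seq_len(ctx$n))
  fits <- lapply(blocks, function(rw) fit_mle(ctx, variant, rows = rw))

  responses <- extract_responses(trial_log)
  test_irts <- responses$irt_s[responses$trial_type == "test" &
                                 responses$engaged]
  threshold <- short_irt_threshold(test_irts)
  trails <- responses[responses$trial_type == "trail", , drop = FALSE]
  trails <- trails[match(ctx$triad_index, trails$triad_index), , drop = FALSE]
  per_tertile <- lapply(seq_along(blocks), function(i) {
    tr <- trails[blocks[[i]], , drop = FALSE]
    short <- sum(tr$engaged & is.finite(tr$irt_s) & tr$irt_s <= threshold)
    data.frame(tertile = i, n_trail = nrow(tr), n_short = short,
               fraction = short / nrow(tr),
               ep = mean(tr$engaged))
  })
  short_irt <- do.call(rbind, per_tertile)

  frac_test <- binomial_proportion_test(
    short_irt$n_short[1L], short_irt$n_trail[1L],
    short_irt$n_short[3L], short_irt$n_trail[3L])
  mle_test <- mle_change_permutation_test(ctx, variant, n_perm = n_perm,
                                          seed = seed)

  structure(list(fits = fits, short_irt = short_irt, threshold = threshold,
                 test_fraction_change = frac_test,
                 test_mle_change = mle_test,
                 variant = variant, seed = seed),
            class = "tertile_analysis")
}

#' @export
print.tertile_analysis <- function(x, ...) {
  cat("Tertile analysis (variant:", x$variant, ")\n")
  for (i in 1:3) {
    th <- x$fits[[i]]$theta
    cat(sprintf("  tertile %d: %s; short-IRT fraction %.3f (n = %d)\n", i,
                paste(sprintf("%s = %.3f", names(th), th), collapse = ", "),
                x$short_irt$fraction[i], x$short_irt$n_trail[i]))
  }
  cat(sprintf("  short-IRT change first vs last: Z = %.3f, p = %.4g\n",
              x$test_fraction_change$statistic,
              x$test_fraction_change$p_value))
  print(x$test_mle_change)
  invisible(x)
}

#' Simulate trail responses from fitted model parameters
#'
#' Draws a trail response for every triad from the model's predictive
#' response distribution given the preceding test observation: belief at
#' the start of the trail trial under (gamma, sigma), then engagement and,
#' if engaged, an IRT from the belief-weighted mixture of the per-type
#' response components.
#'
#' @param trial_log a trial log providing the schedule.
#' @param params named parameter vector (\code{gamma}, \code{sigma}, or
#'   asymmetric \code{gamma_f}, \code{gamma_b}, \code{sigma}).
#' @param resp a \code{\link{response_model}}.
#' @param config a \code{\link{task_config}}.
#' @param seed integer seed.
#' @return data.frame of simulated trail responses (\code{triad_index},
#'   \code{engaged}, \code{irt_s}).
#' @export
simulate_model_trail_responses <- function(trial_log, params, resp,
                                           config = attr(trial_log, "config"),
                                           seed = 1L) {
  stopifnot(inherits(resp, "response_model"))
  set.seed(seed)
  mix <- kernel_mixture(trial_log, params[["sigma"]])
  tests <- trial_log[trial_log$trial_type == "test", , drop = FALSE]
  B <- if ("gamma_f" %in% names(params)) {
    matrix_B_asym(params[["gamma_f"]], params[["gamma_b"]])
  } else {
    matrix_B(params[["gamma"]])
  }
  lik <- observation_type_likelihoods(mix, log10(tests$frequency_hz),
                                      log10(tests$price_s))
  A <- transition_matrix_A()
  eps <- vapply(TRIAL_TYPES, function(tt) resp[[tt]]$ep, numeric(1L))
  n <- nrow(tests)
  engaged <- logical(n); irt <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    post <- lik[i, ] * B["test", ]
    s4 <- as.vector((post / sum(post)) %*% A)
    p_eng <- sum(s4 * eps)
    if (stats::runif(1L) < p_eng) {
      engaged[i] <- TRUE
      comp <- sample(TRIAL_TYPES, 1L, prob = s4 * eps)
      irt[i] <- irt_sample(resp[[comp]]$irt, 1L, upper = 24)
    }
  }
  data.frame(triad_index = tests$triad_index, engaged = engaged, irt_s = irt)
}

#' Compare real and model-simulated trail responses
#'
#' Simulates trail responses from fitted parameters on the same trial
#' schedule and reports the engagement probabilities and earth mover's
#' similarities between real and simulated IRT distributions, overall and
#' split by the region of the preceding test trial.
#'
#' @param fit a \code{fit_result} (or a named parameter vector).
#' @param trial_log the trial log the fit was obtained from.
#' @param config a \code{\link{task_config}}.
#' @param resp the \code{\link{response_model}} used in fitting (refitted
#'   from the log when NULL).
#' @param seed integer seed for the simulation.
#' @return list with \code{ep} (real and simulated trail EP),
#'   \code{similarity_overall}, \code{similarity_by_region} (named vector),
#'   and the simulated response table.
#' @export
simulate_and_compare <- function(fit, trial_log,
                                 config = attr(trial_log, "config"),
                                 resp = NULL, seed = 1L) {
  params <- if (inherits(fit, "fit_result")) fit$theta else fit
  if (is.null(resp)) resp <- fit_response_model(trial_log, config)
  sim <- simulate_model_trail_responses(trial_log, params, resp, config, seed)

  responses <- extract_responses(trial_log)
  real <- responses[responses$trial_type == "trail", , drop = FALSE]
  ep <- c(real = mean(real$engaged), simulated = mean(sim$engaged))

  sim_irts <- sim$irt_s[sim$engaged]
  real_irts <- real$irt_s[real$engaged]
  overall <- if (length(sim_irts) && length(real_irts)) {
    emd_similarity(real_irts, sim_irts, support_max = 24)
  } else NA_real_

  by_region <- sort_trail_by_preceding_region(trial_log, config)
  tests <- trial_log[trial_log$trial_type == "test", , drop = FALSE]
  region <- classify_region(tests$frequency_hz, tests$price_s, config)
  sim_region <- region[match(sim$triad_index, tests$triad_index)]
  reg_sim <- vapply(names(by_region), function(rg) {
    ri <- by_region[[rg]]$irt_s[by_region[[rg]]$engaged]
    si <- sim$irt_s[sim$engaged & sim_region == rg]
    if (length(ri) && length(si)) emd_similarity(ri, si, 24) else NA_real_
  }, numeric(1L))

  list(ep = ep, similarity_overall = overall,
       similarity_by_region = reg_sim, simulated = sim)
}

#' End-to-end analysis report for a trial log
#'
#' Runs the full analysis: response-model estimation, region-sorted trail
#' IRT contrasts (are alpha-preceded short trail IRTs test-like, are
#' beta-preceded ones lead-like), category breakdowns of the short-IRT
#' fraction with binomial proportion tests, per-tertile fits with the
#' learning tests, and the model-versus-data comparison. All randomness is
#' governed by \code{seed}, recorded in the report's provenance.
#'
#' @param trial_log a trial log.
#' @param config a \code{\link{task_config}}.
#' @param variant model variant for the fits.
#' @param n_perm permutations for permutation tests.
#' @param seed integer seed.
#' @return list of class \code{analysis_report}.
#' @export
analyze_session <- function(trial_log, config = attr(trial_log, "config"),
                            variant = "full", n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(config, "task_config"))
  set.seed(seed)
  resp_model <- fit_response_model(trial_log, config)
  responses <- extract_responses(trial_log)
  test_irts <- responses$irt_s[responses$trial_type == "test" &
                                 responses$engaged]
  lead_irts <- responses$irt_s[responses$trial_type == "lead" &
                                 responses$engaged]
  threshold <- short_irt_threshold(test_irts)

  by_region <- sort_trail_by_preceding_region(trial_log, config)
  short_irts <- function(df) {
    df$irt_s[df$engaged & is.finite(df$irt_s) & df$irt_s <= threshold]
  }
  alpha_short <- short_irts(by_region$alpha)
  beta_short <- short_irts(by_region$beta)
  region_tests <- list()
  if (length(alpha_short) >= 2L) {
    region_tests$alpha_test_vs_lead <- emd_contrast_test(
      alpha_short, test_irts[test_irts <= 24], lead_irts,
      support_max = 24, n_perm = n_perm, seed = seed + 1L)
  }
  if (length(beta_short) >= 2L) {
    region_tests$beta_lead_vs_test <- emd_contrast_test(
      beta_short, lead_irts, test_irts[test_irts <= 24],
      support_max = 24, n_perm = n_perm, seed = seed + 2L)
  }

  breakdown <- category_breakdown(trial_log, config, threshold = threshold)
  bt <- function(c1, c2) {
    r1 <- breakdown[breakdown$category == c1, ]
    r2 <- breakdown[breakdown$category == c2, ]
    if (r1$n_trail == 0L || r2$n_trail == 0L) return(NULL)
    binomial_proportion_test(r1$n_short, r1$n_trail, r2$n_short, r2$n_trail)
  }
  category_tests <- list(
    intermediate_vs_low_f = bt("intermediate_f", "low_f"),
    intermediate_vs_high_f = bt("intermediate_f", "high_f"),
    P1s_vs_Pgt7s_high_f = bt("P_1s", "P_gt_7s"),
    low_vs_high_f_short_P = bt("low_f_P_lt_0.3s", "high_f_P_lt_0.3s")
  )

  tertiles <- tertile_analysis(trial_log, variant, config, resp_model,
                               n_perm = n_perm, seed = seed + 3L)
  fit_all <- fit_mle(trial_log, variant, config, resp_model)
  comparison <- simulate_and_compare(fit_all, trial_log, config, resp_model,
                                     seed = seed + 4L)

  structure(list(
    response_model = resp_model,
    threshold = threshold,
    region_tests = region_tests,
    category_breakdown = breakdown,
    category_tests = category_tests,
    fit = fit_all,
    tertiles = tertiles,
    comparison = comparison,
    provenance = list(seed = seed, n_perm = n_perm, variant = variant,
                      subject_id = config$subject_id,
                      n_triads = sum(trial_log$trial_type == "test"),
                      package_version =
                        as.character(utils::packageVersion("triadhmm")))
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report (subject", x$provenance$subject_id, ",",
      x$provenance$n_triads, "triads, seed", x$provenance$seed, ")\n")
  print(x$fit)
  cat(sprintf("Short-IRT threshold: %.2f s\n", x$threshold))
  cat("Short-IRT fraction by tertile:",
      paste(sprintf("%.3f", x$tertiles$short_irt$fraction), collapse = ", "),
      "\n")
  cat(sprintf("Real vs simulated trail EP: %.3f vs %.3f (similarity %.3f)\n",
              x$comparison$ep[["real"]], x$comparison$ep[["simulated"]],
              x$comparison$similarity_overall))
  invisible(x)
}

#' Write an analysis report to JSON
#'
#' Serialises the numeric surface of the report (fits, fractions, test
#' statistics and p-values, provenance); density objects are reduced to
#' their parameters.
#'
#' @param report an \code{analysis_report}.
#' @param path output file path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  as_num <- function(tt) {
    if (is.null(tt)) return(NULL)
    list(statistic = tt$statistic, p_value = tt$p_value)
  }
  fit_out <- function(f) {
    list(variant = f$variant, theta = as.list(f$theta),
         se = as.list(f$se), log_likelihood = f$log_likelihood,
         bic = f$bic, n_data = f$n_data,
         rho = if (!is.null(f$rho) && nrow(f$rho) > 1L) f$rho[1L, 2L] else NULL)
  }
  out <- list(
    provenance = report$provenance,
    threshold = report$threshold,
    fit = fit_out(report$fit),
    tertile_fits = lapply(report$tertiles$fits, fit_out),
    short_irt_by_tertile = report$tertiles$short_irt,
    region_tests = lapply(report$region_tests, as_num),
    category_breakdown = report$category_breakdown,
    category_tests = lapply(report$category_tests, as_num),
    mle_change = report$tertiles$test_mle_change[,
      c("parameter", "observed", "null_q95", "p_value", "significant")],
    ep = as.list(report$comparison$ep),
    similarity_overall = report$comparison$similarity_overall,
    similarity_by_region = as.list(report$comparison$similarity_by_region)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
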