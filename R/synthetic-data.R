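#' Build the survey grid of test-trial conditions
#'
#' A survey is one complete pass over the Cartesian product of the
#' configuration's test frequencies and prices. The packaged defaults use 14
#' log-spaced frequencies spanning the trail-to-lead range and 9 log-spaced
#' prices in [0.25, 25] s, so one survey is 126 conditions (= the number of
#' triads excluded as the adjustment survey).
#'
#' @param config a \code{\link{task_config}}.
#' @return data.frame with columns \code{frequency_hz}, \code{price_s}; one
#'   row per condition, frequencies varying fastest.
#' @export
build_survey_grid <- function(config) {
  stopifnot(inherits(config, "task_config"))
  f <- config$survey_frequencies
  P <- config$survey_prices
  if (length(f) < 1L || length(P) < 1L) {
    stop("build_survey_grid: survey_frequencies and survey_prices must be non-empty",
         call. = FALSE)
  }
  expand.grid(frequency_hz = f, price_s = P, KEEP.OUT.ATTRS = FALSE)
}

#' Simulate a session of cyclic triads
#'
#' Concatenates \code{n_surveys} surveys. Within each survey every grid
#' condition is visited exactly once, in a seed-determined random order, as
#' the test trial of one lead-test-trail triad. Lead and trail trials carry
#' the configuration's fixed frequency and price; durations follow
#' \code{\link{trial_duration}}.
#'
#' @param config a \code{\link{task_config}}.
#' @param n_surveys number of surveys (>= 1).
#' @param seed integer seed; the same seed reproduces the same schedule.
#' @return A \code{triad_session}: a data.frame with one row per trial and
#'   columns \code{triad_index} (1-based, global), \code{survey_index}
#'   (0-based), \code{trial_type}, \code{frequency_hz}, \code{price_s},
#'   \code{duration_s}; the configuration is attached as attribute
#'   \code{"config"}.
#' @export
simulate_session <- function(config, n_surveys, seed = 1L) {
  stopifnot(inherits(config, "task_config"), n_surveys >= 1)
  set.seed(seed)
  grid <- build_survey_grid(config)
  m <- nrow(grid)
  triads <- vector("list", n_surveys)
  for (s in seq_len(n_surveys)) {
    ord <- sample.int(m)
    g <- grid[ord, , drop = FALSE]
    triads[[s]] <- data.frame(
      survey_index = s - 1L,
      test_f = g$frequency_hz,
      test_P = g$price_s
    )
  }
  triads <- do.call(rbind, triads)
  n <- nrow(triads)
  triads$triad_index <- seq_len(n)
  sess <- data.frame(
    triad_index  = rep(triads$triad_index, each = 3L),
    survey_index = rep(triads$survey_index, each = 3L),
    trial_type   = rep(TRIAL_TYPES, times = n),
    frequency_hz = as.vector(rbind(config$f_lead, triads$test_f, config$f_trail)),
    price_s      = as.vector(rbind(config$P_lead, triads$test_P, config$P_trail)),
    stringsAsFactors = FALSE
  )
  sess$duration_s <- trial_duration(sess$price_s, config)
  attr(sess, "config") <- config
  class(sess) <- c("triad_session", "data.frame")
  sess
}

#' Truncated log-normal IRT distribution
#'
#' Parametric initial-response-time distribution used by synthetic agents:
#' a log-normal truncated to (0, \code{support_max}] and renormalised.
#'
#' @param meanlog,sdlog log-normal parameters (natural-log scale, seconds).
#' @param support_max upper support bound, s (24 for lead/trail-type
#'   responses: later initial responses leave no time to earn a reward).
#' @return an object of class \code{c("irt_lnorm", "irt_dist")}.
#' @export
irt_lnorm <- function(meanlog, sdlog, support_max = 24) {
  stopifnot(is.finite(meanlog), sdlog > 0, support_max > 0)
  structure(list(meanlog = meanlog, sdlog = sdlog, support_max = support_max),
            class = c("irt_lnorm", "irt_dist"))
}

#' Evaluate an IRT density
#'
#' @param d an \code{irt_dist} object (\code{\link{irt_lnorm}} or a kernel
#'   density estimate from \code{\link{fit_irt_density}}).
#' @param x evaluation points, s.
#' @return density values (0 outside the support).
#' @export
irt_density <- function(d, x) UseMethod("irt_density")

#' @export
irt_density.irt_lnorm <- function(d, x) {
  z <- stats::plnorm(d$support_max, d$meanlog, d$sdlog)
  out <- stats::dlnorm(x, d$meanlog, d$sdlog) / z
  out[x <= 0 | x > d$support_max] <- 0
  out
}

#' Sample from an IRT distribution
#'
#' @inheritParams irt_density
#' @param n number of draws.
#' @param upper optional tighter upper bound (e.g. the trial's engagement
#'   window D - P); draws exceeding it are rejected, i.e. sampling is from
#'   the distribution truncated to (0, \code{min(upper, support_max)}].
#' @return numeric vector of IRTs, s.
#' @export
irt_sample <- function(d, n, upper = NULL) UseMethod("irt_sample")

#' @export
irt_sample.irt_lnorm <- function(d, n, upper = NULL) {
  ub <- if (is.null(upper)) d$support_max else min(upper, d$support_max)
  pmax <- stats::plnorm(ub, d$meanlog, d$sdlog)
  stats::qlnorm(stats::runif(n) * pmax, d$meanlog, d$sdlog)
}

#' Ground-truth parameters of a synthetic agent
#'
#' Bundles the recognition parameters (gamma, sigma) with the per-type
#' engagement probabilities and IRT distributions that the agent uses to
#' respond. Defaults describe a moderately trained subject: near-certain
#' engagement with short IRTs on lead trials, near-certain engagement with
#' slightly longer IRTs on test trials, and rare, slow engagement on the
#' near-worthless trail trials.
#'
#' @param gamma past-evidence uncertainty in [0,1]; may be a vector (one
#'   value per triad, recycled) to emulate learning across the session.
#' @param sigma kernel width of the agent's perceptual likelihood, log10
#'   frequency-price units.
#' @param gamma_f,gamma_b optional forward/backward uncertainties; when
#'   supplied the agent uses the asymmetric belief-transition matrix and
#'   \code{gamma} is ignored.
#' @param ep named engagement probabilities for \code{lead}, \code{test},
#'   \code{trail}.
#' @param irt named list of \code{irt_dist} objects for the three types.
#' @return object of class \code{agent_params}.
#' @export
agent_params <- function(gamma = 0.3, sigma = 0.2,
                         gamma_f = NULL, gamma_b = NULL,
                         ep = c(lead = 0.99, test = 0.98, trail = 0.25),
                         irt = list(
                           lead  = irt_lnorm(log(1.0), 0.4),
                           test  = irt_lnorm(log(2.5), 0.5),
                           trail = irt_lnorm(log(12), 0.4)
                         )) {
  stopifnot(all(gamma >= 0 & gamma <= 1), sigma > 0,
            all(TRIAL_TYPES %in% names(ep)),
            all(TRIAL_TYPES %in% names(irt)),
            all(ep >= 0 & ep <= 1))
  if (xor(is.null(gamma_f), is.null(gamma_b))) {
    stop("agent_params: supply both gamma_f and gamma_b or neither",
         call. = FALSE)
  }
  structure(list(gamma = gamma, sigma = sigma,
                 gamma_f = gamma_f, gamma_b = gamma_b,
                 ep = ep[TRIAL_TYPES], irt = irt[TRIAL_TYPES]),
            class = "agent_params")
}

#' Simulate responses of a synthetic agent
#'
#' Lead and test responses are drawn directly from the agent's per-type
#' engagement probability and IRT distribution. Trail responses are drawn
#' from the model's predictive response distribution: the belief at the
#' start of the trail trial is computed from the preceding test observation
#' by Bayesian integration with the agent's gamma and sigma, and engagement
#' and IRT are sampled from the resulting mixture over the three per-type
#' response models. IRTs are truncated to the trial's engagement window
#' (duration minus price, capped at 24 s).
#'
#' @param session a \code{triad_session} from \code{\link{simulate_session}}.
#' @param agent an \code{\link{agent_params}} object.
#' @param seed integer seed (independent of the schedule seed).
#' @param trials \code{"all"} (default) to simulate every trial, or
#'   \code{"trail"} for trail trials only.
#' @return data.frame with columns \code{triad_index}, \code{trial_type},
#'   \code{engaged} (logical), \code{irt_s} (NA when not engaged).
#' @export
simulate_responses <- function(session, agent, seed = 1L,
                               trials = c("all", "trail")) {
  stopifnot(inherits(session, "triad_session"), inherits(agent, "agent_params"))
  trials <- match.arg(trials)
  set.seed(seed)
  config <- attr(session, "config")

  mix <- kernel_mixture(session, agent$sigma)
  tests <- session[session$trial_type == "test", , drop = FALSE]
  n <- nrow(tests)
  gamma <- rep_len(agent$gamma, n)
  asym <- !is.null(agent$gamma_f)

  # belief over types at the start of each trail trial (n x 3)
  s4 <- matrix(0, n, 3, dimnames = list(NULL, TRIAL_TYPES))
  lik <- observation_type_likelihoods(mix, log10(tests$frequency_hz),
                                      log10(tests$price_s))
  A <- transition_matrix_A()
  for (i in seq_len(n)) {
    B <- if (asym) matrix_B_asym(agent$gamma_f, agent$gamma_b)
         else matrix_B(gamma[i])
    post <- lik[i, ] * B["test", ]
    post <- post / sum(post)
    s4[i, ] <- post %*% A
  }

  ep <- agent$ep
  out <- vector("list", 3L)
  types_wanted <- if (trials == "all") TRIAL_TYPES else "trail"
  for (tt in types_wanted) {
    rows <- session[session$trial_type == tt, , drop = FALSE]
    window <- pmin(rows$duration_s - rows$price_s, 24)
    m <- nrow(rows)
    if (tt == "trail") {
      p_eng <- as.vector(s4 %*% ep)
      engaged <- stats::runif(m) < p_eng
      irt <- rep(NA_real_, m)
      for (i in which(engaged)) {
        w <- s4[i, ] * ep
        comp <- sample(TRIAL_TYPES, 1L, prob = w)
        irt[i] <- irt_sample(agent$irt[[comp]], 1L, upper = window[i])
      }
    } else {
      engaged <- stats::runif(m) < ep[[tt]]
      irt <- rep(NA_real_, m)
      k <- sum(engaged)
      if (k > 0) {
        # per-trial windows differ on test trials; draw one at a time only
        # where the window binds
        draws <- numeric(k)
        wins <- window[engaged]
        for (j in seq_len(k)) {
          draws[j] <- irt_sample(agent$irt[[tt]], 1L, upper = wins[j])
        }
        irt[engaged] <- draws
      }
    }
    out[[match(tt, TRIAL_TYPES)]] <- data.frame(
      triad_index = rows$triad_index, trial_type = tt,
      engaged = engaged, irt_s = irt, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$triad_index, match(res$trial_type, TRIAL_TYPES)), ]
  rownames(res) <- NULL
  res
}

#' Simulate a full trial log (schedule plus behaviour)
#'
#' Convenience wrapper joining \code{\link{simulate_session}} and
#' \code{\link{simulate_responses}}. Two independent RNG streams are derived
#' from \code{seed} so that the same schedule can be reused across agents.
#'
#' @inheritParams simulate_responses
#' @param config a \code{\link{task_config}}.
#' @param n_surveys number of surveys.
#' @param seed integer seed; the schedule uses \code{seed} and the behaviour
#'   \code{seed + 500009}.
#' @return a \code{trial_log} data.frame: the session columns plus
#'   \code{engaged} and \code{irt_s}; configuration attached as attribute.
#' @export
simulate_trial_log <- function(config, agent = agent_params(),
                               n_surveys = 4L, seed = 1L) {
  sess <- simulate_session(config, n_surveys, seed = seed)
  resp <- simulate_responses(sess, agent, seed = seed + 500009L)
  log <- merge(sess, resp, by = c("triad_index", "trial_type"), sort = FALSE)
  log <- log[order(log$triad_index, match(log$trial_type, TRIAL_TYPES)), ]
  log <- log[, c("triad_index", "survey_index", "trial_type", "frequency_hz",
                 "price_s", "duration_s", "engaged", "irt_s")]
  rownames(log) <- NULL
  attr(log, "config") <- config
  class(log) <- c("trial_log", "data.frame")
  log
}

#' Drop the adjustment survey
#'
#' Removes every triad of the first survey (survey_index 0), mirroring the
#' exclusion of the first 126 triads as adjustment from training to the full
#' task.
#'
#' @param trial_log a trial log or session data.frame with a
#'   \code{survey_index} column.
#' @return the input without survey-0 rows (attributes preserved).
#' @export
exclude_first_survey <- function(trial_log) {
  stopifnot("survey_index" %in% names(trial_log))
  keep <- trial_log$survey_index != 0L
  if (!any(keep)) {
    warning("exclude_first_survey: no triads remain after exclusion")
  }
  out <- trial_log[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- attr(trial_log, "config")
  class(out) <- class(trial_log)
  out
}

#' Write / read a trial-log CSV
#'
#' The on-disk dialect has a header and the columns \code{triad_index},
#' \code{survey_index}, \code{trial_type}, \code{frequency_hz},
#' \code{price_s}, \code{duration_s}, \code{engaged} (0/1), \code{irt_s}
#' (empty for unengaged trials).
#'
#' @param trial_log a trial-log data.frame.
#' @param path file path.
#' @export
write_trial_log <- function(trial_log, path) {
  df <- as.data.frame(trial_log)
  df$engaged <- as.integer(df$engaged)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_log
#' @param config a \code{\link{task_config}} to attach to the result.
#' @export
read_trial_log <- function(path, config = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("triad_index", "survey_index", "trial_type", "frequency_hz",
            "price_s", "duration_s", "engaged", "irt_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("read_trial_log: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$engaged <- as.logical(df$engaged)
  df$irt_s <- as.numeric(df$irt_s)
  if (!is.null(config)) attr(df, "config") <- config
  class(df) <- c("trial_log", "data.frame")
  df
}
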