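#' Extract and validate responses from a trial log
#'
#' Engagement is defined as having earned at least one reward; IRTs are kept
#' only on engaged trials. Initial responses after 24 s on lead and trail
#' trials are impossible (no time remains to earn a reward at price 1 s), so
#' such records are rejected as malformed input.
#'
#' @param trial_log a \code{trial_log} data.frame (see
#'   \code{\link{read_trial_log}}).
#' @return data.frame with columns \code{triad_index}, \code{trial_type},
#'   \code{engaged}, \code{irt_s}.
#' @export
extract_responses <- function(trial_log) {
  need <- c("triad_index", "trial_type", "engaged", "irt_s")
  stopifnot(all(need %in% names(trial_log)))
  df <- as.data.frame(trial_log)[, need]
  bad <- function(cond, what) {
    if (any(cond)) {
      stop("extract_responses: ", what, " at row(s) ",
           paste(utils::head(which(cond), 5L), collapse = ", "),
           call. = FALSE)
    }
  }
  bad(df$engaged & !is.finite(df$irt_s), "engaged trial without an IRT")
  bad(!df$engaged & is.finite(df$irt_s), "IRT recorded on unengaged trial")
  bad(df$engaged & is.finite(df$irt_s) & df$irt_s <= 0, "non-positive IRT")
  bad(df$trial_type %in% c("lead", "trail") & df$engaged & df$irt_s > 24,
      "impossible lead/trail IRT above 24 s")
  df
}

#' Kernel density estimate of an IRT distribution
#'
#' Gaussian KDE with Silverman's rule-of-thumb bandwidth, truncated to
#' (0, \code{support_max}] and renormalised.
#'
#' @param irts observed IRTs, s.
#' @param support_max upper support bound, s.
#' @param min_n minimum number of observations (default 10).
#' @return an object of class \code{c("irt_kde", "irt_dist")}.
#' @export
fit_irt_density <- function(irts, support_max = 24, min_n = 10L) {
  irts <- irts[is.finite(irts)]
  if (length(irts) < min_n) {
    stop("fit_irt_density: need at least ", min_n, " IRTs, got ",
         length(irts), call. = FALSE)
  }
  if (any(irts <= 0 | irts > support_max)) {
    stop("fit_irt_density: IRTs outside (0, support_max]", call. = FALSE)
  }
  structure(list(x = as.numeric(irts), bw = stats::bw.nrd0(irts),
                 support_max = support_max),
            class = c("irt_kde", "irt_dist"))
}

#' @export
irt_density.irt_kde <- function(d, x) {
  # truncated-and-renormalised mixture of Gaussian kernels
  z <- sum(stats::pnorm(d$support_max, d$x, d$bw) - stats::pnorm(0, d$x, d$bw))
  num <- vapply(x, function(t) sum(stats::dnorm(t, d$x, d$bw)), numeric(1L))
  out <- num / z
  out[x <= 0 | x > d$support_max] <- 0
  out
}

#' @export
irt_sample.irt_kde <- function(d, n, upper = NULL) {
  ub <- if (is.null(upper)) d$support_max else min(upper, d$support_max)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1L, sample(d$x, 1L), d$bw)
      if (v > 0 && v <= ub) break
    }
    out[i] <- v
  }
  out
}

#' Lambda-filtered trail response model
#'
#' The trail component of the response model must reflect responses of
#' subjects who correctly believe they are on a trail trial. Trail trials
#' following a confusable test trial are contaminated by mistaken inference,
#' so only trail trials whose preceding test trial falls in the unambiguous
#' lambda region are used. Filtering lowers the engagement probability and
#' largely removes short IRTs relative to the unfiltered trail distribution.
#'
#' @param trial_log a trial log.
#' @param config a \code{\link{task_config}}.
#' @param min_n minimum engaged IRT count for the KDE.
#' @return list with \code{ep}, \code{irt} (an \code{irt_kde}), \code{n}
#'   (number of contributing trail trials).
#' @export
lambda_filtered_trail_model <- function(trial_log, config, min_n = 10L) {
  stopifnot(inherits(config, "task_config"))
  tests <- trial_log[trial_log$trial_type == "test", , drop = FALSE]
  lam <- tests$triad_index[classify_region(tests$frequency_hz, tests$price_s,
                                           config) == "lambda"]
  trails <- trial_log[trial_log$trial_type == "trail" &
                        trial_log$triad_index %in% lam, , drop = FALSE]
  if (nrow(trails) == 0L) {
    stop("lambda_filtered_trail_model: no trail trials follow lambda-region ",
         "test trials; widen the survey grid or use more surveys",
         call. = FALSE)
  }
  irts <- trails$irt_s[trails$engaged]
  list(ep = mean(trails$engaged),
       irt = fit_irt_density(irts, support_max = 24, min_n = min_n),
       n = nrow(trails))
}

#' Estimate the per-type response model from a trial log
#'
#' Engagement probabilities are empirical engagement fractions per trial
#' type; IRT densities are truncated Gaussian KDEs. Lead and trail densities
#' use the (0, 24] support; the test density uses (0, max observed]. The
#' trail component is lambda-filtered by default (see
#' \code{\link{lambda_filtered_trail_model}}); the engagement probabilities
#' and densities are plugged into the response mixture and are not free
#' parameters of the likelihood fit.
#'
#' @param trial_log a trial log covering all three trial types.
#' @param config a \code{\link{task_config}}.
#' @param lambda_filter use only lambda-preceded trail trials for the trail
#'   component (default TRUE).
#' @param min_n minimum engaged IRT count per type for the KDE.
#' @return object of class \code{response_model}: per type a list with
#'   \code{ep}, \code{irt}, \code{n}.
#' @export
fit_response_model <- function(trial_log, config, lambda_filter = TRUE,
                               min_n = 10L) {
  resp <- extract_responses(trial_log)
  out <- list()
  for (tt in c("lead", "test")) {
    rows <- resp[resp$trial_type == tt, , drop = FALSE]
    irts <- rows$irt_s[rows$engaged]
    smax <- if (tt == "test") max(irts) else 24
    out[[tt]] <- list(ep = mean(rows$engaged),
                      irt = fit_irt_density(irts, smax, min_n = min_n),
                      n = nrow(rows))
  }
  if (lambda_filter) {
    out$trail <- lambda_filtered_trail_model(trial_log, config, min_n = min_n)
  } else {
    rows <- resp[resp$trial_type == "trail", , drop = FALSE]
    out$trail <- list(ep = mean(rows$engaged),
                      irt = fit_irt_density(rows$irt_s[rows$engaged], 24,
                                            min_n = min_n),
                      n = nrow(rows))
  }
  structure(out[TRIAL_TYPES], class = "response_model")
}

#' Assemble a response model from components
#'
#' Mostly useful for tests and for synthetic ground truths: wraps per-type
#' engagement probabilities and \code{irt_dist} objects in the interface the
#' likelihood machinery expects.
#'
#' @param ep named engagement probabilities (lead, test, trail).
#' @param irt named list of \code{irt_dist} objects.
#' @return object of class \code{response_model}.
#' @export
response_model <- function(ep, irt) {
  stopifnot(all(TRIAL_TYPES %in% names(ep)), all(TRIAL_TYPES %in% names(irt)),
            all(ep >= 0 & ep <= 1))
  out <- lapply(TRIAL_TYPES, function(tt) {
    list(ep = unname(ep[[tt]]), irt = irt[[tt]], n = NA_integer_)
  })
  names(out) <- TRIAL_TYPES
  structure(out, class = "response_model")
}

#' @export
print.response_model <- function(x, ...) {
  cat("Response model\n")
  for (tt in TRIAL_TYPES) {
    cat(sprintf("  %-5s: EP = %.3f (%s)\n", tt, x[[tt]]$ep,
                class(x[[tt]]$irt)[1L]))
  }
  invisible(x)
}

#' Serialise / load a response model (JSON)
#'
#' Stores per-type engagement probabilities and, for KDE components, the
#' sample points and bandwidth, so fitted models are reproducible.
#'
#' @param model a \code{response_model} with \code{irt_kde} or
#'   \code{irt_lnorm} components.
#' @param path file path.
#' @export
write_response_model <- function(model, path) {
  stopifnot(inherits(model, "response_model"))
  ser <- lapply(model, function(cmp) {
    d <- cmp$irt
    irt <- if (inherits(d, "irt_kde")) {
      list(kind = "kde", x = d$x, bw = d$bw, support_max = d$support_max)
    } else {
      list(kind = "lnorm", meanlog = d$meanlog, sdlog = d$sdlog,
           support_max = d$support_max)
    }
    list(ep = cmp$ep, n = cmp$n, irt = irt)
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_response_model
#' @export
read_response_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(ser, function(cmp) {
    irt <- if (identical(cmp$irt$kind, "kde")) {
      structure(list(x = cmp$irt$x, bw = cmp$irt$bw,
                     support_max = cmp$irt$support_max),
                class = c("irt_kde", "irt_dist"))
    } else {
      irt_lnorm(cmp$irt$meanlog, cmp$irt$sdlog, cmp$irt$support_max)
    }
    list(ep = cmp$ep, irt = irt, n = cmp$n)
  })
  structure(out[TRIAL_TYPES], class = "response_model")
}
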