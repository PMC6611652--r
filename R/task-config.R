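# Canonical trial-type order used throughout: belief vectors, transition
# matrices and likelihoods all index types in this order.
TRIAL_TYPES <- c("lead", "test", "trail")

#' Build a per-subject task configuration
#'
#' Returns the task constants for one subject of the cyclic triad experiment:
#' the fixed lead/trail pulse frequencies (Hz) and prices (s), the region
#' boundaries in frequency-price space used to define the lead-like
#' (\eqn{\alpha}), trail-like (\eqn{\beta}) and unambiguous (\eqn{\lambda})
#' rectangles, and the scheduling constants (intertrial interval, black-out
#' delay, duration rule). Packaged defaults cover subjects 1-6; alternatively
#' a JSON config file with the same field names can be supplied.
#'
#' Frequencies are idiosyncratic per subject because rewarding brain
#' stimulation was calibrated per animal; prices are shared.
#'
#' @param subject_id integer in 1..6 (for the packaged configuration).
#' @param file optional path to a JSON configuration file with a
#'   \code{subjects} array; defaults to the packaged file.
#' @return An object of class \code{task_config}: a list with fields
#'   \code{subject_id}, \code{f_lead}, \code{P_lead}, \code{f_trail},
#'   \code{P_trail}, \code{f_u_beta}, \code{f_l_alpha}, \code{P_l_ab},
#'   \code{P_u_ab}, \code{f_l_lambda}, \code{f_u_lambda}, \code{P_l_lambda},
#'   \code{intertrial_interval}, \code{blackout_delay},
#'   \code{duration_multiplier}, \code{min_duration},
#'   \code{survey_frequencies}, \code{survey_prices}.
#' @examples
#' cfg <- task_config(1)
#' cfg$f_lead     # 217.4 Hz
#' cfg$P_l_lambda # 8.1 s
#' @export
task_config <- function(subject_id, file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "task_config.json", package = "triadhmm",
                        mustWork = TRUE)
  }
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  subs <- raw$subjects
  if (!is.data.frame(subs)) subs <- as.data.frame(subs)
  if (length(subject_id) != 1L || !is.numeric(subject_id) ||
      !(subject_id %in% subs$subject_id)) {
    stop("unknown subject_id '", subject_id, "'; available: ",
         paste(subs$subject_id, collapse = ", "), call. = FALSE)
  }
  cfg <- as.list(subs[subs$subject_id == subject_id, , drop = FALSE])
  cfg <- lapply(cfg, function(x) if (is.list(x)) x[[1]] else unname(x))
  for (nm in names(raw$defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- raw$defaults[[nm]]
  }
  if (is.null(cfg$survey_frequencies)) {
    cfg$survey_frequencies <-
      10^seq(log10(cfg$f_trail), log10(cfg$f_lead), length.out = 14L)
  }
  if (is.null(cfg$survey_prices)) {
    cfg$survey_prices <- 10^seq(log10(0.25), log10(25), length.out = 9L)
  }
  cfg <- cfg[c("subject_id", "f_lead", "P_lead", "f_trail", "P_trail",
               "f_u_beta", "f_l_alpha", "P_l_ab", "P_u_ab",
               "f_l_lambda", "f_u_lambda", "P_l_lambda",
               "intertrial_interval", "blackout_delay",
               "duration_multiplier", "min_duration",
               "survey_frequencies", "survey_prices")]
  class(cfg) <- "task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  num <- unlist(cfg[c("f_lead", "P_lead", "f_trail", "P_trail", "f_u_beta",
                      "f_l_alpha", "P_l_ab", "P_u_ab", "f_l_lambda",
                      "f_u_lambda", "P_l_lambda", "intertrial_interval",
                      "blackout_delay", "duration_multiplier",
                      "min_duration")])
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("task_config: all constants must be finite and positive",
         call. = FALSE)
  }
  # the lambda frequency band may overlap the alpha band (it does for some
  # subjects); the regions stay disjoint because the price bands are disjoint
  ok_f <- cfg$f_trail < cfg$f_u_beta && cfg$f_u_beta < cfg$f_l_lambda &&
    cfg$f_l_lambda <= cfg$f_u_lambda && cfg$f_u_lambda < cfg$f_lead &&
    cfg$f_u_beta < cfg$f_l_alpha && cfg$f_l_alpha < cfg$f_lead
  ok_P <- cfg$P_l_ab < cfg$P_u_ab && cfg$P_u_ab < cfg$P_l_lambda
  if (!ok_f || !ok_P) {
    stop("task_config: region boundaries violate the required ordering",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.task_config <- function(x, ...) {
  cat("Task configuration (subject ", x$subject_id, ")\n", sep = "")
  cat(sprintf("  lead : f = %.1f Hz, P = %.1f s\n", x$f_lead, x$P_lead))
  cat(sprintf("  trail: f = %.1f Hz, P = %.1f s\n", x$f_trail, x$P_trail))
  cat(sprintf("  alpha : f >= %.1f Hz, P in [%.1f, %.1f] s\n",
              x$f_l_alpha, x$P_l_ab, x$P_u_ab))
  cat(sprintf("  beta  : f <= %.1f Hz, P in [%.1f, %.1f] s\n",
              x$f_u_beta, x$P_l_ab, x$P_u_ab))
  cat(sprintf("  lambda: f in [%.1f, %.1f] Hz, P >= %.1f s\n",
              x$f_l_lambda, x$f_u_lambda, x$P_l_lambda))
  cat(sprintf("  survey grid: %d frequencies x %d prices\n",
              length(x$survey_frequencies), length(x$survey_prices)))
  invisible(x)
}

#' Trial duration from price
#'
#' The duration of a trial is 25 times its price, except that trials with a
#' price below 1 s last the minimum duration of 25 s.
#'
#' @param P price(s) in seconds; positive.
#' @param config a \code{\link{task_config}} (supplies the multiplier and
#'   minimum duration).
#' @return duration(s) in seconds.
#' @examples
#' cfg <- task_config(1)
#' trial_duration(1.0, cfg) # 25
#' trial_duration(0.5, cfg) # 25
#' trial_duration(3.9, cfg) # 97.5
#' @export
trial_duration <- function(P, config) {
  stopifnot(inherits(config, "task_config"))
  if (any(!is.finite(P)) || any(P <= 0)) {
    stop("trial_duration: price must be positive", call. = FALSE)
  }
  ifelse(P >= 1, config$duration_multiplier * P, config$min_duration)
}

#' Classify a frequency-price point into a task region
#'
#' Partitions frequency-price space into the rectangles \code{alpha}
#' (lead-like: high frequency, short price), \code{beta} (trail-like: low
#' frequency, short price), \code{lambda} (unambiguous: intermediate
#' frequency and long price) and \code{other}. Boundaries are closed
#' (a point exactly on a boundary belongs to the named region).
#'
#' @param f frequency(ies), Hz.
#' @param P price(s), s; recycled against \code{f}.
#' @param config a \code{\link{task_config}}.
#' @return character vector over \code{c("alpha","beta","lambda","other")}.
#' @examples
#' cfg <- task_config(1)
#' classify_region(158.5, 1.0, cfg) # "alpha"
#' classify_region(15, 2, cfg)      # "beta"
#' classify_region(50, 10, cfg)     # "lambda"
#' @export
classify_region <- function(f, P, config) {
  stopifnot(inherits(config, "task_config"))
  n <- max(length(f), length(P))
  f <- rep_len(f, n); P <- rep_len(P, n)
  if (any(!is.finite(f)) || any(!is.finite(P)) || any(f <= 0) || any(P <= 0)) {
    stop("classify_region: f and P must be positive", call. = FALSE)
  }
  out <- rep("other", n)
  in_ab_price <- P >= config$P_l_ab & P <= config$P_u_ab
  out[f >= config$f_l_alpha & in_ab_price] <- "alpha"
  out[f <= config$f_u_beta & in_ab_price] <- "beta"
  out[f >= config$f_l_lambda & f <= config$f_u_lambda &
        P >= config$P_l_lambda] <- "lambda"
  out
}

#' Categorise a test frequency as low, intermediate or high
#'
#' Reuses the region frequency boundaries: low means at or below the upper
#' beta boundary (trail-like), high means at or above the lower alpha
#' boundary (lead-like).
#'
#' @inheritParams classify_region
#' @return character vector over \code{c("low","intermediate","high")}.
#' @export
frequency_category <- function(f, config) {
  stopifnot(inherits(config, "task_config"))
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("frequency_category: f must be positive", call. = FALSE)
  }
  out <- rep("intermediate", length(f))
  out[f <= config$f_u_beta] <- "low"
  out[f >= config$f_l_alpha] <- "high"
  out
}
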