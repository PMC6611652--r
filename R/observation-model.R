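#' Gaussian kernel mixture likelihood of observations given trial type
#'
#' The perceptual likelihood P(o | s) is a mixture of isotropic 2-D
#' Gaussians in log10 frequency-price space, one kernel per distinct
#' experienced (f, P) point of each trial type, with mixture weights
#' proportional to how often each point was experienced and a single width
#' sigma shared across all kernels and both axes. Lead and trail trials use
#' fixed constants, so their mixtures each collapse to one kernel; the test
#' mixture spans the survey grid.
#'
#' @param trials a \code{triad_session} or \code{trial_log} data.frame with
#'   columns \code{trial_type}, \code{frequency_hz}, \code{price_s}.
#' @param sigma kernel standard deviation, log10 units; > 0.
#' @return object of class \code{kernel_mixture}: per type a list with
#'   \code{centers} (K x 2 matrix of log10 f, log10 P) and \code{weights}
#'   (summing to 1), plus the shared \code{sigma}.
#' @export
kernel_mixture <- function(trials, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("kernel_mixture: sigma must be a positive scalar", call. = FALSE)
  }
  stopifnot(all(c("trial_type", "frequency_hz", "price_s") %in% names(trials)))
  comp <- list()
  for (tt in TRIAL_TYPES) {
    rows <- trials[trials$trial_type == tt, , drop = FALSE]
    if (nrow(rows) == 0L) {
      stop("kernel_mixture: no trials of type '", tt, "'", call. = FALSE)
    }
    key <- paste(rows$frequency_hz, rows$price_s)
    tab <- table(key)
    first <- rows[!duplicated(key), , drop = FALSE]
    first_key <- paste(first$frequency_hz, first$price_s)
    counts <- as.numeric(tab[first_key])
    comp[[tt]] <- list(
      centers = cbind(log_f = log10(first$frequency_hz),
                      log_P = log10(first$price_s)),
      weights = counts / sum(counts)
    )
  }
  structure(list(components = comp, sigma = sigma), class = "kernel_mixture")
}

#' @export
print.kernel_mixture <- function(x, ...) {
  cat("Kernel mixture (sigma =", x$sigma, "log10 units)\n")
  for (tt in TRIAL_TYPES) {
    cat(sprintf("  %-5s: %d kernel(s)\n", tt, nrow(x$components[[tt]]$centers)))
  }
  invisible(x)
}

# n x 3 matrix of per-type 2-D likelihoods at (log_f, log_P)
observation_type_likelihoods <- function(mix, log_f, log_P) {
  out <- sapply(TRIAL_TYPES, function(tt) {
    observation_likelihood(mix, cbind(log_f, log_P), tt)
  })
  matrix(out, ncol = 3L, dimnames = list(NULL, TRIAL_TYPES))
}

#' Observation likelihood density
#'
#' Evaluates the 2-D mixture density (per unit log10-area) of an observation
#' under the kernels of one trial type.
#'
#' @param mix a \code{\link{kernel_mixture}}.
#' @param obs numeric length-2 vector \code{c(log_f, log_P)} or an n x 2
#'   matrix of observations (log10 units).
#' @param type one of \code{"lead"}, \code{"test"}, \code{"trail"}.
#' @return density value(s); strictly positive.
#' @export
observation_likelihood <- function(mix, obs, type) {
  stopifnot(inherits(mix, "kernel_mixture"), type %in% TRIAL_TYPES)
  if (is.null(dim(obs))) obs <- matrix(obs, ncol = 2L)
  cmp <- mix$components[[type]]
  s2 <- mix$sigma^2
  d2 <- outer(obs[, 1L], cmp$centers[, "log_f"], "-")^2 +
        outer(obs[, 2L], cmp$centers[, "log_P"], "-")^2
  as.vector(exp(-d2 / (2 * s2)) %*% cmp$weights) / (2 * pi * s2)
}

#' One-dimensional (marginal) observation likelihood
#'
#' Used by the reduced model variants that ignore one observation axis: the
#' other coordinate is marginalised out of every kernel, leaving a 1-D
#' Gaussian mixture on the retained axis.
#'
#' @inheritParams observation_likelihood
#' @param axis \code{"frequency"} or \code{"price"}: the retained axis.
#' @return density value(s) per unit log10 length.
#' @export
observation_likelihood_1d <- function(mix, obs, type,
                                      axis = c("frequency", "price")) {
  stopifnot(inherits(mix, "kernel_mixture"), type %in% TRIAL_TYPES)
  axis <- match.arg(axis)
  col <- if (axis == "frequency") 1L else 2L
  if (!is.null(dim(obs))) obs <- obs[, col]
  cmp <- mix$components[[type]]
  ctr <- cmp$centers[, col]
  s2 <- mix$sigma^2
  d2 <- outer(obs, ctr, "-")^2
  as.vector(exp(-d2 / (2 * s2)) %*% cmp$weights) / sqrt(2 * pi * s2)
}
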