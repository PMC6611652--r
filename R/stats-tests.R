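#' Two-tailed permutation test
#'
#' Tests whether the observed value of a two-sample statistic could arise
#' for randomly permuted class labels. The two-tailed Monte-Carlo p-value
#' uses the add-one convention, \code{(1 + #{|T_perm| >= |T_obs|}) /
#' (1 + n_perm)}, which never returns 0.
#'
#' @param x,y numeric samples.
#' @param statistic function of two samples; default difference of medians.
#' @param n_perm number of label permutations (default 1000).
#' @param seed optional integer seed for reproducibility.
#' @return list of class \code{triad_test} with \code{statistic},
#'   \code{p_value}, \code{n_perm}, \code{null} (the permuted statistics).
#' @export
permutation_test <- function(x, y,
                             statistic = function(a, b) {
                               stats::median(a) - stats::median(b)
                             },
                             n_perm = 1000L, seed = NULL) {
  if (length(x) < 1L || length(y) < 1L) {
    stop("permutation_test: both samples must be non-empty", call. = FALSE)
  }
  if (n_perm < 1L) stop("permutation_test: n_perm must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t_obs <- statistic(x, y)
  pool <- c(x, y)
  nx <- length(x); n <- length(pool)
  null <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n, nx)
    null[i] <- statistic(pool[idx], pool[-idx])
  }
  p <- (1 + sum(abs(null) >= abs(t_obs))) / (1 + n_perm)
  structure(list(method = "two-tailed permutation test",
                 statistic = t_obs, p_value = p, n_perm = n_perm,
                 null = null),
            class = "triad_test")
}

#' @export
print.triad_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4g, p = %.4g", x$statistic, x$p_value))
  if (!is.null(x$n_perm)) cat(sprintf(" (%d permutations)", x$n_perm))
  cat("\n")
  invisible(x)
}

#' Two-sample binomial proportion test
#'
#' Z statistic for the equality of two binomial proportions using the
#' pooled estimate \code{p = (n1 p1 + n2 p2) / (n1 + n2)},
#' \code{Z = (p1 - p2) / sqrt(p (1 - p) (1/n1 + 1/n2))}, with a two-tailed
#' p-value from the normal approximation.
#'
#' @param k1,n1 successes and size of the first sample.
#' @param k2,n2 successes and size of the second sample.
#' @return list of class \code{triad_test} with \code{statistic} (Z),
#'   \code{p_value}, and the component proportions.
#' @export
binomial_proportion_test <- function(k1, n1, k2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  p1 <- k1 / n1; p2 <- k2 / n2
  p <- (n1 * p1 + n2 * p2) / (n1 + n2)
  denom <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  z <- if (denom == 0) 0 else (p1 - p2) / denom
  structure(list(method = "binomial proportion test (normal approximation)",
                 statistic = z, p_value = 2 * stats::pnorm(-abs(z)),
                 p_hat = p, p1 = p1, p2 = p2, n1 = n1, n2 = n2,
                 n_perm = NULL),
            class = "triad_test")
}

# first Wasserstein distance between two empirical distributions
w1_empirical <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  if (length(grid) < 2L) return(0)
  Fx <- stats::ecdf(x)(grid)
  Fy <- stats::ecdf(y)(grid)
  k <- length(grid)
  sum(abs(Fx[-k] - Fy[-k]) * diff(grid))
}

#' Earth mover's similarity between two IRT samples
#'
#' One minus the first Wasserstein distance between the empirical
#' distributions after rescaling the support to [0, 1] (division by
#' \code{support_max}), so the similarity lies in [0, 1]: identical samples
#' score 1 and maximally separated ones score 0.
#'
#' @param x,y numeric samples within [0, support_max].
#' @param support_max the censoring bound of the support, s (24 for
#'   lead/trail IRTs).
#' @return similarity in [0, 1].
#' @export
emd_similarity <- function(x, y, support_max = 24) {
  if (length(x) < 1L || length(y) < 1L) {
    stop("emd_similarity: both samples must be non-empty", call. = FALSE)
  }
  if (any(x < 0 | x > support_max) || any(y < 0 | y > support_max)) {
    stop("emd_similarity: values outside [0, support_max]", call. = FALSE)
  }
  1 - w1_empirical(x / support_max, y / support_max)
}

#' Short-IRT threshold and fraction
#'
#' The short-IRT threshold is the 95th percentile of the test-trial IRT
#' distribution (linear-interpolation quantile); a trail trial counts as a
#' short-IRT trial when it was engaged with an IRT at or below the
#' threshold. The fraction's denominator is all trail trials, engaged or
#' not, so it tracks confusion per trail-trial opportunity.
#'
#' @param test_irts IRTs observed on test trials, s.
#' @param prob quantile level (default 0.95).
#' @return threshold in s.
#' @export
short_irt_threshold <- function(test_irts, prob = 0.95) {
  test_irts <- test_irts[is.finite(test_irts)]
  if (length(test_irts) < 1L) {
    stop("short_irt_threshold: empty test IRT sample", call. = FALSE)
  }
  unname(stats::quantile(test_irts, prob, type = 7))
}

#' @rdname short_irt_threshold
#' @param trail_responses data.frame of trail responses with columns
#'   \code{engaged} and \code{irt_s}.
#' @param threshold short-IRT threshold, s.
#' @export
short_irt_fraction <- function(trail_responses, threshold) {
  if (nrow(trail_responses) == 0L) {
    stop("short_irt_fraction: no trail trials", call. = FALSE)
  }
  short <- trail_responses$engaged &
    is.finite(trail_responses$irt_s) & trail_responses$irt_s <= threshold
  sum(short) / nrow(trail_responses)
}

#' Permutation test for a contrast of earth mover's similarities
#'
#' Tests whether a sample \code{x} (e.g. short trail IRTs following
#' alpha-region test trials) is more similar to one reference IRT
#' distribution than to another. The statistic is
#' \code{emd_similarity(x, ref1) - emd_similarity(x, ref2)}; the null
#' distribution shuffles the labels between the two reference samples.
#'
#' @param x sample under test.
#' @param ref1,ref2 reference samples (e.g. test and lead IRTs).
#' @param support_max support bound for the similarity.
#' @inheritParams permutation_test
#' @return \code{triad_test} object.
#' @export
emd_contrast_test <- function(x, ref1, ref2, support_max = 24,
                              n_perm = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stat <- function(a, b) {
    emd_similarity(x, a, support_max) - emd_similarity(x, b, support_max)
  }
  t_obs <- stat(ref1, ref2)
  pool <- c(ref1, ref2)
  n1 <- length(ref1); n <- length(pool)
  null <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n, n1)
    null[i] <- stat(pool[idx], pool[-idx])
  }
  p <- (1 + sum(abs(null) >= abs(t_obs))) / (1 + n_perm)
  structure(list(method = "earth mover's similarity contrast (permutation)",
                 statistic = t_obs, p_value = p, n_perm = n_perm,
                 null = null),
            class = "triad_test")
}

#' Permutation test for a change in MLE parameters across tertiles
#'
#' Refits the model to the first and last tertile after randomly permuting
#' the triads' time labels, building a null distribution of absolute
#' parameter differences; the observed absolute difference (unpermuted
#' order) is significant when it exceeds the null's 95th percentile. The
#' reported p-value is the exceedance fraction of the null.
#'
#' @param trial_log a trial log or prebuilt \code{\link{fit_context}}.
#' @param variant model variant to fit.
#' @param n_perm number of permutations (default 1000; each permutation
#'   refits the model twice).
#' @param seed integer seed.
#' @param config,resp passed to \code{\link{fit_context}} when needed.
#' @return data.frame with one row per free parameter: \code{parameter},
#'   \code{observed} (|last - first|), \code{null_q95}, \code{p_value},
#'   \code{significant}, plus attributes \code{fit_first}, \code{fit_last}.
#' @export
mle_change_permutation_test <- function(trial_log, variant = "full",
                                        n_perm = 1000L, seed = 1L,
                                        config = attr(trial_log, "config"),
                                        resp = NULL) {
  ctx <- if (inherits(trial_log, "fit_context")) trial_log
         else fit_context(trial_log, config, resp)
  set.seed(seed)
  blocks <- split_tertiles(seq_len(ctx$n))
  pair_diff <- function(order_idx) {
    first <- order_idx[blocks[[1L]]]
    last <- order_idx[blocks[[3L]]]
    f1 <- fit_mle(ctx, variant, rows = first, se = FALSE)
    f3 <- fit_mle(ctx, variant, rows = last, se = FALSE)
    list(d = abs(f3$theta[f3$free] - f1$theta[f1$free]), f1 = f1, f3 = f3)
  }
  obs <- pair_diff(seq_len(ctx$n))
  free <- names(obs$d)
  null <- matrix(NA_real_, n_perm, length(free),
                 dimnames = list(NULL, free))
  fails <- 0L
  for (i in seq_len(n_perm)) {
    res <- tryCatch(pair_diff(sample.int(ctx$n)), error = function(e) NULL)
    if (is.null(res)) { fails <- fails + 1L; next }
    null[i, ] <- res$d
  }
  if (fails > 0.05 * n_perm) {
    stop("mle_change_permutation_test: fit failures in more than 5% of ",
         "permutations", call. = FALSE)
  }
  out <- data.frame(
    parameter = free,
    observed = unname(obs$d),
    null_q95 = apply(null, 2L, stats::quantile, probs = 0.95,
                     na.rm = TRUE, type = 7),
    p_value = vapply(free, function(nm) {
      mean(null[, nm] >= obs$d[[nm]], na.rm = TRUE)
    }, numeric(1L)),
    row.names = NULL
  )
  out$significant <- out$observed > out$null_q95
  attr(out, "fit_first") <- obs$f1
  attr(out, "fit_last") <- obs$f3
  attr(out, "n_perm") <- n_perm
  out
}
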