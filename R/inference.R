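#' Task transition matrix A
#'
#' The deterministic cyclic structure lead -> test -> trail -> lead as a
#' row-stochastic permutation matrix in the canonical type order. Beliefs
#' are row vectors, so the belief at the next trial is \code{belief \%*\% A}.
#'
#' @return 3 x 3 0/1 matrix with dimnames over the trial types.
#' @export
transition_matrix_A <- function() {
  A <- matrix(0, 3, 3, dimnames = list(TRIAL_TYPES, TRIAL_TYPES))
  A["lead", "test"] <- 1
  A["test", "trail"] <- 1
  A["trail", "lead"] <- 1
  A
}

# shared internal form; gamma may lie slightly outside [0,1] so that
# finite-difference Hessians at a boundary MLE remain computable
matrix_B_unchecked <- function(gamma) {
  B <- (1 - gamma) * diag(3) + (gamma / 3) * matrix(1, 3, 3)
  dimnames(B) <- list(TRIAL_TYPES, TRIAL_TYPES)
  B
}

#' Belief-transition matrix B
#'
#' Encodes uncertainty in past evidence during a test trial. At gamma = 0
#' past evidence fully determines the state (B is the identity); at
#' gamma = 1 past evidence is ignored and all types are a priori equally
#' likely (every entry 1/3). Intermediate gamma interpolates linearly:
#' \code{B = (1 - gamma) I + (gamma/3) J}.
#'
#' @param gamma scalar in [0, 1].
#' @return 3 x 3 row-stochastic matrix.
#' @export
matrix_B <- function(gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma > 1) {
    stop("matrix_B: gamma must be a scalar in [0, 1]", call. = FALSE)
  }
  matrix_B_unchecked(gamma)
}

matrix_B_asym_unchecked <- function(gamma_f, gamma_b) {
  B <- diag(3) * (1 - gamma_f / 3 - gamma_b / 3)
  dimnames(B) <- list(TRIAL_TYPES, TRIAL_TYPES)
  fwd <- c(lead = "test", test = "trail", trail = "lead")
  bwd <- c(lead = "trail", test = "lead", trail = "test")
  for (tt in TRIAL_TYPES) {
    B[tt, fwd[[tt]]] <- gamma_f / 3
    B[tt, bwd[[tt]]] <- gamma_b / 3
  }
  B
}

#' Asymmetric belief-transition matrix
#'
#' Variant of \code{\link{matrix_B}} in which premature 'forward' belief
#' transitions (with the task cycle) and 'backward' transitions (against it)
#' have separate uncertainties. Each row puts gamma_f/3 on the cyclic
#' successor, gamma_b/3 on the cyclic predecessor, and the remainder on
#' staying. \code{matrix_B_asym(g, g)} equals \code{matrix_B(g)}, so the
#' symmetric model is nested.
#'
#' @param gamma_f,gamma_b scalars in [0, 1].
#' @return 3 x 3 row-stochastic matrix.
#' @export
matrix_B_asym <- function(gamma_f, gamma_b) {
  ok <- function(g) is.numeric(g) && length(g) == 1L && g >= 0 && g <= 1
  if (!ok(gamma_f) || !ok(gamma_b)) {
    stop("matrix_B_asym: gamma_f and gamma_b must be scalars in [0, 1]",
         call. = FALSE)
  }
  matrix_B_asym_unchecked(gamma_f, gamma_b)
}

#' Posterior belief at the end of a test trial
#'
#' Bayesian integration of past evidence with the within-trial observation:
#' posterior_i is proportional to P(o | s = i) times the prior propagated
#' through B, \code{(prior \%*\% B)_i}. With the model's assumption that the
#' subject is certain it is on a test trial at the start (prior a delta at
#' test), the propagated prior is B's test row.
#'
#' @param obs length-2 \code{c(log_f, log_P)} observation (log10 units).
#' @param B belief-transition matrix from \code{\link{matrix_B}} or
#'   \code{\link{matrix_B_asym}}.
#' @param mix a \code{\link{kernel_mixture}}.
#' @param prior belief row vector at the start of the test trial; default
#'   certainty on test.
#' @return normalised belief 3-vector (named, canonical order).
#' @export
posterior_end_of_test <- function(obs, B, mix,
                                  prior = c(lead = 0, test = 1, trail = 0)) {
  stopifnot(length(prior) == 3L, all(prior >= 0))
  prior <- prior / sum(prior)
  lik <- vapply(TRIAL_TYPES, function(tt) {
    observation_likelihood(mix, obs, tt)
  }, numeric(1L))
  unnorm <- lik * as.vector(prior %*% B)
  tot <- sum(unnorm)
  if (!is.finite(tot) || tot <= 0) {
    stop("posterior_end_of_test: unnormalisable posterior", call. = FALSE)
  }
  stats::setNames(unnorm / tot, TRIAL_TYPES)
}

#' Propagate a belief to the next trial
#'
#' Applies the task transition matrix, marginalising out the current state:
#' a subject certain it is on a lead trial becomes certain the next trial is
#' a test trial.
#'
#' @param belief normalised belief 3-vector.
#' @param A transition matrix, by default \code{\link{transition_matrix_A}}.
#' @return normalised belief 3-vector.
#' @export
belief_next_trial <- function(belief, A = transition_matrix_A()) {
  stopifnot(length(belief) == 3L, all(belief >= -1e-12))
  out <- as.vector(belief %*% A)
  stats::setNames(out / sum(out), TRIAL_TYPES)
}

#' Predictive response distribution at the start of a trail trial
#'
#' The model's distribution over responses (no engagement, or engagement
#' with an IRT) given the belief s4: a mixture over the three per-type
#' response models weighted by the belief. The no-engagement mass is
#' \code{sum_i s4_i (1 - EP_i)} and the engaged-IRT density is
#' \code{sum_i s4_i EP_i f_i(irt)}.
#'
#' @param s4 normalised belief 3-vector at the start of the trail trial.
#' @param resp a \code{\link{response_model}}.
#' @return list with \code{p_no_engagement}, \code{p_engagement}, and
#'   \code{density(x)}, the engaged-IRT (sub-)density function; the
#'   no-engagement mass plus the integral of \code{density} is 1.
#' @export
response_distribution <- function(s4, resp) {
  stopifnot(inherits(resp, "response_model"), length(s4) == 3L)
  s4 <- stats::setNames(as.vector(s4), TRIAL_TYPES)
  eps <- vapply(TRIAL_TYPES, function(tt) resp[[tt]]$ep, numeric(1L))
  p_no <- sum(s4 * (1 - eps))
  dens <- function(x) {
    out <- numeric(length(x))
    for (tt in TRIAL_TYPES) {
      out <- out + s4[[tt]] * eps[[tt]] * irt_density(resp[[tt]]$irt, x)
    }
    out
  }
  list(p_no_engagement = p_no, p_engagement = 1 - p_no, density = dens)
}
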