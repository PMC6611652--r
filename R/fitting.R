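#' Split ordered triads into three sequential tertiles
#'
#' Blocks are contiguous and ordered; when the count is not divisible by 3
#' the earliest blocks take the remainder (10 -> 4,3,3; 11 -> 4,4,3).
#'
#' @param x an ordered vector of triad identifiers (or any ordered items).
#' @return list of three vectors partitioning \code{x} in order.
#' @export
split_tertiles <- function(x) {
  n <- length(x)
  if (n < 3L) stop("split_tertiles: need at least 3 triads", call. = FALSE)
  sizes <- rep(n %/% 3L, 3L)
  r <- n %% 3L
  if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-3L] + 1L)
  lapply(1:3, function(i) x[starts[i]:ends[i]])
}

# ---- model variants ---------------------------------------------------------

variant_info <- function(variant) {
  switch(variant,
    full   = list(free = c("gamma", "sigma"), fixed = NULL, lik = "2d"),
    gamma0 = list(free = "sigma", fixed = c(gamma = 0), lik = "2d"),
    gamma1 = list(free = "sigma", fixed = c(gamma = 1), lik = "2d"),
    no_f   = list(free = c("gamma", "sigma"), fixed = NULL, lik = "P"),
    no_P   = list(free = c("gamma", "sigma"), fixed = NULL, lik = "f"),
    asym   = list(free = c("gamma_f", "gamma_b", "sigma"), fixed = NULL,
                  lik = "2d"),
    stop("unknown model variant '", variant, "'", call. = FALSE)
  )
}

MODEL_VARIANTS <- c("full", "gamma0", "gamma1", "no_f", "no_P", "asym")

# ---- fit context ------------------------------------------------------------

#' Precompute the per-triad quantities the likelihood needs
#'
#' For each analysable triad (one with a test observation and a trail
#' response) the context stores squared distances from the test observation
#' to every mixture kernel of every trial type (full 2-D and per-axis, so
#' all model variants reuse them) and the three per-type response components
#' of the trail response under the plugged-in response model. Likelihood
#' evaluations then reduce to cheap array algebra, and tertile or
#' permutation refits subset rows for free.
#'
#' @param trial_log a trial log.
#' @param config a \code{\link{task_config}}.
#' @param resp a \code{\link{response_model}} (defaults to one fitted from
#'   the trial log with lambda filtering).
#' @return an environment of class \code{fit_context} with fields
#'   \code{n}, \code{triad_index}, \code{d2}, \code{d2f}, \code{d2P},
#'   \code{weights}, \code{C}, \code{resp}, \code{config}.
#' @export
fit_context <- function(trial_log, config = attr(trial_log, "config"),
                        resp = NULL) {
  stopifnot(inherits(config, "task_config"))
  if (is.null(resp)) resp <- fit_response_model(trial_log, config)
  responses <- extract_responses(trial_log)

  tests <- trial_log[trial_log$trial_type == "test", , drop = FALSE]
  trails <- responses[responses$trial_type == "trail", , drop = FALSE]
  common <- intersect(tests$triad_index, trails$triad_index)
  if (length(common) < 1L) {
    stop("fit_context: no triads with both a test trial and a trail response",
         call. = FALSE)
  }
  tests <- tests[match(sort(common), tests$triad_index), , drop = FALSE]
  trails <- trails[match(sort(common), trails$triad_index), , drop = FALSE]
  n <- length(common)

  km <- kernel_mixture(trial_log, 1)  # sigma irrelevant: centers/weights only
  log_f <- log10(tests$frequency_hz)
  log_P <- log10(tests$price_s)
  d2 <- d2f <- d2P <- weights <- list()
  for (tt in TRIAL_TYPES) {
    cmp <- km$components[[tt]]
    df2 <- outer(log_f, cmp$centers[, "log_f"], "-")^2
    dP2 <- outer(log_P, cmp$centers[, "log_P"], "-")^2
    d2f[[tt]] <- df2
    d2P[[tt]] <- dP2
    d2[[tt]] <- df2 + dP2
    weights[[tt]] <- cmp$weights
  }

  eps <- vapply(TRIAL_TYPES, function(tt) resp[[tt]]$ep, numeric(1L))
  C <- matrix(0, n, 3L, dimnames = list(NULL, TRIAL_TYPES))
  eng <- trails$engaged
  C[!eng, ] <- matrix(1 - eps, sum(!eng), 3L, byrow = TRUE)
  if (any(eng)) {
    irts <- trails$irt_s[eng]
    for (i in seq_along(TRIAL_TYPES)) {
      tt <- TRIAL_TYPES[i]
      C[eng, i] <- eps[[tt]] * irt_density(resp[[tt]]$irt, irts)
    }
  }

  ctx <- new.env(parent = emptyenv())
  ctx$n <- n
  ctx$triad_index <- sort(common)
  ctx$d2 <- d2; ctx$d2f <- d2f; ctx$d2P <- d2P
  ctx$weights <- weights
  ctx$C <- C
  ctx$resp <- resp
  ctx$config <- config
  ctx$cache <- new.env(parent = emptyenv())
  class(ctx) <- "fit_context"
  ctx
}

# n x 3 likelihood matrix at width sigma for one likelihood mode
ctx_lik <- function(ctx, sigma, likmode, rows = NULL, cache = FALSE) {
  key <- paste0(likmode, "|", format(sigma, digits = 17))
  if (cache && !is.null(ctx$cache[[key]])) {
    L <- ctx$cache[[key]]
  } else {
    s2 <- sigma^2
    src <- switch(likmode, "2d" = ctx$d2, "f" = ctx$d2f, "P" = ctx$d2P)
    norm <- if (likmode == "2d") 2 * pi * s2 else sqrt(2 * pi * s2)
    L <- matrix(0, ctx$n, 3L, dimnames = list(NULL, TRIAL_TYPES))
    for (i in seq_along(TRIAL_TYPES)) {
      tt <- TRIAL_TYPES[i]
      L[, i] <- (exp(-src[[tt]] / (2 * s2)) %*% ctx$weights[[tt]]) / norm
    }
    if (cache) ctx$cache[[key]] <- L
  }
  if (is.null(rows)) L else L[rows, , drop = FALSE]
}

# B's test row: prior over s3 given certainty of test at the trial's start
test_row <- function(params) {
  if ("gamma_f" %in% names(params)) {
    gf <- params[["gamma_f"]]; gb <- params[["gamma_b"]]
    c(gb / 3, 1 - gf / 3 - gb / 3, gf / 3)
  } else {
    g <- params[["gamma"]]
    c(g / 3, 1 - 2 * g / 3, g / 3)
  }
}

# core negative log likelihood on a fit context (params: named vector)
nll_ctx <- function(ctx, params, likmode = "2d", rows = NULL,
                    L = NULL) {
  if (is.null(L)) L <- ctx_lik(ctx, params[["sigma"]], likmode, rows = rows)
  b <- test_row(params)
  if (any(b < -1e-9)) return(Inf)
  U <- sweep(L, 2L, b, "*")
  denom <- rowSums(U)
  Crows <- if (is.null(rows)) ctx$C else ctx$C[rows, , drop = FALSE]
  # s4 = posterior %*% A: permutation lead->test->trail->lead
  num <- U[, 3L] * Crows[, 1L] + U[, 1L] * Crows[, 2L] + U[, 2L] * Crows[, 3L]
  p <- num / denom
  if (any(!is.finite(p)) || any(p <= 0)) return(Inf)
  -sum(log(p))
}

#' Negative log likelihood of trail responses under the belief model
#'
#' Minus the summed log probability, over triads, of the observed trail
#' response (no engagement, or engagement with its IRT) given the preceding
#' test observation, under the recognition model with the given parameters.
#'
#' @param trial_log a trial log, or a prebuilt \code{\link{fit_context}}.
#' @param params named parameter vector: \code{gamma} and \code{sigma} (or
#'   \code{gamma_f}, \code{gamma_b}, \code{sigma} for the asymmetric
#'   variant).
#' @param variant model variant (see \code{\link{fit_mle}}).
#' @param config,resp passed to \code{\link{fit_context}} when
#'   \code{trial_log} is a trial log.
#' @return negative log likelihood in nats (\code{Inf} if any response has
#'   zero probability, which signals a support misconfiguration).
#' @export
negative_log_likelihood <- function(trial_log, params, variant = "full",
                                    config = attr(trial_log, "config"),
                                    resp = NULL) {
  ctx <- if (inherits(trial_log, "fit_context")) trial_log
         else fit_context(trial_log, config, resp)
  info <- variant_info(variant)
  params <- c(params, info$fixed)
  miss <- setdiff(c(info$free, names(info$fixed)), names(params))
  if (length(miss)) {
    stop("negative_log_likelihood: missing parameter(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (params[["sigma"]] <= 0) {
    stop("negative_log_likelihood: sigma must be positive", call. = FALSE)
  }
  nll_ctx(ctx, params, likmode = info$lik)
}

#' Bayesian information criterion
#'
#' \code{-2 logL + N_M log N_D} with natural logarithms; N_D is the number
#' of triads (one trail response per triad). Per-subject totals are sums of
#' per-tertile BICs.
#'
#' @param log_likelihood maximised log likelihood, nats.
#' @param n_params number of free parameters N_M.
#' @param n_data number of data points N_D.
#' @return BIC in nats.
#' @export
bic <- function(log_likelihood, n_params, n_data) {
  stopifnot(n_data >= 1)
  -2 * log_likelihood + n_params * log(n_data)
}

#' Standard errors and parameter correlation from the Hessian
#'
#' Computes the Hessian of the log likelihood at the MLE by central finite
#' differences (step \code{1e-4 * max(|theta|, 0.1)} per coordinate), the
#' asymptotic covariance estimate T = -H^{-1}, per-parameter standard
#' errors sqrt(T_ii) and the Pearson correlation matrix
#' T_ij / sqrt(T_ii T_jj).
#'
#' @param loglik function of the free parameter vector returning the log
#'   likelihood.
#' @param theta named MLE parameter vector.
#' @return list with \code{se} (named), \code{rho} (correlation matrix),
#'   \code{H}, \code{T}.
#' @export
hessian_se_and_correlation <- function(loglik, theta) {
  k <- length(theta)
  h <- 1e-4 * pmax(abs(theta), 0.1)
  H <- matrix(0, k, k, dimnames = list(names(theta), names(theta)))
  f0 <- loglik(theta)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    H[i, i] <- (loglik(theta + ei) - 2 * f0 + loglik(theta - ei)) / h[i]^2
    if (i < k) for (j in seq((i + 1), k)) {
      ej <- replace(numeric(k), j, h[j])
      H[i, j] <- H[j, i] <-
        (loglik(theta + ei + ej) - loglik(theta + ei - ej) -
           loglik(theta - ei + ej) + loglik(theta - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  Tm <- tryCatch(-solve(H), error = function(e) {
    stop("hessian_se_and_correlation: Hessian not invertible ",
         "(reciprocal condition number ", format(rcond(H), digits = 3), ")",
         call. = FALSE)
  })
  if (any(diag(Tm) <= 0)) {
    stop("hessian_se_and_correlation: negative variance estimate; ",
         "the MLE may not be an interior maximum", call. = FALSE)
  }
  se <- sqrt(diag(Tm))
  rho <- Tm / outer(se, se)
  list(se = se, rho = rho, H = H, T = Tm)
}

# parameter bounds for the optimiser
param_bounds <- function(name) {
  switch(name,
    gamma = , gamma_f = , gamma_b = c(0, 1),
    sigma = c(0.005, 2),
    stop("unknown parameter ", name))
}

#' Maximum-likelihood fit of the belief model
#'
#' Deterministic two-stage optimisation: a coarse grid search (gamma linear
#' in [0,1] with step 0.05; sigma log-spaced over [0.01, 1] with 25 points)
#' followed by Nelder-Mead refinement from the best grid point, with bounds
#' enforced (out-of-bounds proposals score \code{Inf}). Variants:
#' \describe{
#'   \item{full}{free gamma and sigma (the reference model).}
#'   \item{gamma0 / gamma1}{gamma fixed at 0 / 1; sigma free.}
#'   \item{no_f / no_P}{observation likelihood uses only price / only
#'     frequency; gamma and sigma free.}
#'   \item{asym}{separate forward/backward uncertainties gamma_f, gamma_b
#'     plus sigma.}
#' }
#'
#' @param trial_log a trial log or prebuilt \code{\link{fit_context}}.
#' @param variant one of \code{"full"}, \code{"gamma0"}, \code{"gamma1"},
#'   \code{"no_f"}, \code{"no_P"}, \code{"asym"}.
#' @param config,resp passed to \code{\link{fit_context}} when needed.
#' @param rows optional integer vector of triad positions (1..n in context
#'   order) to fit on, e.g. one tertile.
#' @param se compute Hessian standard errors (default TRUE; skipped, with
#'   NA results, when the Hessian is degenerate, as for gamma0 where sigma
#'   does not enter the likelihood).
#' @return object of class \code{fit_result}: list with \code{variant},
#'   \code{theta}, \code{log_likelihood}, \code{bic}, \code{se}, \code{rho}
#'   (correlation between parameter estimates), \code{n_data}.
#' @export
fit_mle <- function(trial_log, variant = "full",
                    config = attr(trial_log, "config"), resp = NULL,
                    rows = NULL, se = TRUE) {
  ctx <- if (inherits(trial_log, "fit_context")) trial_log
         else fit_context(trial_log, config, resp)
  info <- variant_info(variant)
  n_data <- if (is.null(rows)) ctx$n else length(rows)
  if (n_data < 30L) {
    warning("fit_mle: fewer than 30 triads; estimates will be unstable")
  }

  sigma_grid <- 10^seq(log10(0.01), log10(1), length.out = 25L)
  gamma_grid <- seq(0, 1, by = 0.05)

  # stage 1: grid search, likelihood matrices cached on the full context
  best <- NULL; best_val <- Inf
  for (sg in sigma_grid) {
    L <- ctx_lik(ctx, sg, info$lik, rows = rows, cache = TRUE)
    cand <- switch(variant,
      gamma0 = list(c(gamma = 0, sigma = sg)),
      gamma1 = list(c(gamma = 1, sigma = sg)),
      asym = {
        gg <- seq(0, 1, by = 0.2)
        unlist(lapply(gg, function(gf) lapply(gg, function(gb) {
          c(gamma_f = gf, gamma_b = gb, sigma = sg)
        })), recursive = FALSE)
      },
      lapply(gamma_grid, function(g) c(gamma = g, sigma = sg))
    )
    for (p in cand) {
      v <- nll_ctx(ctx, p, likmode = info$lik, rows = rows, L = L)
      # strict-improvement tie-break: on flat ridges (degenerate data) keep
      # the first-visited candidate so fits stay deterministic
      if (v < best_val - 1e-9) { best_val <- v; best <- p }
    }
  }
  if (!is.finite(best_val)) {
    stop("fit_mle: likelihood not finite anywhere on the search grid",
         call. = FALSE)
  }

  # stage 2: derivative-free local refinement, bounds enforced via Inf
  free <- intersect(names(best), info$free)
  obj <- function(th) {
    names(th) <- free
    for (nm in free) {
      b <- param_bounds(nm)
      if (th[[nm]] < b[1] || th[[nm]] > b[2]) return(Inf)
    }
    nll_ctx(ctx, c(th, info$fixed), likmode = info$lik, rows = rows)
  }
  start <- best[free]
  if (length(free) == 1L) {
    b <- param_bounds(free)
    opt <- stats::optimize(function(v) obj(stats::setNames(v, free)),
                           interval = b, tol = 1e-6)
    theta <- stats::setNames(opt$minimum, free)
    val <- opt$objective
  } else {
    opt <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-9))
    theta <- stats::setNames(opt$par, free)
    val <- opt$value
  }
  if (!(val < best_val - 1e-9)) { theta <- best[free]; val <- best_val }

  se_vec <- stats::setNames(rep(NA_real_, length(free)), free)
  rho <- NULL
  if (se && length(free) >= 1L) {
    on_bound <- vapply(free, function(nm) {
      b <- param_bounds(nm)
      theta[[nm]] <= b[1] + 1e-8 || theta[[nm]] >= b[2] - 1e-8
    }, logical(1L))
    if (any(on_bound)) {
      warning("fit_mle: MLE on a parameter bound; Hessian standard errors ",
              "are asymptotically invalid there")
    }
    ll_fn <- function(th) {
      names(th) <- free
      -nll_ctx(ctx, c(th, info$fixed), likmode = info$lik, rows = rows)
    }
    hs <- tryCatch(hessian_se_and_correlation(ll_fn, theta),
                   error = function(e) NULL)
    if (!is.null(hs)) { se_vec <- hs$se; rho <- hs$rho }
  }

  structure(list(variant = variant,
                 theta = c(theta, info$fixed),
                 free = free,
                 log_likelihood = -val,
                 bic = bic(-val, length(free), n_data),
                 se = se_vec, rho = rho, n_data = n_data),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Belief-model fit (variant:", x$variant, ")\n")
  for (nm in names(x$theta)) {
    se_txt <- if (nm %in% names(x$se) && is.finite(x$se[[nm]])) {
      sprintf(" (SE %.4f)", x$se[[nm]])
    } else ""
    cat(sprintf("  %-8s = %.4f%s\n", nm, x$theta[[nm]], se_txt))
  }
  cat(sprintf("  logL = %.2f, BIC = %.2f, n = %d triads\n",
              x$log_likelihood, x$bic, x$n_data))
  if (!is.null(x$rho) && nrow(x$rho) > 1L) {
    cat(sprintf("  rho(%s, %s) = %.3f\n", rownames(x$rho)[1],
                rownames(x$rho)[2], x$rho[1, 2]))
  }
  invisible(x)
}

#' Compare model variants by summed per-tertile BIC
#'
#' Fits each variant independently to the three sequential tertiles and sums
#' the per-tertile BICs; reports the increase relative to the full model.
#'
#' @param trial_log a trial log or prebuilt \code{\link{fit_context}}.
#' @param variants character vector of variants to compare.
#' @param config,resp passed to \code{\link{fit_context}} when needed.
#' @param tertiles fit per tertile and sum (default TRUE); otherwise one fit
#'   on the whole data.
#' @return data.frame with columns \code{variant}, \code{n_params},
#'   \code{log_likelihood}, \code{bic}, \code{delta_bic} (relative to full).
#' @export
compare_models <- function(trial_log, variants = MODEL_VARIANTS,
                           config = attr(trial_log, "config"), resp = NULL,
                           tertiles = TRUE) {
  ctx <- if (inherits(trial_log, "fit_context")) trial_log
         else fit_context(trial_log, config, resp)
  blocks <- if (tertiles) split_tertiles(seq_len(ctx$n)) else list(seq_len(ctx$n))
  rows_out <- lapply(variants, function(v) {
    fits <- lapply(blocks, function(rw) fit_mle(ctx, v, rows = rw, se = FALSE))
    data.frame(variant = v,
               n_params = length(fits[[1L]]$free),
               log_likelihood = sum(vapply(fits, `[[`, numeric(1L),
                                           "log_likelihood")),
               bic = sum(vapply(fits, `[[`, numeric(1L), "bic")))
  })
  out <- do.call(rbind, rows_out)
  ref <- if ("full" %in% out$variant) out$bic[out$variant == "full"] else min(out$bic)
  out$delta_bic <- out$bic - ref
  out
}
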