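#' Fit the multistate model with a latent resolved state
#'
#' Maximum-likelihood estimation over the working parameter vector
#' (log baseline intensities, regression coefficients) by quasi-Newton
#' (BFGS) ascent of the marginal panel likelihood. The covariance of the
#' estimate is the inverse of a central-finite-difference Hessian at the
#' optimum; when the Hessian cannot be inverted (which is expected in weakly
#' identified settings, e.g. little follow-up after the last disability
#' observation), the fit carries no covariance and a warning is issued.
#'
#' @param data Long-format panel tibble (`subject_id`, `time`, `state_code`,
#'   covariate columns).
#' @param space A [state_space()] object.
#' @param init An [msm_params()] object: starting values, whose `beta`
#'   structure also defines which covariates act on which transitions.
#' @param regime `"partial"` or `"complete"`; see [total_loglik()].
#' @param initial_split Initial-state split for a leading `"0"` code.
#' @param control List overriding optimiser defaults `maxit = 500`,
#'   `reltol = 1e-8`.
#' @param hessian_step Central-difference step on the working scale.
#' @param vcov Compute the covariance matrix? Setting `FALSE` skips the
#'   Hessian (useful in large replicate studies where only point estimates
#'   are needed).
#' @param polish Run a few Newton refinement steps (finite-difference score
#'   and Hessian) after BFGS terminates. BFGS stops on relative change of the
#'   log-likelihood, which limits the accuracy of the maximiser itself to
#'   roughly the square root of that tolerance; polishing pushes the estimate
#'   to the accuracy of the score. Off by default (it can be counterproductive
#'   on the flat ridges of weakly identified fits).
#' @return An object of class `resolution_fit` with elements `params`
#'   (MLE as [msm_params()]), `theta` (working-scale MLE), `vcov`, `loglik`,
#'   `converged`, `n_subjects`, `n_observations`, `term_map`, plus the
#'   `space`, `regime` and `initial_split` used. Methods: [tidy()],
#'   [glance()], [autoplot()], `print()`, `logLik()`.
#' @examples
#' sp <- state_space(0)
#' pp <- msm_params(lambda = c("D0->R" = 0.4), space = sp)
#' sim <- simulate_scenario(scenario_config(1, n_subjects = 60), seed = 1)
#' @export
fit_resolution_msm <- function(data, space, init,
                               regime = c("partial", "complete"),
                               initial_split = c(R = 0, D0 = 1),
                               control = list(),
                               hessian_step = 1e-4,
                               vcov = TRUE,
                               polish = FALSE) {
  regime <- match.arg(regime)
  if (!inherits(init, "msm_params")) {
    stop("`init` must be an msm_params object.", call. = FALSE)
  }
  design <- panel_design(data, init, space, regime, initial_split)
  theta0 <- theta_pack(init)
  negll <- function(theta) {
    v <- panel_loglik_cpp(theta, design)
    if (!is.finite(v)) return(1e12)
    -v
  }
  ctrl <- utils::modifyList(list(maxit = 500L, reltol = 1e-8), control)
  if (!is.null(ctrl$ndeps) && length(ctrl$ndeps) == 1L) {
    ctrl$ndeps <- rep(ctrl$ndeps, length(theta0))
  }
  opt <- stats::optim(theta0, negll, method = "BFGS", control = ctrl)
  theta_hat <- opt$par
  converged <- opt$convergence == 0L

  if (isTRUE(polish)) {
    for (it in 1:10) {
      g <- fd_gradient(negll, theta_hat)
      H <- fd_hessian(negll, theta_hat, h = hessian_step)
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      cand <- theta_hat - step
      if (negll(cand) > opt$value + 1e-8) break
      theta_hat <- cand
      if (max(abs(step)) < 1e-10) break
    }
    opt$value <- negll(theta_hat)
  }

  V <- NULL
  if (isTRUE(vcov)) {
    H <- fd_hessian(negll, theta_hat, h = hessian_step)
    V <- tryCatch({
      Vi <- solve(H)
      if (any(!is.finite(Vi)) || any(diag(Vi) < 0)) stop("not positive definite")
      Vi
    }, error = function(e) {
      warning("Hessian not invertible at the optimum; no covariance ",
              "available (weak identifiability?).", call. = FALSE)
      NULL
    })
  }

  tm <- design$term_map
  if (!is.null(V)) dimnames(V) <- list(tm$term, tm$term)
  structure(
    list(
      params = theta_unpack(theta_hat, init),
      theta = setNames(theta_hat, tm$term),
      vcov = V,
      loglik = -opt$value,
      converged = converged,
      n_subjects = design$n_subjects,
      n_observations = design$n_observations,
      term_map = tm,
      space = space,
      regime = regime,
      initial_split = initial_split,
      counts = opt$counts
    ),
    class = "resolution_fit"
  )
}

# Central finite-difference gradient with fixed step h on each coordinate.
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    ei <- replace(numeric(length(x)), i, h)
    (f(x + ei) - f(x - ei)) / (2 * h)
  }, numeric(1))
}

# Central finite-difference Hessian with fixed step h on each coordinate.
fd_hessian <- function(f, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        ej <- replace(numeric(p), j, h)
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
          (4 * h^2)
      }
    }
  }
  H
}

#' @exportS3Method base::print
print.resolution_fit <- function(x, ...) {
  cat("<resolution_fit> ", x$regime, " observation; ",
      x$n_subjects, " subjects, ", x$n_observations, " visits\n", sep = "")
  cat("  log-likelihood: ", format(x$loglik, digits = 8),
      if (!x$converged) "  (NOT converged)", "\n", sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @export
logLik.resolution_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$theta), class = "logLik")
}

#' Wald confidence intervals for a fitted model
#'
#' Intervals are symmetric on the working scale and reported on the natural
#' scale: baseline intensities (estimated as logs) get exponentiated
#' intervals `exp(theta_hat +/- z se)`, regression coefficients get
#' `theta_hat +/- z se`.
#'
#' @param fit A [fit_resolution_msm()] result.
#' @param level Confidence level (default 0.95).
#' @return Tibble with `term`, `type`, `transition`, `covariate`, `estimate`,
#'   `std.error` (working scale), `conf.low`, `conf.high`. When the fit has
#'   no covariance the interval columns are `NA`.
#' @export
wald_intervals <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "resolution_fit"))
  tm <- fit$term_map
  zq <- qnorm(1 - (1 - level) / 2)
  est_work <- unname(fit$theta)
  se <- if (!is.null(fit$vcov)) sqrt(diag(fit$vcov)) else rep(NA_real_, length(est_work))
  lo <- est_work - zq * se
  hi <- est_work + zq * se
  bl <- tm$type == "baseline"
  tibble::tibble(
    term = tm$term,
    type = tm$type,
    transition = tm$transition,
    covariate = tm$covariate,
    estimate = ifelse(bl, exp(est_work), est_work),
    std.error = unname(se),
    conf.low = ifelse(bl, exp(lo), lo),
    conf.high = ifelse(bl, exp(hi), hi)
  )
}

#' @rdname wald_intervals
#' @param x A `resolution_fit` object.
#' @param ... Unused.
#' @export
tidy.resolution_fit <- function(x, level = 0.95, ...) {
  wald_intervals(x, level = level)
}

#' @export
glance.resolution_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    nobs = x$n_observations,
    n_subjects = x$n_subjects,
    n_parameters = length(x$theta),
    converged = x$converged,
    AIC = -2 * x$loglik + 2 * length(x$theta)
  )
}

#' @export
autoplot.resolution_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2, na.rm = TRUE
    ) +
    ggplot2::facet_wrap(~type, scales = "free") +
    ggplot2::labs(x = "estimate (natural scale)", y = NULL)
  }

#' Format estimates as "estimate (lower, upper)"
#'
#' @param estimate,conf.low,conf.high Numeric vectors.
#' @param digits Significant digits.
#' @return Character vector like `"0.039 (0.024, 0.065)"`.
#' @export
format_estimate_ci <- function(estimate, conf.low, conf.high, digits = 2) {
  paste0(signif(estimate, digits), " (", signif(conf.low, digits), ", ",
         signif(conf.high, digits), ")")
}

#' Likelihood-ratio test for the existence of resolution
#'
#' Tests `lambda_{D0->R} = 0` (no resolved subpopulation) against the full
#' model. Because the null places the rate on the boundary of its parameter
#' space, the statistic `T = 2 (l_full - l_null)` is referred to a 50:50
#' mixture of a point mass at zero and a chi-squared distribution with one
#' degree of freedom: `p = 0.5 P(chisq_1 >= T)` for `T > 0` and `p = 1` at
#' `T = 0`.
#'
#' @param loglik_full,loglik_null Maximised log-likelihoods of the full and
#'   null fits, or the [fit_resolution_msm()] objects themselves.
#' @param tol Numerical tolerance by which `loglik_null` may exceed
#'   `loglik_full` before erroring (the null must be nested).
#' @return Tibble with `statistic`, `p.value`, `method`.
#' @examples
#' boundary_lrt(-100, -101.5)
#' @export
boundary_lrt <- function(loglik_full, loglik_null, tol = 1e-6) {
  if (inherits(loglik_full, "resolution_fit")) loglik_full <- loglik_full$loglik
  if (inherits(loglik_null, "resolution_fit")) loglik_null <- loglik_null$loglik
  if (loglik_null > loglik_full + tol) {
    stop("Null log-likelihood exceeds the full model's: the null must be ",
         "nested in the full model.", call. = FALSE)
  }
  T_ <- max(0, 2 * (loglik_full - loglik_null))
  p <- if (T_ <= 0) 1 else 0.5 * pchisq(T_, df = 1, lower.tail = FALSE)
  tibble::tibble(
    statistic = T_,
    p.value = p,
    method = "boundary LRT, 50:50 mixture of chisq(1) and point mass at 0"
  )
}

#' Probability of having resolved by time t
#'
#' The estimated probability that a subject with covariates `z` who occupies
#' `s0` at time zero has entered the resolved state before `t` years:
#' the `(s0, R)` entry of `expm(Q(theta_hat, z) t)`. Confidence intervals are
#' obtained by simulating parameter vectors from the asymptotic normal
#' distribution of the estimator on the working scale and taking percentile
#' bands of the same functional.
#'
#' @param fit A [fit_resolution_msm()] result (needs a covariance matrix for
#'   intervals).
#' @param s0 Initial state label(s).
#' @param t Vector of horizons (years, non-negative).
#' @param z Named covariate vector (values at which to evaluate).
#' @param n_draws Draws from the asymptotic normal (default 1000).
#' @param seed Seed for the draws (results are deterministic given it).
#' @param level Confidence level.
#' @return Tibble with `initial_state`, `t`, `estimate`, `conf.low`,
#'   `conf.high`; interval columns are `NA` when no covariance is available,
#'   and degenerate for `s0 = "R"`.
#' @export
resolution_probability <- function(fit, s0, t, z = NULL, n_draws = 1000,
                                   seed = NULL, level = 0.95) {
  stopifnot(inherits(fit, "resolution_fit"))
  if (any(t < 0)) stop("`t` must be non-negative.", call. = FALSE)
  space <- fit$space
  state_index(s0, space)
  grid <- tidyr::expand_grid(initial_state = s0, t = t)

  prob_of <- function(params, s0x, tx) {
    if (s0x == "R") return(1)
    if (tx == 0) return(0)
    Q <- build_generator(params, z, space)
    transition_matrix(Q, tx)[s0x, "R"]
  }
  grid$estimate <- purrr::map2_dbl(grid$initial_state, grid$t,
                                   ~prob_of(fit$params, .x, .y))

  if (!is.null(fit$vcov) && n_draws > 0) {
    if (!is.null(seed)) set.seed(seed)
    draws <- MASS::mvrnorm(n_draws, mu = unname(fit$theta), Sigma = fit$vcov)
    qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    band <- matrix(NA_real_, nrow(grid), 2)
    for (g in seq_len(nrow(grid))) {
      if (grid$initial_state[g] == "R" || grid$t[g] == 0) {
        band[g, ] <- grid$estimate[g]
        next
      }
      vals <- apply(draws, 1, function(th) {
        prob_of(theta_unpack(th, fit$params), grid$initial_state[g], grid$t[g])
      })
      band[g, ] <- quantile(vals, qs, names = FALSE)
    }
    grid$conf.low <- band[, 1]
    grid$conf.high <- band[, 2]
  } else {
    grid$conf.low <- NA_real_
    grid$conf.high <- NA_real_
  }
  grid
}
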