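#' Expected proportion resolved by time t (analytic)
#'
#' The design-averaged probability of occupying the resolved state at time
#' `t`: the `(s0, R)` entry of `expm(Q(z) t)` averaged over the configured
#' initial-state allocation and the distribution of the binary covariate.
#' Purely deterministic (matrix exponentials only).
#'
#' @param config A [scenario_config()].
#' @param t Horizon (years); may be a vector.
#' @return Numeric vector of proportions, one per `t`.
#' @examples
#' # under the all-transitions covariate convention (see the vignette):
#' expected_resolved_proportion(
#'   scenario_config(1, beta_on_resolution = TRUE), t = 8)
#' @export
expected_resolved_proportion <- function(config, t) {
  space <- config$space
  w_state <- config$allocation / sum(config$allocation)
  vapply(t, function(tt) {
    if (tt == 0) return(0)
    tot <- 0
    for (zz in c(0, 1)) {
      Q <- build_generator(config$params, c(z = zz), space)
      P <- transition_matrix(Q, tt)
      tot <- tot + 0.5 * sum(w_state * P[config$initial_states, "R"])
    }
    tot
  }, numeric(1))
}

#' Run the replicate simulation study
#'
#' For each replicate: generate a scenario dataset, fit the model under the
#' requested observation regimes (partial fits see `R`/`D0` masked to
#' `"0"`; complete fits see the true labels from the same latent paths), and
#' collect the estimates and Wald bounds. Starting values for every fit are
#' the true baselines perturbed multiplicatively by `exp(U(-0.3, 0.3))` (true
#' coefficients left as given), so fits do not trivially start at the truth.
#' Replicate seeds are derived deterministically from the master seed;
#' failures (non-convergence or errors) are recorded and excluded from
#' summaries, never fatal.
#'
#' @param config A [scenario_config()].
#' @param n_reps Number of replicate datasets.
#' @param seed Master seed.
#' @param regimes Character subset of `c("complete", "partial")`.
#' @return A `simulation_study` object: list with `results` (tibble `rep`,
#'   `regime`, `term`, `type`, `true`, `estimate`, `conf.low`, `conf.high`,
#'   `converged`, `has_vcov`), `n_failed`, `config`, `seed`. Methods:
#'   [summarize_study()], `autoplot()`.
#' @export
run_simulation_study <- function(config, n_reps = 100, seed = 1,
                                 regimes = c("complete", "partial")) {
  stopifnot(n_reps >= 1)
  regimes <- match.arg(regimes, several.ok = TRUE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  true_map <- param_map(config$params)
  true_map$true <- ifelse(true_map$type == "baseline",
                          exp(theta_pack(config$params))[true_map$index],
                          theta_pack(config$params)[true_map$index])
  rows <- vector("list", n_reps * length(regimes))
  n_failed <- 0L
  k <- 0L
  for (r in seq_len(n_reps)) {
    sim <- simulate_scenario(config, regime = "complete", seed = rep_seeds[r])
    # seeded perturbation of the starting values
    init <- config$params
    init$log_lambda <- init$log_lambda +
      runif(length(init$log_lambda), -0.3, 0.3)
    for (tr in names(init$beta)) {
      init$beta[[tr]] <- init$beta[[tr]] +
        runif(length(init$beta[[tr]]), -0.3, 0.3)
    }
    for (regime in regimes) {
      k <- k + 1L
      panel <- sim$panel
      if (regime == "partial") {
        panel$state_code <- mask_resolution(panel$state_code)
      }
      fit <- tryCatch(
        suppressWarnings(
          fit_resolution_msm(panel, config$space, init, regime = regime)
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        n_failed <- n_failed + 1L
        next
      }
      td <- tidy(fit)
      td$rep <- r
      td$regime <- regime
      td$converged <- fit$converged
      td$has_vcov <- !is.null(fit$vcov)
      rows[[k]] <- td
    }
  }
  results <- dplyr::bind_rows(rows)
  results <- dplyr::left_join(
    results, true_map[, c("term", "true")], by = "term"
  )
  results <- dplyr::select(
    results, "rep", "regime", "term", "type", "true", "estimate",
    "conf.low", "conf.high", "converged", "has_vcov"
  )
  structure(
    list(results = results, n_failed = n_failed, n_reps = n_reps,
         config = config, seed = seed),
    class = "simulation_study"
  )
}

#' Summarise a replicate study
#'
#' Means of the parameter estimates and of the Wald interval endpoints across
#' converged replicates, per observation regime, in the layout
#' (parameter, true value, complete-observation columns,
#' partial-observation columns). Also reports the Monte Carlo standard error
#' of each mean estimate.
#'
#' @param study A [run_simulation_study()] result (or its `results` tibble).
#' @return Tibble with one row per parameter: `term`, `true`, then per regime
#'   `mean`, `mc_se`, `mean_lower`, `mean_upper`, `n_reps`.
#' @export
summarize_study <- function(study) {
  results <- if (inherits(study, "simulation_study")) study$results else study
  if (is.null(results) || nrow(results) == 0L) {
    stop("No replicate results to summarise.", call. = FALSE)
  }
  ok <- dplyr::filter(results, .data$converged)
  sm <- ok |>
    dplyr::group_by(.data$term, .data$true, .data$regime) |>
    dplyr::summarise(
      mean = mean(.data$estimate),
      mc_se = sd(.data$estimate) / sqrt(dplyr::n()),
      mean_lower = mean(.data$conf.low[.data$has_vcov]),
      mean_upper = mean(.data$conf.high[.data$has_vcov]),
      n_reps = dplyr::n(),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(
      names_from = "regime",
      values_from = c("mean", "mc_se", "mean_lower", "mean_upper", "n_reps"),
      names_glue = "{regime}_{.value}"
    )
  # stable parameter order: as in the configuration
  ord <- unique(results$term)
  sm <- sm[order(match(sm$term, ord)), ]
  cols <- c("term", "true",
            grep("^complete_", names(sm), value = TRUE),
            grep("^partial_", names(sm), value = TRUE))
  sm[, intersect(cols, names(sm))]
}

#' Format a study summary as a publication-style table
#'
#' Renders each regime as `"mean (mean_lower, mean_upper)"` strings in the
#' column order (Parameters, True, Complete observation, Partial
#' observation).
#'
#' @param summary A [summarize_study()] tibble.
#' @param digits Significant digits.
#' @return Tibble of character columns.
#' @export
format_study_table <- function(summary, digits = 2) {
  out <- tibble::tibble(
    Parameters = summary$term,
    True = as.character(summary$true)
  )
  labels <- c(complete = "Complete observation",
              partial = "Partial observation")
  for (regime in c("complete", "partial")) {
    mcol <- paste0(regime, "_mean")
    if (!mcol %in% names(summary)) next
    out[[labels[[regime]]]] <-
      format_estimate_ci(summary[[mcol]],
                         summary[[paste0(regime, "_mean_lower")]],
                         summary[[paste0(regime, "_mean_upper")]],
                         digits = digits)
  }
  out
}

#' @exportS3Method base::print
print.simulation_study <- function(x, ...) {
  cat("<simulation_study> Scenario ", x$config$scenario, ", ", x$n_reps,
      " replicates (", x$n_failed, " failed fits)\n", sep = "")
  print(summarize_study(x), n = Inf)
  invisible(x)
}

#' @export
autoplot.simulation_study <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$term, y = .data$estimate,
                               fill = .data$regime)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_point(ggplot2::aes(y = .data$true), colour = "red",
                        shape = 4, size = 2, show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "estimate (natural scale)")
}
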