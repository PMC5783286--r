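#' Distribution of the latent state at the first visit
#'
#' An initial observation of a disability code pins the latent state down. An
#' initial code `"0"` is ambiguous between `R` and `D0`; because patients are
#' typically referred to a clinic for active disease, the default treats them
#' as temporarily non-disabled (point mass on `D0`). The split is a knob for
#' sensitivity analyses.
#'
#' @param code Observed code at the first visit.
#' @param space A [state_space()] object.
#' @param split Length-2 numeric `c(R = pR, D0 = pD0)` summing to 1; the
#'   initial distribution used when `code == "0"`.
#' @return Named numeric vector over all latent states summing to 1.
#' @examples
#' initial_state_term("0", state_space(2))
#' initial_state_term("D2", state_space(2))
#' @export
initial_state_term <- function(code, space, split = c(R = 0, D0 = 1)) {
  if (length(split) != 2L || any(split < 0) ||
      abs(sum(split) - 1) > 1e-12) {
    stop("`split` must be two non-negative probabilities (R, D0) summing to 1.",
         call. = FALSE)
  }
  out <- setNames(numeric(length(space$states)), space$states)
  if (identical(code, "0")) {
    out["R"] <- split[[1]]
    out["D0"] <- split[[2]]
  } else {
    st <- code_states(code, space)
    out[st] <- 1
  }
  out
}

subject_check <- function(subject) {
  need <- c("time", "state_code")
  miss <- setdiff(need, names(subject))
  if (length(miss)) {
    stop("Subject data must have columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(subject) < 2L) {
    stop("A subject needs at least two visits to contribute to the likelihood.",
         call. = FALSE)
  }
  dt <- diff(subject$time)
  if (any(dt <= 0)) {
    stop("Visit times must be strictly increasing within a subject ",
         "(tied or out-of-order times).", call. = FALSE)
  }
  invisible(subject)
}

#' Log-likelihood of one completely observed subject
#'
#' For completely observed histories (every visit's latent state known, i.e.
#' no ambiguous `"0"` codes) the likelihood factorises, by the Markov and
#' time-homogeneity properties, into a product of interval transition
#' probabilities, conditioning on the state at the first visit.
#'
#' @param subject Tibble/data frame of one subject's visits, time-ordered,
#'   with columns `time`, `state_code` (latent labels here) and any covariate
#'   columns named in `params`.
#' @param params An [msm_params()] object.
#' @param space A [state_space()] object.
#' @return Log-likelihood (`-Inf` if any interval has probability zero).
#' @export
subject_loglik_complete <- function(subject, params, space) {
  subject_check(subject)
  sets <- code_states(as.character(subject$state_code), space)
  if (length(subject$state_code) > 1L) {
    lens <- vapply(sets, length, integer(1))
  } else {
    lens <- length(sets)
  }
  if (any(lens != 1L)) {
    stop("Complete-observation likelihood requires unambiguous latent labels; ",
         "found code \"0\".", call. = FALSE)
  }
  states <- unlist(sets, use.names = FALSE)
  covs <- param_covariates(params)
  ll <- 0
  cache <- list()
  for (j in seq_len(nrow(subject) - 1L)) {
    z <- if (length(covs)) unlist(subject[j, covs, drop = FALSE]) else NULL
    dt <- subject$time[j + 1L] - subject$time[j]
    key <- paste(c(format(z, digits = 17), format(dt, digits = 17)),
                 collapse = "|")
    P <- cache[[key]]
    if (is.null(P)) {
      P <- transition_matrix(build_generator(params, z, space), dt)
      cache[[key]] <- P
    }
    pj <- P[states[j], states[j + 1L]]
    if (pj <= 0) return(-Inf)
    ll <- ll + log(pj)
  }
  unname(ll)
}

#' Marginal log-likelihood of one partially observed subject
#'
#' Observations of code `"0"` are ambiguous between the resolved state `R` and
#' temporary non-disability `D0`. The marginal likelihood sums, over every
#' assignment of latent states consistent with the censored sets, the product
#' of interval transition probabilities times the initial-state term. The sum
#' is evaluated by a forward recursion over the censored sets
#' (`alpha' <- (alpha P(dt))` restricted to the next set), which is
#' mathematically identical to the nested sums; probabilities are renormalised
#' at each visit and accumulated on the log scale so long histories do not
#' underflow. Assignments that leave `R` receive zero weight automatically
#' because the `R` row of `P` is a point mass.
#'
#' @inheritParams subject_loglik_complete
#' @param initial_split Passed to [initial_state_term()] for a leading `"0"`.
#' @return Log marginal likelihood (`-Inf`, with a diagnostic naming the
#'   subject, if no consistent assignment has positive probability).
#' @export
subject_loglik_partial <- function(subject, params, space,
                                   initial_split = c(R = 0, D0 = 1)) {
  subject_check(subject)
  codes <- as.character(subject$state_code)
  covs <- param_covariates(params)
  alpha <- initial_state_term(codes[1L], space, initial_split)
  ll <- 0
  cache <- list()
  for (j in seq_len(nrow(subject) - 1L)) {
    z <- if (length(covs)) unlist(subject[j, covs, drop = FALSE]) else NULL
    dt <- subject$time[j + 1L] - subject$time[j]
    key <- paste(c(format(z, digits = 17), format(dt, digits = 17)),
                 collapse = "|")
    P <- cache[[key]]
    if (is.null(P)) {
      P <- transition_matrix(build_generator(params, z, space), dt)
      cache[[key]] <- P
    }
    alpha <- drop(alpha %*% P)
    keep <- space$states %in% code_states(codes[j + 1L], space)
    alpha[!keep] <- 0
    s <- sum(alpha)
    if (s <= 0 || !is.finite(s)) {
      id <- if ("subject_id" %in% names(subject)) subject$subject_id[1L] else "?"
      warning("Zero marginal probability for subject ", id,
              " (visit ", j + 1L, "); returning -Inf.", call. = FALSE)
      return(-Inf)
    }
    ll <- ll + log(s)
    alpha <- alpha / s
  }
  unname(ll)
}

#' Total log-likelihood of a panel dataset
#'
#' Sum of per-subject marginal log-likelihoods. Evaluated through the compiled
#' forward-recursion core; transition probability matrices are computed once
#' per unique (covariate profile, interval length) pair within an evaluation.
#'
#' @param data Long-format panel tibble with columns `subject_id`, `time`,
#'   `state_code` and the covariate columns named in `params`.
#' @param params An [msm_params()] object.
#' @param space A [state_space()] object.
#' @param regime `"partial"` (code `"0"` ambiguous between `R` and `D0`) or
#'   `"complete"` (all latent labels observed; the data must contain no `"0"`
#'   code).
#' @param initial_split Initial-state split for a leading `"0"` code; see
#'   [initial_state_term()].
#' @return Total log-likelihood (scalar).
#' @export
total_loglik <- function(data, params, space,
                         regime = c("partial", "complete"),
                         initial_split = c(R = 0, D0 = 1)) {
  regime <- match.arg(regime)
  design <- panel_design(data, params, space, regime, initial_split)
  panel_loglik_cpp(theta_pack(params), design)
}
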