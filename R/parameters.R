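#' Model parameters: baseline intensities and covariate effects
#'
#' The parameter vector of the model collects, per allowed transition, a
#' baseline transition intensity (stored and optimised on the log scale, which
#' keeps it positive) and an optional vector of proportional-hazards
#' regression coefficients. The intensity of the transition from state r to
#' state s for a subject with covariate vector `z` is
#' `lambda_rs * exp(beta_rs' z)`.
#'
#' @param lambda Named numeric vector of positive baseline intensities; names
#'   must be exactly the transition labels of `space` (see
#'   [transition_labels()]), in any order.
#' @param beta Named list: one element per transition that has covariate
#'   effects, each a named numeric vector of coefficients (names are covariate
#'   column names in the data). Transitions absent from `beta` have no
#'   covariate effects.
#' @param space A [state_space()] object.
#' @return An object of class `msm_params` holding `log_lambda` and `beta`.
#' @examples
#' sp <- state_space(2)
#' msm_params(
#'   lambda = c("D0->R" = 0.4, "D0->D1" = 0.4, "D1->D0" = 0.6,
#'              "D1->D2" = 0.6, "D2->D1" = 0.4),
#'   beta = list("D0->D1" = c(z = 1)),
#'   space = sp
#' )
#' @export
msm_params <- function(lambda, beta = list(), space) {
  labs <- transition_labels(space)
  if (is.null(names(lambda)) || !setequal(names(lambda), labs) ||
      length(lambda) != length(labs)) {
    stop("`lambda` must be named by exactly the allowed transitions: ",
         paste(labs, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    stop("Baseline intensities must be finite and strictly positive.",
         call. = FALSE)
  }
  if (length(beta)) {
    if (is.null(names(beta)) || !all(names(beta) %in% labs)) {
      stop("`beta` names must be allowed transitions.", call. = FALSE)
    }
    ok <- vapply(beta, function(b) is.numeric(b) && length(b) > 0 &&
                   !is.null(names(b)) && all(nzchar(names(b))), logical(1))
    if (!all(ok)) {
      stop("Each `beta` element must be a named numeric vector of covariate ",
           "coefficients.", call. = FALSE)
    }
  }
  structure(
    list(log_lambda = log(lambda[labs]), beta = beta[names(beta)]),
    class = "msm_params"
  )
}

#' @exportS3Method base::print
print.msm_params <- function(x, ...) {
  cat("<msm_params>\n baseline intensities:\n")
  print(round(exp(x$log_lambda), 6))
  if (length(x$beta)) {
    cat(" regression coefficients:\n")
    for (tr in names(x$beta)) {
      cat("  ", tr, ": ",
          paste(names(x$beta[[tr]]), "=", signif(x$beta[[tr]], 6),
                collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Covariate names referenced by a parameter set
#' @noRd
param_covariates <- function(params) {
  unique(unlist(lapply(params$beta, names), use.names = FALSE))
}

# Flat description of the free parameter vector theta: one row per coordinate,
# baselines first (in transition order), then coefficients grouped by
# transition. Terms are "lambda(D0->R)" and "beta(D0->D1):z".
param_map <- function(params) {
  lam <- tibble::tibble(
    type = "baseline",
    transition = names(params$log_lambda),
    covariate = NA_character_
  )
  if (length(params$beta)) {
    bet <- purrr::map_dfr(names(params$beta), function(tr) {
      tibble::tibble(type = "coefficient", transition = tr,
                     covariate = names(params$beta[[tr]]))
    })
  } else {
    bet <- tibble::tibble(type = character(), transition = character(),
                          covariate = character())
  }
  out <- dplyr::bind_rows(lam, bet)
  out$term <- ifelse(out$type == "baseline",
                     paste0("lambda(", out$transition, ")"),
                     paste0("beta(", out$transition, "):", out$covariate))
  out$index <- seq_len(nrow(out))
  out
}

theta_pack <- function(params) {
  c(unname(params$log_lambda),
    unlist(params$beta, use.names = FALSE))
}

theta_unpack <- function(theta, template) {
  p <- template
  nl <- length(p$log_lambda)
  p$log_lambda[] <- theta[seq_len(nl)]
  at <- nl
  for (tr in names(p$beta)) {
    nb <- length(p$beta[[tr]])
    p$beta[[tr]][] <- theta[at + seq_len(nb)]
    at <- at + nb
  }
  p
}
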