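#' Build the generator (intensity) matrix for a covariate vector
#'
#' Entry `(r, s)` of the generator is the transition intensity
#' `lambda_rs * exp(beta_rs' z)` for allowed transitions, zero otherwise; the
#' diagonal is set so every row sums to zero, and the row of the absorbing
#' resolved state `R` is identically zero.
#'
#' @param params An [msm_params()] object.
#' @param z Named numeric vector of covariate values (may be `NULL` when no
#'   transition has covariate effects). Every covariate named in a `beta`
#'   vector must be supplied.
#' @param space A [state_space()] object.
#' @return A square numeric matrix with `dimnames` equal to the state labels.
#' @examples
#' sp <- state_space(2)
#' pp <- msm_params(
#'   lambda = c("D0->R" = 0.4, "D0->D1" = 0.4, "D1->D0" = 0.6,
#'              "D1->D2" = 0.6, "D2->D1" = 0.4),
#'   space = sp
#' )
#' build_generator(pp, z = NULL, space = sp)
#' @export
build_generator <- function(params, z = NULL, space) {
  ns <- length(space$states)
  Q <- matrix(0, ns, ns, dimnames = list(space$states, space$states))
  labs <- transition_labels(space)
  for (k in seq_along(labs)) {
    tr <- labs[k]
    lp <- params$log_lambda[[tr]]
    b <- params$beta[[tr]]
    if (!is.null(b)) {
      miss <- setdiff(names(b), names(z))
      if (length(miss)) {
        stop("Missing covariate value(s) ", paste(miss, collapse = ", "),
             " required by transition ", tr, ".", call. = FALSE)
      }
      lp <- lp + sum(b * z[names(b)])
    }
    Q[space$transitions$from[k], space$transitions$to[k]] <- exp(lp)
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

#' Transition probability matrix over an interval
#'
#' Computes `P(dt) = expm(Q * dt)`, whose `(r, s)` entry is the probability of
#' occupying state `s` after time `dt` given state `r` now. The default uses
#' the scaling-and-squaring Pade matrix exponential; `"uniformization"`
#' evaluates the Poisson-weighted series of the uniformised discrete chain,
#' which serves as an independent numerical route. If the default fails
#' numerically the function falls back to uniformization with a message.
#'
#' @param Q Generator matrix from [build_generator()].
#' @param dt Non-negative interval length (years).
#' @param method `"pade"` (default) or `"uniformization"`.
#' @return Row-stochastic matrix of transition probabilities.
#' @examples
#' sp <- state_space(0)
#' pp <- msm_params(lambda = c("D0->R" = 0.4), space = sp)
#' transition_matrix(build_generator(pp, NULL, sp), 8)["D0", "R"]
#' 1 - exp(-0.4 * 8)
#' @export
transition_matrix <- function(Q, dt, method = c("pade", "uniformization")) {
  method <- match.arg(method)
  if (length(dt) != 1L || is.na(dt) || dt < 0) {
    stop("`dt` must be a single non-negative number.", call. = FALSE)
  }
  if (dt == 0) {
    P <- diag(nrow(Q))
    dimnames(P) <- dimnames(Q)
    return(P)
  }
  P <- if (method == "pade") {
    tryCatch(
      as.matrix(Matrix::expm(Matrix::Matrix(Q * dt))),
      error = function(e) {
        message("Pade matrix exponential failed (", conditionMessage(e),
                "); falling back to uniformization.")
        expm_uniformization(Q, dt)
      }
    )
  } else {
    expm_uniformization(Q, dt)
  }
  dimnames(P) <- dimnames(Q)
  P[P < 0] <- 0
  P
}

#' Matrix exponential of a generator by uniformization
#'
#' Writes `expm(Q t)` as `sum_k Pois(k; nu t) A^k` with `A = I + Q/nu` and
#' `nu = max_r (-Q[r, r])`, truncating the Poisson series at a tail mass below
#' `tol`. Valid for generator matrices only (non-negative off-diagonals, zero
#' row sums); used as an alternative numerical route to the Pade exponential.
#'
#' @param Q Generator matrix.
#' @param dt Non-negative interval length.
#' @param tol Poisson tail mass at which the series is truncated.
#' @return Transition probability matrix.
#' @export
expm_uniformization <- function(Q, dt, tol = 1e-14) {
  ns <- nrow(Q)
  nu <- max(-diag(Q))
  if (nu <= 0) {
    P <- diag(ns)
    dimnames(P) <- dimnames(Q)
    return(P)
  }
  A <- diag(ns) + Q / nu
  mu <- nu * dt
  kmax <- max(10L, stats::qpois(tol, mu, lower.tail = FALSE) + 10L)
  w <- exp(-mu)          # Poisson weight at k = 0
  term <- diag(ns)       # A^0
  P <- w * term
  for (k in seq_len(kmax)) {
    term <- term %*% A
    w <- w * mu / k
    P <- P + w * term
  }
  dimnames(P) <- dimnames(Q)
  P
}
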