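# Brute-force marginal likelihood: enumerate every latent assignment
# consistent with the censored state sets and sum the path probabilities.
# Intentionally naive (nested sums, no recursion) so it is an independent
# check of the forward-recursion implementations.
enum_loglik <- function(subject, params, space,
                        initial_split = c(R = 0, D0 = 1)) {
  codes <- as.character(subject$state_code)
  n <- length(codes)
  sets <- lapply(codes, function(cd) code_states(cd, space))
  init <- initial_state_term(codes[1], space, initial_split)
  covs <- unique(unlist(lapply(params$beta, names)))
  P <- vector("list", n - 1)
  for (j in seq_len(n - 1)) {
    z <- if (length(covs)) unlist(subject[j, covs, drop = FALSE]) else NULL
    dt <- subject$time[j + 1] - subject$time[j]
    P[[j]] <- transition_matrix(build_generator(params, z, space), dt)
  }
  grid <- expand.grid(sets, stringsAsFactors = FALSE)
  total <- 0
  for (g in seq_len(nrow(grid))) {
    x <- as.character(grid[g, ])
    w <- init[[x[1]]]
    for (j in seq_len(n - 1)) {
      if (w == 0) break
      w <- w * P[[j]][x[j], x[j + 1]]
    }
    total <- total + w
  }
  log(total)
}

# Random strictly-positive parameter set for a given space, optionally with a
# coefficient for covariate "z" on every transition.
rand_params <- function(space, with_beta = FALSE, rate_range = c(0.05, 1.5)) {
  labs <- transition_labels(space)
  lam <- setNames(runif(length(labs), rate_range[1], rate_range[2]), labs)
  beta <- if (with_beta) {
    bs <- lapply(labs, function(tr) c(z = runif(1, -1, 1)))
    setNames(bs, labs)
  } else {
    list()
  }
  msm_params(lam, beta, space)
}

# Random short panel history for one subject (codes drawn from the observable
# codes, strictly increasing times, optional covariate z).
rand_subject <- function(space, n_visits = 5, with_z = FALSE, id = 1L) {
  codes <- c("0", paste0("D", seq_len(space$n_severity)))
  tibble::tibble(
    subject_id = id,
    time = cumsum(c(0, runif(n_visits - 1, 0.2, 2))),
    state_code = sample(codes, n_visits, replace = TRUE),
    z = if (with_z) rep(sample(0:1, 1), n_visits) else NULL
  )
}

scenario1_params <- function(space = state_space(2)) {
  msm_params(
    c("D0->R" = 0.4, "D0->D1" = 0.4, "D1->D0" = 0.6,
      "D1->D2" = 0.6, "D2->D1" = 0.4),
    space = space
  )
}
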