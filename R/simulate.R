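#' Simulate one continuous-time latent path
#'
#' Standard competing-exponentials (Gillespie) sampling of a continuous-time
#' Markov chain: the holding time in state `s` is exponential with rate
#' `-Q[s, s]`, and the next state is drawn with probabilities proportional to
#' the off-diagonal intensities of row `s`. Simulation stops at the horizon or
#' on entering an absorbing state.
#'
#' @param Q Generator matrix (with state labels as dimnames).
#' @param start Starting state label.
#' @param horizon Follow-up length (years).
#' @return Tibble with columns `time` (jump times, starting at 0) and `state`
#'   (state entered at that time); the last state persists to the horizon.
#' @export
simulate_path <- function(Q, start, horizon) {
  states <- rownames(Q)
  s <- match(start, states)
  if (is.na(s)) stop("Unknown start state: ", start, call. = FALSE)
  times <- 0
  path <- s
  t <- 0
  repeat {
    rate <- -Q[s, s]
    if (rate <= 0) break
    t <- t + rexp(1, rate)
    if (t > horizon) break
    w <- Q[s, ]
    w[s] <- 0
    s <- sample.int(length(states), 1L, prob = w)
    times <- c(times, t)
    path <- c(path, s)
  }
  tibble::tibble(time = times, state = states[path])
}

#' Latent states occupied at a set of visit times
#'
#' Evaluates the right-continuous step function defined by a sample path: a
#' jump occurring exactly at a visit time reports the newly entered state.
#'
#' @param path Tibble from [simulate_path()].
#' @param visit_times Non-decreasing numeric vector of visit times within the
#'   simulation horizon.
#' @return Character vector of latent state labels, one per visit.
#' @examples
#' pth <- tibble::tibble(time = c(0, 2.5), state = c("D0", "R"))
#' panel_observe(pth, 0:8)
#' @export
panel_observe <- function(path, visit_times) {
  idx <- findInterval(visit_times, path$time)
  if (any(idx == 0)) stop("Visit before the start of the path.", call. = FALSE)
  path$state[idx]
}

#' Configuration of a simulation scenario
#'
#' Describes the data-generating design of the simulation study: a four-state
#' process (`R`, `D0`, `D1`, `D2`), annual clinic visits over an 8-year
#' follow-up, 480 subjects equally allocated to the transient states at the
#' first visit, and a subject-level binary covariate `z`, balanced within
#' each initial-state group, acting with log-hazard ratio 1 on every
#' transition except `D0 -> R`. Scenario 1 uses relatively fast baseline
#' rates (0.4/0.6 per year), so most resolution happens early; Scenario 2
#' uses slow rates (0.06/0.08), leaving little follow-up after the last
#' disability observation and making the resolution rate weakly identified
#' under partial observation.
#'
#' @param scenario `1` or `2` (chooses the baseline intensities).
#' @param n_subjects Total number of subjects (default 480), split equally
#'   across the transient initial states.
#' @param visit_times Clinic visit grid (default annual, `0:8`).
#' @param beta Log-hazard ratio of the binary covariate (default 1).
#' @param beta_on_resolution Should the covariate also act on `D0 -> R`?
#'   Default `FALSE` (the study design); `TRUE` applies it to every
#'   transition, the convention under which the analytic resolved-proportion
#'   summary is usually quoted (see the vignette).
#' @param balanced_z Assign `z` as exactly half 0 / half 1 within each
#'   initial-state group (default) rather than independent Bernoulli(1/2)
#'   draws.
#' @param resolution Include the `D0 -> R` transition in the generating
#'   process (default `TRUE`); `FALSE` gives the no-resolution process used
#'   to calibrate the boundary test.
#' @return A `scenario_config` list with the state space, true parameters and
#'   design settings.
#' @export
scenario_config <- function(scenario = 1, n_subjects = 480,
                            visit_times = 0:8, beta = 1,
                            beta_on_resolution = FALSE,
                            balanced_z = TRUE,
                            resolution = TRUE) {
  stopifnot(scenario %in% c(1, 2))
  space <- state_space(2, resolution = resolution)
  lam <- if (scenario == 1) {
    c("D0->R" = 0.4, "D0->D1" = 0.4, "D1->D0" = 0.6,
      "D1->D2" = 0.6, "D2->D1" = 0.4)
  } else {
    c("D0->R" = 0.06, "D0->D1" = 0.06, "D1->D0" = 0.08,
      "D1->D2" = 0.08, "D2->D1" = 0.06)
  }
  if (!resolution) lam <- lam[names(lam) != "D0->R"]
  covar_trans <- transition_labels(space)
  if (!beta_on_resolution) covar_trans <- setdiff(covar_trans, "D0->R")
  betas <- lapply(covar_trans, function(tr) c(z = beta))
  names(betas) <- covar_trans
  init_states <- c("D0", "D1", "D2")
  alloc <- rep(n_subjects %/% length(init_states), length(init_states))
  alloc[seq_len(n_subjects - sum(alloc))] <-
    alloc[seq_len(n_subjects - sum(alloc))] + 1L
  structure(
    list(
      scenario = scenario,
      space = space,
      params = msm_params(lam, betas, space),
      n_subjects = n_subjects,
      initial_states = init_states,
      allocation = alloc,
      visit_times = visit_times,
      horizon = max(visit_times),
      balanced_z = balanced_z,
      z_prob = 0.5
    ),
    class = "scenario_config"
  )
}

#' @exportS3Method base::print
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> Scenario ", x$scenario, ": ", x$n_subjects,
      " subjects (", paste(x$allocation, collapse = "/"),
      " starting in ", paste(x$initial_states, collapse = "/"),
      "), visits at ", paste(range(x$visit_times), collapse = ".."),
      " years\n", sep = "")
  print(x$params)
  invisible(x)
}

#' Generate one scenario dataset
#'
#' Simulates latent paths for every subject under the configured generating
#' process, records the latent state at each clinic visit, and (under the
#' partial regime) masks `R` and `D0` to the ambiguous code `"0"`. The
#' complete and partial regimes from the same seed differ only in that
#' coding.
#'
#' @param config A [scenario_config()].
#' @param regime `"partial"` (mask `R`/`D0` to `"0"`) or `"complete"`.
#' @param seed Integer seed; the dataset is deterministic given it.
#' @return List with `panel` (tibble `subject_id`, `time`, `state_code`, `z`),
#'   `paths` (tibble of true latent jump times and states, for oracle use),
#'   and the `config`, `regime`, `seed` used.
#' @export
simulate_scenario <- function(config, regime = c("partial", "complete"),
                              seed = NULL) {
  regime <- match.arg(regime)
  if (!is.null(seed)) set.seed(seed)
  space <- config$space
  subj_state <- rep(config$initial_states, config$allocation)
  n <- length(subj_state)
  z <- numeric(n)
  at <- 0
  for (g in seq_along(config$initial_states)) {
    ng <- config$allocation[g]
    zg <- if (config$balanced_z) {
      rep(c(0, 1), length.out = ng)[sample.int(ng)]
    } else {
      rbinom(ng, 1, config$z_prob)
    }
    z[at + seq_len(ng)] <- zg
    at <- at + ng
  }
  Qz <- lapply(c(0, 1), function(zz) {
    build_generator(config$params, c(z = zz), space)
  })
  panels <- vector("list", n)
  paths <- vector("list", n)
  for (i in seq_len(n)) {
    pth <- simulate_path(Qz[[z[i] + 1]], subj_state[i], config$horizon)
    st <- panel_observe(pth, config$visit_times)
    code <- if (regime == "partial") mask_resolution(st) else st
    panels[[i]] <- tibble::tibble(
      subject_id = i, time = config$visit_times, state_code = code, z = z[i]
    )
    paths[[i]] <- tibble::tibble(subject_id = i, time = pth$time,
                                 state = pth$state)
  }
  list(
    panel = dplyr::bind_rows(panels),
    paths = dplyr::bind_rows(paths),
    config = config,
    regime = regime,
    seed = seed
  )
}

#' Generate a synthetic clinic-like five-state panel dataset
#'
#' Emulates the shape of a psoriatic-arthritis disability registry: five
#' latent states (`R`, `D0`, `D1`, `D2`, `D3` for none/mild/moderate/severe
#' disability), subject-level covariates (`male`, `age_onset`, `duration`,
#' `damaged_joints`), irregular inter-visit gaps with mean about 1.5 years
#' (snapped to a 0.1-year grid, the precision of recorded visit dates), and
#' `R`/`D0` masked to code `"0"`. The generating intensities are arbitrary
#' but plausible for a slowly progressing disease; by default the only
#' non-zero covariate effect is `male` on `D1 -> D0`. This is a synthetic
#' stand-in for data shapes that cannot be redistributed; it carries the true
#' latent paths and generating parameters for recovery checks.
#'
#' @param n_subjects Number of subjects (default 597).
#' @param seed Integer seed (byte-identical output given the same seed).
#' @param lambda Named baseline intensities (per year) for the 6 transitions
#'   of the five-state space plus `D0->R`.
#' @param beta Named list of covariate effects per transition.
#' @return As [simulate_scenario()]: list with `panel`, `paths`, `params`,
#'   `space`, `seed`.
#' @export
simulate_psa_panel <- function(n_subjects = 597, seed = NULL,
                               lambda = c("D0->R" = 0.04, "D0->D1" = 0.5,
                                          "D1->D0" = 1.0, "D1->D2" = 0.9,
                                          "D2->D1" = 0.75, "D2->D3" = 0.08,
                                          "D3->D2" = 0.6),
                               beta = list("D1->D0" = c(male = 0.75))) {
  if (!is.null(seed)) set.seed(seed)
  space <- state_space(3)
  params <- msm_params(lambda, beta, space)
  covs <- param_covariates(params)
  init_probs <- c(D0 = 0.221, D1 = 0.221, D2 = 0.407, D3 = 0.151)
  panels <- vector("list", n_subjects)
  paths <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    male <- rbinom(1, 1, 0.59)
    zfull <- c(
      male = male,
      age_onset = round(rnorm(1, 36.6, 12.9), 1),
      duration = round(rgamma(1, shape = 1.12, scale = 8.2), 1),
      damaged_joints = rpois(1, rgamma(1, shape = 0.55, scale = 9))
    )
    n_vis <- min(18L, rpois(1, 4.4) + 2L)
    gaps <- round(rgamma(n_vis - 1L, shape = 3, scale = 0.5), 1)
    gaps[gaps < 0.1] <- 0.1
    visits <- cumsum(c(0, gaps))
    s0 <- sample(names(init_probs), 1, prob = init_probs)
    z <- zfull[covs]
    pth <- simulate_path(build_generator(params, z, space), s0, max(visits))
    st <- panel_observe(pth, visits)
    panels[[i]] <- tibble::tibble(
      subject_id = i, time = visits, state_code = mask_resolution(st),
      !!!as.list(zfull)
    )
    paths[[i]] <- tibble::tibble(subject_id = i, time = pth$time,
                                 state = pth$state)
  }
  list(
    panel = dplyr::bind_rows(panels),
    paths = dplyr::bind_rows(paths),
    params = params,
    space = space,
    seed = seed
  )
}
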