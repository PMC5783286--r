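sp4 <- state_space(2)
pp4 <- scenario1_params(sp4)

test_that("complete-observation likelihood matches closed forms", {
  # staying in the absorbing state has probability one
  subj <- tibble::tibble(subject_id = 1, time = c(0, 1),
                         state_code = c("R", "R"))
  expect_equal(subject_loglik_complete(subj, pp4, sp4), 0)

  # two-state chain: P(stay in D0 for 1 year) = exp(-lambda)
  sp2 <- state_space(0)
  pp2 <- msm_params(c("D0->R" = 0.4), space = sp2)
  subj2 <- tibble::tibble(subject_id = 1, time = c(0, 1),
                          state_code = c("D0", "D0"))
  expect_equal(subject_loglik_complete(subj2, pp2, sp2), -0.4)

  # leaving R is impossible
  subj3 <- tibble::tibble(subject_id = 1, time = c(0, 1),
                          state_code = c("R", "D1"))
  expect_identical(subject_loglik_complete(subj3, pp4, sp4), -Inf)

  expect_error(
    subject_loglik_complete(
      tibble::tibble(subject_id = 1, time = c(0, 1), state_code = c("0", "D1")),
      pp4, sp4),
    "unambiguous"
  )
})

test_that("partial likelihood marginalises a trailing zero over {R, D0}", {
  subj <- tibble::tibble(subject_id = 1, time = c(0, 1),
                         state_code = c("D1", "0"))
  P <- transition_matrix(build_generator(pp4, NULL, sp4), 1)
  expect_equal(subject_loglik_partial(subj, pp4, sp4),
               log(P["D1", "R"] + P["D1", "D0"]))
})

test_that("partial equals complete when all latent labels are revealed", {
  set.seed(21)
  for (i in 1:10) {
    sim <- simulate_scenario(scenario_config(1, n_subjects = 6),
                             regime = "complete", seed = i)
    subj <- dplyr::filter(sim$panel, subject_id == 1)
    expect_equal(subject_loglik_partial(subj, pp4, sp4),
                 subject_loglik_complete(subj, pp4, sp4))
  }
})

test_that("forward recursion equals brute-force enumeration", {
  set.seed(31)
  for (i in 1:25) {
    sp <- state_space(sample(1:2, 1))
    with_z <- i %% 2 == 0
    pp <- rand_params(sp, with_beta = with_z)
    subj <- rand_subject(sp, n_visits = sample(3:7, 1), with_z = with_z)
    ll <- suppressWarnings(subject_loglik_partial(subj, pp, sp))
    ll_enum <- enum_loglik(subj, pp, sp)
    if (is.finite(ll)) {
      expect_lt(abs(expm1(ll - ll_enum)), 1e-12)
    } else {
      expect_identical(ll_enum, -Inf)
    }
  }
})

test_that("compiled total log-likelihood equals the per-subject R recursion", {
  set.seed(41)
  sim <- simulate_scenario(scenario_config(1, n_subjects = 40),
                           regime = "partial", seed = 99)
  cfg <- scenario_config(1)
  by_subj <- split(sim$panel, sim$panel$subject_id)
  ll_r <- sum(vapply(by_subj, subject_loglik_partial, numeric(1),
                     params = cfg$params, space = cfg$space))
  expect_equal(total_loglik(sim$panel, cfg$params, cfg$space, "partial"),
               ll_r, tolerance = 1e-10)
  # additivity: duplicating the dataset doubles the log-likelihood
  dup <- dplyr::mutate(sim$panel, subject_id = subject_id + 1000)
  both <- dplyr::bind_rows(sim$panel, dup)
  expect_equal(total_loglik(both, cfg$params, cfg$space, "partial"),
               2 * total_loglik(sim$panel, cfg$params, cfg$space, "partial"),
               tolerance = 1e-10)
})

test_that("longer trailing runs of code 0 shift posterior weight towards resolution", {
  # posterior P(last latent state = R | observations), by enumeration
  post_resolved <- function(run_len) {
    codes <- c("D1", rep("0", run_len))
    subj <- tibble::tibble(subject_id = 1, time = seq_along(codes) - 1,
                           state_code = codes)
    sets <- lapply(codes, code_states, sp4)
    P <- transition_matrix(build_generator(pp4, NULL, sp4), 1)
    grid <- expand.grid(sets, stringsAsFactors = FALSE)
    w <- apply(grid, 1, function(x) {
      prod(P[cbind(x[-length(x)], x[-1])])
    })
    sum(w[grid[[length(codes)]] == "R"]) / sum(w)
  }
  posts <- vapply(1:6, post_resolved, numeric(1))
  expect_true(all(diff(posts) > 0))
})

test_that("assignments that leave R carry zero weight", {
  # an initial split placing all mass on R makes later disability impossible
  subj <- tibble::tibble(subject_id = 7, time = c(0, 1),
                         state_code = c("0", "D1"))
  expect_warning(
    ll <- subject_loglik_partial(subj, pp4, sp4,
                                 initial_split = c(R = 1, D0 = 0)),
    "subject 7"
  )
  expect_identical(ll, -Inf)
})

test_that("initial state term follows the clinic-referral convention and is configurable", {
  expect_equal(initial_state_term("0", sp4),
               c(R = 0, D0 = 1, D1 = 0, D2 = 0))
  expect_equal(initial_state_term("D2", sp4),
               c(R = 0, D0 = 0, D1 = 0, D2 = 1))
  expect_equal(initial_state_term("0", sp4, split = c(R = 0.1, D0 = 0.9)),
               c(R = 0.1, D0 = 0.9, D1 = 0, D2 = 0))
  expect_error(initial_state_term("0", sp4, split = c(0.5, 0.4)), "summing")
})

test_that("invalid panel data is rejected with informative errors", {
  tied <- tibble::tibble(subject_id = 1, time = c(0, 0, 1),
                         state_code = c("D1", "D1", "D1"))
  expect_error(subject_loglik_partial(tied, pp4, sp4), "strictly increasing")
  expect_error(total_loglik(tied, pp4, sp4), "strictly increasing")
  expect_error(
    total_loglik(tibble::tibble(subject_id = 1, time = 0:1,
                                state_code = c("D1", "D9")), pp4, sp4),
    "Unknown state code"
  )
  expect_error(
    total_loglik(dplyr::tibble(subject_id = integer(), time = numeric(),
                               state_code = character()), pp4, sp4),
    "empty"
  )
  one_visit <- tibble::tibble(subject_id = 1:2, time = c(0, 0),
                              state_code = c("D1", "D1"))
  expect_error(suppressWarnings(total_loglik(one_visit, pp4, sp4)),
               "two or more")
})
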