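test_that("paths start at the start state, never leave R, and jump between adjacent states only", {
  set.seed(51)
  cfg <- scenario_config(1)
  Q <- build_generator(cfg$params, c(z = 0), cfg$space)
  # absorbing start: no jumps
  expect_identical(nrow(simulate_path(Q, "R", 100)), 1L)
  sev <- function(s) {
    out <- rep(-1L, length(s))
    d <- s != "R"
    out[d] <- as.integer(sub("D", "", s[d]))
    out
  }
  for (i in 1:400) {
    pth <- simulate_path(Q, sample(c("D0", "D1", "D2"), 1), 50)
    st <- pth$state
    expect_true(all(diff(pth$time) > 0))
    if (length(st) > 1) {
      from <- st[-length(st)]
      to <- st[-1]
      expect_false(any(from == "R"))
      ok <- (from == "D0" & to == "R") |
        (abs(sev(from) - sev(to)) == 1 & from != "R" & to != "R")
      expect_true(all(ok))
    }
  }
})

test_that("holding times have the exponential mean 1/rate", {
  set.seed(61)
  sp <- state_space(0)
  pp <- msm_params(c("D0->R" = 0.4), space = sp)
  Q <- build_generator(pp, NULL, sp)
  first_jump <- replicate(20000, simulate_path(Q, "D0", 1e9)$time[2])
  se <- 2.5 / sqrt(length(first_jump))
  expect_lt(abs(mean(first_jump) - 2.5), 3 * se)
})

test_that("empirical state occupancy matches the matrix exponential", {
  set.seed(71)
  cfg <- scenario_config(1)
  Q <- build_generator(cfg$params, c(z = 0), cfg$space)
  n <- 20000
  at8 <- vapply(seq_len(n), function(i) {
    pth <- simulate_path(Q, "D1", 8)
    pth$state[nrow(pth)]
  }, character(1))
  P <- transition_matrix(Q, 8)["D1", ]
  for (s in names(P)) {
    phat <- mean(at8 == s)
    se <- sqrt(P[[s]] * (1 - P[[s]]) / n)
    expect_lt(abs(phat - P[[s]]), 3 * se + 1e-12)
  }
})

test_that("panel observation is the right-continuous step function of the path", {
  pth <- tibble::tibble(time = c(0, 2.5), state = c("D0", "R"))
  expect_identical(panel_observe(pth, 0:8),
                   c("D0", "D0", "D0", rep("R", 6)))
  # a jump exactly at a visit reports the newly entered state
  pth2 <- tibble::tibble(time = c(0, 3), state = c("D0", "D1"))
  expect_identical(panel_observe(pth2, 0:4), c("D0", "D0", "D0", "D1", "D1"))
  const <- tibble::tibble(time = 0, state = "D2")
  expect_identical(panel_observe(const, c(0, 1.5, 7)), rep("D2", 3))
})

test_that("scenario datasets have the configured design", {
  cfg <- scenario_config(1)
  sim <- simulate_scenario(cfg, regime = "partial", seed = 3)
  panel <- sim$panel
  expect_identical(length(unique(panel$subject_id)), 480L)
  expect_identical(nrow(panel), 480L * 9L)
  first <- dplyr::slice_min(dplyr::group_by(panel, subject_id), time, n = 1)
  # 160 subjects start in each transient state; the first visit shows D0 as "0"
  expect_equal(unname(table(first$state_code)[c("0", "D1", "D2")]),
               rep(160L, 3), ignore_attr = TRUE)
  # the binary covariate is balanced exactly within each initial-state group
  z_by_group <- tapply(first$z, first$state_code, sum)
  expect_equal(unname(z_by_group), rep(80, 3), ignore_attr = TRUE)
  # masking leaves no latent labels behind
  expect_false(any(panel$state_code %in% c("R", "D0")))
  # observed sequences never show disability after the latent path resolves
  paths <- sim$paths
  resolved_at <- tapply(seq_len(nrow(paths)), paths$subject_id, function(ix) {
    tR <- paths$time[ix][paths$state[ix] == "R"]
    if (length(tR)) tR else Inf
  })
  after <- panel[panel$time >= unname(resolved_at[as.character(panel$subject_id)]), ]
  expect_true(all(after$state_code == "0"))
})

test_that("complete and partial regimes from one seed differ only in the masking", {
  cfg <- scenario_config(2, n_subjects = 90)
  a <- simulate_scenario(cfg, regime = "complete", seed = 12)
  b <- simulate_scenario(cfg, regime = "partial", seed = 12)
  expect_identical(mask_resolution(a$panel$state_code), b$panel$state_code)
  expect_identical(a$panel[, c("subject_id", "time", "z")],
                   b$panel[, c("subject_id", "time", "z")])
  expect_identical(a$paths, b$paths)
})

test_that("the synthetic clinic panel has the documented shape and is reproducible", {
  sim <- simulate_psa_panel(n_subjects = 120, seed = 8)
  panel <- sim$panel
  expect_identical(length(unique(panel$subject_id)), 120L)
  expect_true(all(table(panel$subject_id) >= 2))
  expect_true(all(panel$state_code %in% c("0", "D1", "D2", "D3")))
  expect_true(all(c("male", "age_onset", "duration", "damaged_joints")
                  %in% names(panel)))
  # irregular visit gaps with mean around 1.5 years
  gaps <- unlist(tapply(panel$time, panel$subject_id, diff))
  expect_gt(mean(gaps), 1.2)
  expect_lt(mean(gaps), 1.8)
  # byte-identical CSV under the same seed
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_panel_csv(simulate_psa_panel(n_subjects = 40, seed = 99)$panel, f1)
  write_panel_csv(simulate_psa_panel(n_subjects = 40, seed = 99)$panel, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("fitting the five-state model to a large synthetic clinic panel recovers the generating parameters", {
  sim <- simulate_psa_panel(n_subjects = 1200, seed = 2024)
  fit <- fit_resolution_msm(sim$panel, sim$space, sim$params,
                            regime = "partial")
  expect_true(fit$converged)
  td <- tidy(fit)
  truth <- c(exp(sim$params$log_lambda), unlist(sim$params$beta, use.names = FALSE))
  # every parameter within 2 standard errors of its generating value
  # (baselines compared on the log scale, where the SE lives)
  work_truth <- c(sim$params$log_lambda, unlist(sim$params$beta, use.names = FALSE))
  expect_true(all(abs(unname(fit$theta) - unname(work_truth)) <=
                    2 * td$std.error))
})
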