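test_that("utility functions reproduce the worked example", {
  expect_equal(round(utility_gain(12, 0.5, 0.8), 2), 3.65)
  expect_equal(round(utility_loss(-10, 0.5, 0.8, 1.5), 2), -4.73)
  expect_equal(utility_gain(0, 1, 0.8), 0)
  expect_equal(utility_loss(0, 0.5, 0.8, 1.5), 0)
})

test_that("utility identities and domain errors hold", {
  x <- c(0.5, 3, 17.25)
  expect_equal(utility_gain(x, 0.7, 1), 0.7 * x)
  # lambda = 1 makes losses mirror gains
  expect_equal(utility_loss(-x, 0.5, 0.8, 1), -utility_gain(x, 0.5, 0.8))
  expect_error(utility_gain(-1, 0.5, 0.8), "utility_loss")
  expect_error(utility_loss(1, 0.5, 0.8, 1.5), "utility_gain")
  expect_error(utility_gain(5, 1.4, 0.8), "\\[0, 1\\]")
})

test_that("p_accept follows the softmax rule and its limits", {
  tr <- tibble::tibble(risky_gain = 12, risky_loss = -10, guaranteed = 0)
  # hand evaluation: logistic(mu * (3.6502 - 4.7322 - db))
  du <- utility_gain(12, 0.5, 0.8) + utility_loss(-10, 0.5, 0.8, 1.5)
  expect_equal(p_accept(tr, pt_params(0.8, 1.5, 1, 0)),
               1 / (1 + exp(-du)))
  # mu = 0: full randomness
  expect_equal(p_accept(tr, pt_params(0.8, 1.5, 0, 0)), 0.5)
  # zero net advantage minus bias: midpoint
  expect_equal(p_accept(tr, pt_params(0.8, 1.5, 3, du)), 0.5)
})

test_that("p_accept is monotone in loss aversion and decision bias", {
  tr <- tibble::tibble(risky_gain = c(8, 12), risky_loss = c(-4, -10),
                       guaranteed = 0)
  lams <- c(1, 1.5, 2.5)
  p_by_lam <- sapply(lams, function(l) p_accept(tr, pt_params(0.8, l, 2, 0)))
  expect_true(all(diff(t(p_by_lam)[, 1]) < 0))
  expect_true(all(diff(t(p_by_lam)[, 2]) < 0))
  dbs <- c(-1, 0, 1)
  p_by_db <- sapply(dbs, function(b) p_accept(tr, pt_params(0.8, 1.5, 2, b)))
  expect_true(all(apply(p_by_db, 1, diff) < 0))
})

test_that("reflection: rho below 1 discourages gain-only gambles and the
           direction reverses for pure loss gambles", {
  gains <- tibble::tibble(risky_gain = 10, risky_loss = 0, guaranteed = 4)
  p_lowrho <- p_accept(gains, pt_params(0.5, 1.5, 1, 0))
  p_unit <- p_accept(gains, pt_params(1, 1.5, 1, 0))
  expect_lt(p_lowrho, p_unit)
  losses <- tibble::tibble(risky_gain = 0, risky_loss = -10, guaranteed = -4)
  expect_gt(p_accept(losses, pt_params(0.5, 1.5, 1, 0)),
            p_accept(losses, pt_params(1, 1.5, 1, 0)))
})

test_that("scale_outcome is the linear map onto [0, 1]", {
  expect_equal(scale_outcome(-24, -24, 30), 0)
  expect_equal(scale_outcome(30, -24, 30), 1)
  expect_equal(scale_outcome(3, -24, 30), 0.5)
  expect_error(scale_outcome(31, -24, 30), "outside")
  expect_error(scale_outcome(0, 5, 5), "out_min")
})

test_that("update_step applies the additive rule with support floor", {
  expect_equal(as.numeric(update_step(1.57, 1, 0.01)), 1.58)
  expect_equal(as.numeric(update_step(2.2, 0, 0.5)), 2.2)
  expect_equal(as.numeric(update_step(2.2, 0.7, 0)), 2.2)
  floored <- update_step(0.005, 1, -0.05)
  expect_equal(as.numeric(floored), 1e-6)
  expect_true(attr(floored, "floored"))
  unbounded <- update_step(-0.4, 1, -0.5, floor_at = -Inf)
  expect_equal(as.numeric(unbounded), -0.9)
})

test_that("trajectories follow the additive dynamics exactly", {
  pars <- pt_params(0.65, 1.57, 22.2, -0.58)
  zero <- pt_trajectory(c(5, -3, 8, 0), pars, pt_deltas())
  expect_equal(zero$lam, rep(1.57, 4))
  expect_equal(zero$mu, rep(22.2, 4))

  out <- c(10, -5, 3, 7, -2)
  tr <- pt_trajectory(out, pars, pt_deltas(d_lam = 0.01), bounds = c(-24, 30))
  # nondecreasing because scaled outcomes are nonnegative
  expect_true(all(diff(tr$lam) >= 0))
  # exact per-step increments
  s <- scale_outcome(out, -24, 30)
  expect_equal(diff(tr$lam), 0.01 * s[-length(s)])
  # additivity: permuting the feeding outcomes leaves the endpoint fixed
  tr2 <- pt_trajectory(out[c(3, 1, 4, 2, 5)], pars, pt_deltas(d_lam = 0.01),
                       bounds = c(-24, 30))
  expect_equal(tr$lam[5], tr2$lam[5])
})

test_that("choice_loglik matches a naive per-trial product and its limits", {
  sim <- small_cohort()
  one <- dplyr::filter(sim$trials, participant_id == "P1")
  pars <- pt_params(0.7, 1.6, 8, -0.3)
  dls <- pt_deltas(0.004, 0.012, 0.06, 0.02)
  b <- outcome_bounds(one)
  expect_equal(choice_loglik(one, pars, dls, b),
               naive_choice_loglik(one, pars, dls, b), tolerance = 1e-10)
  # mu = 0: every trial contributes log(0.5)
  expect_equal(choice_loglik(one, pt_params(0.7, 1.6, 0, 0), pt_deltas(), b),
               nrow(one) * log(0.5))
  expect_lte(choice_loglik(one, pars, dls, b), 0)
  expect_error(choice_loglik(sim$trials, pars, dls), "single participant")
})

test_that("finite-difference gradient of choice_loglik is stable across
           step sizes", {
  sim <- small_cohort(2, 40, seed = 7)
  one <- dplyr::filter(sim$trials, participant_id == "P1")
  b <- outcome_bounds(one)
  f <- function(th) {
    choice_loglik(one, pt_params(th[1], th[2], th[3], th[4]),
                  pt_deltas(th[5], th[6], th[7], th[8]), b)
  }
  th0 <- c(0.7, 1.5, 4, -0.2, 0.003, 0.01, 0.04, 0.015)
  for (j in seq_along(th0)) {
    fd <- sapply(c(1e-4, 1e-5), function(h) {
      tp <- th0; tm <- th0
      tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
      (f(tp) - f(tm)) / (2 * h)
    })
    expect_equal(fd[1], fd[2], tolerance = 1e-3)
  }
})

test_that("the interventional lag-1 effect of a previous outcome on the
           next choice is negative at the group-mean dynamics", {
  tr <- generate_trials(40, 2 / 3, seed = 3)
  b <- c(-24, 30)
  pars <- pt_params(0.65, 1.57, 22.2, -0.58)
  dls <- pt_deltas(0.005, 0.013, 0.08, 0.03)
  hist_out <- simulate_participant(tr, pars, dls, seed = 5, bounds = b)$outcome
  p_next <- function(forced) {
    o <- hist_out
    o[20] <- forced
    traj <- pt_trajectory(o, pars, dls, bounds = b)
    p_accept(tr[21, ], traj[21, c("rho", "lam", "mu", "db")])
  }
  # larger previous outcomes push every updating channel against gambling
  expect_lt(p_next(20), p_next(-20))
  expect_lt((qlogis(p_next(20)) - qlogis(p_next(-20))) / 40, 0)
})
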