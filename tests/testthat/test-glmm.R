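test_that("design matrices encode the lagged regressors correctly", {
  sim <- small_cohort(4, 30, seed = 12)
  d1 <- build_design(sim$trials, 1)
  d7 <- build_design(sim$trials, 7)

  # one dropped leading trial per participant for lag-1 models
  expect_equal(attr(d1, "n_excluded"), 4)
  expect_equal(attr(d7, "n_excluded"), 4)

  # nesting identity behind the likelihood-ratio test: the three
  # type-specific columns sum to the single previous-outcome column
  type_sum <- d7$prev_out_risky_gain + d7$prev_out_risky_loss +
    d7$prev_out_guaranteed
  expect_equal(type_sum, d1$prev_outcome)
  # each row contributes to exactly one type column (amount-0 rows aside)
  nz <- (d7$prev_out_risky_gain != 0) + (d7$prev_out_risky_loss != 0) +
    (d7$prev_out_guaranteed != 0)
  expect_true(all(nz <= 1))

  # M5 keeps rows with three valid lags
  d5 <- build_design(sim$trials, 5)
  expect_equal(attr(d5, "n_excluded"), 12)
  expect_equal(nrow(d5), nrow(sim$trials) - 12)

  # M6 valence: sign of the previous outcome, zero stays zero
  d6 <- build_design(sim$trials, 6)
  expect_equal(d6$prev_valence, sign(d6$prev_outcome))

  # M2/M8 previous-decision coding is +1 gamble / -1 guaranteed
  d2 <- build_design(sim$trials, 2)
  expect_true(all(d2$prev_choice %in% c(-1, 1)))

  # M3 mean EV of the previous options
  d3 <- build_design(sim$trials, 3)
  trail <- dplyr::group_by(sim$trials, participant_id) |>
    dplyr::mutate(ev = dplyr::lag((0.5 * risky_gain + 0.5 * risky_loss +
                                     guaranteed) / 2)) |>
    dplyr::ungroup()
  expect_equal(d3$prev_mean_ev, trail$ev[!is.na(trail$ev)])

  expect_error(build_design(sim$trials, 10), "1..9")
})

test_that("design coding survives the CSV round trip", {
  sim <- small_cohort(3, 20, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_trials(sim$trials, path)
  back <- read_trials(path)
  for (mid in c(1, 6, 7, 8)) {
    expect_equal(as.data.frame(build_design(back, mid)),
                 as.data.frame(build_design(sim$trials, mid)))
  }
  unlink(path)
})

test_that("fit_glmm recovers known coefficients from a random-intercept
           logistic generator", {
  # data generated directly from the model fit_glmm assumes
  set.seed(21)
  n_sub <- 30; n_tr <- 80
  beta <- c(intercept = -0.4, risky_gain = 0.25, risky_loss = 0.2,
            guaranteed = -0.3, prev_outcome = -0.05)
  rows <- purrr::map_dfr(seq_len(n_sub), function(i) {
    b0 <- rnorm(1, 0, 1)
    g <- runif(n_tr, 2, 12); l <- -runif(n_tr, 1, 10); gu <- runif(n_tr, 0, 6)
    prev <- runif(n_tr, -10, 10)
    eta <- beta[1] + b0 + beta[2] * g + beta[3] * l + beta[4] * gu +
      beta[5] * prev
    tibble::tibble(participant_id = paste0("S", i), trial_index = 1:n_tr,
                   trial_type = "gain_loss", risky_gain = g, risky_loss = l,
                   guaranteed = gu, choice = rbinom(n_tr, 1, plogis(eta)),
                   outcome = prev)
  })
  # lag structure: shift outcome so prev_outcome reproduces `prev`
  rows <- dplyr::group_by(rows, participant_id) |>
    dplyr::mutate(outcome = dplyr::lead(outcome, default = 0)) |>
    dplyr::ungroup()
  fit <- fit_glmm(build_design(rows, 1))
  est <- tidy(fit)
  expect_equal(nrow(est), 5)
  for (k in 2:5) {
    expect_lt(abs(est$estimate[k] - beta[k]), 3 * est$std_error[k])
  }
  expect_gt(fit$sigma_intercept, 0.5)
  expect_lt(fit$sigma_intercept, 1.6)
  expect_lte(fit$loglik, 0)
  expect_true(all(tidy(fit)$std_error > 0))
})

test_that("model ranking orders by log-likelihood with stable ties", {
  mk <- function(id, ll) structure(list(model_id = id, loglik = ll, df = 6),
                                   class = "pt_glmm")
  rk <- compare_loglik(list(mk(1, -120), mk(2, -150), mk(3, -120)))
  expect_equal(rk$model_id, c(1, 3, 2))
  expect_equal(rk$rank, 1:3)
  bad <- list(mk(1, -120), structure(list(model_id = 4, loglik = -100,
                                          df = 8), class = "pt_glmm"))
  expect_error(compare_loglik(bad), "parameter counts")
})

test_that("likelihood-ratio arithmetic matches the chi-square survival
           function", {
  mk <- function(ll, df) structure(list(model_id = 1, loglik = ll, df = df),
                                   class = "pt_glmm")
  # printed comparison: statistic 1.17 on 2 df is non-significant
  res <- lrt(mk(-10639.085, 6), mk(-10638.5, 8))
  expect_equal(res$statistic, 1.17, tolerance = 1e-6)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, pchisq(1.17, 2, lower.tail = FALSE))
  expect_equal(round(res$p_value, 2), 0.56)

  same <- lrt(mk(-100, 6), mk(-100, 6))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(lrt(mk(-101.92, 6), mk(-100, 7))$p_value, 0.05,
               tolerance = 1e-3)
  expect_error(lrt(mk(-90, 6), mk(-100, 8)), "worse")

  # monotone: larger statistics give smaller p
  stats <- seq(0.5, 12, by = 0.5)
  ps <- pchisq(stats, 2, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))
})

test_that("Wald equality test follows its closed form", {
  res <- structure(list(
    model_id = 7,
    coefficients = tibble::tibble(term = c("a", "b"),
                                  estimate = c(0.5, 0.1),
                                  std_error = c(0.1, 0.1)),
    vcov = matrix(c(0.01, 0.002, 0.002, 0.01), 2, 2,
                  dimnames = list(c("a", "b"), c("a", "b")))
  ), class = "pt_glmm")
  w <- wald_equality(res, "a", "b")
  expect_equal(w$statistic, 0.4^2 / (0.01 + 0.01 - 2 * 0.002))
  expect_equal(w$p_value, pchisq(w$statistic, 1, lower.tail = FALSE))

  res$coefficients$estimate <- c(0.3, 0.3)
  expect_equal(wald_equality(res, "a", "b")$statistic, 0)
  expect_equal(wald_equality(res, "a", "b")$p_value, 1)
  expect_error(wald_equality(res, "a", "zz"), "not found")
})

test_that("indifference probabilities and loss-weight illustrations", {
  expect_equal(round(100 * indifference_probability(-0.03, 20)), 35)
  expect_equal(round(100 * indifference_probability(-0.03, -20)), 65)
  expect_equal(indifference_probability(-0.03, 0), 0.5)
  expect_equal(indifference_probability(0, c(-5, 5)), c(0.5, 0.5))

  w <- loss_weight_illustration(0.395, 0.00325, c(-20, 0, 20))
  expect_equal(w$loss_weight[2], 0.395)
  expect_equal(w$loss_weight[3] - w$loss_weight[1], 0.00325 * 40)
  flat <- loss_weight_illustration(0.4, 0, c(-20, 20))
  expect_equal(flat$loss_weight, c(0.4, 0.4))
})
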