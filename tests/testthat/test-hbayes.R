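test_that("log_joint matches an independent scalar evaluation on a tiny
           fixture", {
  trials <- tibble::tibble(
    participant_id = "P1", trial_index = 1:2, trial_type = "gain_loss",
    risky_gain = c(10, 6), risky_loss = c(-5, -3), guaranteed = 0,
    choice = c(1L, 0L), outcome = c(10, 0)
  )
  z <- matrix(c(log(0.8), log(1.5), log(2), -0.2, 0.01, 0.02, 0.03, 0.01),
              1, 8)
  group <- list(mean = rep(0.1, 8), sd = rep(0.5, 8))
  pr <- pt_priors()

  # scalar re-computation with plain R arithmetic
  b <- c(-5, 10)
  th <- c(0.8, 1.5, 2, -0.2)
  p1 <- plogis(th[3] * ((0.5 * 10^th[1] - 0.5 * th[2] * 5^th[1]) - 0 - th[4]))
  s1 <- (10 - b[1]) / (b[2] - b[1])
  th2 <- c(th[1] + s1 * 0.01, th[2] + s1 * 0.02, th[3] + s1 * 0.03,
           th[4] + s1 * 0.01)
  p2 <- plogis(th2[3] * ((0.5 * 6^th2[1] - 0.5 * th2[2] * 3^th2[1]) - 0 -
                           th2[4]))
  lik <- log(p1) + log(1 - p2)
  hier <- sum(dnorm(z[1, ], 0.1, 0.5, log = TRUE))
  prior_m <- sum(dnorm(rep(0.1, 8), pr$mean_loc, pr$mean_scale, log = TRUE))
  prior_s <- sum(dcauchy(rep(0.5, 8), 0, 1, log = TRUE) + log(2))
  expect_equal(log_joint(group, z, trials, pr),
               lik + hier + prior_m + prior_s, tolerance = 1e-10)
})

test_that("with broad group priors, log_joint differences reduce to
           likelihood differences", {
  sim <- small_cohort(1, 20, seed = 31)
  one <- sim$trials
  wide <- pt_priors(mean_scale = stats::setNames(rep(1e6, 8),
                                                 dynpt:::.pt_par_names))
  group <- list(mean = rep(0, 8), sd = rep(1e6, 8))
  za <- matrix(c(log(0.7), log(1.4), log(5), -0.3, 0, 0, 0, 0), 1, 8)
  zb <- matrix(c(log(0.9), log(1.8), log(9), 0.1, 0, 0, 0, 0), 1, 8)
  d_joint <- log_joint(group, za, one, wide) - log_joint(group, zb, one, wide)
  b <- outcome_bounds(one)
  d_lik <- choice_loglik(one, pt_params(0.7, 1.4, 5, -0.3), pt_deltas(), b) -
    choice_loglik(one, pt_params(0.9, 1.8, 9, 0.1), pt_deltas(), b)
  expect_equal(d_joint, d_lik, tolerance = 1e-6)
})

test_that("unconstrained/constrained maps are mutual inverses", {
  th <- c(rho = 0.65, lam = 1.57, mu = 22.2, db = -0.58,
          d_rho = 0.005, d_lam = 0.013, d_mu = 0.08, d_db = 0.03)
  expect_equal(dynpt:::constrain_params(dynpt:::unconstrain_params(th)), th,
               tolerance = 1e-10)
  z <- c(rho = -0.2, lam = 0.4, mu = 3, db = 0.1,
         d_rho = 0, d_lam = 0.01, d_mu = -0.05, d_db = 0.2)
  expect_equal(dynpt:::unconstrain_params(dynpt:::constrain_params(z)), z,
               tolerance = 1e-10)
})

test_that("split-chain Rhat matches a hand-computed formula and detects
           non-mixing", {
  # fixture with known split-half means/variances
  draws <- cbind(c(1, 2, 3, 4, 2, 3, 4, 5), c(2, 3, 4, 5, 3, 4, 5, 6))
  splits <- cbind(draws[1:4, ], draws[5:8, ])
  W <- mean(apply(splits, 2, var))
  B <- 4 * var(colMeans(splits))
  expect_equal(rhat(draws, NULL), sqrt((3 / 4 * W + B / 4) / W))

  set.seed(1)
  mixed <- matrix(rnorm(4000), 1000, 4)
  expect_lt(rhat(mixed, NULL), 1.01)
  expect_gte(rhat(mixed, NULL), 1 - 1e-8)
  stuck <- cbind(rnorm(100, 0, 0.01), rnorm(100, 10, 0.01))
  expect_gt(rhat(stuck, NULL), 5)
  expect_error(rhat(matrix(1:10, 10, 1), NULL), "2 chains")
})

test_that("effective sample size matches i.i.d. and AR(1) oracles", {
  set.seed(2)
  iid <- matrix(rnorm(10000), 2500, 4)
  expect_lt(abs(effective_samples(iid, NULL) - 10000) / 10000, 0.15)

  phi <- 0.6
  ar1 <- sapply(1:2, function(ch) {
    x <- numeric(5000)
    x[1] <- rnorm(1)
    for (t in 2:5000) x[t] <- phi * x[t - 1] + rnorm(1, 0, sqrt(1 - phi^2))
    x
  })
  ess <- effective_samples(ar1, NULL)
  theory <- 10000 * (1 - phi) / (1 + phi)
  expect_lt(abs(ess - theory) / theory, 0.15)
  # cross-check against an independent implementation
  coda_ess <- sum(apply(ar1, 2, function(x) coda::effectiveSize(coda::mcmc(x))))
  expect_lt(abs(ess - coda_ess) / coda_ess, 0.25)

  expect_warning(out <- effective_samples(matrix(1, 50, 2), NULL),
                 "degenerate")
  expect_true(is.na(out))
})

test_that("95% credible intervals and the exclude-zero rule", {
  set.seed(3)
  sym <- matrix(rnorm(4000), 2000, 2)
  ci <- ci95(sym, "x")
  expect_false(ci$excludes_zero)
  expect_equal(ci$low, quantile(as.vector(sym), 0.025), ignore_attr = TRUE)
  pos <- matrix(abs(rnorm(1000)) + 0.01, 500, 2)
  expect_true(ci95(pos, "x")$excludes_zero)
  expect_error(ci95(matrix(1:20, 10, 2), "x"), "100")
})

test_that("sampler reproduces the closed-form posterior on a conjugate
           normal hierarchy", {
  set.seed(7)
  n <- 12
  y <- rnorm(n, 1.5, sqrt(2))
  trials <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:n), trial_index = 1L,
    trial_type = "gain_loss", risky_gain = 10, risky_loss = -5,
    guaranteed = 0, choice = 1L, outcome = pmin(pmax(y, -5), 10)
  )
  y <- trials$outcome
  normal_lik <- function(z, pd) dnorm(pd$raw$outcome[1], z[4], 1, log = TRUE)
  attr(normal_lik, "no_gradient") <- TRUE
  post <- run_mcmc(trials, n_chains = 2, n_draws = 1500, burn_in = 500,
                   seed = 5, loglik = normal_lik,
                   fix_group_sd = rep(1, 8))
  d <- as.vector(posterior_draws(post, "mean_db"))
  prec <- n / 2 + 1
  exact_mean <- (sum(y) / 2) / prec
  exact_sd <- sqrt(1 / prec)
  mc_se <- sd(d) / sqrt(effective_samples(post, "mean_db"))
  expect_lt(abs(mean(d) - exact_mean), 4 * mc_se)
  expect_lt(abs(sd(d) - exact_sd) / exact_sd, 0.2)

  # shrinkage: each individual's posterior mean lies between its own
  # observation and the group mean estimate (conjugate midpoint)
  for (pid in c("P01", "P05")) {
    zi <- mean(posterior_draws(post, paste0(pid, ".db")))
    yi <- y[match(pid, trials$participant_id)]
    expect_true((zi - yi) * (zi - exact_mean) <= 0)
  }
})

test_that("with the likelihood disabled, group-mean marginals reproduce
           their priors", {
  trials <- tibble::tibble(
    participant_id = sprintf("P%d", 1:6), trial_index = 1L,
    trial_type = "gain_loss", risky_gain = 10, risky_loss = -5,
    guaranteed = 0, choice = 1L, outcome = 0
  )
  no_lik <- function(z, pd) 0
  attr(no_lik, "no_gradient") <- TRUE
  post <- run_mcmc(trials, n_chains = 2, n_draws = 3000, burn_in = 500,
                   seed = 9, loglik = no_lik)
  pr <- pt_priors()
  for (par in c("rho", "db")) {
    d <- as.vector(posterior_draws(post, paste0("mean_", par)))
    d <- d[seq(1, length(d), by = 5)]
    ks <- suppressWarnings(
      ks.test(d, "pnorm", pr$mean_loc[[par]], pr$mean_scale[[par]]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("short PT+ runs are reproducible, respect supports, and retain
           finite-density draws", {
  sim <- small_cohort(5, 30, seed = 17)
  a <- run_mcmc(sim$trials, n_chains = 2, n_draws = 120, burn_in = 60,
                seed = 3)
  b <- run_mcmc(sim$trials, n_chains = 2, n_draws = 120, burn_in = 60,
                seed = 3)
  expect_identical(a$chains[[1]]$mean, b$chains[[1]]$mean)
  expect_equal(a$n_kept, 60)
  # back-transformed draws respect supports
  expect_true(all(exp(posterior_draws(a, "mean_rho")) > 0))
  expect_true(all(posterior_draws(a, "sd_lam") > 0))
  expect_true(all(is.finite(a$chains[[1]]$individuals)))
  # a retained draw has finite joint density
  lj <- log_joint(list(mean = a$chains[[1]]$mean[60, ],
                       sd = a$chains[[1]]$sd[60, ]),
                  a$chains[[1]]$individuals[60, , ], sim$trials)
  expect_true(is.finite(lj))
  expect_error(run_mcmc(sim$trials, n_chains = 1, n_draws = 100,
                        burn_in = 10, seed = 1), "n_chains")
  expect_error(run_mcmc(sim$trials, n_chains = 2, n_draws = 100,
                        burn_in = 100, seed = 1), "burn_in")
})
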