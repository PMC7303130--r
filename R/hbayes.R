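# Hierarchical Bayesian estimation of the 8-parameter dynamic PT+ model.
#
# Sampling scale: individual-level parameters live on an unconstrained
# vector z = (log rho, log lam, log mu, db, d_rho, d_lam, d_mu, d_db);
# individual z's are normal around group-level means/SDs on that scale, so
# any draw respects the supports after back-transformation.

.pt_par_names <- c("rho", "lam", "mu", "db", "d_rho", "d_lam", "d_mu", "d_db")

#' Prior configuration for the hierarchical PT+ model
#'
#' Group-level means get independent normal priors on the unconstrained
#' scale (log scale for `rho`, `lam`, `mu`), centered at canonical values
#' with broad scales; group-level SDs get half-Cauchy priors. All pieces are
#' overridable.
#'
#' @param mean_loc,mean_scale Location/scale of the normal priors on the
#'   eight group means (unconstrained scale), named vectors to override.
#' @param sd_scale Half-Cauchy scale for the eight group SDs.
#' @return A list of class `pt_priors`.
#' @examples
#' pt_priors()
#' @export
pt_priors <- function(mean_loc = NULL, mean_scale = NULL, sd_scale = NULL) {
  loc <- stats::setNames(c(log(0.8), log(1.5), log(10), 0, 0, 0, 0, 0),
                         .pt_par_names)
  scl <- stats::setNames(c(1, 1, 2, 1, 1, 1, 1, 1), .pt_par_names)
  A <- stats::setNames(rep(1, 8), .pt_par_names)
  if (!is.null(mean_loc)) loc[names(mean_loc)] <- mean_loc
  if (!is.null(mean_scale)) scl[names(mean_scale)] <- mean_scale
  if (!is.null(sd_scale)) A[names(sd_scale)] <- sd_scale
  if (any(scl <= 0) || any(A <= 0)) stop("prior scales must be > 0", call. = FALSE)
  structure(list(mean_loc = loc, mean_scale = scl, sd_scale = A),
            class = "pt_priors")
}

# Split a trial table into per-participant lists consumed by the likelihood.
# Outcome scaling bounds are computed once over the whole dataset.
prep_mcmc_data <- function(trials) {
  check_choice_columns(trials)
  stopifnot(all(c("participant_id", "choice", "outcome") %in% names(trials)))
  bounds <- outcome_bounds(trials)
  split_idx <- split(seq_len(nrow(trials)), trials$participant_id)
  pdata <- lapply(split_idx, function(ix) {
    d <- trials[ix, ]
    if ("trial_index" %in% names(d)) d <- d[order(d$trial_index), ]
    list(gain = d$risky_gain, loss = d$risky_loss, guar = d$guaranteed,
         choice = as.integer(d$choice),
         s = scale_outcome(d$outcome, bounds[[1]], bounds[[2]]),
         raw = d)
  })
  list(pdata = pdata, bounds = bounds, ids = names(split_idx))
}

# Default per-participant log-likelihood on the unconstrained scale.
pt_loglik_unc <- function(z, pd) {
  cpp_choice_loglik(pd$gain, pd$loss, pd$guar, pd$choice, pd$s,
                    exp(z[1]), exp(z[2]), exp(z[3]), z[4],
                    z[5], z[6], z[7], z[8], .pt_floor_eps)
}

#' Joint log density of the hierarchical PT+ model
#'
#' Sum of (a) each participant's choice log-likelihood under the dynamic
#' PT+ model, (b) normal densities of the individual unconstrained
#' parameters around the group means/SDs, and (c) the priors on the group
#' means (normal) and SDs (half-Cauchy). Useful for direct checks and as
#' the target density of the sampler.
#'
#' @param group List with `mean` and `sd`: length-8 vectors on the
#'   unconstrained scale (SDs positive).
#' @param individuals n x 8 matrix of unconstrained individual parameters.
#' @param trials Trial records (CSV schema) for the same participants, in
#'   the row order of `individuals`' participants (sorted ids).
#' @param priors A [pt_priors()] configuration.
#' @param loglik Per-participant log-likelihood `function(z, pdata)`;
#'   defaults to the PT+ choice likelihood.
#' @return Scalar log density; an informative error names the offending
#'   component if any piece is non-finite.
#' @export
log_joint <- function(group, individuals, trials, priors = pt_priors(),
                      loglik = NULL) {
  if (is.null(loglik)) loglik <- pt_loglik_unc
  prep <- prep_mcmc_data(trials)
  n <- length(prep$pdata)
  stopifnot(nrow(individuals) == n, ncol(individuals) == 8,
            length(group$mean) == 8, length(group$sd) == 8,
            all(group$sd > 0))
  ll <- sum(vapply(seq_len(n),
                   function(i) loglik(individuals[i, ], prep$pdata[[i]]),
                   numeric(1)))
  if (!is.finite(ll)) stop("non-finite choice log-likelihood", call. = FALSE)
  lp_ind <- sum(stats::dnorm(t(individuals), group$mean, group$sd, log = TRUE))
  if (!is.finite(lp_ind)) stop("non-finite individual-level density", call. = FALSE)
  lp_mean <- sum(stats::dnorm(group$mean, priors$mean_loc, priors$mean_scale,
                              log = TRUE))
  A <- priors$sd_scale
  lp_sd <- sum(log(2) - log(pi) - log(A) - log1p((group$sd / A)^2))
  if (!is.finite(lp_mean + lp_sd)) stop("non-finite group-level prior density",
                                        call. = FALSE)
  ll + lp_ind + lp_mean + lp_sd
}

rinvgamma1 <- function(shape, rate) 1 / stats::rgamma(1, shape, rate = rate)

#' Sample the hierarchical PT+ posterior by MCMC
#'
#' Adaptive Metropolis-within-Gibbs sampler for the joint posterior over
#' group-level means/SDs and individual-level parameters:
#' single-site Gaussian random-walk updates (step sizes adapted during
#' burn-in toward 44% acceptance) for each individual's unconstrained
#' parameters; conjugate Gibbs updates for the group means; parameter-
#' expanded Gibbs updates for the half-Cauchy group SDs; and, per
#' coordinate, a joint translation move that shifts a group mean together
#' with all its individual values (keeping the hierarchy term fixed), which
#' maintains mixing when a coordinate is only weakly informed by the data.
#'
#' @param trials Multi-participant trial records (CSV schema).
#' @param priors [pt_priors()].
#' @param n_chains Number of chains, >= 2.
#' @param n_draws Total iterations per chain (including burn-in).
#' @param burn_in Iterations discarded per chain, < `n_draws`.
#' @param seed Integer seed; fixes all chains' randomness.
#' @param loglik Optional replacement per-participant log-likelihood
#'   `function(z, pdata)` (test hook; the default is the PT+ choice
#'   likelihood).
#' @param fix_group_sd Optional length-8 vector fixing the group SDs
#'   (skips their Gibbs update).
#' @param sweeps Kernel cycles applied per recorded draw (internal
#'   thinning; higher values lower autocorrelation at proportional cost).
#' @param sweeps_burn Kernel cycles per burn-in draw (defaults to the
#'   sampling intensity).
#' @return An object of class `pt_posterior` holding per-chain draw
#'   matrices for the group means (`mean_<par>`), group SDs (`sd_<par>`)
#'   and individual parameters, plus run metadata.
#' @export
run_mcmc <- function(trials, priors = pt_priors(), n_chains = 4,
                     n_draws = 1500, burn_in = 500, seed = 1,
                     loglik = NULL, fix_group_sd = NULL, sweeps = 3,
                     sweeps_burn = sweeps) {
  if (n_chains < 2) stop("`n_chains` must be >= 2", call. = FALSE)
  if (burn_in >= n_draws) stop("`burn_in` must be < `n_draws`", call. = FALSE)
  if (is.null(loglik)) loglik <- pt_loglik_unc
  prep <- prep_mcmc_data(trials)
  n <- length(prep$pdata)
  chain_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, n_chains))
  z_mode <- init_individual_modes(prep$pdata, priors, loglik)
  # the mass matrix and step size are adapted on the first chain and
  # shared with the rest (cross-chain warmup): per-chain metrics are the
  # main source of post-burn-in step-size mismatch
  first <- withr::with_seed(chain_seeds[1],
    run_one_chain(prep, priors, n_draws, burn_in, loglik, fix_group_sd,
                  z_mode, sweeps, sweeps_burn))
  metric <- list(inv_sd = first$inv_sd, ls_eps = log(first$step_size))
  chains <- c(list(first), lapply(seq_len(n_chains)[-1], function(ch) {
    withr::with_seed(chain_seeds[ch],
      run_one_chain(prep, priors, n_draws, burn_in, loglik, fix_group_sd,
                    z_mode, sweeps, sweeps_burn, fixed_metric = metric))
  }))
  structure(list(
    chains = chains, par_names = .pt_par_names, ids = prep$ids,
    n_chains = n_chains, n_draws = n_draws, burn_in = burn_in,
    n_kept = n_draws - burn_in, seed = seed, priors = priors,
    bounds = prep$bounds, fixed_sd = fix_group_sd
  ), class = "pt_posterior")
}

# Penalized individual-level mode, used to start every chain near the
# posterior bulk (the coordinate-wise kernel mixes locally, so a cold start
# at the prior can strand a chain in the random-choice mode).
init_individual_modes <- function(pdata, priors, loglik) {
  loc <- priors$mean_loc
  # ridge toward the no-updating reference: a delta of 0.1 per unit scaled
  # outcome already shifts a parameter by several units over a session, so
  # flat likelihood directions should start near zero, not wander
  pen_scale <- pmin(priors$mean_scale, c(1, 1, 1, 1, 0.1, 0.1, 0.1, 0.1))
  t(vapply(pdata, function(pd) {
    nlp <- function(z) {
      v <- loglik(z, pd) + sum(stats::dnorm(z, loc, pen_scale, log = TRUE))
      if (!is.finite(v)) return(1e10)
      -v
    }
    stats::optim(loc, nlp, method = "Nelder-Mead",
                 control = list(maxit = 800, reltol = 1e-8))$par
  }, numeric(8)))
}

run_one_chain <- function(prep, priors, n_draws, burn_in, loglik,
                          fix_group_sd, z_mode, sweeps, sweeps_burn = sweeps,
                          fixed_metric = NULL) {
  pdata <- prep$pdata
  n <- length(pdata)
  loc <- priors$mean_loc; scl <- priors$mean_scale; A <- priors$sd_scale
  lhc <- function(s, a) log(2) - log(pi) - log(a) - log1p((s / a)^2)
  use_hmc <- is.null(attr(loglik, "no_gradient"))
  fixed_sd <- !is.null(fix_group_sd)
  # every move must target the same density; under the Hamiltonian kernel
  # that is the unclipped likelihood the gradient code evaluates
  ll_fn <- if (use_hmc) {
    function(zv, pd) cpp_choice_loglik_grad(pd$gain, pd$loss, pd$guar,
                                            pd$choice, pd$s, zv,
                                            .pt_floor_eps)$ll
  } else loglik
  # flattened cohort data for batched evaluation (one native call per move)
  fl_gain <- unlist(lapply(prep$pdata, `[[`, "gain"), use.names = FALSE)
  fl_loss <- unlist(lapply(prep$pdata, `[[`, "loss"), use.names = FALSE)
  fl_guar <- unlist(lapply(prep$pdata, `[[`, "guar"), use.names = FALSE)
  fl_choice <- unlist(lapply(prep$pdata, `[[`, "choice"), use.names = FALSE)
  fl_s <- unlist(lapply(prep$pdata, `[[`, "s"), use.names = FALSE)
  fl_starts <- c(0L, cumsum(vapply(prep$pdata, function(p) length(p$gain),
                                   integer(1))))
  fl_lg <- ifelse(fl_gain > 0, log(pmax(fl_gain, 1e-300)), 0)
  fl_llo <- ifelse(fl_loss < 0, log(-pmin(fl_loss, -1e-300)), 0)
  fl_lgu <- ifelse(fl_guar != 0, log(abs(fl_guar)), 0)
  batch_ll <- if (use_hmc) {
    function(Z) cpp_cohort_loglik(fl_gain, fl_loss, fl_guar, fl_choice, fl_s,
                                  fl_starts, Z, .pt_floor_eps,
                                  fl_lg, fl_llo, fl_lgu)
  } else {
    function(Z) vapply(seq_len(nrow(Z)),
                       function(i) loglik(Z[i, ], prep$pdata[[i]]), numeric(1))
  }
  batch_grad <- function(Z) {
    cpp_cohort_loglik_grad(fl_gain, fl_loss, fl_guar, fl_choice, fl_s,
                           fl_starts, Z, .pt_floor_eps)
  }

  # init: individuals jittered around their penalized modes (overdispersed
  # across chains, with the jitter scaled to the cohort spread of each
  # coordinate), then each offset halved until that participant sits within
  # a sane band of its mode likelihood -- large steps in an updating term
  # compound over the trial sequence and would start the chain on a cliff
  ll_mode <- batch_ll(z_mode)
  if (any(!is.finite(ll_mode))) {
    stop("could not initialize at finite density", call. = FALSE)
  }
  jit_sd <- pmax(apply(z_mode, 2, stats::sd), 0.02)
  z <- z_mode
  ll <- ll_mode
  for (i in seq_len(n)) {
    off <- stats::rnorm(8, 0, 0.5 * jit_sd)
    for (halving in 1:30) {
      cand <- z_mode[i, ] + off
      ll_i <- ll_fn(cand, pdata[[i]])
      if (is.finite(ll_i) && ll_i > ll_mode[i] - 100) {
        z[i, ] <- cand; ll[i] <- ll_i
        break
      }
      off <- off / 2
    }
  }
  m <- colMeans(z) + stats::rnorm(8, 0, 0.2 * jit_sd)
  s <- if (fixed_sd) fix_group_sd else {
    pmax(apply(z, 2, stats::sd), 0.02) * stats::runif(8, 0.7, 1.5)
  }
  aux <- rep(1, 8)  # parameter-expansion auxiliaries for the half-Cauchy SDs

  kept <- n_draws - burn_in
  mean_draws <- matrix(NA_real_, kept, 8,
                       dimnames = list(NULL, paste0("mean_", .pt_par_names)))
  sd_draws <- matrix(NA_real_, kept, 8,
                     dimnames = list(NULL, paste0("sd_", .pt_par_names)))
  ind_draws <- array(NA_real_, c(kept, n, 8),
                     dimnames = list(NULL, prep$ids, .pt_par_names))

  # ---- non-centered joint state for the Hamiltonian updates -------------
  # theta = (m, v = log s, u) with z = m + exp(v) * u; the non-centered
  # form removes the hierarchical funnel, and the centered conjugate Gibbs
  # interweave after each trajectory covers the strongly informed regime.
  v <- log(s)
  u <- sweep(sweep(z, 2, m), 2, s, "/")
  npar <- 16 + 8 * n
  # joint log target and gradient in (m, v, u); used by the step-size
  # pre-tuning (the sampling transitions run in compiled code)
  eval_joint <- function(m, v, u) {
    sv <- exp(v)
    z <- sweep(sweep(u, 2, sv, "*"), 2, m, "+")
    gl <- batch_grad(z)
    lls <- gl$ll
    G <- gl$grad
    if (any(!is.finite(lls))) return(list(lp = -Inf))
    lp <- sum(lls) - sum(u^2) / 2 +
      sum(stats::dnorm(m, loc, scl, log = TRUE))
    gm <- colSums(G) - (m - loc) / scl^2
    gu <- sweep(G, 2, sv, "*") - u
    gv <- colSums(G * u) * sv
    if (!fixed_sd) {
      lp <- lp + sum(lhc(sv, A)) + sum(v)
      gv <- gv - 2 * sv^2 / (A^2 + sv^2) + 1
    } else gv <- gv * 0
    list(lp = lp, gm = gm, gv = gv, gu = gu, lls = lls, z = z)
  }

  pack <- function(m, v, u) c(m, v, as.vector(u))
  ls_eps <- if (is.null(fixed_metric)) log(0.01) else fixed_metric$ls_eps
  inv_sd <- if (is.null(fixed_metric)) {
    c(rep(0.1, 16), rep(0.3, 8 * n))          # sqrt mass^{-1}, adapted
  } else fixed_metric$inv_sd
  if (fixed_sd) inv_sd[9:16] <- 0             # log-sd coordinates frozen
  tsum <- numeric(npar); tss <- numeric(npar); nmom <- 0
  acc_hmc <- 0; try_hmc <- 0
  acc_win <- 0; try_win <- 0                  # windowed acceptance
  acc_moves <- numeric(0)                     # per-family acceptance

  # coarse pre-tuning: halve the step until short trajectories accept
  if (use_hmc && is.null(fixed_metric)) {
    for (tune in 1:30) {
      ej <- eval_joint(m, v, u)
      eps <- exp(ls_eps) * inv_sd
      qm <- m; qv <- v; qu <- u
      p <- stats::rnorm(npar)
      h0 <- ej$lp - sum(p^2) / 2
      g <- pack(ej$gm, ej$gv, ej$gu)
      ok <- is.finite(ej$lp)
      if (ok) for (st in 1:5) {
        p <- p + 0.5 * eps * g
        q <- pack(qm, qv, qu) + eps * p
        qm <- q[1:8]; qv <- q[9:16]
        qu <- matrix(q[-(1:16)], n, 8)
        ejp <- eval_joint(qm, qv, qu)
        if (!is.finite(ejp$lp)) { ok <- FALSE; break }
        g <- pack(ejp$gm, ejp$gv, ejp$gu)
        p <- p + 0.5 * eps * g
      }
      apr <- if (ok) {
        lr <- (ejp$lp - sum(p^2) / 2) - h0
        if (is.finite(lr)) min(1, exp(lr)) else 0
      } else 0
      if (apr > 0.5) break
      ls_eps <- ls_eps - log(2)
    }
  }

  # gradient-free fallback state
  ls_step <- matrix(log(0.1), n, 8)
  ls_shift <- rep(log(0.1), 8)
  ls_scale <- rep(log(0.3), 8)
  # baseline/updating mean pairs share a likelihood ridge; moved jointly
  # with covariance adapted from the group-mean draws
  pairs <- list(c(1, 5), c(2, 6), c(3, 7), c(4, 8))
  ls_pair <- rep(log(0.3), 4)
  ls_full <- log(0.3)
  ls_trade <- rep(log(0.02), 4)
  # mean cumulative scaled outcome per participant: the average multiplier
  # an updating term receives over that participant's session
  cum_wt <- vapply(prep$pdata, function(pd) {
    cums <- c(0, cumsum(pd$s))[seq_along(pd$s)]
    mean(cums)
  }, numeric(1))
  msum <- numeric(8); mss <- matrix(0, 8, 8); mn_mom <- 0
  chol_mpair <- vector("list", 4)
  chol_mfull <- NULL
  cyc <- 0

  for (k in seq_len(n_draws)) {
   for (sw in seq_len(if (k <= burn_in) sweeps_burn else sweeps)) {
    cyc <- cyc + 1
    adapting <- k <= burn_in
    gam <- min(0.25, 1 / sqrt(cyc))

    if (use_hmc) {
      # No-U-Turn transition (compiled) on the joint non-centered state:
      # group means, log group SDs and whitened individuals move together
      # under the diagonal mass adapted below
      # step size jittered per transition: robust to a residually
      # mis-tuned base step after adaptation freezes
      eps_draw <- exp(ls_eps + stats::runif(1, -2, 0.3))
      res <- cpp_nuts_draw(fl_gain, fl_loss, fl_guar, fl_choice, fl_s,
                           fl_starts, pack(m, v, u), inv_sd, eps_draw,
                           loc, scl, A, fixed_sd, .pt_floor_eps, 5L)
      apr <- 0
      if (isTRUE(res$ok)) {
        apr <- res$accept_stat
        if (isTRUE(res$moved)) {
          th <- res$theta
          m <- th[1:8]; v <- th[9:16]
          u <- matrix(th[-(1:16)], n, 8)
          s <- exp(v)
          ll <- res$lls
          z <- sweep(sweep(u, 2, s, "*"), 2, m, "+")
        }
      }
      if (adapting) {
        gain <- if (is.null(fixed_metric)) max(0.05, gam) else 0.02
        ls_eps <- ls_eps + gain * (apr - 0.8)
        ls_eps <- min(max(ls_eps, log(1e-7)), log(1))
      }
      try_hmc <- try_hmc + 1; acc_hmc <- acc_hmc + apr

      # mass refreshes stop well before burn-in ends so the step size can
      # re-equilibrate under the final metric
      if (adapting && is.null(fixed_metric) && cyc > 50 &&
          cyc <= burn_in * sweeps_burn - 200) {
        th <- pack(m, v, u)
        tsum <- tsum + th; tss <- tss + th^2; nmom <- nmom + 1
        if (nmom >= 100 && nmom %% 50 == 0) {
          # refresh the mass only from a window that actually moved
          if (acc_win / try_win > 0.2) {
            sds <- sqrt(pmax(tss / nmom - (tsum / nmom)^2, 1e-10))
            inv_sd <- pmax(sds, 1e-4)
            if (fixed_sd) inv_sd[9:16] <- 0
            # restart step-size search under the new metric
            ls_eps <- log(0.5)
          }
          tsum[] <- 0; tss[] <- 0; nmom <- 0
          acc_win <- 0; try_win <- 0
        }
      }
      try_win <- try_win + 1; acc_win <- acc_win + apr
      if (fixed_sd) { v <- log(fix_group_sd); s <- fix_group_sd }
    } else {
      # gradient-free fallback: adaptive single-site random walk plus
      # interweaved translation/rescale moves (for custom likelihoods
      # supplied without gradients)
      for (j in 1:8) {
        prop <- z[, j] + exp(ls_step[, j]) * stats::rnorm(n)
        zp <- z; zp[, j] <- prop
        llp <- batch_ll(zp)
        lr <- llp - ll +
          stats::dnorm(prop, m[j], s[j], log = TRUE) -
          stats::dnorm(z[, j], m[j], s[j], log = TRUE)
        acc <- is.finite(lr) & (log(stats::runif(n)) < lr)
        z[acc, j] <- prop[acc]
        ll[acc] <- llp[acc]
        if (adapting) ls_step[, j] <- ls_step[, j] + gam * (acc - 0.44)
      }
    }

    # group-mean pair covariance, learned across the whole burn-in
    if (adapting) {
      msum <- msum + m; mss <- mss + tcrossprod(m); mn_mom <- mn_mom + 1
      if (mn_mom >= 100 && mn_mom %% 50 == 0) {
        Cm <- mss / mn_mom - tcrossprod(msum / mn_mom)
        for (pp in 1:4) {
          ix <- pairs[[pp]]
          ch <- tryCatch(chol(Cm[ix, ix] + 1e-10 * diag(2)),
                         error = function(e) NULL)
          if (!is.null(ch)) chol_mpair[[pp]] <- ch
        }
        ch <- tryCatch(chol(Cm + 1e-10 * diag(8)), error = function(e) NULL)
        if (!is.null(ch)) chol_mfull <- ch
      }
    }

    for (round in 1:2) {
    # full 8-d translation of all group means with every individual, along
    # the learned cross-correlation of the means (utility-parameter
    # trade-offs couple rho, lam, mu and db)
    if (!is.null(chol_mfull)) {
      eps8 <- exp(ls_full) * drop(stats::rnorm(8) %*% chol_mfull)
      zp <- sweep(z, 2, eps8, "+")
      llp <- batch_ll(zp)
      mp <- m + eps8
      lr <- sum(llp - ll) +
        sum(stats::dnorm(mp, loc, scl, log = TRUE)) -
        sum(stats::dnorm(m, loc, scl, log = TRUE))
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        z <- zp; ll <- llp; m <- mp
        f_acc <- 1
      } else f_acc <- 0
      if (adapting) ls_full <- ls_full + gam * (f_acc - 0.23)
    }

    for (trade_rep in 1:4) {
    # delta-trade: shift every individual's updating term by eps and
    # compensate its baseline on the natural scale by the participant's
    # mean cumulative outcome, walking the curved baseline/updating ridge
    # with the likelihood nearly invariant
    for (pp in 1:4) {
      jb <- pairs[[pp]][1]; jd <- pairs[[pp]][2]
      eps <- exp(ls_trade[pp]) * stats::rnorm(1)
      zp <- z
      zp[, jd] <- z[, jd] + eps
      ljac <- 0
      okm <- TRUE
      if (jb <= 3) {
        base_new <- exp(z[, jb]) - eps * cum_wt
        if (any(base_new <= .pt_floor_eps)) okm <- FALSE
        else {
          zp[, jb] <- log(base_new)
          ljac <- sum(z[, jb] - zp[, jb])
        }
      } else {
        zp[, jb] <- z[, jb] - eps * cum_wt
      }
      if (okm) {
        dzb <- mean(zp[, jb] - z[, jb])
        mp <- m; mp[jb] <- m[jb] + dzb; mp[jd] <- m[jd] + eps
        llp <- batch_ll(zp)
        lr <- sum(llp - ll) +
          sum(stats::dnorm(zp[, jb], mp[jb], s[jb], log = TRUE)) -
          sum(stats::dnorm(z[, jb], m[jb], s[jb], log = TRUE)) +
          sum(stats::dnorm(mp[c(jb, jd)], loc[c(jb, jd)], scl[c(jb, jd)],
                           log = TRUE)) -
          sum(stats::dnorm(m[c(jb, jd)], loc[c(jb, jd)], scl[c(jb, jd)],
                           log = TRUE)) + ljac
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          z <- zp; ll <- llp; m <- mp
          tr_acc <- 1
        } else tr_acc <- 0
      } else tr_acc <- 0
      if (adapting) ls_trade[pp] <- ls_trade[pp] + gam * (tr_acc - 0.3)
      nm <- paste0("trade", pp)
      acc_moves[nm] <- sum(acc_moves[nm], tr_acc, na.rm = TRUE)
    }
    }

    # 2-d ridge translation: a baseline mean and its updating-term mean
    # move together with every individual along the learned covariance
    for (pp in 1:4) {
      if (is.null(chol_mpair[[pp]])) next
      ix <- pairs[[pp]]
      eps2 <- exp(ls_pair[pp]) * drop(stats::rnorm(2) %*% chol_mpair[[pp]])
      zp <- z
      zp[, ix[1]] <- z[, ix[1]] + eps2[1]
      zp[, ix[2]] <- z[, ix[2]] + eps2[2]
      llp <- batch_ll(zp)
      mp <- m; mp[ix] <- mp[ix] + eps2
      lr <- sum(llp - ll) +
        sum(stats::dnorm(mp[ix], loc[ix], scl[ix], log = TRUE)) -
        sum(stats::dnorm(m[ix], loc[ix], scl[ix], log = TRUE))
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        z <- zp; ll <- llp; m <- mp
        pr_acc <- 1
      } else pr_acc <- 0
      if (adapting) ls_pair[pp] <- ls_pair[pp] + gam * (pr_acc - 0.23)
      nm <- paste0("pair", pp)
      acc_moves[nm] <- sum(acc_moves[nm], pr_acc, na.rm = TRUE)
    }

    # cheap coordinate-wise move families shared by both kernels; they
    # target the prior-dominated directions the data barely constrain
    for (j in 1:8) {
      # independence proposal from the hierarchy (flat directions)
      prop <- stats::rnorm(n, m[j], s[j])
      zp <- z; zp[, j] <- prop
      llp <- batch_ll(zp)
      lr <- llp - ll
      acc <- is.finite(lr) & (log(stats::runif(n)) < lr)
      z[acc, j] <- prop[acc]
      ll[acc] <- llp[acc]

      # joint translation of mean_j with all z_.j
      eps <- exp(ls_shift[j]) * stats::rnorm(1)
      zp <- z; zp[, j] <- z[, j] + eps
      llp <- batch_ll(zp)
      lr <- sum(llp - ll) +
        stats::dnorm(m[j] + eps, loc[j], scl[j], log = TRUE) -
        stats::dnorm(m[j], loc[j], scl[j], log = TRUE)
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        z[, j] <- zp[, j]; ll <- llp; m[j] <- m[j] + eps
        sh_acc <- 1
      } else sh_acc <- 0
      if (adapting) ls_shift[j] <- ls_shift[j] + gam * (sh_acc - 0.44)

      # joint rescale of sd_j with its offsets (funnel fix)
      if (!fixed_sd) {
        eps <- exp(ls_scale[j]) * stats::rnorm(1)
        cf <- exp(eps)
        zp <- z; zp[, j] <- m[j] + cf * (z[, j] - m[j])
        llp <- batch_ll(zp)
        lr <- sum(llp - ll) + lhc(cf * s[j], A[j]) - lhc(s[j], A[j]) + eps
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          z[, j] <- zp[, j]; ll <- llp; s[j] <- cf * s[j]
          sc_acc <- 1
        } else sc_acc <- 0
        if (adapting) ls_scale[j] <- ls_scale[j] + gam * (sc_acc - 0.44)
      }
    }
    }

    # centered-form interweave: conjugate Gibbs for the group means and
    # parameter-expanded Gibbs for the half-Cauchy group SDs
    prec <- n / s^2 + 1 / scl^2
    mu_post <- (colSums(z) / s^2 + loc / scl^2) / prec
    m <- stats::rnorm(8, mu_post, sqrt(1 / prec))
    if (!fixed_sd) {
      ss <- colSums(sweep(z, 2, m)^2)
      for (j in 1:8) {
        s2 <- max(rinvgamma1((n + 1) / 2, 1 / aux[j] + ss[j] / 2), 1e-16)
        s[j] <- sqrt(s2)
        aux[j] <- rinvgamma1(1, 1 / A[j]^2 + 1 / s2)
      }
    }
    if (use_hmc) {
      v <- log(s)
      u <- sweep(sweep(z, 2, m), 2, s, "/")
    }
   }

    if (k > burn_in) {
      kk <- k - burn_in
      mean_draws[kk, ] <- m
      sd_draws[kk, ] <- s
      ind_draws[kk, , ] <- z
    }
  }
  list(mean = mean_draws, sd = sd_draws, individuals = ind_draws,
       accept_hmc = if (try_hmc > 0) acc_hmc / try_hmc else NA_real_,
       accept_moves = acc_moves / (cyc * 4),
       step_size = exp(ls_eps), inv_sd = inv_sd,
       move_scales = list(shift = exp(ls_shift), scale = exp(ls_scale),
                          trade = exp(ls_trade), pair = exp(ls_pair),
                          full = exp(ls_full)))
}

#' @export
print.pt_posterior <- function(x, ...) {
  cat("<pt_posterior>", x$n_chains, "chains x", x$n_kept,
      "post-burn-in draws (", x$burn_in, "burn-in ),",
      length(x$ids), "participants\n")
  print(tidy(x))
  invisible(x)
}

#' Extract draws for one parameter
#'
#' @param post A `pt_posterior`.
#' @param parameter Name such as `"mean_lam"`, `"sd_db"`, or an individual
#'   parameter `"P3.d_mu"`.
#' @return Matrix of draws, chains in columns.
#' @export
posterior_draws <- function(post, parameter) {
  stopifnot(inherits(post, "pt_posterior"))
  get1 <- function(ch) {
    if (parameter %in% colnames(ch$mean)) return(ch$mean[, parameter])
    if (parameter %in% colnames(ch$sd)) return(ch$sd[, parameter])
    parts <- strsplit(parameter, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2 && parts[1] %in% post$ids &&
        parts[2] %in% post$par_names) {
      return(ch$individuals[, parts[1], parts[2]])
    }
    stop("unknown parameter: ", parameter, call. = FALSE)
  }
  vapply(post$chains, get1, numeric(post$n_kept))
}

#' Split-chain potential scale reduction (Rhat)
#'
#' Each chain is split in half and the classical between/within-variance
#' ratio is computed over the resulting 2m sequences; values near 1 indicate
#' the chains sample the same distribution.
#'
#' @inheritParams posterior_draws
#' @return Scalar Rhat (>= 1 up to numerical tolerance).
#' @export
rhat <- function(post, parameter) {
  draws <- if (is.matrix(post)) post else posterior_draws(post, parameter)
  if (ncol(draws) < 2) stop("rhat needs >= 2 chains", call. = FALSE)
  if (nrow(draws) < 4) stop("rhat needs >= 4 draws per chain", call. = FALSE)
  half <- floor(nrow(draws) / 2)
  splits <- cbind(draws[seq_len(half), , drop = FALSE],
                  draws[(nrow(draws) - half + 1):nrow(draws), , drop = FALSE])
  n <- nrow(splits); m <- ncol(splits)
  mu <- colMeans(splits)
  W <- mean(apply(splits, 2, stats::var))
  B <- n * stats::var(mu)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size
#'
#' Autocorrelation-adjusted sample count across chains, using chain-averaged
#' autocovariances combined with the between-chain variance and Geyer's
#' initial-positive-sequence truncation. Approximately the total draw count
#' for independent draws, and `n (1 - phi) / (1 + phi)` for an AR(1) chain
#' with autocorrelation `phi`.
#'
#' @inheritParams posterior_draws
#' @return Scalar ESS; `NA` with a warning for a degenerate (constant) chain.
#' @export
effective_samples <- function(post, parameter) {
  draws <- if (is.matrix(post)) post else posterior_draws(post, parameter)
  if (ncol(draws) < 1) stop("no chains", call. = FALSE)
  n <- nrow(draws); m <- ncol(draws)
  if (n < 4) stop("need >= 4 draws per chain", call. = FALSE)
  W <- mean(apply(draws, 2, stats::var))
  if (W == 0) {
    warning("degenerate (constant) chain; ESS undefined")
    return(NA_real_)
  }
  B_over_n <- if (m > 1) stats::var(colMeans(draws)) else 0
  var_plus <- (n - 1) / n * W + B_over_n
  # chain-averaged autocovariances
  max_lag <- n - 2
  acov <- vapply(seq_len(m), function(ch) {
    a <- stats::acf(draws[, ch], lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  }, numeric(max_lag + 1))
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus  # lag 0 first
  # Geyer: sum consecutive pairs while positive
  tau <- 0
  t <- 1  # index of lag 1 in rho (rho[1] is lag 0)
  while (t + 1 <= length(rho) - 1) {
    pair <- rho[t + 1] + rho[t + 2]
    if (!is.finite(pair) || pair <= 0) break
    tau <- tau + pair
    t <- t + 2
  }
  ess <- m * n / (1 + 2 * tau)
  min(ess, m * n)
}

#' Central 95% credible interval
#'
#' 2.5% and 97.5% posterior quantiles pooled over chains, with a flag for
#' whether the interval excludes zero — the decision rule used to declare an
#' updating parameter reliably nonzero.
#'
#' @inheritParams posterior_draws
#' @return Tibble with `parameter`, `low`, `high`, `excludes_zero`.
#' @export
ci95 <- function(post, parameter) {
  draws <- as.vector(if (is.matrix(post)) post
                     else posterior_draws(post, parameter))
  if (length(draws) < 100) stop("need >= 100 draws", call. = FALSE)
  q <- unname(stats::quantile(draws, c(0.025, 0.975)))
  tibble::tibble(parameter = if (is.character(parameter)) parameter else "draws",
                 low = q[1], high = q[2],
                 excludes_zero = q[1] > 0 || q[2] < 0)
}

#' @method tidy pt_posterior
#' @export
tidy.pt_posterior <- function(x, ...) {
  pars <- c(paste0("mean_", x$par_names), paste0("sd_", x$par_names))
  purrr::map_dfr(pars, function(p) {
    d <- posterior_draws(x, p)
    ci <- ci95(x, p)
    base <- sub("^(mean|sd)_", "", p)
    est <- mean(d)
    natural <- if (grepl("^mean_", p) && base %in% c("rho", "lam", "mu")) {
      exp(est)
    } else est
    tibble::tibble(parameter = p, mean = est, natural = natural,
                   sd = stats::sd(d), low = ci$low, high = ci$high,
                   excludes_zero = ci$excludes_zero,
                   rhat = rhat(x, p), ess = effective_samples(x, p))
  })
}

#' @method glance pt_posterior
#' @export
glance.pt_posterior <- function(x, ...) {
  means <- paste0("mean_", x$par_names)
  rh <- vapply(means, function(p) rhat(x, p), numeric(1))
  es <- vapply(means, function(p) effective_samples(x, p), numeric(1))
  tibble::tibble(
    n_chains = x$n_chains, n_draws = x$n_draws, burn_in = x$burn_in,
    n_kept_total = x$n_chains * x$n_kept,
    max_rhat = max(rh), min_ess = min(es),
    converged = max(rh) < 1.01 && min(es) > 400
  )
}
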