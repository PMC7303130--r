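# Shared fixtures: small simulated cohorts and a naive R re-implementation
# of the dynamic PT+ likelihood used as an independent oracle.

small_cohort <- function(n_participants = 4, n_trials = 25, seed = 101) {
  simulate_cohort(n_participants, n_trials, seed = seed)
}

# brute-force per-trial likelihood: plain R loop, no shared code with the
# compiled evaluator beyond the exported utility functions
naive_choice_loglik <- function(records, params, deltas, bounds) {
  th <- c(params$rho, params$lam, params$mu, params$db)
  dl <- c(deltas$d_rho, deltas$d_lam, deltas$d_mu, deltas$d_db)
  total <- 0
  for (t in seq_len(nrow(records))) {
    row <- records[t, ]
    u_g <- 0.5 * row$risky_gain^th[1] +
      (if (row$risky_loss < 0) -0.5 * th[2] * (-row$risky_loss)^th[1] else 0)
    u_s <- if (row$guaranteed >= 0) row$guaranteed^th[1] else {
      -th[2] * (-row$guaranteed)^th[1]
    }
    p <- 1 / (1 + exp(-th[3] * (u_g - u_s - th[4])))
    p <- min(max(p, 1e-12), 1 - 1e-12)
    total <- total + if (row$choice == 1) log(p) else log(1 - p)
    s <- (row$outcome - bounds[[1]]) / (bounds[[2]] - bounds[[1]])
    th <- c(pmax(th[1:3] + s * dl[1:3], 1e-6), th[4] + s * dl[4])
  }
  total
}
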