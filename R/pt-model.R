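#' Prospect-theory utilities for gains and losses
#'
#' The PT+ value functions. A prospect paying `x >= 0` with probability `p`
#' is worth `p * x^rho`; a prospect paying `x <= 0` with probability `p` is
#' worth `-p * lam * (-x)^rho`, i.e. losses are raised to the same exponent
#' and multiplied by the loss-aversion weight `lam`. Probability weighting is
#' the identity: `p` enters linearly.
#'
#' @param x Dollar amount; non-negative for `utility_gain()`, non-positive
#'   for `utility_loss()`. Vectorized.
#' @param p Probability of receiving `x`, in \[0, 1\].
#' @param rho Risk-attitude exponent, > 0.
#' @param lam Loss-aversion multiplier, > 0.
#' @return Utility (dimensionless), same length as `x`.
#' @examples
#' utility_gain(12, 0.5, 0.8)        # +3.65
#' utility_loss(-10, 0.5, 0.8, 1.5)  # -4.73
#' @export
utility_gain <- function(x, p, rho) {
  stopifnot(is.numeric(x), is.numeric(p), is.numeric(rho))
  if (any(x < 0)) stop("`x` must be >= 0; use utility_loss() for losses",
                       call. = FALSE)
  if (any(p < 0 | p > 1)) stop("`p` must be in [0, 1]", call. = FALSE)
  if (any(rho <= 0)) stop("`rho` must be > 0", call. = FALSE)
  p * x^rho
}

#' @rdname utility_gain
#' @export
utility_loss <- function(x, p, rho, lam) {
  stopifnot(is.numeric(x), is.numeric(p), is.numeric(rho), is.numeric(lam))
  if (any(x > 0)) stop("`x` must be <= 0; use utility_gain() for gains",
                       call. = FALSE)
  if (any(p < 0 | p > 1)) stop("`p` must be in [0, 1]", call. = FALSE)
  if (any(rho <= 0)) stop("`rho` must be > 0", call. = FALSE)
  if (any(lam <= 0)) stop("`lam` must be > 0", call. = FALSE)
  -p * lam * (-x)^rho
}

# Utility of the certain amount: gain branch when >= 0, loss branch when < 0,
# always at probability 1. The task never offers negative guaranteed amounts,
# but the model is total.
guaranteed_utility <- function(g, rho, lam) {
  ifelse(g >= 0, g^rho, -lam * (-g)^rho)
}

# Utility of the 50/50 gamble: gain and loss branches at p = 0.5 each.
gamble_utility <- function(risky_gain, risky_loss, rho, lam) {
  utility_gain(risky_gain, 0.5, rho) +
    ifelse(risky_loss < 0, -0.5 * lam * (-risky_loss)^rho, 0)
}

#' Probability of accepting the gamble
#'
#' Softmax (logistic) choice rule of PT+:
#' `p(accept) = 1 / (1 + exp(-mu * (u(gamble) - u(guaranteed) - db)))`,
#' where `u(gamble)` is the summed utility of the two equiprobable risky
#' outcomes and `u(guaranteed)` the utility of the certain amount. `mu = 0`
#' gives fully random choice (p = 0.5 everywhere); `db < 0` shifts choice
#' toward gambling independently of the values on offer.
#'
#' @param trials A data frame with columns `risky_gain`, `risky_loss`,
#'   `guaranteed` (dollars), one row per trial.
#' @param params A [pt_params()] set, or a data frame with per-trial columns
#'   `rho`, `lam`, `mu`, `db` (e.g. a trajectory from [pt_trajectory()]).
#' @return Numeric vector of acceptance probabilities, one per row.
#' @examples
#' tr <- tibble::tibble(risky_gain = 12, risky_loss = -10, guaranteed = 0)
#' p_accept(tr, pt_params(0.8, 1.5, 1, 0))
#' @export
p_accept <- function(trials, params) {
  check_choice_columns(trials)
  if (inherits(params, "pt_params")) {
    rho <- params$rho; lam <- params$lam; mu <- params$mu; db <- params$db
  } else {
    stopifnot(all(c("rho", "lam", "mu", "db") %in% names(params)))
    if (nrow(params) != nrow(trials) && nrow(params) != 1) {
      stop("per-trial `params` must have one row per trial", call. = FALSE)
    }
    rho <- params$rho; lam <- params$lam; mu <- params$mu; db <- params$db
  }
  u_g <- gamble_utility(trials$risky_gain, trials$risky_loss, rho, lam)
  u_s <- guaranteed_utility(trials$guaranteed, rho, lam)
  stats::plogis(mu * (u_g - u_s - db))
}

check_choice_columns <- function(trials) {
  need <- c("risky_gain", "risky_loss", "guaranteed")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("`trials` is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(trials)
}

#' Linear outcome scaling
#'
#' Maps a realized dollar outcome onto \[0, 1\] linearly over the session's
#' full offered-outcome range; this scaled value multiplies the updating
#' terms in the trial-by-trial parameter dynamics.
#'
#' @param outcome Realized outcome(s), dollars.
#' @param out_min,out_max Lower/upper bound of the offered-outcome range;
#'   `out_min < out_max` and every `outcome` must lie inside.
#' @return Scaled values in \[0, 1\].
#' @export
scale_outcome <- function(outcome, out_min, out_max) {
  if (out_min >= out_max) stop("`out_min` must be < `out_max`", call. = FALSE)
  if (any(outcome < out_min | outcome > out_max)) {
    stop("`outcome` outside [out_min, out_max]", call. = FALSE)
  }
  (outcome - out_min) / (out_max - out_min)
}

#' Offered-outcome range of a trial set
#'
#' The smallest and largest outcome any trial in the data could realize
#' (across risky losses, guaranteed amounts and risky gains), used as the
#' bounds of [scale_outcome()]. Computed once per dataset.
#'
#' @param trials Data frame with `risky_gain`, `risky_loss`, `guaranteed`.
#' @return Named numeric vector `c(out_min, out_max)`.
#' @export
outcome_bounds <- function(trials) {
  check_choice_columns(trials)
  offered <- c(trials$risky_gain, trials$risky_loss, trials$guaranteed)
  c(out_min = min(offered), out_max = max(offered))
}

#' One updating step of a PT+ parameter
#'
#' `theta_t = theta_{t-1} + scaled_outcome * delta`, after which `rho`, `lam`
#' and `mu` are floored at a small positive epsilon if the step crossed zero
#' (`db` is unbounded). The return value carries a `floored` attribute
#' reporting whether the floor was applied.
#'
#' @param theta_prev Parameter value before the step.
#' @param scaled_outcome Previous trial's outcome scaled to \[0, 1\].
#' @param delta Updating term for this parameter.
#' @param floor_at Lower support bound; use `.pt_floor_eps` default for
#'   `rho`/`lam`/`mu` and `-Inf` for `db`.
#' @return Updated value with attribute `floored`.
#' @export
update_step <- function(theta_prev, scaled_outcome, delta,
                        floor_at = .pt_floor_eps) {
  stopifnot(is.finite(theta_prev), is.finite(scaled_outcome), is.finite(delta))
  raw <- theta_prev + scaled_outcome * delta
  hit <- raw < floor_at && raw < theta_prev
  out <- if (hit) floor_at else raw
  attr(out, "floored") <- hit
  out
}

#' Trial-by-trial parameter trajectory
#'
#' Runs the PT+ updating dynamics over a sequence of realized outcomes:
#' trial 1 uses the initial parameters, and before each later trial every
#' parameter is shifted by its updating term times the previous trial's
#' scaled outcome. Because updates are additive, the trajectory depends on
#' the outcome history only through cumulative scaled outcomes.
#'
#' @param outcomes Ordered realized outcomes (dollars), one per trial.
#' @param params Initial [pt_params()].
#' @param deltas [pt_deltas()] updating terms.
#' @param bounds Scaling bounds `c(out_min, out_max)`; defaults to the range
#'   of `outcomes` extended to include 0.
#' @return Tibble with columns `trial`, `rho`, `lam`, `mu`, `db`, and
#'   `floored` (TRUE where a support floor was applied at that step).
#' @examples
#' pt_trajectory(c(10, -5, 3), pt_params(0.65, 1.57, 22.2, -0.58),
#'               pt_deltas(d_lam = 0.01))
#' @export
pt_trajectory <- function(outcomes, params, deltas, bounds = NULL) {
  stopifnot(length(outcomes) >= 1, inherits(params, "pt_params"),
            inherits(deltas, "pt_deltas"))
  if (is.null(bounds)) bounds <- range(c(outcomes, 0))
  s <- scale_outcome(outcomes, bounds[[1]], bounds[[2]])
  n <- length(outcomes)
  out <- matrix(NA_real_, n, 4, dimnames = list(NULL, c("rho", "lam", "mu", "db")))
  floored <- logical(n)
  th <- c(params$rho, params$lam, params$mu, params$db)
  dl <- c(deltas$d_rho, deltas$d_lam, deltas$d_mu, deltas$d_db)
  out[1, ] <- th
  for (t in seq_len(n - 1L)) {
    raw <- th + s[t] * dl
    hit <- raw[1:3] < .pt_floor_eps & raw[1:3] < th[1:3]
    th <- c(ifelse(hit, .pt_floor_eps, raw[1:3]), raw[4])
    floored[t + 1L] <- any(hit)
    out[t + 1L, ] <- th
  }
  dplyr::bind_cols(tibble::tibble(trial = seq_len(n)),
                   tibble::as_tibble(out),
                   tibble::tibble(floored = floored))
}

#' Choice log-likelihood of one participant under dynamic PT+
#'
#' Sums, over a participant's time-ordered trials, the log Bernoulli
#' probability of the observed accept/reject decision under the softmax rule,
#' with parameters evolving by the updating dynamics driven by realized,
#' scaled outcomes. Evaluated in compiled code with a numerically stable
#' log-logistic; probabilities are clipped 1e-12 from the boundary inside the
#' log only.
#'
#' @param records Data frame of one participant's trials, time-ordered, with
#'   columns `risky_gain`, `risky_loss`, `guaranteed`, `choice` (1 = gamble,
#'   0 = guaranteed), `outcome` (realized dollars). A `participant_id` column,
#'   if present, must be constant; a `trial_index` column must be increasing.
#' @param params Initial [pt_params()].
#' @param deltas [pt_deltas()].
#' @param bounds Outcome-scaling bounds; defaults to [outcome_bounds()] of
#'   `records` (compute them once on the full dataset when looping over
#'   participants).
#' @return Log-likelihood (scalar, <= 0).
#' @export
choice_loglik <- function(records, params, deltas, bounds = NULL) {
  check_choice_columns(records)
  stopifnot(all(c("choice", "outcome") %in% names(records)),
            inherits(params, "pt_params"), inherits(deltas, "pt_deltas"))
  if ("participant_id" %in% names(records) &&
      length(unique(records$participant_id)) > 1) {
    stop("`records` must contain a single participant", call. = FALSE)
  }
  if ("trial_index" %in% names(records) &&
      is.unsorted(records$trial_index, strictly = TRUE)) {
    stop("`records` must be time-ordered by `trial_index`", call. = FALSE)
  }
  if (!all(records$choice %in% c(0L, 1L))) {
    stop("`choice` must be 0/1", call. = FALSE)
  }
  if (is.null(bounds)) bounds <- outcome_bounds(records)
  s <- scale_outcome(records$outcome, bounds[[1]], bounds[[2]])
  cpp_choice_loglik(records$risky_gain, records$risky_loss, records$guaranteed,
                    as.integer(records$choice), s,
                    params$rho, params$lam, params$mu, params$db,
                    deltas$d_rho, deltas$d_lam, deltas$d_mu, deltas$d_db,
                    .pt_floor_eps)
}
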