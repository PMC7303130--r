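#' Generate choice sets for the mixed gambling task
#'
#' Builds a randomized sequence of two trial types emulating the risky-choice
#' task: *gain-loss* trials offer a 50/50 gamble between a gain of $2-$12 and
#' a loss equal to minus 0.25-2 times that gain, against a guaranteed amount
#' (default $0); *gain-only* trials offer a 50/50 gamble between a gain of
#' $2-$30 and $0, against a smaller guaranteed amount of $1-$12. Amounts are
#' drawn uniformly on those ranges and rounded to a $0.25 grid (the loss is
#' then clamped so its multiple of the gain stays in \[0.25, 2\]).
#'
#' @param n_trials Number of trials, 1-1000.
#' @param fraction_gain_loss Proportion of gain-loss trials, in \[0, 1\].
#' @param seed Integer seed; the same seed reproduces the same trial list.
#'   `NULL` uses the current RNG stream (for callers that manage their own
#'   seed).
#' @param gl_guaranteed Guaranteed amount on gain-loss trials (dollars).
#' @param grid Rounding step for dollar amounts.
#' @return Tibble with one row per trial: `trial_index`, `trial_type`,
#'   `risky_gain`, `risky_loss`, `guaranteed`, `p_risky` (always 0.5).
#' @examples
#' generate_trials(10, 0.6, seed = 1)
#' @export
generate_trials <- function(n_trials, fraction_gain_loss, seed = NULL,
                            gl_guaranteed = 0, grid = 0.25) {
  if (!is.numeric(n_trials) || n_trials < 1 || n_trials > 1000 ||
      n_trials != round(n_trials)) {
    stop("`n_trials` must be an integer in [1, 1000]", call. = FALSE)
  }
  if (!is.numeric(fraction_gain_loss) || fraction_gain_loss < 0 ||
      fraction_gain_loss > 1) {
    stop("`fraction_gain_loss` must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) {
    return(withr::with_seed(seed,
      generate_trials(n_trials, fraction_gain_loss, seed = NULL,
                      gl_guaranteed = gl_guaranteed, grid = grid)))
  }
  n_trials <- as.integer(n_trials)
  n_gl <- as.integer(round(n_trials * fraction_gain_loss))
  n_go <- n_trials - n_gl
  snap <- function(x) round(x / grid) * grid

  gl_gain <- snap(stats::runif(n_gl, 2, 12))
  mult <- stats::runif(n_gl, 0.25, 2)
  gl_loss <- pmin(pmax(snap(-mult * gl_gain), -2 * gl_gain), -0.25 * gl_gain)
  go_gain <- snap(stats::runif(n_go, 2, 30))
  # guaranteed must stay below the gain; cap the draw one grid step under it
  go_guar <- snap(stats::runif(n_go, 1, pmin(12, go_gain - grid)))
  go_guar <- pmin(go_guar, go_gain - grid)

  out <- tibble::tibble(
    trial_type = c(rep("gain_loss", n_gl), rep("gain_only", n_go)),
    risky_gain = c(gl_gain, go_gain),
    risky_loss = c(gl_loss, rep(0, n_go)),
    guaranteed = c(rep(gl_guaranteed, n_gl), go_guar),
    p_risky = 0.5
  )
  out <- out[sample.int(n_trials), ]
  dplyr::bind_cols(tibble::tibble(trial_index = seq_len(n_trials)), out)
}

#' Group-level parameter distributions
#'
#' Describes the population the simulator draws individuals from: a normal
#' distribution per parameter on the *unconstrained* sampling scale (log
#' scale for `rho`, `lam`, `mu`; raw scale for `db` and the four updating
#' terms). `means` are given on the natural scale (so `rho = 0.65` puts the
#' log-scale mean at `log(0.65)`); `sds` are on the unconstrained scale.
#'
#' @param means Named numeric vector over
#'   `rho, lam, mu, db, d_rho, d_lam, d_mu, d_db` (natural scale). Defaults
#'   to the published group means ([pt_reference_means()]).
#' @param sds Named numeric vector of positive unconstrained-scale SDs.
#' @return A list of class `pt_group` with elements `mean_unc` and `sd`
#'   (both length-8 named vectors on the unconstrained scale).
#' @examples
#' pt_group_params()
#' @export
pt_group_params <- function(means = NULL, sds = NULL) {
  nm <- c("rho", "lam", "mu", "db", "d_rho", "d_lam", "d_mu", "d_db")
  m <- stats::setNames(pt_reference_means()$value, nm)
  if (!is.null(means)) m[names(means)] <- means
  s <- c(rho = 0.2, lam = 0.2, mu = 0.3, db = 0.2,
         d_rho = 0.01, d_lam = 0.01, d_mu = 0.05, d_db = 0.02)
  if (!is.null(sds)) s[names(sds)] <- sds
  if (any(s <= 0)) stop("all group SDs must be > 0", call. = FALSE)
  if (m[["rho"]] <= 0 || m[["lam"]] <= 0 || m[["mu"]] <= 0) {
    stop("group means for rho, lam, mu must be > 0", call. = FALSE)
  }
  structure(list(mean_unc = unconstrain_params(m), sd = s), class = "pt_group")
}

# natural <-> unconstrained maps for the 8-parameter vector
unconstrain_params <- function(theta) {
  out <- theta
  out[c("rho", "lam", "mu")] <- log(theta[c("rho", "lam", "mu")])
  out
}

constrain_params <- function(z) {
  out <- z
  out[c("rho", "lam", "mu")] <- exp(z[c("rho", "lam", "mu")])
  out
}

#' Draw individual parameter sets from a group distribution
#'
#' Each of the eight parameters is drawn independently from its group normal
#' on the unconstrained scale and mapped back to its support (exponential for
#' `rho`, `lam`, `mu`), so every individual respects the parameter bounds.
#'
#' @param group A [pt_group_params()] object.
#' @param n Number of individuals, >= 1.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return Tibble with `participant_id` and the eight natural-scale
#'   parameter columns.
#' @export
sample_individuals <- function(group, n, seed = NULL) {
  stopifnot(inherits(group, "pt_group"))
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, sample_individuals(group, n, seed = NULL)))
  }
  nm <- names(group$mean_unc)
  z <- vapply(nm, function(p) stats::rnorm(n, group$mean_unc[[p]], group$sd[[p]]),
              numeric(n))
  z <- matrix(z, nrow = n, dimnames = list(NULL, nm))
  nat <- t(apply(z, 1, constrain_params))
  dplyr::bind_cols(tibble::tibble(participant_id = paste0("P", seq_len(n))),
                   tibble::as_tibble(nat))
}

#' Simulate one participant's choices on a trial sequence
#'
#' Runs a PT+ agent over the choice sets: trial 1 uses the initial
#' parameters; after each trial every parameter is shifted by its updating
#' term times the realized outcome scaled to \[0, 1\] over the offered
#' range. The agent accepts the gamble with the softmax probability; an
#' accepted gamble resolves by a fair coin between gain and loss, a declined
#' one pays the guaranteed amount.
#'
#' @param trials Choice sets from [generate_trials()] (or any data frame
#'   with `risky_gain`, `risky_loss`, `guaranteed`).
#' @param params Initial [pt_params()].
#' @param deltas [pt_deltas()].
#' @param seed Integer seed, or `NULL` for the current RNG stream.
#' @param bounds Outcome-scaling bounds; defaults to the offered range of
#'   `trials`. Pass cohort-wide bounds when simulating several participants
#'   of one dataset.
#' @param participant_id Identifier stored in the output.
#' @return Tibble of trial records: the choice-set columns plus
#'   `participant_id`, `choice` (1 = gamble), `outcome` (realized dollars).
#' @export
simulate_participant <- function(trials, params, deltas, seed = NULL,
                                 bounds = NULL, participant_id = "P1") {
  check_choice_columns(trials)
  stopifnot(nrow(trials) >= 1, inherits(params, "pt_params"),
            inherits(deltas, "pt_deltas"))
  if (!is.null(seed)) {
    return(withr::with_seed(seed,
      simulate_participant(trials, params, deltas, seed = NULL,
                           bounds = bounds, participant_id = participant_id)))
  }
  if (is.null(bounds)) bounds <- outcome_bounds(trials)
  n <- nrow(trials)
  th <- c(params$rho, params$lam, params$mu, params$db)
  dl <- c(deltas$d_rho, deltas$d_lam, deltas$d_mu, deltas$d_db)
  choice <- integer(n)
  outcome <- numeric(n)
  for (t in seq_len(n)) {
    row <- trials[t, ]
    p <- p_accept(row, pt_params(th[1], th[2], th[3], th[4]))
    choice[t] <- stats::rbinom(1, 1, p)
    outcome[t] <- if (choice[t] == 1L) {
      if (stats::runif(1) < 0.5) row$risky_gain else row$risky_loss
    } else {
      row$guaranteed
    }
    s <- scale_outcome(outcome[t], bounds[[1]], bounds[[2]])
    raw <- th + s * dl
    hit <- raw[1:3] < .pt_floor_eps & raw[1:3] < th[1:3]
    th <- c(ifelse(hit, .pt_floor_eps, raw[1:3]), raw[4])
  }
  dplyr::bind_cols(
    tibble::tibble(participant_id = participant_id),
    trials,
    tibble::tibble(choice = choice, outcome = outcome)
  )
}

#' Simulate a cohort of PT+ agents
#'
#' Draws individual parameter sets from the group distribution (or uses the
#' provided ones), generates an independent trial sequence per participant,
#' and simulates each participant's choices. Outcome scaling uses one
#' offered-outcome range shared by the whole dataset.
#'
#' @param n_participants Number of agents.
#' @param n_trials Trials per agent.
#' @param group [pt_group_params()] population, used when `individuals` is
#'   `NULL`.
#' @param individuals Optional tibble as returned by [sample_individuals()];
#'   overrides `group`.
#' @param fraction_gain_loss Proportion of gain-loss trials.
#' @param seed Integer seed for the whole cohort.
#' @return A list with `trials` (stacked trial records, CSV schema) and
#'   `individuals` (the generating parameters), classed `pt_cohort`.
#' @examples
#' sim <- simulate_cohort(3, 20, seed = 1)
#' dplyr::count(sim$trials, participant_id)
#' @export
simulate_cohort <- function(n_participants, n_trials,
                            group = pt_group_params(), individuals = NULL,
                            fraction_gain_loss = 2 / 3, seed = 1) {
  withr::with_seed(seed, {
    if (is.null(individuals)) {
      individuals <- sample_individuals(group, n_participants)
    }
    n_participants <- nrow(individuals)
    all_trials <- purrr::map(seq_len(n_participants), function(i) {
      generate_trials(n_trials, fraction_gain_loss)
    })
    # dataset-wide offered-outcome range for the updating dynamics
    bounds <- outcome_bounds(dplyr::bind_rows(all_trials))
    recs <- purrr::map(seq_len(n_participants), function(i) {
      row <- individuals[i, ]
      simulate_participant(
        all_trials[[i]],
        pt_params(row$rho, row$lam, row$mu, row$db),
        pt_deltas(row$d_rho, row$d_lam, row$d_mu, row$d_db),
        bounds = bounds, participant_id = row$participant_id
      )
    })
    structure(list(trials = dplyr::bind_rows(recs), individuals = individuals,
                   bounds = bounds, seed = seed),
              class = "pt_cohort")
  })
}

#' Read and write trial data
#'
#' Trial records round-trip through a plain CSV with columns
#' `participant_id, trial_index, trial_type, risky_gain, risky_loss,
#' guaranteed, choice, outcome` (one row per trial, header required, UTF-8).
#'
#' @param trials Trial-record tibble.
#' @param path File path.
#' @return `read_trials()` returns the tibble; `write_trials()` returns
#'   `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  cols <- c("participant_id", "trial_index", "trial_type", "risky_gain",
            "risky_loss", "guaranteed", "choice", "outcome")
  miss <- setdiff(cols, names(trials))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  readr::write_csv(trials[cols], path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    trial_index = readr::col_integer(),
    trial_type = readr::col_character(),
    risky_gain = readr::col_double(),
    risky_loss = readr::col_double(),
    guaranteed = readr::col_double(),
    choice = readr::col_integer(),
    outcome = readr::col_double()
  ))
}
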