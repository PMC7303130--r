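#' Pipeline configuration
#'
#' Collects every knob of an end-to-end run — simulate a cohort, fit a set
#' of sequential-history regressions, optionally sample the hierarchical
#' posterior — with one explicit seed, so a config fully determines a run.
#'
#' @param n_participants,n_trials Cohort dimensions.
#' @param fraction_gain_loss Gain-loss trial proportion.
#' @param group [pt_group_params()] generating population.
#' @param models Integer vector of regression models (subset of 1..9) to fit.
#' @param mcmc `NULL` to skip posterior sampling, or a list with `n_chains`,
#'   `n_draws`, `burn_in`.
#' @param seed Integer master seed.
#' @param out_dir Output directory for artifacts.
#' @return A list of class `pt_config`.
#' @export
pipeline_config <- function(n_participants = 5, n_trials = 20,
                            fraction_gain_loss = 2 / 3,
                            group = pt_group_params(), models = 1L,
                            mcmc = NULL, seed = 1,
                            out_dir = tempfile("dynpt_run_")) {
  stopifnot(n_participants >= 2, n_trials >= 1, all(models %in% 1:9))
  structure(list(n_participants = n_participants, n_trials = n_trials,
                 fraction_gain_loss = fraction_gain_loss, group = group,
                 models = as.integer(models), mcmc = mcmc,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pt_config")
}

config_json <- function(config) {
  jsonlite::toJSON(list(
    n_participants = config$n_participants, n_trials = config$n_trials,
    fraction_gain_loss = config$fraction_gain_loss,
    group_mean_unc = as.list(config$group$mean_unc),
    group_sd = as.list(config$group$sd),
    models = config$models,
    mcmc = config$mcmc, seed = config$seed
  ), auto_unbox = TRUE, digits = NA)
}

#' Run the full pipeline
#'
#' Simulates a cohort, writes the trial CSV, fits the requested regression
#' models (each saved as JSON), optionally runs the hierarchical sampler
#' (posterior summary and diagnostics saved as JSON), and writes a manifest
#' recording the config, its hash, the seed, package version, per-stage
#' status and every output file. Identical configs produce identical
#' artifacts apart from timestamps.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (list), invisibly; artifacts under `config$out_dir`.
#' @examples
#' \donttest{
#' man <- run_pipeline(pipeline_config(n_participants = 4, n_trials = 12))
#' man$stages
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pt_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(config$out_dir, "config.json")
  writeLines(config_json(config), cfg_path)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("dynpt")),
    created = format(Sys.time(), tz = "UTC"),
    stages = list(), outputs = list("config.json")
  )
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) e)
    ok <- !inherits(res, "error")
    manifest$stages[[name]] <<- list(
      ok = ok, seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      error = if (ok) NULL else conditionMessage(res))
    if (!ok) message("stage '", name, "' failed: ", conditionMessage(res))
    if (ok) res else NULL
  }

  sim <- stage("simulate", {
    s <- simulate_cohort(config$n_participants, config$n_trials,
                         group = config$group,
                         fraction_gain_loss = config$fraction_gain_loss,
                         seed = config$seed)
    write_trials(s$trials, file.path(config$out_dir, "trials.csv"))
    manifest$outputs <- c(manifest$outputs, "trials.csv")
    s
  })

  if (!is.null(sim)) {
    for (mid in config$models) {
      nm <- paste0("glmm_model_", mid)
      stage(nm, {
        fit <- fit_glmm(build_design(sim$trials, mid))
        out <- list(model_id = mid,
                    coefficients = tidy(fit),
                    summary = glance(fit))
        path <- file.path(config$out_dir, paste0(nm, ".json"))
        jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                             dataframe = "rows")
        manifest$outputs <- c(manifest$outputs, basename(path))
        fit
      })
    }
    if (!is.null(config$mcmc)) {
      stage("hbayes", {
        post <- run_mcmc(sim$trials,
                         n_chains = config$mcmc$n_chains,
                         n_draws = config$mcmc$n_draws,
                         burn_in = config$mcmc$burn_in,
                         seed = config$seed)
        out <- list(summary = tidy(post), diagnostics = glance(post))
        path <- file.path(config$out_dir, "posterior.json")
        jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                             dataframe = "rows")
        manifest$outputs <- c(manifest$outputs, "posterior.json")
        post
      })
    }
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Probability-at-indifference table
#'
#' Tabulates, on a $1 grid from -$20 to +$20, the gambling probability a
#' previous-outcome slope implies when the current options are at
#' indifference. At the published slope of -0.03 per dollar the endpoints
#' round to 65% (after -$20) and 35% (after +$20).
#'
#' @param beta_prev Previous-outcome coefficient (logit per dollar).
#' @param outcomes Grid of previous outcomes, dollars.
#' @return Tibble with `prev_outcome`, `probability`, `percent` (rounded).
#' @examples
#' fig_indifference_table(-0.03)
#' @export
fig_indifference_table <- function(beta_prev = -0.03, outcomes = -20:20) {
  p <- indifference_probability(beta_prev, outcomes)
  tibble::tibble(prev_outcome = outcomes, probability = p,
                 percent = round(100 * p))
}

#' Loss-aversion trajectories under different outcome histories
#'
#' Runs the updating dynamics for one hypothetical individual under several
#' outcome histories, showing how the same initial loss-aversion value
#' diverges with experience. Defaults use the published group means
#' (initial lambda 1.57, updating term 0.01 per unit scaled outcome).
#'
#' @param outcome_histories List of dollar outcome sequences.
#' @param lambda_init Initial loss-aversion value.
#' @param d_lam Updating term for lambda.
#' @param bounds Outcome-scaling bounds shared by the histories; defaults to
#'   the pooled range (including 0).
#' @return Tibble with `history`, `trial`, `lambda`.
#' @export
fig_lambda_trajectories <- function(outcome_histories, lambda_init = 1.57,
                                    d_lam = 0.01, bounds = NULL) {
  stopifnot(length(outcome_histories) >= 1)
  if (is.null(bounds)) bounds <- range(c(unlist(outcome_histories), 0))
  purrr::imap_dfr(outcome_histories, function(h, i) {
    tr <- pt_trajectory(h, pt_params(0.65, lambda_init, 22.2, -0.58),
                        pt_deltas(d_lam = d_lam), bounds = bounds)
    tibble::tibble(history = as.character(i), trial = tr$trial,
                   lambda = tr$lam)
  })
}

#' Plot helpers
#'
#' `plot_indifference()` draws the probability-at-indifference curve;
#' `plot_lambda_trajectories()` draws one loss-aversion trajectory per
#' outcome history; `autoplot.pt_posterior()` shows posterior densities of
#' the group-level means with their 95% intervals.
#'
#' @param table Output of [fig_indifference_table()] or
#'   [fig_lambda_trajectories()].
#' @return A ggplot object.
#' @export
plot_indifference <- function(table = fig_indifference_table()) {
  ggplot2::ggplot(table, ggplot2::aes(.data$prev_outcome, .data$probability)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "Previous outcome ($)",
                  y = "P(choose gamble) at indifference") +
    ggplot2::theme_minimal()
}

#' @rdname plot_indifference
#' @export
plot_lambda_trajectories <- function(table) {
  ggplot2::ggplot(table, ggplot2::aes(.data$trial, .data$lambda,
                                      colour = .data$history)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Trial", y = "Loss aversion (lambda)",
                  colour = "History") +
    ggplot2::theme_minimal()
}

#' @param object A `pt_posterior`.
#' @param ... Unused.
#' @rdname plot_indifference
#' @method autoplot pt_posterior
#' @export
autoplot.pt_posterior <- function(object, ...) {
  pars <- paste0("mean_", object$par_names)
  df <- purrr::map_dfr(pars, function(p) {
    tibble::tibble(parameter = p, draw = as.vector(posterior_draws(object, p)))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$draw)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "Unconstrained group-mean draw", y = "Density") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
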