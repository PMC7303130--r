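#' Build the design table for one sequential-history regression model
#'
#' Constructs the response and regressors for one of the nine
#' random-intercept logistic regressions of binary choice on current options
#' and lagged events. Every model includes the current risky gain, risky
#' loss and guaranteed amounts; the models differ in which lagged features
#' they add:
#'
#' * **1** previous outcome (dollars)
#' * **2** previous decision (+1 gamble / -1 guaranteed)
#' * **3** mean expected value of the previous options,
#'   `((0.5 gain + 0.5 loss) + guaranteed) / 2`
#' * **4** all three of the above
#' * **5** outcomes one, two and three trials back
#' * **6** previous outcome plus its valence (+1 gain / 0 zero / -1 loss)
#' * **7** previous outcome split into three type-specific regressors
#'   (risky-gain / risky-loss / guaranteed outcome, zero when the previous
#'   outcome was not of that type); these columns sum to model 1's regressor
#' * **8** previous gain amount (risky and guaranteed collapsed), previous
#'   loss amount, previous decision (+1/-1), and the gain-amount-by-decision
#'   interaction
#' * **9** previous outcome plus its interactions with each current option
#'
#' Trials lacking the required lags are dropped per participant; the count
#' is recorded in the `n_excluded` attribute. A $0 outcome from a lost
#' gain-only gamble is typed as a risky-gain outcome of amount 0 and has
#' valence 0.
#'
#' @param records Multi-participant trial records (CSV schema), time-ordered
#'   within participant.
#' @param model_id Integer 1-9.
#' @return A tibble of class `pt_design` with `participant_id`, `choice`,
#'   the current-option columns, and the model's lagged features; attributes
#'   `model_id`, `predictors` and `n_excluded`.
#' @examples
#' sim <- simulate_cohort(3, 15, seed = 2)
#' build_design(sim$trials, 1)
#' @export
build_design <- function(records, model_id) {
  if (!is.numeric(model_id) || !(model_id %in% 1:9)) {
    stop("`model_id` must be one of 1..9", call. = FALSE)
  }
  check_choice_columns(records)
  stopifnot(all(c("participant_id", "choice", "outcome") %in% names(records)))

  d <- records |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(
      prev_outcome = dplyr::lag(.data$outcome),
      prev_outcome2 = dplyr::lag(.data$outcome, 2),
      prev_outcome3 = dplyr::lag(.data$outcome, 3),
      prev_choice = dplyr::lag(2 * .data$choice - 1),
      prev_mean_ev = dplyr::lag(
        (0.5 * .data$risky_gain + 0.5 * .data$risky_loss + .data$guaranteed) / 2
      ),
      prev_valence = sign(.data$prev_outcome),
      # outcome type of trial t-1: which branch produced the realized outcome
      prev_from_gamble = .data$prev_choice == 1,
      prev_out_risky_gain = ifelse(.data$prev_from_gamble & .data$prev_outcome >= 0,
                                   .data$prev_outcome, 0),
      prev_out_risky_loss = ifelse(.data$prev_from_gamble & .data$prev_outcome < 0,
                                   .data$prev_outcome, 0),
      prev_out_guaranteed = ifelse(!.data$prev_from_gamble, .data$prev_outcome, 0),
      prev_gain_amount = ifelse(.data$prev_outcome >= 0, .data$prev_outcome, 0),
      prev_loss_amount = ifelse(.data$prev_outcome < 0, .data$prev_outcome, 0),
      prev_gain_x_choice = .data$prev_gain_amount * .data$prev_choice,
      prev_outcome_x_risky_gain = .data$prev_outcome * .data$risky_gain,
      prev_outcome_x_risky_loss = .data$prev_outcome * .data$risky_loss,
      prev_outcome_x_guaranteed = .data$prev_outcome * .data$guaranteed
    ) |>
    dplyr::ungroup()

  feats <- switch(model_id,
    c("prev_outcome"),
    c("prev_choice"),
    c("prev_mean_ev"),
    c("prev_outcome", "prev_choice", "prev_mean_ev"),
    c("prev_outcome", "prev_outcome2", "prev_outcome3"),
    c("prev_outcome", "prev_valence"),
    c("prev_out_risky_gain", "prev_out_risky_loss", "prev_out_guaranteed"),
    c("prev_gain_amount", "prev_loss_amount", "prev_choice", "prev_gain_x_choice"),
    c("prev_outcome", "prev_outcome_x_risky_gain", "prev_outcome_x_risky_loss",
      "prev_outcome_x_guaranteed")
  )
  keep <- c("participant_id", "choice", "risky_gain", "risky_loss",
            "guaranteed", feats)
  out <- d[stats::complete.cases(d[feats]), keep]
  structure(tibble::as_tibble(out),
            class = c("pt_design", class(tibble::tibble())),
            model_id = as.integer(model_id),
            predictors = c("risky_gain", "risky_loss", "guaranteed", feats),
            n_excluded = nrow(d) - nrow(out))
}

#' Fit a random-intercept logistic regression
#'
#' Maximizes the marginal likelihood of a logistic model with the design's
#' fixed effects and a normally distributed per-participant intercept,
#' integrating the random effect by adaptive Gauss-Hermite quadrature.
#'
#' @param design A `pt_design` from [build_design()].
#' @param nAGQ Number of quadrature nodes (>= 15 recommended for accurate
#'   marginal likelihoods).
#' @return An object of class `pt_glmm`: coefficient table (estimate, SE,
#'   z, two-sided p from the normal approximation), random-intercept SD,
#'   log-likelihood, sample sizes, and the underlying `lme4` fit.
#' @export
fit_glmm <- function(design, nAGQ = 15) {
  stopifnot(inherits(design, "pt_design"))
  if (length(unique(design$participant_id)) < 2) {
    stop("need >= 2 participants to estimate a random intercept", call. = FALSE)
  }
  preds <- attr(design, "predictors")
  fml <- stats::as.formula(
    paste("choice ~", paste(preds, collapse = " + "), "+ (1 | participant_id)")
  )
  fit <- tryCatch(
    lme4::glmer(fml, data = design, family = stats::binomial, nAGQ = nAGQ),
    error = function(e) stop("glmm estimation failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  sm <- summary(fit)
  co <- sm$coefficients
  coefs <- tibble::tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    std_error = co[, "Std. Error"],
    statistic = co[, "z value"],
    p_value = co[, "Pr(>|z|)"]
  )
  structure(list(
    model_id = attr(design, "model_id"),
    coefficients = coefs,
    sigma_intercept = sqrt(unname(lme4::VarCorr(fit)$participant_id[1, 1])),
    loglik = as.numeric(stats::logLik(fit)),
    df = attr(stats::logLik(fit), "df"),
    n_obs = nrow(design),
    n_participants = length(unique(design$participant_id)),
    n_excluded = attr(design, "n_excluded"),
    vcov = as.matrix(stats::vcov(fit)),
    fit = fit
  ), class = "pt_glmm")
}

#' @export
print.pt_glmm <- function(x, ...) {
  cat("<pt_glmm> model", x$model_id, "| logLik", format(x$loglik),
      "| n =", x$n_obs, "obs /", x$n_participants, "participants\n")
  print(x$coefficients)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy pt_glmm
#' @export
tidy.pt_glmm <- function(x, ...) x$coefficients

#' @method glance pt_glmm
#' @export
glance.pt_glmm <- function(x, ...) {
  tibble::tibble(model_id = x$model_id, logLik = x$loglik, df = x$df,
                 sigma_intercept = x$sigma_intercept, n_obs = x$n_obs,
                 n_participants = x$n_participants, n_excluded = x$n_excluded)
}

#' Rank models by log-likelihood
#'
#' Orders fitted regressions by log-likelihood, descending, so the
#' best-fitting (least negative) model ranks first. Only models with equal
#' parameter counts are comparable this way; use [lrt()] for nested pairs.
#'
#' @param results List of `pt_glmm` fits.
#' @return Tibble with `model_id`, `logLik`, `rank` (stable under ties).
#' @export
compare_loglik <- function(results) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, TRUE, "pt_glmm")))
  dfs <- vapply(results, function(r) r$df, numeric(1))
  if (length(unique(dfs)) > 1) {
    stop("models have unequal parameter counts; use lrt() for nested models",
         call. = FALSE)
  }
  tab <- purrr::map_dfr(results, function(r) {
    tibble::tibble(model_id = r$model_id, logLik = r$loglik)
  })
  tab$rank <- rank(-tab$logLik, ties.method = "first")
  dplyr::arrange(tab, .data$rank)
}

#' Likelihood-ratio test of nested regressions
#'
#' `statistic = 2 * (logLik(full) - logLik(nested))`, compared against a
#' chi-square with `df` degrees of freedom (defaults to the difference in
#' parameter counts).
#'
#' @param nested,full `pt_glmm` fits, with `nested`'s regressors a subset of
#'   `full`'s.
#' @param df Degrees of freedom of the test.
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @examples
#' lrt_pvalue <- stats::pchisq(1.17, df = 2, lower.tail = FALSE)  # ~0.557
#' @export
lrt <- function(nested, full, df = NULL) {
  stopifnot(inherits(nested, "pt_glmm"), inherits(full, "pt_glmm"))
  if (is.null(df)) df <- full$df - nested$df
  stat <- 2 * (full$loglik - nested$loglik)
  if (stat < -1e-6) {
    stop("full model fits worse than nested model (statistic ",
         format(stat), "); check convergence", call. = FALSE)
  }
  stat <- max(stat, 0)
  tibble::tibble(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Wald test of coefficient equality
#'
#' Tests `beta_a = beta_b` within one fitted model:
#' `statistic = (beta_a - beta_b)^2 / Var(beta_a - beta_b)`, chi-square with
#' one degree of freedom.
#'
#' @param result A `pt_glmm` fit.
#' @param coef_a,coef_b Coefficient names as in `tidy(result)$term`.
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
wald_equality <- function(result, coef_a, coef_b) {
  stopifnot(inherits(result, "pt_glmm"))
  terms <- result$coefficients$term
  if (!all(c(coef_a, coef_b) %in% terms)) {
    stop("coefficients not found: ",
         paste(setdiff(c(coef_a, coef_b), terms), collapse = ", "),
         call. = FALSE)
  }
  b <- stats::setNames(result$coefficients$estimate, terms)
  V <- result$vcov
  diff <- b[[coef_a]] - b[[coef_b]]
  v <- V[coef_a, coef_a] + V[coef_b, coef_b] - 2 * V[coef_a, coef_b]
  if (!is.finite(v) || v <= 0) stop("non-positive variance of the difference",
                                    call. = FALSE)
  stat <- diff^2 / v
  tibble::tibble(statistic = stat, df = 1,
                 p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Choice probability at indifference implied by a lagged-outcome coefficient
#'
#' If the current options contribute zero net logit (the participant is
#' indifferent between gamble and guaranteed), a previous-outcome slope
#' `beta_prev` implies a gambling probability `plogis(beta_prev *
#' prev_outcome)`. With the published slope of -0.03 per dollar this gives
#' 35% after a +$20 outcome and 65% after -$20.
#'
#' @param beta_prev Previous-outcome coefficient (logit per dollar).
#' @param prev_outcome Previous outcome(s), dollars. Vectorized.
#' @return Probability of choosing the risky option.
#' @examples
#' indifference_probability(-0.03, c(-20, 0, 20))
#' @export
indifference_probability <- function(beta_prev, prev_outcome) {
  stopifnot(is.finite(beta_prev), all(is.finite(prev_outcome)))
  stats::plogis(beta_prev * prev_outcome)
}

#' Effective loss weight implied by an outcome-by-loss interaction
#'
#' Illustrates how the previous outcome changes the weight the current
#' choice puts on potential losses: the effective slope on the current risky
#' loss is `base_loss_coef + interaction_coef * scaling(prev_outcome)`. Sign
#' convention: the current risky loss is coded in (negative) dollars, so a
#' *positive* effective weight means larger potential losses deter gambling;
#' a larger weight means losses matter more.
#'
#' @param base_loss_coef Coefficient on the current risky loss.
#' @param interaction_coef Coefficient on previous-outcome-by-risky-loss.
#' @param prev_outcome Previous outcome(s), dollars. Vectorized.
#' @param scaling Function applied to `prev_outcome` before multiplying the
#'   interaction (identity by default, i.e. dollar units).
#' @return Tibble with `prev_outcome` and `loss_weight`.
#' @export
loss_weight_illustration <- function(base_loss_coef, interaction_coef,
                                     prev_outcome, scaling = identity) {
  tibble::tibble(
    prev_outcome = prev_outcome,
    loss_weight = base_loss_coef + interaction_coef * scaling(prev_outcome)
  )
}
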