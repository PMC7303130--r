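#' PT+ parameter sets
#'
#' `pt_params()` bundles the four Prospect Theory Plus parameters: the
#' risk-attitude exponent `rho` (> 0; below 1 means risk aversion for gains
#' and, by reflection, risk seeking for losses), the loss-aversion multiplier
#' `lam` (> 0; above 1 overweights losses), the softmax inverse temperature
#' `mu` (>= 0; 0 is fully random choice), and the decision bias `db`
#' (utility units; negative values bias toward gambling). `pt_deltas()`
#' bundles the four per-trial updating terms, one per parameter: the additive
#' shift applied per unit of the previous trial's outcome after that outcome
#' has been rescaled to \[0, 1\]. Zero means no updating.
#'
#' @param rho Risk-attitude exponent, > 0.
#' @param lam Loss-aversion multiplier, > 0.
#' @param mu Choice consistency (inverse temperature), >= 0.
#' @param db Decision bias, any finite value.
#' @return A named list of class `pt_params`.
#' @examples
#' pt_params(rho = 0.8, lam = 1.5, mu = 1, db = 0)
#' @export
pt_params <- function(rho, lam, mu, db) {
  stopifnot(is.numeric(rho), is.numeric(lam), is.numeric(mu), is.numeric(db))
  if (!all(is.finite(c(rho, lam, mu, db)))) {
    stop("all PT+ parameters must be finite", call. = FALSE)
  }
  if (rho <= 0) stop("`rho` must be > 0", call. = FALSE)
  if (lam <= 0) stop("`lam` must be > 0", call. = FALSE)
  if (mu < 0) stop("`mu` must be >= 0", call. = FALSE)
  structure(list(rho = rho, lam = lam, mu = mu, db = db),
            class = "pt_params")
}

#' @param d_rho,d_lam,d_mu,d_db Additive shift per unit scaled outcome for
#'   `rho`, `lam`, `mu`, `db` respectively.
#' @rdname pt_params
#' @export
pt_deltas <- function(d_rho = 0, d_lam = 0, d_mu = 0, d_db = 0) {
  v <- c(d_rho, d_lam, d_mu, d_db)
  if (!all(is.finite(v))) stop("all updating terms must be finite", call. = FALSE)
  structure(list(d_rho = d_rho, d_lam = d_lam, d_mu = d_mu, d_db = d_db),
            class = "pt_deltas")
}

#' @export
print.pt_params <- function(x, ...) {
  cat("<pt_params> rho =", x$rho, " lam =", x$lam,
      " mu =", x$mu, " db =", x$db, "\n")
  invisible(x)
}

#' @export
print.pt_deltas <- function(x, ...) {
  cat("<pt_deltas> d_rho =", x$d_rho, " d_lam =", x$d_lam,
      " d_mu =", x$d_mu, " d_db =", x$d_db, "\n")
  invisible(x)
}

# Support floor applied when updating drives rho/lam/mu toward zero.
.pt_floor_eps <- 1e-6

#' Published group-level parameter values
#'
#' Group-mean estimates for the eight dynamic PT+ parameters reported for the
#' pooled gambling-task sample: baseline risk attitude, loss aversion, choice
#' consistency and decision bias, plus the four updating terms. These are the
#' default generating values for the simulation presets and parameter-recovery
#' experiments.
#'
#' @return A tibble with columns `parameter` and `value`.
#' @examples
#' pt_reference_means()
#' @export
pt_reference_means <- function() {
  tibble::tibble(
    parameter = c("rho", "lam", "mu", "db", "d_rho", "d_lam", "d_mu", "d_db"),
    value = c(0.65, 1.57, 22.2, -0.58, 0.005, 0.013, 0.08, 0.03)
  )
}
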