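# broom-style tidiers for fitted objects.

#' Tidy a rate fit
#'
#' @param x An `mk_fit` from [fit_rates()].
#' @param ... Unused.
#' @return A tibble with one row per rate constant: `term`, `estimate`
#'   (s^-1), `fixed`.
#' @export
tidy.mk_fit <- function(x, ...) {
  all_rates <- unlist(unclass(x$rates))
  tibble(term = names(all_rates), estimate = as.numeric(all_rates),
         fixed = !names(all_rates) %in% x$free)
}

#' Glance at a rate fit
#'
#' @inheritParams tidy.mk_fit
#' @return A one-row tibble: `mechanism`, `logLik`, `AIC`, `BIC`, `sigma`,
#'   `n_parameters`, `n_obs`, `converged`.
#' @export
glance.mk_fit <- function(x, ...) {
  tibble(mechanism = x$mechanism$kind, logLik = x$logLik, AIC = x$AIC,
         BIC = x$BIC, sigma = x$sigma, n_parameters = x$n_parameters,
         n_obs = x$n_obs, converged = x$converged)
}

#' Tidy a mechanism selection
#'
#' @param x An `mk_selection` from [select_mechanism()].
#' @param ... Unused.
#' @return The per-mechanism AIC table, best first (`delta_AIC = 0`).
#' @export
tidy.mk_selection <- function(x, ...) x$table

#' Glance at a mechanism selection
#'
#' @inheritParams tidy.mk_selection
#' @return A one-row tibble: the selected mechanism and its AIC margin over
#'   the runner-up.
#' @export
glance.mk_selection <- function(x, ...) {
  margin <- if (nrow(x$table) > 1) x$table$delta_AIC[2] else NA_real_
  tibble(best = x$best, aic_margin = margin,
         n_candidates = nrow(x$table))
}

#' Tidy a phenotype call
#'
#' @param x An `mk_phenotype` from [classify_phenotype()].
#' @param ... Unused.
#' @return A one-row tibble with the class and its supporting metrics.
#' @export
tidy.mk_phenotype <- function(x, ...) {
  tibble(class = x$class, sc_end = x$sc_end, peak_oc = x$peak_oc,
         lin_end = x$lin_end, yield_end = x$yield_end, t_end = x$t_end)
}
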