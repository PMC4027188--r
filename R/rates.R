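# Rate constants, their default calibration, and transposase variants.

#' Rate constants of the cleavage state machine
#'
#' All first-order rate constants, in s^-1:
#' * `k_syn` — pseudo-first-order synapsis of the two ends (transposase is in
#'   excess over substrate, so binding is folded into this single step);
#' * `k_nts` — NTS nicking, per end;
#' * `k_trans` — the coordinated conformational transition between NTS and TS
#'   cleavage (constrained mechanism only);
#' * `k_ts` — TS cleavage chemistry, per end;
#' * `k_int` — lumped integration of the excised transposon into a target.
#'
#' @param k_syn,k_nts,k_trans,k_ts,k_int Non-negative finite rates, s^-1.
#' @return An object of class `mk_rates` (a named list).
#' @seealso [default_rates()] for the calibrated defaults.
#' @export
rate_set <- function(k_syn, k_nts, k_trans, k_ts, k_int = k_ts) {
  r <- list(k_syn = k_syn, k_nts = k_nts, k_trans = k_trans,
            k_ts = k_ts, k_int = k_int)
  for (nm in names(r)) {
    if (!is.numeric(r[[nm]]) || length(r[[nm]]) != 1L ||
        !is.finite(r[[nm]]) || r[[nm]] < 0) {
      abort(sprintf("`%s` must be a single finite rate >= 0", nm))
    }
  }
  structure(r, class = "mk_rates")
}

#' @export
print.mk_rates <- function(x, ...) {
  cat("<rate set, s^-1>\n")
  for (nm in names(x)) cat(sprintf("  %-8s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

# Survival of the supercoiled class (FREE + synapsed-uncut) for a wild-type
# substrate: two sequential exponential stages, synapsis at r1 and the first
# nick (either end) at r2.
.sc_survival <- function(t, r1, r2) {
  if (abs(r1 - r2) < 1e-12 * max(r1, r2)) {
    return(exp(-r1 * t) * (1 + r1 * t))
  }
  (r2 * exp(-r1 * t) - r1 * exp(-r2 * t)) / (r2 - r1)
}

# Survival of the "no TS cut yet" set for the wild-type constrained chain:
# FREE -> UU -> one-nick -> NN/pre -> NN/post -> (first TS cut exits).
.ts_survival <- function(t, k_syn, k_nts, k_trans, k_ts) {
  rates <- c(k_syn, 2 * k_nts, k_nts, k_trans, 2 * k_ts)
  n <- length(rates) + 1L
  Q <- matrix(0, n, n)
  for (i in seq_along(rates)) {
    Q[i, i] <- -rates[i]
    Q[i, i + 1L] <- rates[i]
  }
  p0 <- c(1, rep(0, n - 1L))
  p <- as.numeric(p0 %*% .expm(Q * t))
  sum(p[seq_along(rates)])
}

#' Calibrate default rate constants from the two observed half-lives
#'
#' Under the constrained mechanism with a wild-type substrate, solves for the
#' rate constants such that (i) the supercoiled substrate is consumed with the
#' stated half-life and (ii) half the molecules have suffered their first TS
#' cut at the stated TS half-life. Synapsis is taken as rate-limiting for SC
#' consumption (`k_nts = nts_to_syn * k_syn`, default 10: nicking is fast once
#' the ends are synapsed), and the coordinated transition as rate-limiting for
#' TS cleavage (`k_ts = ts_to_trans * k_trans`, default 10). `k_int = k_ts`.
#'
#' @param nts_half_life Target SC-consumption (synapsis + first nick)
#'   half-life, s. Default 30 s.
#' @param ts_half_life Target first-TS-cut half-life, s. Default 900 s
#'   (15 min).
#' @param nts_to_syn,ts_to_trans Fixed rate ratios apportioning each
#'   half-life between its two steps.
#' @return A [rate_set()].
#' @export
#' @examples
#' calibrate_rates()
calibrate_rates <- function(nts_half_life = 30, ts_half_life = 900,
                            nts_to_syn = 10, ts_to_trans = 10) {
  stopifnot(nts_half_life > 0, ts_half_life > nts_half_life)
  k_syn <- uniroot(
    function(k) .sc_survival(nts_half_life, k, 2 * nts_to_syn * k) - 0.5,
    interval = c(1e-8, 1e3) / nts_half_life, tol = 1e-14
  )$root
  k_nts <- nts_to_syn * k_syn
  k_trans <- uniroot(
    function(k) .ts_survival(ts_half_life, k_syn, k_nts, k, ts_to_trans * k) - 0.5,
    interval = c(1e-10, 1e4) / ts_half_life, tol = 1e-14
  )$root
  rate_set(k_syn = k_syn, k_nts = k_nts, k_trans = k_trans,
           k_ts = ts_to_trans * k_trans)
}

.mk_cache <- new.env(parent = emptyenv())

#' Default calibrated rate constants
#'
#' The package default rates: SC-consumption half-life 30 s and TS-cleavage
#' half-life 15 min, with synapsis and the coordinated transition as the
#' respective rate-limiting steps. Computed once per session by
#' [calibrate_rates()] and cached.
#'
#' @return A [rate_set()].
#' @export
default_rates <- function() {
  if (is.null(.mk_cache$default_rates)) {
    .mk_cache$default_rates <- calibrate_rates()
  }
  .mk_cache$default_rates
}

#' Transposase variant
#'
#' Multiplicative modifiers applied by a mutant transposase to the whole
#' transpososome: `syn_multiplier` on synapsis, `trans_multiplier` on the
#' coordinated transition, `ts_multiplier` on TS chemistry, plus an optional
#' override of the coupling rule by which the two ends' competences combine.
#' Presets: `"WT"`; `"W118R"` (hyperactive linker mutant: fast synapsis,
#' mildly slowed transition, and a brittle, multiplicative coupling that
#' cannot rescue a defective partner end); `"V119G"` (hypoactive linker
#' mutant: fast synapsis but a strongly impaired transition).
#'
#' @param name `"WT"`, `"W118R"`, `"V119G"` or `"custom"`.
#' @param syn_multiplier,trans_multiplier,ts_multiplier Non-negative
#'   multipliers (ignored for the named presets, which fix their own values).
#' @param coupling_override Optional coupling rule (`"additive"`,
#'   `"multiplicative"`, `"min"`) replacing the mechanism's rule.
#' @return An object of class `mk_tpase`.
#' @export
transposase_variant <- function(name = c("WT", "W118R", "V119G", "custom"),
                                syn_multiplier = 1, trans_multiplier = 1,
                                ts_multiplier = 1, coupling_override = NULL) {
  name <- match.arg(name)
  preset <- switch(name,
    WT = list(1, 1, 1, NULL),
    W118R = list(5, 0.5, 1, "multiplicative"),
    V119G = list(5, 0.05, 1, NULL),
    custom = list(syn_multiplier, trans_multiplier, ts_multiplier,
                  coupling_override)
  )
  m <- c(preset[[1]], preset[[2]], preset[[3]])
  if (any(!is.finite(m)) || any(m < 0)) abort("multipliers must be finite and >= 0")
  if (!is.null(preset[[4]])) {
    preset[[4]] <- match.arg(preset[[4]], c("additive", "multiplicative", "min"))
  }
  structure(list(name = name, syn_multiplier = preset[[1]],
                 trans_multiplier = preset[[2]], ts_multiplier = preset[[3]],
                 coupling_override = preset[[4]]),
            class = "mk_tpase")
}

#' @export
print.mk_tpase <- function(x, ...) {
  cat(sprintf("<transposase '%s'> syn x%g, transition x%g, ts x%g%s\n",
              x$name, x$syn_multiplier, x$trans_multiplier, x$ts_multiplier,
              if (is.null(x$coupling_override)) "" else
                paste0(", coupling -> ", x$coupling_override)))
  invisible(x)
}
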