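# Rate fitting, mechanism discrimination by AIC, diagnostics and phenotype
# calls.

.rate_names <- c("k_syn", "k_nts", "k_trans", "k_ts", "k_int")

# Model-predicted observables on the data's (time, observable) support.
.predict_observables <- function(mech, rates, sub, tpase, t_grid, observables) {
  Q <- suppressWarnings(build_generator(mech, rates, sub, tpase))
  tc <- solve_master(Q, t_grid)
  out <- list()
  if ("native" %in% observables) {
    nf <- native_fractions(tc, mech)
    out$native <- tibble(time_s = nf$time_s,
                         observable = as.character(nf$species),
                         value = nf$fraction)
  }
  if ("seb_nick" %in% observables) {
    seb <- .seb_states(mech)
    m <- tc_matrix(tc)
    mass <- rowSums(m[, seb$all, drop = FALSE])
    nicked <- rowSums(m[, seb$partner_nicked, drop = FALSE])
    p <- ifelse(mass > 0, nicked / mass, 0)
    out$seb_nick <- tibble(time_s = t_grid, observable = "seb_nick", value = p)
  }
  if ("denaturing" %in% observables) {
    out$denaturing <- .denaturing_observables(tc, mech)
  }
  bind_rows(out)
}

# Column-index sets of the state matrix for each observable label, cached
# per mechanism kind (hot path of the likelihood).
.obs_cols <- function(kind) {
  cached <- .mk_cache$obs_cols[[kind]]
  if (!is.null(cached)) return(cached)
  st <- enumerate_states(kind)
  cls <- native_species(st$state, kind)
  seb <- .seb_states(kind)
  out <- list(
    SC = which(cls == "SC"), OC = which(cls == "OC"),
    LIN = which(cls == "LIN"), BB_ETF = which(cls == "BB_ETF"),
    INTEGRATED = which(cls == "INTEGRATED"),
    nts_left = which(st$left != "U"), nts_right = which(st$right != "U"),
    ts_left = which(st$left == "D"), ts_right = which(st$right == "D"),
    seb_all = match(seb$all, st$state),
    seb_nicked = match(seb$partner_nicked, st$state)
  )
  if (is.null(.mk_cache$obs_cols)) .mk_cache$obs_cols <- list()
  .mk_cache$obs_cols[[kind]] <- out
  out
}

# Fast model prediction: (time x label) matrix from one master-equation
# solve, no tibbles.
.predict_matrix <- function(mech, rates, sub, tpase, t_grid, labels, oc) {
  Q <- suppressWarnings(build_generator(mech, rates, sub, tpase))
  m <- .propagate(Q, t_grid, c(1, numeric(ncol(Q) - 1L)))
  P <- matrix(0, length(t_grid), length(labels))
  for (j in seq_along(labels)) {
    lab <- labels[j]
    if (lab == "seb_nick") {
      tot <- rowSums(m[, oc$seb_all, drop = FALSE])
      nick <- rowSums(m[, oc$seb_nicked, drop = FALSE])
      P[, j] <- ifelse(tot > 0, nick / tot, 0)
    } else {
      P[, j] <- rowSums(m[, oc[[lab]], drop = FALSE])
    }
  }
  P
}

# Latin-hypercube starting points in [0,1]^d, deterministic under the
# caller's RNG state.
.lhs_unit <- function(n, d) {
  vapply(seq_len(d), function(j) (sample.int(n) - runif(n)) / n,
         numeric(n))
}

#' Fit rate constants to a quantified-gel dataset
#'
#' Maximizes a Gaussian log-likelihood on log-intensities,
#' `log(value + floor)` vs `log(model + floor)` — the natural scale for the
#' multiplicative lognormal noise of gel densitometry — over the chosen free
#' rate constants, by bounded multi-start quasi-Newton optimization in
#' log10-rate space. The noise standard deviation is profiled out
#' analytically and counts as one fitted parameter. Deterministic for a fixed
#' `seed`.
#'
#' @param data An `mk_dataset` (or a tibble with columns `time_s`,
#'   `observable`, `value`, and optionally `replicate`).
#' @param mech Mechanism to fit (spec or kind string).
#' @param free Character vector of free rates among
#'   `k_syn, k_nts, k_trans, k_ts`; `k_trans` is dropped automatically for
#'   non-constrained mechanisms. `k_int` is tied to the fitted `k_ts`
#'   when both start equal in `rates_init`.
#' @param rates_init Baseline [rate_set()] providing fixed rates and the
#'   first start; defaults to [default_rates()].
#' @param sub,tpase Substrate and transposase context; taken from the
#'   dataset's generating truth when available.
#' @param bounds Length-2 rate bounds, s^-1, for all free rates.
#' @param n_starts Number of optimization starts (first at `rates_init`,
#'   the rest Latin-hypercube in log-rate space).
#' @param seed Integer seed for the starts.
#' @param floor Additive floor inside the logs.
#' @return An object of class `mk_fit`; see [tidy()] and [glance()] methods.
#' @export
fit_rates <- function(data, mech, free = c("k_nts", "k_trans", "k_ts"),
                      rates_init = NULL, sub = NULL, tpase = NULL,
                      bounds = c(1e-6, 10), n_starts = 10, seed = 1,
                      floor = 1e-4) {
  mech <- as_mechanism(mech)
  truth <- attr(data, "truth")
  sub <- sub %||% truth$substrate %||% substrate()
  tpase <- tpase %||% truth$tpase %||% transposase_variant("WT")
  rates_init <- rates_init %||% default_rates()
  if (length(free)) free <- match.arg(free, .rate_names, several.ok = TRUE)
  if (mech$kind != "constrained") free <- setdiff(free, "k_trans")
  tie_int <- !("k_int" %in% free) &&
    isTRUE(all.equal(rates_init$k_int, rates_init$k_ts))

  contexts <- attr(data, "contexts")
  data <- as_tibble(data)
  if (!"replicate" %in% names(data)) data$replicate <- 1L
  if (!"scenario" %in% names(data)) data$scenario <- "custom"
  if (is.null(contexts)) {
    contexts <- list()
    for (sc in unique(data$scenario)) {
      contexts[[sc]] <- list(substrate = sub, tpase = tpase)
    }
  }
  missing_ctx <- setdiff(unique(data$scenario), names(contexts))
  if (length(missing_ctx)) {
    abort(sprintf("no substrate/transposase context for scenario(s): %s",
                  paste(missing_ctx, collapse = ", ")))
  }
  known_labels <- c("SC", "OC", "LIN", "BB_ETF", "INTEGRATED", "seb_nick",
                    "nts_left", "nts_right", "ts_left", "ts_right")
  data <- data[data$observable %in% known_labels, ]
  if (!nrow(data)) abort("no recognized observables in `data`")
  oc <- .obs_cols(mech$kind)
  scen_info <- lapply(unique(data$scenario), function(sc) {
    rows <- which(data$scenario == sc)
    d <- data[rows, ]
    labels <- unique(d$observable)
    t_grid <- sort(unique(d$time_s))
    list(scenario = sc, rows = rows, t_grid = t_grid, labels = labels,
         idx = cbind(match(d$time_s, t_grid), match(d$observable, labels)),
         sub = contexts[[sc]]$substrate, tpase = contexts[[sc]]$tpase)
  })

  n_informative <- nrow(distinct(data, .data$scenario, .data$time_s,
                                 .data$observable))
  flagged <- length(free) >= n_informative
  if (flagged) {
    warn("more free parameters than informative observables: fit flagged as non-identifiable")
  }

  make_rates <- function(theta) {
    r <- unclass(rates_init)
    r[free] <- as.list(10^theta)
    if (tie_int) r$k_int <- r$k_ts
    do.call(rate_set, r)
  }
  log_obs <- log(data$value + floor)
  n_obs <- nrow(data)
  predict_all <- function(rates) {
    pv <- rep(NA_real_, n_obs)
    for (si in scen_info) {
      P <- .predict_matrix(mech, rates, si$sub, si$tpase, si$t_grid,
                           si$labels, oc)
      pv[si$rows] <- P[si$idx]
    }
    pv
  }
  negll <- function(theta) {
    pv <- predict_all(make_rates(theta))
    if (anyNA(pv)) return(1e10)
    r <- log_obs - log(pv + floor)
    s2 <- mean(r^2)
    if (!is.finite(s2) || s2 <= 0) s2 <- 1e-12
    n_obs / 2 * (log(2 * pi * s2) + 1)
  }

  lo <- log10(bounds[1]); hi <- log10(bounds[2])
  if (length(free)) {
    init <- pmin(pmax(log10(unlist(unclass(rates_init)[free])), lo), hi)
    starts <- matrix(init, nrow = 1)
    if (n_starts > 1) {
      extra <- .with_seed(seed, .lhs_unit(n_starts - 1L, length(free)))
      starts <- rbind(starts, lo + extra * (hi - lo))
    }
    runs <- lapply(seq_len(nrow(starts)), function(i) {
      tryCatch(
        optim(starts[i, ], negll, method = "L-BFGS-B", lower = lo, upper = hi,
              control = list(factr = 1e4, maxit = 500)),
        error = function(e) list(value = Inf, par = starts[i, ],
                                 convergence = 99)
      )
    })
  } else {
    # nothing to optimize: evaluate the likelihood at the supplied rates
    starts <- matrix(numeric(0), nrow = 1, ncol = 0)
    runs <- list(list(par = numeric(0), value = negll(numeric(0)),
                      convergence = 0))
  }
  vals <- vapply(runs, function(r) r$value, numeric(1))
  best <- runs[[which.min(vals)]]
  # did a second start land on the same optimum (parameter agreement in
  # log10-rate space)? objective values are not comparable near the optimum
  # of noiseless data, where the profiled variance makes the well
  # arbitrarily deep
  replicated <- if (nrow(starts) > 1 && length(best$par)) {
    hits <- vapply(runs, function(r) {
      is.finite(r$value) && max(abs(r$par - best$par)) <= 1e-3
    }, logical(1))
    sum(hits) >= 2
  } else NA
  # optimizer success, or an abnormal line-search stop at an optimum that
  # another start reproduced
  converged <- best$convergence == 0 || isTRUE(replicated)

  est_rates <- make_rates(best$par)
  pv <- predict_all(est_rates)
  sigma <- sqrt(mean((log_obs - log(pv + floor))^2))
  fitted <- data %>%
    select("scenario", "time_s", "observable") %>%
    mutate(value = pv) %>%
    distinct()
  ll <- -best$value
  p <- length(free) + 1L  # + profiled noise sd
  structure(
    list(mechanism = mech, free = free,
         estimates = setNames(as.numeric(10^best$par), free),
         rates = est_rates, sigma = sigma, logLik = ll,
         AIC = 2 * p - 2 * ll, BIC = p * log(n_obs) - 2 * ll,
         n_parameters = p, n_obs = n_obs, converged = converged,
         replicated = replicated,
         flagged_non_identifiable = flagged, n_starts = nrow(starts),
         seed = seed, contexts = contexts, floor = floor,
         fitted = fitted, data = data),
    class = "mk_fit"
  )
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("<%s-mechanism fit> logLik %.2f, AIC %.2f, %s\n",
              x$mechanism$kind, x$logLik, x$AIC,
              if (x$converged) "converged" else "NOT converged"))
  for (nm in x$free) cat(sprintf("  %-8s %.5g s^-1\n", nm, x$estimates[[nm]]))
  cat(sprintf("  sigma    %.4g (log scale)\n", x$sigma))
  invisible(x)
}

#' Discriminate cleavage mechanisms by information criteria
#'
#' Fits each candidate mechanism to the same dataset with the same free
#' parameters (plus `k_trans` for the constrained candidate, which alone has
#' the coordinated transition) and ranks them by AIC; ties break by BIC, then
#' by fewer parameters. A candidate whose fit fails is excluded with a
#' warning.
#'
#' @inheritParams fit_rates
#' @param mechanisms Candidate mechanism kinds (>= 2).
#' @param free Free rates shared by all candidates.
#' @param ... Passed on to [fit_rates()].
#' @return An object of class `mk_selection`: `table` (per-mechanism tibble
#'   with `delta_AIC`), `fits` (named list of `mk_fit`), `best` (the selected
#'   mechanism kind).
#' @export
select_mechanism <- function(data,
                             mechanisms = c("independent", "sequential",
                                            "constrained"),
                             free = c("k_syn", "k_nts", "k_ts"),
                             n_starts = 5, seed = 1, ...) {
  if (length(mechanisms) < 2) abort("supply at least two candidate mechanisms")
  fits <- list()
  for (mk in mechanisms) {
    f <- tryCatch(
      fit_rates(data, mk,
                free = if (mk == "constrained") union(free, "k_trans") else free,
                n_starts = n_starts, seed = seed, ...),
      error = function(e) {
        warn(sprintf("fit of the %s mechanism failed (%s); candidate excluded",
                     mk, conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(f)) fits[[mk]] <- f
  }
  if (!length(fits)) abort("all candidate fits failed")
  tab <- bind_rows(lapply(names(fits), function(mk) {
    f <- fits[[mk]]
    tibble(mechanism = mk, n_parameters = f$n_parameters, logLik = f$logLik,
           AIC = f$AIC, BIC = f$BIC, converged = f$converged)
  }))
  tab <- tab[order(tab$AIC, tab$BIC, tab$n_parameters), ]
  tab$delta_AIC <- tab$AIC - tab$AIC[1]
  tab$selected <- seq_len(nrow(tab)) == 1L
  structure(list(table = tab, fits = fits, best = tab$mechanism[1]),
            class = "mk_selection")
}

#' @export
print.mk_selection <- function(x, ...) {
  cat(sprintf("<mechanism selection> best: %s\n", x$best))
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}

#' Diagnostic statistics of a reaction time course
#'
#' Computes the three summary statistics used to compare reactions: the
#' partner-nick probability of the SEB intermediate (at `t_nick`), the peak
#' fraction of the open-circular (nicked) class, and — when a reference
#' (wild-type) time course is supplied — the rescue ratio, i.e. the cumulative
#' excision yield at `t_end` relative to the reference. A statistic that is
#' unavailable (e.g. no SEB mass) is reported as `NA`, not zero.
#'
#' @param tc A time course.
#' @param reference Optional reference time course for the rescue ratio.
#' @param t_nick Time at which the partner-nick probability is evaluated, s.
#' @param t_end End point for yields, s.
#' @param mech Mechanism if `tc` lacks the attribute.
#' @return A tibble `metric`, `value`.
#' @export
diagnostics <- function(tc, reference = NULL, t_nick = 900, t_end = 10800,
                        mech = NULL) {
  mech <- mech %||% attr(tc, "mechanism")
  nick <- tryCatch(seb_partner_nick_prob(tc, t_nick, mech),
                   error = function(e) NA_real_)
  oc <- native_fractions(tc, mech)
  peak_oc <- max(oc$fraction[oc$species == "OC"])
  rescue <- if (is.null(reference)) NA_real_ else
    excision_yield(tc, t_end) / excision_yield(reference, t_end)
  tibble(metric = c("seb_partner_nick_prob", "peak_OC_fraction", "rescue_ratio"),
         value = c(nick, peak_oc, rescue))
}

#' Classify the qualitative phenotype of a reaction
#'
#' Calls one of four phenotype classes from a time course covering at least
#' `t_end`:
#' * `inactive` — the supercoiled substrate is still mostly intact at the end
#'   point (SC fraction > `inactive_sc`);
#' * `nick_stall` — the nicked intermediate accumulates (peak OC >
#'   `stall_oc`) with little double-end cleavage (cumulative yield <
#'   `stall_yield`);
#' * `seb_stall` — the single-end-break intermediate persists (LIN >
#'   `seb_lin` at the end point) with little double-end cleavage;
#' * `fast_complete` — otherwise.
#'
#' @param tc A time course.
#' @param t_end End point, s (default 3 h); the grid must reach it.
#' @param thresholds Named list overriding `inactive_sc` (0.8), `stall_oc`
#'   (0.5), `stall_yield` (0.2), `seb_lin` (0.3).
#' @param mech Mechanism if `tc` lacks the attribute.
#' @return An object of class `mk_phenotype`: `class` plus the supporting
#'   metrics.
#' @export
#' @examples
#' classify_phenotype(scenario_time_course("-1T x -1T"))$class  # nick_stall
classify_phenotype <- function(tc, t_end = 10800, thresholds = list(),
                               mech = NULL) {
  mech <- mech %||% attr(tc, "mechanism")
  if (max(tc$time_s) < t_end) {
    abort(sprintf("time course too short: must reach t_end = %g s", t_end))
  }
  th <- modifyList(list(inactive_sc = 0.8, stall_oc = 0.5, stall_yield = 0.2,
                        seb_lin = 0.3), thresholds)
  nf <- native_fractions(tc, mech)
  at_end <- function(cls) {
    d <- nf[nf$species == cls, ]
    approx(d$time_s, d$fraction, xout = t_end, rule = 2)$y
  }
  sc_end <- at_end("SC")
  lin_end <- at_end("LIN")
  peak_oc <- max(nf$fraction[nf$species == "OC"])
  yield_end <- excision_yield(tc, t_end)
  cls <- if (sc_end > th$inactive_sc) "inactive"
  else if (peak_oc > th$stall_oc && yield_end < th$stall_yield) "nick_stall"
  else if (lin_end > th$seb_lin && yield_end < th$stall_yield) "seb_stall"
  else "fast_complete"
  structure(list(class = cls, sc_end = sc_end, peak_oc = peak_oc,
                 lin_end = lin_end, yield_end = yield_end, t_end = t_end,
                 thresholds = th),
            class = "mk_phenotype")
}

#' @export
print.mk_phenotype <- function(x, ...) {
  cat(sprintf("<phenotype: %s> SC(end)=%.3f peakOC=%.3f LIN(end)=%.3f yield(end)=%.3f\n",
              x$class, x$sc_end, x$peak_oc, x$lin_end, x$yield_end))
  invisible(x)
}
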