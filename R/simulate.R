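# Deterministic (master-equation) and stochastic (Gillespie) time courses.

#' Default sampling time grid
#'
#' Time points mimicking the lanes of a kinetic gel experiment: 0, 15 s,
#' 30 s, 1, 2, 4, 8, 15, 30, 60, 120 and 180 min.
#'
#' @return Numeric vector of times, s.
#' @export
default_time_grid <- function() {
  c(0, 15, 30, 60, 120, 240, 480, 900, 1800, 3600, 7200, 10800)
}

new_time_course <- function(mat, times, mech = NULL) {
  states <- colnames(mat)
  tc <- tibble(
    time_s = rep(times, each = length(states)),
    state = rep(states, length(times)),
    fraction = as.vector(t(mat))
  )
  structure(tc, class = c("mk_tc", class(tibble())),
            states = states, mechanism = mech)
}

#' Wide state-occupancy matrix of a time course
#'
#' @param tc A time course from [solve_master()] or [gillespie()].
#' @return Numeric matrix, times x states, with times as rownames.
#' @export
tc_matrix <- function(tc) {
  states <- attr(tc, "states") %||% unique(tc$state)
  times <- unique(tc$time_s)
  m <- matrix(tc$fraction, nrow = length(times), ncol = length(states),
              byrow = TRUE, dimnames = list(times, states))
  m
}

.check_generator <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) abort("generator must be square")
  if (any(!is.finite(Q))) abort("generator entries must be finite")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) abort("off-diagonal generator entries must be >= 0")
  if (any(abs(rowSums(Q)) > 1e-9 * max(1, max(abs(Q))))) {
    abort("generator rows must sum to zero")
  }
}

# Propagate an initial distribution over a time grid by stepwise matrix
# exponentials; returns a (time x state) matrix.
.propagate_expm <- function(Q, t_grid, p0) {
  n <- ncol(Q)
  out <- matrix(0, length(t_grid), n, dimnames = list(NULL, colnames(Q)))
  p <- p0
  t_prev <- 0
  for (i in seq_along(t_grid)) {
    dt <- t_grid[i] - t_prev
    if (dt > 0) p <- as.numeric(p %*% .expm(Q * dt))
    t_prev <- t_grid[i]
    out[i, ] <- p
  }
  out
}

# Spectral propagator: p(t) = p0 V exp(L t) V^-1. Much faster over many time
# points; returns NULL when the eigenbasis is ill-conditioned (defective or
# nearly defective generator), in which case the caller falls back to
# stepwise exponentials.
.propagate_eigen <- function(Q, t_grid, p0) {
  ev <- tryCatch(eigen(Q), error = function(e) NULL)
  if (is.null(ev)) return(NULL)
  V <- ev$vectors
  Vinv <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vinv)) return(NULL)
  cond1 <- max(colSums(Mod(V))) * max(colSums(Mod(Vinv)))
  if (!is.finite(cond1) || cond1 > 1e9) return(NULL)
  a <- as.vector(p0 %*% V)
  out <- matrix(0, length(t_grid), ncol(Q), dimnames = list(NULL, colnames(Q)))
  for (i in seq_along(t_grid)) {
    out[i, ] <- Re((a * exp(ev$values * t_grid[i])) %*% Vinv)
  }
  # guard against catastrophic cancellation
  if (max(abs(rowSums(out) - 1)) > 1e-7) return(NULL)
  pmin(pmax(out, 0), 1)
}

# Binary-power propagator for grids whose times are integer multiples of a
# common base step: one matrix exponential E = exp(Q d), then p(t) advances
# by cached powers E^(2^j). Exact (up to the one expm) and fast. Returns
# NULL when the grid is not commensurate.
.propagate_power <- function(Q, t_grid, p0) {
  pos <- t_grid[t_grid > 0]
  if (!length(pos)) {
    return(matrix(rep(p0, length(t_grid)), length(t_grid), byrow = TRUE,
                  dimnames = list(NULL, colnames(Q))))
  }
  d <- min(pos)
  k <- round(t_grid / d)
  if (max(k) > 2^20 || any(abs(t_grid - k * d) > 1e-9 * pmax(1, t_grid))) {
    return(NULL)
  }
  n_pow <- max(1L, ceiling(log2(max(k) + 1)))
  pow <- vector("list", n_pow)
  pow[[1]] <- .expm(Q * d)
  for (j in seq_len(n_pow - 1L)) pow[[j + 1L]] <- pow[[j]] %*% pow[[j]]
  out <- matrix(0, length(t_grid), ncol(Q), dimnames = list(NULL, colnames(Q)))
  p <- p0
  k_prev <- 0
  for (i in seq_along(t_grid)) {
    step <- k[i] - k_prev
    j <- 1L
    while (step > 0) {
      if (step %% 2L == 1L) p <- as.numeric(p %*% pow[[j]])
      step <- step %/% 2L
      j <- j + 1L
    }
    k_prev <- k[i]
    out[i, ] <- p
  }
  out
}

.propagate <- function(Q, t_grid, p0, method = c("auto", "eigen", "expm")) {
  method <- match.arg(method)
  if (method == "auto") {
    out <- .propagate_power(Q, t_grid, p0)
    if (!is.null(out)) return(out)
    out <- .propagate_eigen(Q, t_grid, p0)
    if (!is.null(out)) return(out)
  }
  if (method == "eigen") {
    out <- .propagate_eigen(Q, t_grid, p0)
    if (is.null(out)) abort("eigen propagation failed for this generator")
    return(out)
  }
  .propagate_expm(Q, t_grid, p0)
}

#' Solve the master equation of a cleavage generator
#'
#' Propagates the state distribution p(t) = p(0) exp(Q t) over a time grid.
#' All mass starts in FREE unless `p0` is given.
#'
#' @param generator Rate matrix from [build_generator()].
#' @param t_grid Strictly increasing times, s; first value >= 0.
#' @param p0 Optional initial distribution over the generator's states.
#' @param method `"auto"` (spectral propagator with automatic fallback),
#'   `"eigen"`, or `"expm"` (stepwise scaling-and-squaring matrix
#'   exponentials); the two routes agree to well below 1e-8 on these small
#'   generators.
#' @return A tidy time course (class `mk_tc`): columns `time_s`, `state`,
#'   `fraction`; every time point sums to 1.
#' @export
#' @examples
#' Q <- build_generator("constrained")
#' tc <- solve_master(Q, default_time_grid())
#' native_fractions(tc)
solve_master <- function(generator, t_grid = default_time_grid(), p0 = NULL,
                         method = c("auto", "eigen", "expm")) {
  .check_generator(generator)
  if (any(diff(t_grid) <= 0) || t_grid[1] < 0) {
    abort("t_grid must be strictly increasing and start at >= 0")
  }
  n <- ncol(generator)
  if (is.null(p0)) p0 <- c(1, rep(0, n - 1L))
  if (length(p0) != n || any(p0 < 0) || abs(sum(p0) - 1) > 1e-9) {
    abort("p0 must be a distribution over the generator's states")
  }
  mat <- .propagate(generator, t_grid, p0, method = match.arg(method))
  new_time_course(mat, t_grid, attr(generator, "mechanism"))
}

#' Stochastic simulation of cleavage trajectories (Gillespie algorithm)
#'
#' Simulates `n_molecules` independent realizations of the CTMC defined by
#' the mechanism's generator, recording every transition, and bins state
#' occupancy at the grid times. With a fixed seed the output is reproducible;
#' as `n_molecules` grows the binned fractions converge to [solve_master()].
#'
#' @inheritParams build_generator
#' @param n_molecules Number of molecules (>= 1).
#' @param t_max Simulation horizon, s (> 0).
#' @param seed Integer seed.
#' @param t_grid Times at which occupancy is binned; defaults to the part of
#'   [default_time_grid()] within `t_max`.
#' @return A list of class `mk_ssa`: `trajectories` (tibble with columns
#'   `molecule`, `time_s`, `from_state`, `to_state`), `time_course` (an
#'   `mk_tc` of binned fractions) and `seed`.
#' @export
gillespie <- function(mech, rates = default_rates(), sub = substrate(),
                      tpase = transposase_variant("WT"),
                      n_molecules = 1000, t_max = 10800, seed = 1,
                      t_grid = NULL) {
  if (n_molecules < 1) abort("n_molecules must be >= 1")
  if (t_max <= 0) abort("t_max must be positive")
  Q <- build_generator(mech, rates, sub, tpase)
  states <- colnames(Q)
  n_state <- length(states)
  exit <- -diag(Q)
  jumpP <- Q
  diag(jumpP) <- 0
  pos <- exit > 0
  jumpP[pos, ] <- jumpP[pos, , drop = FALSE] / exit[pos]

  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)

  cur <- rep(1L, n_molecules)       # state index; all start in FREE
  now <- rep(0, n_molecules)
  active <- exit[cur] > 0
  ev_times <- list(); ev_from <- list(); ev_to <- list(); ev_mol <- list()
  step_times <- list(); step_states <- list()  # per-step matrices for binning
  while (any(active)) {
    idx <- which(active)
    dt <- rexp(length(idx), rate = exit[cur[idx]])
    t_new <- now[idx] + dt
    ok <- t_new <= t_max
    # molecules whose next event falls beyond the horizon stay put, inactive
    active[idx[!ok]] <- FALSE
    idx <- idx[ok]
    if (!length(idx)) break
    t_new <- t_new[ok]
    from <- cur[idx]
    to <- integer(length(idx))
    for (s in unique(from)) {
      sel <- from == s
      to[sel] <- sample.int(n_state, sum(sel), replace = TRUE, prob = jumpP[s, ])
    }
    ev_mol[[length(ev_mol) + 1L]] <- idx
    ev_times[[length(ev_times) + 1L]] <- t_new
    ev_from[[length(ev_from) + 1L]] <- from
    ev_to[[length(ev_to) + 1L]] <- to
    tcol <- rep(NA_real_, n_molecules); tcol[idx] <- t_new
    scol <- rep(NA_integer_, n_molecules); scol[idx] <- to
    step_times[[length(step_times) + 1L]] <- tcol
    step_states[[length(step_states) + 1L]] <- scol
    now[idx] <- t_new
    cur[idx] <- to
    active[idx] <- exit[to] > 0
  }

  trajectories <- tibble(
    molecule = unlist(ev_mol) %||% integer(),
    time_s = unlist(ev_times) %||% numeric(),
    from_state = states[unlist(ev_from) %||% integer()],
    to_state = states[unlist(ev_to) %||% integer()]
  ) %>% arrange(.data$molecule, .data$time_s)

  if (is.null(t_grid)) t_grid <- default_time_grid()[default_time_grid() <= t_max]
  tmat <- if (length(step_times)) do.call(cbind, step_times) else
    matrix(NA_real_, n_molecules, 0)
  smat <- if (length(step_states)) do.call(cbind, step_states) else
    matrix(NA_integer_, n_molecules, 0)
  occ <- matrix(0, length(t_grid), n_state, dimnames = list(NULL, states))
  for (i in seq_along(t_grid)) {
    nev <- if (ncol(tmat)) rowSums(tmat <= t_grid[i], na.rm = TRUE) else
      rep(0L, n_molecules)
    st <- rep(1L, n_molecules)
    has <- nev > 0
    if (any(has)) st[has] <- smat[cbind(which(has), nev[has])]
    occ[i, ] <- tabulate(st, nbins = n_state) / n_molecules
  }

  structure(list(trajectories = trajectories,
                 time_course = new_time_course(occ, t_grid,
                                               attr(Q, "mechanism")),
                 seed = seed),
            class = "mk_ssa")
}

#' Half-life of a declining set of species
#'
#' Time at which the summed fraction of `species_set` first crosses half of
#' its initial value, by linear interpolation between grid points. The summed
#' fraction must be monotone non-increasing.
#'
#' @param tc A time course.
#' @param species_set Character vector of state labels to sum.
#' @return Half-life, s.
#' @export
#' @examples
#' Q <- build_generator("constrained")
#' tc <- solve_master(Q, seq(0, 200, by = 0.5))
#' half_life(tc, c("FREE", "UU"))  # ~30 s by calibration
half_life <- function(tc, species_set) {
  sub <- tc[tc$state %in% species_set, , drop = FALSE]
  if (!nrow(sub)) abort("species_set matches no state in the time course")
  agg <- tapply(sub$fraction, sub$time_s, sum)
  times <- as.numeric(names(agg))
  o <- order(times)
  times <- times[o]; y <- as.numeric(agg)[o]
  if (any(diff(y) > 1e-8)) {
    abort("summed fraction of species_set is not monotone decreasing")
  }
  target <- y[1] / 2
  below <- which(y <= target)
  if (!length(below)) {
    abort("half-life not reached within the time grid",
          class = "mk_not_reached")
  }
  i <- below[1]
  if (i == 1L) return(times[1])
  t0 <- times[i - 1L]; t1 <- times[i]
  y0 <- y[i - 1L]; y1 <- y[i]
  if (y0 == y1) return(t1)
  t0 + (y0 - target) / (y0 - y1) * (t1 - t0)
}

# SEB states (exactly one end with a double-strand break) and, among them,
# those whose partner end is nicked.
.seb_states <- function(mech) {
  st <- enumerate_states(mech)
  seb <- st[xor(st$left == "D", st$right == "D") & st$phase == "SYNAPSED", ]
  list(all = seb$state,
       partner_nicked = seb$state[(seb$left == "D" & seb$right == "N") |
                                    (seb$right == "D" & seb$left == "N")])
}

#' Probability that the partner end of an SEB molecule is nicked
#'
#' Among molecules carrying a single-end break (exactly one end with a
#' double-strand break) at time `t`, the probability that the other end has
#' its NTS nicked. This is the discriminating statistic of the denatured-SEB
#' experiment: it is identically 1 under the constrained mechanism, rises
#' from 0 under the sequential mechanism, and takes intermediate values under
#' the independent mechanism.
#'
#' @param tc A time course whose `mechanism` attribute (or `mech`) identifies
#'   the state space.
#' @param t Time, s (interpolated linearly between grid points).
#' @param mech Mechanism, if `tc` lacks the attribute.
#' @return Probability in `[0, 1]`.
#' @export
seb_partner_nick_prob <- function(tc, t, mech = NULL) {
  mech <- mech %||% attr(tc, "mechanism")
  if (is.null(mech)) abort("supply `mech`: the time course carries no mechanism")
  seb <- .seb_states(mech)
  at_t <- function(state) {
    s <- tc[tc$state == state, , drop = FALSE]
    approx(s$time_s, s$fraction, xout = t, rule = 2)$y
  }
  total <- sum(vapply(seb$all, at_t, numeric(1)))
  if (total < 1e-12) {
    abort("no SEB mass at this time: partner-nick probability undefined",
          class = "mk_undefined")
  }
  nicked <- sum(vapply(seb$partner_nicked, at_t, numeric(1)))
  nicked / total
}

#' Native-gel species class of each molecule state
#'
#' Classifies states by what a native agarose gel resolves: `SC` (supercoiled;
#' no breaks), `OC` (open circular; nicked but no double-strand break), `LIN`
#' (linear single-end-break), `BB_ETF` (double-end break: backbone plus
#' excised transposon) and `INTEGRATED`.
#'
#' @param states Character vector of state labels.
#' @param mech Mechanism (spec or kind string).
#' @return Character vector of class labels.
#' @export
native_species <- function(states, mech = "constrained") {
  st <- enumerate_states(mech)
  idx <- match(states, st$state)
  if (anyNA(idx)) abort("unknown state label")
  l <- st$left[idx]; r <- st$right[idx]
  ifelse(states == "INTEGRATED", "INTEGRATED",
  ifelse(l == "D" & r == "D", "BB_ETF",
  ifelse(l == "D" | r == "D", "LIN",
  ifelse(l == "N" | r == "N", "OC", "SC"))))
}

#' Native species fractions of a time course
#'
#' @param tc A time course.
#' @param mech Mechanism, if `tc` lacks the attribute.
#' @return A tibble `time_s`, `species`, `fraction` with species in the fixed
#'   order SC, OC, LIN, BB_ETF, INTEGRATED.
#' @export
native_fractions <- function(tc, mech = NULL) {
  mech <- mech %||% attr(tc, "mechanism")
  if (is.null(mech)) abort("supply `mech`: the time course carries no mechanism")
  cls <- c("SC", "OC", "LIN", "BB_ETF", "INTEGRATED")
  tc %>%
    mutate(species = factor(native_species(.data$state, mech), levels = cls)) %>%
    group_by(.data$time_s, .data$species) %>%
    summarise(fraction = sum(.data$fraction), .groups = "drop") %>%
    tidyr::complete(time_s = unique(tc$time_s), species = factor(cls, levels = cls),
                    fill = list(fraction = 0)) %>%
    arrange(.data$time_s, .data$species)
}

#' Cumulative excision yield
#'
#' Fraction of molecules that have completed double-end cleavage by time `t`:
#' occupancy of the double-end-break state plus everything already
#' integrated. On a native gel this is what the persistent backbone band
#' reports, since integration consumes the excised transposon but not the
#' backbone.
#'
#' @param tc A time course.
#' @param t Time, s.
#' @return Fraction in `[0, 1]`.
#' @export
excision_yield <- function(tc, t) {
  s <- tc[tc$state %in% c("DD", "INTEGRATED"), , drop = FALSE]
  agg <- tapply(s$fraction, s$time_s, sum)
  approx(as.numeric(names(agg)), as.numeric(agg), xout = t, rule = 2)$y
}
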