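# The CTMC state space of transposon cleavage and the rate generator of each
# mechanism.
#
# Per-end cleavage status: U (uncut), N (NTS nicked), D (double-strand
# break). The NTS is always cleaved before the TS at a given end, so there is
# no TS-only state. A molecule is FREE (no synapse; both ends U), SYNAPSED
# (two-letter left/right status), or INTEGRATED (absorbing). The constrained
# mechanism splits the doubly nicked state into NN/pre and NN/post, separated
# by the coordinated conformational transition.

#' Mechanism specification
#'
#' @param kind `"independent"` (each end cleaves on its own), `"sequential"`
#'   (one end completes its double-strand break before the other begins) or
#'   `"constrained"` (both NTS nicks precede the first TS cut, gated by a
#'   coordinated transition).
#' @param coupling_rule How the two ends' competences combine into the rate of
#'   the coordinated transition (constrained only): `"additive"`,
#'   `"multiplicative"` or `"min"`.
#' @return An object of class `mk_mechanism`.
#' @export
mechanism_spec <- function(kind = c("constrained", "independent", "sequential"),
                           coupling_rule = c("additive", "multiplicative", "min")) {
  kind <- match.arg(kind)
  coupling_rule <- match.arg(coupling_rule)
  structure(list(kind = kind, coupling_rule = coupling_rule),
            class = "mk_mechanism")
}

as_mechanism <- function(mech) {
  if (inherits(mech, "mk_mechanism")) mech else mechanism_spec(mech)
}

#' Enumerate the reachable molecule states of a mechanism
#'
#' Returns the states reachable from FREE under the mechanism's transition
#' rules, in the stable order used by every generator and time course:
#' FREE first, then synapsed states by increasing total number of strand
#' breaks (left-end status varying slowest), then INTEGRATED. Mirror states
#' (left/right swapped) are distinct.
#'
#' @param mech A [mechanism_spec()] or its `kind` string.
#' @return A tibble with columns `state` (label), `phase`, `left`, `right`
#'   (`"U"`, `"N"`, `"D"`) and `transition_done`.
#' @export
#' @examples
#' enumerate_states("constrained")$state
enumerate_states <- function(mech) {
  mech <- as_mechanism(mech)
  cached <- .mk_cache$states[[mech$kind]]
  if (!is.null(cached)) return(cached)
  syn <- switch(mech$kind,
    independent = c("UU", "NU", "UN", "NN", "DU", "UD", "DN", "ND", "DD"),
    sequential  = c("UU", "NU", "UN", "DU", "UD", "DN", "ND", "DD"),
    constrained = c("UU", "NU", "UN", "NN_pre", "NN_post", "DN", "ND", "DD")
  )
  states <- c("FREE", syn, "INTEGRATED")
  ends <- function(s) {
    if (s == "FREE") c("U", "U")
    else if (s == "INTEGRATED") c("D", "D")
    else if (s %in% c("NN_pre", "NN_post")) c("N", "N")
    else c(substr(s, 1, 1), substr(s, 2, 2))
  }
  em <- t(vapply(states, ends, character(2)))
  done <- if (mech$kind == "constrained") {
    states %in% c("NN_post", "DN", "ND", "DD", "INTEGRATED")
  } else {
    rep(NA, length(states))
  }
  out <- tibble(
    state = states,
    phase = ifelse(states == "FREE", "FREE",
                   ifelse(states == "INTEGRATED", "INTEGRATED", "SYNAPSED")),
    left = em[, 1], right = em[, 2],
    transition_done = done
  )
  if (is.null(.mk_cache$states)) .mk_cache$states <- list()
  .mk_cache$states[[mech$kind]] <- out
  out
}

#' Combine end competences into the coordinated-transition rate
#'
#' @param k_trans Base transition rate, s^-1.
#' @param c_left,c_right End competences in `[0, 1]`.
#' @param rule `"additive"` (a competent end can drive the transition for
#'   both halves: rescue), `"multiplicative"` (both halves must contribute:
#'   no rescue) or `"min"`.
#' @return The transition rate, s^-1.
#' @export
#' @examples
#' coupling(1, 1, 0.05, "additive")        # 0.525: rescue by the WT end
#' coupling(1, 1, 0.05, "multiplicative")  # 0.05: no rescue
coupling <- function(k_trans, c_left, c_right,
                     rule = c("additive", "multiplicative", "min")) {
  rule <- match.arg(rule)
  stopifnot(c_left >= 0, c_left <= 1, c_right >= 0, c_right <= 1)
  k_trans * switch(rule,
    additive = (c_left + c_right) / 2,
    multiplicative = c_left * c_right,
    min = min(c_left, c_right)
  )
}

#' Build the CTMC rate generator of a mechanism
#'
#' Constructs the square rate matrix over [enumerate_states()]: off-diagonal
#' entries are transition rates, the diagonal makes every row sum to zero.
#' Transitions: synapsis `FREE -> UU` at `k_syn * syn_multiplier`; NTS
#' nicking `U -> N` at end e at `k_nts * nts_factor(e)` (independent and
#' constrained: whenever end e is uncut; sequential: from UU at either end,
#' afterwards only once the other end carries a double-strand break); TS
#' cleavage `N -> D` at end e at `k_ts * ts_factor(e) * ts_multiplier`
#' (independent: whenever end e is nicked; sequential: only at the end that
#' initiated; constrained: only after the coordinated transition);
#' constrained only, `NN_pre -> NN_post` at the [coupling()] of the two end
#' competences; `DD -> INTEGRATED` at `k_int`.
#'
#' @param mech A [mechanism_spec()] or kind string.
#' @param rates A [rate_set()].
#' @param sub A [substrate()].
#' @param tpase A [transposase_variant()].
#' @return A numeric matrix with state labels as dimnames and attribute
#'   `"mechanism"`.
#' @export
build_generator <- function(mech, rates = default_rates(), sub = substrate(),
                            tpase = transposase_variant("WT")) {
  mech <- as_mechanism(mech)
  if (mech$kind != "constrained" && rates$k_trans > 0) {
    warn("`k_trans` is unused by non-constrained mechanisms and was ignored",
         .frequency = "once", .frequency_id = "marinerkin_k_trans_unused")
  }
  st <- enumerate_states(mech)$state
  n <- length(st)
  Q <- matrix(0, n, n, dimnames = list(st, st))
  add <- function(from, to, rate) Q[from, to] <<- Q[from, to] + rate
  nick <- c(left = rates$k_nts * sub$left_end$nts_factor,
            right = rates$k_nts * sub$right_end$nts_factor)
  ts <- c(left = rates$k_ts * sub$left_end$ts_factor,
          right = rates$k_ts * sub$right_end$ts_factor) * tpase$ts_multiplier

  add("FREE", "UU", rates$k_syn * tpase$syn_multiplier)
  add("DD", "INTEGRATED", rates$k_int)

  if (mech$kind == "independent") {
    add("UU", "NU", nick["left"]); add("UU", "UN", nick["right"])
    add("NU", "NN", nick["right"]); add("UN", "NN", nick["left"])
    add("DU", "DN", nick["right"]); add("UD", "ND", nick["left"])
    add("NU", "DU", ts["left"]); add("UN", "UD", ts["right"])
    add("NN", "DN", ts["left"]); add("NN", "ND", ts["right"])
    add("DN", "DD", ts["right"]); add("ND", "DD", ts["left"])
  } else if (mech$kind == "sequential") {
    add("UU", "NU", nick["left"]); add("UU", "UN", nick["right"])
    add("NU", "DU", ts["left"]); add("UN", "UD", ts["right"])
    add("DU", "DN", nick["right"]); add("UD", "ND", nick["left"])
    add("DN", "DD", ts["right"]); add("ND", "DD", ts["left"])
  } else {
    rule <- tpase$coupling_override %||% mech$coupling_rule
    k_trans <- coupling(rates$k_trans * tpase$trans_multiplier,
                        sub$left_end$competence, sub$right_end$competence,
                        rule)
    add("UU", "NU", nick["left"]); add("UU", "UN", nick["right"])
    add("NU", "NN_pre", nick["right"]); add("UN", "NN_pre", nick["left"])
    add("NN_pre", "NN_post", k_trans)
    add("NN_post", "DN", ts["left"]); add("NN_post", "ND", ts["right"])
    add("DN", "DD", ts["right"]); add("ND", "DD", ts["left"])
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  attr(Q, "mechanism") <- mech
  Q
}

# Strand breaks carried by a state label (per mechanism state table).
.state_breaks <- function(states, mech) {
  st <- enumerate_states(mech)
  idx <- match(states, st$state)
  if (anyNA(idx)) {
    abort(sprintf("unknown state(s): %s",
                  paste(states[is.na(idx)], collapse = ", ")))
  }
  score <- c(U = 0, N = 1, D = 2)
  score[st$left[idx]] + score[st$right[idx]]
}

#' Count strand breaking and joining events along a trajectory
#'
#' A complete excision-plus-integration path involves six chemical events:
#' two NTS nicks, two TS cuts, and the joining of both transposon 3' ends to
#' the target. Each `U -> N` or `N -> D` step counts one break; the
#' coordinated transition is purely conformational and counts none;
#' `DD -> INTEGRATED` counts the two strand-joining events.
#'
#' @param trajectory Character vector of successive state labels (a valid
#'   transition path of the mechanism).
#' @param mech A [mechanism_spec()] or kind string.
#' @return Integer event count.
#' @export
#' @examples
#' chemical_event_count(
#'   c("FREE", "UU", "NU", "NN_pre", "NN_post", "DN", "DD", "INTEGRATED"),
#'   "constrained"
#' )  # 6
chemical_event_count <- function(trajectory, mech = "constrained") {
  mech <- as_mechanism(mech)
  if (length(trajectory) < 2L) return(0L)
  .state_breaks(trajectory, mech)  # validates state labels
  unit <- rate_set(1, 1, 1, 1, 1)
  Qs <- suppressWarnings(build_generator(mech, unit))
  from <- trajectory[-length(trajectory)]
  to <- trajectory[-1L]
  ok <- mapply(function(a, b) a != b && Qs[a, b] > 0, from, to)
  if (!all(ok)) {
    abort(sprintf("illegal transition in path: %s -> %s",
                  from[!ok][1], to[!ok][1]))
  }
  br <- .state_breaks(trajectory, mech)
  as.integer(sum(pmax(diff(br), 0)) + 2L * sum(to == "INTEGRATED"))
}
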