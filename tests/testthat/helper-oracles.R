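# Independent brute-force oracles, implemented without reference to the
# package internals they check.

# Reachability oracle: breadth-first search over an explicit rule-based
# successor function, states encoded as (phase, left, right, post).
oracle_reachable_states <- function(kind) {
  enc <- function(s) paste(s$phase, s$left, s$right, s$post, sep = "|")
  successors <- function(s) {
    out <- list()
    if (s$phase == "FREE") {
      return(list(list(phase = "SYN", left = "U", right = "U", post = FALSE)))
    }
    if (s$phase == "INT") return(out)
    for (e in c("left", "right")) {
      other <- if (e == "left") "right" else "left"
      # NTS nick
      nick_ok <- s[[e]] == "U" && switch(kind,
        independent = TRUE,
        constrained = TRUE,
        sequential = (s[[other]] == "U" || s[[other]] == "D"))
      if (nick_ok) {
        nxt <- s; nxt[[e]] <- "N"; out <- c(out, list(nxt))
      }
      # TS cleavage
      ts_ok <- s[[e]] == "N" && switch(kind,
        independent = TRUE,
        sequential = s[[other]] != "N",
        constrained = isTRUE(s$post))
      if (ts_ok) {
        nxt <- s; nxt[[e]] <- "D"; out <- c(out, list(nxt))
      }
    }
    if (kind == "constrained" && s$left == "N" && s$right == "N" && !s$post) {
      nxt <- s; nxt$post <- TRUE; out <- c(out, list(nxt))
    }
    if (s$left == "D" && s$right == "D" && s$phase == "SYN") {
      out <- c(out, list(list(phase = "INT", left = "D", right = "D",
                              post = s$post)))
    }
    out
  }
  start <- list(phase = "FREE", left = "U", right = "U", post = FALSE)
  seen <- new.env(parent = emptyenv())
  assign(enc(start), start, envir = seen)
  frontier <- list(start)
  while (length(frontier)) {
    nxt_frontier <- list()
    for (s in frontier) {
      for (nx in successors(s)) {
        k <- enc(nx)
        if (!exists(k, envir = seen)) {
          assign(k, nx, envir = seen)
          nxt_frontier <- c(nxt_frontier, list(nx))
        }
      }
    }
    frontier <- nxt_frontier
  }
  states <- mget(ls(seen), envir = seen)
  # post flag only distinguishes states for the constrained doubly nicked pair
  if (kind != "constrained") {
    keys <- unique(vapply(states, function(s)
      paste(s$phase, s$left, s$right, sep = "|"), character(1)))
    return(keys)
  }
  unique(vapply(states, function(s) {
    pp <- if (s$left == "N" && s$right == "N" && s$phase == "SYN")
      paste0("|post=", s$post) else ""
    paste0(paste(s$phase, s$left, s$right, sep = "|"), pp)
  }, character(1)))
}

# Fragment-walk oracle: given per-strand break boundaries on a circle of
# size `total`, fragment lengths are the sorted-position differences.
oracle_fragment_lengths <- function(breaks_pos, total) {
  b <- sort(unique(breaks_pos %% total))
  if (!length(b)) return(total)
  diff(c(b, b[1] + total))
}

# Random cut map construction (direct object assembly).
random_cutmap <- function(total, n_breaks, seed) {
  set.seed(seed)
  structure(list(
    total_length = total, circular = TRUE,
    breaks = tibble::tibble(
      strand = sample(c("fwd", "rev"), n_breaks, replace = TRUE),
      pos = sample.int(total, n_breaks, replace = TRUE) - 1L,
      kind = sample(c("nick", "restriction", "transposition_cut"), n_breaks,
                    replace = TRUE)
    )
  ), class = "mk_cutmap")
}

dense_log_grid <- function(t_min = 0.5, t_max = 3e4, n = 500) {
  c(0, exp(seq(log(t_min), log(t_max), length.out = n)))
}
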