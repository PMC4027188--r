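test_that("state enumeration matches brute-force reachability", {
  counts <- c(independent = 11L, sequential = 10L, constrained = 10L)
  for (kind in names(counts)) {
    st <- enumerate_states(kind)
    expect_equal(nrow(st), counts[[kind]], info = kind)
    expect_equal(length(oracle_reachable_states(kind)), counts[[kind]],
                 info = kind)
    # no TS-only end anywhere: every end status is U, N or D by construction
    expect_true(all(st$left %in% c("U", "N", "D")))
    expect_true(all(st$right %in% c("U", "N", "D")))
  }
  # mirror states are distinct
  st <- enumerate_states("sequential")
  expect_true(all(c("NU", "UN", "DU", "UD", "DN", "ND") %in% st$state))
})

test_that("constrained reachable states never pair a DSB with an uncut partner", {
  st <- enumerate_states("constrained")
  has_d <- st$left == "D" | st$right == "D"
  partner <- ifelse(st$left == "D", st$right, st$left)
  expect_true(all(partner[has_d] %in% c("N", "D")))
  expect_true(all(st$transition_done[has_d]))
  # and the same from the oracle's reachable set
  reach <- oracle_reachable_states("constrained")
  bad <- grepl("D\\|U|U\\|D", reach)
  expect_false(any(bad))
})

test_that("coupling rules combine end competences as documented", {
  expect_equal(coupling(1, 1, 0.05, "additive"), 0.525)
  expect_equal(coupling(1, 1, 0.05, "multiplicative"), 0.05)
  expect_equal(coupling(1, 1, 0.05, "min"), 0.05)
  expect_equal(coupling(2, 0.3, 0.7, "min"), 2 * 0.3)
  for (rule in c("additive", "multiplicative", "min")) {
    expect_equal(coupling(3.7, 1, 1, rule), 3.7)
  }
  expect_error(coupling(1, 1, 0.5, "geometric"))
  expect_error(coupling(1, 1.5, 0.5, "additive"))
})

test_that("generators are proper CTMC rate matrices for every mechanism", {
  subs <- list(substrate(), substrate("5G", "WT"), substrate("-1T", "-1T"))
  tps <- list(transposase_variant("WT"), transposase_variant("W118R"))
  for (kind in c("independent", "sequential", "constrained")) {
    for (s in subs) for (tp in tps) {
      Q <- suppressWarnings(build_generator(kind, default_rates(), s, tp))
      off <- Q; diag(off) <- 0
      expect_true(all(off >= 0))
      expect_lt(max(abs(rowSums(Q))), 1e-12)
    }
  }
})

test_that("end factors scale the corresponding transitions", {
  s <- substrate("5G", "WT")
  Q <- build_generator("constrained", default_rates(), s)
  # left-end nick rate is nts_factor(5G) times the right-end (WT) rate
  expect_equal(Q["UU", "NU"] / Q["UU", "UN"], s$left_end$nts_factor)
  # no direct route from the pre-transition doubly nicked state to a DSB
  expect_equal(Q["NN_pre", "DN"], 0)
  expect_equal(Q["NN_pre", "ND"], 0)
  expect_gt(Q["NN_post", "DN"], 0)
  # W118R override makes the coupling multiplicative: a WT partner cannot
  # rescue a low-competence end
  s2 <- substrate("-1T", "WT")
  q_wt <- build_generator("constrained", default_rates(), s2)["NN_pre", "NN_post"]
  q_118 <- build_generator("constrained", default_rates(), s2,
                           transposase_variant("W118R"))["NN_pre", "NN_post"]
  expect_gt(q_wt, q_118 * 10)
})

test_that("heteroduplex generators reduce to the homoduplex at unit factors", {
  neutral <- end_variant("neutral-test", mutated_positions = 2L,
                         nts_factor = 1, ts_factor = 1, competence = 1)
  s_het <- substrate(neutral, "WT")
  s_hom <- substrate("WT", "WT")
  for (kind in c("independent", "sequential", "constrained")) {
    Qh <- suppressWarnings(build_generator(kind, default_rates(), s_het))
    Qw <- suppressWarnings(build_generator(kind, default_rates(), s_hom))
    expect_equal(unname(Qh), unname(Qw), info = kind)
  }
})

test_that("k_trans is flagged as unused outside the constrained mechanism", {
  rlang::reset_warning_verbosity("marinerkin_k_trans_unused")
  expect_warning(build_generator("independent", default_rates()), "k_trans")
})

test_that("chemical events are counted along trajectories", {
  full <- c("FREE", "UU", "NU", "NN_pre", "NN_post", "DN", "DD", "INTEGRATED")
  expect_equal(chemical_event_count(full, "constrained"), 6L)
  expect_equal(chemical_event_count(head(full, -1), "constrained"), 4L)
  expect_equal(chemical_event_count(character(), "constrained"), 0L)
  expect_equal(chemical_event_count("FREE", "constrained"), 0L)
  seq_path <- c("FREE", "UU", "UN", "UD", "ND", "DD", "INTEGRATED")
  expect_equal(chemical_event_count(seq_path, "sequential"), 6L)
  expect_error(chemical_event_count(c("FREE", "NN_pre"), "constrained"),
               "illegal transition")
  expect_error(chemical_event_count(c("FREE", "UU", "XX"), "constrained"),
               "unknown state")
})

test_that("constrained kinetics collapse onto independent in the degenerate limit", {
  # with nicking and the coordinated transition made non-limiting the
  # constrained model becomes indistinguishable from independent cleavage on
  # native-gel classes -- the identifiability hazard that motivates the
  # joint heteroduplex benchmark design
  r_fast <- rate_set(k_syn = 0.02, k_nts = 50, k_trans = 1e5, k_ts = 5e-3,
                     k_int = 1e-4)
  grid <- default_time_grid()
  nf_con <- native_fractions(
    solve_master(build_generator("constrained", r_fast), grid), "constrained")
  nf_ind <- native_fractions(
    solve_master(suppressWarnings(build_generator("independent", r_fast)),
                 grid), "independent")
  expect_lt(max(abs(nf_con$fraction - nf_ind$fraction)), 1e-3)
  # sequential does NOT collapse: only the initiating end is cleavage-active,
  # so the first TS cut appears at half the rate
  nf_seq <- native_fractions(
    solve_master(suppressWarnings(build_generator("sequential", r_fast)),
                 grid), "sequential")
  expect_gt(max(abs(nf_seq$fraction - nf_ind$fraction)), 0.05)
})
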