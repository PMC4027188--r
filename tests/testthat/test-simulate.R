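test_that("the master equation reproduces closed-form decay", {
  k <- log(2) / 30
  Q <- matrix(c(-k, k, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("FREE", "UU"), c("FREE", "UU")))
  tc <- solve_master(Q, c(0, 10, 30, 90))
  m <- tc_matrix(tc)
  expect_equal(unname(m[, "FREE"]), exp(-k * c(0, 10, 30, 90)), tolerance = 1e-9)
  expect_equal(unname(m[3, "FREE"]), 0.5, tolerance = 1e-9)
  # t = 0 leaves the initial distribution untouched
  expect_equal(unname(m[1, ]), c(1, 0))
})

test_that("propagation methods agree and conserve mass", {
  r <- rate_set(0.02, 0.3, 1e-3, 8e-3, 5e-3)
  # an asymmetric substrate breaks the mirror degeneracy, keeping the
  # generator diagonalizable for the spectral route
  s_asym <- substrate("-1T", "WT")
  for (kind in c("independent", "sequential", "constrained")) {
    Q <- suppressWarnings(build_generator(kind, r, s_asym))
    grid <- default_time_grid()
    m_pow <- tc_matrix(solve_master(Q, grid))
    m_exp <- tc_matrix(solve_master(Q, grid, method = "expm"))
    m_eig <- tc_matrix(solve_master(Q, grid, method = "eigen"))
    expect_lt(max(abs(m_pow - m_exp)), 1e-8)
    expect_lt(max(abs(m_eig - m_exp)), 1e-8)
    expect_lt(max(abs(rowSums(m_pow) - 1)), 1e-9)
    expect_true(all(m_pow >= -1e-12 & m_pow <= 1 + 1e-12))
    # INTEGRATED is absorbing: occupancy non-decreasing
    expect_true(all(diff(m_pow[, "INTEGRATED"]) >= -1e-12))
  }
  # a defective generator (mirror-symmetric sequential model) silently falls
  # back from the spectral route and still conserves mass
  Qd <- suppressWarnings(build_generator("sequential", r))
  md <- tc_matrix(solve_master(Qd, c(0, 13, 210, 999)))
  expect_lt(max(abs(md - tc_matrix(solve_master(Qd, c(0, 13, 210, 999),
                                                method = "expm")))), 1e-8)
  # incommensurate grids exercise the fallback and still conserve mass
  Qc <- build_generator("constrained", r)
  m <- tc_matrix(solve_master(Qc, c(0, exp(seq(0, 9, length.out = 40)))))
  expect_lt(max(abs(rowSums(m) - 1)), 1e-9)
})

test_that("invalid generators and grids are rejected", {
  Q <- build_generator("constrained")
  expect_error(solve_master(Q, c(0, 10, 10)), "increasing")
  expect_error(solve_master(Q, c(-1, 10)), "increasing|>= 0")
  bad <- Q; bad[1, 1] <- bad[1, 1] + 1
  expect_error(solve_master(bad, c(0, 1)), "sum to zero")
  bad2 <- Q; bad2[1, 2] <- NaN
  expect_error(solve_master(bad2, c(0, 1)), "finite")
  expect_error(solve_master(Q, c(0, 1), p0 = c(2, numeric(9))), "distribution")
})

test_that("default calibration reproduces the two observed half-lives", {
  tc <- solve_master(build_generator("constrained"), dense_log_grid())
  expect_equal(half_life(tc, c("FREE", "UU")), 30, tolerance = 0.005)
  no_ts_cut <- c("FREE", "UU", "NU", "UN", "NN_pre", "NN_post")
  expect_equal(half_life(tc, no_ts_cut), 900, tolerance = 0.005)
  # long-time limit: everything integrates
  m <- tc_matrix(solve_master(build_generator("constrained"), c(0, 1e6)))
  expect_gt(m[2, "INTEGRATED"], 0.999)
})

test_that("half_life interpolates exponentials and flags bad input", {
  k <- log(2) / 900
  Q <- matrix(c(-k, k, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  tc <- solve_master(Q, seq(0, 4000, by = 20))
  expect_equal(half_life(tc, "A"), 900, tolerance = 1e-3)
  expect_error(half_life(tc, "B"), "monotone")
  tc_short <- solve_master(Q, seq(0, 100, by = 10))
  expect_error(half_life(tc_short, "A"), class = "mk_not_reached")
  expect_error(half_life(tc, "Z"), "matches no state")
})

test_that("the SEB partner-nick probability separates the mechanisms", {
  grid <- c(0, 0.5, 2, 15, 60, 300, 900)
  tc_con <- solve_master(build_generator("constrained"), grid)
  tc_ind <- solve_master(suppressWarnings(build_generator("independent")), grid)
  tc_seq <- solve_master(suppressWarnings(build_generator("sequential")), grid)
  # constrained: identically 1 wherever SEB mass exists
  for (t in c(60, 300, 900)) {
    expect_equal(seb_partner_nick_prob(tc_con, t), 1)
  }
  # sequential: SEB mass enters with an uncut partner, so the probability
  # vanishes as t -> 0+ and rises with time
  p_early <- seb_partner_nick_prob(tc_seq, 0.5)
  expect_lt(p_early, 0.1)
  expect_lt(p_early, seb_partner_nick_prob(tc_seq, 2))
  expect_lt(seb_partner_nick_prob(tcs <- tc_seq, 2),
            seb_partner_nick_prob(tc_seq, 60))
  # independent: intermediate values, strictly inside (0,1) at early times
  p_ind <- seb_partner_nick_prob(tc_ind, 15)
  expect_gt(p_ind, 0); expect_lt(p_ind, 1)
  p_ind900 <- seb_partner_nick_prob(tc_ind, 900)
  expect_gt(p_ind900, 0.99); expect_lte(p_ind900, 1)
  # undefined before any SEB mass exists
  expect_error(seb_partner_nick_prob(tc_con, 0), class = "mk_undefined")
})

test_that("nicked-intermediate accumulation decreases with faster coordination", {
  r <- default_rates()
  peaks <- vapply(c(0.2, 1, 5, 25), function(mult) {
    rr <- rate_set(r$k_syn, r$k_nts, r$k_trans * mult, r$k_ts, r$k_int)
    nf <- native_fractions(solve_master(build_generator("constrained", rr),
                                        dense_log_grid()), "constrained")
    max(nf$fraction[nf$species == "OC"])
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("Gillespie simulation is seed-reproducible and converges to the master equation", {
  g1 <- gillespie("constrained", n_molecules = 200, t_max = 3600, seed = 11)
  g2 <- gillespie("constrained", n_molecules = 200, t_max = 3600, seed = 11)
  expect_identical(g1$trajectories, g2$trajectories)
  g3 <- gillespie("constrained", n_molecules = 200, t_max = 3600, seed = 12)
  expect_false(identical(g1$trajectories, g3$trajectories))
  # moderate-n agreement with the deterministic solution
  g <- gillespie("constrained", n_molecules = 5000, t_max = 10800, seed = 5)
  m_ode <- tc_matrix(solve_master(build_generator("constrained"),
                                  default_time_grid()))
  expect_lt(max(abs(tc_matrix(g$time_course) - m_ode)), 0.03)
  expect_error(gillespie("constrained", n_molecules = 0), "n_molecules")
  expect_error(gillespie("constrained", t_max = 0), "t_max")
})

test_that("single-molecule trajectories carry the full chemical event count", {
  for (seed in 1:5) {
    g <- gillespie("constrained", n_molecules = 1, t_max = 1e7, seed = seed)
    path <- c("FREE", g$trajectories$to_state)
    expect_identical(path[length(path)], "INTEGRATED")
    expect_equal(chemical_event_count(path, "constrained"), 6L)
  }
})

test_that("native species classes follow the break pattern", {
  expect_equal(native_species(c("FREE", "UU"), "constrained"), c("SC", "SC"))
  expect_equal(native_species("NN_pre", "constrained"), "OC")
  expect_equal(native_species(c("NU", "UN"), "sequential"), c("OC", "OC"))
  expect_equal(native_species(c("DN", "ND"), "constrained"), c("LIN", "LIN"))
  expect_equal(native_species("DU", "independent"), "LIN")
  expect_equal(native_species("DD", "constrained"), "BB_ETF")
  expect_equal(native_species("INTEGRATED", "constrained"), "INTEGRATED")
  nf <- native_fractions(solve_master(build_generator("constrained"),
                                      default_time_grid()), "constrained")
  sums <- tapply(nf$fraction, nf$time_s, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})
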