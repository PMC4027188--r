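test_that("noiseless data returns the generating rate exactly", {
  d <- simulate_gel_dataset("WT x WT", noise_sd = 0, seed = 1, n_replicates = 1)
  truth <- attr(d, "truth")$rates
  f <- fit_rates(d, "constrained", free = "k_nts", n_starts = 2, seed = 1)
  expect_lt(abs(f$estimates[["k_nts"]] - truth$k_nts) / truth$k_nts, 1e-3)
  expect_true(f$converged)
})

test_that("the noiseless likelihood is maximal at the generating rates", {
  d <- simulate_gel_dataset("WT x WT", noise_sd = 0, seed = 1, n_replicates = 1)
  truth <- attr(d, "truth")$rates
  ll_truth <- fit_rates(d, "constrained", free = character())$logLik
  for (fac in c(0.5, 2, 5)) {
    perturbed <- rate_set(truth$k_syn, truth$k_nts * fac, truth$k_trans,
                          truth$k_ts, truth$k_int)
    ll_p <- fit_rates(d, "constrained", free = character(),
                      rates_init = perturbed)$logLik
    expect_lt(ll_p, ll_truth)
  }
})

test_that("rates are recovered from noisy replicated gels", {
  errs <- sapply(1:20, function(s) {
    d <- simulate_gel_dataset("WT x WT", noise_sd = 0.15, seed = 100 + s,
                              n_replicates = 3)
    f <- fit_rates(d, "constrained", free = c("k_nts", "k_trans", "k_ts"),
                   n_starts = 2, seed = s)
    truth <- unlist(attr(d, "truth")$rates)[f$free]
    abs(f$estimates - truth) / truth
  })
  med <- apply(errs, 1, median)
  expect_true(all(med < 0.25))
})

test_that("estimation error shrinks with the noise level", {
  err_at <- function(sd, seeds) {
    mean(sapply(seeds, function(s) {
      d <- simulate_gel_dataset("WT x WT", noise_sd = sd, seed = 200 + s,
                                n_replicates = 3)
      f <- fit_rates(d, "constrained", free = c("k_trans", "k_ts"),
                     n_starts = 2, seed = s)
      truth <- unlist(attr(d, "truth")$rates)[f$free]
      mean(abs(f$estimates - truth) / truth)
    }))
  }
  e0 <- err_at(0, 1)
  e15 <- err_at(0.15, 1:4)
  expect_lt(e0, 1e-3)
  expect_lt(e0, e15)
})

test_that("each mechanism wins model selection on its own noiseless data", {
  for (truth in c("independent", "sequential", "constrained")) {
    d <- benchmark_dataset(truth, seed = 1, noise_sd = 0, n_replicates = 1)
    s <- select_mechanism(d, n_starts = 2, seed = 1)
    expect_equal(s$best, truth)
  }
})

test_that("dropping the partner-nick observable degrades constrained-vs-independent discrimination", {
  # probe in a regime where nicking does not saturate, so the partner-nick
  # statistic is informative (~0.5 under independence, 1 under constraint)
  r <- rate_set(k_syn = 0.025, k_nts = 0.01, k_trans = 2e-3, k_ts = 0.01)
  margin <- function(obs) {
    d <- simulate_gel_dataset(mech = "constrained", rates = r,
                              noise_sd = 0.1, seed = 31, n_replicates = 3,
                              observables = obs)
    s <- select_mechanism(d, mechanisms = c("independent", "constrained"),
                          n_starts = 2, seed = 1, rates_init = r)
    if (s$best == "constrained") s$table$delta_AIC[2] else -s$table$delta_AIC[2]
  }
  m_full <- margin(c("native", "seb_nick"))
  m_bare <- margin("native")
  expect_gt(m_full, m_bare)
  expect_gt(m_full, 10)
})

test_that("selection margins grow with replication", {
  m_of <- function(nrep) {
    d <- benchmark_dataset("constrained", seed = 5, noise_sd = 0.1,
                           n_replicates = nrep)
    s <- select_mechanism(d, n_starts = 2, seed = 1)
    s$table$delta_AIC[2]
  }
  expect_gt(m_of(3), m_of(1))
})

test_that("overparameterized fits are flagged", {
  d <- simulate_gel_dataset("WT x WT", noise_sd = 0, seed = 1,
                            n_replicates = 1,
                            t_grid = c(0, 900), observables = "native")
  small <- d[d$observable == "SC", ]
  attributes(small)$contexts <- attr(d, "contexts")
  expect_warning(
    f <- fit_rates(small, "constrained",
                   free = c("k_syn", "k_nts", "k_trans", "k_ts"),
                   n_starts = 1),
    "non-identifiable"
  )
  expect_true(f$flagged_non_identifiable)
})

test_that("diagnostics report the reaction summary statistics, NA when unavailable", {
  tc <- scenario_time_course("WT x WT")
  dg <- diagnostics(tc, reference = tc)
  expect_equal(dg$value[dg$metric == "seb_partner_nick_prob"], 1)
  expect_equal(dg$value[dg$metric == "rescue_ratio"], 1)
  expect_gt(dg$value[dg$metric == "peak_OC_fraction"], 0.5)
  # no reference: rescue unavailable, not zero
  expect_true(is.na(diagnostics(tc)$value[3]))
  # no SEB mass (near-inert substrate): partner-nick probability unavailable
  dg5 <- diagnostics(scenario_time_course("5G x 5G"), t_nick = 15)
  expect_true(is.na(dg5$value[dg5$metric == "seb_partner_nick_prob"]))
  # rescue comparison across transposase variants
  wt <- scenario_time_course("WT x WT")
  r1 <- diagnostics(scenario_time_course("-1T x WT"), wt)
  r2 <- diagnostics(scenario_time_course("W118R -1T x WT"), wt)
  expect_gt(r1$value[3], r2$value[3])
})

test_that("phenotype calls follow the documented thresholds", {
  expect_error(classify_phenotype(scenario_time_course("WT x WT",
                                                       c(0, 100, 1000))),
               "too short")
  ph <- classify_phenotype(scenario_time_course("WT x WT"))
  expect_equal(ph$class, "fast_complete")
  # thresholds are configurable: loosening the OC criterion reclassifies the
  # nick-stalled mutant
  tc5 <- scenario_time_course("5G x 5G")
  expect_equal(classify_phenotype(tc5)$class, "inactive")
  tcm <- scenario_time_course("-1T x -1T")
  expect_equal(classify_phenotype(tcm)$class, "nick_stall")
  expect_equal(classify_phenotype(tcm, thresholds = list(stall_oc = 1.01))$class,
               "fast_complete")
  expect_equal(tidy(classify_phenotype(tc5))$class, "inactive")
})

test_that("tidy and glance methods expose fit results", {
  d <- simulate_gel_dataset("WT x WT", noise_sd = 0.1, seed = 2,
                            n_replicates = 1)
  f <- fit_rates(d, "constrained", free = c("k_ts"), n_starts = 2, seed = 1)
  td <- tidy(f)
  expect_setequal(td$term, c("k_syn", "k_nts", "k_trans", "k_ts", "k_int"))
  expect_equal(sum(!td$fixed), 1)
  gl <- glance(f)
  expect_equal(gl$mechanism, "constrained")
  expect_equal(gl$AIC, 2 * gl$n_parameters - 2 * gl$logLik)
  s <- select_mechanism(d, mechanisms = c("independent", "constrained"),
                        n_starts = 2, seed = 1)
  expect_equal(tidy(s)$delta_AIC[1], 0)
  expect_equal(glance(s)$best, s$best)
  expect_s3_class(autoplot(f), "ggplot")
})
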