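# Synthetic quantified-gel datasets: the statistical stand-in for
# densitometry of kinetic gel series.

# Per-end strand-cleavage fractions (what a denaturing gel quantifies per
# labeled strand): fraction of molecules with each end's NTS cut (>= nicked)
# and TS cut (double-strand break).
.denaturing_observables <- function(tc, mech) {
  st <- enumerate_states(mech)
  m <- tc_matrix(tc)
  st <- st[match(colnames(m), st$state), ]
  tibble(
    time_s = rep(unique(tc$time_s), 4),
    observable = rep(c("nts_left", "nts_right", "ts_left", "ts_right"),
                     each = length(unique(tc$time_s))),
    value = c(rowSums(m[, st$left != "U", drop = FALSE]),
              rowSums(m[, st$right != "U", drop = FALSE]),
              rowSums(m[, st$left == "D", drop = FALSE]),
              rowSums(m[, st$right == "D", drop = FALSE]))
  )
}

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Ready-made reaction scenarios
#'
#' Substrate / transposase / mechanism configurations reproducing the
#' qualitative phenotypes of the characterized reactions: the wild-type
#' reaction, the near-inert symmetric 5G mutant, the nick-stalled symmetric
#' -1T mutant, the heteroduplex rescue substrates, and the WVPHEL-motif
#' transposase mutants W118R and V119G (on wild-type and -1T x WT
#' substrates). All use the constrained mechanism with additive coupling and
#' the calibrated default rates.
#'
#' @param name Optional scenario name; omit to get the full named list.
#' @return One scenario (a list with elements `name`, `substrate`, `tpase`,
#'   `mechanism`, `rates`) or the named list of all scenarios.
#' @export
#' @examples
#' names(scenario_presets())
#' scenario_presets("-1T x WT")
scenario_presets <- function(name = NULL) {
  mk <- function(nm, sub, tp = "WT") {
    list(name = nm, substrate = sub, tpase = transposase_variant(tp),
         mechanism = mechanism_spec("constrained"), rates = default_rates())
  }
  presets <- list(
    "WT x WT" = mk("WT x WT", substrate()),
    "5G x 5G" = mk("5G x 5G", substrate("5G", "5G")),
    "5G x WT" = mk("5G x WT", substrate("5G", "WT")),
    "WT x 5G" = mk("WT x 5G", substrate("WT", "5G")),
    "-1T x -1T" = mk("-1T x -1T", substrate("-1T", "-1T")),
    "-1T x WT" = mk("-1T x WT", substrate("-1T", "WT")),
    "WT x -1T" = mk("WT x -1T", substrate("WT", "-1T")),
    "WT x +1A" = mk("WT x +1A", substrate("WT", "+1A")),
    "WT x +1C" = mk("WT x +1C", substrate("WT", "+1C")),
    "WT x +1G" = mk("WT x +1G", substrate("WT", "+1G")),
    "W118R" = mk("W118R", substrate(), "W118R"),
    "W118R -1T x WT" = mk("W118R -1T x WT", substrate("-1T", "WT"), "W118R"),
    "V119G" = mk("V119G", substrate(), "V119G")
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) abort(sprintf("unknown scenario '%s'", name))
  presets[[name]]
}

#' Noiseless time course of a scenario
#'
#' @param scenario A scenario name or a preset list from [scenario_presets()].
#' @param t_grid Times, s.
#' @return An `mk_tc` time course.
#' @export
scenario_time_course <- function(scenario, t_grid = default_time_grid()) {
  if (is.character(scenario)) scenario <- scenario_presets(scenario)
  Q <- build_generator(scenario$mechanism, scenario$rates,
                       scenario$substrate, scenario$tpase)
  solve_master(Q, t_grid)
}

#' Generate a synthetic quantified-gel dataset
#'
#' Computes the true species fractions from the master equation, derives the
#' observables a quantified gel series would report, and perturbs each
#' observation with independent multiplicative lognormal noise
#' (`value * exp(e)`, `e ~ N(0, noise_sd^2)`), independently per observable,
#' time point and replicate. Observables:
#'
#' * `"native"` — the five native-gel class fractions (SC, OC, LIN, BB_ETF,
#'   INTEGRATED) at every grid time, optionally renormalized per lane;
#' * `"seb_nick"` — the probability that the uncleaved partner end of an SEB
#'   molecule is nicked (the denatured-SEB diagnostic), reported at times
#'   where SEB mass exceeds `1e-4`.
#'
#' @param scenario Scenario name or preset (see [scenario_presets()]);
#'   alternatively supply `mech`, `rates`, `sub`, `tpase` directly.
#' @param mech,rates,sub,tpase Model configuration (overridden by `scenario`).
#' @param t_grid Sampling times, s.
#' @param noise_sd Lognormal sigma on the natural-log scale (>= 0).
#' @param seed Integer seed.
#' @param n_replicates Replicate gel series.
#' @param observables Subset of `c("native", "seb_nick", "denaturing")`;
#'   `"denaturing"` adds the per-end strand-cleavage fractions a denaturing
#'   gel quantifies (`nts_left`, `nts_right`, `ts_left`, `ts_right`: fraction
#'   of molecules with that end's NTS at least nicked / TS cut).
#' @param normalization `"per_lane"` (native class fractions renormalized to
#'   sum to 1 at each time, as densitometry of one lane would be) or
#'   `"none"`.
#' @return A tibble of class `mk_dataset` with columns `scenario`,
#'   `replicate`, `time_s`, `observable`, `value`, and the generating truth
#'   in `attr(, "truth")`.
#' @export
#' @examples
#' d <- simulate_gel_dataset("WT x WT", noise_sd = 0.1, seed = 1)
#' dplyr::count(d, observable)
simulate_gel_dataset <- function(scenario = NULL,
                                 mech = mechanism_spec("constrained"),
                                 rates = default_rates(), sub = substrate(),
                                 tpase = transposase_variant("WT"),
                                 t_grid = default_time_grid(),
                                 noise_sd = 0.15, seed = 1, n_replicates = 3,
                                 observables = c("native", "seb_nick"),
                                 normalization = c("per_lane", "none")) {
  normalization <- match.arg(normalization)
  observables <- match.arg(observables,
                           c("native", "seb_nick", "denaturing"),
                           several.ok = TRUE)
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (!length(t_grid)) abort("empty time grid")
  scenario_name <- "custom"
  if (!is.null(scenario)) {
    if (is.character(scenario)) scenario <- scenario_presets(scenario)
    mech <- scenario$mechanism; rates <- scenario$rates
    sub <- scenario$substrate; tpase <- scenario$tpase
    scenario_name <- scenario$name
  }
  mech <- as_mechanism(mech)
  Q <- suppressWarnings(build_generator(mech, rates, sub, tpase))
  tc <- solve_master(Q, t_grid)

  truth_rows <- list()
  if ("native" %in% observables) {
    nf <- native_fractions(tc)
    truth_rows$native <- tibble(time_s = nf$time_s,
                                observable = as.character(nf$species),
                                value = nf$fraction)
  }
  if ("seb_nick" %in% observables) {
    seb <- .seb_states(mech)
    m <- tc_matrix(tc)
    mass <- rowSums(m[, seb$all, drop = FALSE])
    keep <- mass > 1e-4
    if (any(keep)) {
      p <- rowSums(m[, seb$partner_nicked, drop = FALSE])[keep] / mass[keep]
      truth_rows$seb_nick <- tibble(time_s = t_grid[keep],
                                    observable = "seb_nick", value = p)
    }
  }
  if ("denaturing" %in% observables) {
    truth_rows$denaturing <- .denaturing_observables(tc, mech)
  }
  truth_tbl <- bind_rows(truth_rows)

  obs <- .with_seed(seed, {
    bind_rows(lapply(seq_len(n_replicates), function(r) {
      d <- truth_tbl
      d$value <- d$value * exp(rnorm(nrow(d), 0, noise_sd))
      d$replicate <- r
      d
    }))
  })
  native_classes <- c("SC", "OC", "LIN", "BB_ETF", "INTEGRATED")
  if (normalization == "per_lane" && "native" %in% observables) {
    obs <- obs %>%
      group_by(.data$replicate, .data$time_s) %>%
      mutate(value = ifelse(.data$observable %in% native_classes,
                            .data$value /
                              sum(.data$value[.data$observable %in% native_classes]),
                            .data$value)) %>%
      ungroup()
  }
  obs <- obs %>%
    mutate(scenario = scenario_name) %>%
    select("scenario", "replicate", "time_s", "observable", "value") %>%
    arrange(.data$replicate, .data$time_s, .data$observable)
  contexts <- list()
  contexts[[scenario_name]] <- list(substrate = sub, tpase = tpase)
  structure(obs, class = c("mk_dataset", class(tibble())),
            contexts = contexts,
            truth = list(mechanism = mech, rates = rates, substrate = sub,
                         tpase = tpase, t_grid = t_grid, noise_sd = noise_sd,
                         seed = seed, n_replicates = n_replicates,
                         normalization = normalization,
                         observables = observables, truth_tbl = truth_tbl))
}

#' Combine datasets from several reactions into one joint dataset
#'
#' Row-binds `mk_dataset` objects (e.g. a wild-type and a heteroduplex
#' series) keeping each scenario's substrate/transposase context, so that
#' [fit_rates()] and [select_mechanism()] can fit shared rate constants
#' jointly across reactions.
#'
#' @param ... `mk_dataset` objects with distinct scenario names.
#' @return A joint `mk_dataset`.
#' @export
bind_datasets <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1, all(vapply(parts, inherits, logical(1),
                                           "mk_dataset")))
  contexts <- do.call(c, lapply(parts, attr, "contexts"))
  if (anyDuplicated(names(contexts))) {
    abort("scenario names must be distinct across datasets")
  }
  obs <- bind_rows(lapply(parts, as_tibble))
  structure(obs, class = c("mk_dataset", class(tibble())),
            contexts = contexts,
            truth = attr(parts[[1]], "truth"))
}

#' Synthetic benchmark dataset for mechanism discrimination
#'
#' Generates the joint dataset used to benchmark [select_mechanism()]: a
#' wild-type (WT x WT) series plus a heteroduplex (5G x WT) series under one
#' generating mechanism, with all three observable families — native class
#' fractions, the SEB partner-nick probability, and per-end strand-cleavage
#' fractions. This mirrors the experimental logic: with fast NTS nicking a
#' wild-type substrate alone barely separates the mechanisms, and the
#' discrimination rests on the crosstalk revealed by the near-inert partner
#' end together with the denatured-strand readout.
#'
#' @param mech Generating (true) mechanism kind.
#' @param seed Integer seed.
#' @param noise_sd Lognormal noise sigma.
#' @param n_replicates Replicates per scenario.
#' @param t_grid Sampling times, s.
#' @param scenarios Scenario names (substrate/transposase presets) to pool.
#' @return A joint `mk_dataset`.
#' @export
benchmark_dataset <- function(mech = "constrained", seed = 1, noise_sd = 0.1,
                              n_replicates = 3, t_grid = default_time_grid(),
                              scenarios = c("WT x WT", "5G x WT")) {
  mech <- as_mechanism(mech)
  parts <- lapply(seq_along(scenarios), function(i) {
    sc <- scenario_presets(scenarios[i])
    d <- simulate_gel_dataset(
      mech = mech, rates = sc$rates, sub = sc$substrate, tpase = sc$tpase,
      t_grid = t_grid, noise_sd = noise_sd, seed = seed + (i - 1L) * 7919L,
      n_replicates = n_replicates,
      observables = c("native", "seb_nick", "denaturing")
    )
    d$scenario <- scenarios[i]
    ctx <- list(); ctx[[scenarios[i]]] <- list(substrate = sc$substrate,
                                               tpase = sc$tpase)
    attr(d, "contexts") <- ctx
    d
  })
  do.call(bind_datasets, parts)
}

#' Write a synthetic dataset and its generating truth to disk
#'
#' The observations go to `<path>.csv` (tidy: scenario, replicate, time_s,
#' observable, value) and the generating configuration (mechanism, rates,
#' factors, seed, noise) to `<path>.json`.
#'
#' @param dataset An `mk_dataset`.
#' @param path Output path without extension.
#' @return Invisibly, the two file paths.
#' @export
write_dataset <- function(dataset, path) {
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  utils::write.csv(as.data.frame(dataset), csv, row.names = FALSE)
  tr <- attr(dataset, "truth")
  side <- list(
    mechanism = tr$mechanism$kind,
    coupling_rule = tr$mechanism$coupling_rule,
    rates = unclass(tr$rates),
    substrate = list(
      name = tr$substrate$name,
      element_length = tr$substrate$element_length,
      backbone_length = tr$substrate$backbone_length,
      digest_site = tr$substrate$digest_site,
      left = unclass(tr$substrate$left_end),
      right = unclass(tr$substrate$right_end)
    ),
    tpase = unclass(tr$tpase),
    t_grid = tr$t_grid, noise_sd = tr$noise_sd, seed = tr$seed,
    n_replicates = tr$n_replicates, normalization = tr$normalization
  )
  jsonlite::write_json(side, json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(csv = csv, json = json))
}
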