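# Scenario files and tabular exports.

#' Read a reaction scenario from a YAML (or JSON) file
#'
#' A scenario file describes one reaction: mechanism kind and coupling rule,
#' rate constants (omit to use the calibrated defaults), substrate geometry
#' and end variants (preset names like `"-1T"`, or explicit
#' name/positions/factors), and the transposase variant. See
#' `system.file("extdata", "example_scenario.yaml", package = "marinerkin")`.
#'
#' @param path File path (`.yaml`/`.yml`/`.json`).
#' @return A scenario list usable by [simulate_gel_dataset()] and
#'   [scenario_time_course()].
#' @export
read_scenario <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  mech <- mechanism_spec(cfg$mechanism %||% "constrained",
                         cfg$coupling_rule %||% "additive")
  rates <- if (is.null(cfg$rates)) default_rates() else
    do.call(rate_set, as.list(cfg$rates))
  mk_end <- function(x) {
    if (is.character(x)) return(end_variant_preset(x))
    end_variant(x$name, x$mutated_positions %||% integer(),
                x$nts_factor %||% 1, x$ts_factor %||% 1, x$competence %||% 1)
  }
  g <- cfg$geometry %||% list()
  sub <- substrate(mk_end(cfg$left_end %||% "WT"), mk_end(cfg$right_end %||% "WT"),
                   element_length = g$element_length %||% 1500,
                   backbone_length = g$backbone_length %||% 2500,
                   digest_site = g$digest_site,
                   flank_dinucleotide = g$flank_dinucleotide %||% "TA",
                   name = cfg$name)
  tp <- cfg$transposase %||% "WT"
  tpase <- if (is.character(tp)) transposase_variant(tp) else
    transposase_variant("custom", tp$syn_multiplier %||% 1,
                        tp$trans_multiplier %||% 1, tp$ts_multiplier %||% 1,
                        tp$coupling_override)
  list(name = cfg$name %||% sub$name, substrate = sub, tpase = tpase,
       mechanism = mech, rates = rates)
}

#' Write the mutant catalog as TSV
#'
#' @param catalog Tibble from [build_mutant_catalog()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_catalog_tsv <- function(catalog, path) {
  flat <- catalog %>%
    mutate(positions = vapply(.data$substrate, function(s) {
      paste(union(s$left_end$mutated_positions, s$right_end$mutated_positions),
            collapse = ",")
    }, character(1))) %>%
    select("name", "left", "right", "class", "positions",
           "nts_factor", "ts_factor", "competence")
  utils::write.table(as.data.frame(flat), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a labeled rate generator as TSV
#'
#' @param generator Matrix from [build_generator()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_generator_tsv <- function(generator, path) {
  utils::write.table(cbind(state = rownames(generator),
                           as.data.frame(generator)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a time course as tidy CSV
#'
#' @param tc An `mk_tc`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_time_course <- function(tc, path) {
  utils::write.csv(as.data.frame(tc), path, row.names = FALSE)
  invisible(path)
}

#' Write Gillespie trajectories as an event-list TSV
#'
#' @param ssa An `mk_ssa` from [gillespie()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_trajectories_tsv <- function(ssa, path) {
  utils::write.table(as.data.frame(ssa$trajectories), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read user-supplied transposon-end sequences from FASTA
#'
#' Optional convenience: end identity is symbolic in this package (variant
#' name and mutated positions), but literal end sequences can be attached
#' from a standard FASTA file. When `validate_ta_flank = TRUE`, sequences
#' that include flanking DNA must begin with the TA target-site duplication.
#'
#' @param path FASTA file.
#' @param validate_ta_flank Check that each sequence starts with `TA`.
#' @return A tibble `name`, `sequence`.
#' @export
read_end_fasta <- function(path, validate_ta_flank = FALSE) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTA requires the Biostrings package")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  out <- tibble(name = names(seqs), sequence = as.character(seqs))
  if (validate_ta_flank && !all(substr(out$sequence, 1, 2) == "TA")) {
    abort("flanked end sequences must begin with the TA duplication")
  }
  out
}
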