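# Virtual restriction digest, end labeling and denaturing-gel band tables.
#
# A cut map lists single-strand break boundaries on the circular plasmid map
# (boundary k = between base k and base k+1, modulo the total length).
# Denaturation separates the two physical strands; each strand is walked
# independently between its own breaks.

#' Cut map of a molecule state
#'
#' Places the transposition breaks implied by a molecule state on the plasmid
#' map: an NTS nick for each nicked end, NTS plus TS cuts for each end with a
#' double-strand break, and (optionally) the restriction double-strand break
#' at the substrate's digest site. The restriction cut is modelled as blunt
#' (one boundary on both strands): its few-nt stagger is below gel
#' resolution, but its termini are flagged for fill-in labeling. An
#' INTEGRATED molecule is mapped like the double-end-break state: the
#' backbone fragments are unchanged and the excised transposon has joined a
#' target that is not part of this map.
#'
#' @param state State label (e.g. `"DN"`, `"NN_pre"`).
#' @param sub A [substrate()].
#' @param map A [cleavage_site_map()].
#' @param digest Add the restriction double-strand break?
#' @param mech Mechanism whose state space `state` belongs to.
#' @return An object of class `mk_cutmap`: `total_length`, `circular`, and a
#'   `breaks` tibble (`strand`, `pos`, `kind`).
#' @export
build_cutmap <- function(state, sub = substrate(), map = cleavage_site_map(),
                         digest = TRUE, mech = "constrained") {
  st <- enumerate_states(mech)
  row <- st[st$state == state, ]
  if (!nrow(row)) abort(sprintf("unknown state '%s'", state))
  breaks <- list()
  for (end in c("left", "right")) {
    status <- if (end == "left") row$left else row$right
    cuts <- cleavage_positions(sub, end, map)
    if (status == "N") {
      breaks[[length(breaks) + 1L]] <-
        tibble(strand = cuts$strand[cuts$cut == "nts"],
               pos = cuts$pos[cuts$cut == "nts"], kind = "nick")
    } else if (status == "D") {
      breaks[[length(breaks) + 1L]] <-
        tibble(strand = cuts$strand, pos = cuts$pos, kind = "transposition_cut")
    }
  }
  if (digest) {
    breaks[[length(breaks) + 1L]] <-
      tibble(strand = c("fwd", "rev"), pos = sub$digest_site,
             kind = "restriction")
  }
  breaks <- if (length(breaks)) bind_rows(breaks) else
    tibble(strand = character(), pos = numeric(), kind = character())
  structure(list(total_length = sub$total_length, circular = TRUE,
                 breaks = breaks),
            class = "mk_cutmap")
}

#' Single-strand fragments of a cut map
#'
#' Walks each physical strand between its own consecutive breaks around the
#' circle. A strand with no break yields one circular fragment of the full
#' length; otherwise fragments run boundary-to-boundary and their lengths sum
#' to the total length.
#'
#' @param cm An `mk_cutmap`.
#' @return A tibble `strand`, `start`, `end` (boundary coordinates; `NA` for
#'   a circular fragment), `length` (nt), `circular`.
#' @export
single_strand_fragments <- function(cm) {
  stopifnot(inherits(cm, "mk_cutmap"))
  total <- cm$total_length
  out <- lapply(c("fwd", "rev"), function(s) {
    b <- sort(unique(cm$breaks$pos[cm$breaks$strand == s] %% total))
    if (!length(b)) {
      return(tibble(strand = s, start = NA_real_, end = NA_real_,
                    length = total, circular = TRUE))
    }
    ends <- c(b[-1], b[1] + total)
    tibble(strand = s, start = b, end = ends %% total, length = ends - b,
           circular = FALSE)
  })
  bind_rows(out)
}

#' Label fragments and collect them into gel bands
#'
#' Assigns a radiolabel count to each single-strand fragment and merges
#' fragments of (near-)equal length into bands, as on a denaturing gel:
#'
#' * `five_prime_kinase` — dephosphorylation followed by polynucleotide
#'   kinase labels the 5' end of every linear fragment once (circular
#'   strands have no end and carry no label);
#' * `three_prime_fill_in` — Klenow fill-in labels only fragments whose 3'
#'   terminus lies at a restriction cut.
#'
#' Band intensity is molar abundance times label count (one isotope per
#' labeled end; no length weighting). Fragments merge into one band when
#' their relative length difference is at most `tolerance`; the default 0
#' merges only identical lengths (co-migrating complementary strands).
#'
#' @param fragments Tibble from [single_strand_fragments()], optionally with
#'   a `molar_abundance` column (default 1 per fragment).
#' @param labeling `"five_prime_kinase"` or `"three_prime_fill_in"`.
#' @param restriction_ends Boundary positions of restriction cuts (needed for
#'   fill-in labeling).
#' @param tolerance Relative length difference below which bands merge.
#' @return A band table (class `mk_bands`): `length`, `n_fragments`,
#'   `label_count`, `molar_abundance`, `intensity`, sorted by length
#'   descending.
#' @export
label_and_band <- function(fragments,
                           labeling = c("five_prime_kinase", "three_prime_fill_in"),
                           restriction_ends = numeric(), tolerance = 0) {
  labeling <- match.arg(labeling)
  fr <- as_tibble(fragments)
  if (!"molar_abundance" %in% names(fr)) fr$molar_abundance <- 1
  lbl <- if (labeling == "five_prime_kinase") {
    as.integer(!fr$circular)
  } else {
    three_prime <- ifelse(fr$strand == "fwd", fr$end, fr$start)
    as.integer(!fr$circular & three_prime %in% restriction_ends)
  }
  fr$label_count <- lbl
  fr$intensity <- fr$molar_abundance * fr$label_count
  fr <- fr[order(-fr$length), ]
  band <- integer(nrow(fr))
  if (nrow(fr)) {
    band[1] <- 1L
    ref <- fr$length[1]
    for (i in seq_len(nrow(fr))[-1]) {
      if ((ref - fr$length[i]) / ref <= tolerance) {
        band[i] <- band[i - 1L]
      } else {
        band[i] <- band[i - 1L] + 1L
        ref <- fr$length[i]
      }
    }
  }
  fr$band <- band
  out <- fr %>%
    group_by(.data$band) %>%
    summarise(length = max(.data$length), n_fragments = dplyr::n(),
              label_count = sum(.data$label_count),
              molar_abundance = sum(.data$molar_abundance),
              intensity = sum(.data$intensity), .groups = "drop") %>%
    select(-"band") %>%
    arrange(dplyr::desc(.data$length))
  structure(out, class = c("mk_bands", class(tibble())),
            tolerance = tolerance, labeling = labeling)
}

#' Number of visible (labeled) bands in a band table
#'
#' @param bands An `mk_bands` table.
#' @return Integer count of bands with positive intensity.
#' @export
n_bands <- function(bands) sum(bands$intensity > 1e-12)

# Is a fragment [start, start+len) inside the clockwise arc from `a` to `b`?
.in_arc <- function(start, len, a, b, total) {
  arclen <- (b - a) %% total
  if (arclen == 0) arclen <- total
  offset <- (start - a) %% total
  offset + len <= arclen + 1e-9
}

#' Band table of a gel-purified single-end-break fragment
#'
#' Reproduces the SEB diagnostic: cut one transposon end (NTS + TS), optionally
#' nick the partner end's NTS, digest at the backbone restriction site,
#' purify the transposon-containing digest fragment on a native gel, end
#' label, denature and count bands. An SEB whose partner end is nicked
#' denatures into three labeled strands of similar molar abundance; without
#' the nick the duplex denatures into two.
#'
#' @inheritParams build_cutmap
#' @param cleaved_end Which end carries the double-strand break.
#' @param partner_nick Is the other end's NTS nicked?
#' @param labeling Labeling chemistry, as in [label_and_band()].
#' @param piece `"transposon"` for the SEB fragment, `"backbone"` for the
#'   backbone-only marker fragment.
#' @param tolerance Band-merge tolerance.
#' @return An `mk_bands` table.
#' @export
#' @examples
#' n_bands(seb_band_table(substrate(), partner_nick = TRUE))   # 3
#' n_bands(seb_band_table(substrate(), partner_nick = FALSE))  # 2
seb_band_table <- function(sub = substrate(), map = cleavage_site_map(),
                           cleaved_end = c("left", "right"),
                           partner_nick = TRUE,
                           labeling = "five_prime_kinase",
                           piece = c("transposon", "backbone"),
                           tolerance = 0) {
  cleaved_end <- match.arg(cleaved_end)
  piece <- match.arg(piece)
  state <- if (cleaved_end == "left") {
    if (partner_nick) "DN" else "DU"
  } else {
    if (partner_nick) "ND" else "UD"
  }
  # DU/UD are expressible in the independent state space
  cm <- build_cutmap(state, sub, map, digest = TRUE, mech = "independent")
  fr <- single_strand_fragments(cm)
  total <- sub$total_length
  L <- sub$element_length
  # the purified duplex is bounded by the digest site and the cleaved end's
  # cuts; the backbone piece keeps the few-nt NTS stub beyond the junction
  arc <- if (cleaved_end == "left") {
    if (piece == "transposon") c(map$ts_offset, sub$digest_site) else
      c(sub$digest_site, map$nts_offset)
  } else {
    if (piece == "transposon") c(sub$digest_site, L - map$ts_offset) else
      c(L - map$nts_offset, sub$digest_site)
  }
  keep <- vapply(seq_len(nrow(fr)), function(i) {
    !fr$circular[i] && .in_arc(fr$start[i], fr$length[i], arc[1], arc[2], total)
  }, logical(1))
  label_and_band(fr[keep, ], labeling, restriction_ends = sub$digest_site,
                 tolerance = tolerance)
}

#' Simulated denaturing-gel lane of a reaction at one time point
#'
#' Takes the state distribution of a time course at time `t`, builds the cut
#' map of every occupied state, digests, labels and pools all fragments
#' weighted by state occupancy: the in-silico counterpart of quantifying one
#' lane of a kinetic gel.
#'
#' @param tc A time course.
#' @param t Time, s.
#' @inheritParams build_cutmap
#' @inheritParams label_and_band
#' @param mech Mechanism, if `tc` lacks the attribute.
#' @return An `mk_bands` table.
#' @export
lane_profile <- function(tc, t, sub = substrate(), map = cleavage_site_map(),
                         digest = TRUE,
                         labeling = c("five_prime_kinase", "three_prime_fill_in"),
                         mech = NULL, tolerance = 0) {
  labeling <- match.arg(labeling)
  mech <- mech %||% attr(tc, "mechanism")
  if (is.null(mech)) abort("supply `mech`: the time course carries no mechanism")
  states <- attr(tc, "states") %||% unique(tc$state)
  frac <- vapply(states, function(s) {
    d <- tc[tc$state == s, , drop = FALSE]
    approx(d$time_s, d$fraction, xout = t, rule = 2)$y
  }, numeric(1))
  pieces <- lapply(states[frac > 1e-9], function(s) {
    cm <- build_cutmap(s, sub, map, digest = digest, mech = mech)
    fr <- single_strand_fragments(cm)
    fr$molar_abundance <- frac[[s]]
    fr$state <- s
    fr
  })
  if (!length(pieces)) abort("no occupied state at this time")
  label_and_band(bind_rows(pieces), labeling,
                 restriction_ends = if (digest) sub$digest_site else numeric(),
                 tolerance = tolerance)
}

#' @export
print.mk_bands <- function(x, width_chars = 40, ...) {
  cat(sprintf("<denaturing-gel band table: %d fragments, %d labeled bands>\n",
              sum(x$n_fragments), n_bands(x)))
  if (nrow(x)) {
    imax <- max(x$intensity, 1e-12)
    for (i in seq_len(nrow(x))) {
      bar <- strrep("#", max(0L, round(width_chars * x$intensity[i] / imax)))
      cat(sprintf("  %8.0f nt | %-8.3g %s\n", x$length[i], x$intensity[i], bar))
    }
  }
  invisible(x)
}
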