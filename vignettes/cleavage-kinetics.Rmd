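---
title: "Modelling the order of strand-cleavage events in mariner transposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the order of strand-cleavage events in mariner transposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marinerkin)
```

## The model

A mariner transpososome pairs the two inverted-repeat ends of a transposon
with a transposase dimer and excises the element by four hydrolysis
reactions: at each end the non-transferred strand (NTS) is nicked 3 nt
inside the element, then the transferred strand (TS) is cut exactly at the
junction. There is no hairpin intermediate, and at a given end the NTS is
always cleaved before the TS; the open question the package formalizes is
how the cuts are ordered *across* the two ends.

`marinerkin` represents one substrate molecule as a continuous-time Markov
chain. The per-end status is U (uncut), N (NTS nicked) or D (double-strand
break); a molecule is FREE (unsynapsed, both ends U), SYNAPSED, or
INTEGRATED (absorbing). Three mechanisms define which transitions exist:

* **independent** — after synapsis, each end nicks (`k_nts`) and then cuts
  its TS (`k_ts`) regardless of the partner. 11 states.
* **sequential** — one end completes U → N → D before the partner may
  begin. 10 states; the doubly nicked state does not exist.
* **constrained** — both ends nick first; a coordinated conformational
  transition (`k_trans`) then licenses TS cleavage at either end. 10
  states, with the doubly nicked state split into `NN_pre`/`NN_post`.

Synapsis is modelled as irreversible and pseudo-first-order: the transposase
(20 nM in the reference reaction conditions) is in ~3-fold excess over
substrate (6.7 nM), and nicking requires prior pairing of both ends, so
binding and synapsis are lumped into the single rate `k_syn`. Integration
is a single lumped terminal step `k_int`; target choice and integration
topology are out of scope.

In the constrained mechanism the rate of the coordinated transition couples
the two ends' *competences* \(c_L, c_R \in [0,1]\):

\[
k_\mathrm{trans}' = k_\mathrm{trans} \cdot
  \begin{cases}
  (c_L + c_R)/2 & \text{additive (default)}\\
  c_L \, c_R & \text{multiplicative}\\
  \min(c_L, c_R) & \text{min}
  \end{cases}
\]

The additive rule lets a wild-type end drive the transition for a defective
partner (rescue); the multiplicative rule cannot. The hyperactive linker
mutant transposase W118R overrides the rule to multiplicative — its
coordination works for two good ends but fails to rescue a bad one.

## Parameters and calibration

| rate | meaning | default (s⁻¹) | why |
| --- | --- | --- | --- |
| `k_syn` | synapsis (pseudo-first-order) | 0.0248 | SC half-life 30 s, synapsis-limited |
| `k_nts` | NTS nick, per end | 10 × `k_syn` | nicking fast once synapsed |
| `k_trans` | coordinated transition | 8.73 × 10⁻⁴ | TS half-life 15 min, transition-limited |
| `k_ts` | TS cut, per end | 10 × `k_trans` | chemistry fast once licensed |
| `k_int` | lumped integration | = `k_ts` | not rate-analyzed in scope |

`calibrate_rates()` solves two one-dimensional root problems: `k_syn` such
that the supercoiled class (FREE + synapsed-uncut) crosses half its initial
value at 30 s, and `k_trans` such that half the molecules have suffered
their first TS cut at 900 s. The two half-lives are the only quantitative
kinetic anchors available; everything else is a ratio choice.

Two ratio choices deserve comment. First, SC consumption is made
*synapsis-limited* (`k_nts = 10 k_syn`) rather than split evenly between
synapsis and nicking. The decisive observation is that a heteroduplex
carrying one near-inert 5G end consumes supercoiled substrate at the same
rate as the wild type: with even apportionment, removing one of the two
competing nick channels would lengthen the SC half-life by ~46%, while the
synapsis-limited choice keeps it within ~7% (the preset test asserts 10%).
Second, the NTS → TS delay is attributed to the coordinated transition
(`k_ts = 10 k_trans`), consistent with the long lag being conformational
rather than chemical.

### End-variant factors

Mutant transposon ends enter the model as three multipliers: `nts_factor`
on nicking, `ts_factor` on TS chemistry, and `competence` for the
transition. The experiments constrain phenotypes, not rates, so the preset
values are chosen once to reproduce the qualitative panel and are exposed
as configuration:

| variant | nts | ts | competence | phenotype reproduced |
| --- | --- | --- | --- | --- |
| WT | 1 | 1 | 1 | fast completion |
| −1 (flank) | 1 | 0.3 | 0.01 | nick-stall, rescuable by a WT partner |
| −2 (flank) | 1 | 1 | 0.9 | near wild type |
| +1C/+1G/+2G | 0.5 | 0.2 | 0.5 | mild NTS defect, stronger TS defect |
| other +1..+4 | 1 | 0.5 | 0.8 | mild TS defect |
| 5G (−2..+3) | 2 × 10⁻⁵ | 0.01 | 0.05 | near-inert over hours |

Two of these required care. Because post-synaptic nicking is fast
(0.248 s⁻¹), an end that still looks mostly supercoiled after 3 h needs a
very small nicking multiplier — 2 × 10⁻⁵ gives SC(3 h) ≈ 0.9, matching the
"inactive" classification threshold; a multiplier of 10⁻² would nick
everything within half an hour. Likewise the −1 competence must be ~0.01
for the symmetric −1 mutant's cumulative double-end cleavage to stay below
0.1 at 3 h while its nicked intermediate exceeds 0.6; at 0.05 the additive
coupling leaks too much transition. Which of `competence` and `ts_factor`
carries the −1 defect is not separable from the data; the default splits it
and both knobs are exposed.

The experiments cannot distinguish these factor values beyond rank order;
only the orderings (and the classification thresholds applied to them) are
asserted by tests.

## Observables

`native_species()` maps states onto what a native gel resolves: SC (no
breaks), OC (nicked circle), LIN (single-end break, SEB), BB_ETF
(backbone + excised transposon) and INTEGRATED. The *cumulative excision
yield* used for phenotype calls is P(DD) + P(INTEGRATED): on a gel the
backbone band persists after integration, so the readout accumulates.

The virtual gel pipeline converts a state into strand breaks on the
circular plasmid map (`build_cutmap()`), walks each physical strand between
its own breaks (`single_strand_fragments()`), routes the radiolabel
(`label_and_band()`: 5'-kinase labels every linear strand once; 3'-fill-in
labels only termini at a restriction cut), and merges near-equal lengths
into bands. Two geometric conventions matter:

* Because the ends are inverted repeats, the NTS lies on opposite physical
  strands at the two ends. The excised transposon fragment is therefore
  bounded by the two TS cuts (span = element length) and the two NTS cuts
  (span = element length − 2 × 3 nt); `etf_strand_lengths()` reports these
  spans.
* The restriction cut is modelled as blunt (its few-nt stagger is below gel
  resolution) but its termini are flagged for fill-in labeling. The default
  band-merge tolerance is 0: identical lengths co-migrate (complementary
  strands of an intact duplex), while a 3-nt difference — invisible on a
  real agarose gel but meaningful molecular accounting — stays resolved, so
  that the SEB diagnostic reports 3 bands with the partner nick and 2
  without. A user can set `tolerance = 0.005` to emulate true gel
  resolution.

The headline structural prediction is `seb_partner_nick_prob()`: among
molecules with exactly one double-strand-broken end, the probability that
the partner end is nicked. It is identically 1 under the constrained
mechanism (no SEB-with-uncut-partner state is reachable), rises from 0
under the sequential mechanism, and takes intermediate values under
independence.

## Numerical choices

* `solve_master()` propagates p(t) = p(0)·exp(Qt). For grids whose times
  are integer multiples of a base step (the default gel grid is), a single
  `expm` plus binary matrix powers is used; otherwise a spectral
  (eigendecomposition) route with an automatic fallback to stepwise
  scaling-and-squaring exponentials when the generator is defective — which
  the default one is, since `k_int = k_ts` creates repeated eigenvalues.
  The routes agree to < 10⁻⁸ and are cross-checked in the tests.
* `gillespie()` is an exact SSA, vectorized across molecules; every state
  path has at most 7 transitions, so the simulation runs in a handful of
  vectorized sweeps. Seeds are explicit arguments and recorded in outputs.
* `half_life()` interpolates linearly between grid points and refuses
  non-monotone species sets; calibration itself uses closed-form survival
  functions and `uniroot` at tolerance 10⁻¹⁴.
* The likelihood is Gaussian on log(intensity + 10⁻⁴), matching the
  lognormal generator; the noise SD is profiled analytically and counted as
  a parameter. Optimization is multi-start L-BFGS-B in log10-rate space in
  [10⁻⁶, 10] s⁻¹, first start at the supplied baseline rates, remaining
  starts Latin-hypercube. `converged` means the best run succeeded or its
  optimum was reproduced by another start to 10⁻³ in log10-parameters
  (objective *values* are incomparable on noiseless data, where the
  profiled variance makes the optimum arbitrarily deep).
* AIC is used for mechanism selection because the three mechanisms are
  non-nested; ties break by BIC, then parameter count.

## The synthetic-data generator

`simulate_gel_dataset()` emulates densitometry of a kinetic gel series:
true fractions from the master equation at the default 12-lane grid (0 s to
3 h), multiplied by exp(ε), ε ~ N(0, σ²) independently per observable, time
and replicate, with σ = 0.15 by default (0.1 in the discrimination
benchmark) and 3 replicates, then optional per-lane renormalization of the
native classes. Three observable families are available: native class
fractions, the SEB partner-nick probability (reported where SEB mass
exceeds 10⁻⁴), and per-end strand-cleavage fractions (`nts_left`, …,
`ts_right`) — the quantities an end-labeled denaturing gel reports.

What the generator does *not* emulate: correlated lane-loading errors,
background subtraction artifacts, partial digestion or labeling efficiency
differences, band overlap, and image saturation. Passing tests therefore
show that the inference machinery is correct and well-powered under an
idealized error model, not that real gel quantifications would achieve the
same margins.

## Design of the discrimination benchmark

With the calibrated rates, nicking is ~30-fold faster than TS cleavage, and
in that regime a wild-type-only experiment barely separates the mechanisms:
the constrained model with a fast transition collapses onto the independent
model (a tested degenerate limit), and the partner-nick probability is ≈ 1
under every mechanism. This mirrors the experimental logic — the denatured
SEB pattern alone cannot exclude fast-nicking independent cleavage, and the
decisive evidence came from heteroduplex substrates in which an inert end
blocks TS cleavage at its *wild-type* partner, plus denaturing per-strand
readouts. `benchmark_dataset()` therefore pools a WT × WT and a 5G × WT
series with all three observable families. Under that design
`select_mechanism()` recovers the generating mechanism (constrained or
independent) with ΔAIC margins in the hundreds to thousands in 20/20 seeded
runs at σ = 0.1 (recomputed by `scripts/acceptance.R`). One further limit
is worth knowing: the sequential model does *not* collapse onto the
independent one even with instant second-end nicking, because only the
initiating end is cleavage-active and the first TS cut appears at half the
rate.

## Problem sizes

The test suite and acceptance script use: master-equation grids of 12
(default) to 600 (half-life measurement) time points; 50 000 molecules for
SSA-vs-ODE agreement; 1 000 random cut maps against the fragment-walk
oracle; 20 seeds × 3 replicates for parameter-recovery statistics; and
20 seeded runs per generating truth for the discrimination benchmark —
sizes at which every stochastic check has comfortable statistical margin
while the whole suite runs in a few minutes on one CPU.

## Known limitations

* All rate symbols are model-defined; the source experiments publish gel
  images, not rate constants, so absolute rates inherit the uncertainty of
  the two anchoring half-lives (which were measured under their own
  conditions).
* End-variant factors are configuration, not predictions from sequence; no
  attempt is made to model transposase–DNA energetics.
* Synapsis has no reverse step and no transposase-concentration dependence
  beyond the pseudo-first-order lumping.
* Integration is one absorbing step; inter- vs intra-molecular targets,
  target-site choice and hairpin-exclusion chemistry are out of scope.
* The native-gel intensity model is molar (one label per strand); stained
  native gels would weight by length, which `lane_profile()` does not
  attempt.
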