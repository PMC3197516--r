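---
title: "Measuring no-flow time in resuscitation event logs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring no-flow time in resuscitation event logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cprflow)
```

## The measurement problem

In-hospital cardiac arrest response unfolds in two organisationally
distinct phases: ward staff ("first responders") recognise the arrest,
call for help and start basic CPR; some minutes later an ad hoc
cardiac arrest team arrives with a defibrillator and takes over
advanced life support (ALS). The quality question is how much of the
arrest passes without chest compressions — the *no-flow time* (NFT) —
and how that burden splits between the two phases.

`cprflow` operates on a per-scenario **event log**: the instants of
every chest-compression downstroke plus annotated clinical events
(arrest recognition, CPR start, defibrillator arrival, first rhythm on
the scope, rhythm checks, shocks, pulse checks, handover to the team,
and a terminal ROSC or scenario end). All times are seconds, re-based
on ingest so that recognition of the arrest is Time 0. Whether "Time
0" should be the scripted onset of the arrest or the moment staff
recognise it is genuinely ambiguous in this study design; the package
anchors on the `arrest_recognized` annotation, since in an unannounced
scenario recognition is the first observable event, and every marker
is defined relative to it.

## Flow and no-flow

The compression stream is turned into a set of half-open *flow*
intervals: each pair of consecutive compressions separated by at most
`gap_threshold_s` (default **1.5 s**, the conventional boundary
between compression rhythm and interruption in CPR-quality work)
contributes its whole span as flow; wider gaps, the span before the
first compression, and the span after the last one are no-flow. NFT
over a window is the window length minus the measure of the flow set
clipped to it.

Two design choices matter here:

* **Half-open windows.** Every window is `[start, end)`, so an event
  exactly at a boundary (e.g. at handover) belongs to the later
  window and phase windows partition the timeline without double
  counting.
* **Global flow, clipped per window.** The flow set is computed once
  from the full compression stream and then intersected with the
  analysis window. A compression run that straddles the handover is
  thereby split between the phases, which makes phase NFTs *exactly*
  additive: first-responder NFT + team NFT = overall NFT. Computing
  flow only from compressions inside a window would instead count the
  straddling run's tail as no-flow in both phases.

The no-flow ratio is `NFR = NFT / duration`; the 30-second segment
profile applies the same clipping to consecutive 30 s segments from
Time 0 (the final partial segment keeps its true length), so segment
NFTs also sum exactly to the overall NFT.

## Allowance-adjusted metrics

ALS guidelines sanction brief pauses: per two-minute cycle, up to
**5 s** for rhythm analysis, **10 s** for charging and shock delivery
(only when a shock is actually indicated), and **10 s** for a pulse
check. `allowance_credit()` partitions the horizon into cycles of
`cycle_s = 120` anchored at Time 0 (the anchor is configurable; a
`first_rhythm` anchor is available for analyses that prefer to align
cycles with the first rhythm check) and grants at most one credit per
type per cycle, each capped by its allowance *and* by the no-flow time
still uncredited in the cycle — so the total credit can never exceed
the measured NFT and `NFT_adj = NFT − credit` is nonnegative by
construction.

Attribution is event-matched when possible: if the log annotates pulse
checks (or rhythm checks, or shocks), credits of that type are granted
only in cycles containing such an event and are attached to the
no-flow pause containing (or nearest to) it, additionally capped by
that pause's length. If a type is never annotated, a schedule-based
fallback credits its cap in every cycle up to the cycle's available
no-flow — this reflects the reading of the allowance rule as a
per-cycle budget when the log cannot localise the maneuvers. Shock
credit always requires an annotated shock: "when appropriate" is
operationalised literally as *a shock occurred in this cycle*. Both
modes are exposed because device logs differ in how much they
annotate; the event-matched mode is the default behaviour whenever
annotations exist.

For per-phase adjustment, each ledger credit belongs to the phase
containing its event time (schedule credits: the cycle midpoint), and
the per-phase credited total is capped at that phase's NFT, so
`0 ≤ NFR_adj ≤ NFR` holds within each phase even when a cycle
straddles the handover.

## Rates and markers

Device reports distinguish the *pace while compressing* from the
*delivered dose*. `compression_rates()` reproduces the pair: the rate
is the median of `60/gap` over consecutive compression pairs with
sub-threshold gaps (0 if fewer than two such pairs), and the delivered
rate is simply compressions per elapsed minute of the window. For
uninterrupted CPR the two coincide; with a chest-compression fraction
of ~0.7 a pace of ~117/min delivers ~82/min.

Time-to-event markers (CPR initiation, defibrillator arrival, first
rhythm) are event times minus Time 0. Time to CPR falls back to the
first compression when no `cpr_started` annotation exists, because
initiation is operationally defined by observed compressions; markers
absent from a log are reported as missing, never as zero.

## Cohort statistics

Cohort summaries are medians with 25th–75th percentiles, using the
weighted-average-at-`(n+1)p` quantile (`stats::quantile` type 6). That
convention is the SPSS-compatible one, chosen so that summaries of
small cohorts match what legacy statistical workflows produce; types
7 and 2 are selectable for cross-checking.

The phase comparison is an **exact two-sided Mann–Whitney U test**,
authored in the package:

* U is computed from rank sums with midranks for ties.
* Without ties and for `n1 + n2 ≤ 30`, the full null distribution of
  U is counted by the dynamic programme
  `f(i, j, u) = f(i−1, j, u−j) + f(i, j−1, u)`; the two-sided p is
  `min(1, 2·min(P(U ≤ u), P(U ≥ u)))`. At `n1 = n2 = 13` complete
  separation gives `p = 2 / C(26,13) ≈ 1.9e-7`, the smallest
  attainable value at the study size.
* With ties and `n1 + n2 ≤ 12`, the exact p comes from exhaustive
  enumeration over all labelings of the pooled sample.
* Otherwise the normal approximation with tie correction and
  continuity correction is used and labelled `normal_approx`.

The two phases are paired within scenario, yet the primary analysis
treats them as independent groups — this mirrors the analysis design
the package reproduces. A paired Wilcoxon signed-rank variant is
available behind `paired = TRUE` in `compare_phases()` as a clearly
labelled extension, off by default.

## The scenario simulator

No raw per-scenario logs are publicly available for this class of
study — only cohort medians and IQRs — so validation rests on a
synthetic generator whose *defaults are the study conditions*:
13-scenario cohorts; time to CPR lognormal with median 29 s (IQR
22–46); handover and defibrillator arrival lognormal, median 214 s
(180–254); first rhythm lognormal, median 311 s (283–349); arrest
duration lognormal, median 600 s (sdlog 0.20, a spread chosen so
scenarios comfortably contain the later markers); compression pace
normal (117, 5) per minute; first-responder and team no-flow targets
from Beta distributions fitted to medians/quartiles 0.39 (0.32–0.46)
and 0.25 (0.19–0.29); half the scenarios start in a shockable rhythm,
with a 0.3 per-cycle probability of the rhythm state flipping; and
unstructured pause lengths gamma with mean 8 s (shape 2, right-skewed
as observed pause-length data are).

Distribution *families* are a modelling choice, not an observed fact:
lognormals for nonnegative right-skewed times and a scaled Beta for
ratios match the printed medians and quartiles without claiming the
true shapes. The Beta fit weights the median heavily, because a
two-parameter Beta cannot reproduce three asymmetric quantiles exactly
and all downstream calibration anchors on medians; the fitted team
quartiles are within ~0.01 of their targets.

Each scenario is built *constructively* rather than by rejection: the
leading no-flow is the drawn time-to-CPR; extra first-responder pauses
are drawn from the pause distribution and rescaled so the phase NFT
equals the drawn target exactly; the team phase is laid out as 120 s
ALS cycles from handover, each holding a rhythm-analysis pause
(~3–5 s), a pulse-check pause (~6–10 s), a shock pause (~6–10 s) in
shockable cycles, and rescaled filler pauses to meet the drawn team
target. Compression runs are filled at the drawn pace with endpoints
hit exactly, so every inter-compression gap is either a sub-threshold
step or a designed pause and the achieved phase NFRs match their
targets to well within ±0.01. Draws violating the event ordering
(CPR before handover before ROSC, defibrillator before first rhythm)
or making a target infeasible are redrawn up to a cap. Each scenario
uses its own RNG stream derived from `(seed, index)`, so cohorts are
reproducible and order-independent, and generation restores the
caller's RNG state.

What the simulator does *not* emulate: drift in compression rate and
depth with fatigue, ventilation pauses, imperfect event annotation,
correlated behaviour between phases of one crew, and measurement noise
in the device's compression detection. Passing tests therefore
demonstrate that the pipeline measures what the generator encodes —
interval algebra, allowance accounting, statistics — not that real
device logs are this clean; with real data the gap threshold and the
annotation completeness are the quantities to scrutinise.

## Numerical choices and degenerate inputs

* Times are doubles in seconds; sub-second precision is preserved, and
  the CSV writer serialises times at `%.17g` so read∘write is the
  identity.
* Zero-length intervals are dropped; abutting intervals merge.
* An empty compression stream yields NFT = window length; a window
  with no sub-threshold gaps reports a compression pace of 0 with a
  warning rather than an error.
* Credits are compared against no-flow with a 1 ns slack to absorb
  float accumulation; a credit exceeding NFT raises an error, as it
  can only indicate a ledger bug.
* The exact U-test counts reach `C(26,13) ≈ 1.04e7`, far inside exact
  double-integer range; the DP is O(n1·n2·(n1+n2)) and instantaneous
  at these sizes.

## Validation scales

The test suite exercises: the millisecond occupancy-grid brute force
against the interval implementation on 1,000 random logs (log times
are quantised to the 1 ms lattice so the grid is exact and the
agreement bound is one grid step); exhaustive-enumeration checks of
the exact U test for all sample-size shapes with `n1 + n2 ≤ 10` plus
an independent reference implementation; closed-form allowance
credits; conservation and monotonicity properties on generated logs;
parameter recovery on a 200-scenario cohort (phase-NFR medians within
±0.02 of the configured distribution medians; marker medians within
~3 Monte-Carlo standard errors of a 200-draw median); and the
headline phase comparison on 200 replicate 13-scenario cohorts, where
the median exact Mann–Whitney p-value is on the order of 3×10⁻⁴ —
comfortably below the 0.001 significance headline. These problem
sizes keep the whole suite under a few minutes on a single core while
leaving the Monte-Carlo tolerances honest.

## Known limitations

* The allowance rule's cycle anchor is a convention; analyses of logs
  where the team's cycle clock demonstrably starts elsewhere should
  use the `first_rhythm` anchor and check sensitivity.
* Per-phase adjusted metrics depend on the credit-attribution rule at
  the handover boundary; alternatives (proportional splitting) would
  differ by at most one cycle's allowance.
* The unpaired primary test ignores the within-scenario pairing of
  phases and is therefore conservative when phases are positively
  correlated.
* Compression depth, recoil and ventilation are out of scope: the
  event model carries no per-compression quality payload.
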