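---
title: "Schedules, virtual rats and lick microstructure: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Schedules, virtual rats and lick microstructure: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lickometry)
```

This vignette is the package's account of the models it implements, the
parameters that matter, and the places where the design was genuinely
open and a choice had to be made.

## The session model

A session is driven by a time-ordered stream of raw input events — licks
on the active and inactive spout, motion-sensor triggers, RFID scans —
and produces the full event log an acquisition system would write. The
leading RFID scan starts the session clock: a `session_start` event is
emitted at the scan and all logged times are seconds since that instant.
The subject's identity is the scan's 12-hexadecimal-character tag
(enough to uniquely label ~2.8 × 10^14 animals), and a tag→schedule map
lets particular tags select particular schedules, defaulting to VR10.

Active-spout licks feed the reinforcement schedule. Inactive-spout licks
and motion events are logged with no programmed consequence. Each reward
appends a `reward` and a `cue_on` event at the rewarding lick's time and
schedules a `cue_off` exactly `cue_s` later. FR and VR sessions last a
fixed `session_s` (default 3600 s) and input beyond that is discarded;
PR sessions end `pr_idle_stop_s` (default 600 s) after the last
active-spout lick, a rule that can only be evaluated once the stream is
exhausted, so trailing inactive/motion events past that point are
dropped from the log.

### Schedule semantics and tie conventions

The counter logic is shared by all three families:

* a lick inside the post-reward timeout window is logged but not
  counted. The window is half-open, `[reward_t, reward_t + timeout_s)`:
  a lick landing *exactly* at its end counts. One consequence worth
  stating: successive rewards are always separated by more than
  `timeout_s` (with continuous lick times, equality has probability
  zero).
* the reward-triggering lick is included in the requirement count and
  the counter resets to zero immediately after the reward.
* the cue window and the timeout window run concurrently and
  independently; with the defaults (cue 5 s < timeout 20 s) cue windows
  can never overlap, but if a configuration makes them overlap each
  `cue_on` still gets its own `cue_off` exactly `cue_s` later. The final
  `cue_off` is truncated at session end.
* when a `cue_off` falls at exactly the same time as an input event, the
  `cue_off` is logged first. Ties among input events keep input order.
  These stable conventions are what make full runs byte-reproducible.

Two parameters were only ever described loosely by the hardware systems
this package models, so the package makes explicit, configurable
choices:

**The VR draw distribution.** "A randomly chosen number of licks with a
predetermined average" underdetermines the distribution. We draw
uniformly on the integers `{1, …, 2·mean − 1}`: the mean is exact, the
support is bounded, and the minimum requirement is 1. For exact replays
and for testing, an explicit requirement sequence (`vr_draws`, consumed
cyclically) can be supplied instead; `vr_draws = m` makes VR(m)
literally identical to FR(m), a reduction the test suite exercises.

**The PR progression.** Progressive-ratio implementations vary widely
(arithmetic, geometric, exponential). We use the arithmetic rule
`requirement_k = base + (k − 1)·step` with defaults base 10, step 5,
both configurable. PR termination uses the idle-stop rule — the session
ends a fixed window after the last active lick — rather than a
"failed to earn a reward within T" rule; the two differ when an animal
keeps licking slowly without completing a ratio.

VR requirement draws come from an RNG stream that is seeded per session
and isolated from the caller's RNG (the global `.Random.seed` is saved
and restored), so a session is a pure function of (stream, spec, seed).

## The event log

No standard on-disk schema exists for lickometer logs, so the package
defines one: a plain CSV with `#`-prefixed metadata lines (subject tag,
schedule parameters, absolute start time as epoch seconds, seed)
followed by `time_s,kind,tag` rows. Times are decimal text with enough
significant digits (18) that parsing returns the identical double —
`read_event_log(write_event_log(r))` is exact, which the suite checks on
randomized 10,000-event logs. At least three fractional digits are
always kept: licks arrive ~0.15 s apart, so millisecond resolution is
the floor of what the format must express legibly.

## The virtual rat

The generator is a renewal process over lick clusters:

| parameter | meaning | sucrose preset | water preset |
|---|---|---|---|
| `ili_mean_s`, `ili_sd_s` | within-cluster inter-lick interval, truncated normal on (0, 0.5) | 0.15, 0.03 | 0.22, 0.05 |
| `cluster_size_mean` | mean licks per cluster, shifted geometric, minimum 2 | 35.7 | 7.2 |
| `inter_cluster_gap_mean_s` | exponential pause between bursts | 20 | 150 |
| `active_preference` | P(burst targets the active spout) | 0.95 | 0.6 |
| `motion_rate_per_min` | Poisson motion events | 5 | 2 |

The ILI and cluster-size means of the presets are the published
statistics for rats licking 10% sucrose or water on the active spout
under FR10. The distribution *families* are a modeling choice —
published microstructure reports moments, not families — picked for
tractability: the shifted geometric has the overdispersion real cluster
sizes show, the truncation at 0.5 s guarantees generated bursts cohere
under the standard segmentation threshold, and the exponential pause
makes the process memoryless between bursts. Pause means are not
reported anywhere we know of; 20 s and 150 s were chosen once so that an
hour of simulated behavior lands on the reported order of total
responding (~5,000 licks/h for sucrose, ~10²/h for water) and were not
revisited. Minimum cluster size is 2 so every generated burst is
detectable under the ≥2-lick rule.

What the generator deliberately does **not** emulate: reward feedback
(licking is open-loop — consistent with animals licking straight through
the timeout), satiation or within-session drift, spout-dependent
microstructure (both spouts share one ILI/size distribution, whereas
real inactive-spout clusters are smaller), and inter-animal variance
beyond what the renewal process produces. Passing parameter-recovery
tests therefore shows the analysis is correct *for cluster-structured
renewal input*, not that real rats are renewal processes.

One known bias, quantified: exponential pauses occasionally dip below
the 0.5 s threshold (P ≈ 2.5% at a 20 s mean), merging adjacent
generated bursts into one detected cluster. This inflates recovered
cluster size by roughly the merge probability (~2–3%), which is why the
recovery criterion is a 5% median relative error rather than something
tighter, and why the segmentation-identity test conditions on a stream
whose pauses all exceed the threshold.

## Lick microstructure analysis

A cluster is a maximal run of licks whose consecutive gaps are *strictly
less than* the threshold (default 0.5 s); "within 0.5 s" is ambiguous at
equality, so the tie convention is explicit: a gap of exactly 0.5 s
splits. Runs of one lick are excluded. Spouts are segmented
independently — a lick on the other spout does not break a cluster —
matching how per-spout statistics are conventionally reported.

The grand ILI is pooled (one mean over all within-cluster gaps) rather
than a mean of per-cluster means, matching the single reported ILI per
condition in the literature; `ili_mode = "per_cluster"` exposes the
alternative, which weights small clusters more heavily. Whether an
inactive-spout ILI should pool all licks or only clustered licks is
genuinely ambiguous in published descriptions; this package always
computes ILIs within clusters, on both spouts, and reports
`total_licks` alongside so the excluded fraction is visible.

Group comparisons use the pooled-variance two-sample Student's t
(implemented from the formula; the suite cross-checks it against
`stats::t.test(var.equal = TRUE)` to 10⁻¹⁰), two-sided, with the usual
star mapping (`*` < 0.05, `**` < 0.01, `***` < 0.001). The degenerate
zero-variance cases are defined rather than errors: identical constant
groups give t = 0, p = 1; separated constant groups give ±∞, p = 0.

Motion activity is binned into half-open windows `[k·bin, (k+1)·bin)`;
an event exactly at the session end is assigned to the last bin so the
bins always sum to the event count.

## Environmental monitoring

The simulated room samples every 10 min (144/day): a square-wave lux
trace on a reverse light cycle (off 09:00, on 21:00 by default), flat
climate baselines with Gaussian sensor noise, optional single-sample
lux spikes (technician entries during the dark phase) and an optional
step change in temperature/humidity (an airflow adjustment).

Device comparison pairs samples by nearest timestamp within 5 min (half
the cadence) and reports mean ± SD of the paired differences — the
standard side-by-side sensor-agreement check, antisymmetric under
swapping the devices.

Light-cycle detection thresholds the lux trace at the midpoint of its
5th and 95th percentiles by default: the lux sensor is treated as
uncalibrated (its absolute reading is angle-sensitive), so only the
relative level is meaningful; an absolute threshold can be supplied. A
state change registers only after `debounce = 2` consecutive samples on
the new side, which is exactly what suppresses single-sample technician
spikes; the transition is timed at the first sample of the new state, so
a detected switch is within one sample (10 min) of the true clock time.

Step changes are estimated by an exhaustive least-squares single-
changepoint fit (the split minimizing total within-segment sum of
squares; O(n) with cumulative sums). At 144 samples/day a ±1 °C step
against 0.1 °C noise is recovered well within 3× the noise SD.

## Problem sizes and numerical choices

The test suite and acceptance script run: 1,000 randomized streams of
10–10,000 licks for schedule-oracle equivalence; 1,000 streams for
segmentation-oracle equivalence including exact-threshold ties; 10⁵
draws for VR calibration (3-standard-error band); 20 two-hour
sucrose-like rats (≈10⁴ licks each) for parameter recovery; 5-vs-5
one-hour cohorts for the group contrast; and 2–7 day environmental
series. These sizes give the Monte-Carlo checks comfortable power while
keeping a full run in well under a minute per suite on one core.

All stochastic components take explicit integer seeds and restore the
caller's RNG state, so every pipeline stage — generation, session
replay, analysis, serialization — is byte-identical across reruns at a
fixed seed; the suite asserts this at the file level.

## Limitations

The package models the *logic* of an operant rig, not its physics: no
touch-sensor debouncing or capacitance thresholds, no pump step counts
(drop volume is carried only as configuration), no clock drift between
devices, no RFID read failures. In vivo summary numbers (total licks,
rewards, break points) reflect real animals and are matched only in
order of magnitude and direction by the presets, never digit for digit.
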