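---
title: "From phone state logs to screen-time measures: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From phone state logs to screen-time measures: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenbouts)
```

## The estimation problem

Digital-phenotyping apps record a phone's power-state transitions
passively: iOS logs `Unlocked`/`Locked` events plus one battery event
per 1% change in charge level; Android logs `Screen turned on`/`Screen
turned off`. From these event streams we want (a) *screen-on bouts* —
maximal intervals of consecutive use, (b) labels separating genuinely
phone-free time from periods where the logger itself was dead, (c)
daily volume and fragmentation measures, and (d) a minute-level binary
use profile for functional analyses.

The difficulty is that the logs are incomplete in structured ways:
events are dropped when the OS suspends the logger, Android screens
wake briefly for notifications without any user interaction, and a
missing close event turns one tap into an apparently hours-long bout.
Every stage of this package is a response to one of those failure
modes.

## Bout identification

`pair_events()` runs a state machine over time-ordered open/close
roles. Under imputation (the default):

* open while no bout is open → start a bout;
* close while a bout is open → close it (a zero-length bout, close at
  the same millisecond, is dropped);
* open while a bout is open → the close event was evidently lost; the
  current bout is closed *at the new open's timestamp* and flagged
  `close_imputed`. This uses all information present while the
  downstream cap bounds the damage of the unknown true close;
* close with no open bout → dropped. We considered imputing a bout
  backwards from an orphan close, but its open time cannot be bounded
  from the left without inventing data;
* a bout still open at end-of-stream is closed at `start + cap`, or
  dropped when no cap is configured — deterministic and conservative.

Without imputation, only immediately adjacent (open, close) pairs form
bouts; everything unmatched is discarded. This is deliberately the
simplest defensible reading, and it is the one checked against a
brute-force adjacent-pair oracle in the tests.

Two post-processing steps follow, in this order:

1. **Notification filter** (Android only): bouts shorter than
   `notification_min_seconds` (default 10 s) are removed. Platform
   logs do not label notification wakes, so a duration threshold is
   one admissible operationalisation — short screen-wakes without an
   unlock are the plausible target, and iOS unlock events already
   imply interaction. The threshold is configurable and `0` disables
   it.
2. **Cap**: bouts longer than `cap_minutes` (default 30) are truncated
   at `start + cap`. Thirty minutes sits near the 97th percentile of
   naturalistic bout durations, so the cap mostly bites exactly where
   imputation guessed a close; there is no principled optimum, which
   is why comparator modes exist (6-hour cap; no imputation + no cap;
   no imputation + 30-minute cap).

Filtering precedes capping because capping can only shorten bouts — it
never creates a short bout for the filter to remove — so this order
keeps the cap the last word on duration.

## Validity labelling

A day with no events is ambiguous: unused phone, or dead logger? For
iOS the battery stream disambiguates, since a live logger emits an
event for every 1% change. A minute is **valid** when

* it overlaps a gap of ≤ 60 minutes between consecutive battery events
  (events fire per 1% change, so inter-event spacing *is* the
  empirical rate; the gap form operationalises "changing at least
  1%/hour" without choosing a smoothing window), or
* it lies within 12 hours after a 100% battery event with no
  intervening battery event — a full battery on a plugged-in phone is
  silent. The window ends at the first subsequent event (a level
  reading means discharging resumed, re-enabling the gap rule) and a
  repeated 100% reading restarts it.

Minutes are half-open `[t, t + 60 s)`, so the minute containing a
qualifying event is valid. A valid iOS day has ≥ 1080 valid minutes
(18 h). Android has no battery stream; a day is valid when ≥ 8
distinct UTC clock hours contain at least one bout, with an
hour-spanning bout counting toward every hour it overlaps (counting
start-hours only would make validity depend on bout placement within
the hour for no reason).

The analysis filter retains a valid day only if some 28-consecutive-day
window containing it holds ≥ 14 valid days, and a participant only
with ≥ 28 retained days. Windows *slide* by calendar day over the
observation span — anchored/tiled windows would make retention depend
on an arbitrary phase — and are clipped at the span's edges.

## Daily and minute-level measures

Days are UTC midnight-to-midnight, the logs' native clock. Bouts are
split at midnight and fragments counted per day, which makes the
conservation identity exact: summed daily totals equal total capped
bout duration, and `mean_on × count = total` per day (both are tested
identities). Off-bouts are the *interior* gaps between consecutive
fragments within a day; the partial gaps at the day boundaries are
censored intervals, so days with ≤ 1 fragment have an undefined (not
zero) mean off-bout. The bout count enters analyses as `log(count)`;
a zero count has no defined log and the measure is simply absent for
that day rather than shifted by a +1 offset.

The minute grid assigns each of the 1440 half-open minutes its overlap
in seconds with the bout set, and `binary_on = 1` iff that overlap is
positive. Cohort summaries (median and 10/25/75/90th percentiles per
day relative to study start) are smoothed with a centred 7-day moving
average, edge days using the available part of the window.

## The clock-change design and its estimator

A daylight-saving transition shifts everyone's schedule by an hour
overnight — a natural experiment on phone-use timing.
`dst_design()` keeps participant-days within ±`window_days` (default
14; 7 and 28 for sensitivity) of the transition date and attaches a
post indicator. The transition day itself is excluded from both
groups: its local day is 23 or 25 hours long and internally
inconsistent.

`pointwise_logodds()` is a deliberately naive estimator: per minute,
the log odds ratio of the empirical post vs pre proportions, with a
0.5/n continuity correction when a proportion is 0 or 1. It ignores
within-participant correlation and carries no joint inference — a
proper analysis would fit a function-on-scalar generalized mixed model
with joint confidence bands, which is out of scope here. The estimator
exists so that the *design construction* can be validated end-to-end:
on simulated cohorts with a known −60 min sleep shift it must recover
the sign and location of the effect (strongly negative in the vacated
evening hour, centred on zero at midday). Its per-minute sampling
noise at cohort sizes of ~20 participants is of order 0.2 on the
log-odds scale, so bias checks use the *mean* estimate over an
unaffected window, not minute-wise magnitudes.

`logodds_to_or()` converts average functional coefficients to the odds
factors usually reported; e.g. `exp(0.71) ≈ 2.03`.

## What the simulator emulates — and what it does not

`simulate_participant()` generates, from one seed:

* a sleep/wake schedule in a fixed local clock (UTC +
  `tz_offset_hours`, default −5). Full tz-database semantics are
  intentionally avoided: the clock-change experiment is induced
  explicitly by shifting the sleep schedule by
  `dst_sleep_shift_minutes` after a stated transition instant, keeping
  the clock model transparent and testable;
* bout starts as a Poisson process during wake (default 4/wake-hour
  over 16 wake hours), durations lognormal in log-seconds (default
  `meanlog = 4.55`, `sdlog = 1.4`). These defaults give ≈ 60 bouts and
  4–4.5 h of screen time per day with mean bout duration ≈ 4 minutes
  and roughly the 97th duration percentile near the 30-minute cap —
  the region reported for real adolescent/adult cohorts. Starts
  falling inside an active bout are discarded (thinning), preserving
  Poisson-like starts while guaranteeing non-overlapping truth;
* iOS battery: piecewise-linear drain (default 5%/h awake) with an
  overnight charge to 100% (default 30%/h) and events at every
  integer-percent crossing, mirroring the 1%-change logging rule;
* Android notification wakes: Poisson around the clock (default 2/h),
  3 s each, flagged in the truth;
* dropout: `inject_dropout()` deletes events inside given windows
  while leaving the truth untouched for recovery scoring.

It does **not** emulate app-level content, hardware battery chemistry,
weekday/weekend structure, multi-device participants, or gradual
schedule drift. Passing recovery tests therefore show the pipeline is
*algorithmically* correct under the stated missingness mechanisms, not
that real logs satisfy those mechanisms.

## Numerical conventions and problem sizes

Timestamps are numeric epoch milliseconds (doubles hold integer ms
exactly far beyond any realistic date). All intervals are half-open;
ties in event timestamps are preserved in file order by a stable sort.
Zero-length bouts are dropped. Simulated timestamps are rounded to
whole milliseconds before serialisation so CSV round-trips are exact.

The shipped checks run at sizes chosen to exercise every code path
while staying quick to verify: 30-day single participants for
recovery and comparator ordering, a 20-participant, 30-day cohort for
the clock-change sign recovery, 1000 random sequences of ≤ 50 events
for the pairing oracle, and 100 random bout sets for the conservation
identities.

## Known limitations

* The imputation and notification rules are one admissible reading of
  under-specified preprocessing; the comparator modes measure, rather
  than remove, that sensitivity.
* There is no gold standard for log missingness; the iOS heuristic is
  indirect (battery telemetry as liveness proxy) and the Android rule
  conflates non-use with non-collection on sparse days.
* Off-bout means depend on the interior-gap convention; analyses
  comparing them across packages should confirm the same convention.
* The pointwise estimator is for validation only; substantive
  inference about clock-change effects needs a functional
  mixed-effects model.
```{r example}
p <- sim_params("android", n_days = 5, seed = 1,
                notification_wake_rate_per_hour = 0)
out <- simulate_participant(p)
b <- extract_bouts(out$stream, extraction_config("default"))
all.equal(b$start_ms, out$truth_bouts$start_ms)
```
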