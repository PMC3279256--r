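---
title: "Inferring activities from roaming beats: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring activities from roaming beats: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbeats)
```

## The inference model

`rbeats` treats an activity as a pattern in the handling of physical
artifacts. Each artifact is reduced to a two-state process: `1` while it is
recognized on a designated base location and at rest, `0` while it is away
being used. A **roaming beat** is one transition of that process, stamped
with its time and, when a frame clock is available, the index of the video
frame current at that instant. The model assumes that (i) every activity of
interest manipulates at least one tagged artifact through the base location,
(ii) artifacts are reliably recognized there, and (iii) activities express
themselves as bounded bursts of beats. When an artifact never visits the
base location the framework is blind to the activity — that is a stated
limitation of the approach, not a failure mode the engine can detect.

An activity is configured by four criteria: its artifact set, a minimum
beat count per artifact, a duration window $\Delta T = [t_{\min}, t_{\max}]$
in minutes, and a quantum $q$ of post-last-beat silence, by convention
$q = t_{\min}$. The engine keeps one tracker per (activity, artifact). A
tracker in `COUNTING` phase accepts the next beat if it arrives within the
waiting interval (loaded with $t_{\max}$ at episode start) and aborts the
episode otherwise; reaching its beat minimum moves it to `SATISFIED`, sets
the artifact flag, and shrinks the waiting interval to $q$. A coordinator
emits the activity at the first clock tick at which $q$ has elapsed since
the last counted beat among satisfied artifacts and the flag condition
holds: all artifacts in *strict* mode, at least `k_required` (default 2) in
*flexible* mode. On emission all trackers of that activity reset, so
instances of one activity never overlap; different activities share nothing
and may interleave freely. Beats are non-exclusive across activities: an
artifact referenced by two activities feeds both trackers, and the differing
beat requirements and groupings disambiguate.

## Tunable parameters

| parameter | units | default | role |
|---|---|---|---|
| `t_min`, `t_max` | minutes | per activity | episode duration window; `t_max` is also the waiting interval between beats |
| `quantum` | minutes | `t_min` | silence after the last beat before emission |
| `min_beats`, `max_beats` | beats | per artifact | beats established; `max_beats` is advisory (see below) |
| `mode`, `k_required` | — | strict / 2 | flag combination rule |
| `tick` | seconds | 1 | virtual clock resolution; emission-time error is at most one tick and finer than any configured interval |
| accelerometer `threshold`, rest band, `min_dwell` | g, s | 1.3, [0.9, 1.1], 0 | motion/rest discrimination and debounce |
| vision `threshold` | score | required | acceptance level on correlation peaks; deployment-specific, so it is a configuration parameter rather than a constant |

The packaged configuration (`default_criteria_path()`) encodes the
nursing-home characterization: feeding (tray, 2 beats, 5–50 min), blood
pressure (device, 3–4 beats, 5–10 min, quantum 5), hygiene (solution ≥3,
cream ≥3, paper towel ≥6, 10–30 min, flexible with `k_required = 2`),
medications (pillbox ≥2, 3–5 min).

## Semantics decided where the design was open

Several points of the tracker semantics admit more than one reading; the
package fixes them as follows.

* **Waiting interval at episode start.** The waiting interval is loaded with
  $t_{\max}$ when the first beat opens the episode (rather than re-loaded
  after a late beat). A beat arriving after the interval has lapsed starts a
  fresh episode instead of extending a stale one.
* **Emission instant.** An episode is ready when the current time is at
  least `last beat + quantum`; with the default 1-second tick and the
  packaged minute-valued quanta, emission lands exactly one quantum after
  the last counted beat, which is what the canonical traces require (5
  minutes for blood pressure, 10 for hygiene). A beat arriving exactly at
  the expiry instant is processed before the clock check and re-arms the
  quantum.
* **`max_beats` is advisory.** The blood-pressure configuration says 3–4
  beats: the flag is set at 3, and a 4th beat before the quantum expires is
  counted and re-arms the quantum rather than aborting — artifacts sometimes
  stay on the base location after the activity has concluded.
* **Duration criterion.** The episode span (last counted beat minus first)
  must not exceed $t_{\max}$ at emission; a ready episode that violates it is
  discarded and its trackers reset. The lower bound is enforced implicitly
  by the quantum wait, which is the only reading consistent with the worked
  traces (the 4-beat blood-pressure episode spans 7 minutes of a 5–10 window
  and is inferred 5 minutes later).
* **One instance per activity at a time.** A counted beat belongs to at most
  one instance of a given activity; overlapping instances of the *same*
  activity are forbidden, while different activities overlap freely. If two
  activities become inferable at the same tick both are emitted, ordered by
  name for determinism.
* **Concurrency is logical.** The deployment description speaks of parent
  and child processes; the package models them as deterministic trackers
  stepped by a single chronological event loop. The coordination contract —
  flag notification, any satisfied artifact may trigger emission — is
  preserved, and results are a pure function of the time-ordered stream.

Two implementations of these semantics exist: the event-driven engine
(`run_inference()`, discrete 1-second virtual clock over the merged
multi-activity stream) and an independent continuous-time reference
(`oracle_inference()`, per-activity analytic emission instants). The test
suite holds them to agreement on a thousand randomized small scenarios;
agreement is exact whenever beat times and quanta lie on the tick grid,
and within one tick otherwise.

## Discretization choices

RFID tag-gain/tag-loss events map directly to presence; repeated
announcements of the current state are reader chatter and collapse to the
first occurrence. Accelerometers report absolute g-force, and the bare
threshold rule — above threshold: state 0; back inside the band: state 1 —
inflates beat counts because the sensor is touchy; the discretizer therefore
adds a rest band and a `min_dwell` debounce (a return to rest is accepted,
stamped at the re-entry time, only after the signal stays in the band that
long), with `min_dwell = 0` reproducing the bare rule. Vision scores at or
above the threshold are accepted; each transition keeps its frame time, so
beats map back to frame indexes by `floor((t - t0) * frame_rate)` — the
frame current at that instant (the rounding is a package choice; `floor`
matches "current frame"). Time is a real-valued offset in seconds from a
per-run origin, which keeps tests deterministic; wall-clock anchoring is
metadata.

The composite correlation filter is the re-normalized average of zero-mean,
unit-energy reference images, applied as normalized cross-correlation
(numerator in the frequency domain, local energies via integral images) over
placements where the template fully overlaps the frame. Scores are invariant
to affine intensity rescaling, a single-reference filter scores exactly 1 on
a verbatim copy, and locally constant patches score 0 by convention.
Nonlinear composite filters are known to tolerate object deformation and
noise better; this package deliberately uses the linear average-spectrum
composite, a well-defined, testable operator that preserves the pipeline
role — score, threshold, beat. Occlusion is not handled
in-filter; it is the motivation for fusing a second technology.

## What the simulator emulates — and what it does not

`generate_scenario()` emulates the evaluated deployment at desk scale: ten
12-hour days, 74 episodes mixed as 21 hygiene, 23 feeding, 16 medications
and 14 blood pressure, with medications nested inside feeding episodes (as
at breakfast and dinner). Episode durations are drawn inside each activity's
$\Delta T$; per-artifact beat patterns are evenly spaced with 5% jitter,
constructed so that every episode satisfies its criteria and every
post-satisfaction inter-beat gap stays below the quantum (one episode, one
emission). Episodes of the same activity are separated by more than the
longest window. Raw values are rendered per technology: gain/loss events;
rest-band magnitudes around 1 g with bursts of 1.5–1.8 g while handled
(the stream only shows rest while the artifact sits on the base, a
simplification of real accelerometry); correlation scores of 0.85–0.9
versus 0.1–0.2 around a 0.5 threshold. Sample streams are event-driven
(samples at transitions and interval midpoints), not fixed-rate.

Noise is injected by `corrupt()`: sequential dropout of transition-causing
samples (at probability 1 the stream discretizes to silence), Poisson
spurious events, Gaussian time jitter. All randomness descends from a single
seed: the scenario from `cfg$seed`, corruption from its own seed, so
noise studies can reuse one scenario.

What passing simulator tests do **not** show: real deployments have
occlusion-correlated dropout (not independent), beat patterns far more
ragged than jittered even spacing, shared artifacts across activities, and
vision scores that drift with lighting. The zero-noise 100% effectiveness
result is a consistency check of generator + discretizers + engine, not a
prediction of field accuracy; the in-situ figure the package's evaluation
mirrors arithmetically (74 correct of 81 recorded ≈ 91.35%) came from ten
days of real video.

Scoring follows the recorded-events convention: effectiveness is the
percentage of *inferred* events that match a truth episode (greedy
one-to-one matching by temporal overlap, intersection over the shorter
interval, ≥ 0.5 by default — the matching rule is a package invention, since
no standard correctness-matching procedure exists). The truth-denominated rate
is reported alongside, so either convention is inspectable.

## Numerical and degenerate-input behavior

Binary signals enforce strictly increasing times and strict alternation;
empty streams yield empty signals, zero beats, and no inferences. Equal-time
beats across artifacts are ordered lexicographically by artifact id;
equal-time emission of two activities is ordered by name. The engine's
deadline scan advances the virtual clock only to grid points where a tracker
can change state, which is semantically identical to ticking every second
but keeps ten-day runs subsecond. Correlation denominators below
`1e-10 × max` are treated as zero-variance and score 0; peak scores are
clamped to $[-1, 1]$ against floating-point overshoot.

## Problem sizes used by the tests

The packaged checks run at desk scale: canonical single-episode traces; a
thousand randomized small streams (≤ 48 beats) for engine/oracle agreement;
one 74-episode, ten-day zero-noise scenario (~400 beats); vision fixtures of
roughly 100×100 pixels with 12×15-pixel templates. These sizes exercise
every code path while keeping the whole suite comfortably under two minutes
on one CPU.

## Known limitations

Criteria are hand-characterized, not learned; there is no probabilistic
smoothing, so a single missed beat below an artifact's minimum suppresses
inference until the episode is re-presented. Person events from the door
antenna provide identity context only and never feed activity criteria. The
store is an in-memory table set with JSONL persistence — adequate for runs
of this scale, not a concurrent database. Vision recognition assumes one
filter per artifact and no occlusion handling. Beats shared between
concurrent instances of the same activity are unsupported by design.
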