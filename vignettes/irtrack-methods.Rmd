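---
title: "Models and methods behind irtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind irtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irtrack)
```

This vignette documents the models, conventions and numerical choices the
package is built on, in the spirit of a methods section: what each
component assumes, which parameters matter, and what the tests do and do
not demonstrate.

## Position detection

An infrared touch frame is modelled as two orthogonal banks of beams with
a common pitch; beam $i$ on the $x$ axis is the line $x = i \cdot p$. A
convex occupant (a square cube footprint or a disk body approximation)
blocks every beam line intersecting its closed footprint, and the decoder
reports the center of the smallest axis-aligned rectangle covering all
blocked beams, at 60 Hz. Both halves are exact set computations, so the
only positional error is quantization: at most $p/2$ per axis for any
convex occupant fully inside the frame, independent of where in the frame
the occupant sits. The default pitch is 2 mm, which reproduces the ~1 mm
accuracy class of commercial frames; it is configurable, and the accuracy
bound is asserted in the test suite by sweeping occupant centers over a
fine off-lattice grid.

The frame's active area defaults to 900 × 520 mm (a 42-inch 16:9 frame).
Commercial data sheets rarely state the active dimensions; any size can be
passed to `beam_grid()`.

Two conventions worth noting:

* **Multi-blob snapshots.** Disjoint blocked runs (which a single animal
  does not produce) are covered by one overall enclosing rectangle; the
  toolkit is single-animal by design.
* **Dropouts.** `stream_decode()` linearly interpolates invalid runs of at
  most 500 ms when bracketed by valid samples and flags them in an
  `interpolated` column; longer runs stay invalid. The 500 ms cap is a
  package decision — hardware dropouts of that order are bridgeable
  without inventing behavior, while longer blind stretches should stay
  visible to the analyst.

## Arena geometry

`make_layout()` builds the published apparatus dimensions: a Ø500 mm
circular open area with a concentric Ø250 mm trigger zone and a
400 × 100 mm refuge alley for the looming family (foot-shock and
optogenetics reuse this geometry, only the floor or stimulus differs), a
plus maze with 235 × 50 mm arms around a 50 × 50 mm center, and a
two-chamber box of two 250 × 300 mm chambers with 100 × 100 mm food and
no-food corner regions. The refuge alley is placed along $-x$, to the left
of the open circle, which makes the full looming layout tile the default
900 × 520 mm frame exactly (400 + 500 mm); the doorway midpoint is
recorded as `refuge_entry`.

Membership tests are closed (boundaries count as inside). "Entering" a
region is evaluated on the decoded body-center point — the only definition
available from a single decoded coordinate; a track that starts inside a
region counts an entry at its first sample so entries and occupancy stay
consistent. No hysteresis is applied at region boundaries: with ≤ 1 mm
decode error, chatter at mouse speeds is negligible, and a configurable
dwell-time debounce (default 0, i.e. off) is available where a noisier
tracker needs it. In the plus maze, the central square belongs to neither
arm, matching the apparatus description.

## The closed-loop trigger engine

`evaluate_triggers()` is a pure function of (track, layout, config) that
replays the real-time loop in sample order with no look-ahead, so
closed-loop behavior is deterministic and bit-reproducible. A trigger is
emitted at the first sample where all gates hold:

| gate | looming default | foot-shock | opto |
|---|---|---|---|
| habituation | 300 s | 300 s | 300 s |
| zone | Ø250 mm central disk | same | same |
| speed | < 150 mm/s | same | same |
| refractory | 180 s | (controller lockout) | 180 s |
| cap | 1 / session | uncapped | 5 |
| session end | trigger + 120 s, cap 900 s | cap 900 s | 300 s + 30 min |

The speed gate uses a 3-sample (50 ms at 60 Hz) trailing mean of
instantaneous speed: raw one-sample speed under 2 mm quantization can
alias above threshold for an animal moving well below it. The window is
configurable (`speed_window`); the analysis-side speed series
(`instantaneous_speed()`) is deliberately unsmoothed and documented
separately, so control-side and analysis-side definitions never mix.

**Foot-shock episodes.** The shock starts at the trigger, stops as soon as
the animal enters the refuge, restarts if it exits within 6 s of the
initial trigger, stops unconditionally 6 s after the trigger, and the
trigger is then inactive for 3 min. Two readings of the rule text are
possible for the re-arm window ("within 6 s after the initial trigger")
and both anchors are separate config fields (`rearm_window_ms`,
`max_on_ms`), so the alternative reading is one config change. The 3-min
lockout is anchored at the close of the 6-s shock window, so consecutive
accepted triggers are at least 3 min 6 s apart; it lives in
`shock_controller()` (which consumes candidate triggers) rather than in
the generic engine, because it depends on when the shock episode ends.

**Optogenetics.** "No more than 5 times in 30 min" is implemented as a
session cap of 5 with the 30-min active window starting at habituation
end; a sliding-window reading would only matter for sessions longer than
the protocol allows. Pulse trains are scheduled as
$\lfloor \text{epoch} \cdot \text{rate} \rfloor$ pulse events; a pulse
longer than the period is rejected at construction.

**Looming timeline.** The disk expands linearly from 2° to 40° of visual
angle in 300 ms, holds 50 ms, and repeats 15 times with 30-ms gaps between
repeats (14 gaps), giving a 5 670 ms stimulus; the on-screen diameter for
a monitor height $h$ is $2h\tan(\theta/2)$. Some published figure captions
round this schedule to "5.5 s"; the parameter arithmetic and that caption
disagree by 170 ms, and the timeline follows the parameters. Whether the
looming trigger re-arms within a session is not specified by the protocol;
the default is one trigger per session, configurable via `max_triggers`
and `refractory_ms`.

## Behavioral statistics

Speeds are backward differences over valid samples at the native rate
(16.7 ms at 60 Hz). Occupancy attributes each inter-sample interval to its
left sample's region (sample-and-hold). The flight summary measures
latency (trigger to first refuge entry), hiding time (entry to first
exit; truncated at session end and flagged when the session ends while
hiding), path length (sum of segment lengths from the trigger sample to
the entry sample), and the distance ratio — path length over the
straight-line distance from the trigger position to the refuge-entry
position.

The denominator endpoint deserves a note: "the center of the refuge-entry
point" admits two readings. The default uses the actual position at the
entry sample, which makes distance ratio ≥ 1 a theorem (triangle
inequality) — asserted on 10⁴ random paths in the tests; the doorway
midpoint is available via `denominator = "doorway_midpoint"`. Event-aligned
averages resample trials onto a common grid at the series' native rate and
drop (and report) trials without full window coverage.

## Fiber photometry

The ΔF/F chain is, in order: (1) low-pass filter the dark-box segment
(≥ 60 s recorded before the session) and fit a single exponential decay
$A e^{-t/\tau} + C$; extrapolate it over the recording as the instrument
background $B(t)$ — the minimal reading of "deduce the background of the
recording" from a pre-session fit; (2) subtract: $F_{ca} = F_{ex} - B$;
(3) low-pass filter $F_{ca}$ and fit a second exponential — the bleaching
baseline $F_0(t)$; (4) $\Delta F/F = (F_{ca} - F_0)/F_0$. Filtering is
used *only* for the two baseline fits; the ΔF/F output is computed from
the unsmoothed signal. The 410-nm reference channel is ingested, filtered
and exported but does not enter the formula — the stated computation uses
only the signal channel, and isosbestic motion correction is out of scope.

Numerical choices:

* The low-pass filter is a second-order Butterworth run forward and
  backward (zero phase, unit DC gain), with odd-reflection padding of
  $9 f_s / f_c$ samples to suppress start-up transients; the cutoff
  default is 2 Hz — unspecified in the protocol, chosen as comfortably
  below transient kinetics while passing the slow bleaching trend — and
  configurable everywhere.
* The exponential fit is Levenberg–Marquardt on the residuals with fixed,
  declared starts ($C$ at the 5th percentile, $A$ as first sample minus
  $C$, $\tau$ a third of the segment duration; $\tau$ bounded positive),
  so fits are reproducible. Constant series are rejected ($A$
  unidentifiable); non-convergence is an error carrying the initializer
  and the residual trail.
* A non-positive fitted baseline anywhere is an error naming the first
  offending time, rather than silently producing unbounded ΔF/F.

The generative model for testing (`synth_photometry()`) adds
difference-of-exponential transients — chosen because their peak value is
analytic, so "peak ΔF/F within x% of amplitude/F₀" is a closed-form
check — on an exponential bleaching baseline plus an exponential dark
background and Gaussian noise. Recovery is verified over 50 seeds with
bleaching constants of 100–600 s: fitted τ within 5% (on the 60-s
dark-segment scale where τ is identifiable) and event-aligned peak ΔF/F
within 10% of the generative ratio.

## Grid calibration

Coordinates are corrected through a checkerboard corner lattice
(reference corners at the true 40-mm pitch; observed corners as measured):
the containing observed cell is found, inverted analytically through the
bilinear map (a quadratic in one parameter; the root with both coordinates
in the unit square wins, ties broken toward the smaller $u$ — declared for
determinism), and forward-mapped into the reference cell. The map is exact
at the corner nodes and continuous across shared cell edges; both
properties, plus forward∘inverse identity to 10⁻⁹ on 10⁴ random convex
quads, are asserted in the tests. The corner count is layout-dependent
(a 12 × 22 lattice gives 264 corners); any congruent lattice pair is
accepted.

The camera side of the accuracy comparison is a synthetic pinhole model:
an overhead camera projects the 8 corners of a 40-mm cube onto the floor
plane and estimates position as the silhouette's bounding-box center. This
suffices to reproduce the visual-angle deviation — the estimate is biased
outward in proportion to distance from the optical axis — as a
monotonicity assertion on binned errors, contrasted with the flat
beam-decode error. Lens distortion models are out of scope.

## The synthetic mouse agent

Exploration is a mean-reverting (Ornstein–Uhlenbeck) velocity process,
discretized exactly ($v \leftarrow a v + \sigma\sqrt{1-a^2}\,\mathcal N$,
$a = e^{-\Delta t/\tau_v}$), reflected at the open-area boundary inset by
half the body size. The per-axis scale is set so the stationary mean speed
(Rayleigh) equals `explore_speed_mms`; defaults — 80 mm/s mean exploration
speed, 500 ms velocity relaxation, 40 mm body, 600 mm/s commanded flight
speed, 100 ms reaction latency, 20 s refuge dwell — are chosen as
representative of adult mouse open-field locomotion and looming-evoked
escape, and are parameters of the generator, not empirical claims. Flight
is a straight dash to the refuge doorway (optional lateral waypoint noise
turns it into a wall-following escape); after the dwell the agent walks
back to the arena center and resumes exploring.

The closed-loop simulator applies the *same* gates as the batch engine
online, and a test asserts that `evaluate_triggers()` over the recorded
track reproduces the online trigger decisions bit-for-bit. Ground truth
(trigger times, flight onsets, commanded speed) is recorded so parameter
recovery — measured latency ≈ distance/speed, distance ratio ≈ 1, max
speed ≈ commanded speed within one-sample discretization — is testable
across seeds.

What the generator does *not* emulate: body-shape and posture changes
(rearing, freezing), tail/paw structure in the shadow, learning or
habituation across trials, multi-animal interactions, and real photometry
artifacts (motion, hemodynamics). Passing tests therefore demonstrate the
correctness of the decoding, triggering, and analysis chain under the
stated generative assumptions — not the biological realism of the agent.

## Problem sizes and defaults used in the checks

The automated checks run scripted sessions of 16–40 simulated minutes at
60 Hz (60 k–150 k samples), the full 20-position × 4-displacement ×
5-repeat cube protocol (400 trials), 10⁴ random quads and paths for the
geometric identities, and 50-seed photometry batches of 120-s traces at
200 Hz. These sizes keep every property estimate comfortably stable while
running in a few tens of seconds on one CPU.

## Known limitations

* The decoder assumes raw beam masks; frames that report pre-computed
  touch points would bypass `occlude()` but reuse everything downstream.
* Planar geometry only — apparatus heights are ignored.
* The engine models batch evaluation of an idealized 60 Hz stream; serial
  latency, jitter and dropped frames of a physical rig are not modelled
  beyond the dropout-interpolation policy.
* Water-based paradigms are unsupported (water interferes with infrared
  localization), and multi-animal paradigms are out of scope by design.
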