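---
title: "Methods: quantifying bucket bridging in shimmering waves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying bucket bridging in shimmering waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shimmerwave)
```

## The measurement model

Shimmering waves are cascades of individual abdomen flips.  The package
works from two inputs: grayscale frame stacks at a fixed frame rate
(default 60 fps, i.e. a 16.67 ms frame interval) and per-frame thorax
positions of individually identified surface bees ("agent bees").  All
coordinates use the image convention — x rightward, y downward, origin
top-left — in both pixels and millimetres (default scale 0.30 mm/px, the
scale at which a 6 mm abdomen covers ~20 px); frame indices are 0-based
and intervals half-open.

**Motion metric.** The strength of an agent's movement between two
consecutive frames is the sum of absolute per-pixel luminance differences
over a 60 × 60 px region of interest centred on the thorax (18 × 18 mm;
large enough to cover most of the bee including stretched wings, small
enough not to swallow the neighbours).  The sum is normalized by 10^4:
a quiescent bee jitters at ~3 grey levels per pixel, hence the quiescent
reference level `rel_xymov = 1.08`; massive flips reach roughly tenfold
that.  The subtraction is absolute-valued — motion energy has no sign —
and ROIs clipped by the frame border are excluded rather than padded,
which simply drops agents near the image rim.  The ROI is centred on the
position at the *later* frame of each pair, because onsets are defined on
that frame.  An optional per-pixel noise floor (default 0) can be
subtracted before summation for noisy sensors.

**Incident detection.** An abdomen flip shows up as a sharp rise of the
motion trace.  A *wave incident* requires the supra-baseline excess to
exceed the participation threshold for at least five successive frames;
shorter excursions are treated as noise.  The onset `t0` is defined one
frame before the first supra-threshold frame `t1`.  The threshold default
is +1.0 normalized units (10^4 raw-sum units) above baseline, consistent
with a threshold grid for ensemble analyses that starts at 1.0; the
per-agent baseline is the median of the trace over a declared quiescent
window, falling back to the global quiescent level 1.08.  Supra-threshold
runs closer together than the refractory window (800 ms = 48 frames)
are merged into one incident.  Peaks are graded into eight wave-strength
levels `c_ws` by half-open boundaries; the level boundaries are nowhere
published, so the defaults are multiples {1.5, 2, 3, 4.5, 6.5, 9, 12, 16}
of the quiescent level, chosen once so that default simulations put the
mode at mid levels (`c_ws` 2–4), and fully configurable.

**Neighbourhoods and triggers.** Around each *focus bee* the near
(r < 40 mm) and far (r < 100 mm) neighbourhoods are discs in the nest
plane (z is ignored; the radii are stated on the curtain surface), with a
strict `<` bound.  Directions are binned into eight 45° sectors labelled
by where the activity comes *from*: sector 1 "from Right" centred at 0°,
sector 3 "from Bottom" at 90° (y points down), sector 5 "from Left",
sector 7 "from Top"; a boundary angle belongs to the next sector
(half-open bins).  The trigger of a focus incident is the spatially
closest near-neighbour incident of the same wave that started 1–5 frames
earlier; ties break by earlier onset, then lower agent id, making the
assignment permutation-invariant.  (Five frames at 60 fps are 83.3 ms;
we implement the frame rule.)  Incidents with no such candidate are
*untriggered-active* — members of an alternative spreading mechanism such
as saltatoric daughter waves — and are excluded from the directional
statistics.  Incidents are grouped into waves beforehand by temporal
clustering: a gap in onsets longer than the refractory window starts a
new wave.

**Wave direction.** The field workflow labelled the four key directions
(1 from Right to Left, 2 from Bottom to Top, 3 from Left to Right, 4 from
Top to Bottom) visually, which is not reproducible; the package fits the
least-squares plane `t0 ~ a + b·x + c·y` to a wave's onsets and takes the
source direction `atan2(-c, -b)` snapped to the nearest key direction.
A manual override is honoured for users who keep the visual workflow.
Waves with fewer than 10 incidents, all-equal onsets or a vanishing
gradient are flagged undefined.

## The three statistics

**Linearity.** Focus incidents (strength levels 1–6 pooled) are counted
per (wave direction, trigger sector) and normalized within each wave
direction by the maximum count (`rel_n_fb`, so the best-populated sector
is 1).  Directedness is summarized two ways: *estimate A* integrates the
normalized excess above the "fuzziness level", the minimum of a
polynomial fitted to `rel_n_fb` over the trigger angle (degree 4 by
default; the angle axis is rotated so the wave's source angle sits
mid-domain, because a plain polynomial is not periodic — the estimates
are insensitive to the degree since only the fitted minimum enters);
*estimate B* integrates the excess above the stratum median.  Both are
percentages of the stratum's summed normalized rates, and
`estimate_B <= estimate_A` whenever the fitted minimum does not exceed
the median.

The *coincidence* test asks whether the histogram is anchored at the
wave's origin once the directional window is widened to ±45° (the key
sector plus both flanking sectors, matching the tolerance of the manual
direction labelling).  A literal rule "all sectors strictly above the
stratum median lie inside the window" cannot work for continuous data:
exactly four of eight untied values exceed their own median while the
window holds three sectors, so the rule would be almost surely false.
The implemented test therefore checks the majority/minority substance of
the criterion: at least one sector strictly above the median (a flat
histogram never passes), the best-populated sector inside the window,
and more trigger mass inside the window than in the opposite window.

**Continuity.** For each focus incident the far neighbours that were
active in the same wave before the focus onset (within a 250 ms = 15
frame pre-onset window, matching the passive build-up seen before
onsets) are binned by the deviation of their sector from the trigger
sector (Δα, 45° bins from −135° to 180°).  Counts are averaged per
strength level and normalized to a maximum of 1.  The *excess rate* is
the relative surplus of the Δα = 0 bin over the mean of its two
flanking bins — the share of active neighbours specifically in the
trigger direction.  (The published adjacent-to-peak ratios are
internally ambiguous — 0.60/0.80 vs the printed percentages do not
reconcile exactly — so this package documents its reading rather than
asserting the original construction.)

**Graduality.** The focus bee's peak strength is regressed on the mean
peak strength of her previously active far neighbours in the trigger
sector (*ds*, direct-sector) or the sector 180° opposite (*os*); the
same pre-onset window is applied to both modes.  Peak `rel_xymov` values
enter the regression, not the ordinal `c_ws` levels, and the neighbour
statistic is the mean of qualifying peaks (the aggregation is not
specified in the source workflow; the mean is the natural choice).  The
Pearson correlation `r`, the slope `k`, and the share `100·r²` of agents
governed by gradual transfer are reported per strength level, together
with a paired t-test of the matched `r_ds` and `r_os` series (identical
series yield the well-defined limit t = 0, P = 1).  A third mode (`tn`)
regresses on the single assigned trigger neighbour in the near
neighbourhood; it is the cleanest estimator of the simulator's coupling
coefficient.

**Time courses.** Focus traces are synchronized at their own `t0` and
averaged per strength level on a −200…+600 ms grid; trigger-neighbour
curves are aligned to the *focus bee's* `t0` and restricted to trigger
incidents of the same strength level as their focus bee.  The transfer
time is the mean over 14 threshold levels (`rel_xymov` 1.0–2.3 in steps
of 0.1) of the difference in rising-phase crossing times (linear
interpolation; the last upward crossing before each curve's peak, which
is robust to baseline noise).  Thresholds either curve fails to cross
are excluded and counted, and estimates from fewer than three usable
thresholds are flagged unreliable.  The "weighted interpolation and
cross-correlation" of the original workflow is not fully specified, so
threshold-crossing interpolation is primary and a cross-correlation lag
of the mean curves is reported alongside as a cross-check.  Propagation
speed is distance over transfer time (mm/ms = m/s) with the standard
error propagated by the delta method.

## The synthetic-data generator

The simulator exists so that every downstream stage can be validated by
parameter recovery; it emulates the study conditions, not any particular
recording.

*Lattice.* Agents sit on a hexagonal lattice with 29 mm spacing and 2 mm
Gaussian jitter, clipped to the requested extent.  The published near
(5–7 agents within 40 mm) and far (20–30 within 100 mm) occupancies are
mutually inconsistent for any uniform density; the near count drives
trigger assignment, so the lattice matches it (6 neighbours unjittered,
4–7 with jitter) and the resulting far count is ~36–43, documented here.

*Dynamics.* A cohort of generator agents — every agent within one lattice
spacing of the edge the wave comes from; no quantitative generator-bee
criterion exists, so generator placement is a free simulator choice —
fires in bursts.  An inactive, non-refractory agent joins once a near
neighbour fired `latency_frames` earlier (default 3 frames = 50 ms per
hop).  With probability `p_directed` the join is bucket bridging proper:
the recorded trigger is the nearest such neighbour.  Otherwise the agent
responds to an undirected (e.g. visual) cue: its recorded trigger sector
is drawn uniformly over 1–8 (the trigger agent being the nearest far
neighbour in that sector), and its onset is delayed by a uniform random
0–12 frames.  The random delay is what makes `p_directed` measurable
downstream: it blurs the wave front, so trigger assignment — which sees
only the spatio-temporal pattern — degrades smoothly from fully directed
to unordered as `p_directed` falls.  After its onset an agent is
refractory for 800 ms (48 frames); generator bursts at the refractory
interval emulate saturation driving, under which the minimum inter-onset
interval recovers the refractory phase and the repetition rate its
reciprocal.

*Pulses.* Each incident emits a motion pulse of 200 ms (12 frames): a
sharp rise peaking within ~40 ms — onsets in the field peak within two
to three frames, and an amplitude-independent rise is what makes the
five-frame detection rule time onsets consistently — followed by a
raised-cosine decay and an optional damped oscillation tail (25% of the
peak, mimicking the curtain's mechanical resonance).  The sampled pulse
maximum equals the nominal amplitude exactly, so simulated peak
strengths are recovered without bias.  Peak excess couples to the
trigger as `k_couple·amp_trig + (1−k_couple)·amp_base + noise`; per-agent
base excesses are lognormal (meanlog log 3, sdlog 0.45), placing the
strength mode at mid levels with small weak and strong tails, which
mirrors the field's strength distribution.  A fraction (default 0.3) of
the mean near-neighbour pulse activity is superimposed on every trace as
passive deflection of the curtain; this produces the slow sub-threshold
build-up that precedes onsets in the field.  Baseline traces sit at 1.08
with Gaussian noise (default sd 0.05).

*Rendering.* For end-to-end tests of the motion metric, agents are drawn
as bright body + abdomen ellipses (abdomen ~20 px wide) whose abdomen
displaces proportionally to the instantaneous supra-baseline strength,
over optional per-pixel background noise; with zero noise, equal
strengths render bit-identical pixels.  The renderer is deliberately
schematic: it reproduces localized, displacement-monotone difference
energy, not photometrically calibrated `rel_xymov` values, so
quantitative analyses run on simulated traces while the rendered path is
validated for locality and monotonicity.

*What passing tests do and do not show.* The simulator has no nest
architecture, no mouth-zone polarity, no 3D curtain layers, no saltatoric
daughter waves beyond the random-jump option, and its undirected joins
are a stylized stand-in for all non-mechanical triggering.  Parameter
recovery on this synthetic world validates the measurement chain — that
the pipeline recovers known trigger graphs, latencies, refractory phases
and coupling coefficients — not the biological claims themselves; the
field percentages cannot be reproduced without the original video.

## Numerical choices and degenerate inputs

* Frame bookkeeping is 0-based throughout; a trace sample at frame *i*
  derives from frames *(i−1, i)*.
* Sector bins are half-open; the boundary angle belongs to the next
  sector (22.5° is in sector 2, 337.5° wraps into sector 1).
* Distance ties in trigger assignment break by earlier onset, then lower
  agent id; seeded runs are bit-reproducible, and every simulator
  draw is governed by a single integer seed.
* All-baseline traces yield an empty incident list (valid); waves that
  never leave the generator cohort are flagged empty; zero-variance
  regressions report missing correlations; degenerate direction fits are
  flagged rather than guessed.
* Analyses in the test suite and the acceptance script run on a
  600 × 600 mm lattice (~500 agents) with a handful of waves per
  condition — large enough for stable sector statistics, small enough
  that the full suite runs in about a minute.

## Known limitations

The participation threshold's published value ("10") is dimensionally
ambiguous against the 10^4-normalized metric; the package reads it as
+1.0 normalized units and keeps it configurable.  The strength-level
boundaries and the polynomial degree of the linearity fit are likewise
package defaults, not published constants — results that depend on them
should be reported together with the configuration hash that every
output table carries.  Stereoscopic identification and tracking of real
bees is out of scope: track tables are taken as input.
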