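---
title: "A fuzzy model of in-wake flight in bird line formations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A fuzzy model of in-wake flight in bird line formations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flockwake)
```

## The problem

Birds flying in line or V formations can save energy by riding the upwash
shed outboard of a leader's wingtips, while the region directly behind the
leader's body holds downwash and should be avoided. Classifying a
follower's state from trajectory data therefore hinges on *where* it sits
relative to a leader, not merely *how close* it is. Because vortex strength
fades gradually in every direction, the in-wake region has no crisp
boundary — which makes fuzzy logic the natural formalism. This package
scores every ordered dyad of a flock with a knowledge-based zero-order
Takagi–Sugeno fuzzy inference system (FIS), assigns each bird at most one
wake provider per snapshot, and derives flock-level statistics from the
resulting assignment stream.

## From absolute tracks to leader-relative coordinates

Input data are per-bird time series of 3D positions (metres, shared local
tangent frame) at a fixed sampling rate (5 Hz by default, the typical rate
of high-precision GNSS loggers). For a leader at snapshot *t* the flight
heading is estimated from three consecutive fixes: the horizontal
displacement into *t* gives an angle α, the displacement out of *t* an
angle β, and the heading γ is their circular mean. We compute γ as the
arctangent of the summed unit vectors rather than the arithmetic mean of
the angles; the two coincide away from ±π but the arithmetic mean produces
a spurious reversal when α and β straddle the wrap (e.g. +175° and −175°
must average to 180°, not 0°). The three-fix window filters GNSS jitter;
it is fixed at three by default and the window is not widened adaptively —
noisier data should instead raise the observation-noise term when judging
results.

The follower's horizontal coordinates are translated so the leader sits at
the origin and rotated so γ points along +y, giving the lateral (e|w) and
anteroposterior (n|s, positive = ahead) components. The vertical component
is handled by subtraction only (u|d = leader z − follower z); heading
estimation and rotation never touch the vertical channel, since flight
direction is an essentially horizontal quantity at these time scales. The
sign convention for u|d is documented prominently but observationally
irrelevant to the model: the co-planarity memberships are symmetric in u|d.
The transform is an isometry, so the 3D dyad distance is preserved exactly
(tested to 1e−9 m).

Boundary snapshots (each bird's first and last fix) have no smoothed
heading and are dropped; missing fixes are *not* interpolated — a gap
simply yields no rows, and timestamps are snapped to the nominal grid with
a 1 ms tolerance so float jitter in input files does not silently
misalign birds.

## The rule base

Three linguistic variables describe a follower's position in the leader's
frame; all membership functions are piecewise linear (no smooth
Gaussian or sigmoidal sets are used) and hold their
boundary value outside the modelled universe:

* `bird_ew`: `wingtip_aligned` is 0 on [−0.8, 0.8] m (downwash corridor),
  rises to 1 at ±1.3 m and falls to 0 at ±1.8 m. With a 1.5 m wingspan the
  1.3 m optimum corresponds to a 20 cm wingtip overlap, and ±1.8 m to
  complete misalignment. `wingtip_misaligned` is the exact pointwise
  complement (both share the same knots, so the complement is also
  piecewise linear).
* `bird_ns`: `close` rises from 0 at 0 to 1 at −0.1 m, then decays to 0 at
  −5 m. `too_close` is a narrow spike between −0.1 and 0 m modelling
  collision risk at the leader's wing. `distant` ramps from 0 at −0.1 m to
  1 at −5 m and stays 1 beyond. Every `bird_ns` membership is zero for
  n|s ≥ 0: there is no wake ahead of or level with the leader.
* `bird_plane`: `same_plane` is 1 at u|d = 0 and 0 at ±0.75 m (half a
  wingspan); `different_plane` is its complement.

Five rules with crisp consequents (`in_wake` = 1, `not_in_wake` = 0):

1. aligned ∧ close ∧ same plane → in_wake
2. misaligned → not_in_wake
3. too close → not_in_wake
4. distant → not_in_wake
5. different plane → not_in_wake

Zero-order Takagi–Sugeno inference defuzzifies as the strength-weighted
mean of the consequents. The response surface on the co-planar plane
peaks at (e|w, n|s) = (±1.3, −0.1) m, is mirror-symmetric in e|w and u|d,
and decays monotonically behind the optimum — all verified by grid search
in the test suite and recomputed by `scripts/acceptance.R`.

### Choices the literature-derived set shapes leave open

* **Anteroposterior spike (`too_close`).** Only its support — a sharp rise
  and fall between 0 and −0.1 m — is determined. We use a triangle with
  apex at −0.05 m, zero at both ends. By construction it cannot perturb
  rule 1 at the −0.1 m optimum; its apex is configurable.
* **`distant` shape.** Not numerically specified; we use the complement of
  `close` on the decaying limb (0 at −0.1 m, 1 at −5 m, plateau beyond).
  This makes rules 1 and 4 compete smoothly and reproduces the gradual
  decay of the response surface.
* **Point peak vs plateau.** Whether `wingtip_aligned` has a point peak at
  ±1.3 m or a short flat top is not determined by the literature-derived set shapes;
  we adopt a point peak, with an optional plateau half-width in
  `wake_config()`.
* **t-norm.** The conjunction operator is the min t-norm (the default of
  the common FIS tooling); a product t-norm is available for sensitivity
  analysis. The five rules use only AND, but OR/NOT helpers (max, 1 − m)
  are provided for completeness.
* **Zero-fire output.** Inputs can fire no rule at all (e.g. a perfectly
  aligned, co-planar bird *ahead* of its candidate leader). The
  defuzzified ratio is then 0/0; we define the output as 0 ("not in
  wake"), consistent with treating a zero output as not-in-wake
  downstream, and set a `zero_fire` flag so callers can distinguish "no
  rule fired" from "a not_in_wake rule fired".

## Assignment, threshold and tie-breaks

A follower may exploit only a single upwash at a time, so per snapshot the
candidate leader with the highest output wins. The follower is in-wake
when that output strictly exceeds τ. The default τ = 0 classifies any
positive upwash credit as in-wake, matching the convention that a zero
output marks not-in-wake flight; a stricter cut (e.g. 0.5) is available to
suppress the high-frequency leader switching that dense flocks produce.
Argmax ties break by smaller 3D distance, then lexicographic bird id —
deterministic, and exercised only on degenerate symmetric geometry.

Candidate leaders are *all* other birds: the FIS itself zeroes implausible
candidates, so no hard distance prefilter is applied (unlike the FNN). A
follower that is not in-wake is recorded with the nearest bird in front of
it (any bird at n|s > 0 in the follower's own frame, nearest by 3D
distance, with that bird's coordinates in the follower's frame), or as
alone with zero coordinates when nobody is ahead. Front-bird candidacy
deliberately uses only n|s > 0 — no range or co-planarity filter — because
it records "someone to potentially follow", not an aerodynamic judgement.

## The FNN baseline

The frontal nearest neighbour assigns the closest bird that is leading
(n|s > 0 in the focal bird's frame), co-planar (−0.75 < u|d < 0.75,
strict) and within 6 m horizontal range (inclusive: the range condition is
a ≤, the co-planarity window a pair of strict inequalities). "Closest"
ranks by horizontal distance by default — consistent
with the horizontal range condition — with a 3D option. The reported
coordinates are the focal bird's position relative to its chosen leader,
the same orientation the FIS reports, so the two models' positional
distributions are directly comparable.

## Flock-level analytics

* **Bouts** are maximal runs of constant state on the sampling grid;
  in-wake bouts additionally split at leader changes by default (the
  200–400 ms switches of dense flocks are real events worth resolving); a
  state-only mode gives coarser bouts. Grid gaps terminate runs. Durations
  are run length × Δt, and per bird they partition the analysed flight
  exactly.
* **Alone time** is the complement of in-wake time, split into "no bird in
  front" and "front bird present but not exploited".
* **Leader preference**: observed per-leader proportions of in-wake
  snapshots, against a bootstrap no-preference null. The resampling unit
  is the *bout*, not the snapshot — at 5 Hz consecutive snapshots are
  strongly autocorrelated and snapshot-level resampling would shrink the
  null intervals unrealistically. Each replicate redraws every bout's
  leader uniformly among the other N − 1 birds, keeping bout lengths;
  intervals are the empirical 2.5/97.5 percentiles with linear
  interpolation. The generative counterpart of this null
  (`simulate_null_assignments()`) yields 95% intervals that cover the
  observed proportion for ~96% of (bird, leader) cells in the calibration
  test (100 focal streams × 7 leaders, 400 bouts each, 1000 replicates) —
  the slight overcoverage reflects the residual discreteness of
  bout-weighted proportions.
* **Formation graphs**: per snapshot, a directed arc joins each in-wake
  follower to its provider; out-degree is ≤ 1 by the single-upwash
  constraint. Weakly connected components delimit subgroups; their size
  distribution excludes singletons by default (a "subgroup" starts at a
  dyad), with an inclusion flag. The wake relation is expected to be
  acyclic, but because each dyad is judged in its own leader's frame,
  mutual-front geometries can produce 2-cycles; these are detected and
  reported with a warning, never silently forbidden.
* **Model agreement** counts snapshots on which both models name the same
  leader. The default denominator is snapshots where *both* name one;
  "either" and "all" denominators are available since the notion of a
  comparable case is a reporting choice, not a modelling one. Per-axis
  histograms of the follower's position relative to the chosen leader are
  emitted overall and restricted to disagreement snapshots.

## The synthetic flock

The simulator exists so every stage is testable with planted ground truth.
A lead bird flies a heading random walk (sd 0.01 rad/sample) at 10 m/s —
values chosen as ecologically plausible for a medium-sized soaring-flapping
bird, not estimated from data — and each planted follower pursues a slot at
the configured offset in its current leader's instantaneous frame
(first-order pursuit; gain 1 places it exactly on the slot). Default
offsets are the modelled optimum (e|w ±1.3 m, n|s −0.5 m, u|d 0) with
0.05 m white Gaussian observation noise per axis; an AR(1) mode mimics the
temporal smoothness of GNSS error. Followers can re-draw their leader at a
per-sample probability, and a configurable fraction of birds flies solo,
far outside any wake region.

What the simulator does *not* emulate: flapping kinematics and
phase-synchronisation, aerodynamic forces and vortex transport, wind, or
behavioural decision rules. Passing recovery tests therefore demonstrates
that the geometry pipeline and the FIS recover planted spatial structure
through realistic observation noise — not that real birds follow the
planted policy.

Within the trajectory simulator, leader re-draws are restricted to
already-constructed birds so chained pursuit stays causally computable;
the exactly uniform no-preference null used for bootstrap calibration is
generated directly at the assignment level by
`simulate_null_assignments()`.

## Numerical choices and degenerate inputs

* Membership evaluation is linear interpolation with constant plateaus
  outside the anchor range; anchors must be strictly increasing.
* Heading is undefined (error, or row dropped in bulk processing) for
  stationary birds and for exactly opposing displacement vectors (summed
  unit vector below 1e−12).
* Timestamps: numeric seconds or ISO-8601; snapped to the nominal grid
  (tolerance 1 ms), duplicates rejected with the offending row named.
* The rule base serializes to JSON with full double precision and
  round-trips bit-exactly.
* Problem sizes in the test suite (60 s flights at 5 Hz, flocks of 5–10,
  1000 bootstrap replicates, 150-bird random-geometry batches) are chosen
  to give stable statistics while keeping the default suite fast on a
  single CPU.

## Known limitations

* The model is purely geometric: it cannot distinguish a bird *using* the
  upwash from one merely positioned in it, and it ignores flapping-phase
  effects entirely.
* Anchor values encode one species' wingspan (1.5 m); applying the model
  to other species requires rescaling `wake_config()`.
* With τ = 0, high-frequency leader switching is expected in dense flocks;
  consumers needing stable bouts should raise τ or filter bouts by minimum
  duration downstream.
* Empirical summary statistics of any real flight depend on the actual
  dataset; this package reproduces the computation pathway and validates
  it on synthetic data, but ships no empirical data.
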