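---
title: "Quantifying wind-oriented navigation in circular arenas: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying wind-oriented navigation in circular arenas: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(windnav)
```

## The measurement problem

A four-quadrant circular olfactometer delivers air through four peripheral
arms and removes it through a central suction hole. The airflow field is
therefore radial: at every point in the arena the wind blows inward and the
*upwind* direction is the outward radial bearing. Walking flies that value
an odor (or whose relevant neurons are optogenetically activated) steer and
surge upwind, which in this geometry means moving from the center toward
the periphery. `windnav` quantifies that behavior from per-frame tracked
trajectories: positions `(x, y)` in arena-centered mm and body headings in
degrees, at a fixed frame rate (30 Hz by default).

Everything downstream rests on a small set of conventions, fixed once:

* Angles live on the half-open interval (−180, 180], counterclockwise
  positive, with 0° along an arbitrary +x axis. Because the +x choice is
  arbitrary, every metric must be (and is property-tested to be) invariant
  under a global rotation of the arena frame.
* Frames are 0-based; the time of frame *k* is `k / frame_rate`; epochs are
  half-open `[onset, onset + duration)`. These choices remove off-by-one
  ambiguity between frame-valued windows (e.g. "the first 10 frames") and
  second-valued thresholds (e.g. "within 15 s").
* Odor stimuli become analytically effective 3.5 s after the solenoid valve
  switch — the sum of the valve-to-arena delivery delay (~2 s) and the time
  to fill the arena with odorized air (~3 s). LED stimuli are treated as
  instantaneous: light has no delivery lag, so no latency is applied.

## The radial position index

The area of an annulus grows with r², so a fly walking at random spends
far more time at large radii: in a 50-mm arena the 40–50 mm ring is nine
times larger than the 0–10 mm disk (`annulus_area_ratio(40, 50, 0, 10)`).
Raw mean radius is therefore a biased readout of "upwindness". The package
uses the **area-normalized distance-from-center index** `(r/R)²`, which is
uniform on [0, 1] under uniform occupancy, with mean 1/2; equivalently the
RMS of `r/R` under the uniform null is 1/√2 ≈ 0.7071. Both identities are
verified analytically and by Monte Carlo in the test suite.

**Upwind displacement** subtracts, per movie, the fly-population mean index
at the effective stimulus onset from its value at each time point, so each
movie contributes a baseline-zero time course; the endpoint at
`onset + 10 s` is the usual scalar summary. The movie is the default unit
of replication (population means are computed per movie, then across
movies); a per-fly mode exists for trajectory-level dot plots. SEM bands
follow the chosen unit of replication, which is an explicit flag rather
than a hidden convention.

## Upwind-angle kinematics

The signed angle to upwind is `alpha = wrap(upwind_bearing − heading)`,
with `upwind_bearing = atan2(y, x)` for inward flow (plus 180° when the
flow is reversed; undefined when wind is off). `alpha = 0` is facing
upwind, ±180° facing the center. At `r = 0` the bearing is undefined: the
frame is flagged `NA` rather than raising an error, since a fly standing on
the suction hole is a legitimate (if rare) pose.

Differentiation uses plain forward first differences with no smoothing —
callers who want smoothing apply their own. `dtheta`, angular velocity and
forward speed therefore carry `NA` at each fly's *last* frame (one
consistent forward convention for all derivatives; the window
`[t0, t0 + n)` then sums exactly the `n` forward differences starting at
`t0`). Forward walking speed is the displacement projected on the unit
heading vector, so it can be negative (backing) and scores sideways drift
as zero; the unprojected translational speed is emitted alongside, because
which of the two the original video pipelines used is not knowable from
published descriptions.

## Quality filters

Two exclusion rules and one analysis gate:

* **Tracking errors.** A one-frame displacement > 5 mm or wrapped heading
  change > 180° marks a tracking artifact. Wrapped one-frame changes cannot
  exceed 180° in magnitude, so with the default threshold the operative
  angular trigger is a change of (numerically) exactly 180° — the
  sign-ambiguous head/tail flip that body-axis trackers produce — and it is
  detected with a 10⁻⁹-degree tolerance so floating-point wrapping cannot
  hide it. Exclusion granularity is a genuine design choice the published
  descriptions leave open ("trajectories were excluded"): discarding the
  fly's whole movie wastes data, discarding only the bad frame biases
  window statistics. The package excludes the fly's data within the
  *analysis window* containing the artifact (windows delimited by the
  stimulus schedule's effective onsets by default, configurable via
  `breaks_s`). A frame-by-frame brute-force oracle is tested to agree
  exactly with the vectorized implementation on a thousand artifact-laden
  synthetic tracks.
* **Edge gate.** Single-trajectory analyses require a wall distance of at
  least 3 mm, *inclusive* (`radius − r ≥ 3`). Published wordings disagree
  on inclusivity ("more than 3 mm" vs "3 mm or more"); the inclusive figure
  wording is adopted and the threshold is an ordinary argument, so the
  exclusive variant is a one-character change.
* **Orientation gate.** Turning-direction statistics are only meaningful
  for flies that start broadside: the gate passes initial angles with
  90° ≤ |α₀| ≤ 150° (both sides). Flies facing straight up- or downwind
  carry no information about the *choice* of turn direction.

## Onset turning and the binned response curve

Cumulative turning over the 10-frame (333 ms) onset window is the sum of
wrapped per-frame heading changes, i.e. net rotation including direction
reversals, not the difference of endpoint headings. The "toward upwind"
version folds the signed sum by `sign(α₀)`: positive means net rotation
toward the upwind bearing whichever side the fly started on, making left-
and right-starting flies poolable. A fly at exactly α₀ = 0 scores 0 by
convention (there is no "toward" side). Folding by `sign(α₀)` was chosen
over differencing |α| endpoints because the quantity of interest is summed
frame-wise rotation, and the endpoint difference conflates body rotation
with translation past the wind source.

The population curve averages a per-fly onset metric over flies whose α₀
falls within ±30° of each grid angle (default grid every 5°), a sliding
circular window. Empty bins yield `NA` entries, never an error. The window
smooths a sinusoidal response by `sin(w)/w` with `w = π/6` (≈ 0.955), which
is why injected sinusoids are recovered at ~95% amplitude — the tests
account for exactly this factor.

## Return probability

A fly *revisits* its location at reference time `time0` if, within the
following 15 s, it first moves more than 10 mm from that location and then
comes back to within 3 mm of it — excursion strictly before return, both
inside the window. This is the only reading consistent with "moved away
… and came back … within 15 s"; the excursion trivially starts within 3 mm
because it starts at the reference point itself. For 60-s movies `time0`
ranges over 0–45 s (movie length minus window). The grid steps at the frame
rate by default; screen summaries use a coarser 0.5-s grid purely for
speed, which changes nothing statistically since neighboring reference
frames are almost perfectly correlated. The implementation is tested for
exact agreement with a per-frame brute-force oracle, and for monotonicity:
longer windows and smaller excursion thresholds can only increase the
probability.

## Preference index and reciprocal averaging

Quadrants are the four 90° sectors delimited by the arena diagonals,
indexed counterclockwise from the sector centered on +x. The published
material never fixes sector boundaries; any fixed convention works because
the preference index only ever contrasts *diagonal pairs*. Per frame,
`PI = (N_odor1 − N_other) / N_total` over valid flies; the result is the
mean over the final 30 s of the 60-s test, per movie, then across movies.
PI is antisymmetric under swapping the quadrant pair (tested).

Reciprocal experiments swap the odors between quadrant pairs. Both PIs are
measured toward the same physical pair; with CS+ in that pair in run A and
in the opposite pair in run B, `(PI_A − PI_B)/2` expresses preference
toward CS+ while cancelling any shared position bias and innate odor
preference. The cancellation is verified end-to-end: a generator with a
pure spatial bias field (no stimulus response) yields a strongly positive
single-run PI but a reciprocal mean of 0 within Monte-Carlo error.

## The activation-screen matrix

For screening driver lines, each line's recordings are reduced to five
parameters — upwind displacement, mean cos α, angular velocity, forward
speed, return probability — in 2-s bins tiling
`[onset − 4 s, onset + duration + 10 s)`: 2 bins before, 5 during a 10-s
stimulation, 5 after (all three counts configurable; published figures do
not pin the exact span). Values are standardized per (parameter, bin)
**across driver lines** — the only population that makes a screen heat map
comparable across its rows — using the sample SD (n − 1; appropriate for a
dozen-line screen). Both choices are recorded in the object's metadata.
Zero-spread cells get z = 0 with a flag rather than NaN. Standardization is
exactly invertible from the stored per-cell mean/SD, and z is invariant
under uniform affine rescaling of any one cell — both tested. Hit ranking
orders lines by mean z over chosen bins with stable ties; it is descriptive
triage, not a significance call (between-genotype hypothesis testing is
deliberately out of scope and left to standard routines).

## The synthetic fly-walk generator

No raw trajectory recordings are publicly deposited for this paradigm, so
the package carries a first-class generator whose defaults are the study
conditions: 20 flies per movie, 60-s movies at 30 fps in a 50-mm arena,
base walking speed 10 ± 3 mm/s (a realistic walking-fly pace), per-frame
heading noise of 8° (a correlated random walk whose heading decorrelates
over ~1–2 s), and a non-directional startle — extra unsigned turning of
scale 15°/frame for the first 10 frames of each stimulus — because even
control genotypes show a ~300-ms angular-speed transient at stimulus
onset. The *default* fly is a control: all directional gains are zero.

Phenotypes are injected through four gains:

* `upwind_turn_gain` (deg/frame per unit sin α, stimulus-gated): the
  minimal smooth orientation-dependent turn bias — zero when facing up- or
  downwind, maximal broadside, always rotating toward upwind. This is a
  modeling choice, not a claim about flies; the recovery tests only need
  *some* known injected form.
* `speed_mod_gain` (mm/s per unit cos α, stimulus-gated): faster when
  heading upwind, slower downwind; a cos α stand-in for the real (unknown,
  non-closed-form) orientation dependence, parameterized so other forms can
  be swapped in.
* `startle_upwind_bias` (fraction of startle rotation directed toward
  upwind; 0 for control-like nulls).
* `return_gain` (deg/frame toward the stimulus-offset location, for 15 s
  after offset). Note a real property of this mechanism: very strong
  attraction traps flies in orbits of radius `speed/turn-rate` *below* the
  10-mm excursion threshold, so the measured return probability is
  non-monotone in the gain, peaking near 4°/frame. Tests therefore probe
  the moderate-gain regime.

Walls default to `turn_away` (heading reflected off the tangent, position
clamped just inside) to avoid trapping; a specular `reflect` mode is kept
for uniform-occupancy null checks. Artifact injection adds the two error
classes the filter targets — 7–10 mm single-frame jumps and exact head/tail
flips — at Poisson-sampled frames with ground truth recorded in provenance,
giving the filter-recall tests an exact reference.

Randomness: one master integer seed; each movie's stream is derived
deterministically from it (`seed + movie_index × 100003`, mod 2³¹), and
flies within a movie are advanced vectorized in a single stream. Identical
(parameters, configuration, schedule, seed) give byte-identical output.
Per-movie rather than per-fly streams were chosen so whole-movie vector
updates stay possible; the cost is that changing `n_flies` re-randomizes
individual flies, which no test or analysis relies on.

What the generator does *not* emulate — and hence what green tests do not
show about real data: odor-plume structure and sharpness of quadrant
boundaries (wind is a geometric direction field only), inter-fly
interactions and collisions, pausing/grooming bout structure, identity
swaps between flies (only jumps and flips are injected), and any
neural-circuit dynamics. Passing tests demonstrate that the *pipeline*
measures what it claims on data with known structure, not that flies behave
like the model.

## Numerical choices and degenerate inputs

* Angle wrapping is `x − 360·ceiling((x − 180)/360)`, mapping exactly onto
  (−180, 180] including the boundary.
* `r = 0` poses and wind-off configurations flag α as `NA`; empty bins in
  curves are `NA`; zero-spread screen cells are z = 0 with a flag; a zero
  peak response makes the learning rate `NA` with a warning. None of these
  raise errors, because all occur in legitimate data.
* Frame indices derive from times as `round(t · frame_rate)`; time is
  continuous seconds internally.
* On-disk tracks are written with fixed 6-decimal formatting so a
  read/write/re-write cycle is byte-stable and every metric survives a
  round trip to ≤ 10⁻⁶.
* Test problem sizes were chosen as the smallest that make the checks
  sharp: 10⁶ Monte-Carlo points for the disk identities (3-SE bands),
  1000 short tracks for oracle equivalence, 400 trajectories (20 movies of
  20 flies) for gain recovery at the 15% band, and 20 seeds of a 12-line
  screen for the top-hit rate.

## Known limitations

* The per-frame table assumes whatever body point the upstream tracker
  emits (centroid vs body-axis midpoint is not distinguishable downstream).
* Exclusion granularity, SEM unit of replication, and the screen bin span
  are configurable because the published descriptions underdetermine them;
  defaults are documented above and in the function help.
* The generator's orientation dependences (sin α turning, cos α speed) are
  stand-ins sufficient for parameter-recovery validation, not fitted
  models of fly behavior.
* No inferential statistics: genotype comparisons (Kruskal–Wallis, Dunn,
  ANOVA) belong to standard tools outside this package.
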