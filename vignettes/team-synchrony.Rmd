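---
title: "Measuring team synchrony from player-ball-goal angles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring team synchrony from player-ball-goal angles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teamsync)
```

## The model

A football team is treated as a population of phase oscillators. Each
player's phase at a frame is not a temporal oscillation but a *spatial*
one: the player-ball-goal angle (PBGA)

$$\theta_k(t) = \mathrm{atan2}\!\big(\lVert (P_k - B) \times (G - B)\rVert,\;
(P_k - B)\cdot(G - B)\big) \in [0, \pi],$$

the angle at the ball between the ball-to-player and ball-to-goal vectors.
The goal $G$ is always the goal-mouth center of the goal being attacked by
the team in possession, for *both* teams: the attacking team orients its
support play toward it and the defending team organizes its cover around the
same axis, so it is the shared visual anchor of the frame. Using a
geometrically defined phase avoids the known pitfalls of extracting
continuous phases from displacement time series with the Hilbert transform,
which requires separating longitudinal from lateral movement and assumes an
oscillation football positions do not deliver; the package deliberately
contains no Hilbert step anywhere.

Per frame and team, cluster phase analysis summarises the phases through the
Kuramoto order parameter

$$r'(t)\,e^{i\psi(t)} = \frac{1}{n}\sum_{k=1}^{n} e^{i\theta_k(t)},$$

computed as a single complex mean whose modulus is the synchronization
$r' \in [0,1]$ and whose argument is the cluster phase $\psi$. Because every
$\theta_k$ lies in $[0,\pi]$, the complex mean lies in the closed upper half
plane and $\psi \in [0, \pi]$; the player-team relative phase
$\Phi_k = \theta_k - \psi$ therefore lies in $[-\pi, \pi]$ without any
wrapping. We read $\psi$ as the argument of the complex mean (the standard
cluster-phase definition) rather than the arithmetic mean of $\theta_k$;
the two differ only when phases are widely spread, and the circular reading
is the one consistent with $r'$ coming from the same complex sum.

Four derived views cover the classical synergy properties:

* **Dimensional compression** — $r'$ itself, summarised by team, half,
  possession role and pitch zone, and modelled with linear mixed-effects
  models.
* **Reciprocal compensation** — the relative phases $\Phi_k$: sustained
  departures of individual players from 0, and whether teammates' phases
  drift oppositely to absorb them, explain when $r'$ holds and when it
  breaks.
* **Interpersonal linkages** — per-player relative-frequency profiles of
  $\theta_k$ over 18 bins of $10^\circ$, split by role. Both raw frame
  counts and proportions are emitted, since polar-profile plots
  conventionally show counts while comparisons across roles need
  proportions.
* **Degeneracy** — team configuration codes: the counts of players in the
  three sectors $[0, \pi/3)$, $[\pi/3, 2\pi/3)$, $[2\pi/3, \pi]$ (front,
  lateral, back support when in possession; cover otherwise), printed
  `fs-ls-bs`, with the convex hull of each subgroup available per frame.

## Assumptions and conventions

**Coordinates.** Pitch-centered origin, longitudinal axis $x$ toward the
$+x$ goal, meters. Default pitch 105 × 68 m (the FIFA standard; overridable
in metadata, which also carries frame rate, goal centers and per-half attack
directions). Teams swap ends at half time; `normalize_attack_direction()`
reflects second-half positions through the pitch center so each team attacks
one direction all match. This is an explicit analysis step, not an I/O
default, because raw storage should preserve the recorded geometry.

**Filtering.** Dead-ball frames are stored but excluded from every analysis
(`filter_frames()`, and internally by the summary, histogram and model-table
builders). Possession is taken as given input per frame — tracking vendors
attribute it upstream and no attempt is made to re-derive it from positions.

**Zones.** The pitch is split 4 longitudinal × 5 lateral = 20 zones, coded
`D/MD/MO/O × L/CL/C/CR/R` in the attacked-goal frame ("O" nearest the goal
being attacked). The default grid uses equal bands (26.25 m × 13.6 m); real
analyses sometimes align edges with the penalty area, so the edges are
overridable. Whether left/right should be read in the attacking team's frame
or the fixed pitch frame is genuinely ambiguous in practice; the
`lateral_frame` switch exposes both, defaulting to the attacking frame,
which keeps "L" meaning the attacking team's left. Zones are indexed by the
*ball* position, the variable that drives both teams' angular organization.

## Numerical choices

* **Degenerate geometry.** If the player or the goal is within $10^{-6}$ m
  of the ball the angle is undefined. `atan2(0, 0)` would return 0 — perfect
  front alignment — and silently bias synchrony upward, so such entries are
  flagged and dropped from the frame's complex mean with $n$ reduced; a
  frame with no defined phase yields `NA`.
* **Interval rules.** All angular bins (18-bin histograms, 3-bin TCC
  sectors) and all zone bands are half-open $[lo, hi)$ with the final
  interval closed. Printed sector bounds in the literature overlap at the
  boundaries; a partition must not, and the measure-zero boundary makes the
  choice statistically inconsequential — but it must be deterministic, and
  the 18-bin histogram must aggregate 6+6+6 exactly onto the 3-bin code
  (a tested invariant).
* **Quantization.** Positions are written at 0.01 m resolution by default,
  matching optical tracking feeds, with decimal-aware rounding (so 12.345
  rounds to 12.35 rather than falling to banker's rounding); writing is a
  fixed point at that resolution and can be disabled.
* **No smoothing.** $r'$ is reported unfiltered; a centered moving average
  is available for plots only (`smooth_synchrony()`), off by default.

## The simulator

`simulate_match()` generates tracking data *in angle space first*: each
team's target PBGA performs a reflected random walk on $[0, \pi]$, each
player's angle is the target plus von Mises noise with concentration
$\kappa$ (role-dependent), folded into $[0, \pi]$ by reflection — which
keeps the stationary distribution symmetric about the target — and the
player is then placed at that angle about the ball, at a radius (5–40 m)
and side of the ball-goal axis redrawn per possession segment. The ball
follows a bounded random waypoint path inset 3 m from the lines, which
incidentally guarantees no degenerate ball-goal geometry. Possession flips
as a Bernoulli process; dead time arrives in Markov spells with a stationary
rate. Simulating the measured quantity directly gives exact ground truth for
every downstream test: $\kappa = 0$ yields uniform phases (so $r'$ must
approach the analytic $2/\pi$ limit), $\kappa \to \infty$ locks the team,
and mean $r'$ must increase monotonically in $\kappa$.

Default parameters are fixed once: 2500 frames per half at 25 Hz (a
desk-scale match segment), $\kappa =$ 1.5 with ball / 2.0 without, placing
match-level mean synchrony near 0.8 in possession and slightly higher out
of possession, as observed in elite play; possession spells of ~20 s
(switch rate 0.002/frame); 35% dead time in ~15 s spells, the typical
out-of-play share of a match.

What the simulator does **not** emulate: physical player dynamics (speeds,
inertia, collisions), tactical formations, offside, or any correlation
between a player's angle and a persistent positional role. Passing tests on
simulated data therefore validates the *measurement pipeline* — geometry,
phase statistics, binning, model recovery — not the sporting realism of any
conclusion drawn from a real match.

`inject_desync_event()` rotates a subset of players away from the team mean
with a smooth rise-and-relax profile ($\sin \pi s$), with alternating sign
per player so the spread widens symmetrically, emulating the loss and
recovery of balance around match events; the ground truth records the exact
window.

## The mixed-effects stage

`build_model_table()` assembles one row per (frame, team) with $r'$, team,
role, half and the ball's zone; `fit_lmm()` fits
`r_prime ~ fixed effects + (1 | half)` by maximum likelihood through
`lme4::lmer()` — this stage is supporting statistics, and an established
estimator is the right tool — and runs a likelihood-ratio $\chi^2$ for each
term against the model with that term removed. Removing a main effect also
removes any interaction containing it, keeping every null nested and
well-formed; users wanting other null structures can fit the two models
directly. Reference levels (away, with-ball, D, L) are chosen so positive
coefficients read as "home higher", "losing the ball raises synchrony".

Caveats stated once and plainly: frames 40 ms apart are strongly
autocorrelated, and the model treats them as independent — standard errors
and $\chi^2$ statistics are anti-conservative on real data; and a random
effect with two levels (halves) is estimable but weakly identified, often
shrinking its variance to zero (the `boundary (singular) fit` message from
lme4, which is expected and harmless here). The constant-response corner
case (zero variance) is reported as zero coefficients and zero LRT without
attempting an ill-posed fit.

## Problem sizes in the test suite

The property tests run at sizes chosen to make Monte-Carlo error small
relative to the asserted tolerances while keeping the suite quick: the
uniform-phase limit uses $10^5$ phases (tolerance 0.01 about $2/\pi$); the
coupling-monotonicity check uses 5000 frames × 11 players per $\kappa \in
\{0, 1, 4, 16, 64\}$, requiring successive means to separate beyond twice
the summed standard errors; parameter recovery uses 20,000 frames with a
known +0.15 role effect (tolerance ±0.01) and 50 replicate null simulations
for type-I calibration of the team test (rejections within the central 99%
binomial band around 5%); the oracle-equivalence check compares 1000 random
frames against a naive complex-sum loop at $10^{-12}$.

## Limitations

* Synchrony is planar; ball height is ignored.
* Possession and ball status are trusted inputs; no event detection is
  attempted beyond the injected-event test harness.
* The LMM stage quantifies association, not causation, and inherits the
  independence caveat above.
* Zone summaries depend on the (configurable) grid; the default equal grid
  is a convention, not a claim that any particular published analysis used
  it.
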