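# teamsync

Measuring team synchronization in football from planar tracking data, via
player-ball-goal angles and cluster phase analysis.

## The problem

Optical tracking systems record the positions of all 22 players and the ball
at 25 Hz. A long-standing question in collective-behaviour kinematics is how
to compress those 23 trajectories into an interpretable *order parameter* for
the team — a single number per frame that says how coherently the team is
moving, and that is anchored to the variables players actually perceive: the
ball and the goals, not abstract displacement axes.

`teamsync` does this with the **player-ball-goal angle (PBGA)**. For player
*k* at frame *t*, with player position *P_k*, ball *B* and the center *G* of
the goal being attacked by the team in possession,

    θ_k(t) = atan2( ‖(P_k − B) × (G − B)‖ , (P_k − B)·(G − B) )  ∈ [0, π]

— the angle at the ball between the ball→player and ball→goal vectors. θ = 0
means the player sits on the ball-goal line on the goal side; θ = π means
directly behind the ball. The team's per-frame synchrony is the Kuramoto
order parameter of these phases,

    r′(t) e^{iψ(t)} = (1/n) Σ_k e^{iθ_k(t)} ,

with cluster amplitude r′ ∈ [0, 1] (1 = perfectly aligned angles) and
cluster phase ψ. Around this core the package measures the four classical
properties of team synergies:

- **dimensional compression** — r′ summaries by team, half, possession role
  and 20-zone pitch grid, with linear mixed-effects models (team/role/zone
  fixed effects, half random effect, ML fit, likelihood-ratio tests);
- **reciprocal compensation** — player-team relative phase
  Φ_k(t) = θ_k(t) − ψ(t);
- **interpersonal linkages** — per-player 18-bin PBGA relative-frequency
  profiles by role;
- **degeneracy** — 3-bin team configuration codes (front/lateral/back
  support or cover, e.g. `6-4-1`) with convex hulls of each subgroup.

A synthetic match simulator with controllable angular coupling (von Mises
concentration per team and role) generates tracking data with known ground
truth, so the whole pipeline is testable without proprietary match feeds.

## Worked example

```r
library(teamsync)

sim  <- simulate_match(simulation_config(n_frames_per_half = 1000,
                                         possession_switch_rate = 0.01,
                                         seed = 42))
ds   <- sim$dataset
pbga <- dplyr::bind_rows(compute_pbga(ds, "home"), compute_pbga(ds, "away"))
sync <- kuramoto(pbga)
summarize_synchrony(sync, ds, group_by = c("team", "role"))
#> # A tibble: 4 × 5
#>   team  role         mean_r_prime sd_r_prime n_frames
#> 1 away  with_ball           0.780     0.0885     1218
#> 2 away  without_ball        0.816     0.0781      782
#> 3 home  with_ball           0.764     0.0876      782
#> 4 home  without_ball        0.798     0.0793     1218
```

Typical match play sits near r′ ≈ 0.8 — teams are highly synchronized — and
both teams here are slightly *more* synchronized without the ball, when play
collapses onto the ball-goal axis. The mixed model quantifies that:

```r
tab <- build_model_table(sync, ds)
fit_lmm(tab, fixed = c("team", "role"))
#> Fixed effects:
#>              term estimate       se
#>       (Intercept)  0.78016 0.005214
#>          teamhome -0.01734 0.002700
#>  rolewithout_ball  0.03530 0.002700
#>
#> Likelihood-ratio tests (term vs model without it):
#>  term  chisq df         p
#>  team  41.05  1 1.480e-10
#>  role 167.35  1 2.803e-38
```

Losing the ball raises this simulated match's synchrony by 0.035 ± 0.003
(LRT χ² = 167.4, p < 0.001). Team configuration codes read the same frames
as front/lateral/back subgroup counts:

```r
tcc <- team_configuration_code(compute_pbga(ds, "away"), ds, "away")
head(tcc, 3)
#>    half frame team  role_label  fs_c  ls_c  bs_c n_defined tcc
#> 1     1     1 away  support        1     4     6        11 1-4-6
#> 2     1     2 away  support        0     4     7        11 0-4-7
#> 3     1     3 away  support        0     3     8        11 0-3-8
```

`subgroup_hulls()` returns the convex hull of each subgroup for a frame, and
`relative_phase()` gives each player's deviation Φ_k from the cluster phase.

A command-line front end is installed at
`system.file("cli/teamsync", package = "teamsync")` with subcommands
`validate`, `simulate`, `sync`, `profile`, `tcc` and `lmm`.

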