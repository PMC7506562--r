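#' Simulation configuration
#'
#' Parameters of the synthetic match generator. Players are simulated directly
#' in PBGA space — each player's angle about the ball is the team's
#' slowly-drifting target angle plus von Mises noise, folded into `[0, pi]` —
#' and then mapped to planar positions, giving exact control over the angular
#' structure the synchrony pipeline measures.
#'
#' @param n_frames_per_half Frames per half (default 2500; at 25 Hz a desk-scale
#'   100 s segment per half).
#' @param frame_rate Hz.
#' @param coupling_kappa Von Mises concentration of player angles about the
#'   team target, per team and role. A single number applies everywhere; a
#'   named vector `c(with_ball = , without_ball = )` applies to both teams; or
#'   a list `list(home = c(...), away = c(...))`. Defaults to
#'   `c(with_ball = 1.5, without_ball = 2)`, which puts match-level mean
#'   synchrony near 0.8 in possession and slightly higher out of possession:
#'   teams hold tighter angular order when defending, as play collapses onto
#'   the ball-goal axis.
#' @param mean_angle_sd Per-frame SD (radians) of the team target-angle random
#'   walk, reflected at 0 and `pi`.
#' @param possession_switch_rate Per-frame probability that possession flips
#'   (default 0.002: mean possession spells of 20 s at 25 Hz).
#' @param dead_ball_rate Stationary probability that a frame is dead (default
#'   0.35, the typical out-of-play share of match time); dead time arrives in
#'   spells with mean length `dead_spell_s`.
#' @param dead_spell_s Mean dead-ball spell length in seconds (default 15).
#' @param ball_speed Ball speed in m/s along its random waypoint path.
#' @param radius_range Range (m) of each player's distance from the ball,
#'   redrawn per player per possession segment.
#' @param event_schedule Optional data frame with columns `half`, `frame`,
#'   `event` copied into the ground truth.
#' @param seed Integer RNG seed for reproducibility, or `NULL`.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_frames_per_half = 2500L,
                              frame_rate = 25,
                              coupling_kappa = c(with_ball = 1.5, without_ball = 2),
                              mean_angle_sd = 0.02,
                              possession_switch_rate = 0.002,
                              dead_ball_rate = 0.35,
                              dead_spell_s = 15,
                              ball_speed = 7,
                              radius_range = c(5, 40),
                              event_schedule = NULL,
                              seed = NULL) {
  kappa <- normalize_kappa(coupling_kappa)
  stopifnot(n_frames_per_half >= 1, frame_rate > 0,
            possession_switch_rate >= 0, possession_switch_rate <= 1,
            dead_ball_rate >= 0, dead_ball_rate < 1,
            all(unlist(kappa) >= 0), mean_angle_sd >= 0,
            radius_range[1] > 0, radius_range[2] >= radius_range[1])
  structure(
    list(n_frames_per_half = as.integer(n_frames_per_half),
         frame_rate = frame_rate, coupling_kappa = kappa,
         mean_angle_sd = mean_angle_sd,
         possession_switch_rate = possession_switch_rate,
         dead_ball_rate = dead_ball_rate, dead_spell_s = dead_spell_s,
         ball_speed = ball_speed, radius_range = radius_range,
         event_schedule = event_schedule, seed = seed),
    class = "simulation_config"
  )
}

normalize_kappa <- function(k) {
  roles <- c("with_ball", "without_ball")
  expand <- function(v) {
    if (length(v) == 1L && is.null(names(v))) v <- stats::setNames(rep(v, 2), roles)
    if (!all(roles %in% names(v))) stop("coupling_kappa needs with_ball and without_ball entries")
    v[roles]
  }
  if (is.list(k)) {
    if (!all(c("home", "away") %in% names(k))) {
      stop("coupling_kappa list needs 'home' and 'away' entries")
    }
    lapply(k[c("home", "away")], expand)
  } else {
    v <- expand(k)
    list(home = v, away = v)
  }
}

#' Von Mises random angles
#'
#' Samples from the von Mises distribution with mean 0 and concentration
#' `kappa` by the Best-Fisher rejection method; `kappa = 0` gives the uniform
#' circular distribution and very large `kappa` (> 1000) uses the Gaussian
#' limit `N(0, 1/kappa)`.
#'
#' @param n Number of draws.
#' @param kappa Concentration (>= 0).
#' @return Angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, kappa) {
  if (n == 0L) return(numeric(0))
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (kappa > 1000) return(stats::rnorm(n, 0, 1 / sqrt(kappa)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  remaining <- n
  filled <- 0L
  while (remaining > 0L) {
    m <- max(remaining, 64L)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    acc <- which(ok)
    take <- utils::head(acc, remaining)
    if (length(take)) {
      out[filled + seq_along(take)] <- sign(u3[take] - 0.5) * acos(pmin(pmax(f[take], -1), 1))
      filled <- filled + length(take)
      remaining <- remaining - length(take)
    }
  }
  out
}

# Reflect an unconstrained angle into [0, pi] (reflection at both boundaries,
# period 2*pi). Folding a cumulative random walk this way is equivalent to
# reflecting its increments step by step.
fold_angle <- function(t) {
  t <- t %% (2 * pi)
  ifelse(t > pi, 2 * pi - t, t)
}

#' Simulate a synthetic match
#'
#' Generates a tracked match in the long-format tracking schema together with
#' its ground truth. The ball follows a bounded random waypoint path inside
#' the pitch; possession flips as a Bernoulli process; dead-ball time arrives
#' in spells with the configured stationary rate. Each team's target PBGA
#' performs a reflected random walk on `[0, pi]`, each player's angle is the
#' target plus folded von Mises noise with the role-dependent concentration,
#' and the player is placed at that angle about the ball (side of the
#' ball-goal axis and radial distance fixed per player per possession
#' segment). The emitted dataset always passes [validate_tracking()], and the
#' same seed reproduces it bit-exactly.
#'
#' @param cfg A [simulation_config()].
#' @param metadata A [match_metadata()] describing the pitch.
#' @return A list with elements `dataset` (a [match_dataset()]) and `truth`
#'   (a tibble: `half`, `frame`, `possession`, `ball_status`, `mu_home`,
#'   `mu_away`, `kappa_home`, `kappa_away`, `event`).
#' @examples
#' sim <- simulate_match(simulation_config(n_frames_per_half = 50, seed = 7))
#' sim$dataset
#' @export
simulate_match <- function(cfg = simulation_config(), metadata = match_metadata()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_half <- cfg$n_frames_per_half
  n_total <- 2L * n_half
  half <- rep(c(1L, 2L), each = n_half)
  frame <- rep(seq_len(n_half), 2L)

  # possession and dead-ball processes
  switches <- stats::rbinom(n_total, 1L, cfg$possession_switch_rate)
  switches[1] <- 0L
  seg <- cumsum(switches)
  possession <- c("home", "away")[1L + (seg + stats::rbinom(1, 1, 0.5)) %% 2L]
  ball_status <- simulate_dead_spells(n_total, cfg$dead_ball_rate,
                                      cfg$dead_spell_s * cfg$frame_rate)

  # ball random waypoint path, inset from the lines so the ball never reaches
  # a goal-mouth center (keeps every PBGA well defined)
  bx_max <- metadata$pitch_length / 2 - 3
  by_max <- metadata$pitch_width / 2 - 3
  step <- cfg$ball_speed / cfg$frame_rate
  bx <- numeric(n_total); by <- numeric(n_total)
  wx <- stats::runif(1, -bx_max, bx_max); wy <- stats::runif(1, -by_max, by_max)
  x <- stats::runif(1, -bx_max, bx_max); y <- stats::runif(1, -by_max, by_max)
  for (i in seq_len(n_total)) {
    dx <- wx - x; dy <- wy - y
    dist <- sqrt(dx^2 + dy^2)
    if (dist < step) {
      x <- wx; y <- wy
      wx <- stats::runif(1, -bx_max, bx_max); wy <- stats::runif(1, -by_max, by_max)
    } else {
      x <- x + step * dx / dist; y <- y + step * dy / dist
    }
    bx[i] <- x; by[i] <- y
  }

  # team target angles: reflected random walks on [0, pi]
  mu <- lapply(c(home = "home", away = "away"), function(tm) {
    fold_angle(cumsum(c(stats::runif(1, 0, pi),
                        stats::rnorm(n_total - 1L, 0, cfg$mean_angle_sd))))
  })

  g <- attacked_goal(metadata, possession, half)
  ux <- g$x - bx; uy <- g$y - by
  un <- sqrt(ux^2 + uy^2)
  ux <- ux / un; uy <- uy / un

  kappa_of <- function(tm) {
    ifelse(possession == tm,
           cfg$coupling_kappa[[tm]][["with_ball"]],
           cfg$coupling_kappa[[tm]][["without_ball"]])
  }
  player_rows <- lapply(c("home", "away"), function(tm) {
    kap <- kappa_of(tm)
    theta <- matrix(0, n_total, 11L)
    for (kv in unique(kap)) {
      sel <- which(kap == kv)
      theta[sel, ] <- fold_angle(mu[[tm]][sel] +
                                   rvonmises(length(sel) * 11L, kv))
    }
    # side of the ball-goal axis and radius, per player per possession segment
    n_seg <- max(seg) + 1L
    sides <- matrix(sample(c(-1, 1), n_seg * 11L, replace = TRUE), n_seg, 11L)
    radii <- matrix(stats::runif(n_seg * 11L, cfg$radius_range[1],
                                 cfg$radius_range[2]), n_seg, 11L)
    rows <- lapply(seq_len(11L), function(k) {
      a <- sides[seg + 1L, k] * theta[, k]
      r <- radii[seg + 1L, k]
      tibble::tibble(
        half = half, frame = frame, object_type = "player", team = tm,
        player_id = k,
        x_m = bx + r * (cos(a) * ux - sin(a) * uy),
        y_m = by + r * (sin(a) * ux + cos(a) * uy),
        ball_status = ball_status, possession = possession
      )
    })
    dplyr::bind_rows(rows)
  })

  ball_rows <- tibble::tibble(
    half = half, frame = frame, object_type = "ball", team = "none",
    player_id = NA_integer_, x_m = bx, y_m = by,
    ball_status = ball_status, possession = possession
  )
  frames <- dplyr::arrange(dplyr::bind_rows(c(list(ball_rows), player_rows)),
                           .data$half, .data$frame, .data$object_type,
                           .data$team, .data$player_id)

  truth <- tibble::tibble(
    half = half, frame = frame, possession = possession,
    ball_status = ball_status,
    mu_home = mu$home, mu_away = mu$away,
    kappa_home = kappa_of("home"), kappa_away = kappa_of("away"),
    event = NA_character_
  )
  if (!is.null(cfg$event_schedule)) {
    for (i in seq_len(nrow(cfg$event_schedule))) {
      ev <- cfg$event_schedule[i, ]
      sel <- truth$half == ev$half & truth$frame == ev$frame
      truth$event[sel] <- ev$event
    }
  }
  list(dataset = match_dataset(frames, metadata, validate = FALSE),
       truth = truth)
}

# Two-state Markov chain for alive/dead with given stationary dead probability
# and mean dead-spell length (frames), started from the stationary law.
simulate_dead_spells <- function(n, p_dead, mean_len) {
  if (p_dead == 0) return(rep("alive", n))
  p_exit <- min(1, 1 / mean_len)
  p_enter <- min(1, p_exit * p_dead / (1 - p_dead))
  state <- logical(n)  # TRUE = dead
  state[1] <- stats::runif(1) < p_dead
  u <- stats::runif(n)
  for (i in 2:n) {
    state[i] <- if (state[i - 1L]) u[i] >= p_exit else u[i] < p_enter
  }
  ifelse(state, "dead", "alive")
}

#' Inject a transient desynchronization event
#'
#' Perturbs a subset of one team's players away from the team's angular mean
#' for a window of frames, then relaxes them back, emulating the loss and
#' recovery of team balance around match events (possession losses, crosses,
#' goals). Players are rotated about the ball by
#' `magnitude * sin(pi * s)` (with `s` running 0 to 1 across the window), with
#' alternating sign per perturbed player so the team's phase spread widens
#' symmetrically. The ground truth is annotated with the exact window.
#'
#' @param sim A [simulate_match()] result (list with `dataset` and `truth`).
#' @param half Half of the window.
#' @param frame_start First frame of the window (within-half index).
#' @param duration Window length in frames.
#' @param magnitude Peak angular perturbation in radians (0 leaves the
#'   dataset unchanged).
#' @param team Team to perturb.
#' @param n_players Number of players perturbed (ids `1..n_players`).
#' @return A list with the perturbed `dataset` and the annotated `truth`
#'   (columns `event_window`, `event`).
#' @export
inject_desync_event <- function(sim, half, frame_start, duration,
                                magnitude = 1.5, team = c("away", "home"),
                                n_players = 5L) {
  team <- match.arg(team)
  ds <- sim$dataset; truth <- sim$truth
  frames_in_half <- truth$frame[truth$half == half]
  if (!length(frames_in_half) ||
      frame_start < min(frames_in_half) ||
      frame_start + duration - 1L > max(frames_in_half)) {
    stop(errorCondition("event window out of range for the requested half",
                        class = c("teamsync_bounds_error", "error")))
  }
  window <- frame_start:(frame_start + duration - 1L)
  fr <- ds$frames
  ball <- fr[fr$object_type == "ball" & fr$half == half & fr$frame %in% window, ]
  ball_lookup <- stats::setNames(seq_len(nrow(ball)), ball$frame)
  sel <- which(fr$object_type == "player" & fr$team == team &
                 fr$half == half & fr$frame %in% window &
                 fr$player_id <= n_players)
  s <- (match(fr$frame[sel], window) - 0.5) / duration
  delta <- magnitude * sin(pi * s) * ifelse(fr$player_id[sel] %% 2L == 0L, -1, 1)
  bi <- ball_lookup[as.character(fr$frame[sel])]
  dx <- fr$x_m[sel] - ball$x_m[bi]
  dy <- fr$y_m[sel] - ball$y_m[bi]
  fr$x_m[sel] <- ball$x_m[bi] + cos(delta) * dx - sin(delta) * dy
  fr$y_m[sel] <- ball$y_m[bi] + sin(delta) * dx + cos(delta) * dy
  if (isTRUE(attr(ds, "normalized"))) attr(fr, "normalized") <- TRUE
  in_window <- truth$half == half & truth$frame %in% window
  truth$event_window <- in_window
  truth$event[in_window] <- "desync"
  list(dataset = match_dataset(fr, ds$metadata, validate = FALSE),
       truth = truth)
}
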