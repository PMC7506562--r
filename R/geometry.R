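#' Player-ball-goal angles (PBGA)
#'
#' Computes, for every player of one team and every frame, the angle at the
#' ball between the ball-to-player vector and the ball-to-goal vector:
#'
#' \deqn{\theta_k(t) = \mathrm{atan2}\big(\lVert (P_k - B) \times (G - B)
#'   \rVert,\ (P_k - B) \cdot (G - B)\big) \in [0, \pi]}
#'
#' where \eqn{P_k} is the player position, \eqn{B} the ball and \eqn{G} the
#' goal-mouth center of the goal being attacked by the team in possession —
#' the same goal for both teams, taken as the strongest shared visual anchor
#' of play. \eqn{\theta_k = 0} means the player sits on the ball-goal line on
#' the goal side; \eqn{\pi} means directly behind the ball.
#'
#' Frames where the player (or the goal) coincides with the ball within
#' `tol` meters have no defined angle; these entries are flagged
#' (`defined = FALSE`, `theta = NA`) rather than silently set to zero, so they
#' can be excluded from downstream synchrony sums.
#'
#' @param ds A [match_dataset()].
#' @param team `"home"` or `"away"`: the team whose players are measured.
#' @param tol Degeneracy tolerance in meters (default `1e-6`).
#' @return A tibble with columns `half`, `frame`, `team`, `player_id`,
#'   `theta` (radians in `[0, pi]`, `NA` when undefined) and `defined`.
#' @examples
#' ds <- simulate_match(simulation_config(n_frames_per_half = 10, seed = 1))$dataset
#' pbga <- compute_pbga(ds, "home")
#' range(pbga$theta, na.rm = TRUE)
#' @export
compute_pbga <- function(ds, team = c("home", "away"), tol = 1e-6) {
  team <- match.arg(team)
  fr <- ds$frames
  players <- dplyr::filter(fr, .data$object_type == "player", .data$team == !!team)
  ball <- dplyr::filter(fr, .data$object_type == "ball")
  ball <- tibble::tibble(half = ball$half, frame = ball$frame,
                         bx = ball$x_m, by = ball$y_m,
                         possession = ball$possession)
  d <- dplyr::inner_join(
    tibble::tibble(half = players$half, frame = players$frame,
                   player_id = players$player_id,
                   px = players$x_m, py = players$y_m),
    ball,
    by = c("half", "frame")
  )
  g <- attacked_goal(ds$metadata, d$possession, d$half,
                     normalized = isTRUE(attr(ds, "normalized")))
  theta <- pbga_angle(d$px, d$py, d$bx, d$by, g$x, g$y, tol = tol)
  tibble::tibble(
    half = d$half, frame = d$frame, team = team, player_id = d$player_id,
    theta = theta, defined = !is.na(theta)
  )
}

# Vectorized planar angle at B between (P - B) and (G - B).
pbga_angle <- function(px, py, bx, by, gx, gy, tol = 1e-6) {
  vx <- px - bx; vy <- py - by
  wx <- gx - bx; wy <- gy - by
  degenerate <- (vx * vx + vy * vy) < tol^2 | (wx * wx + wy * wy) < tol^2
  cross <- abs(vx * wy - vy * wx)
  dot <- vx * wx + vy * wy
  theta <- atan2(cross, dot)
  theta[degenerate] <- NA_real_
  theta
}

# Goal-mouth center of the goal attacked by the possessing team. Under the
# centered convention both goals sit at opposite longitudinal ends, so the
# attacked goal is the one whose longitudinal sign matches the possessing
# team's attack direction. After normalize_attack_direction() every team keeps
# its first-half direction for the whole match.
attacked_goal <- function(meta, possession, half, normalized = FALSE) {
  dir_of <- function(tm, h) {
    d <- meta$attack_direction[[tm]]
    if (normalized) d[["1"]] else d[[as.character(h)]]
  }
  dirs <- numeric(length(possession))
  for (tm in c("home", "away")) {
    for (h in c(1L, 2L)) {
      sel <- possession == tm & half == h
      if (any(sel)) dirs[sel] <- dir_of(tm, h)
    }
  }
  goals <- rbind(meta$home_goal_center, meta$away_goal_center)
  pos_goal <- goals[goals[, 1] > 0, ]
  neg_goal <- goals[goals[, 1] < 0, ]
  tibble::tibble(
    x = ifelse(dirs > 0, pos_goal[1], neg_goal[1]),
    y = ifelse(dirs > 0, pos_goal[2], neg_goal[2])
  )
}

#' Normalize attack direction across halves
#'
#' Teams swap ends at half time. This operation reflects all second-half
#' positions through the pitch center (both axes negated) so that each team
#' attacks one fixed direction for the whole match; spatial summaries (zone
#' effects, heatmaps) then aggregate cleanly over halves. Applying it twice
#' restores the original dataset.
#'
#' @param ds A [match_dataset()] with attack directions set in its metadata.
#' @return A [match_dataset()] flagged as normalized.
#' @export
normalize_attack_direction <- function(ds) {
  if (is.null(ds$metadata$attack_direction)) {
    stop(errorCondition("attack_direction metadata is required",
                        class = c("teamsync_config_error", "error")))
  }
  fr <- ds$frames
  flip <- fr$half == 2L
  fr$x_m[flip] <- -fr$x_m[flip]
  fr$y_m[flip] <- -fr$y_m[flip]
  attr(fr, "normalized") <- !isTRUE(attr(ds, "normalized"))
  match_dataset(fr, ds$metadata, validate = FALSE)
}

#' Pitch zone grid
#'
#' Partitions the pitch into 4 longitudinal bands (D, MD, MO, O: defensive to
#' offensive, in the attacked-goal frame) times 5 lateral bands (L, CL, C, CR,
#' R), 20 zones in total. The default grid splits each axis into equal bands —
#' longitudinal quarters of 26.25 m and lateral fifths of 13.6 m on a
#' 105 x 68 m pitch — and can be overridden with explicit edge vectors.
#'
#' @param pitch_length,pitch_width Pitch extents in meters (centered origin).
#' @param longitudinal_edges 5 ascending coordinates spanning
#'   `[-pitch_length/2, pitch_length/2]`.
#' @param lateral_edges 6 ascending coordinates spanning
#'   `[-pitch_width/2, pitch_width/2]`.
#' @return An object of class `zone_grid`.
#' @export
zone_grid <- function(pitch_length = 105, pitch_width = 68,
                      longitudinal_edges = NULL, lateral_edges = NULL) {
  if (is.null(longitudinal_edges)) {
    longitudinal_edges <- seq(-pitch_length / 2, pitch_length / 2, length.out = 5)
  }
  if (is.null(lateral_edges)) {
    lateral_edges <- seq(-pitch_width / 2, pitch_width / 2, length.out = 6)
  }
  if (length(longitudinal_edges) != 5L || is.unsorted(longitudinal_edges, strictly = TRUE)) {
    stop("longitudinal_edges must be 5 strictly ascending coordinates")
  }
  if (length(lateral_edges) != 6L || is.unsorted(lateral_edges, strictly = TRUE)) {
    stop("lateral_edges must be 6 strictly ascending coordinates")
  }
  structure(
    list(
      longitudinal_edges = as.numeric(longitudinal_edges),
      lateral_edges = as.numeric(lateral_edges),
      longitudinal_labels = c("D", "MD", "MO", "O"),
      lateral_labels = c("L", "CL", "C", "CR", "R")
    ),
    class = "zone_grid"
  )
}

#' @export
print.zone_grid <- function(x, ...) {
  cat("<zone_grid> 4 longitudinal x 5 lateral = 20 zones\n")
  cat("  longitudinal edges:", paste(signif(x$longitudinal_edges, 4), collapse = ", "), "\n")
  cat("  lateral edges:", paste(signif(x$lateral_edges, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Assign planar points to pitch zones
#'
#' Maps each point to exactly one of the 20 zone codes (`"LONG-LAT"`, e.g.
#' `"MO-CL"`). Intervals are half-open `[lo, hi)` with the final band closed,
#' so every in-bounds point receives one and only one code. Points outside the
#' pitch are clamped to the nearest cell and flagged.
#'
#' Coordinates are interpreted in the attacked-goal frame: the positive
#' longitudinal axis points toward the goal being attacked, so `"O"` is the
#' band nearest that goal. Use [orient_to_attack()] to move points into this
#' frame before assignment.
#'
#' @param x,y Point coordinates in meters (vectors of equal length).
#' @param grid A [zone_grid()].
#' @return A tibble with columns `longitudinal_zone`, `lateral_zone`
#'   (factors ordered D..O and L..R), `zone` (the `"LONG-LAT"` code) and
#'   `clamped`.
#' @examples
#' assign_zone(0, 0, zone_grid())$zone   # "MO-C"
#' @export
assign_zone <- function(x, y, grid = zone_grid()) {
  le <- grid$longitudinal_edges
  la <- grid$lateral_edges
  clamped <- x < le[1] | x > le[length(le)] | y < la[1] | y > la[length(la)]
  xc <- pmin(pmax(x, le[1]), le[length(le)])
  yc <- pmin(pmax(y, la[1]), la[length(la)])
  li <- findInterval(xc, le, rightmost.closed = TRUE)
  yi <- findInterval(yc, la, rightmost.closed = TRUE)
  long <- factor(grid$longitudinal_labels[li], levels = grid$longitudinal_labels)
  lat <- factor(grid$lateral_labels[yi], levels = grid$lateral_labels)
  tibble::tibble(
    longitudinal_zone = long,
    lateral_zone = lat,
    zone = paste(as.character(long), as.character(lat), sep = "-"),
    clamped = clamped
  )
}

#' Orient points into a team's attacked-goal frame
#'
#' Rotates pitch coordinates so the positive longitudinal axis points toward
#' the goal the team attacks. With `lateral_frame = "attacking"` the point is
#' reflected through the pitch center when the team attacks the negative end
#' (left/right as seen by the attacking team); with `"absolute"` only the
#' longitudinal axis is flipped and left/right stay in the fixed pitch frame.
#'
#' @param x,y Coordinates in meters.
#' @param direction `+1` or `-1`: the longitudinal sign the team attacks.
#' @param lateral_frame `"attacking"` (default) or `"absolute"`.
#' @return A list with components `x` and `y`.
#' @export
orient_to_attack <- function(x, y, direction,
                             lateral_frame = c("attacking", "absolute")) {
  lateral_frame <- match.arg(lateral_frame)
  list(
    x = direction * x,
    y = if (lateral_frame == "attacking") direction * y else y
  )
}
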