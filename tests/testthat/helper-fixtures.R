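# Fixture builders: hand-constructed datasets with exactly known geometry.

# Long-format rows for one frame: 1 ball + 11 home + 11 away players.
rows_for_frame <- function(half, frame, ball, home, away,
                           status = "alive", possession = "home") {
  tibble::tibble(
    half = as.integer(half), frame = as.integer(frame),
    object_type = c("ball", rep("player", 22L)),
    team = c("none", rep("home", 11L), rep("away", 11L)),
    player_id = c(NA_integer_, 1:11, 1:11),
    x_m = c(ball[1], home[, 1], away[, 1]),
    y_m = c(ball[2], home[, 2], away[, 2]),
    ball_status = status, possession = possession
  )
}

# Positions with exact PBGA `thetas` about `ball`, measured against `goal`.
place_players_at_angles <- function(ball, goal, thetas, radius = 10,
                                    sides = 1) {
  u <- goal - ball
  u <- u / sqrt(sum(u^2))
  sides <- rep_len(sides, length(thetas))
  a <- sides * thetas
  cbind(ball[1] + radius * (cos(a) * u[1] - sin(a) * u[2]),
        ball[2] + radius * (sin(a) * u[1] + cos(a) * u[2]))
}

# Dataset in which every player of both teams holds the given PBGA per frame.
# theta_mat: n_frames x 11 matrix of angles.
angles_dataset <- function(theta_mat, possession = "home", status = "alive",
                           half = 1L, ball = c(0, 0), radius = 10,
                           metadata = match_metadata()) {
  n <- nrow(theta_mat)
  possession <- rep_len(possession, n)
  status <- rep_len(status, n)
  half <- rep_len(as.integer(half), n)
  frame <- stats::ave(seq_len(n), half, FUN = seq_along)
  goals <- rbind(metadata$home_goal_center, metadata$away_goal_center)
  dir <- vapply(seq_len(n), function(i) {
    metadata$attack_direction[[possession[i]]][[as.character(half[i])]]
  }, numeric(1))
  gx <- ifelse(dir > 0, goals[goals[, 1] > 0, 1], goals[goals[, 1] < 0, 1])
  gy <- ifelse(dir > 0, goals[goals[, 1] > 0, 2], goals[goals[, 1] < 0, 2])
  ux <- gx - ball[1]; uy <- gy - ball[2]
  un <- sqrt(ux^2 + uy^2); ux <- ux / un; uy <- uy / un
  player_rows <- lapply(1:11, function(k) {
    a <- theta_mat[, k]
    px <- ball[1] + radius * (cos(a) * ux - sin(a) * uy)
    py <- ball[2] + radius * (sin(a) * ux + cos(a) * uy)
    tibble::tibble(half = half, frame = frame, player_id = k,
                   x_m = px, y_m = py,
                   ball_status = status, possession = possession)
  })
  players <- dplyr::bind_rows(player_rows)
  both <- dplyr::bind_rows(
    dplyr::mutate(players, object_type = "player", team = "home"),
    dplyr::mutate(players, object_type = "player", team = "away")
  )
  ball_rows <- tibble::tibble(half = half, frame = frame,
                              object_type = "ball", team = "none",
                              player_id = NA_integer_,
                              x_m = ball[1], y_m = ball[2],
                              ball_status = status, possession = possession)
  fr <- dplyr::arrange(dplyr::bind_rows(ball_rows, both),
                       half, frame, object_type, team, player_id)
  match_dataset(fr[c("half", "frame", "object_type", "team", "player_id",
                     "x_m", "y_m", "ball_status", "possession")], metadata)
}

# Small valid dataset with players on a circle around the ball.
toy_dataset <- function(n_frames = 2L, status = "alive", possession = "home") {
  theta <- matrix(seq(0.1, 3.0, length.out = 11), n_frames, 11L, byrow = TRUE)
  angles_dataset(theta, possession = possession, status = status)
}

# Naive complex-sum Kuramoto oracle for one frame of phases.
kuramoto_naive <- function(theta) {
  s <- 0 + 0i
  n <- 0L
  for (t in theta) {
    if (!is.na(t)) {
      s <- s + complex(modulus = 1, argument = t)
      n <- n + 1L
    }
  }
  if (n == 0L) return(list(r = NA_real_, psi = NA_real_, n = 0L))
  m <- s / n
  list(r = Mod(m), psi = Arg(m), n = n)
}

# Point-in-convex-polygon oracle (vertices in ring order, either orientation).
point_in_hull <- function(p, vertices, tol = 1e-9) {
  nv <- nrow(vertices)
  if (nv == 1L) return(sum((p - vertices[1, ])^2) < tol)
  if (nv == 2L) {
    a <- vertices[1, ]; b <- vertices[2, ]
    cross <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    along <- sum((p - a) * (b - a)) / sum((b - a)^2)
    return(abs(cross) < 1e-6 && along >= -tol && along <= 1 + tol)
  }
  signs <- vapply(seq_len(nv), function(i) {
    a <- vertices[i, ]; b <- vertices[if (i == nv) 1L else i + 1L, ]
    (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  }, numeric(1))
  all(signs >= -1e-6) || all(signs <= 1e-6)
}
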