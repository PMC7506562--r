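#' Match metadata
#'
#' Describes the pitch and recording setup for a tracked match: pitch extents,
#' frame rate, the two goal-mouth centers and, per team and half, the attacked
#' longitudinal direction.
#'
#' Coordinates are pitch-centered: the origin is the pitch center, `x` is the
#' longitudinal axis (positive toward the goal at the `+x` end) and `y` the
#' lateral axis, both in meters. Goal centers sit on the goal lines at
#' `x = -pitch_length/2` and `x = +pitch_length/2`. `attack_direction` gives,
#' for each team and half, the sign of the longitudinal direction that team
#' attacks; it must flip between halves.
#'
#' @param pitch_length Longitudinal pitch extent in meters.
#' @param pitch_width Lateral pitch extent in meters.
#' @param frame_rate Recording rate in Hz.
#' @param home_goal_center,away_goal_center Planar points (length-2 numeric,
#'   meters) of the goal defended by each team in the first half. They must lie
#'   on opposite ends of the pitch.
#' @param attack_direction Named list with elements `home` and `away`, each a
#'   named vector with elements `"1"` and `"2"` in `{-1, +1}`: the sign of the
#'   longitudinal direction the team attacks in that half.
#'
#' @return An object of class `match_metadata`.
#' @examples
#' meta <- match_metadata()
#' meta$pitch_length
#' @export
match_metadata <- function(pitch_length = 105,
                           pitch_width = 68,
                           frame_rate = 25,
                           home_goal_center = c(-pitch_length / 2, 0),
                           away_goal_center = c(pitch_length / 2, 0),
                           attack_direction = list(
                             home = c("1" = 1, "2" = -1),
                             away = c("1" = -1, "2" = 1)
                           )) {
  meta <- structure(
    list(
      pitch_length = as.numeric(pitch_length),
      pitch_width = as.numeric(pitch_width),
      frame_rate = as.numeric(frame_rate),
      home_goal_center = as.numeric(home_goal_center),
      away_goal_center = as.numeric(away_goal_center),
      attack_direction = attack_direction
    ),
    class = "match_metadata"
  )
  validate_match_metadata(meta)
}

#' @export
print.match_metadata <- function(x, ...) {
  cat("<match_metadata>\n")
  cat(sprintf("  pitch: %.1f x %.1f m, frame rate %g Hz\n",
              x$pitch_length, x$pitch_width, x$frame_rate))
  cat(sprintf("  home goal (half 1): (%.1f, %.1f); away goal: (%.1f, %.1f)\n",
              x$home_goal_center[1], x$home_goal_center[2],
              x$away_goal_center[1], x$away_goal_center[2]))
  for (tm in c("home", "away")) {
    d <- x$attack_direction[[tm]]
    cat(sprintf("  %s attacks %+d (half 1), %+d (half 2)\n", tm, d[["1"]], d[["2"]]))
  }
  invisible(x)
}

validate_match_metadata <- function(meta) {
  stop_config <- function(msg) {
    stop(errorCondition(msg, class = c("teamsync_config_error", "error")))
  }
  if (!all(c(meta$pitch_length, meta$pitch_width, meta$frame_rate) > 0)) {
    stop_config("pitch_length, pitch_width and frame_rate must all be positive")
  }
  if (length(meta$home_goal_center) != 2L || length(meta$away_goal_center) != 2L) {
    stop_config("goal centers must be planar points (length-2 numeric)")
  }
  if (sign(meta$home_goal_center[1]) * sign(meta$away_goal_center[1]) != -1) {
    stop_config("goal centers must lie on opposite pitch ends (opposite longitudinal signs)")
  }
  ad <- meta$attack_direction
  if (!is.list(ad) || !all(c("home", "away") %in% names(ad))) {
    stop_config("attack_direction must be a list with elements 'home' and 'away'")
  }
  for (tm in c("home", "away")) {
    d <- ad[[tm]]
    if (!all(c("1", "2") %in% names(d)) || !all(d[c("1", "2")] %in% c(-1, 1))) {
      stop_config(sprintf("attack_direction$%s needs halves '1' and '2' valued in {-1, +1}", tm))
    }
    if (d[["1"]] == d[["2"]]) {
      stop_config(sprintf("attack_direction for team '%s' must flip between halves", tm))
    }
  }
  meta
}

tracking_columns <- c("half", "frame", "object_type", "team", "player_id",
                      "x_m", "y_m", "ball_status", "possession")

#' Match dataset
#'
#' Bundles long-format tracking frames with their [match_metadata()]. Each
#' tracked frame consists of one `ball` row and eleven `player` rows per team;
#' every row carries the frame-level ball status (`alive`/`dead`) and the team
#' in possession.
#'
#' @param frames A data frame with columns `half`, `frame`, `object_type`
#'   (`"ball"` or `"player"`), `team` (`"home"`, `"away"`, or `"none"` for the
#'   ball), `player_id` (integer, `NA` for the ball), `x_m`, `y_m` (meters),
#'   `ball_status` (`"alive"`/`"dead"`), `possession` (`"home"`/`"away"`).
#' @param metadata A [match_metadata()] object.
#' @param validate Run full invariant checks (default `TRUE`).
#'
#' @return An object of class `match_dataset` with elements `frames` (tibble)
#'   and `metadata`.
#' @export
match_dataset <- function(frames, metadata = match_metadata(), validate = TRUE) {
  frames <- tibble::as_tibble(frames)
  ds <- structure(
    list(frames = frames, metadata = validate_match_metadata(metadata)),
    class = "match_dataset",
    normalized = isTRUE(attr(frames, "normalized"))
  )
  if (validate) validate_tracking(ds)
  ds
}

#' @export
print.match_dataset <- function(x, ...) {
  idx <- dplyr::distinct(x$frames, .data$half, .data$frame)
  cat("<match_dataset>\n")
  cat(sprintf("  %d frames (%s), %d rows\n", nrow(idx),
              paste(sprintf("half %d: %d", sort(unique(idx$half)),
                            table(idx$half)), collapse = ", "),
              nrow(x$frames)))
  if (isTRUE(attr(x, "normalized"))) cat("  attack direction normalized\n")
  invisible(x)
}

stop_tracking <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "teamsync_error", "error")))
}

#' Validate a match dataset against the tracking schema
#'
#' Checks column presence and types, categorical levels, per-frame roster
#' completeness (exactly 11 players per team and one ball row), uniqueness of
#' `(half, frame, team, player_id)`, frame ordering within halves, and
#' frame-level consistency of `ball_status` and `possession`. Violations are
#' reported with the offending row numbers or frame indices.
#'
#' @param ds A [match_dataset()].
#' @return `ds`, invisibly, if valid; otherwise an error of class
#'   `teamsync_schema_error`, `teamsync_integrity_error` or
#'   `teamsync_roster_error`.
#' @export
validate_tracking <- function(ds) {
  fr <- ds$frames
  missing_cols <- setdiff(tracking_columns, names(fr))
  if (length(missing_cols)) {
    stop_tracking("teamsync_schema_error",
                  paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  bad_type <- which(!fr$object_type %in% c("ball", "player"))
  if (length(bad_type)) {
    stop_tracking("teamsync_schema_error",
                  paste0("invalid object_type at row(s): ",
                         paste(utils::head(bad_type, 5), collapse = ", ")))
  }
  bad_status <- which(!fr$ball_status %in% c("alive", "dead"))
  if (length(bad_status)) {
    stop_tracking("teamsync_schema_error",
                  paste0("invalid ball_status at row(s): ",
                         paste(utils::head(bad_status, 5), collapse = ", ")))
  }
  bad_poss <- which(!fr$possession %in% c("home", "away"))
  if (length(bad_poss)) {
    stop_tracking("teamsync_schema_error",
                  paste0("invalid possession at row(s): ",
                         paste(utils::head(bad_poss, 5), collapse = ", ")))
  }
  is_player <- fr$object_type == "player"
  bad_team <- which(is_player & !fr$team %in% c("home", "away"))
  if (length(bad_team)) {
    stop_tracking("teamsync_schema_error",
                  paste0("player rows must have team home/away; row(s): ",
                         paste(utils::head(bad_team, 5), collapse = ", ")))
  }
  if (anyNA(fr$x_m) || anyNA(fr$y_m)) {
    bad <- which(is.na(fr$x_m) | is.na(fr$y_m))
    stop_tracking("teamsync_schema_error",
                  paste0("missing coordinates at row(s): ",
                         paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (!all(fr$half %in% c(1L, 2L))) {
    stop_tracking("teamsync_schema_error", "half must be 1 or 2")
  }

  pl <- fr[is_player, ]
  key <- paste(pl$half, pl$frame, pl$team, pl$player_id)
  if (anyDuplicated(key)) {
    dup <- which(is_player)[duplicated(key)]
    stop_tracking("teamsync_integrity_error",
                  paste0("duplicate (half, frame, team, player_id) at row(s): ",
                         paste(utils::head(dup, 5), collapse = ", ")))
  }

  # one ball row and 11 players per team per frame
  counts <- dplyr::count(fr, .data$half, .data$frame, .data$object_type, .data$team)
  ball_counts <- dplyr::filter(counts, .data$object_type == "ball")
  idx <- dplyr::distinct(fr, .data$half, .data$frame)
  bad_ball <- dplyr::anti_join(idx, dplyr::filter(ball_counts, .data$n == 1L),
                               by = c("half", "frame"))
  multi_ball <- dplyr::filter(ball_counts, .data$n > 1L)
  if (nrow(multi_ball)) {
    stop_tracking("teamsync_integrity_error",
                  paste0("more than one ball row in frame(s): ",
                         paste(utils::head(multi_ball$frame, 5), collapse = ", ")))
  }
  if (nrow(bad_ball)) {
    stop_tracking("teamsync_roster_error",
                  paste0("missing ball row in frame(s): ",
                         paste(utils::head(bad_ball$frame, 5), collapse = ", ")))
  }
  pcount <- dplyr::count(pl, .data$half, .data$frame, .data$team)
  full <- tidyr::expand_grid(idx, team = c("home", "away"))
  pcount <- dplyr::left_join(full, pcount, by = c("half", "frame", "team"))
  pcount$n[is.na(pcount$n)] <- 0L
  bad_roster <- dplyr::filter(pcount, .data$n != 11L)
  if (nrow(bad_roster)) {
    b <- bad_roster[1, ]
    stop_tracking("teamsync_roster_error",
                  sprintf("expected 11 %s players in half %d frame %d, found %d (%d frame(s) affected)",
                          b$team, b$half, b$frame, b$n, nrow(bad_roster)))
  }

  # frame indices strictly increasing within each half
  for (h in unique(fr$half)) {
    f <- unique(fr$frame[fr$half == h])
    if (is.unsorted(f, strictly = TRUE)) {
      stop_tracking("teamsync_integrity_error",
                    sprintf("frame indices not strictly increasing within half %d", h))
    }
  }

  # frame-level flags must be constant across the frame's rows
  flag_chk <- dplyr::summarise(
    dplyr::group_by(fr, .data$half, .data$frame),
    ok = dplyr::n_distinct(.data$ball_status) == 1L &&
      dplyr::n_distinct(.data$possession) == 1L,
    .groups = "drop"
  )
  bad_flag <- dplyr::filter(flag_chk, !.data$ok)
  if (nrow(bad_flag)) {
    stop_tracking("teamsync_integrity_error",
                  paste0("inconsistent ball_status/possession within frame(s): ",
                         paste(utils::head(bad_flag$frame, 5), collapse = ", ")))
  }
  invisible(ds)
}

#' Read tracking data
#'
#' Reads a long-format tracking CSV (one row per tracked object per frame) and
#' a YAML metadata file, and returns a validated [match_dataset()].
#'
#' @param path Path to the tracking CSV.
#' @param metadata_path Path to the YAML metadata file
#'   (see [write_match_metadata()]).
#' @return A validated [match_dataset()].
#' @seealso [write_tracking()], [validate_tracking()]
#' @export
read_tracking <- function(path, metadata_path) {
  meta <- read_match_metadata(metadata_path)
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing_cols <- setdiff(tracking_columns, header)
  if (length(missing_cols)) {
    stop_tracking("teamsync_schema_error",
                  paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  fr <- readr::read_csv(
    path,
    col_types = readr::cols(
      half = readr::col_integer(),
      frame = readr::col_integer(),
      object_type = readr::col_character(),
      team = readr::col_character(),
      player_id = readr::col_integer(),
      x_m = readr::col_double(),
      y_m = readr::col_double(),
      ball_status = readr::col_character(),
      possession = readr::col_character()
    ),
    progress = FALSE
  )
  missing_cols <- setdiff(tracking_columns, names(fr))
  if (length(missing_cols)) {
    stop_tracking("teamsync_schema_error",
                  paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  match_dataset(fr[tracking_columns], meta, validate = nrow(fr) > 0)
}

#' Write tracking data
#'
#' Writes a [match_dataset()]'s frames to CSV. Positions are quantized to the
#' stated spatial resolution by default (0.01 m, matching optical tracking
#' feeds); reading the file back with [read_tracking()] reproduces the dataset
#' bit-exactly at that resolution.
#'
#' @param ds A [match_dataset()].
#' @param path Output CSV path.
#' @param quantize Spatial quantization step in meters, or `NULL`/`0` to write
#'   full double precision.
#' @return `path`, invisibly.
#' @export
write_tracking <- function(ds, path, quantize = 0.01) {
  fr <- ds$frames
  if (!is.null(quantize) && quantize > 0) {
    # decimal-aware rounding for power-of-ten steps (0.01 m -> round(x, 2))
    digits <- -log10(quantize)
    if (abs(digits - round(digits)) < 1e-9) {
      fr$x_m <- round(fr$x_m, round(digits))
      fr$y_m <- round(fr$y_m, round(digits))
    } else {
      fr$x_m <- round(fr$x_m / quantize) * quantize
      fr$y_m <- round(fr$y_m / quantize) * quantize
    }
  }
  readr::write_csv(fr[tracking_columns], path, progress = FALSE)
  invisible(path)
}

#' Read or write match metadata as YAML
#'
#' @param path File path.
#' @return `read_match_metadata()` returns a [match_metadata()];
#'   `write_match_metadata()` returns `path` invisibly.
#' @export
read_match_metadata <- function(path) {
  y <- yaml::read_yaml(path)
  ad <- lapply(y$attack_direction, function(d) {
    v <- as.numeric(unlist(d))
    names(v) <- names(unlist(d))
    v
  })
  match_metadata(
    pitch_length = y$pitch_length,
    pitch_width = y$pitch_width,
    frame_rate = y$frame_rate,
    home_goal_center = as.numeric(y$home_goal_center),
    away_goal_center = as.numeric(y$away_goal_center),
    attack_direction = ad
  )
}

#' @rdname read_match_metadata
#' @param meta A [match_metadata()] object.
#' @export
write_match_metadata <- function(meta, path) {
  y <- list(
    pitch_length = meta$pitch_length,
    pitch_width = meta$pitch_width,
    frame_rate = meta$frame_rate,
    home_goal_center = meta$home_goal_center,
    away_goal_center = meta$away_goal_center,
    attack_direction = lapply(meta$attack_direction, as.list)
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Filter frames by ball status, possession role and half
#'
#' Selects the subsequence of frames matching all selectors. Dead-ball frames
#' are retained in storage and removed here at analysis time, following the
#' convention that synchrony is only interpreted while the match is running.
#'
#' @param ds A [match_dataset()].
#' @param status `"alive"`, `"dead"`, or `"any"`.
#' @param role_for_team `"with_ball"`, `"without_ball"`, or `"any"`:
#'   `"with_ball"` keeps frames where `possession == team`.
#' @param team `"home"` or `"away"`; required when `role_for_team != "any"`.
#' @param half `1`, `2`, or `"any"`.
#' @return A [match_dataset()] with the selected frames (possibly empty).
#' @examples
#' ds <- simulate_match(simulation_config(n_frames_per_half = 20, seed = 1))$dataset
#' alive <- filter_frames(ds, status = "alive")
#' @export
filter_frames <- function(ds, status = "any", role_for_team = "any",
                          team = NULL, half = "any") {
  status <- match.arg(status, c("any", "alive", "dead"))
  role_for_team <- match.arg(role_for_team, c("any", "with_ball", "without_ball"))
  fr <- ds$frames
  keep <- rep(TRUE, nrow(fr))
  if (status != "any") keep <- keep & fr$ball_status == status
  if (role_for_team != "any") {
    if (is.null(team)) {
      stop_tracking("teamsync_config_error",
                    "role_for_team requires a team ('home' or 'away')")
    }
    team <- match.arg(team, c("home", "away"))
    has_ball <- fr$possession == team
    keep <- keep & if (role_for_team == "with_ball") has_ball else !has_ball
  }
  if (!identical(half, "any")) keep <- keep & fr$half == as.integer(half)
  out <- fr[keep, ]
  attr(out, "normalized") <- isTRUE(attr(ds, "normalized"))
  match_dataset(out, ds$metadata, validate = FALSE)
}

#' Frame index of a match dataset
#'
#' @param ds A [match_dataset()].
#' @return A tibble with one row per tracked frame: `half`, `frame`,
#'   `ball_status`, `possession`, and the ball position `ball_x`, `ball_y`.
#' @export
frame_index <- function(ds) {
  ball <- dplyr::filter(ds$frames, .data$object_type == "ball")
  tibble::tibble(
    half = ball$half, frame = ball$frame,
    ball_status = ball$ball_status, possession = ball$possession,
    ball_x = ball$x_m, ball_y = ball$y_m
  )
}
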