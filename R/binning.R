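#' Per-player PBGA relative-frequency profiles
#'
#' Histograms each player's PBGA over the frames in which the match was
#' running and the team held the stated role, using `n_bins` equal bins on
#' `[0, pi]` (default 18 bins of 10 degrees). The profile characterises the
#' player's interpersonal linkage: a narrow, tall profile means the player
#' held a tight angular relation to the ball-goal axis in that role; a flat
#' one means unconstrained movement.
#'
#' Raw frame counts and proportions of qualifying frames are both reported,
#' since "relative frequency" is used for raw counts in polar-profile plots
#' while proportions support cross-role comparison.
#'
#' Bins are half-open `[lo, hi)` with the final bin closed at `pi`.
#'
#' @param pbga A [compute_pbga()] tibble for the team.
#' @param ds The source [match_dataset()].
#' @param team `"home"` or `"away"`.
#' @param role `"with_ball"` or `"without_ball"`.
#' @param n_bins Number of bins (default 18).
#' @return A tibble with columns `player_id`, `role`, `bin`, `bin_lo_rad`,
#'   `bin_hi_rad`, `count`, `proportion`, `total_frames`. With zero
#'   qualifying frames the histogram is all-zero with `total_frames = 0`.
#' @export
pbga_relative_frequency <- function(pbga, ds, team = c("home", "away"),
                                    role = c("with_ball", "without_ball"),
                                    n_bins = 18L) {
  team <- match.arg(team)
  role <- match.arg(role)
  idx <- frame_index(ds)
  keep <- idx$ball_status == "alive" &
    (if (role == "with_ball") idx$possession == team else idx$possession != team)
  idx <- idx[keep, c("half", "frame")]
  d <- dplyr::inner_join(pbga[pbga$team == team & pbga$defined, ], idx,
                         by = c("half", "frame"))
  edges <- seq(0, pi, length.out = n_bins + 1L)
  players <- sort(unique(pbga$player_id[pbga$team == team]))
  grid <- tidyr::expand_grid(player_id = players, bin = seq_len(n_bins))
  if (nrow(d)) {
    d$bin <- bin_phase(d$theta, edges)
    counts <- dplyr::count(d, .data$player_id, .data$bin, name = "count")
  } else {
    counts <- tibble::tibble(player_id = integer(), bin = integer(),
                             count = integer())
  }
  out <- dplyr::left_join(grid, counts, by = c("player_id", "bin"))
  out$count[is.na(out$count)] <- 0L
  totals <- dplyr::summarise(dplyr::group_by(out, .data$player_id),
                             total_frames = sum(.data$count), .groups = "drop")
  out <- dplyr::left_join(out, totals, by = "player_id")
  out$role <- role
  out$bin_lo_rad <- edges[out$bin]
  out$bin_hi_rad <- edges[out$bin + 1L]
  out$proportion <- ifelse(out$total_frames > 0, out$count / out$total_frames, 0)
  out[c("player_id", "role", "bin", "bin_lo_rad", "bin_hi_rad",
        "count", "proportion", "total_frames")]
}

# Half-open binning of phases in [0, pi]; the last bin is closed at pi.
bin_phase <- function(theta, edges) {
  b <- findInterval(theta, edges, rightmost.closed = TRUE)
  pmin(pmax(b, 1L), length(edges) - 1L)
}

tcc_edges <- c(0, pi / 3, 2 * pi / 3, pi)

#' Team configuration codes (TCC)
#'
#' Collapses the PBGA of a team into three angular sectors about the ball-goal
#' axis and counts players per sector, per frame:
#' front support/cover `[0, pi/3)`, lateral support/cover `[pi/3, 2*pi/3)` and
#' back support/cover `[2*pi/3, pi]`. The triple (printed in the fixed order
#' FS/C-LS/C-BS/C, e.g. `6-4-1`) is the team's configuration code; the role
#' label is `"support"` when the team holds possession and `"cover"`
#' otherwise. The sector intervals are half-open with the final sector closed
#' so the three counts partition the defined players exactly.
#'
#' @param pbga A [compute_pbga()] tibble for the team.
#' @param ds The source [match_dataset()].
#' @param team `"home"` or `"away"`.
#' @param alive_only Restrict to alive frames (default `TRUE`).
#' @return A tibble with columns `half`, `frame`, `team`, `role_label`,
#'   `fs_c`, `ls_c`, `bs_c`, `n_defined` and `tcc` (the printed code).
#' @export
team_configuration_code <- function(pbga, ds, team = c("home", "away"),
                                    alive_only = TRUE) {
  team <- match.arg(team)
  idx <- frame_index(ds)
  if (alive_only) idx <- idx[idx$ball_status == "alive", ]
  d <- dplyr::inner_join(pbga[pbga$team == team, ],
                         idx[c("half", "frame", "possession")],
                         by = c("half", "frame"))
  d$sector <- ifelse(d$defined, bin_phase(d$theta, tcc_edges), NA_integer_)
  out <- dplyr::summarise(
    dplyr::group_by(d, .data$half, .data$frame, .data$possession),
    fs_c = sum(.data$sector == 1L, na.rm = TRUE),
    ls_c = sum(.data$sector == 2L, na.rm = TRUE),
    bs_c = sum(.data$sector == 3L, na.rm = TRUE),
    n_defined = sum(.data$defined),
    .groups = "drop"
  )
  tibble::tibble(
    half = out$half, frame = out$frame, team = team,
    role_label = ifelse(out$possession == team, "support", "cover"),
    fs_c = out$fs_c, ls_c = out$ls_c, bs_c = out$bs_c,
    n_defined = out$n_defined,
    tcc = sprintf("%d-%d-%d", out$fs_c, out$ls_c, out$bs_c)
  )
}

#' Convex hulls of TCC subgroups
#'
#' For one frame, partitions a team's players into the three TCC sectors and
#' returns the planar convex hull of each non-empty subgroup. Subgroups with
#' fewer than three members (or collinear members) cannot span a polygon and
#' are flagged degenerate; their "hull" is the point or segment itself.
#'
#' @param ds A [match_dataset()].
#' @param pbga The team's [compute_pbga()] tibble (the same bin assignment
#'   used for [team_configuration_code()]).
#' @param team `"home"` or `"away"`.
#' @param half,frame Frame selector.
#' @return A named list (`fs_c`, `ls_c`, `bs_c`) of lists with elements
#'   `members` (player ids), `vertices` (matrix of hull vertex coordinates,
#'   counter-clockwise) and `degenerate`. Empty subgroups are `NULL`.
#' @export
subgroup_hulls <- function(ds, pbga, team = c("home", "away"), half, frame) {
  team <- match.arg(team)
  ph <- pbga[pbga$team == team & pbga$half == half & pbga$frame == frame, ]
  if (nrow(ph) == 0L) stop(sprintf("frame %d (half %d) not found", frame, half))
  pos <- dplyr::filter(ds$frames, .data$object_type == "player",
                       .data$team == !!team, .data$half == !!half,
                       .data$frame == !!frame)
  d <- dplyr::inner_join(
    ph[ph$defined, c("player_id", "theta")],
    tibble::tibble(player_id = pos$player_id, x = pos$x_m, y = pos$y_m),
    by = "player_id"
  )
  d$sector <- bin_phase(d$theta, tcc_edges)
  out <- list(fs_c = NULL, ls_c = NULL, bs_c = NULL)
  for (s in 1:3) {
    m <- d[d$sector == s, ]
    if (nrow(m) == 0L) next
    xy <- cbind(m$x, m$y)
    hull_idx <- grDevices::chull(xy)
    vertices <- xy[hull_idx, , drop = FALSE]
    colnames(vertices) <- c("x", "y")
    degenerate <- nrow(m) < 3L || length(hull_idx) < 3L
    out[[s]] <- list(members = m$player_id, vertices = vertices,
                     degenerate = degenerate)
  }
  out
}

#' Export subgroup hulls as GeoJSON-style polygons
#'
#' @param hulls A [subgroup_hulls()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_subgroup_hulls <- function(hulls, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the 'jsonlite' package is required to write hull polygons")
  }
  features <- Filter(Negate(is.null), lapply(names(hulls), function(nm) {
    h <- hulls[[nm]]
    if (is.null(h)) return(NULL)
    ring <- rbind(h$vertices, h$vertices[1, , drop = FALSE])
    list(
      type = "Feature",
      properties = list(subgroup = nm, members = h$members,
                        degenerate = h$degenerate),
      geometry = list(type = "Polygon",
                      coordinates = list(unname(apply(ring, 1, c, simplify = FALSE))))
    )
  }))
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
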