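#' Kuramoto order parameter over PBGA phases
#'
#' Treats the players of a team as a population of phase oscillators and
#' measures their coherence per frame with the Kuramoto order parameter:
#'
#' \deqn{r'(t) e^{i\psi(t)} = \frac{1}{n}\sum_{k=1}^{n} e^{i\theta_k(t)}}
#'
#' `r_prime` is the modulus of the complex mean (1 = all players at the same
#' angle, 0 = full cancellation) and `psi` its argument, the team's cluster
#' phase. The complex mean is computed once per frame; no Hilbert transform or
#' other phase-unwrapping step is involved, since the PBGA is already a phase.
#'
#' Players whose angle is undefined in a frame (degenerate geometry) are
#' dropped from that frame's mean, with `n` reduced accordingly; frames with no
#' defined phase at all yield `NA`.
#'
#' @param pbga A PBGA tibble from [compute_pbga()] (one or both teams).
#' @return A tibble with columns `half`, `frame`, `team`, `r_prime` in
#'   `[0, 1]`, `psi` (radians) and `n` (count of defined phases).
#' @examples
#' p <- tibble::tibble(half = 1L, frame = 1L, team = "home",
#'                     player_id = 1:2, theta = c(0, pi / 2),
#'                     defined = TRUE)
#' kuramoto(p)  # r_prime = sqrt(2)/2, psi = pi/4
#' @export
kuramoto <- function(pbga) {
  if (nrow(pbga) == 0L) {
    stop(errorCondition("empty phase series: at least one player is required",
                        class = c("teamsync_contract_error", "error")))
  }
  out <- dplyr::summarise(
    dplyr::group_by(pbga, .data$half, .data$frame, .data$team),
    n = sum(.data$defined),
    re = mean(cos(.data$theta[.data$defined])),
    im = mean(sin(.data$theta[.data$defined])),
    .groups = "drop"
  )
  out$r_prime <- ifelse(out$n > 0L, sqrt(out$re^2 + out$im^2), NA_real_)
  out$psi <- ifelse(out$n > 0L, atan2(out$im, out$re), NA_real_)
  # guard against floating-point overshoot at perfect coherence
  out$r_prime <- pmin(out$r_prime, 1)
  out[c("half", "frame", "team", "r_prime", "psi", "n")]
}

#' Player-team relative phase
#'
#' The deviation of each player's PBGA from the team's cluster phase,
#' \eqn{\Phi_k(t) = \theta_k(t) - \psi(t)}. With \eqn{\theta_k \in [0, \pi]}
#' and \eqn{\psi \in [0, \pi]} the difference already lies in
#' \eqn{[-\pi, \pi]} and is reported without further wrapping. A player
#' in-phase with the team holds \eqn{\Phi_k} near 0; sustained departures mark
#' the compensations (or failures to compensate) that precede drops in team
#' synchrony.
#'
#' @param pbga A PBGA tibble from [compute_pbga()].
#' @param sync The matching [kuramoto()] output computed from the same series.
#' @return The `pbga` tibble with an added `phi` column (radians, `NA` where
#'   the player's angle is undefined).
#' @export
relative_phase <- function(pbga, sync) {
  d <- dplyr::left_join(pbga, sync[c("half", "frame", "team", "psi")],
                        by = c("half", "frame", "team"))
  if (anyNA(d$psi[d$defined])) {
    stop(errorCondition(
      "phase series and synchrony series do not align: frames missing from sync",
      class = c("teamsync_alignment_error", "error")
    ))
  }
  d$phi <- d$theta - d$psi
  d
}

#' Grouped synchrony summaries
#'
#' Mean, standard deviation and frame count of the order parameter `r_prime`,
#' grouped by any subset of team, half, possession role and ball-position
#' zone. Only alive frames contribute, mirroring the convention that synchrony
#' is interpreted while the match is running.
#'
#' @param sync A [kuramoto()] output.
#' @param ds The [match_dataset()] the phases came from.
#' @param group_by Character subset of
#'   `c("team", "half", "role", "lateral_zone", "longitudinal_zone")`.
#' @param grid A [zone_grid()] used when grouping by zone.
#' @param lateral_frame Passed to [orient_to_attack()] for zone assignment.
#' @return A tibble with the grouping columns plus `mean_r_prime`,
#'   `sd_r_prime` and `n_frames`. Empty groups appear with `n_frames = 0` and
#'   `NA` mean.
#' @export
summarize_synchrony <- function(sync, ds,
                                group_by = c("team", "half", "role"),
                                grid = zone_grid(ds$metadata$pitch_length,
                                                 ds$metadata$pitch_width),
                                lateral_frame = "attacking") {
  allowed <- c("team", "half", "role", "lateral_zone", "longitudinal_zone")
  bad <- setdiff(group_by, allowed)
  if (length(bad)) {
    stop(sprintf("unknown grouping column(s): %s", paste(bad, collapse = ", ")))
  }
  tab <- build_model_table(sync, ds, grid = grid, lateral_frame = lateral_frame,
                           quiet = TRUE)
  grouped <- dplyr::group_by(tab, dplyr::across(dplyr::all_of(group_by)),
                             .drop = FALSE)
  out <- dplyr::summarise(
    grouped,
    mean_r_prime = mean(.data$r_prime),
    sd_r_prime = stats::sd(.data$r_prime),
    n_frames = dplyr::n(),
    .groups = "drop"
  )
  out$mean_r_prime[out$n_frames == 0L] <- NA_real_
  out
}

#' Moving-average smoothing of a synchrony series
#'
#' Optional centered moving average for visualising `r_prime`; the analysis
#' functions never smooth by default.
#'
#' @param sync A [kuramoto()] output.
#' @param window Odd window length in frames.
#' @return `sync` with `r_prime` replaced by its within-(half, team) moving
#'   average (edges keep shorter one-sided windows).
#' @export
smooth_synchrony <- function(sync, window = 25L) {
  if (window <= 1L) return(sync)
  smooth_one <- function(r) {
    z <- as.numeric(stats::filter(r, rep(1 / window, window), sides = 2))
    ifelse(is.na(z), r, z)
  }
  out <- dplyr::mutate(dplyr::group_by(sync, .data$half, .data$team),
                       r_prime = smooth_one(.data$r_prime))
  dplyr::ungroup(out)
}
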