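test_that("a player fixed in one bin concentrates the whole histogram there", {
  n <- 40L
  ds <- angles_dataset(matrix(0.05, n, 11L), possession = "home")
  pb <- compute_pbga(ds, "home")
  h <- pbga_relative_frequency(pb, ds, "home", "with_ball")
  p1 <- h[h$player_id == 1L, ]
  expect_identical(p1$count[p1$bin == 1L], n)
  expect_true(all(p1$count[p1$bin != 1L] == 0L))
  expect_equal(p1$proportion[p1$bin == 1L], 1)
})

test_that("histogram counts sum to the qualifying frames per player and role", {
  set.seed(21)
  sim <- simulate_match(simulation_config(n_frames_per_half = 150L,
                                          possession_switch_rate = 0.02,
                                          seed = 21))
  ds <- sim$dataset
  pb <- compute_pbga(ds, "away")
  idx <- frame_index(ds)
  for (role in c("with_ball", "without_ball")) {
    h <- pbga_relative_frequency(pb, ds, "away", role)
    qualifying <- sum(idx$ball_status == "alive" &
                        (idx$possession == "away") == (role == "with_ball"))
    sums <- dplyr::summarise(dplyr::group_by(h, .data$player_id),
                             s = sum(.data$count), .groups = "drop")
    expect_true(all(sums$s == qualifying))
    expect_identical(unique(h$total_frames), qualifying)
  }
})

test_that("zero qualifying frames give an all-zero histogram", {
  ds <- angles_dataset(matrix(1, 5L, 11L), possession = "home")
  pb <- compute_pbga(ds, "home")
  h <- pbga_relative_frequency(pb, ds, "home", "without_ball")
  expect_true(all(h$count == 0L))
  expect_true(all(h$total_frames == 0L))
})

test_that("uniform angles spread over the 18 bins within binomial bounds", {
  set.seed(31)
  n <- 3600L
  theta <- matrix(stats::runif(n * 11L, 0, pi), n)
  ds <- angles_dataset(theta, possession = "home")
  pb <- compute_pbga(ds, "home")
  h <- pbga_relative_frequency(pb, ds, "home", "with_ball")
  expected <- n / 18
  sigma <- sqrt(n * (1 / 18) * (17 / 18))
  expect_true(all(abs(h$count - expected) < 3.5 * sigma))
})

test_that("team configuration codes count the three angular sectors", {
  # all players in the front sector
  ds <- angles_dataset(matrix(0.2, 3L, 11L), possession = "home")
  pb <- compute_pbga(ds, "home")
  tcc <- team_configuration_code(pb, ds, "home")
  expect_true(all(tcc$tcc == "11-0-0"))
  expect_true(all(tcc$role_label == "support"))

  # constructed 4-4-3 split; home has no possession so the role is cover
  theta <- matrix(c(rep(0.1, 4), rep(1.2, 4), rep(3.0, 3)), 2L, 11L,
                  byrow = TRUE)
  ds2 <- angles_dataset(theta, possession = "away")
  pb2 <- compute_pbga(ds2, "home")
  tcc2 <- team_configuration_code(pb2, ds2, "home")
  expect_true(all(tcc2$tcc == "4-4-3"))
  expect_true(all(tcc2$role_label == "cover"))
})

test_that("TCC components conserve the defined-player count on simulated play", {
  sim <- simulate_match(simulation_config(n_frames_per_half = 120L, seed = 8))
  pb <- compute_pbga(sim$dataset, "home")
  tcc <- team_configuration_code(pb, sim$dataset, "home")
  expect_true(all(tcc$fs_c + tcc$ls_c + tcc$bs_c == tcc$n_defined))
  expect_true(all(tcc$n_defined == 11L))
})

test_that("aggregating the 18-bin histogram 6+6+6 equals the direct 3-bin TCC", {
  sim <- simulate_match(simulation_config(n_frames_per_half = 100L, seed = 13))
  ds <- sim$dataset
  pb <- compute_pbga(ds, "away")
  tcc <- team_configuration_code(pb, ds, "away", alive_only = FALSE)
  edges18 <- seq(0, pi, length.out = 19L)
  pb$bin18 <- teamsync:::bin_phase(pb$theta, edges18)
  agg <- dplyr::summarise(
    dplyr::group_by(pb, .data$half, .data$frame),
    fs = sum(.data$bin18 <= 6L), ls = sum(.data$bin18 >= 7L & .data$bin18 <= 12L),
    bs = sum(.data$bin18 >= 13L), .groups = "drop"
  )
  j <- dplyr::inner_join(tcc, agg, by = c("half", "frame"))
  expect_identical(nrow(j), nrow(tcc))
  expect_identical(j$fs_c, j$fs)
  expect_identical(j$ls_c, j$ls)
  expect_identical(j$bs_c, j$bs)
})

test_that("subgroup hulls enclose their members and flag degenerate groups", {
  # 3 front players in a triangle, 1 lateral player, and back players on a line
  b <- c(0, 0); g <- c(52.5, 0)
  front <- rbind(c(10, 1), c(14, -2), c(12, 4))           # theta near 0
  lateral <- rbind(c(0, 8))                               # theta = pi/2
  back <- cbind(seq(-8, -20, length.out = 7), 0)          # theta = pi
  ds <- match_dataset(rows_for_frame(
    1L, 1L, b, home = rbind(front, lateral, back),
    away = rbind(front, lateral, back)
  ), match_metadata())
  pb <- compute_pbga(ds, "home")
  hulls <- subgroup_hulls(ds, pb, "home", half = 1L, frame = 1L)

  expect_identical(sort(hulls$fs_c$members), 1:3)
  expect_identical(nrow(hulls$fs_c$vertices), 3L)
  expect_false(hulls$fs_c$degenerate)

  expect_identical(hulls$ls_c$members, 4L)
  expect_true(hulls$ls_c$degenerate)

  # collinear back subgroup is degenerate too
  expect_true(hulls$bs_c$degenerate)

  # every member lies inside or on its hull (point-in-polygon oracle)
  pos <- ds$frames[ds$frames$team == "home", ]
  for (sg in hulls) {
    if (is.null(sg)) next
    for (m in sg$members) {
      p <- c(pos$x_m[pos$player_id == m], pos$y_m[pos$player_id == m])
      expect_true(point_in_hull(p, sg$vertices))
    }
  }
})

test_that("a point interior to the others is not a hull vertex", {
  b <- c(0, 0); g <- c(52.5, 0)
  quad <- rbind(c(10, -5), c(20, -5), c(20, 5), c(10, 5))
  inner <- c(15, 0)
  others <- place_players_at_angles(b, g, rep(2.9, 6), radius = 15)
  ds <- match_dataset(rows_for_frame(
    1L, 1L, b, home = rbind(quad, inner, others),
    away = rbind(quad, inner, others)
  ), match_metadata())
  pb <- compute_pbga(ds, "home")
  hulls <- subgroup_hulls(ds, pb, "home", half = 1L, frame = 1L)
  expect_identical(sort(hulls$fs_c$members), 1:5)
  expect_identical(nrow(hulls$fs_c$vertices), 4L)
  expect_true(point_in_hull(inner, hulls$fs_c$vertices))
})
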