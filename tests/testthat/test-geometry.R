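test_that("PBGA matches the analytic cases at the ball vertex", {
  b <- c(0, 0); g <- c(52.5, 0)
  expect_equal(teamsync:::pbga_angle(26.25, 0, b[1], b[2], g[1], g[2]), 0)
  expect_equal(teamsync:::pbga_angle(-10, 0, b[1], b[2], g[1], g[2]), pi)
  expect_equal(teamsync:::pbga_angle(0, 7, b[1], b[2], g[1], g[2]), pi / 2)
  # degenerate: player on the ball
  expect_true(is.na(teamsync:::pbga_angle(0, 0, b[1], b[2], g[1], g[2])))
  # degenerate: ball on the goal center
  expect_true(is.na(teamsync:::pbga_angle(1, 1, g[1], g[2], g[1], g[2])))
})

test_that("PBGA is invariant under similarity transforms and agrees with acos", {
  set.seed(42)
  for (i in 1:200) {
    p <- stats::runif(2, -50, 50); b <- stats::runif(2, -50, 50)
    g <- stats::runif(2, -50, 50)
    if (sum((p - b)^2) < 1e-4 || sum((g - b)^2) < 1e-4) next
    th <- teamsync:::pbga_angle(p[1], p[2], b[1], b[2], g[1], g[2])

    # rotation + translation + positive scaling
    a <- stats::runif(1, 0, 2 * pi); s <- stats::runif(1, 0.1, 10)
    t <- stats::runif(2, -100, 100)
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
    tp <- s * R %*% p + t; tb <- s * R %*% b + t; tg <- s * R %*% g + t
    th2 <- teamsync:::pbga_angle(tp[1], tp[2], tb[1], tb[2], tg[1], tg[2])
    expect_lt(abs(th - th2), 1e-9)

    # acos of the normalized dot product
    v <- p - b; w <- g - b
    th3 <- acos(sum(v * w) / sqrt(sum(v^2) * sum(w^2)))
    expect_lt(abs(th - th3), 1e-7)
  }
})

test_that("compute_pbga uses the goal attacked by the possessing team for both teams", {
  # home possesses in half 1 and attacks +x: G = (52.5, 0) for everyone
  theta <- matrix(seq(0.2, 2.8, length.out = 11), 1L, 11L)
  ds <- angles_dataset(theta, possession = "home", half = 1L)
  for (tm in c("home", "away")) {
    pb <- compute_pbga(ds, tm)
    expect_equal(sort(pb$theta), sort(theta[1, ]), tolerance = 1e-10)
  }
  # away possesses: attacked goal flips to (-52.5, 0); the same player
  # positions are built against that goal, so angles still match
  ds2 <- angles_dataset(theta, possession = "away", half = 1L)
  pb2 <- compute_pbga(ds2, "home")
  expect_equal(sort(pb2$theta), sort(theta[1, ]), tolerance = 1e-10)
})

test_that("compute_pbga flags degenerate geometry instead of zeroing it", {
  ds <- toy_dataset(1L)
  fr <- ds$frames
  idx <- which(fr$team == "home" & fr$player_id == 3L)
  fr$x_m[idx] <- 0; fr$y_m[idx] <- 0  # on the ball
  ds2 <- match_dataset(fr, ds$metadata)
  pb <- compute_pbga(ds2, "home")
  expect_false(pb$defined[pb$player_id == 3L])
  expect_true(is.na(pb$theta[pb$player_id == 3L]))
  expect_true(all(pb$defined[pb$player_id != 3L]))
})

test_that("normalize_attack_direction reflects half 2 only and is an involution", {
  theta <- matrix(1, 4L, 11L)
  ds <- angles_dataset(theta, half = c(1L, 1L, 2L, 2L), ball = c(10, 5))
  nd <- normalize_attack_direction(ds)
  h1 <- ds$frames$half == 1L
  expect_equal(nd$frames$x_m[h1], ds$frames$x_m[h1])
  expect_equal(nd$frames$x_m[!h1], -ds$frames$x_m[!h1])
  expect_equal(nd$frames$y_m[!h1], -ds$frames$y_m[!h1])
  expect_true(attr(nd, "normalized"))
  back <- normalize_attack_direction(nd)
  expect_equal(back$frames, ds$frames, ignore_attr = TRUE)
  expect_false(attr(back, "normalized"))
})

test_that("zone assignment follows the half-open rule on the default grid", {
  g <- zone_grid()
  expect_identical(assign_zone(0, 0, g)$zone, "MO-C")
  expect_identical(assign_zone(-52.5, -34, g)$zone, "D-L")
  # upper pitch boundary closed
  expect_identical(assign_zone(52.5, 34, g)$zone, "O-R")
  # interior edge belongs to the upper cell
  expect_identical(assign_zone(-26.25, -20.4, g)$zone, "MD-CL")
  # out-of-bounds points are clamped and flagged
  z <- assign_zone(60, -40, g)
  expect_identical(z$zone, "O-L")
  expect_true(z$clamped)
})

test_that("zones tile the pitch: one code per point, areas sum to pitch area", {
  g <- zone_grid(105, 68)
  set.seed(7)
  x <- stats::runif(500, -52.5, 52.5); y <- stats::runif(500, -34, 34)
  z <- assign_zone(x, y, g)
  expect_false(any(is.na(z$zone)))
  expect_false(any(z$clamped))
  expect_lte(length(unique(z$zone)), 20L)
  areas <- outer(diff(g$longitudinal_edges), diff(g$lateral_edges))
  expect_equal(sum(areas), 105 * 68)
  # each of the 20 codes is reachable
  cx <- (g$longitudinal_edges[-1] + g$longitudinal_edges[-5]) / 2
  cy <- (g$lateral_edges[-1] + g$lateral_edges[-6]) / 2
  centers <- expand.grid(x = cx, y = cy)
  expect_identical(length(unique(assign_zone(centers$x, centers$y, g)$zone)), 20L)
})

test_that("orient_to_attack keeps or flips the lateral axis as configured", {
  o <- orient_to_attack(10, 5, -1, lateral_frame = "attacking")
  expect_equal(c(o$x, o$y), c(-10, -5))
  o2 <- orient_to_attack(10, 5, -1, lateral_frame = "absolute")
  expect_equal(c(o2$x, o2$y), c(-10, 5))
  o3 <- orient_to_attack(10, 5, 1)
  expect_equal(c(o3$x, o3$y), c(10, 5))
})
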