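test_that("write/read round-trip reproduces a dataset exactly", {
  ds <- toy_dataset(n_frames = 3L)
  csv <- withr::local_tempfile(fileext = ".csv")
  yml <- withr::local_tempfile(fileext = ".yml")
  write_match_metadata(ds$metadata, yml)

  # full precision
  write_tracking(ds, csv, quantize = NULL)
  back <- read_tracking(csv, yml)
  expect_equal(back$frames, ds$frames, ignore_attr = TRUE)

  # positions already on the 0.01 m lattice survive quantized writing
  ds2 <- ds
  ds2$frames$x_m <- round(ds2$frames$x_m, 2)
  ds2$frames$y_m <- round(ds2$frames$y_m, 2)
  write_tracking(ds2, csv, quantize = 0.01)
  back2 <- read_tracking(csv, yml)
  expect_equal(back2$frames$x_m, ds2$frames$x_m)
  expect_equal(back2$frames$y_m, ds2$frames$y_m)

  # quantization rounds to the nearest centimeter
  ds3 <- ds
  ds3$frames$x_m[2] <- 12.345
  write_tracking(ds3, csv, quantize = 0.01)
  expect_equal(read_tracking(csv, yml)$frames$x_m[2], 12.35)
})

test_that("metadata YAML round-trips and invalid metadata is rejected", {
  meta <- match_metadata(pitch_length = 100, pitch_width = 64, frame_rate = 10)
  yml <- withr::local_tempfile(fileext = ".yml")
  write_match_metadata(meta, yml)
  back <- read_match_metadata(yml)
  expect_equal(back$pitch_length, 100)
  expect_equal(back$attack_direction$home[["2"]], -1)

  expect_error(match_metadata(pitch_length = -1), class = "teamsync_config_error")
  expect_error(match_metadata(home_goal_center = c(52.5, 0)),
               class = "teamsync_config_error")
  expect_error(
    match_metadata(attack_direction = list(home = c("1" = 1, "2" = 1),
                                           away = c("1" = -1, "2" = 1))),
    class = "teamsync_config_error"
  )
})

test_that("schema, integrity and roster violations are reported with locations", {
  ds <- toy_dataset(n_frames = 2L)
  csv <- withr::local_tempfile(fileext = ".csv")
  yml <- withr::local_tempfile(fileext = ".yml")
  write_match_metadata(ds$metadata, yml)

  # missing possession column
  broken <- ds$frames[setdiff(names(ds$frames), "possession")]
  readr::write_csv(broken, csv)
  expect_error(read_tracking(csv, yml), regexp = "possession",
               class = "teamsync_schema_error")

  # a frame with 10 away players, citing the frame index
  drop_row <- which(ds$frames$team == "away" & ds$frames$frame == 2L)[1]
  expect_error(
    match_dataset(ds$frames[-drop_row, ], ds$metadata),
    regexp = "11 away players.*frame 2", class = "teamsync_roster_error"
  )

  # duplicated player row
  dup <- dplyr::bind_rows(ds$frames, ds$frames[ds$frames$object_type == "player", ][1, ])
  dup <- dplyr::arrange(dup, half, frame)
  expect_error(match_dataset(dup, ds$metadata), class = "teamsync_integrity_error")

  # inconsistent per-frame possession flag
  bad <- ds$frames
  bad$possession[5] <- "away"
  expect_error(match_dataset(bad, ds$metadata), class = "teamsync_integrity_error")
})

test_that("an empty dataset writes a header-only file", {
  ds <- toy_dataset(1L)
  empty <- match_dataset(ds$frames[0, ], ds$metadata, validate = FALSE)
  csv <- withr::local_tempfile(fileext = ".csv")
  yml <- withr::local_tempfile(fileext = ".yml")
  write_match_metadata(ds$metadata, yml)
  write_tracking(empty, csv)
  expect_identical(length(readr::read_lines(csv)), 1L)
  expect_identical(nrow(read_tracking(csv, yml)$frames), 0L)
})

test_that("filter_frames selects by status, role and half, and is idempotent", {
  theta <- matrix(1, 15L, 11L)
  ds <- angles_dataset(
    theta,
    status = c(rep("alive", 10), rep("dead", 5)),
    possession = rep(c("home", "away", "home"), each = 5L)
  )
  alive <- filter_frames(ds, status = "alive")
  expect_identical(nrow(frame_index(alive)), 10L)

  wb <- filter_frames(ds, role_for_team = "with_ball", team = "home")
  expect_true(all(frame_index(wb)$possession == "home"))

  again <- filter_frames(wb, role_for_team = "with_ball", team = "home")
  expect_equal(again$frames, wb$frames, ignore_attr = TRUE)

  # no-op selectors are the identity
  expect_equal(filter_frames(ds)$frames, ds$frames, ignore_attr = TRUE)

  expect_error(filter_frames(ds, role_for_team = "with_ball"),
               class = "teamsync_config_error")
})

test_that("with/without-ball frames partition the alive frames", {
  ds <- angles_dataset(matrix(1, 9L, 11L),
                       status = rep(c("alive", "alive", "dead"), 3L),
                       possession = rep(c("home", "away", "home"), each = 3L))
  alive <- filter_frames(ds, status = "alive")
  wb <- filter_frames(alive, role_for_team = "with_ball", team = "home")
  wob <- filter_frames(alive, role_for_team = "without_ball", team = "home")
  key <- function(d) paste(frame_index(d)$half, frame_index(d)$frame)
  expect_length(intersect(key(wb), key(wob)), 0L)
  expect_setequal(c(key(wb), key(wob)), key(alive))
})
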