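#' Build the synchrony regression table
#'
#' Assembles one row per (frame, team) combining the order parameter with the
#' covariates used in the mixed-model analysis: team, possession role, half,
#' and the lateral/longitudinal zone of the ball. Only alive frames enter.
#' Zones are assigned from the ball position oriented into the analysed team's
#' attacked-goal frame (see [orient_to_attack()]), so `"O"` always means the
#' band nearest the goal that team is attacking; on datasets that have not
#' been through [normalize_attack_direction()] the per-half attack direction
#' from the metadata is used.
#'
#' Reference levels are chosen so coefficient signs read naturally: team
#' `away`, role `with_ball`, longitudinal zone `D`, lateral zone `L`.
#'
#' @param sync A [kuramoto()] output covering one or both teams.
#' @param ds The source [match_dataset()].
#' @param grid A [zone_grid()].
#' @param lateral_frame `"attacking"` or `"absolute"` (see
#'   [orient_to_attack()]).
#' @param quiet Suppress the dropped-frame message.
#' @return A tibble with columns `half`, `frame`, `team`, `r_prime`, `role`,
#'   `lateral_zone`, `longitudinal_zone`, `zone`. Frames with undefined
#'   `r_prime` are dropped with a reported count.
#' @export
build_model_table <- function(sync, ds,
                              grid = zone_grid(ds$metadata$pitch_length,
                                               ds$metadata$pitch_width),
                              lateral_frame = "attacking",
                              quiet = FALSE) {
  idx <- frame_index(ds)
  d <- dplyr::inner_join(sync, idx, by = c("half", "frame"))
  d <- d[d$ball_status == "alive", ]
  n_undef <- sum(is.na(d$r_prime))
  if (n_undef > 0) {
    if (!quiet) message(sprintf("dropping %d frame-team rows with undefined r'", n_undef))
    d <- d[!is.na(d$r_prime), ]
  }
  dirs <- effective_attack_direction(ds, d$team, d$half)
  o <- orient_to_attack(d$ball_x, d$ball_y, dirs, lateral_frame = lateral_frame)
  z <- assign_zone(o$x, o$y, grid)
  tibble::tibble(
    half = factor(d$half, levels = c(1L, 2L)),
    frame = d$frame,
    team = factor(d$team, levels = c("away", "home")),
    r_prime = d$r_prime,
    role = factor(ifelse(d$possession == d$team, "with_ball", "without_ball"),
                  levels = c("with_ball", "without_ball")),
    lateral_zone = z$lateral_zone,
    longitudinal_zone = z$longitudinal_zone,
    zone = z$zone
  )
}

effective_attack_direction <- function(ds, team, half) {
  meta <- ds$metadata
  normalized <- isTRUE(attr(ds, "normalized"))
  vapply(seq_along(team), function(i) {
    d <- meta$attack_direction[[team[i]]]
    if (normalized) d[["1"]] else d[[as.character(half[i])]]
  }, numeric(1))
}

#' Fit a linear mixed-effects model of synchrony
#'
#' Fits, by maximum likelihood, a linear mixed model of the per-frame order
#' parameter with the requested fixed effects (plus optional pairwise
#' interactions) and a random intercept by half, and runs a likelihood-ratio
#' chi-square test for every fixed term against the model with that term
#' removed (a main effect is removed together with any interaction containing
#' it, keeping the null nested and well-formed).
#'
#' Frames are treated as independent observations; serial correlation of the
#' order parameter is not modelled and p-values should be read accordingly.
#'
#' @param table A [build_model_table()] tibble.
#' @param fixed Character vector of fixed-effect columns, a subset of
#'   `c("team", "role", "lateral_zone", "longitudinal_zone")`.
#' @param interactions `"none"`, `"all-pairs"`, or a character vector of
#'   interaction terms like `"team:role"`.
#' @param lrt Run the likelihood-ratio tests (default `TRUE`).
#' @return An object of class `teamsync_lmm`: a list with `fit` (the `lmerMod`
#'   or `lm` fit), `coefficients` (tibble: term, estimate, se), `lrt` (tibble:
#'   term, chisq, df, p) and `formula`.
#' @export
fit_lmm <- function(table, fixed = c("team", "role"),
                    interactions = "none", lrt = TRUE) {
  missing_cols <- setdiff(fixed, names(table))
  if (length(missing_cols)) {
    stop(sprintf("fixed effect(s) not present in the model table: %s",
                 paste(missing_cols, collapse = ", ")))
  }
  for (f in fixed) {
    if (length(unique(table[[f]][!is.na(table[[f]])])) < 2L) {
      stop(errorCondition(
        sprintf("fixed effect '%s' has fewer than 2 observed levels", f),
        class = c("teamsync_design_error", "error")
      ))
    }
  }
  if (identical(interactions, "all-pairs")) {
    interactions <- if (length(fixed) >= 2) {
      utils::combn(fixed, 2, FUN = paste, collapse = ":")
    } else character()
  } else if (identical(interactions, "none")) {
    interactions <- character()
  }
  terms_all <- c(fixed, interactions)
  rhs <- paste(c(terms_all, "(1 | half)"), collapse = " + ")
  form <- stats::as.formula(paste("r_prime ~", rhs))

  # constant response: nothing to estimate, report the degenerate result
  if (stats::var(table$r_prime) == 0) {
    mm <- stats::model.matrix(
      stats::as.formula(paste("~", paste(terms_all, collapse = " + "))), table)
    co <- tibble::tibble(term = colnames(mm),
                         estimate = c(table$r_prime[1], rep(0, ncol(mm) - 1L)),
                         se = 0)
    lrt_tab <- tibble::tibble(term = terms_all, chisq = 0,
                              df = NA_integer_, p = 1)
    return(structure(list(fit = NULL, coefficients = co, lrt = lrt_tab,
                          formula = form),
                     class = "teamsync_lmm"))
  }

  check_design_rank(table, terms_all)
  fit <- lme4::lmer(form, data = table, REML = FALSE)
  co <- summary(fit)$coefficients
  coefficients <- tibble::tibble(term = rownames(co),
                                 estimate = co[, "Estimate"],
                                 se = co[, "Std. Error"])
  lrt_tab <- NULL
  if (lrt) {
    lrt_tab <- dplyr::bind_rows(lapply(terms_all, function(tm) {
      drop_terms <- if (tm %in% fixed) {
        c(tm, interactions[vapply(strsplit(interactions, ":"),
                                  function(p) tm %in% p, logical(1))])
      } else tm
      null_terms <- setdiff(terms_all, drop_terms)
      null_rhs <- paste(c(null_terms, "(1 | half)"), collapse = " + ")
      null_form <- stats::as.formula(paste("r_prime ~", null_rhs))
      null_fit <- lme4::lmer(null_form, data = table, REML = FALSE)
      chisq <- max(0, 2 * (as.numeric(stats::logLik(fit)) -
                             as.numeric(stats::logLik(null_fit))))
      df <- attr(stats::logLik(fit), "df") - attr(stats::logLik(null_fit), "df")
      tibble::tibble(term = tm, chisq = chisq, df = df,
                     p = stats::pchisq(chisq, df, lower.tail = FALSE))
    }))
  }
  structure(list(fit = fit, coefficients = coefficients, lrt = lrt_tab,
                 formula = form),
            class = "teamsync_lmm")
}

check_design_rank <- function(table, terms_all) {
  mm <- stats::model.matrix(
    stats::as.formula(paste("~", paste(terms_all, collapse = " + "))), table)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1L):ncol(mm)]]
    stop(errorCondition(
      sprintf("design matrix is rank deficient; collinear term(s): %s",
              paste(dropped, collapse = ", ")),
      class = c("teamsync_design_error", "error")
    ))
  }
  invisible(TRUE)
}

#' @export
print.teamsync_lmm <- function(x, ...) {
  cat("<teamsync_lmm>", deparse(x$formula), "\n\nFixed effects:\n")
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 4)
  if (!is.null(x$lrt)) {
    cat("\nLikelihood-ratio tests (term vs model without it):\n")
    print(as.data.frame(x$lrt), row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write a fitted synchrony model to CSV
#'
#' @param model A [fit_lmm()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lmm_results <- function(model, path) {
  co <- model$coefficients
  co$chisq <- NA_real_; co$df <- NA_integer_; co$p <- NA_real_
  if (!is.null(model$lrt)) {
    lrt <- model$lrt
    lrt$estimate <- NA_real_; lrt$se <- NA_real_
    co <- dplyr::bind_rows(co, lrt[names(co)])
  }
  readr::write_csv(co, path, progress = FALSE)
  invisible(path)
}

#' Simulate a synchrony table from the mixed-model class
#'
#' Generates a regression table directly from the linear-mixed-model data
#' class fitted by [fit_lmm()]: per-frame `r_prime` values composed of an
#' intercept, additive team and role effects, a random intercept per half and
#' Gaussian residual noise. Possession (hence role) alternates in geometric
#' segments so both roles occur in both halves. This is the generator for
#' parameter-recovery and type-I-error calibration experiments, where the
#' truth must live on the model's own scale.
#'
#' @param n_frames Total frames (split evenly over 2 halves).
#' @param intercept Baseline `r_prime` for the reference cell
#'   (away, with_ball).
#' @param team_effect Additive effect of `team == "home"`.
#' @param role_effect Additive effect of `role == "without_ball"`.
#' @param half_sd SD of the by-half random intercept.
#' @param sigma Residual SD.
#' @param switch_prob Per-frame possession switch probability.
#' @return A tibble shaped like [build_model_table()] output (without zone
#'   columns).
#' @export
simulate_model_table <- function(n_frames = 20000L, intercept = 0.75,
                                 team_effect = 0, role_effect = 0.15,
                                 half_sd = 0.02, sigma = 0.1,
                                 switch_prob = 0.01) {
  n_half <- ceiling(n_frames / 2)
  half <- rep(c(1L, 2L), times = c(n_half, n_frames - n_half))
  switches <- stats::rbinom(n_frames, 1L, switch_prob)
  possession <- c("home", "away")[1L + cumsum(switches) %% 2L]
  b_half <- stats::rnorm(2L, 0, half_sd)
  per_team <- lapply(c("away", "home"), function(tm) {
    role <- ifelse(possession == tm, "with_ball", "without_ball")
    tibble::tibble(
      half = factor(half, levels = c(1L, 2L)),
      frame = seq_len(n_frames),
      team = factor(tm, levels = c("away", "home")),
      role = factor(role, levels = c("with_ball", "without_ball")),
      r_prime = intercept +
        team_effect * (tm == "home") +
        role_effect * (role == "without_ball") +
        b_half[half] +
        stats::rnorm(n_frames, 0, sigma)
    )
  })
  dplyr::bind_rows(per_team)
}
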