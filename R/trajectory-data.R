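#' Extract change points from a trial
#'
#' A change point is a reversal in the sign of the shooter's vertical
#' joystick input between consecutive recorded steps, with both magnitudes
#' above a dead-zone threshold (inputs near zero are treated as jitter, not
#' direction). The first recorded step is never a change point.
#'
#' @param trial A `ps_trial`.
#' @param dead_zone Minimum `|u|` on both sides of a flip. Default `0.2`.
#' @return Integer vector of step indices `t` at which the new direction is
#'   first applied (positions into the trial's recorded `t` series).
#' @export
extract_changepoints <- function(trial, dead_zone = 0.2) {
  u <- trial$states$puck_u
  if (all(u == 0)) {
    warning("all-zero joystick series: no change points")
    return(integer(0))
  }
  n <- length(u)
  if (n < 3L) return(integer(0))
  prev <- u[seq(2L, n - 1L)] # row 1 is step 0 with u = 0, never a change point
  nxt <- u[seq(3L, n)]
  flip <- sign(prev) * sign(nxt) < 0 &
    abs(prev) >= dead_zone & abs(nxt) >= dead_zone
  as.integer(trial$states$t[seq(3L, n)][flip])
}

#' Build the model design matrix from trials
#'
#' One labelled row per timestep (from the second recorded step onward, since
#' velocities are first differences of positions). The seven state predictors
#' are the puck's x and y positions, the bar's y position, both vertical
#' velocities, the time since the last change point (as a fraction of trial
#' length, resetting to `1/trial_length` on the step after a change point),
#' and the per-opponent experience ordinal in `[0, 1]`; opponent identity
#' `omega` enters as an eighth, unstandardised input. The binary action label
#' `a` marks timesteps at which the shooter changes direction on the *next*
#' step; `win` is the trial outcome, shared by every row of the trial.
#'
#' Continuous predictors are standardised per participant (mean 0, sd 1) so
#' that kernel length scales are comparable across inputs; the scaling used
#' is attached as `attr(, "scaling")`.
#'
#' @param trials A list of `ps_trial` (or a `ps_dataset`).
#' @param dead_zone Change-point dead zone, see [extract_changepoints()].
#' @param standardize `"participant"` (default; also `TRUE`) standardises the
#'   continuous predictors within each participant, the right scaling for
#'   per-participant policy models; `"global"` standardises across the whole
#'   dataset, preserving cross-participant differences in positioning and so
#'   appropriate for value models pooled over participants; `"none"` (also
#'   `FALSE`) leaves raw screen units.
#' @return A data.frame with the seven predictors, `omega`, `a`, `win`,
#'   `participant_id`, `trial_id`, `opponent_id`, `trial_index`, and `t`.
#' @export
build_design <- function(trials, dead_zone = 0.2,
                         standardize = c("participant", "global", "none")) {
  if (isTRUE(standardize)) standardize <- "participant"
  if (isFALSE(standardize)) standardize <- "none"
  standardize <- match.arg(standardize)
  if (inherits(trials, "ps_dataset")) trials <- trials$trials
  if (inherits(trials, "ps_trial")) trials <- list(trials)
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    st <- tr$states
    n <- nrow(st)
    if (n < 2L) stop("trials need at least 2 recorded steps")
    n_total <- max(st$t) # trial length in steps
    u <- st$puck_u
    # change-point flags per row: row j is a change point if sign flipped there
    flip <- c(FALSE, FALSE, sign(u[seq(3L, n)]) * sign(u[seq(2L, n - 1L)]) < 0 &
                abs(u[seq(3L, n)]) >= dead_zone & abs(u[seq(2L, n - 1L)]) >= dead_zone)
    # time since last change point, counted in steps then normalised
    last_cp <- 0L
    tslc <- numeric(n)
    for (j in seq_len(n)) {
      if (flip[j]) last_cp <- st$t[j]
      tslc[j] <- st$t[j] - last_cp
    }
    keep <- seq(2L, n) # velocities need a predecessor
    flip_next <- c(flip[-1], FALSE) # does a change point occur at the next step?
    a <- flip_next[keep]
    data.frame(
      puck_x = st$puck_x[keep],
      puck_y = st$puck_y[keep],
      bar_y = st$bar_y[keep],
      puck_vy = st$puck_y[keep] - st$puck_y[keep - 1L],
      bar_vy = st$bar_y[keep] - st$bar_y[keep - 1L],
      time_since_last_cp = tslc[keep] / n_total,
      opponent_experience = NA_real_, # filled below from trial counters
      omega = tr$opponent_id,
      a = as.integer(a),
      win = as.integer(tr$outcome == "win"),
      participant_id = tr$participant_id,
      trial_id = i,
      opponent_id = tr$opponent_id,
      trial_index = tr$trial_index,
      t = st$t[keep],
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  # opponent experience: per participant x opponent, ordinal scaled to [0, 1]
  key <- paste(df$participant_id, df$opponent_id)
  for (k in unique(key)) {
    sel <- key == k
    idx <- df$trial_index[sel]
    rng <- range(idx)
    df$opponent_experience[sel] <- if (rng[2] > rng[1])
      (idx - rng[1]) / (rng[2] - rng[1]) else 0
  }
  scaling <- NULL
  if (standardize != "none") {
    vars <- state_predictors()
    scaling <- list()
    groups <- if (standardize == "participant")
      unique(df$participant_id) else "(all)"
    for (p in groups) {
      sel <- if (standardize == "participant") df$participant_id == p
        else rep(TRUE, nrow(df))
      mu <- vapply(vars, function(v) mean(df[[v]][sel]), 0)
      sg <- vapply(vars, function(v) sd(df[[v]][sel]), 0)
      sg[sg < 1e-12] <- 1 # constant predictors pass through centred
      for (v in vars) df[[v]][sel] <- (df[[v]][sel] - mu[[v]]) / sg[[v]]
      scaling[[p]] <- list(mean = mu, sd = sg)
    }
  }
  attr(df, "scaling") <- scaling
  df
}

#' Names of the seven state predictors
#' @return Character vector of predictor column names (excluding `omega`).
#' @export
state_predictors <- function() {
  c("puck_x", "puck_y", "bar_y", "puck_vy", "bar_vy",
    "time_since_last_cp", "opponent_experience")
}

#' Train/test split at the timepoint level
#'
#' A uniform random split over rows (not trials), matching the evaluation
#' protocol of the policy and value models; rows within a trial are treated
#' as independent given the state.
#'
#' @param rows A design data.frame from [build_design()].
#' @param fraction Training fraction in `(0, 1)`. Default `0.8`.
#' @param seed Integer seed.
#' @return A list with `train` and `test` data.frames (disjoint, exhaustive;
#'   `round(n * fraction)` training rows).
#' @export
split_train_test <- function(rows, fraction = 0.8, seed = 1L) {
  n <- nrow(rows)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must be strictly inside (0, 1)")
  n_train <- round(n * fraction)
  if (n_train < 1 || n_train >= n)
    stop("degenerate split: both parts need at least one row")
  idx <- withr::with_seed(as.integer(seed), sample.int(n, n_train))
  list(train = rows[idx, , drop = FALSE],
       test = rows[-idx, , drop = FALSE])
}
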