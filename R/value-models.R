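#' Empirical action-value model
#'
#' A GP probit classifier over the seven state predictors, opponent
#' identity, and the observed binary action (did the shooter change
#' direction at the next step), predicting whether the shooter ultimately
#' won the trial. This is the empirical `Q(a | s, omega)` under both
#' players' observed strategies.
#'
#' @param design A [build_design()] data.frame (with `a` and `win` columns).
#' @param ... Passed to [fit_svgp()].
#' @return An `empirical_q` object wrapping the fitted `svgp`.
#' @export
fit_empirical_q <- function(design, ...) {
  cols <- c(state_predictors(), "omega", "a")
  X <- as.matrix(design[, cols])
  fit <- fit_svgp(X, design$win, ...)
  structure(list(svgp = fit, inputs = cols), class = "empirical_q")
}

#' @export
predict.empirical_q <- function(object, newdata, a = NULL, ...) {
  nd <- newdata[, setdiff(object$inputs, "a"), drop = FALSE]
  nd$a <- if (is.null(a)) newdata$a else a
  predict(object$svgp, nd[, object$inputs, drop = FALSE])
}

#' Final-move expected-value model
#'
#' The value of changing direction a final time and travelling in a straight
#' line thereafter, estimated as a stopping-problem value: one GP probit
#' classifier per opponent condition, trained only on the state at the final
#' change point of each trial, with the trial's win/loss as the label.
#' Trials without any change point are excluded from fitting (their count is
#' recorded); they still count toward win-rate denominators downstream.
#'
#' @param design A [build_design()] data.frame.
#' @param ... Passed to [fit_svgp()].
#' @return A `final_move_ev` object: one fitted `svgp` per `opponent_id`,
#'   plus the per-trial final-move table and the number of excluded trials.
#' @export
fit_final_move_ev <- function(design, ...) {
  fm <- final_move_rows(design)
  n_all <- length(unique(design$trial_id))
  n_excluded <- n_all - length(unique(fm$trial_id))
  if (n_excluded > 0)
    message(n_excluded, " trial(s) without a change point excluded from final-move fitting")
  models <- list()
  for (om in sort(unique(fm$opponent_id))) {
    rows <- fm[fm$opponent_id == om, , drop = FALSE]
    if (length(unique(rows$win)) < 2L)
      stop("opponent stratum ", om, " has single-class outcomes; cannot fit EV model")
    X <- as.matrix(rows[, state_predictors()])
    models[[as.character(om)]] <- fit_svgp(X, rows$win, ...)
  }
  structure(list(models = models, final_moves = fm, n_excluded = n_excluded),
            class = "final_move_ev")
}

# Rows of the design at each trial's final change point (the decision
# timepoint whose action label marks the last direction change).
final_move_rows <- function(design) {
  dt <- data.table::as.data.table(design)
  fm <- dt[a == 1L, .SD[which.max(t)], by = trial_id]
  as.data.frame(fm)
}

#' Counterfactual final-move EV at every timestep
#'
#' Evaluates the opponent-matched final-move EV model at each design row:
#' the value of making one's final move *now*, as a function of time in the
#' trial.
#'
#' @param object A [fit_final_move_ev()] model.
#' @param design Design rows to evaluate.
#' @return The design keys with an `ev` column.
#' @export
ev_curves <- function(object, design) {
  stopifnot(inherits(object, "final_move_ev"))
  ev <- rep(NA_real_, nrow(design))
  for (om in names(object$models)) {
    sel <- design$opponent_id == as.integer(om)
    if (!any(sel)) next
    ev[sel] <- predict(object$models[[om]],
                       design[sel, state_predictors(), drop = FALSE])$prob
  }
  if (anyNA(ev)) stop("design contains opponent conditions with no fitted model")
  data.frame(participant_id = design$participant_id,
             trial_id = design$trial_id,
             opponent_id = design$opponent_id,
             t = design$t, win = design$win, ev = ev,
             stringsAsFactors = FALSE)
}

#' Final-move timing analysis
#'
#' For each trial, the counterfactual EV curve is evaluated at every
#' timestep; the optimal final-move time `t_opt` is the curve's argmax
#' (earliest step on ties) and the observed final move `t_move` is the
#' trial's last change point. The timing deviation `|t_move - t_opt|` is
#' reported in normalised time (fraction of the trial's steps).
#'
#' @param object A [fit_final_move_ev()] model.
#' @param design A [build_design()] data.frame covering the trials to score.
#' @return A `timing_result`: `trials` (per-trial `t_move`, `t_opt`,
#'   `deviation`, `ev_at_move`, `ev_trial_mean`, `ev_late_mean`, `win`),
#'   `participants` (per-participant, per-opponent means and win rates), and
#'   `curves` (per-timestep EV).
#' @export
timing_analysis <- function(object, design) {
  curves <- ev_curves(object, design)
  fm <- object$final_moves
  fm_in <- final_move_rows(design)
  cv <- data.table::as.data.table(curves)
  per_trial <- cv[, {
    i_opt <- which.max(ev) # which.max takes the earliest maximum
    n_steps <- max(t)
    list(participant_id = participant_id[1],
         opponent_id = opponent_id[1],
         win = win[1],
         t_opt = t[i_opt],
         ev_trial_mean = mean(ev),
         ev_late_mean = mean(ev[t > 0.5 * n_steps]),
         n_steps = n_steps)
  }, by = trial_id]
  fmdt <- data.table::as.data.table(
    fm_in[, c("trial_id", "t")])
  data.table::setnames(fmdt, "t", "t_move")
  per_trial <- merge(per_trial, fmdt, by = "trial_id", all.x = TRUE)
  ev_at <- cv[per_trial, on = c("trial_id", t = "t_move"), ev]
  per_trial$ev_at_move <- ev_at
  per_trial$deviation <- abs(per_trial$t_move - per_trial$t_opt) / per_trial$n_steps
  pt <- as.data.frame(per_trial)
  parts <- data.table::as.data.table(pt)[, .(
    win_rate = mean(win),
    mean_deviation = mean(deviation, na.rm = TRUE),
    mean_ev_at_move = mean(ev_at_move, na.rm = TRUE),
    mean_ev_trial = mean(ev_trial_mean),
    mean_ev_late = mean(ev_late_mean),
    timing_gain = mean(ev_at_move - ev_trial_mean, na.rm = TRUE),
    n_trials = .N
  ), by = c("participant_id", "opponent_id")]
  structure(list(trials = pt, participants = as.data.frame(parts),
                 curves = curves),
            class = "timing_result")
}

#' @export
print.timing_result <- function(x, ...) {
  cat("Final-move timing analysis\n")
  print(x$participants, digits = 3)
  invisible(x)
}

#' Positioning vs timing hypothesis comparison
#'
#' Contrasts the top and bottom participants by overall win rate with two
#' statistics on the same win-probability scale, so the data decide which
#' skill account holds: the *positioning* statistic (H1) is the top-bottom
#' difference in mean late-trial EV (better players occupy higher-value
#' states), and the *timing* statistic (H2) is the top-bottom difference in
#' timing gain, the mean excess of EV at the chosen final move over the
#' trial's average EV (better players place their final moves in fleeting
#' high-value moments).
#'
#' @param timing A [timing_analysis()] result (at least 2 participants with
#'   differing win rates).
#' @return A `hypothesis_report`: both statistics, the participants
#'   compared, and which hypothesis the data favour (`"H1"`, `"H2"`, or
#'   `"neither"` when both are negligible).
#' @export
hypothesis_comparison <- function(timing) {
  stopifnot(inherits(timing, "timing_result"))
  overall <- data.table::as.data.table(timing$trials)[, .(
    win_rate = mean(win),
    ev_late = mean(ev_late_mean),
    gain = mean(ev_at_move - ev_trial_mean, na.rm = TRUE)
  ), by = participant_id]
  if (nrow(overall) < 2L) stop("need at least 2 participants")
  if (diff(range(overall$win_rate)) == 0)
    warning("participants have identical win rates; contrast is uninformative")
  top <- overall[which.max(overall$win_rate), ]
  bot <- overall[which.min(overall$win_rate), ]
  h1 <- top$ev_late - bot$ev_late
  h2 <- top$gain - bot$gain
  # differences below ~5 win-probability points are within sampling noise
  # for cohorts of tens of trials per participant
  favoured <- if (max(abs(h1), abs(h2)) < 0.05) "neither"
    else if (abs(h1) > abs(h2)) "H1" else "H2"
  structure(list(
    h1_positioning = h1, h2_timing = h2, favoured = favoured,
    top = top$participant_id, bottom = bot$participant_id,
    top_win_rate = top$win_rate, bottom_win_rate = bot$win_rate
  ), class = "hypothesis_report")
}

#' @export
print.hypothesis_report <- function(x, ...) {
  cat("Positioning (H1) vs timing (H2) comparison\n")
  cat(sprintf("  top scorer %s (win rate %.2f) vs bottom scorer %s (win rate %.2f)\n",
              x$top, x$top_win_rate, x$bottom, x$bottom_win_rate))
  cat(sprintf("  H1 late-trial EV offset:  %+.3f\n", x$h1_positioning))
  cat(sprintf("  H2 timing-gain offset:    %+.3f\n", x$h2_timing))
  cat(sprintf("  data favour: %s\n", x$favoured))
  invisible(x)
}

#' Straight-line shot oracle
#'
#' Kinematic roll-out of the puck dynamics for a shooter who commits to a
#' direction at full joystick and never switches again, against a bar frozen
#' at a fixed height: the shot scores iff the puck's height at the bar's x
#' position clears the bar by more than `bar_half_height + puck_radius`.
#' Used as a brute-force reference for the final-move EV model in degenerate
#' (frozen-goalie) settings.
#'
#' @param puck_x,puck_y Puck position at the moment of the final move.
#' @param bar_y Frozen bar height.
#' @param direction `+1` (up) or `-1` (down).
#' @param cfg A [game_config()].
#' @return Logical: does the straight-line shot score?
#' @export
straight_shot_wins <- function(puck_x, puck_y, bar_y, direction, cfg) {
  steps <- ceiling((cfg$bar_start[1] - puck_x) / cfg$puck_speed - 1e-9)
  if (steps < 0) stop("puck already past the bar")
  y_cross <- clamp(puck_y + direction * cfg$puck_speed * steps,
                   -1 + cfg$puck_radius, 1 - cfg$puck_radius)
  abs(y_cross - bar_y) > cfg$bar_half_height + cfg$puck_radius
}
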