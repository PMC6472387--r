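#' Initial game state
#'
#' @param cfg A [game_config()] object.
#' @return A `ps_state` list: step index `t`, puck position (`puck_x`,
#'   `puck_y`), bar centre `bar_y`, the joystick inputs that produced the
#'   state (`puck_u`, `bar_u`), the bar's speed multiplier `theta`, and the
#'   bar's acceleration streak counter.
#' @export
initial_state <- function(cfg) {
  structure(list(
    t = 0L,
    puck_x = cfg$puck_start[1], puck_y = cfg$puck_start[2],
    bar_y = cfg$bar_start[2],
    puck_u = 0, bar_u = 0,
    theta = 1, accel_streak = 0L
  ), class = "ps_state")
}

check_input <- function(u) {
  if (!is.numeric(u) || length(u) != 1L || is.na(u) || u < -1 || u > 1)
    stop("joystick input must be a single number in [-1, 1]")
  u
}

#' Advance the puck one step
#'
#' The puck moves rightward by exactly `puck_speed` and vertically by
#' `puck_speed * u`; its centre is clamped so the puck stays on screen.
#'
#' @param state A `ps_state`.
#' @param u Shooter joystick input in `[-1, 1]`.
#' @param cfg A [game_config()].
#' @return The updated `ps_state` (puck fields and `t` advanced).
#' @export
step_puck <- function(state, u, cfg) {
  check_input(u)
  state$puck_x <- state$puck_x + cfg$puck_speed
  state$puck_y <- clamp(state$puck_y + cfg$puck_speed * u,
                        -1 + cfg$puck_radius, 1 - cfg$puck_radius)
  state$puck_u <- u
  state$t <- state$t + 1L
  state
}

#' Advance the bar one step
#'
#' Holding near-maximal input (`|u| >= accel_input_threshold`) in an unchanged
#' direction builds an acceleration streak; once the streak reaches
#' `accel_steps_required` the speed multiplier grows by `accel_increment`
#' each step (so it first exceeds 1 on the third qualifying step), and any
#' break in the streak resets it to 1. The vertical step is
#' `bar_speed_factor * theta * puck_speed * u`, clamped so the whole bar
#' stays on screen.
#'
#' @inheritParams step_puck
#' @param u Goalie joystick input in `[-1, 1]`.
#' @return The updated `ps_state` (bar fields; `t` is advanced by
#'   [step_puck()], which callers should apply in the same step).
#' @export
step_bar <- function(state, u, cfg) {
  check_input(u)
  qualifying <- abs(u) >= cfg$accel_input_threshold
  same_dir <- sign(u) == sign(state$bar_u)
  streak <- if (qualifying && (state$accel_streak == 0L || same_dir))
    state$accel_streak + 1L else if (qualifying) 1L else 0L
  theta <- if (streak >= cfg$accel_steps_required)
    state$theta + cfg$accel_increment else 1
  v_bar <- cfg$bar_speed_factor * theta * cfg$puck_speed
  state$bar_y <- clamp(state$bar_y + v_bar * u,
                       -1 + cfg$bar_half_height, 1 - cfg$bar_half_height)
  state$bar_u <- u
  state$theta <- theta
  state$accel_streak <- streak
  state
}

#' Decide the trial outcome at the goal-line crossing
#'
#' The shooter loses if, at the first step where the puck reaches the bar's
#' x position, the puck and bar overlap vertically
#' (`|puck_y - bar_y| <= bar_half_height + puck_radius`); otherwise the
#' shooter wins. This 1-D interval-overlap rule is the package's collision
#' model and is configurable through `bar_half_height` and `puck_radius`.
#'
#' @param trial A `ps_trial` (see [run_trial()]).
#' @param cfg A [game_config()].
#' @return `"win"` or `"loss"` (for the shooter).
#' @export
determine_outcome <- function(trial, cfg) {
  st <- trial$states
  idx <- which(st$puck_x >= cfg$bar_start[1] - 1e-12)
  if (!length(idx)) stop("trial ended before the puck reached the bar")
  i <- idx[1]
  blocked <- abs(st$puck_y[i] - st$bar_y[i]) <=
    cfg$bar_half_height + cfg$puck_radius
  if (blocked) "loss" else "win"
}

#' Simulate one trial of the penalty-shot game
#'
#' Both players move simultaneously: at each step each policy sees the current
#' state and returns a joystick input in `[-1, 1]` (zero-order hold, no
#' sub-step integration). The trial ends early with a loss at the step where
#' the puck first reaches the bar's x position if the two avatars overlap
#' there; otherwise it runs until the puck crosses the goal line, a win.
#'
#' @param shooter_policy,goalie_policy Policy objects from [make_policy()]
#'   (or bare functions `function(state, mem)` returning a scalar input).
#' @param cfg A [game_config()].
#' @param seed Integer seed; the trial is a deterministic function of
#'   `(cfg, policies, seed)`.
#' @param participant_id,opponent_id,trial_index Labels attached to the trial;
#'   `opponent_id` is 0 for the computer goalie and 1 for a human-like goalie.
#' @return A `ps_trial`: list with `states` (one row per recorded timestep,
#'   including step 0), the labels above, `outcome`, and `info` (per-trial
#'   draws the policies chose to expose, e.g. the goalie's guess step).
#' @examples
#' cfg <- game_config()
#' tr <- run_trial(constant_policy(0), constant_policy(0), cfg, seed = 1)
#' tr$outcome  # "loss": both avatars sit at centre, maximal overlap
#' @export
run_trial <- function(shooter_policy, goalie_policy, cfg, seed,
                      participant_id = "p1", opponent_id = 0L,
                      trial_index = 1L) {
  validate_game_config(cfg)
  shooter_policy <- as_policy(shooter_policy)
  goalie_policy <- as_policy(goalie_policy)
  withr::with_seed(as.integer(seed), {
    s_mem <- shooter_policy$init(cfg)
    g_mem <- goalie_policy$init(cfg)
    n <- cfg$n_steps
    rec <- matrix(NA_real_, nrow = n + 1L, ncol = 7L)
    colnames(rec) <- c("t", "puck_x", "puck_y", "bar_y", "puck_u", "bar_u", "theta")
    state <- initial_state(cfg)
    rec[1L, ] <- c(0, state$puck_x, state$puck_y, state$bar_y, 0, 0, 1)
    outcome <- NA_character_
    last <- n + 1L
    for (k in seq_len(n)) {
      s_out <- shooter_policy$step(state, s_mem)
      g_out <- goalie_policy$step(state, g_mem)
      s_mem <- s_out$mem
      g_mem <- g_out$mem
      state <- step_puck(state, s_out$u, cfg)
      state <- step_bar(state, g_out$u, cfg)
      rec[k + 1L, ] <- c(state$t, state$puck_x, state$puck_y, state$bar_y,
                         state$puck_u, state$bar_u, state$theta)
      if (state$puck_x >= cfg$bar_start[1] - 1e-12 &&
          rec[k, "puck_x"] < cfg$bar_start[1] - 1e-12) {
        blocked <- abs(state$puck_y - state$bar_y) <=
          cfg$bar_half_height + cfg$puck_radius
        if (blocked) {
          outcome <- "loss"
          last <- k + 1L
          break
        }
      }
    }
    trial <- structure(list(
      states = as.data.frame(rec[seq_len(last), , drop = FALSE]),
      participant_id = participant_id,
      opponent_id = as.integer(opponent_id),
      trial_index = as.integer(trial_index),
      outcome = NA_character_,
      info = list(shooter = policy_info(s_mem), goalie = policy_info(g_mem),
                  seed = as.integer(seed))
    ), class = "ps_trial")
    trial$outcome <- if (is.na(outcome)) determine_outcome(trial, cfg) else outcome
    trial
  })
}

policy_info <- function(mem) {
  if (is.list(mem) && !is.null(mem$info)) mem$info else NULL
}

#' @export
print.ps_trial <- function(x, ...) {
  cat(sprintf("Penalty-shot trial: participant %s vs opponent %d (trial %d)\n",
              x$participant_id, x$opponent_id, x$trial_index))
  cat(sprintf("  %d recorded timesteps, outcome: %s\n",
              nrow(x$states), x$outcome))
  invisible(x)
}

#' Flatten trials to the tabular serialisation schema
#'
#' One row per timestep with columns `participant_id, opponent_id,
#' trial_index, t, puck_x, puck_y, bar_y, puck_u, bar_u, outcome`.
#'
#' @param trials A `ps_trial` or list of them.
#' @return A data.frame in the schema above.
#' @export
trials_to_df <- function(trials) {
  if (inherits(trials, "ps_trial")) trials <- list(trials)
  out <- lapply(trials, function(tr) {
    st <- tr$states
    data.frame(
      participant_id = tr$participant_id,
      opponent_id = tr$opponent_id,
      trial_index = tr$trial_index,
      t = as.integer(st$t),
      puck_x = st$puck_x, puck_y = st$puck_y, bar_y = st$bar_y,
      puck_u = st$puck_u, bar_u = st$bar_u,
      outcome = tr$outcome,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Write / read trials as CSV
#'
#' Full-precision CSV round trip of the [trials_to_df()] schema.
#'
#' @param trials A list of `ps_trial` objects (or a data.frame already in the
#'   serialisation schema).
#' @param path File path.
#' @return `write_trials_csv` returns `path` invisibly; `read_trials_csv`
#'   returns a list of `ps_trial` objects.
#' @export
write_trials_csv <- function(trials, path) {
  df <- if (is.data.frame(trials)) trials else trials_to_df(trials)
  dt <- data.table::as.data.table(df)
  data.table::fwrite(dt, path) # fwrite preserves full double precision
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  need <- c("participant_id", "opponent_id", "trial_index", "t",
            "puck_x", "puck_y", "bar_y", "puck_u", "bar_u", "outcome")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("trial CSV missing columns: ", paste(missing_cols, collapse = ", "))
  key <- interaction(df$participant_id, df$opponent_id, df$trial_index,
                     drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$t), ]
    structure(list(
      states = data.frame(t = d$t, puck_x = d$puck_x, puck_y = d$puck_y,
                          bar_y = d$bar_y, puck_u = d$puck_u, bar_u = d$bar_u,
                          theta = NA_real_),
      participant_id = as.character(d$participant_id[1]),
      opponent_id = as.integer(d$opponent_id[1]),
      trial_index = as.integer(d$trial_index[1]),
      outcome = as.character(d$outcome[1]),
      info = NULL
    ), class = "ps_trial")
  })
}
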