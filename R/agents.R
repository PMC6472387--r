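#' Policy objects
#'
#' A policy is a pair of functions: `init(cfg)` draws any per-trial randomness
#' and returns a memory object, and `step(state, mem)` maps the current game
#' state (and memory) to `list(u = <input in [-1, 1]>, mem = <updated memory>)`.
#' Memory lists may carry an `info` element, which [run_trial()] copies into
#' the trial record (used by the synthetic agents to expose ground truth).
#'
#' @param step A function `(state, mem) -> list(u, mem)`.
#' @param init A function `(cfg) -> mem`; defaults to no memory.
#' @return A `ps_policy` object.
#' @export
make_policy <- function(step, init = function(cfg) NULL) {
  structure(list(init = init, step = step), class = "ps_policy")
}

as_policy <- function(x) {
  if (inherits(x, "ps_policy")) return(x)
  if (is.function(x)) return(make_policy(function(state, mem) list(u = x(state, mem), mem = mem)))
  stop("a policy must be a ps_policy object or a function(state, mem)")
}

#' @rdname make_policy
#' @param u A fixed input value; `constant_policy(0)` is the frozen goalie
#'   used as a kinematic oracle in the value analyses.
#' @export
constant_policy <- function(u) {
  force(u)
  make_policy(function(state, mem) list(u = u, mem = mem))
}

#' Parameters of the computer goalie's track-then-guess heuristic
#'
#' The goalie tracks the puck's vertical position with a per-trial reaction
#' lag, then at a random late point in the trial commits to a maximal-speed
#' guess in one direction for the remainder. The source task describes this
#' heuristic qualitatively; the lag and onset distributions here are the
#' package's defaults and are configurable.
#'
#' @param reaction_lag_range Integer range (inclusive) of the per-trial
#'   tracking lag, in steps; drawn discrete-uniform. Default `c(3, 12)`.
#' @param guess_onset_range Range of the guess onset as a fraction of the
#'   trial; drawn uniform. Default `c(0.75, 0.9)`.
#' @param guess_direction_prob Probability the committed guess is "up".
#'   Default `0.5`.
#' @param guess_toward_puck_prob If non-`NULL`, overrides
#'   `guess_direction_prob`: the guess points toward the puck's current side
#'   with this probability (used for the human-like goalie parameterisation).
#' @param track_gain Proportional gain of the tracking controller; the input
#'   `clamp(track_gain * (lagged_puck_y - bar_y), -1, 1)` saturates for
#'   errors beyond `1/track_gain`. Default `25`.
#' @return A `goalie_params` list.
#' @export
goalie_params <- function(reaction_lag_range = c(3L, 12L),
                          guess_onset_range = c(0.75, 0.9),
                          guess_direction_prob = 0.5,
                          guess_toward_puck_prob = NULL,
                          track_gain = 25) {
  stopifnot(all(reaction_lag_range >= 0),
            guess_onset_range[1] > 0, guess_onset_range[2] <= 1,
            guess_direction_prob >= 0, guess_direction_prob <= 1)
  structure(list(reaction_lag_range = as.integer(reaction_lag_range),
                 guess_onset_range = guess_onset_range,
                 guess_direction_prob = guess_direction_prob,
                 guess_toward_puck_prob = guess_toward_puck_prob,
                 track_gain = track_gain),
            class = "goalie_params")
}

draw_goalie_trial <- function(params, cfg) {
  lag <- sample(seq(params$reaction_lag_range[1], params$reaction_lag_range[2]), 1L)
  onset <- runif(1, params$guess_onset_range[1], params$guess_onset_range[2])
  list(lag = lag,
       guess_step = as.integer(round(onset * cfg$n_steps)),
       # direction resolved at guess time when it may depend on the puck side
       dir_up = runif(1) < params$guess_direction_prob)
}

#' Track-then-guess goalie policy
#'
#' @param params A [goalie_params()] object.
#' @param draws Optional fixed per-trial draws (`lag`, `guess_step`,
#'   `dir_up`), as produced internally; when `NULL` they are drawn in
#'   `init()` from `params`. Fixing them lets a data generator couple agents
#'   to the goalie's ground truth.
#' @return A `ps_policy`.
#' @export
goalie_policy <- function(params = goalie_params(), draws = NULL) {
  force(params); force(draws)
  make_policy(
    init = function(cfg) {
      d <- if (is.null(draws)) draw_goalie_trial(params, cfg) else draws
      list(history = numeric(0), guess_dir = NA_real_,
           d = d, info = list(goalie_lag = d$lag, goalie_guess_step = d$guess_step))
    },
    step = function(state, mem) {
      mem$history <- c(mem$history, state$puck_y)
      t_now <- state$t # producing input for step t_now + 1
      if (t_now + 1L >= mem$d$guess_step) {
        if (is.na(mem$guess_dir)) {
          up <- if (!is.null(params$guess_toward_puck_prob)) {
            toward <- state$puck_y >= state$bar_y
            if (runif(1) < params$guess_toward_puck_prob) toward else !toward
          } else mem$d$dir_up
          mem$guess_dir <- if (up) 1 else -1
          mem$info$goalie_guess_dir <- mem$guess_dir
        }
        return(list(u = mem$guess_dir, mem = mem))
      }
      # lagged observation; before `lag` steps have elapsed the goalie still
      # sees the puck's starting height
      i <- max(1L, length(mem$history) - mem$d$lag)
      target <- mem$history[i]
      u <- clamp(params$track_gain * (target - state$bar_y), -1, 1)
      list(u = u, mem = mem)
    }
  )
}

#' Parameters of the parametric synthetic shooter
#'
#' The synthetic shooter holds its joystick at `u_scale` in its current
#' direction and at each step flips direction with probability
#' `pnorm(f_true)`, where the ground-truth latent
#' `f_true = base_switch_logit + sum(state_weights * s) + opponent_effect * omega`
#' is linear in the raw game-state predictors. A linear latent keeps the
#' generative gradients known exactly, which the sensitivity tests exploit.
#'
#' Defaults were fixed once so that, with the default goalie and game
#' configuration, direction changes occur at roughly 4.6% of timepoints, the
#' change-point sparsity of the task this package emulates: the hazard rises
#' with time since the last change point and with progress across the screen,
#' and is modestly higher against the human-like opponent.
#'
#' @param base_switch_logit Probit-scale intercept of the switch hazard.
#' @param state_weights Named weights on the raw-scale predictors
#'   `puck_x, puck_y, bar_y, puck_vy, bar_vy, time_since_last_cp,
#'   opponent_experience` (velocities in screen units per step).
#' @param opponent_effect Probit-scale shift when `omega = 1`.
#' @param u_scale Joystick magnitude held between flips, in `(0, 1]`.
#'   Values below 1 model timid vertical positioning.
#' @param final_move `"none"` for a pure hazard policy, or `"timed"` to
#'   commit to a final direction change at a chosen step and never switch
#'   afterwards.
#' @param skill For `final_move = "timed"`: probability in `[0, 1]` that the
#'   final move is timed reactively (a few steps after the goalie commits to
#'   its guess, aimed away from the goalie) rather than placed uniformly at
#'   random in the trial.
#' @param react_delay Mean delay, in steps, between the goalie's guess and a
#'   reactively timed final move. Default `3`.
#' @return A `shooter_params` list.
#' @export
shooter_params <- function(base_switch_logit = -11,
                           state_weights = c(puck_x = 2, puck_y = -1,
                                             bar_y = 0, puck_vy = 0, bar_vy = 0,
                                             time_since_last_cp = 60,
                                             opponent_experience = 0),
                           opponent_effect = 1.5,
                           u_scale = 1,
                           final_move = c("timed", "none"),
                           skill = 0.7,
                           react_delay = 3) {
  final_move <- match.arg(final_move)
  nm <- c("puck_x", "puck_y", "bar_y", "puck_vy", "bar_vy",
          "time_since_last_cp", "opponent_experience")
  w <- setNames(numeric(7), nm)
  w[names(state_weights)] <- state_weights
  stopifnot(u_scale > 0, u_scale <= 1, skill >= 0, skill <= 1)
  structure(list(base_switch_logit = base_switch_logit, state_weights = w,
                 opponent_effect = opponent_effect, u_scale = u_scale,
                 final_move = final_move, skill = skill,
                 react_delay = react_delay),
            class = "shooter_params")
}

shooter_latent <- function(params, feats, omega) {
  params$base_switch_logit + sum(params$state_weights * feats) +
    params$opponent_effect * omega
}

#' Synthetic shooter policy with known switching ground truth
#'
#' @param params A [shooter_params()] object.
#' @param omega Opponent identity for this trial (0 computer, 1 human-like).
#' @param opponent_experience Per-opponent trial ordinal normalised to
#'   `[0, 1]` for this trial.
#' @param goalie_draws The goalie's per-trial draws (needed when
#'   `final_move = "timed"` so skilled timing can react to the goalie's
#'   commitment); pass the same object given to [goalie_policy()].
#' @return A `ps_policy`; the resulting trial's `info$shooter` records the
#'   ground-truth switch steps, the final-move step (if any), and the true
#'   hazard at every step.
#' @export
synthetic_shooter_policy <- function(params = shooter_params(), omega = 0L,
                                     opponent_experience = 0,
                                     goalie_draws = NULL) {
  force(params); force(omega); force(opponent_experience); force(goalie_draws)
  make_policy(
    init = function(cfg) {
      dir <- if (runif(1) < 0.5) -1 else 1
      t_final <- NA_integer_
      final_dir <- NA_real_
      if (params$final_move == "timed") {
        reactive <- runif(1) < params$skill
        if (reactive && !is.null(goalie_draws)) {
          t_final <- goalie_draws$guess_step +
            max(1L, as.integer(round(rnorm(1, params$react_delay, 1.5))))
        } else {
          t_final <- sample(seq(as.integer(0.3 * cfg$n_steps), cfg$n_steps - 3L), 1L)
        }
        t_final <- as.integer(clamp(t_final, 5L, cfg$n_steps - 2L))
      }
      list(dir = dir, committed = FALSE, t_final = t_final,
           final_dir = final_dir, last_switch = 0L, prev_bar_y = NA_real_,
           n_steps = cfg$n_steps,
           info = list(switch_steps = integer(0), final_move_step = t_final,
                       true_hazard = numeric(0), params = params))
    },
    step = function(state, mem) {
      t_next <- state$t + 1L
      bar_vy <- if (is.na(mem$prev_bar_y)) 0 else state$bar_y - mem$prev_bar_y
      mem$prev_bar_y <- state$bar_y
      if (!mem$committed && !is.na(mem$t_final) && t_next >= mem$t_final) {
        # final move: commit to a direction away from the goalie's motion,
        # falling back to the open side of the screen
        new_dir <- if (abs(state$bar_u) > 0.5) -sign(state$bar_u)
          else if (abs(state$puck_y - state$bar_y) > 0.02)
            sign(state$puck_y - state$bar_y)
          else if (runif(1) < 0.5) -1 else 1
        if (new_dir != mem$dir) {
          mem$dir <- new_dir
          mem$info$switch_steps <- c(mem$info$switch_steps, t_next)
        }
        mem$committed <- TRUE
        mem$info$final_move_step <- t_next
      }
      hazard <- 0
      if (!mem$committed) {
        # vy features on joystick scale (vertical speed / puck_speed)
        feats <- c(puck_x = state$puck_x, puck_y = state$puck_y,
                   bar_y = state$bar_y,
                   puck_vy = state$puck_u,
                   bar_vy = bar_vy,
                   time_since_last_cp = (state$t - mem$last_switch) / mem$n_steps,
                   opponent_experience = opponent_experience)
        hazard <- pnorm(shooter_latent(params, feats, omega))
        if (runif(1) < hazard) {
          mem$dir <- -mem$dir
          mem$last_switch <- state$t
          mem$info$switch_steps <- c(mem$info$switch_steps, t_next)
        }
      }
      mem$info$true_hazard <- c(mem$info$true_hazard, hazard)
      list(u = mem$dir * params$u_scale, mem = mem)
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic penalty-shot dataset
#'
#' Simulates a cohort of synthetic shooters against the track-then-guess
#' goalie under two opponent conditions (`omega = 0`, the computer
#' parameterisation; `omega = 1`, a human-like parameterisation that guesses
#' toward the puck more often). Opponent order is randomised per participant;
#' the per-opponent trial ordinal is recorded so the opponent-experience
#' predictor (0 on the first trial against an opponent, 1 on the last) can be
#' built downstream. Ground-truth shooter parameters and per-trial goalie
#' draws are stored alongside the trials for recovery tests.
#'
#' @param n_participants Number of synthetic participants.
#' @param n_trials_per_opponent Trials per opponent condition per participant.
#' @param cfg A [game_config()].
#' @param seed Integer seed; the dataset is a deterministic function of all
#'   arguments.
#' @param shooters A single [shooter_params()] applied to everyone, or a list
#'   of length `n_participants`.
#' @param goalie_computer,goalie_human [goalie_params()] for the two opponent
#'   conditions.
#' @return A `ps_dataset`: list with `trials` (list of `ps_trial`), `truth`
#'   (per-participant shooter parameters), and `cfg`.
#' @export
generate_dataset <- function(n_participants, n_trials_per_opponent,
                             cfg = game_config(), seed = 1L,
                             shooters = shooter_params(),
                             goalie_computer = goalie_params(),
                             goalie_human = goalie_params(
                               reaction_lag_range = c(2L, 8L),
                               guess_onset_range = c(0.7, 0.88),
                               guess_toward_puck_prob = 0.7)) {
  stopifnot(n_participants >= 1, n_trials_per_opponent >= 1)
  if (inherits(shooters, "shooter_params"))
    shooters <- rep(list(shooters), n_participants)
  stopifnot(length(shooters) == n_participants)
  n_tot <- 2L * n_trials_per_opponent
  plan <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_participants), function(p) {
      list(opponents = sample(rep(c(0L, 1L), n_trials_per_opponent)),
           seeds = sample.int(.Machine$integer.max - 1L, n_tot))
    })
  })
  trials <- list()
  truth <- list()
  for (p in seq_len(n_participants)) {
    pid <- sprintf("p%02d", p)
    truth[[pid]] <- shooters[[p]]
    counters <- c(`0` = 0L, `1` = 0L)
    for (k in seq_len(n_tot)) {
      om <- plan[[p]]$opponents[k]
      counters[as.character(om)] <- counters[as.character(om)] + 1L
      idx <- counters[as.character(om)]
      oexp <- if (n_trials_per_opponent > 1)
        (idx - 1) / (n_trials_per_opponent - 1) else 0
      gpar <- if (om == 0L) goalie_computer else goalie_human
      tr_seed <- plan[[p]]$seeds[k]
      draws <- withr::with_seed(tr_seed, draw_goalie_trial(gpar, cfg))
      tr <- run_trial(
        synthetic_shooter_policy(shooters[[p]], omega = om,
                                 opponent_experience = oexp,
                                 goalie_draws = draws),
        goalie_policy(gpar, draws = draws),
        cfg, seed = tr_seed + 1L,
        participant_id = pid, opponent_id = om, trial_index = idx
      )
      trials[[length(trials) + 1L]] <- tr
    }
  }
  structure(list(trials = trials, truth = truth, cfg = cfg),
            class = "ps_dataset")
}

#' @export
print.ps_dataset <- function(x, ...) {
  n_p <- length(unique(vapply(x$trials, function(t) t$participant_id, "")))
  wins <- mean(vapply(x$trials, function(t) t$outcome == "win", TRUE))
  cat(sprintf("Synthetic penalty-shot dataset: %d trials, %d participants, win rate %.2f\n",
              length(x$trials), n_p, wins))
  invisible(x)
}
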