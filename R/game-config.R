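#' Game configuration for the penalty-shot task
#'
#' Constructs the physical constants of the penalty-shot game in normalised
#' screen coordinates (`[-1, 1]` on both axes, x rightward, y upward). The
#' puck starts at `(-0.75, 0)` and drifts rightward at constant horizontal
#' speed `v_p`; the goal line sits at `x = 0.77`; the goalie's bar starts at
#' `(0.75, 0)`. The trial length is tied to the geometry:
#' `n_steps = ceil((goal_line_x - puck_start[1]) / puck_speed)`, and with the
#' default `puck_speed = 1.52 / 95` a trial lasts exactly 95 steps
#' (~1.5 s of play, so `dt = 1.5 / 95` seconds per step).
#'
#' The bar may accelerate: holding near-maximal input (`|u| >= 0.8`) in a
#' constant direction for three consecutive steps starts ramping its speed
#' multiplier `theta` by `accel_increment` per step (first applied on the
#' third qualifying step); any break resets `theta` to 1. The bar's vertical
#' step is `(2/3) * theta * puck_speed * u`.
#'
#' @param puck_speed Horizontal (and maximal vertical) puck speed per step,
#'   in screen widths of 2 units. Default `1.52 / 95`.
#' @param puck_start Numeric length-2, puck start position. Default `c(-0.75, 0)`.
#' @param goal_line_x Goal line x position. Default `0.77`.
#' @param puck_radius Puck radius; the puck's diameter is 1/64 of the screen
#'   width (2 units), so the default radius is `2 / 64 / 2 = 0.015625`.
#' @param bar_start Numeric length-2, bar centre start position. Default `c(0.75, 0)`.
#' @param bar_half_height Half the bar's vertical extent. The source task does
#'   not publish this; default `0.15`, configurable.
#' @param bar_speed_factor Bar speed as a fraction of `puck_speed`. Default `2/3`.
#' @param accel_increment Additive `theta` increment per accelerating step. Default `0.85`.
#' @param accel_input_threshold Minimum `|u|` that counts toward acceleration. Default `0.8`.
#' @param accel_steps_required Consecutive qualifying steps before acceleration
#'   engages (inclusive count; the increment first applies on this step). Default `3`.
#' @param trial_seconds Nominal wall-clock trial duration, used only to convert
#'   step indices to seconds. Default `1.5`.
#'
#' @return An object of class `ps_config` (a validated list) with the fields
#'   above plus `n_steps` and `dt`.
#' @examples
#' cfg <- game_config()
#' cfg$n_steps            # 95
#' cfg$puck_speed * cfg$n_steps + cfg$puck_start[1]  # 0.77, the goal line
#' @export
game_config <- function(puck_speed = 1.52 / 95,
                        puck_start = c(-0.75, 0),
                        goal_line_x = 0.77,
                        puck_radius = 2 / 64 / 2,
                        bar_start = c(0.75, 0),
                        bar_half_height = 0.15,
                        bar_speed_factor = 2 / 3,
                        accel_increment = 0.85,
                        accel_input_threshold = 0.8,
                        accel_steps_required = 3L,
                        trial_seconds = 1.5) {
  cfg <- list(
    puck_speed = puck_speed, puck_start = puck_start,
    goal_line_x = goal_line_x, puck_radius = puck_radius,
    bar_start = bar_start, bar_half_height = bar_half_height,
    bar_speed_factor = bar_speed_factor, accel_increment = accel_increment,
    accel_input_threshold = accel_input_threshold,
    accel_steps_required = as.integer(accel_steps_required),
    trial_seconds = trial_seconds
  )
  if (!is.numeric(puck_speed) || length(puck_speed) != 1L || puck_speed <= 0)
    stop("puck_speed must be > 0 (non-terminating configuration rejected)")
  cfg$n_steps <- as.integer(ceiling((goal_line_x - puck_start[1]) / puck_speed - 1e-9))
  cfg$dt <- trial_seconds / cfg$n_steps
  class(cfg) <- "ps_config"
  validate_game_config(cfg)
  cfg
}

validate_game_config <- function(cfg) {
  stopifnot(inherits(cfg, "ps_config"))
  if (!is.numeric(cfg$puck_speed) || cfg$puck_speed <= 0)
    stop("puck_speed must be > 0 (non-terminating configuration rejected)")
  if (cfg$puck_start[1] >= cfg$goal_line_x)
    stop("puck must start left of the goal line")
  if (cfg$goal_line_x > 1 || cfg$bar_start[1] > 1)
    stop("goal line and bar must lie on screen")
  if (cfg$bar_start[1] > cfg$goal_line_x + 1e-12)
    stop("bar must not sit beyond the goal line")
  if (abs(cfg$puck_start[2]) > 1 || abs(cfg$bar_start[2]) > 1)
    stop("start positions must lie within screen bounds")
  if (cfg$bar_half_height <= 0 || cfg$puck_radius <= 0)
    stop("puck_radius and bar_half_height must be positive")
  invisible(cfg)
}

#' Read a game/run configuration from a YAML file
#'
#' Any field of [game_config()] may be overridden; unknown top-level sections
#' are returned untouched so a single file can also carry agent and model
#' settings (see [run_pipeline()]).
#'
#' @param path Path to a YAML file with an optional `game:` section.
#' @return A list with elements `game` (a `ps_config`) and any other sections
#'   present in the file.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  game_over <- raw$game
  if (is.null(game_over)) game_over <- list()
  known <- names(formals(game_config))
  bad <- setdiff(names(game_over), known)
  if (length(bad)) stop("unknown game config fields: ", paste(bad, collapse = ", "))
  raw$game <- do.call(game_config, game_over)
  raw
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @export
print.ps_config <- function(x, ...) {
  cat("Penalty-shot game configuration\n")
  cat(sprintf("  puck: start (%.2f, %.2f), speed %.5f/step, radius %.4f\n",
              x$puck_start[1], x$puck_start[2], x$puck_speed, x$puck_radius))
  cat(sprintf("  bar:  start (%.2f, %.2f), half height %.3f, speed factor %.3f\n",
              x$bar_start[1], x$bar_start[2], x$bar_half_height, x$bar_speed_factor))
  cat(sprintf("  goal line x = %.2f; %d steps/trial (dt = %.4f s)\n",
              x$goal_line_x, x$n_steps, x$dt))
  invisible(x)
}
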