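#' Game configuration for one Auto Orbit speed
#'
#' Builds the full parameter set of the orbiting-shooter environment at one of
#' the two game speeds. The low speed is the high speed with every rate
#' (orbital speed, missile speed, deflation rate) multiplied by the speed
#' multiplier 0.5 and both firing-interval bounds divided by it, so that the
#' game is proportionally slowed; points per burst are set independently
#' (200 at high speed, 300 at low speed).
#'
#' Timing is discrete: one game tick is 16 ms and a 3-minute game is exactly
#' 11,250 ticks. The ship orbits clockwise on a circle of radius 124.34 px,
#' chosen so that a full revolution at the high-speed orbital rate of
#' 0.5 px/tick takes 25.0 s. The balloon is a circle of radius 8 px when
#' deflated, gaining 1 px per inflation step up to 18 px at full
#' vulnerability (10 steps); while deflating it shrinks by 0.5% of its full
#' size (0.09 px) per tick.
#'
#' @param speed `"high"` or `"low"`.
#' @param ... named overrides for any configuration field (used mainly by
#'   tests; overrides are applied after speed scaling and re-validated).
#'
#' @return An object of class `orbit_config`: a named list with fields
#'   `speed_label`, `speed_multiplier`, `orbital_speed` (px/tick),
#'   `missile_speed` (px/tick), `firing_lower_bound` / `firing_upper_bound`
#'   (ms), `points_per_burst`, `miss_penalty`, `double_shot_window` (ms),
#'   `inflation_step`, `deflation_rate` (fraction of full size per tick),
#'   `rotation_probability`, `rotation_magnitude_range` (degrees),
#'   `rotation_onset_range` (ms after cycle start), `post_rotation_grace`
#'   (ms), `game_duration_ms`, `tick_ms`, `turn_step` (degrees),
#'   `orbit_radius` (px), `balloon_full_size` and `balloon_base_size` (px).
#' @examples
#' cfg <- game_config("high")
#' cfg$firing_lower_bound  # 500 ms
#' game_config("low")$firing_upper_bound  # 2400 ms
#' @export
game_config <- function(speed = c("high", "low"), ...) {
  speed <- match.arg(speed)
  mult <- if (speed == "high") 1.0 else 0.5
  cfg <- list(
    speed_label = speed,
    speed_multiplier = mult,
    orbital_speed = 0.5 * mult,
    missile_speed = 5 * mult,
    firing_lower_bound = 500 / mult,
    firing_upper_bound = 1200 / mult,
    points_per_burst = if (speed == "high") 200 else 300,
    miss_penalty = 2,
    double_shot_window = 250,
    inflation_step = 1 / 10,
    deflation_rate = 0.005 * mult,
    rotation_probability = 1 / 3,
    rotation_magnitude_range = c(60, 120),
    rotation_onset_range = c(1000, 4000),
    post_rotation_grace = 4000,
    game_duration_ms = 180000,
    tick_ms = 16,
    turn_step = 15,
    orbit_radius = 124.34,
    balloon_full_size = 18,
    balloon_base_size = 8
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  class(cfg) <- "orbit_config"
  validate_config(cfg)
  cfg
}

#' Validate a game configuration
#'
#' Checks the structural invariants of an [game_config()] object and stops
#' with a configuration error on the first violation.
#'
#' @param cfg an `orbit_config`.
#' @return `cfg`, invisibly.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "orbit_config"))
  if (!is.numeric(cfg$firing_lower_bound) || !is.numeric(cfg$firing_upper_bound) ||
      cfg$firing_lower_bound >= cfg$firing_upper_bound) {
    stop("configuration error: firing_lower_bound must be < firing_upper_bound")
  }
  if (cfg$inflation_step <= 0 || cfg$inflation_step > 1) {
    stop("configuration error: inflation_step must lie in (0, 1]")
  }
  if (cfg$tick_ms != 16) stop("configuration error: tick_ms is fixed at 16")
  if (cfg$orbital_speed <= 0 || cfg$missile_speed <= 0 || cfg$orbit_radius <= 0) {
    stop("configuration error: speeds and orbit radius must be positive")
  }
  if (cfg$rotation_probability < 0 || cfg$rotation_probability > 1) {
    stop("configuration error: rotation_probability must lie in [0, 1]")
  }
  if (diff(cfg$rotation_magnitude_range) < 0 || diff(cfg$rotation_onset_range) < 0) {
    stop("configuration error: rotation ranges must be non-decreasing")
  }
  if (cfg$balloon_base_size <= 0 || cfg$balloon_full_size <= cfg$balloon_base_size) {
    stop("configuration error: balloon sizes must satisfy 0 < base < full")
  }
  if (cfg$game_duration_ms %% cfg$tick_ms != 0) {
    stop("configuration error: game duration must be a whole number of ticks")
  }
  invisible(cfg)
}

#' @export
print.orbit_config <- function(x, ...) {
  cat(sprintf("<orbit_config> %s speed (multiplier %.1f)\n", x$speed_label, x$speed_multiplier))
  cat(sprintf("  firing interval: [%g, %g] ms; %d pts/burst; miss penalty %d\n",
              x$firing_lower_bound, x$firing_upper_bound,
              x$points_per_burst, x$miss_penalty))
  cat(sprintf("  orbital speed %.3g px/tick, missile %.3g px/tick, orbit radius %.5g px\n",
              x$orbital_speed, x$missile_speed, x$orbit_radius))
  invisible(x)
}

#' Read or write a game configuration as YAML
#'
#' Round-trips an `orbit_config` through a flat YAML mapping. Presets
#' matching the two published speeds ship with the package under
#' `inst/extdata/high.yaml` and `inst/extdata/low.yaml`.
#'
#' @param path file path.
#' @param cfg an `orbit_config` (for writing).
#' @return `read_config()` returns an `orbit_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$speed_label)) stop("configuration error: missing speed_label in ", path)
  speed <- raw$speed_label
  raw$speed_label <- NULL
  do.call(game_config, c(list(speed = speed), raw))
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}
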