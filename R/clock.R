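#' Pacemaker-accumulator interval clock
#'
#' The internal clock that paces the agent's waiting times counts time in
#' "ticks" whose durations grow geometrically: the first tick lasts
#' `start_tick` ms and each subsequent noise-free tick is `multiplier` times
#' the previous one, so the cumulative noise-free time of `n` ticks is
#' `start_tick * (multiplier^n - 1) / (multiplier - 1)`. With the defaults
#' (11 ms, 1.1) ten ticks span about 175 ms and thirty ticks about 1,809 ms.
#' When noise is on, each tick duration receives additive zero-mean logistic
#' noise with standard deviation `noise_fraction` times the noise-free
#' duration of that tick.
#'
#' The default start tick of 11 ms is fixed by the 10-tick / 30-tick
#' millisecond equivalents above under the 1.1 growth ratio.
#'
#' @param start_tick duration of the first tick, ms.
#' @param multiplier geometric growth ratio of successive tick durations.
#' @param noise_fraction multiplicative noise level (standard deviation as a
#'   fraction of the current tick duration).
#' @return An object of class `orbit_clock`.
#' @examples
#' cl <- temporal_clock()
#' ticks_to_ms(cl, 10)  # ~175 ms
#' ticks_to_ms(cl, 30)  # ~1809 ms
#' @export
temporal_clock <- function(start_tick = 11, multiplier = 1.1, noise_fraction = 0.0165) {
  stopifnot(start_tick > 0, multiplier > 1, noise_fraction >= 0)
  structure(list(start_tick = start_tick, multiplier = multiplier,
                 noise_fraction = noise_fraction),
            class = "orbit_clock")
}

#' Noise-free cumulative duration of n clock ticks
#'
#' Closed form `start_tick * (multiplier^n - 1) / (multiplier - 1)`.
#'
#' @param clock an [temporal_clock()].
#' @param n number of ticks (vectorised, non-negative).
#' @return cumulative duration in ms.
#' @export
ticks_to_ms <- function(clock, n) {
  stopifnot(all(n >= 0))
  clock$start_tick * (clock$multiplier^n - 1) / (clock$multiplier - 1)
}

#' Sample successive tick durations
#'
#' Draws the durations of ticks `1..n`. With `noise = FALSE` these are the
#' deterministic geometric durations; with noise on, each duration gets
#' additive logistic noise with sd `noise_fraction * t_n` (scale
#' `sd * sqrt(3) / pi`). Durations are floored at a tenth of their noise-free
#' value so a pathological draw cannot make time run backwards.
#'
#' @inheritParams ticks_to_ms
#' @param noise logical.
#' @return numeric vector of `n` tick durations in ms.
#' @export
tick_durations <- function(clock, n, noise = TRUE) {
  if (n == 0) return(numeric(0))
  base <- clock$start_tick * clock$multiplier^(seq_len(n) - 1)
  if (!noise || clock$noise_fraction == 0) return(base)
  scale <- clock$noise_fraction * base * sqrt(3) / pi
  pmax(base + stats::rlogis(n, location = 0, scale = scale), 0.1 * base)
}

#' Sampled waiting time for n accumulated ticks
#'
#' Total duration of accumulating `n` ticks, noisy by default. This is the
#' waiting time the agent realises when its timing tracker asks for `n`
#' ticks.
#'
#' @inheritParams tick_durations
#' @return scalar duration in ms.
#' @export
wait_for_ticks <- function(clock, n, noise = TRUE) {
  sum(tick_durations(clock, n, noise = noise))
}

#' Count whole clock ticks elapsed in a duration
#'
#' Simulates the accumulator for a fixed wall-time `duration` and returns how
#' many whole ticks completed. Resetting the accumulator always restarts the
#' count at zero, so each call is an independent accumulation episode.
#'
#' @inheritParams tick_durations
#' @param duration elapsed wall time in ms (non-negative).
#' @return integer tick count.
#' @export
accumulate_ticks <- function(clock, duration, noise = TRUE) {
  stopifnot(duration >= 0)
  if (!noise || clock$noise_fraction == 0) {
    # invert the closed form: n = log1p(duration * (m-1)/start) / log(m)
    m <- clock$multiplier
    return(as.integer(floor(log1p(duration * (m - 1) / clock$start_tick) / log(m) + 1e-9)))
  }
  total <- 0
  n <- 0L
  t_n <- clock$start_tick
  repeat {
    scale <- clock$noise_fraction * t_n * sqrt(3) / pi
    d <- max(t_n + stats::rlogis(1, 0, scale), 0.1 * t_n)
    if (total + d > duration) break
    total <- total + d
    n <- n + 1L
    t_n <- t_n * clock$multiplier
  }
  n
}

#' @export
print.orbit_clock <- function(x, ...) {
  cat(sprintf("<orbit_clock> start %g ms, ratio %g, noise %g\n",
              x$start_tick, x$multiplier, x$noise_fraction))
  invisible(x)
}
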