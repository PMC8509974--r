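#' Softmax temperature schedule
#'
#' Annealing schedule for tracker sampling: `T(t) = A / (1 + B * t)` with
#' `t` the tracker-local tuning time in seconds. With the defaults
#' (`A = 1`, `B = 1/180`) the temperature starts at 1.0 and halves after
#' 180 s of active tuning.
#'
#' @param A initial temperature.
#' @param B scaling factor per second.
#' @return a `temperature_schedule` list.
#' @export
temperature_schedule <- function(A = 1.0, B = 1 / 180) {
  stopifnot(A > 0, B > 0)
  structure(list(A = A, B = B), class = "temperature_schedule")
}

#' Temperature at tuning time t
#'
#' @param schedule a [temperature_schedule()].
#' @param t tuning time in seconds (non-negative, vectorised).
#' @return temperature(s) `A / (1 + B t)`.
#' @examples
#' temperature(temperature_schedule(), 0)    # 1
#' temperature(temperature_schedule(), 180)  # 0.5
#' @export
temperature <- function(schedule, t) {
  if (any(t < 0)) stop("tuning time must be non-negative")
  schedule$A / (1 + schedule$B * t)
}

#' A bounded-parameter control tracker
#'
#' A tracker tunes one continuous control parameter (for example the shot
#' waiting time in clock ticks, or an aim offset in degrees) inside a fixed
#' range. The range is discretised into `grid_resolution` equally spaced
#' candidate values; a candidate `S` is selected with probability
#' proportional to `exp(V(S) / T(t))`, where `V(S)` is a quadratic payoff
#' estimate and `T(t)` the annealed temperature. `V` is refit after every
#' outcome by weighted least squares on decayed sufficient statistics: all
#' accumulated weights are multiplied by `lambda` before the new
#' `(S, payoff)` observation enters with weight 1, so old experience is
#' forgotten exponentially.
#'
#' While a tracker is suspended its entire state — payoff estimate,
#' accumulated experience and tuning clock — is frozen; resuming continues
#' exactly where it left off. `reset_temperature()` zeroes only the tuning
#' clock so the next selection happens at the initial temperature.
#'
#' @param range_min,range_max parameter bounds (`range_min < range_max`).
#' @param grid_resolution number of candidate values (at least 2).
#' @param lambda exponential forgetting factor per update, in (0, 1].
#' @param schedule a [temperature_schedule()].
#' @param label optional name for printing.
#' @return object of class `orbit_tracker`.
#' @export
new_tracker <- function(range_min, range_max, grid_resolution = 21,
                        lambda = 0.99, schedule = temperature_schedule(),
                        label = NULL) {
  if (!(range_min < range_max)) stop("range_min must be < range_max")
  if (grid_resolution < 2) stop("degenerate grid: resolution must be >= 2")
  structure(list(
    range = c(range_min, range_max),
    grid = seq(range_min, range_max, length.out = grid_resolution),
    lambda = lambda,
    schedule = schedule,
    elapsed_t = 0,
    status = "active",
    label = label,
    # decayed moment statistics of (u, payoff), u = scaled parameter in [-1, 1]
    m = c(w = 0, u = 0, u2 = 0, u3 = 0, u4 = 0, y = 0, uy = 0, u2y = 0)
  ), class = "orbit_tracker")
}

# scale a parameter value into [-1, 1] for numerically stable quadratic fits
.tracker_u <- function(tracker, S) {
  mid <- mean(tracker$range)
  half <- diff(tracker$range) / 2
  (S - mid) / half
}

#' Quadratic payoff estimate over the tracker grid
#'
#' Solves the decay-weighted least-squares quadratic through the accumulated
#' (value, payoff) statistics and evaluates it at the grid points. With
#' fewer than three distinct observed values the fit is rank-deficient; a
#' small ridge keeps the system solvable, which leaves the estimate near the
#' flat prior except around the observed values.
#'
#' @param tracker an `orbit_tracker`.
#' @return numeric vector of `V(S)` at `tracker$grid`.
#' @export
tracker_payoff <- function(tracker) {
  m <- tracker$m
  if (m["w"] <= 0) return(rep(0, length(tracker$grid)))
  A <- matrix(c(m["w"],  m["u"],  m["u2"],
                m["u"],  m["u2"], m["u3"],
                m["u2"], m["u3"], m["u4"]), 3, 3)
  b <- c(m["y"], m["uy"], m["u2y"])
  beta <- solve(A + diag(1e-6, 3), b)
  u <- .tracker_u(tracker, tracker$grid)
  as.numeric(beta[1] + beta[2] * u + beta[3] * u^2)
}

#' Current temperature of a tracker
#' @param tracker an `orbit_tracker`.
#' @return scalar temperature at the tracker's local tuning time.
#' @export
tracker_temperature <- function(tracker) {
  temperature(tracker$schedule, tracker$elapsed_t)
}

#' Softmax selection probabilities over the grid
#'
#' @param tracker an `orbit_tracker`.
#' @return probability vector over `tracker$grid`, summing to 1.
#' @export
tracker_probs <- function(tracker) {
  V <- tracker_payoff(tracker)
  Tt <- tracker_temperature(tracker)
  z <- V / Tt
  p <- exp(z - max(z))
  p / sum(p)
}

#' Sample a parameter value from a tracker
#'
#' Draws one candidate from the discretised range with softmax
#' probabilities. Uses R's global random number stream.
#'
#' @param tracker an `orbit_tracker` (must be active).
#' @return scalar sampled parameter value.
#' @export
tracker_sample <- function(tracker) {
  if (tracker$status != "active") stop("cannot sample from a suspended tracker")
  if (length(tracker$grid) < 2) stop("degenerate grid")
  sample(tracker$grid, 1L, prob = tracker_probs(tracker))
}

#' Record an outcome and refit the payoff estimate
#'
#' Decays all accumulated weights by `lambda`, then adds the new
#' observation with weight 1.
#'
#' @param tracker an `orbit_tracker`.
#' @param S the sampled parameter value the payoff is attributed to
#'   (within range).
#' @param payoff signed finite scalar.
#' @return the updated tracker.
#' @export
record_outcome <- function(tracker, S, payoff) {
  if (!is.finite(payoff)) stop("payoff must be finite")
  if (S < tracker$range[1] - 1e-9 || S > tracker$range[2] + 1e-9) {
    stop("S outside tracker range")
  }
  u <- .tracker_u(tracker, S)
  tracker$m <- tracker$lambda * tracker$m +
    c(1, u, u^2, u^3, u^4, payoff, u * payoff, u^2 * payoff)
  tracker
}

#' Advance a tracker's tuning clock
#'
#' Tracker-local time advances with simulated game time only while the
#' tracker is active; suspended trackers do not anneal.
#'
#' @param tracker an `orbit_tracker`.
#' @param dt elapsed simulated time in seconds.
#' @return the updated tracker.
#' @export
tracker_advance <- function(tracker, dt) {
  stopifnot(dt >= 0)
  if (tracker$status == "active") tracker$elapsed_t <- tracker$elapsed_t + dt
  tracker
}

#' Suspend, resume or re-anneal a tracker
#'
#' @param tracker an `orbit_tracker`.
#' @return the updated tracker.
#' @export
suspend <- function(tracker) {
  tracker$status <- "suspended"
  tracker
}

#' @rdname suspend
#' @export
resume <- function(tracker) {
  if (tracker$status == "active") {
    warning("resuming a tracker that is already active: no-op")
    return(tracker)
  }
  tracker$status <- "active"
  tracker
}

#' @rdname suspend
#' @export
reset_temperature <- function(tracker) {
  tracker$elapsed_t <- 0
  tracker
}

#' @export
print.orbit_tracker <- function(x, ...) {
  V <- tracker_payoff(x)
  cat(sprintf("<orbit_tracker>%s [%g, %g] x %d, %s\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$range[1], x$range[2], length(x$grid), x$status))
  cat(sprintf("  T = %.3f (t = %.1f s), argmax V = %g, weight = %.1f\n",
              tracker_temperature(x), x$elapsed_t,
              x$grid[which.max(V)], x$m[["w"]]))
  invisible(x)
}
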