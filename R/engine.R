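# Tick-level simulation of the orbiting-shooter environment.
#
# All motion is discretised to 16-ms game ticks. The balloon sits at the
# origin; the ship orbits clockwise on a circle of radius `orbit_radius`,
# its orbit angle advancing by orbital_speed / orbit_radius radians per
# tick. The nose (firing direction) is absolute; the aim error is the
# signed angular difference between the nose and the ship-to-balloon
# direction, and it drains at the orbital angular rate as the ship moves.
# Missiles inherit the nose direction at the press and are resolved by
# segment-circle intersection against the balloon.

.EVENT_KINDS <- c("hold-key", "release-key", "random-rotation",
                  "vulnerability-reset", "vulnerability-increase",
                  "missile-fired", "balloon-respawn", "balloon-burst",
                  "balloon-deflation-onset", "missile-miss")

# signed wrap into (-180, 180]
.wrap180 <- function(a) {
  a <- a %% 360
  if (a > 180) a - 360 else a
}

#' Classify an inter-shot interval against the firing bounds
#'
#' A shot faster than the firing interval's lower bound pops the balloon
#' (a "reset"); anything else is a valid shot. Slow play is not resolved
#' here: the deflation clock fires an onset when the time since the last
#' shot exceeds the upper bound (or the post-rotation grace expires).
#'
#' @param isi inter-shot interval in ms (non-negative).
#' @param config an [game_config()].
#' @return `"reset"` or `"valid"`.
#' @export
resolve_shot_timing <- function(isi, config) {
  stopifnot(isi >= 0)
  if (isi < config$firing_lower_bound) "reset" else "valid"
}

#' Geometric resolution of a fired missile
#'
#' A missile fired with aim error `aim_error` (degrees between the nose and
#' the ship-to-balloon direction) from the orbit circle hits iff its ray
#' passes within the balloon circle: perpendicular distance
#' `orbit_radius * |sin(aim_error)| <= balloon_size` with the balloon ahead
#' of the ship. Returns the outcome and the flight time in game ticks
#' (to the entry point for hits, to the closest approach for misses).
#'
#' @param aim_error signed aim error in degrees.
#' @param balloon_size current balloon radius in px.
#' @param config an [game_config()].
#' @return list with `hit` (logical) and `travel_ticks` (integer >= 1).
#' @export
resolve_missile <- function(aim_error, balloon_size, config) {
  e <- .wrap180(aim_error) * pi / 180
  R <- config$orbit_radius
  perp <- R * abs(sin(e))
  ahead <- cos(e) > 0
  if (ahead && perp <= balloon_size) {
    dist <- R * cos(e) - sqrt(balloon_size^2 - perp^2)
    list(hit = TRUE,
         travel_ticks = max(1L, as.integer(ceiling(dist / config$missile_speed))))
  } else {
    dist <- if (ahead) R * cos(e) else R / 2
    list(hit = FALSE,
         travel_ticks = max(1L, as.integer(ceiling(dist / config$missile_speed))))
  }
}

#' Schedule the random ship rotation for a game cycle
#'
#' At the start of every cycle a disruptive ship rotation is scheduled with
#' probability 1/3: its onset is uniform within 1 to 4 s after the cycle
#' start and its magnitude uniform in 60 to 120 degrees with random sign.
#' Uses R's global random number stream.
#'
#' @param cycle_start_ms cycle start time in ms.
#' @param config an [game_config()].
#' @return `NULL` (no rotation this cycle) or a list with `onset_ms`
#'   (quantised to the tick grid) and `angle` (signed degrees).
#' @export
schedule_rotation <- function(cycle_start_ms, config) {
  if (stats::runif(1) >= config$rotation_probability) return(NULL)
  onset <- cycle_start_ms + stats::runif(1, config$rotation_onset_range[1],
                                         config$rotation_onset_range[2])
  onset <- round(onset / config$tick_ms) * config$tick_ms
  mag <- stats::runif(1, config$rotation_magnitude_range[1],
                      config$rotation_magnitude_range[2])
  sgn <- if (stats::runif(1) < 0.5) -1 else 1
  list(onset_ms = onset, angle = sgn * mag)
}

.log_event <- function(st, t, kind, payload) {
  n <- st$n_events + 1L
  if (n > length(st$ev_ts)) {
    grow <- length(st$ev_ts)
    st$ev_ts <- c(st$ev_ts, numeric(grow))
    st$ev_kind <- c(st$ev_kind, integer(grow))
    st$ev_payload <- c(st$ev_payload, character(grow))
  }
  st$ev_ts[n] <- t
  st$ev_kind[n] <- kind
  st$ev_payload[n] <- payload
  st$n_events <- n
}

.do_respawn <- function(st, t) {
  .log_event(st, t, 7L, "")
  st$n_respawns <- st$n_respawns + 1L
  st$vuln <- 0L
  st$size <- st$base_size
  st$deflating <- FALSE
  st$cycle_start <- t
  st$defl_deadline <- t + st$upper
  st$last_shot <- -Inf
  st$last_full_hit <- -Inf
  st$pending_respawn <- FALSE
  rot <- schedule_rotation(t, st$cfg)
  if (is.null(rot)) {
    st$rot_onset <- Inf
    st$rot_angle <- 0
  } else {
    st$rot_onset <- rot$onset_ms
    st$rot_angle <- rot$angle
  }
  invisible(st)
}

#' Initialise a game state
#'
#' Seeds R's random number stream, places the ship at orbit angle 0 with the
#' nose aimed at the balloon, spawns the balloon at vulnerability 0, and logs
#' the opening balloon-respawn event. Game state is a mutable environment:
#' [step()] advances it in place.
#'
#' @param config an [game_config()].
#' @param seed integer seed for all randomness in this game.
#' @return the game-state environment (unclassed for tick-loop speed).
#' @export
init_game <- function(config, seed) {
  validate_config(config)
  set.seed(as.integer(seed))
  st <- new.env(parent = emptyenv())
  st$cfg <- config
  st$seed <- as.integer(seed)
  # unpacked hot-loop constants
  st$tick_ms <- config$tick_ms
  st$dur_ticks <- as.integer(config$game_duration_ms / config$tick_ms)
  st$ang_step <- config$orbital_speed / config$orbit_radius * 180 / pi
  st$lower <- config$firing_lower_bound
  st$upper <- config$firing_upper_bound
  st$points <- config$points_per_burst
  st$penalty <- config$miss_penalty
  st$window <- config$double_shot_window
  st$grace <- config$post_rotation_grace
  st$base_size <- config$balloon_base_size
  st$full_size <- config$balloon_full_size
  st$step_px <- (config$balloon_full_size - config$balloon_base_size) *
    config$inflation_step / 0.1 * 0.1  # px gained per inflation step
  st$defl_px <- config$deflation_rate * config$balloon_full_size
  st$mspeed <- config$missile_speed
  st$turn <- config$turn_step
  st$orbit_radius <- config$orbit_radius
  # kinematic state
  st$tick <- 0L
  st$time_ms <- 0
  st$orbit_angle <- 0
  st$nose_angle <- 180  # aimed at the balloon
  # balloon
  st$vuln <- 0L
  st$size <- st$base_size
  st$deflating <- FALSE
  st$pending_respawn <- FALSE
  # timing bookkeeping
  st$last_shot <- -Inf
  st$last_full_hit <- -Inf
  st$defl_deadline <- st$upper
  st$cycle_start <- 0
  # missiles in flight (parallel queues, head pointer)
  st$m_arr <- numeric(0)
  st$m_hit <- logical(0)
  st$m_head <- 1L
  # held keys
  st$hA <- FALSE; st$hD <- FALSE; st$hL <- FALSE
  # counters
  st$score <- 0
  st$n_bursts <- 0L; st$n_misses <- 0L; st$n_resets <- 0L
  st$n_vulninc <- 0L; st$n_deflations <- 0L; st$n_respawns <- 0L
  st$n_hits <- 0L
  # event log buffers
  st$ev_ts <- numeric(2048)
  st$ev_kind <- integer(2048)
  st$ev_payload <- character(2048)
  st$n_events <- 0L
  st$ended <- FALSE
  # left unclassed: S3 dispatch on `$` would dominate the tick loop
  .do_respawn(st, 0)
  st
}

# advance one 16-ms tick; hA/hD/hL are the keys held during this tick
.tick <- function(st, hA, hD, hL) {
  t <- st$time_ms
  if (st$pending_respawn) .do_respawn(st, t)

  # --- key transitions (actions trigger on press edges) ---
  if (hA != st$hA) {
    if (hA) {
      .log_event(st, t, 1L, "A")
      st$nose_angle <- (st$nose_angle - st$turn) %% 360
    } else .log_event(st, t, 2L, "A")
    st$hA <- hA
  }
  if (hD != st$hD) {
    if (hD) {
      .log_event(st, t, 1L, "D")
      st$nose_angle <- (st$nose_angle + st$turn) %% 360
    } else .log_event(st, t, 2L, "D")
    st$hD <- hD
  }
  if (hL != st$hL) {
    if (hL) {
      .log_event(st, t, 1L, "L")
      .log_event(st, t, 6L, "")
      isi <- t - st$last_shot
      too_fast <- is.finite(isi) && isi < st$lower && st$vuln < 10L
      st$last_shot <- t
      st$defl_deadline <- t + st$upper
      st$deflating <- FALSE
      if (too_fast) {
        .log_event(st, t, 4L, "")
        st$n_resets <- st$n_resets + 1L
        st$vuln <- 0L
        st$size <- st$base_size
        # the popped balloon absorbs this missile: no hit, no miss
      } else {
        e <- .wrap180(st$nose_angle - (st$orbit_angle + 180))
        res <- resolve_missile(e, st$size, st$cfg)
        st$m_arr <- c(st$m_arr, t + res$travel_ticks * st$tick_ms)
        st$m_hit <- c(st$m_hit, res$hit)
      }
    } else .log_event(st, t, 2L, "L")
    st$hL <- hL
  }

  # --- scheduled random rotation ---
  if (t >= st$rot_onset) {
    .log_event(st, t, 3L, formatC(st$rot_angle, format = "f", digits = 2))
    st$nose_angle <- (st$nose_angle + st$rot_angle) %% 360
    st$defl_deadline <- max(st$defl_deadline, t + st$grace)
    st$rot_onset <- Inf
  }

  # --- missiles arriving this tick (fired first, arrives first) ---
  while (st$m_head <= length(st$m_arr) && st$m_arr[st$m_head] <= t) {
    hit <- st$m_hit[st$m_head]
    st$m_head <- st$m_head + 1L
    if (st$m_head > 16L) {  # compact the queue occasionally
      keep <- st$m_head <= seq_along(st$m_arr)
      st$m_arr <- st$m_arr[keep]
      st$m_hit <- st$m_hit[keep]
      st$m_head <- 1L
    }
    if (hit) {
      st$n_hits <- st$n_hits + 1L
      if (st$vuln >= 10L) {
        if (t - st$last_full_hit <= st$window) {
          st$score <- st$score + st$points
          st$n_bursts <- st$n_bursts + 1L
          .log_event(st, t, 8L, "")
          st$pending_respawn <- TRUE
          st$vuln <- 0L
          st$size <- st$base_size
          st$last_full_hit <- -Inf
        } else {
          # ordinary hit on an already-full balloon: arms the double shot
          st$last_full_hit <- t
        }
      } else {
        st$vuln <- st$vuln + 1L
        st$size <- st$base_size + st$vuln * st$step_px
        .log_event(st, t, 5L, "")
        st$n_vulninc <- st$n_vulninc + 1L
      }
    } else {
      .log_event(st, t, 10L, "")
      st$score <- st$score - st$penalty
      st$n_misses <- st$n_misses + 1L
    }
  }

  # --- deflation clock ---
  if (!st$deflating && t >= st$defl_deadline) {
    .log_event(st, t, 9L, "")
    st$n_deflations <- st$n_deflations + 1L
    st$deflating <- TRUE
  }
  if (st$deflating && st$size > st$base_size) {
    s <- st$size - st$defl_px
    if (s < st$base_size) s <- st$base_size
    st$size <- s
    v <- as.integer((s - st$base_size) / st$step_px + 1e-9)
    if (v < st$vuln) st$vuln <- v
  }

  # --- kinematics ---
  a <- st$orbit_angle + st$ang_step
  st$orbit_angle <- if (a >= 360) a - 360 else a

  st$tick <- st$tick + 1L
  st$time_ms <- st$tick * st$tick_ms
  if (st$tick >= st$dur_ticks) st$ended <- TRUE
  invisible(st)
}

#' Advance the game by one 16-ms tick
#'
#' Applies one tick of simulation with the given held keys: press edges
#' trigger turns (A/D, 15 degrees counter-/clockwise) and missile launches
#' (L), in-flight missiles advance and resolve, the deflation clock and any
#' scheduled rotation fire, and the orbit advances. Unknown keys are
#' ignored. The state environment is modified in place.
#'
#' @param state an `orbit_state` from [init_game()].
#' @param held_keys character vector, subset of `c("A", "D", "L")`, the keys
#'   held during this tick.
#' @return list with `state` (the same environment) and `events`, a
#'   data.frame of the events emitted this tick (`timestamp_ms`, `kind`,
#'   `payload`).
#' @export
step <- function(state, held_keys = character(0)) {
  if (state$ended) stop("game already ended: no ticks past ", state$cfg$game_duration_ms, " ms")
  n0 <- state$n_events
  .tick(state, "A" %in% held_keys, "D" %in% held_keys, "L" %in% held_keys)
  idx <- seq_len(state$n_events - n0) + n0
  events <- data.frame(
    timestamp_ms = state$ev_ts[idx],
    kind = .EVENT_KINDS[state$ev_kind[idx]],
    payload = state$ev_payload[idx],
    stringsAsFactors = FALSE
  )
  list(state = state, events = events)
}

#' Run one full 3-minute game under a key policy
#'
#' Executes the 11,250 ticks of one game, querying `policy` every tick for
#' the set of held keys. A policy is a function of the game-state
#' environment returning either a character vector (subset of `A`, `D`,
#' `L`) or a logical vector of length 3 in the order (A, D, L); the logical
#' form avoids per-tick conversion and is what the built-in agents use.
#' Identical (config, seed, policy) triples produce identical logs.
#'
#' @param policy policy function; see Details. Exceptions raised by the
#'   policy propagate annotated with the tick at which they occurred.
#' @param config an [game_config()].
#' @param seed integer seed.
#' @param game_index game number within a session (1-based).
#' @param condition condition label stored in the log (defaults to the
#'   speed label).
#' @return an [orbit_log] with one game.
#' @export
run_game <- function(policy, config, seed, game_index = 1L, condition = NULL) {
  st <- init_game(config, seed)
  logical_keys <- NA  # decided on first policy return
  tryCatch({
    while (!st$ended) {
      k <- policy(st)
      if (is.na(logical_keys)) logical_keys <- is.logical(k)
      if (logical_keys) {
        .tick(st, k[1L], k[2L], k[3L])
      } else {
        .tick(st, "A" %in% k, "D" %in% k, "L" %in% k)
      }
    }
  }, error = function(e) {
    stop("policy/engine error at tick ", st$tick, " (", st$time_ms, " ms): ",
         conditionMessage(e), call. = FALSE)
  })
  finalize_log(st, game_index = game_index, condition = condition)
}

# package a finished (or partial) game state into an orbit_log
finalize_log <- function(st, game_index = 1L, condition = NULL) {
  idx <- seq_len(st$n_events)
  condition <- condition %||% st$cfg$speed_label
  events <- data.frame(
    timestamp_ms = st$ev_ts[idx],
    kind = .EVENT_KINDS[st$ev_kind[idx]],
    payload = st$ev_payload[idx],
    game_index = as.integer(game_index),
    condition = condition,
    speed = st$cfg$speed_label,
    stringsAsFactors = FALSE
  )
  games <- data.frame(
    game_index = as.integer(game_index),
    speed = st$cfg$speed_label,
    seed = st$seed,
    final_score = st$score,
    n_ticks = st$tick,
    stringsAsFactors = FALSE
  )
  new_orbit_log(events, games, condition)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Idle policy: hold no keys
#'
#' @return a policy for [run_game()] that never presses a key.
#' @export
policy_idle <- function() {
  none <- c(FALSE, FALSE, FALSE)
  function(st) none
}

#' Scripted metronome player
#'
#' A deterministic (given the engine seed) scripted policy that fires at a
#' fixed target inter-shot interval, schedules the clockwise turns needed to
#' keep the nose on the balloon, fine-tunes each press time so the aim error
#' is near zero at the shot, and executes the double shot when the balloon
#' is full. Used as a competent reference player in engine tests.
#'
#' @param config the [game_config()] the game will run under.
#' @param isi_ms target inter-shot interval (defaults to the middle of the
#'   firing interval).
#' @param double_gap_ms gap between the two presses of the double shot.
#' @return a policy function for [run_game()].
#' @export
policy_metronome <- function(config, isi_ms = NULL,
                             double_gap_ms = 128) {
  isi_ms <- isi_ms %||% ((config$firing_lower_bound + config$firing_upper_bound) / 2)
  tick_ms <- config$tick_ms
  turn <- config$turn_step
  hold <- 2 * tick_ms
  e <- new.env(parent = emptyenv())
  e$sch_t <- numeric(0)   # press times (tick-aligned)
  e$sch_k <- integer(0)   # 1 = A, 2 = D, 3 = L
  e$head <- 1L
  e$next_t <- -Inf        # nothing can happen before this time
  e$c_resp <- 0L
  none <- c(FALSE, FALSE, FALSE)

  q16 <- function(x) round(x / tick_ms) * tick_ms

  plan <- function(st) {
    t <- st$time_ms
    t0 <- if (is.finite(st$last_shot)) st$last_shot else st$cycle_start
    Tf <- max(t0 + isi_ms, t + 3 * tick_ms)
    # aim: project the error to the fire time, turn in 15-degree steps,
    # then shift the fire time to drain the residual
    e_now <- .wrap180(st$nose_angle - (st$orbit_angle + 180))
    eT <- .wrap180(e_now - st$ang_step * (Tf - t) / tick_ms)
    k <- round(-eT / turn)
    r <- eT + k * turn
    dt <- round(r / st$ang_step) * tick_ms
    lo <- t0 + st$lower + 3 * tick_ms
    hi <- t0 + st$upper - 3 * tick_ms
    Tf <- q16(min(max(Tf + dt, lo, t + 3 * tick_ms), max(hi, t + 3 * tick_ms)))
    times <- numeric(0); keys <- integer(0)
    if (k != 0) {
      kk <- min(abs(k), 8)
      tt <- q16(seq(t + 2 * tick_ms, by = 6 * tick_ms, length.out = kk))
      tt <- tt[tt < Tf - 2 * tick_ms]
      if (length(tt)) {
        times <- c(times, tt)
        keys <- c(keys, rep(if (k > 0) 2L else 1L, length(tt)))
      }
    }
    times <- c(times, Tf); keys <- c(keys, 3L)
    if (st$vuln + (length(st$m_arr) - st$m_head + 1L) >= 10L) {
      times <- c(times, q16(Tf + double_gap_ms)); keys <- c(keys, 3L)
    }
    ord <- order(times)
    e$sch_t <- times[ord]; e$sch_k <- keys[ord]
    e$head <- 1L
    e$next_t <- e$sch_t[1]
  }

  function(st) {
    t <- st$time_ms
    if (st$n_respawns != e$c_resp) {
      # new cycle: drop stale presses (e.g. the second shot of a planned
      # double aimed at a balloon that has just burst) and replan
      e$c_resp <- st$n_respawns
      keep <- e$sch_t <= t - hold
      e$sch_t <- e$sch_t[keep]; e$sch_k <- e$sch_k[keep]
      e$head <- length(e$sch_t) + 1L
      e$next_t <- t
    }
    if (t < e$next_t) return(none)
    n <- length(e$sch_t)
    if (e$head > n) {
      plan(st)
      if (t < e$next_t) return(none)
      n <- length(e$sch_t)
    }
    while (e$head <= n && e$sch_t[e$head] + hold <= t) e$head <- e$head + 1L
    hA <- FALSE; hD <- FALSE; hL <- FALSE
    i <- e$head
    while (i <= n && e$sch_t[i] <= t) {
      kk <- e$sch_k[i]
      if (kk == 1L) hA <- TRUE else if (kk == 2L) hD <- TRUE else hL <- TRUE
      i <- i + 1L
    }
    e$next_t <- if (e$head > n) t else if (e$sch_t[e$head] <= t) t else e$sch_t[e$head]
    c(hA, hD, hL)
  }
}
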