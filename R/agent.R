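# Control-tuning agent.
#
# The agent plays through a fixed operator cycle: check/adjust aim (offset
# and width trackers), wait until the interval clock has accumulated the
# sampled number of ticks, fire (single shot below full vulnerability,
# quick double shot at full), and decide via the turn-threshold tracker
# whether the "aiming again" step takes the short path (no extra turn) or
# the long path (one extra turn). Each planning pass runs either through
# the interpreted operator path (several ~50-ms steps) or, once formed,
# through a compiled shortcut (one step); the two paths compete on
# difference-learned utilities with reward equal to minus the elapsed
# planning time, an abstraction of production compilation that reproduces
# its behavioral signature (faster, chunkier action sequences).
#
# Speed changes are never read off the game index: the agent flags a
# change when shots near the tracker's own best estimate draw penalty
# feedback (reset or deflation) twice in a row after the tracker is well
# tuned. What happens then depends on the model variant: the one-tracker
# model carries on and relearns by forgetting; the two-tracker models
# suspend the current shot-timing tracker, explore for one cycle, open a
# fresh tracker on the range bracketing the inter-shot intervals that drew
# no penalty (keeping or resetting the annealed temperature), and swap the
# original tracker back in at the next detected change.

.AGENT_VARIANTS <- c("one_tracker", "two_trackers_keep_temp", "two_trackers_reset_temp")

#' Create a control-tuning agent
#'
#' @param variant one of `"one_tracker"`, `"two_trackers_keep_temp"`,
#'   `"two_trackers_reset_temp"`.
#' @param params named list of overrides for the agent parameters; see
#'   [agent_params()].
#' @return an environment of class `orbit_agent`.
#' @export
new_agent <- function(variant = .AGENT_VARIANTS, params = list()) {
  variant <- match.arg(variant)
  p <- agent_params()
  if (length(params)) {
    bad <- setdiff(names(params), names(p))
    if (length(bad)) stop("unknown agent parameter(s): ", paste(bad, collapse = ", "))
    p[names(params)] <- params
  }
  A <- new.env(parent = emptyenv())
  A$variant <- variant
  A$p <- p
  A$clock <- temporal_clock()
  sched <- temperature_schedule(p$temp_A, p$temp_B)
  A$timing <- list(new_tracker(p$timing_range[1], p$timing_range[2], p$grid,
                               p$lambda, sched, label = "shot timing"))
  A$timing_active <- 1L
  A$offset <- new_tracker(p$offset_range[1], p$offset_range[2], p$grid,
                          p$lambda, sched, label = "aim offset")
  A$width <- new_tracker(p$width_range[1], p$width_range[2], p$grid,
                         p$lambda, sched, label = "aim width")
  A$thr <- new_tracker(p$thr_range[1], p$thr_range[2], p$grid,
                       p$lambda, sched, label = "turn threshold")
  A$u_interp <- production_utility(0, p$alpha)
  A$u_compiled <- production_utility(0, p$alpha)
  A$n_plans <- 0L
  A$plans_game <- 0L
  A$compiled_game <- 0L
  A$session_ms <- 0
  A$share_hist <- numeric(0)  # per-game compiled-path share
  A$last_change_ms <- -Inf
  A$changes <- numeric(0)   # session times of detected speed changes
  A$consec_bad <- 0L
  A$bad_type <- ""
  A$exploring <- FALSE
  A$explore_defl <- FALSE
  A$explore_good <- numeric(0)
  A$explore_bad_fast <- numeric(0)
  A$explore_bad_slow <- numeric(0)
  A$explore_shots <- 0L
  class(A) <- c("orbit_agent", "environment")
  agent_reset_game(A)
  A
}

#' Default agent parameters
#'
#' Tunables of the cognitive agent with their defaults: tracker ranges
#' (shot timing 10-30 clock ticks; aim offset -18 to 0 degrees; aim width
#' 5 to 15 degrees; turn threshold -10 to 0 degrees), grid resolution 21,
#' forgetting `lambda` 0.99 per update, temperature schedule A = 1 and
#' B = 1/180 per second, utility learning rate `alpha` 0.05, motor
#' preparation/execution mean 50 ms with 10 ms Gaussian jitter, interpreted
#' path of 4 operator steps against a 1-step compiled path formed after 12
#' plans, and the speed-change detector (armed after 120 s of tracker
#' tuning, 150 s refractory, penalty feedback within 2 grid steps of the
#' payoff argmax counted as inconsistent).
#'
#' @return named list of parameters.
#' @export
agent_params <- function() {
  list(
    timing_range = c(10, 30),
    offset_range = c(-18, 0),
    width_range = c(5, 15),
    thr_range = c(-10, 0),
    grid = 21L,
    lambda = 0.99,
    temp_A = 1.0,
    temp_B = 1 / 180,
    alpha = 0.05,
    motor_mean = 50,
    motor_sd = 10,
    hold_ms = 32,
    interp_steps = 4L,
    compile_after = 12L,
    util_noise = 0.1,
    double_gap_ms = 96,
    detect_min_weight = 50,
    detect_min_payoff = 0.5,
    refractory_ms = 150000,
    detect_grid_steps = 2,
    explore_max_shots = 12L,
    explore_ticks = c(5, 40),
    new_range_factor = c(0.6, 1.4),
    range_clip = c(5, 60),
    payoff_hit = 1,
    payoff_reset = -1,
    payoff_deflation = -1,
    payoff_miss = -1
  )
}

# clear per-game state (schedules, feedback snapshots); trackers persist
agent_reset_game <- function(A) {
  if (!is.null(A$plans_game) && A$plans_game > 0L) {
    A$share_hist <- c(A$share_hist, A$compiled_game / A$plans_game)
  }
  A$sch_t <- numeric(0)
  A$sch_k <- integer(0)
  A$sch_head <- 1L
  # attribution queue of planned shots (parallel vectors)
  A$q_n <- numeric(0)      # sampled timing ticks
  A$q_shift <- numeric(0)  # aim-induced displacement of the fire time (ms)
  A$q_O <- numeric(0)      # sampled aim offset
  A$q_W <- numeric(0)      # sampled aim width
  A$q_thr <- numeric(0)    # sampled turn threshold
  A$q_press <- numeric(0)  # scheduled press time
  A$q_isi <- numeric(0)    # scheduled inter-shot interval
  A$q_open <- logical(0)   # awaiting resolution
  A$q_head <- 1L
  # engine counter snapshots
  A$c_resets <- 0L; A$c_hits <- 0L; A$c_misses <- 0L
  A$c_defl <- 0L; A$c_bursts <- 0L
  A$defl_flag <- FALSE
  A$cur_n <- NA_real_
  A$cur_shift <- 0
  A$last_plan_ms <- 0
  A$plans_game <- 0L
  A$compiled_game <- 0L
  A$next_t <- -Inf     # wake-time cache: nothing scheduled before this
  A$c_nev <- 0L        # engine event count at the last feedback scan
  A$c_respawns <- 0L
  invisible(A)
}

# advance the tuning clocks of all active trackers
.agent_advance_time <- function(A, dt_ms) {
  if (dt_ms <= 0) return(invisible(A))
  dt <- dt_ms / 1000
  A$timing[[A$timing_active]] <- tracker_advance(A$timing[[A$timing_active]], dt)
  A$offset <- tracker_advance(A$offset, dt)
  A$width <- tracker_advance(A$width, dt)
  A$thr <- tracker_advance(A$thr, dt)
  invisible(A)
}

# tick count whose noise-free accumulation best matches a duration
.ms_to_ticks <- function(clock, ms) {
  log1p(ms * (clock$multiplier - 1) / clock$start_tick) / log(clock$multiplier)
}

# structural response to a detected speed change
.on_speed_change <- function(A, st) {
  A$consec_bad <- 0L
  A$last_change_ms <- A$session_ms + st$time_ms
  A$changes <- c(A$changes, A$last_change_ms)
  if (A$variant == "one_tracker") return(invisible(A))
  if (length(A$timing) >= 2L) {
    # second change: reactivate the suspended tracker, suspend the current
    other <- which(vapply(A$timing, function(tr) tr$status == "suspended", logical(1)))[1]
    cur <- A$timing_active
    A$timing[[cur]] <- suspend(A$timing[[cur]])
    A$timing[[other]] <- resume(A$timing[[other]])
    A$timing_active <- other
  } else {
    # first change: suspend and explore for one cycle before requesting
    # a fresh tracker on an informed range
    A$timing[[A$timing_active]] <- suspend(A$timing[[A$timing_active]])
    A$exploring <- TRUE
    A$explore_defl <- FALSE
    A$explore_good <- numeric(0)
    A$explore_bad_fast <- numeric(0)
    A$explore_bad_slow <- numeric(0)
    A$explore_shots <- 0L
  }
  invisible(A)
}

# close the exploration cycle: open the new tracker
.finish_explore <- function(A) {
  p <- A$p
  old <- A$timing[[A$timing_active]]
  if (length(A$explore_good)) {
    n_c <- stats::median(.ms_to_ticks(A$clock, A$explore_good))
  } else if (length(A$explore_bad_fast) &&
             length(A$explore_bad_fast) >= length(A$explore_bad_slow)) {
    # everything drew resets: the true interval is longer than anything tried
    n_c <- max(.ms_to_ticks(A$clock, A$explore_bad_fast)) * 1.6
  } else if (length(A$explore_bad_slow)) {
    n_c <- min(.ms_to_ticks(A$clock, A$explore_bad_slow)) * 0.7
  } else {
    n_c <- mean(p$timing_range)
  }
  lo <- max(p$range_clip[1], p$new_range_factor[1] * n_c)
  hi <- min(p$range_clip[2], p$new_range_factor[2] * n_c)
  if (hi - lo < 2) { lo <- max(p$range_clip[1], n_c - 2); hi <- n_c + 2 }
  tr <- new_tracker(lo, hi, p$grid, p$lambda,
                    temperature_schedule(p$temp_A, p$temp_B),
                    label = "shot timing (2)")
  if (A$variant == "two_trackers_keep_temp") tr$elapsed_t <- old$elapsed_t
  A$timing <- c(A$timing, list(tr))
  A$timing_active <- length(A$timing)
  A$exploring <- FALSE
  invisible(A)
}

# apply feedback since the last tick to trackers and the detector
.agent_feedback <- function(A, st) {
  p <- A$p
  # -- resets happen at the press: attribute to the most recent planned shot
  d <- st$n_resets - A$c_resets
  if (d > 0L) {
    A$c_resets <- st$n_resets
    j <- length(A$q_n)
    if (j >= 1L) {
      tr <- A$timing[[A$timing_active]]
      if (A$exploring) {
        A$explore_bad_fast <- c(A$explore_bad_fast, A$q_isi[j])
        A$explore_shots <- A$explore_shots + 1L
      } else {
        n <- min(max(A$q_n[j], tr$range[1]), tr$range[2])
        A$timing[[A$timing_active]] <- record_outcome(tr, n, p$payoff_reset)
        # a shot the aim logic pulled earlier is not a probe of the
        # timing estimate: its reset is self-inflicted, not evidence
        if (A$q_shift[j] > -50) .detect_bad(A, st, n, "reset")
      }
      A$q_open[j] <- FALSE
    }
  }
  # -- resolved missiles, in firing order
  dh <- st$n_hits - A$c_hits
  dm <- st$n_misses - A$c_misses
  if (dh > 0L || dm > 0L) {
    # hits and misses resolve in firing order; pull outcomes in that order
    outs <- c(rep(TRUE, dh), rep(FALSE, dm))
    A$c_hits <- st$n_hits
    A$c_misses <- st$n_misses
    for (hit in outs) {
      while (A$q_head <= length(A$q_n) && !A$q_open[A$q_head]) {
        A$q_head <- A$q_head + 1L
      }
      j <- A$q_head
      if (j > length(A$q_n)) break
      A$q_open[j] <- FALSE
      A$q_head <- j + 1L
      pay <- if (hit) p$payoff_hit else p$payoff_miss
      A$offset <- record_outcome(A$offset, A$q_O[j], pay)
      A$width <- record_outcome(A$width, A$q_W[j], pay)
      A$thr <- record_outcome(A$thr, A$q_thr[j], pay)
      if (A$exploring) {
        # a hit only certifies its interval if no deflation tainted it
        if (hit && !A$explore_defl) A$explore_good <- c(A$explore_good, A$q_isi[j])
        A$explore_defl <- FALSE
        A$explore_shots <- A$explore_shots + 1L
      } else if (hit) {
        tr <- A$timing[[A$timing_active]]
        n <- min(max(A$q_n[j], tr$range[1]), tr$range[2])
        A$timing[[A$timing_active]] <- record_outcome(tr, n, p$payoff_hit)
        # a hit on an interval that already drew a deflation onset does not
        # disconfirm a slowed-down firing window; only a clean hit does
        if (A$defl_flag) A$defl_flag <- FALSE else A$consec_bad <- 0L
      }
    }
  }
  # -- deflation onsets: the current waiting policy is too slow
  d <- st$n_deflations - A$c_defl
  if (d > 0L) {
    A$c_defl <- st$n_deflations
    if (A$exploring) {
      if (!is.na(A$cur_n)) {
        A$explore_bad_slow <- c(A$explore_bad_slow, ticks_to_ms(A$clock, A$cur_n))
        A$explore_defl <- TRUE
        A$explore_shots <- A$explore_shots + 1L
      }
    } else if (!is.na(A$cur_n)) {
      tr <- A$timing[[A$timing_active]]
      n <- min(max(A$cur_n, tr$range[1]), tr$range[2])
      A$timing[[A$timing_active]] <- record_outcome(tr, n, p$payoff_deflation)
      A$defl_flag <- TRUE
      # likewise a shot the aim logic delayed explains its own deflation
      if (A$cur_shift < 50) .detect_bad(A, st, n, "deflation")
    }
  }
  # exploration ends after one completed cycle (a burst) or a shot budget
  if (A$exploring &&
      (st$n_bursts > A$c_bursts || A$explore_shots >= p$explore_max_shots)) {
    .finish_explore(A)
  }
  A$c_bursts <- st$n_bursts
  invisible(A)
}

# penalty feedback near the tracker's own best estimate: evidence of a
# changed environment. A genuine speed change pushes the firing window in
# one direction, so the evidence must be of a consistent type: consecutive
# resets (window moved up: too fast now) or consecutive deflation onsets
# (window moved down: too slow now), with no successful hit in between.
.detect_bad <- function(A, st, n, type) {
  tr <- A$timing[[A$timing_active]]
  p <- A$p
  # armed only once the tracker has real experience behind its estimate
  armed <- tr$m[["w"]] >= p$detect_min_weight &&
    (A$session_ms + st$time_ms) - A$last_change_ms > p$refractory_ms
  if (!armed) return(invisible(A))
  gstep <- (tr$range[2] - tr$range[1]) / (length(tr$grid) - 1)
  V <- tracker_payoff(tr)
  n_best <- tr$grid[which.max(V)]
  # only penalties where the tracker confidently expected reward count:
  # a mediocre estimate drawing mixed feedback is ordinary tuning noise
  if (max(V) > p$detect_min_payoff && abs(n - n_best) <= p$detect_grid_steps * gstep) {
    if (identical(A$bad_type, type)) {
      A$consec_bad <- A$consec_bad + 1L
    } else {
      A$bad_type <- type
      A$consec_bad <- 1L
    }
    if (A$consec_bad >= 2L) .on_speed_change(A, st)
  }
  invisible(A)
}

# plan the next shot: operator-path latency, timing sample, aim turns,
# single or double press
.agent_plan <- function(A, st) {
  p <- A$p
  t <- st$time_ms
  .agent_advance_time(A, t - A$last_plan_ms)
  A$last_plan_ms <- t

  # operator path: interpreted chain vs compiled shortcut
  A$n_plans <- A$n_plans + 1L
  A$plans_game <- A$plans_game + 1L
  compiled_ok <- A$n_plans > p$compile_after
  use_compiled <- FALSE
  if (compiled_ok) {
    uc <- A$u_compiled$U + stats::rlogis(1, 0, p$util_noise)
    ui <- A$u_interp$U + stats::rlogis(1, 0, p$util_noise)
    use_compiled <- uc >= ui
  }
  if (use_compiled) {
    latency <- max(10, stats::rnorm(1, p$motor_mean, p$motor_sd))
    A$u_compiled <- update_utility(A$u_compiled, -latency / 1000)
    A$compiled_game <- A$compiled_game + 1L
  } else {
    latency <- sum(pmax(10, stats::rnorm(p$interp_steps, p$motor_mean, p$motor_sd)))
    A$u_interp <- update_utility(A$u_interp, -latency / 1000)
    if (!compiled_ok && A$n_plans == p$compile_after) {
      # the compiled production inherits its parent's utility when formed
      A$u_compiled$U <- A$u_interp$U
    }
  }

  # shot timing: tracker sample (or uniform exploration), paced by the clock
  if (A$exploring) {
    n_ticks <- sample(seq(p$explore_ticks[1], p$explore_ticks[2]), 1L)
  } else {
    n_ticks <- tracker_sample(A$timing[[A$timing_active]])
  }
  A$cur_n <- n_ticks
  wait_ms <- wait_for_ticks(A$clock, round(n_ticks))
  t0 <- if (is.finite(st$last_shot)) st$last_shot else st$cycle_start
  Tf <- max(t0 + wait_ms, t + latency) + stats::rnorm(1, p$motor_mean, p$motor_sd)

  # aim: project the error to the fire time, quantised 15-degree turns
  O <- tracker_sample(A$offset)
  W <- tracker_sample(A$width)
  thr <- tracker_sample(A$thr)
  e_now <- .wrap180(st$nose_angle - (st$orbit_angle + 180))
  eT <- .wrap180(e_now - st$ang_step * (Tf - t) / st$tick_ms)
  k <- round((O - eT) / st$turn)
  r <- eT + k * st$turn - O
  if (r < thr) {  # long path: one extra turn, then wait out the overshoot
    k <- k + 1
    r <- r + st$turn
  }
  Tf_paced <- Tf  # fire time the timing tracker asked for
  if (abs(r) > W) {
    # drain part of the residual by shifting the fire time, but never by
    # more than ~190 ms: pacing belongs to the timing tracker, and larger
    # shifts would push the inter-shot interval out of any firing window
    shift <- max(-12, min(12, round(r / st$ang_step)))
    Tf <- Tf + shift * st$tick_ms
  }
  Tf <- max(Tf, t + 3 * st$tick_ms)

  times <- numeric(0); keys <- integer(0)
  kk <- min(abs(k), 9)
  if (kk > 0) {
    tt <- t + 2 * st$tick_ms + 6 * st$tick_ms * (seq_len(kk) - 1)
    Tf <- max(Tf, tt[kk] + 3 * st$tick_ms)
    times <- c(times, tt)
    keys <- c(keys, rep(if (k > 0) 2L else 1L, kk))
  }
  q16 <- st$tick_ms
  Tf <- round(Tf / q16) * q16
  times <- round(times / q16) * q16
  times <- c(times, Tf); keys <- c(keys, 3L)
  presses <- Tf
  pending <- length(st$m_arr) - st$m_head + 1L
  if (st$vuln + pending >= 10L) {
    # the within-pair gap varies trial to trial (motor noise), which keeps
    # the double shot under 250 ms without imprinting a fixed short lag
    # onto the shot-series autocorrelation
    gap <- p$double_gap_ms + stats::runif(1, 0, 100)
    T2 <- round((Tf + gap) / q16) * q16
    times <- c(times, T2); keys <- c(keys, 3L)
    presses <- c(presses, T2)
  }
  ord <- order(times)
  A$sch_t <- times[ord]; A$sch_k <- keys[ord]
  A$sch_head <- 1L
  A$next_t <- A$sch_t[1]
  A$cur_shift <- Tf - Tf_paced

  # queue attribution contexts, one per shot press
  prev <- c(t0, presses[-length(presses)])
  A$q_shift <- c(A$q_shift, rep(Tf - Tf_paced, length(presses)))
  A$q_n <- c(A$q_n, rep(n_ticks, length(presses)))
  A$q_O <- c(A$q_O, rep(O, length(presses)))
  A$q_W <- c(A$q_W, rep(W, length(presses)))
  A$q_thr <- c(A$q_thr, rep(thr, length(presses)))
  A$q_press <- c(A$q_press, presses)
  A$q_isi <- c(A$q_isi, presses - prev)
  A$q_open <- c(A$q_open, rep(TRUE, length(presses)))
  invisible(A)
}

#' Per-tick key policy of an agent
#'
#' Returns the policy closure to hand to [run_game()]. The agent keeps its
#' trackers, utilities and internal clock across games; call
#' [agent_reset_game()] (done by [play_condition()]) between games.
#'
#' @param A an [new_agent()] environment.
#' @return function mapping game state to held keys (logical A/D/L).
#' @export
agent_policy <- function(A) {
  hold <- A$p$hold_ms
  none <- c(FALSE, FALSE, FALSE)
  function(st) {
    t <- st$time_ms
    if (st$n_events != A$c_nev) {
      A$c_nev <- st$n_events
      .agent_feedback(A, st)
      if (st$n_respawns != A$c_respawns) {
        # new cycle: cancel presses aimed at the balloon that is gone
        A$c_respawns <- st$n_respawns
        drop <- A$sch_t > t - hold
        if (any(drop)) {
          cancelled <- A$q_open & A$q_press %in% A$sch_t[drop & A$sch_k == 3L]
          A$q_open[cancelled] <- FALSE
          A$sch_t <- A$sch_t[!drop]; A$sch_k <- A$sch_k[!drop]
        }
        A$sch_head <- length(A$sch_t) + 1L
        A$next_t <- t
      }
    }
    if (t < A$next_t) return(none)
    n <- length(A$sch_t)
    if (A$sch_head > n) {
      .agent_plan(A, st)
      if (t < A$next_t) return(none)
      n <- length(A$sch_t)
    }
    while (A$sch_head <= n && A$sch_t[A$sch_head] + hold <= t) {
      A$sch_head <- A$sch_head + 1L
    }
    hA <- FALSE; hD <- FALSE; hL <- FALSE
    i <- A$sch_head
    while (i <= n && A$sch_t[i] <= t) {
      kk <- A$sch_k[i]
      if (kk == 1L) hA <- TRUE else if (kk == 2L) hD <- TRUE else hL <- TRUE
      i <- i + 1L
    }
    A$next_t <- if (A$sch_head > n || A$sch_t[A$sch_head] <= t) t else A$sch_t[A$sch_head]
    c(hA, hD, hL)
  }
}

#' Reset an agent's per-game state
#'
#' Clears schedules and feedback bookkeeping at a game boundary while
#' keeping all learned state (trackers, utilities, plan count).
#'
#' @param A an [new_agent()] environment.
#' @return the agent, invisibly.
#' @export
agent_reset_game <- agent_reset_game

#' Run one agent session through an ABA condition
#'
#' Plays the 15 games of a condition (5 games per phase: Start, Middle,
#' Final, with the middle phase at the other speed in the transfer
#' conditions HLH and LHL), carrying the agent's learned state across
#' games. Per-game engine seeds are derived reproducibly from `seed`.
#'
#' @param variant agent variant, see [new_agent()].
#' @param condition `"HHH"`, `"HLH"`, `"LHL"` or `"LLL"`.
#' @param seed integer session seed.
#' @param n_games games in the session (15 in the full design).
#' @param params agent parameter overrides.
#' @return an [orbit_log] with `n_games` games; the agent is attached as
#'   attribute `"agent"` for inspection.
#' @export
play_condition <- function(variant = .AGENT_VARIANTS,
                           condition = c("HHH", "HLH", "LHL", "LLL"),
                           seed = 1, n_games = 15, params = list()) {
  variant <- match.arg(variant)
  condition <- match.arg(condition)
  speeds <- condition_speeds(condition, n_games)
  set.seed(as.integer(seed))
  game_seeds <- sample.int(.Machine$integer.max - 1, n_games)
  A <- new_agent(variant, params)
  logs <- vector("list", n_games)
  for (g in seq_len(n_games)) {
    cfg <- game_config(speeds[g])
    agent_reset_game(A)
    logs[[g]] <- run_game(agent_policy(A), cfg, seed = game_seeds[g],
                          game_index = g, condition = condition)
    A$session_ms <- A$session_ms + cfg$game_duration_ms
  }
  out <- bind_logs(logs, condition,
                   meta = list(variant = variant, seed = seed))
  attr(out, "agent") <- A
  out
}

#' Number of shot-timing trackers an agent holds
#'
#' @param A an agent, or a session log returned by [play_condition()].
#' @return integer count.
#' @export
n_timing_trackers <- function(A) {
  if (inherits(A, "orbit_log")) A <- attr(A, "agent")
  length(A$timing)
}

#' Compiled-path share of plans, per game
#'
#' Fraction of planning passes taken through the compiled shortcut in each
#' completed game so far (including the game in progress, if any plans have
#' been made in it).
#'
#' @param A an agent.
#' @return numeric vector of per-game fractions in [0, 1].
#' @export
compiled_share <- function(A) {
  cur <- if (A$plans_game > 0L) A$compiled_game / A$plans_game else numeric(0)
  c(A$share_hist, cur)
}
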