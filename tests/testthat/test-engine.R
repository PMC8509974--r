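cfg_hi <- game_config("high")

test_that("init_game starts a defined, reproducible state", {
  st <- init_game(cfg_hi, seed = 1)
  expect_equal(st$cfg$firing_lower_bound, 500)
  expect_equal(st$vuln, 0L)
  expect_equal(st$ev_kind[1], 7L)  # opening balloon-respawn
  st_lo <- init_game(game_config("low"), seed = 1)
  expect_equal(st_lo$cfg$firing_lower_bound, 1000)
  expect_equal(st_lo$cfg$firing_upper_bound, 2400)
  expect_error(init_game(game_config("high", firing_upper_bound = 100), 1),
               "configuration")
})

test_that("identical config, seed and policy give byte-identical logs", {
  short <- game_config("high", game_duration_ms = 32000)
  l1 <- run_game(policy_metronome(short), short, seed = 99)
  l2 <- run_game(policy_metronome(short), short, seed = 99)
  expect_identical(l1$events, l2$events)
  expect_identical(l1$games, l2$games)
})

test_that("an idle tick advances the orbit and emits nothing", {
  st <- init_game(cfg_hi, seed = 1)
  a0 <- st$orbit_angle
  res <- step(st, character(0))
  expect_equal(nrow(res$events), 0)
  # 0.5 px of arc per tick
  expect_equal((st$orbit_angle - a0) * pi / 180 * cfg_hi$orbit_radius, 0.5,
               tolerance = 1e-9)
  # unknown keys are ignored
  expect_silent(step(st, c("X", "Q")))
})

test_that("shot-timing resolution splits at the firing lower bound", {
  expect_equal(resolve_shot_timing(800, cfg_hi), "valid")
  expect_equal(resolve_shot_timing(400, cfg_hi), "reset")
  expect_equal(resolve_shot_timing(1200, game_config("low")), "valid")
  expect_equal(resolve_shot_timing(900, game_config("low")), "reset")
  expect_error(resolve_shot_timing(-5, cfg_hi))
})

test_that("a too-fast second shot pops the balloon: vulnerability reset event", {
  st <- init_game(cfg_hi, seed = 1)
  fire_at <- function(st, target_ms) {
    while (st$time_ms < target_ms) step(st, character(0))
    step(st, "L")$events
  }
  fire_at(st, 1000)
  step(st, character(0))  # release
  ev <- fire_at(st, 1400)  # 400 ms after the previous shot: too fast
  expect_true("vulnerability-reset" %in% ev$kind)
  expect_equal(st$vuln, 0L)
})

test_that("ten paced aimed shots inflate to full vulnerability", {
  st <- init_game(cfg_hi, seed = 1)
  shots <- 0
  while (shots < 10) {
    # aim dead-on just before firing, then fire at a legal pace
    target <- st$time_ms + 800
    while (st$time_ms < target) step(st, character(0))
    st$nose_angle <- (st$orbit_angle + 180) %% 360
    step(st, "L")
    step(st, character(0))
    shots <- shots + 1
  }
  for (i in 1:40) step(st, character(0))  # let the last missile land
  expect_equal(st$vuln, 10L)
  expect_equal(st$n_vulninc, 10L)
  ev_kinds <- st$ev_kind[seq_len(st$n_events)]
  expect_equal(sum(ev_kinds == 5L), 10)  # vulnerability-increase events
})

test_that("missile geometry: dead-on hits, 90 degrees off misses with -2", {
  hit <- resolve_missile(0, 8, cfg_hi)
  expect_true(hit$hit)
  miss <- resolve_missile(90, 18, cfg_hi)
  expect_false(miss$hit)
  # a full game: firing 90 degrees off costs 2 points per miss
  st <- init_game(cfg_hi, seed = 2)
  st$nose_angle <- (st$orbit_angle + 180 + 90) %% 360
  step(st, "L")
  for (i in 1:100) step(st, character(0))
  expect_equal(st$n_misses, 1L)
  expect_equal(st$score, -2)
})

test_that("double shot at full vulnerability bursts; slow second shot only re-arms", {
  st <- init_game(cfg_hi, seed = 1)
  st$vuln <- 10L
  st$size <- st$base_size + 10 * st$step_px
  aim_fire <- function(st) {
    st$nose_angle <- (st$orbit_angle + 180) %% 360
    step(st, "L")
    step(st, character(0))
  }
  t0 <- st$time_ms
  aim_fire(st)  # arming hit on the full balloon
  while (st$time_ms < t0 + 96) step(st, character(0))
  aim_fire(st)  # hits 96 ms after the first: inside the 250 ms window
  for (i in 1:40) step(st, character(0))
  expect_equal(st$n_bursts, 1L)
  expect_equal(st$score, cfg_hi$points_per_burst)
  # a second full-vulnerability hit outside the window only re-arms
  st2 <- init_game(cfg_hi, seed = 1)
  st2$vuln <- 10L
  st2$size <- st2$base_size + 10 * st2$step_px
  t0 <- st2$time_ms
  aim_fire(st2)
  while (st2$time_ms < t0 + 600) step(st2, character(0))
  aim_fire(st2)
  for (i in 1:40) step(st2, character(0))
  expect_equal(st2$n_bursts, 0L)
})

test_that("rotation scheduling: 1/3 rate, onsets inside 1-4 s, grace respected", {
  set.seed(11)
  draws <- replicate(3000, !is.null(schedule_rotation(0, cfg_hi)))
  ci <- stats::binom.test(sum(draws), 3000, p = 1 / 3)$p.value
  expect_gt(ci, 0.001)
  set.seed(12)
  rots <- Filter(Negate(is.null),
                 replicate(300, schedule_rotation(10000, cfg_hi), simplify = FALSE))
  on <- vapply(rots, `[[`, numeric(1), "onset_ms")
  mag <- vapply(rots, `[[`, numeric(1), "angle")
  expect_true(all(on >= 11000 & on <= 14000))
  expect_true(all(abs(mag) >= 60 & abs(mag) <= 120))
  # after a rotation with no shot, deflation starts exactly at grace expiry
  st <- init_game(cfg_hi, seed = 3)
  st$rot_onset <- 480
  st$rot_angle <- 90
  while (st$time_ms <= 480) step(st, character(0))
  expect_true(st$defl_deadline >= 480 + cfg_hi$post_rotation_grace)
  while (!st$deflating) step(st, character(0))
  onset <- st$ev_ts[seq_len(st$n_events)][st$ev_kind[seq_len(st$n_events)] == 9L]
  expect_equal(onset, 480 + cfg_hi$post_rotation_grace)
})

test_that("an idle game scores zero with at least one deflation onset", {
  log <- run_game(policy_idle(), cfg_hi, seed = 5)
  expect_equal(log$games$final_score, 0)
  expect_gte(sum(log$events$kind == "balloon-deflation-onset"), 1)
  expect_equal(log$games$n_ticks, 11250L)
  expect_true(all(log$events$timestamp_ms <= 180000))
})

test_that("score conservation: points per burst times bursts minus 2 per miss", {
  for (speed in c("high", "low")) {
    cfg <- game_config(speed)
    log <- run_game(policy_metronome(cfg), cfg, seed = 8)
    b <- sum(log$events$kind == "balloon-burst")
    m <- sum(log$events$kind == "missile-miss")
    expect_gt(b, 0)
    expect_equal(log$games$final_score, cfg$points_per_burst * b - 2 * m)
  }
})

test_that("vulnerability stays within 0..10 and resets on respawn", {
  cfg <- game_config("high", game_duration_ms = 60 * 1000)
  st <- init_game(cfg, seed = 13)
  pol <- policy_metronome(cfg)
  vmax <- 0L
  while (!st$ended) {
    k <- pol(st)
    step(st, c("A", "D", "L")[k])
    vmax <- max(vmax, st$vuln)
    if (st$pending_respawn) expect_equal(st$vuln, 0L)
  }
  expect_lte(vmax, 10L)
  expect_gte(vmax, 10L)  # the metronome does reach full inflation
})

test_that("orbit revolution takes 25 s at high speed and twice that at low", {
  for (mult in c(1, 0.5)) {
    cfg <- game_config(if (mult == 1) "high" else "low")
    st <- init_game(cfg, seed = 1)
    ticks <- 0
    repeat {
      step(st, character(0))
      ticks <- ticks + 1
      if (st$orbit_angle < st$ang_step) break  # wrapped past 360
    }
    expect_equal(ticks * 0.016, 25 / mult, tolerance = 0.1 / 25)
  }
})

test_that("policy errors propagate with tick context", {
  bad <- function(st) if (st$time_ms >= 160) stop("boom") else c(FALSE, FALSE, FALSE)
  expect_error(run_game(bad, cfg_hi, seed = 1), "tick 10.*boom")
})
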