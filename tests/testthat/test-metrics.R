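test_that("cycle segmentation: complete cycles only, rotations flagged", {
  ts <- c(0, 500, 1000, 1500, 2000, 2500, 3000)
  kind <- c("balloon-respawn", "balloon-burst",
            "balloon-respawn", "random-rotation", "balloon-burst",
            "balloon-respawn", "missile-fired")  # trailing incomplete cycle
  log <- tiny_log(ts, kind)
  cyc <- segment_cycles(log)
  expect_equal(nrow(cyc), 2)
  expect_equal(cyc$has_rotation, c(FALSE, TRUE))
  # burst before any respawn is a format error
  expect_error(segment_cycles(tiny_log(c(0, 100), c("balloon-burst", "balloon-respawn"))),
               "format error")
  # a log with no complete cycle yields an empty cycle list
  none <- tiny_log(0, "balloon-respawn")
  expect_equal(nrow(segment_cycles(none)), 0)
})

test_that("performance counts are capped and cap application is idempotent", {
  ts <- c(0, seq(16, by = 16, length.out = 150), seq(4000, by = 16, length.out = 250))
  kind <- c("balloon-respawn", rep("vulnerability-reset", 150), rep("missile-miss", 250))
  log <- tiny_log(ts, kind, score = -123)
  perf <- performance_summary(log)
  expect_equal(perf$resets, 100)
  expect_equal(perf$misses, 200)
  expect_equal(perf$score, -123)
  expect_equal(min(perf$resets, 100), perf$resets)
  # a perfect scripted player has no penalty events at all
  clean <- periodic_shooter(script_spec(isi_mean = 800, seed = 1))
  p2 <- performance_summary(clean)
  expect_equal(c(p2$resets, p2$deflations, p2$misses), c(0, 0, 0))
})

test_that("triple entropy matches a hand-computed smoothed distribution", {
  expect_equal(round(shannon_entropy(rep(1 / 27, 27)), 2), 4.75)
  # sequence L L L L L L A D L: triples LLL, LLL, ADL
  presses <- c("L", "L", "L", "L", "L", "L", "A", "D", "L")
  ts <- c(0, 16 * seq_along(presses), 16 * length(presses) + 16)
  kind <- c("balloon-respawn", rep("hold-key", 9), "balloon-burst")
  log <- tiny_log(ts, kind, payload = c("", presses, ""))
  h <- triple_entropy(log, 1)
  p_hand <- c(3, 2, rep(1, 25)) / 30  # add-one smoothing of counts (2, 1, 0 x 25)
  expect_equal(h, -sum(p_hand * log2(p_hand)))
  # fewer than one complete triple: undefined, flagged NA rather than zero
  short <- tiny_log(c(0, 16, 32, 64), c("balloon-respawn", "hold-key", "hold-key",
                                        "balloon-burst"),
                    payload = c("", "L", "L", ""))
  expect_true(is.na(triple_entropy(short, 1)))
})

test_that("entropy is invariant under a consistent permutation of key labels", {
  spec <- script_spec(triple_distribution = (1:27) / sum(1:27), seed = 7)
  log <- triple_sampler(spec, n_triples = 900)
  h1 <- triple_entropy(log)
  swapped <- log
  map <- c(A = "D", D = "L", L = "A")
  idx <- swapped$events$kind %in% c("hold-key", "release-key")
  swapped$events$payload[idx] <- map[swapped$events$payload[idx]]
  expect_equal(triple_entropy(swapped), h1)
})

test_that("log CV of inter-shot intervals matches the direct formula", {
  log <- shots_log(c(96, 596, 1196, 1896))  # ISIs 500, 600, 700
  cv <- sqrt(mean((c(500, 600, 700) - 600)^2)) / 600
  expect_equal(log_cv_isi(log, 1), log(cv))
  expect_equal(round(log_cv_isi(log, 1), 3), -1.994)
  # constant intervals: CV 0, logarithm undefined, flagged invalid
  const <- shots_log(seq(96, by = 560, length.out = 6))
  expect_true(is.na(log_cv_isi(const, 1)))
  # scripted shooter recovery at n = 500 shots
  spec <- script_spec(isi_mean = 560, isi_jitter_sd = 20, n_games = 2, seed = 8)
  lg <- periodic_shooter(spec)
  rec <- exp(log_cv_isi(lg, 1))
  expect_lt(abs(rec - 20 / 560) / (20 / 560), 0.1)
})

test_that("the binary shot series mirrors hold and release events", {
  ts <- c(0, 160, 208, 800, 816, 2000)
  kind <- c("balloon-respawn", "hold-key", "release-key", "hold-key",
            "release-key", "balloon-burst")
  payload <- c("", "L", "L", "L", "L", "")
  log <- tiny_log(ts, kind, payload)
  x <- shot_series(log, 1, 0, 2000)
  expect_equal(length(x), 125)
  expect_equal(which(x == 1), c(11, 12, 13, 51))  # held 3 ticks, then 1 tick
  expect_equal(sum(shot_series(shots_log(c(800)), 1, 0, 640)), 0)
})

test_that("the autocorrelation follows the lag-0-normalised definition", {
  set.seed(9)
  x <- rbinom(400, 1, 0.2)
  r <- acf_series(x, 50)
  expect_equal(r[1], 1)
  # independent oracle: direct evaluation of the normalised sum
  xb <- mean(x)
  den <- sum((x - xb)^2)
  hand <- vapply(0:50, function(l) {
    sum((x[1:(400 - l)] - xb) * (x[(1 + l):400] - xb)) / den
  }, numeric(1))
  expect_equal(r, hand, tolerance = 1e-12)
  expect_true(all(abs(r) <= 1 + 1e-9))
  # strictly periodic impulse train: maxima at multiples of the period
  per <- integer(3750); per[seq(1, 3750, by = 35)] <- 1L
  rp <- acf_series(per, 125)
  peaks <- which(diff(sign(diff(rp))) == -2)  # position i: local max at lag i
  expect_true(all(c(35, 70, 105) %in% peaks))
  # white noise: no spurious structure beyond the Bartlett band
  set.seed(10)
  w <- rnorm(10000)
  rw <- acf_series(w, 125)
  expect_true(all(abs(rw[-1]) < 0.05, na.rm = TRUE))
  # constant series: undefined, all NA
  expect_true(all(is.na(acf_series(rep(1, 500), 20))))
})

test_that("scripted periodic shooters yield their generating periodicity", {
  lg35 <- periodic_shooter(script_spec(isi_mean = 35 * 16, seed = 11))
  pr35 <- periodicity_regularity(lg35, 1)
  expect_true(pr35$valid)
  expect_equal(pr35$periodicity_ms, 560)
  lg80 <- periodic_shooter(script_spec(isi_mean = 80 * 16, seed = 12))
  pr80 <- periodicity_regularity(lg80, 1)
  expect_equal(pr80$periodicity_ms, 1280)
  # sub-threshold peaks invalidate the game rather than report noise
  r <- c(1, rep(0, 125)); r[31] <- 0.015
  expect_null(first_acf_peak(r))
  r[31] <- 0.03
  expect_equal(first_acf_peak(r)$periodicity_ms, 30 * 16)
})

test_that("periodicity recovery is exact-to-one-lag under small jitter and
           regularity decreases with jitter", {
  cases <- expand.grid(seed = 1:20, sd_ticks = 0:2)  # jitter sd up to 2 ticks
  lags_off <- vapply(seq_len(nrow(cases)), function(i) {
    lg <- periodic_shooter(script_spec(isi_mean = 35 * 16,
                                       isi_jitter_sd = cases$sd_ticks[i] * 16,
                                       seed = 400 + cases$seed[i]))
    pr <- periodicity_regularity(lg, 1)
    if (!pr$valid) return(Inf)
    abs(pr$periodicity_ms / 16 - 35)
  }, numeric(1))
  expect_gte(mean(lags_off <= 1), 0.95)
  regs <- vapply(c(0, 1, 2, 4, 8), function(sd_ticks) {
    mean(vapply(1:4, function(s) {
      lg <- periodic_shooter(script_spec(isi_mean = 35 * 16,
                                         isi_jitter_sd = sd_ticks * 16,
                                         seed = 500 + s))
      periodicity_regularity(lg, 1)$regularity
    }, numeric(1)))
  }, numeric(1))
  expect_equal(stats::cor(regs, c(0, 1, 2, 4, 8), method = "spearman"), -1)
})

test_that("motor-learning measures skip rotation cycles; performance keeps them", {
  # two cycles: the first clean with 560-ms pacing, the second rotated with
  # wild 250-ms pacing that would corrupt the CV if included
  c1 <- c(96, 656, 1216, 1776)
  c2 <- c(3000, 3250, 3500, 3750)
  ts <- c(0, rep(c1, each = 3) + rep(c(0, 0, 16), 4), 2200,
          2400, 2900, rep(c2, each = 3) + rep(c(0, 0, 16), 4), 4000)
  kind <- c("balloon-respawn", rep(c("hold-key", "missile-fired", "release-key"), 4),
            "balloon-burst",
            "balloon-respawn", "random-rotation",
            rep(c("hold-key", "missile-fired", "release-key"), 4), "balloon-burst")
  payload <- c("", rep(c("L", "", "L"), 4), "",
               "", "45.00", rep(c("L", "", "L"), 4), "")
  ord <- order(ts)
  log <- tiny_log(ts[ord], kind[ord], payload[ord])
  # CV uses only the clean cycle: its ISIs are exactly constant -> flagged
  expect_true(is.na(log_cv_isi(log, 1)))
  m <- game_metrics(log)
  expect_equal(m$resets, 0)
  expect_equal(nrow(m), 1)
})

test_that("session metrics stack runs into the transfer input shape", {
  logs <- list(a = periodic_shooter(script_spec(isi_mean = 700, n_games = 2, seed = 1)),
               b = periodic_shooter(script_spec(isi_mean = 700, n_games = 2, seed = 2)))
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- session_metrics(logs, file = path)
  expect_equal(nrow(tab), 4)
  expect_true(all(c("run", "game_index", "score", "entropy", "log_cv_isi",
                    "periodicity_ms", "regularity", "valid_peak") %in% names(tab)))
  expect_true(file.exists(path))
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 4)
})
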