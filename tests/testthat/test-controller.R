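test_that("temperature anneals as A / (1 + B t)", {
  sch <- temperature_schedule()
  expect_equal(temperature(sch, 0), 1.0)
  expect_equal(temperature(sch, 180), 0.5)
  ts <- seq(0, 2000, by = 10)
  expect_true(all(diff(temperature(sch, ts)) < 0))
  expect_error(temperature(sch, -1), "non-negative")
})

test_that("softmax sampling is a proper distribution over the grid", {
  tr <- new_tracker(10, 30)
  p <- tracker_probs(tr)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p > 0))
  # constant payoff estimate: sampling is uniform over the grid
  set.seed(1)
  draws <- replicate(10000, tracker_sample(tr))
  tab <- table(factor(draws, levels = tr$grid))
  chi <- suppressWarnings(stats::chisq.test(tab))
  expect_gt(chi$p.value, 0.001)
  # strongly curved payoff at low temperature: the mode takes almost all draws
  tr2 <- new_tracker(10, 30)
  for (i in 1:200) {
    S <- sample(tr2$grid, 1)
    tr2 <- record_outcome(tr2, S, 1 - 0.5 * (S - 20)^2)
  }
  tr2$elapsed_t <- 180 * 99  # T = 0.01
  set.seed(2)
  draws2 <- replicate(2000, tracker_sample(tr2))
  expect_gt(mean(draws2 == 20), 0.99)
  expect_error(tracker_sample(new_tracker(0, 1, grid_resolution = 1)),
               "degenerate|resolution")
})

test_that("the quadratic payoff estimate recovers a noiseless generating quadratic", {
  truth <- function(S) 2 - 0.03 * (S - 21)^2
  tr <- new_tracker(10, 30)
  set.seed(3)
  for (i in 1:200) {
    S <- sample(tr$grid, 1)
    tr <- record_outcome(tr, S, truth(S))
  }
  V <- tracker_payoff(tr)
  gstep <- diff(tr$grid[1:2])
  expect_lt(abs(tr$grid[which.max(V)] - 21), gstep / 2 + 1e-9)
  # single observation: under-determined fit stays close to the flat prior
  tr1 <- record_outcome(new_tracker(10, 30), 20, 1)
  expect_true(all(is.finite(tracker_payoff(tr1))))
})

test_that("exponential forgetting lets the estimate track a moved payoff peak", {
  tr <- new_tracker(0, 20, lambda = 0.99)
  set.seed(4)
  hist_S <- numeric(0); hist_y <- numeric(0)
  feed <- function(tr, S0, n) {
    for (i in seq_len(n)) {
      S <- sample(tr$grid, 1)
      y <- 1 - 0.05 * (S - S0)^2
      hist_S <<- c(hist_S, S); hist_y <<- c(hist_y, y)
      tr <- record_outcome(tr, S, y)
    }
    tr
  }
  tr <- feed(tr, 5, 200)
  expect_lt(abs(tr$grid[which.max(tracker_payoff(tr))] - 5), 1.01)
  tr <- feed(tr, 15, 500)
  expect_lt(abs(tr$grid[which.max(tracker_payoff(tr))] - 15), 1.01)
  # oracle: the constant-memory moment fit equals the weighted least-squares
  # fit recomputed from the full history with geometric weights
  w <- 0.99^(rev(seq_along(hist_S)) - 1)
  u <- (hist_S - 10) / 10
  X <- cbind(1, u, u^2)
  beta <- solve(crossprod(X * sqrt(w)) + diag(1e-6, 3),
                crossprod(X, w * hist_y))
  ug <- (tr$grid - 10) / 10
  expect_equal(tracker_payoff(tr),
               as.numeric(beta[1] + beta[2] * ug + beta[3] * ug^2),
               tolerance = 1e-8)
})

test_that("suspension freezes tracker state exactly; reset touches only the clock", {
  tr <- new_tracker(10, 30)
  set.seed(5)
  for (i in 1:50) tr <- record_outcome(tr, sample(tr$grid, 1), rnorm(1))
  tr <- tracker_advance(tr, 300)
  frozen <- suspend(tr)
  frozen2 <- tracker_advance(frozen, 500)  # no annealing while suspended
  expect_equal(frozen2$elapsed_t, tr$elapsed_t)
  back <- resume(frozen2)
  expect_equal(tracker_payoff(back), tracker_payoff(tr))
  expect_equal(tracker_temperature(back), tracker_temperature(tr))
  expect_warning(resume(back), "already active")
  # temperature reset: T back to A, payoff argmax untouched, idempotent
  r1 <- reset_temperature(tr)
  expect_equal(tracker_temperature(r1), 1.0)
  expect_equal(reset_temperature(r1), r1)
  expect_equal(which.max(tracker_payoff(r1)), which.max(tracker_payoff(tr)))
})

test_that("annealing concentrates sampling: distribution entropy is non-increasing", {
  tr <- new_tracker(10, 30)
  set.seed(6)
  for (i in 1:100) {
    S <- sample(tr$grid, 1)
    tr <- record_outcome(tr, S, 1 - 0.02 * (S - 22)^2)
  }
  ent <- vapply(c(0, 60, 180, 600, 1800), function(t) {
    tr$elapsed_t <- t
    p <- tracker_probs(tr)
    -sum(p * log(p))
  }, numeric(1))
  expect_true(all(diff(ent) <= 1e-12))
})

test_that("a shot-timing tracker locks onto a rewarded firing window", {
  # payoff +1 inside the true window, -1 outside; one selection per
  # simulated second for 120 s of tuning
  tr <- new_tracker(10, 30, label = "shot timing")
  set.seed(7)
  for (i in 1:120) {
    S <- tracker_sample(tr)
    tr <- record_outcome(tr, S, if (S >= 18 && S <= 25) 1 else -1)
    tr <- tracker_advance(tr, 1)
  }
  draws <- replicate(400, tracker_sample(tr))
  expect_gt(mean(draws >= 18 & draws <= 25), 0.8)
})
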