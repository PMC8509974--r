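# The eight behavioral measures: four performance counts with caps and
# four motor-learning measures (keypress-triple entropy, log CV of
# inter-shot intervals, shot periodicity and shot regularity from the
# autocorrelation of the shot-key series). Motor-learning measures are
# computed over game cycles (balloon-respawn to balloon-burst) that contain
# no random rotation; performance counts use all cycles.

.RESET_CAP <- 100L
.DEFLATION_CAP <- 100L
.MISS_CAP <- 200L
.ACF_LAGS <- 125L
.PEAK_MIN <- 0.02

#' Segment a game's events into cycles
#'
#' A cycle runs from a balloon-respawn event to the next balloon-burst
#' event; a trailing respawn with no burst is an incomplete cycle and is
#' dropped. Cycles containing a random-rotation event are flagged: they are
#' excluded from the motor-learning measures but retained for the
#' performance counts.
#'
#' @param log an [orbit_log].
#' @param game game index to segment (default: each game in the log).
#' @return data.frame with columns `game_index`, `cycle`, `start`, `end`,
#'   `has_rotation`.
#' @export
segment_cycles <- function(log, game = NULL) {
  ev <- log$events
  games <- if (is.null(game)) sort(unique(ev$game_index)) else game
  out <- vector("list", length(games))
  for (i in seq_along(games)) {
    g <- games[i]
    e <- ev[ev$game_index == g, ]
    respawns <- e$timestamp_ms[e$kind == "balloon-respawn"]
    bursts <- e$timestamp_ms[e$kind == "balloon-burst"]
    if (length(bursts) && (!length(respawns) || bursts[1] < respawns[1])) {
      stop("format error: balloon-burst before any balloon-respawn in game ", g)
    }
    rot <- e$timestamp_ms[e$kind == "random-rotation"]
    n <- min(length(respawns), length(bursts))
    if (n == 0) {
      out[[i]] <- data.frame(game_index = integer(0), cycle = integer(0),
                             start = numeric(0), end = numeric(0),
                             has_rotation = logical(0))
      next
    }
    start <- respawns[seq_len(n)]
    end <- bursts[seq_len(n)]
    has_rot <- vapply(seq_len(n), function(k) {
      any(rot >= start[k] & rot <= end[k])
    }, logical(1))
    out[[i]] <- data.frame(game_index = g, cycle = seq_len(n),
                           start = start, end = end, has_rotation = has_rot)
  }
  do.call(rbind, out)
}

#' Capped performance counts per game
#'
#' Score is taken from the log header; resets and deflations are the event
#' counts capped at 100 per game; misses are the missile-miss count capped
#' at 200 per game. (With every scripted or simulated missile resolving as
#' exactly one of hit or miss, the missile-miss count equals fired missiles
#' minus balloon hits.)
#'
#' @param log an [orbit_log].
#' @return data.frame with one row per game: `game_index`, `score`,
#'   `resets`, `deflations`, `misses`.
#' @export
performance_summary <- function(log) {
  ev <- log$events
  games <- sort(unique(log$games$game_index))
  do.call(rbind, lapply(games, function(g) {
    e <- ev[ev$game_index == g, ]
    data.frame(
      game_index = g,
      score = log$games$final_score[log$games$game_index == g],
      resets = min(sum(e$kind == "vulnerability-reset"), .RESET_CAP),
      deflations = min(sum(e$kind == "balloon-deflation-onset"), .DEFLATION_CAP),
      misses = min(sum(e$kind == "missile-miss"), .MISS_CAP)
    )
  }))
}

#' Shannon entropy of a probability distribution, base 2
#'
#' Terms with zero probability contribute zero.
#'
#' @param p probability vector (non-negative, summing to 1 within 1e-6).
#' @return entropy in bits.
#' @examples
#' shannon_entropy(rep(1 / 27, 27))  # 4.7548...
#' shannon_entropy(c(1, rep(0, 26)))  # 0
#' @export
shannon_entropy <- function(p) {
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-6)
  p <- p[p > 0]
  -sum(p * log2(p)) + 0  # + 0 normalises the sign of a zero entropy
}

# keypress symbols of a game's eligible cycles, concatenated in time order
.eligible_presses <- function(log, g, cycles = NULL) {
  if (is.null(cycles)) cycles <- segment_cycles(log, g)
  cyc <- cycles[cycles$game_index == g & !cycles$has_rotation, ]
  ev <- log$events
  e <- ev[ev$game_index == g & ev$kind == "hold-key", ]
  keep <- logical(nrow(e))
  for (k in seq_len(nrow(cyc))) {
    keep <- keep | (e$timestamp_ms >= cyc$start[k] & e$timestamp_ms <= cyc$end[k])
  }
  e$payload[keep][order(e$timestamp_ms[keep])]
}

#' Keypress-triple counts and smoothed probabilities
#'
#' Partitions a keypress symbol sequence into consecutive non-overlapping
#' triples starting at the first press (a remainder shorter than three is
#' dropped), counts each of the 27 ordered triples, and applies add-one
#' (Laplace) smoothing.
#'
#' @param presses character vector of key symbols in time order.
#' @return list with `counts` (named integer, length 27), `p` (smoothed
#'   probabilities) and `n_triples`.
#' @export
triple_counts <- function(presses) {
  n3 <- length(presses) %/% 3
  triples <- key_triples()
  counts <- stats::setNames(integer(27), triples)
  if (n3 > 0) {
    idx <- seq_len(3 * n3)
    words <- paste0(presses[idx[c(TRUE, FALSE, FALSE)]],
                    presses[idx[c(FALSE, TRUE, FALSE)]],
                    presses[idx[c(FALSE, FALSE, TRUE)]])
    tab <- table(factor(words, levels = triples))
    counts[] <- as.integer(tab)
  }
  sm <- counts + 1L
  list(counts = counts, p = sm / sum(sm), n_triples = n3)
}

#' Keypress-triple Shannon entropy of a game
#'
#' Concatenates the keypresses of the game's rotation-free cycles in time
#' order, forms non-overlapping triples (running across cycle boundaries),
#' smooths the 27 triple counts by add-one smoothing and returns the
#' base-2 Shannon entropy. Games with fewer than one complete triple are
#' undefined and return `NA` (flagged, not zero).
#'
#' @param log an [orbit_log].
#' @param game game index; `NULL` pools the eligible presses of all games.
#' @return entropy in bits, or `NA_real_` if undefined.
#' @export
triple_entropy <- function(log, game = NULL) {
  cycles <- segment_cycles(log)
  games <- if (is.null(game)) sort(unique(log$games$game_index)) else game
  presses <- unlist(lapply(games, function(g) .eligible_presses(log, g, cycles)),
                    use.names = FALSE)
  tc <- triple_counts(presses)
  if (tc$n_triples < 1) return(NA_real_)
  shannon_entropy(tc$p)
}

#' Log coefficient of variation of inter-shot intervals
#'
#' For each rotation-free cycle with at least two inter-shot intervals,
#' the CV is the population standard deviation of the ISIs divided by
#' their mean; the per-cycle CVs are averaged within the game and the
#' natural logarithm of that average is returned. Degenerate games (no
#' eligible ISIs, or average CV of exactly zero, where the log is
#' undefined) return `NA`.
#'
#' @param log an [orbit_log].
#' @param game game index.
#' @return log mean CV (dimensionless), or `NA_real_`.
#' @export
log_cv_isi <- function(log, game) {
  cycles <- segment_cycles(log, game)
  cyc <- cycles[!cycles$has_rotation, ]
  ev <- log$events
  e <- ev[ev$game_index == game & ev$kind == "missile-fired", ]
  cvs <- numeric(0)
  for (k in seq_len(nrow(cyc))) {
    ts <- sort(e$timestamp_ms[e$timestamp_ms >= cyc$start[k] &
                                e$timestamp_ms <= cyc$end[k]])
    if (length(ts) < 3) next  # need >= 2 intervals for a spread
    isi <- diff(ts)
    m <- mean(isi)
    if (m <= 0) next
    cvs <- c(cvs, sqrt(mean((isi - m)^2)) / m)
  }
  if (!length(cvs)) return(NA_real_)
  avg <- mean(cvs)
  if (avg <= 0) return(NA_real_)
  log(avg)
}

#' Binary shot-key series of a cycle at tick resolution
#'
#' One element per 16-ms tick from the cycle start to its end: 1 while the
#' shot key L is held (between its hold-key and release-key events), else
#' 0. A hold left open at the cycle end is closed there with a warning.
#'
#' @param log an [orbit_log].
#' @param game game index.
#' @param start,end cycle bounds in ms.
#' @return integer vector of 0/1.
#' @export
shot_series <- function(log, game, start, end) {
  ev <- log$events
  e <- ev[ev$game_index == game & ev$payload == "L" &
            ev$kind %in% c("hold-key", "release-key") &
            ev$timestamp_ms >= start & ev$timestamp_ms <= end, ]
  n <- as.integer((end - start) / 16)
  x <- integer(n)
  if (n == 0) return(x)
  holds <- e$timestamp_ms[e$kind == "hold-key"]
  rels <- e$timestamp_ms[e$kind == "release-key"]
  for (h in holds) {
    r <- rels[rels > h]
    r <- if (length(r)) min(r) else {
      warning("unmatched shot-key hold at ", h, " ms closed at cycle end")
      end
    }
    i0 <- as.integer((h - start) / 16) + 1L
    i1 <- as.integer((r - start) / 16)
    if (i1 >= i0) x[i0:min(i1, n)] <- 1L
  }
  x
}

#' Autocorrelation function of a binary series
#'
#' The normalised sample autocorrelation
#' `r_l = sum_{i=1}^{N-l} (x_i - xbar)(x_{i+l} - xbar) / sum (x_i - xbar)^2`
#' for lags `0..n_lags` (the lag-0 denominator, i.e. the biased
#' normalisation). Lags that the series is too short to support are `NA`.
#' A constant series has no defined autocorrelation and returns all-`NA`
#' (flagged), never a substituted value.
#'
#' @param x numeric series.
#' @param n_lags maximum lag (default 125 lags of 16 ms).
#' @return numeric vector of length `n_lags + 1` (`r[1]` is lag 0).
#' @export
acf_series <- function(x, n_lags = .ACF_LAGS) {
  n <- length(x)
  out <- rep(NA_real_, n_lags + 1)
  if (n < 2 || stats::var(x) == 0) return(out)
  lag_max <- min(n_lags, n - 1)
  r <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  out[seq_len(lag_max + 1)] <- r
  out
}

#' Game-averaged shot autocorrelation function
#'
#' Computes each rotation-free cycle's shot-series ACF on its own length,
#' then averages across cycles at each lag where defined (lags undefined
#' for short cycles are skipped in the average).
#'
#' @param log an [orbit_log].
#' @param game game index.
#' @param n_lags maximum lag.
#' @return numeric vector of length `n_lags + 1`, possibly all `NA`.
#' @export
game_acf <- function(log, game, n_lags = .ACF_LAGS) {
  cycles <- segment_cycles(log, game)
  cyc <- cycles[!cycles$has_rotation, ]
  if (!nrow(cyc)) return(rep(NA_real_, n_lags + 1))
  acfs <- lapply(seq_len(nrow(cyc)), function(k) {
    acf_series(shot_series(log, game, cyc$start[k], cyc$end[k]), n_lags)
  })
  mat <- do.call(rbind, acfs)
  out <- colMeans(mat, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  out
}

#' First non-zero positive peak of an averaged ACF
#'
#' The first lag `l >= 1` that is a strict local maximum
#' (`r[l-1] < r[l] > r[l+1]`, the final lag allowed as a boundary maximum)
#' with amplitude greater than 0.02. Ties break toward the smaller lag by
#' construction.
#'
#' @param r averaged ACF as returned by [game_acf()] (`r[1]` is lag 0).
#' @return list with `lag` (in lags), `periodicity_ms`, `regularity` — or
#'   `NULL` when no qualifying peak exists.
#' @export
first_acf_peak <- function(r) {
  n <- length(r) - 1
  for (l in 1:n) {
    rl <- r[l + 1]
    if (!is.finite(rl) || rl <= .PEAK_MIN) next
    left <- r[l]
    right <- if (l < n) r[l + 2] else -Inf  # boundary maximum allowed
    if (is.finite(left) && left < rl && (!is.finite(right) || right < rl)) {
      return(list(lag = l, periodicity_ms = l * 16, regularity = rl))
    }
  }
  NULL
}

#' Shot periodicity and regularity of a game
#'
#' Averages the shot-series ACFs of the game's rotation-free cycles and
#' extracts the first positive non-zero-lag peak with amplitude above 0.02.
#' Periodicity is the peak's lag in ms; regularity is its height. Games
#' whose averaged ACF has no qualifying peak are invalid and the row is
#' expected to be filtered from downstream motor-learning analyses.
#'
#' @param log an [orbit_log].
#' @param game game index.
#' @return list with `periodicity_ms`, `regularity`, `valid`.
#' @export
periodicity_regularity <- function(log, game) {
  r <- game_acf(log, game)
  peak <- first_acf_peak(r)
  if (is.null(peak)) {
    list(periodicity_ms = NA_real_, regularity = NA_real_, valid = FALSE)
  } else {
    list(periodicity_ms = peak$periodicity_ms, regularity = peak$regularity,
         valid = TRUE)
  }
}

#' All eight measures for every game of a log
#'
#' @param log an [orbit_log].
#' @return data.frame with one row per game: `game_index`, `speed`,
#'   `condition`, the four performance counts, `entropy`, `log_cv_isi`,
#'   `periodicity_ms`, `regularity`, and `valid_peak`.
#' @export
game_metrics <- function(log) {
  validate_log(log)
  perf <- performance_summary(log)
  rows <- lapply(perf$game_index, function(g) {
    pr <- periodicity_regularity(log, g)
    data.frame(
      game_index = g,
      speed = log$games$speed[log$games$game_index == g],
      condition = log$condition,
      score = perf$score[perf$game_index == g],
      resets = perf$resets[perf$game_index == g],
      deflations = perf$deflations[perf$game_index == g],
      misses = perf$misses[perf$game_index == g],
      entropy = triple_entropy(log, g),
      log_cv_isi = log_cv_isi(log, g),
      periodicity_ms = pr$periodicity_ms,
      regularity = pr$regularity,
      valid_peak = pr$valid,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Metrics table for a set of session logs
#'
#' Applies [game_metrics()] to each session and stacks the results with a
#' run identifier, the tidy input expected by the transfer statistics.
#'
#' @param logs named or unnamed list of [orbit_log] sessions.
#' @param file optional path: when given, the table is also written as CSV.
#' @return data.frame with a `run` column followed by the [game_metrics()]
#'   columns.
#' @export
session_metrics <- function(logs, file = NULL) {
  runs <- names(logs) %||% as.character(seq_along(logs))
  out <- do.call(rbind, lapply(seq_along(logs), function(i) {
    m <- game_metrics(logs[[i]])
    cbind(run = runs[i], m, stringsAsFactors = FALSE)
  }))
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
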