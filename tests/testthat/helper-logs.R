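# Hand-built miniature logs for metric unit tests.

# one game whose events are given as (timestamp, kind, payload) triples
tiny_log <- function(ts, kind, payload = rep("", length(ts)),
                     game_index = 1L, speed = "high", score = 0) {
  events <- data.frame(timestamp_ms = ts, kind = kind, payload = payload,
                       game_index = game_index, condition = speed,
                       speed = speed, stringsAsFactors = FALSE)
  games <- data.frame(game_index = unique(game_index), speed = speed,
                      seed = 0L, final_score = score,
                      n_ticks = 11250L, stringsAsFactors = FALSE)
  new_orbit_log(events, games, speed)
}

# a single-cycle log with missile-fired events at the given times
shots_log <- function(shot_ts, end = max(shot_ts) + 64) {
  n <- length(shot_ts)
  ts <- c(0, rep(shot_ts, each = 3) + rep(c(0, 0, 16), n), end)
  kind <- c("balloon-respawn",
            rep(c("hold-key", "missile-fired", "release-key"), n),
            "balloon-burst")
  payload <- c("", rep(c("L", "", "L"), n), "")
  ord <- order(ts)
  tiny_log(ts[ord], kind[ord], payload[ord])
}

# per-game mean scores table for the transfer statistics
toy_scores <- function(n_runs = 4, jitter = 0, seed = 1) {
  set.seed(seed)
  base <- list(HHH = c(rep(1000, 5), rep(2000, 5), rep(2100, 5)),
               HLH = c(rep(1000, 5), rep(1500, 5), rep(2100, 5)),
               LHL = c(rep(500, 5), rep(1800, 5), rep(1200, 5)),
               LLL = c(rep(500, 5), rep(1100, 5), rep(1200, 5)))
  do.call(rbind, lapply(names(base), function(cond) {
    do.call(rbind, lapply(seq_len(n_runs), function(r) {
      data.frame(run = paste0(cond, "_", r), condition = cond,
                 game_index = 1:15,
                 score = base[[cond]] + stats::rnorm(15, 0, jitter))
    }))
  }))
}
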