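# Scripted-player log generators with known statistical structure.
# These bypass game physics (every scripted shot hits unless a scripted
# miss fires) so that the behavioral metrics can be tested against known
# generating parameters independently of the engine and the agent.

#' Specification of a scripted player
#'
#' @param isi_mean mean inter-shot interval, ms (> 0, and at least one game
#'   tick).
#' @param isi_jitter_sd Gaussian jitter of the shot times, ms.
#' @param miss_probability probability that a scripted shot misses.
#' @param triple_distribution optional probability vector of length 27 over
#'   the ordered keypress triples of (A, D, L) (used by [triple_sampler()];
#'   must sum to 1 with non-negative entries).
#' @param n_games number of games to generate.
#' @param speeds speed label per game (recycled).
#' @param seed integer seed.
#' @return an object of class `script_spec`.
#' @export
script_spec <- function(isi_mean = 560, isi_jitter_sd = 0,
                        miss_probability = 0, triple_distribution = NULL,
                        n_games = 1, speeds = "high", seed = 1) {
  if (!is.numeric(isi_mean) || isi_mean < 16) {
    stop("isi_mean must be at least one 16-ms game tick")
  }
  stopifnot(isi_jitter_sd >= 0, miss_probability >= 0, miss_probability <= 1)
  if (!is.null(triple_distribution)) {
    if (length(triple_distribution) != 27 || any(triple_distribution < 0)) {
      stop("triple_distribution must be 27 non-negative probabilities")
    }
    if (sum(triple_distribution) <= 0) stop("zero-support triple distribution")
    if (abs(sum(triple_distribution) - 1) > 1e-8) {
      stop("triple_distribution must sum to 1")
    }
  }
  structure(list(isi_mean = isi_mean, isi_jitter_sd = isi_jitter_sd,
                 miss_probability = miss_probability,
                 triple_distribution = triple_distribution,
                 n_games = n_games, speeds = speeds, seed = seed),
            class = "script_spec")
}

#' The 27 ordered keypress triples
#'
#' @return character vector of the triples "AAA" ... "LLL" in lexicographic
#'   order over the alphabet A, D, L.
#' @export
key_triples <- function() {
  keys <- c("A", "D", "L")
  g <- expand.grid(k3 = keys, k2 = keys, k1 = keys, stringsAsFactors = FALSE)
  paste0(g$k1, g$k2, g$k3)
}

#' Scripted periodic shooter
#'
#' Generates logs in which the shot key is pressed at `isi_mean` plus
#' Gaussian jitter (quantised to the 16-ms tick grid), with a clockwise
#' turn press midway between consecutive shots to mimic aim maintenance.
#' Every shot hits unless a scripted miss fires. Shots are grouped into
#' rotation-free cycles of `shots_per_cycle` (a burst closes each cycle and
#' a respawn opens the next, mirroring the game's cycle structure), so
#' every event is eligible for the motor-learning metrics and the per-cycle
#' autocorrelations average the way simulated games do. The generating
#' parameters are stored in the log's `meta` for recovery tests.
#'
#' @param spec a [script_spec()].
#' @param shots_per_cycle shots per respawn-to-burst cycle.
#' @return an [orbit_log].
#' @export
periodic_shooter <- function(spec, shots_per_cycle = 12) {
  stopifnot(inherits(spec, "script_spec"))
  set.seed(as.integer(spec$seed))
  speeds <- rep_len(spec$speeds, spec$n_games)
  logs <- vector("list", spec$n_games)
  for (g in seq_len(spec$n_games)) {
    dur <- 180000
    n_max <- ceiling(dur / spec$isi_mean) + 8
    isis <- spec$isi_mean + stats::rnorm(n_max, 0, spec$isi_jitter_sd)
    isis <- pmax(isis, 32)
    shots <- round(cumsum(isis) / 16) * 16
    shots <- shots[shots < dur - 64]
    n <- length(shots)
    if (n < 1) stop("isi_mean too long for a 3-minute game")
    miss <- stats::runif(n) < spec$miss_probability
    ts <- c(0); kind <- c("balloon-respawn"); payload <- c("")
    turn_t <- round((shots - spec$isi_mean / 2) / 16) * 16
    turn_t <- pmax(turn_t, 16)
    for (i in seq_len(n)) {
      # interleaved clockwise turn, then the shot press
      ts <- c(ts, turn_t[i], turn_t[i] + 16)
      kind <- c(kind, "hold-key", "release-key")
      payload <- c(payload, "D", "D")
      ts <- c(ts, shots[i], shots[i], shots[i] + 16)
      kind <- c(kind, "hold-key", "missile-fired", "release-key")
      payload <- c(payload, "L", "", "L")
      if (miss[i]) {
        ts <- c(ts, shots[i] + 32); kind <- c(kind, "missile-miss"); payload <- c(payload, "")
      } else {
        ts <- c(ts, shots[i] + 32); kind <- c(kind, "vulnerability-increase"); payload <- c(payload, "")
      }
      # close the cycle and open the next
      if (i %% shots_per_cycle == 0 && i < n) {
        ts <- c(ts, shots[i] + 48, shots[i] + 64)
        kind <- c(kind, "balloon-burst", "balloon-respawn")
        payload <- c(payload, "", "")
      }
    }
    end_t <- shots[n] + 48
    ts <- c(ts, end_t); kind <- c(kind, "balloon-burst"); payload <- c(payload, "")
    ord <- order(ts)
    events <- data.frame(
      timestamp_ms = ts[ord], kind = kind[ord], payload = payload[ord],
      game_index = g, condition = speeds[g], speed = speeds[g],
      stringsAsFactors = FALSE
    )
    games <- data.frame(game_index = g, speed = speeds[g], seed = spec$seed,
                        final_score = sum(!miss), n_ticks = dur / 16,
                        stringsAsFactors = FALSE)
    logs[[g]] <- new_orbit_log(events, games, speeds[g])
  }
  out <- bind_logs(logs, condition = speeds[1],
                   meta = list(generator = "periodic_shooter",
                               isi_mean = spec$isi_mean,
                               isi_jitter_sd = spec$isi_jitter_sd,
                               miss_probability = spec$miss_probability))
  validate_log(out)
  out
}

#' Scripted triple sampler
#'
#' Concatenates keypress triples drawn i.i.d. from a 27-way distribution
#' into a log with synthetic timestamps (one press every two ticks), wrapped
#' in a single respawn-to-burst cycle per game. Draws that exceed one
#' game's 3-minute capacity are split across consecutive games (at most
#' 1,800 triples per game), so large samples remain valid logs. The
#' generating distribution is stored in `meta` for entropy-recovery tests.
#'
#' @param spec a [script_spec()] with a `triple_distribution`.
#' @param n_triples total number of triples to draw.
#' @return an [orbit_log].
#' @export
triple_sampler <- function(spec, n_triples = 1000) {
  stopifnot(inherits(spec, "script_spec"))
  if (is.null(spec$triple_distribution)) stop("spec has no triple_distribution")
  set.seed(as.integer(spec$seed))
  triples <- key_triples()
  per_game <- 1800L
  n_games <- max(1L, as.integer(ceiling(n_triples / per_game)))
  sizes <- rep(per_game, n_games)
  sizes[n_games] <- n_triples - per_game * (n_games - 1L)
  logs <- vector("list", n_games)
  speeds <- rep_len(spec$speeds, n_games)
  for (g in seq_len(n_games)) {
    draw <- sample(triples, sizes[g], replace = TRUE,
                   prob = spec$triple_distribution)
    keys <- unlist(strsplit(draw, "", fixed = TRUE), use.names = FALSE)
    press_t <- 16 + 32 * (seq_along(keys) - 1)
    ts <- c(0, rbind(press_t, press_t + 16), max(press_t) + 48)
    kind <- c("balloon-respawn",
              rbind(rep("hold-key", length(keys)), rep("release-key", length(keys))),
              "balloon-burst")
    payload <- c("", rbind(keys, keys), "")
    events <- data.frame(timestamp_ms = ts, kind = kind, payload = payload,
                         game_index = g, condition = speeds[g],
                         speed = speeds[g], stringsAsFactors = FALSE)
    games <- data.frame(game_index = g, speed = speeds[g], seed = spec$seed,
                        final_score = 0, n_ticks = ceiling(max(ts) / 16),
                        stringsAsFactors = FALSE)
    logs[[g]] <- new_orbit_log(events, games, speeds[g])
  }
  out <- bind_logs(logs, condition = speeds[1],
                   meta = list(generator = "triple_sampler",
                               triple_distribution = spec$triple_distribution))
  validate_log(out)
  out
}
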