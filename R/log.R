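#' Event logs of simulated (or recorded) sessions
#'
#' An `orbit_log` holds the ordered, 16-ms-timestamped event records of one
#' or more games together with per-game metadata. `events` is a data.frame
#' with columns `timestamp_ms`, `kind`, `payload`, `game_index`,
#' `condition`, `speed`; `games` a data.frame with one row per game
#' (`game_index`, `speed`, `seed`, `final_score`, `n_ticks`). Timestamps
#' are 0-based within each game and non-decreasing. Event kinds are:
#' hold-key / release-key (payload A, D or L), random-rotation (payload the
#' signed angle), vulnerability-reset, vulnerability-increase,
#' missile-fired, balloon-respawn, balloon-burst, and the two bookkeeping
#' kinds balloon-deflation-onset and missile-miss that make slow-play
#' penalties and miss counts explicit in the log.
#'
#' @param events event data.frame (see Description).
#' @param games per-game metadata data.frame.
#' @param condition condition label (`"HHH"`, `"HLH"`, `"LHL"`, `"LLL"`, or
#'   a speed label for single-speed logs).
#' @param meta optional named list of provenance (generator parameters of
#'   scripted logs live here).
#' @return an object of class `orbit_log`.
#' @seealso [run_game()], [play_condition()], [write_log()], [validate_log()]
#' @export
new_orbit_log <- function(events, games, condition, meta = list()) {
  structure(list(events = events, games = games,
                 condition = condition, meta = meta),
            class = "orbit_log")
}

#' @export
print.orbit_log <- function(x, ...) {
  cat(sprintf("<orbit_log> condition %s: %d game(s), %d events\n",
              x$condition, nrow(x$games), nrow(x$events)))
  if (nrow(x$games)) {
    cat("  scores: ", paste(x$games$final_score, collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Concatenate single-game logs into a session log
#'
#' @param logs list of `orbit_log` objects (their `game_index` values must
#'   already be distinct and increasing).
#' @param condition session condition label.
#' @param meta optional provenance list.
#' @return an `orbit_log` spanning all games.
#' @export
bind_logs <- function(logs, condition, meta = list()) {
  events <- do.call(rbind, lapply(logs, function(l) {
    ev <- l$events
    ev$condition <- condition
    ev
  }))
  games <- do.call(rbind, lapply(logs, `[[`, "games"))
  new_orbit_log(events, games, condition, meta)
}

#' Validate a log's structural invariants
#'
#' Checks event kinds, key payloads, per-game non-decreasing timestamps
#' within the game duration, and that respawns are at least as numerous as
#' bursts. Stops with an informative error on the first violation.
#'
#' @param log an `orbit_log`.
#' @return `log`, invisibly.
#' @export
validate_log <- function(log) {
  stopifnot(inherits(log, "orbit_log"))
  ev <- log$events
  if (nrow(ev) == 0) stop("empty log: no events")
  bad <- setdiff(unique(ev$kind), .EVENT_KINDS)
  if (length(bad)) stop("unknown event kind(s): ", paste(bad, collapse = ", "))
  keys <- ev$payload[ev$kind %in% c("hold-key", "release-key")]
  if (!all(keys %in% c("A", "D", "L"))) {
    stop("hold/release events must carry a key payload in {A, D, L}")
  }
  for (g in unique(ev$game_index)) {
    ts <- ev$timestamp_ms[ev$game_index == g]
    if (is.unsorted(ts)) stop("timestamps out of order in game ", g)
    if (any(ts < 0) || any(ts > 180000)) {
      stop("timestamps outside the 3-minute game in game ", g)
    }
  }
  n_respawn <- sum(ev$kind == "balloon-respawn")
  n_burst <- sum(ev$kind == "balloon-burst")
  if (n_respawn < n_burst) stop("log has more bursts than respawns")
  invisible(log)
}

# serialisable header carried in comment lines / the JSONL meta record
.log_header <- function(log) {
  list(condition = log$condition, games = log$games, meta = log$meta)
}

#' Write and read event logs
#'
#' Two dialects, both lossless: a TSV with header
#' `timestamp_ms  kind  payload  game_index  condition  speed` preceded by a
#' single `#`-prefixed JSON comment line carrying the per-game metadata, and
#' a JSONL mirror whose first line is a meta record followed by one event
#' object per line. The round trip `read_log(write_log(x))` reproduces the
#' log exactly.
#'
#' @param log an `orbit_log`.
#' @param path output file.
#' @param format `"tsv"` or `"jsonl"` (inferred from the file extension when
#'   omitted).
#' @return `write_log()` returns `path` invisibly; `read_log()` an
#'   `orbit_log`. Malformed rows are reported with their line numbers;
#'   empty files are an error, not a silent empty log.
#' @export
write_log <- function(log, path, format = c("auto", "tsv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "tsv"
  }
  header <- jsonlite::toJSON(.log_header(log), dataframe = "columns",
                             auto_unbox = TRUE, digits = NA)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", header), con)
    utils::write.table(log$events, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    lines <- c(as.character(header),
               vapply(seq_len(nrow(log$events)), function(i) {
                 as.character(jsonlite::toJSON(as.list(log$events[i, ]),
                                               auto_unbox = TRUE, digits = NA))
               }, character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_log
#' @export
read_log <- function(path, format = c("auto", "tsv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "tsv"
  }
  lines <- readLines(path)
  if (length(lines) == 0 || all(!nzchar(lines))) {
    stop("empty log file: ", path)
  }
  if (format == "tsv") {
    if (!startsWith(lines[1], "# ")) stop("line 1: missing metadata header")
    header <- jsonlite::fromJSON(sub("^# ", "", lines[1]))
    body <- lines[-1]
    if (length(body) < 2) stop("log file has no event rows: ", path)
    cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
    expected <- c("timestamp_ms", "kind", "payload", "game_index", "condition", "speed")
    if (!identical(cols, expected)) stop("line 2: unexpected column header")
    rows <- strsplit(body[-1], "\t", fixed = TRUE)
    nf <- lengths(rows)
    if (any(nf != 6)) {
      stop("malformed row(s) at line(s): ",
           paste(which(nf != 6) + 2, collapse = ", "))
    }
    mat <- do.call(rbind, rows)
    events <- data.frame(
      timestamp_ms = as.numeric(mat[, 1]),
      kind = mat[, 2],
      payload = mat[, 3],
      game_index = as.integer(mat[, 4]),
      condition = mat[, 5],
      speed = mat[, 6],
      stringsAsFactors = FALSE
    )
  } else {
    header <- jsonlite::fromJSON(lines[1])
    body <- lines[-1]
    if (!length(body)) stop("log file has no event records: ", path)
    rows <- lapply(seq_along(body), function(i) {
      tryCatch(jsonlite::fromJSON(body[i]),
               error = function(e) stop("malformed record at line ", i + 1,
                                        ": ", conditionMessage(e)))
    })
    events <- do.call(rbind, lapply(rows, function(r) {
      data.frame(timestamp_ms = as.numeric(r$timestamp_ms), kind = r$kind,
                 payload = as.character(r$payload),
                 game_index = as.integer(r$game_index),
                 condition = r$condition, speed = r$speed,
                 stringsAsFactors = FALSE)
    }))
  }
  games <- as.data.frame(header$games, stringsAsFactors = FALSE)
  meta <- header$meta
  if (length(meta) == 0) meta <- list()
  log <- new_orbit_log(events, games, header$condition, meta)
  validate_log(log)
  log
}
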