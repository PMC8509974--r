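# Session-level statistics of the ABA transfer design: phase means,
# percent transfer with bootstrap resampling at the run level, and
# RMSE/BIC comparison of model game-mean vectors against reference means.

.PHASES <- c(Start = 1, Middle = 6, Final = 11)

#' Phase of a game index
#'
#' Games 1-5 are the Start phase, 6-10 the Middle phase, 11-15 the Final
#' phase.
#'
#' @param game_index integer vector in 1..15.
#' @return factor with levels Start, Middle, Final.
#' @export
game_phase <- function(game_index) {
  stopifnot(all(game_index >= 1 & game_index <= 15))
  cut(game_index, breaks = c(0, 5, 10, 15),
      labels = c("Start", "Middle", "Final"))
}

#' Speed sequence of an ABA condition
#'
#' @param condition one of `"HHH"`, `"HLH"`, `"LHL"`, `"LLL"`.
#' @param n_games games per session.
#' @return character vector of per-game speed labels.
#' @export
condition_speeds <- function(condition, n_games = 15) {
  condition <- match.arg(condition, c("HHH", "HLH", "LHL", "LLL"))
  lab <- c(H = "high", L = "low")
  per_phase <- unname(lab[strsplit(condition, "")[[1]]])
  rep(per_phase, each = ceiling(n_games / 3))[seq_len(n_games)]
}

#' Percent transfer
#'
#' `100 * (mid_transfer - start_same_speed) / (mid_control -
#' start_same_speed)`: the middle-phase gain of the transfer group at a
#' speed, as a percentage of the gain the control group shows at that same
#' speed over its own start baseline. 100% means the transfer group plays
#' the new speed as well as the control group that practised it from the
#' start; 0% means no better than the speed-matched start baseline.
#'
#' @param points_mid_transfer middle-phase (games 6-10) score of the
#'   transfer condition at the target speed.
#' @param points_start_same_speed start-phase (games 1-5) score at that same
#'   speed (pooled over the two conditions starting at it).
#' @param points_mid_control middle-phase score of the same-speed control
#'   condition.
#' @return percent transfer, or `NA` (flagged) when the denominator is zero.
#' @examples
#' transfer_percent(900, 600, 1000)  # 75
#' @export
transfer_percent <- function(points_mid_transfer, points_start_same_speed,
                             points_mid_control) {
  den <- points_mid_control - points_start_same_speed
  if (!is.finite(den) || den == 0) return(NA_real_)
  100 * (points_mid_transfer - points_start_same_speed) / den
}

# per-run phase mean scores: one row per (run, condition, phase)
.phase_means <- function(scores) {
  need <- c("run", "condition", "game_index", "score")
  if (!all(need %in% names(scores))) {
    stop("scores table needs columns: ", paste(need, collapse = ", "))
  }
  scores$phase <- game_phase(scores$game_index)
  out <- stats::aggregate(score ~ run + condition + phase, data = scores, FUN = mean)
  out
}

# transfer at one speed from per-run phase means, using `center` across runs
.transfer_from_means <- function(pm, speed = c("low", "high"),
                                 center = stats::median) {
  speed <- match.arg(speed)
  cell <- function(cond, phase) {
    v <- pm$score[pm$condition %in% cond & pm$phase == phase]
    if (!length(v)) stop("empty cell: condition ", paste(cond, collapse = "/"),
                         ", phase ", phase)
    center(v)
  }
  if (speed == "low") {
    transfer_percent(cell("HLH", "Middle"),
                     cell(c("LHL", "LLL"), "Start"),
                     cell("LLL", "Middle"))
  } else {
    transfer_percent(cell("LHL", "Middle"),
                     cell(c("HLH", "HHH"), "Start"),
                     cell("HHH", "Middle"))
  }
}

#' Percent transfer at a speed, with bootstrap
#'
#' From a table of per-game scores over runs of the four ABA conditions,
#' computes the percent transfer at the given speed: for low speed the
#' middle phase of HLH against the pooled low-speed start baseline (LHL and
#' LLL games 1-5) and the LLL middle phase; for high speed the middle phase
#' of LHL against the pooled high-speed start baseline (HLH and HHH) and
#' the HHH middle phase. Scores are first averaged per run within phase,
#' then summarised across runs with `center`.
#'
#' The bootstrap resamples runs with replacement within each condition,
#' recomputes the phase summaries and the transfer for each of `n_boot`
#' draws, and is reproducible under `seed`.
#'
#' @param scores data.frame with columns `run`, `condition`, `game_index`,
#'   `score` (one row per game; conditions HHH, HLH, LHL, LLL).
#' @param speed `"low"` or `"high"`.
#' @param n_boot bootstrap resamples (0 skips the bootstrap).
#' @param seed integer seed for the bootstrap.
#' @param center summary across runs: `median` (default) or `mean`.
#' @return object of class `transfer_result`: list with `speed`,
#'   `estimate` (%), `boot` (numeric vector), `median` and `quartiles` of
#'   the bootstrap distribution.
#' @export
bootstrap_transfer <- function(scores, speed = c("low", "high"),
                               n_boot = 10000, seed = 1,
                               center = stats::median) {
  speed <- match.arg(speed)
  pm <- .phase_means(scores)
  conds <- c("HHH", "HLH", "LHL", "LLL")
  for (cc in conds) {
    if (sum(pm$condition == cc) < 2) stop("empty or singleton cell: condition ", cc)
  }
  estimate <- .transfer_from_means(pm, speed, center)
  boot <- numeric(0)
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    runs_by_cond <- lapply(conds, function(cc) unique(pm$run[pm$condition == cc]))
    names(runs_by_cond) <- conds
    boot <- vapply(seq_len(n_boot), function(b) {
      res <- do.call(rbind, lapply(conds, function(cc) {
        runs <- runs_by_cond[[cc]]
        pick <- sample(runs, length(runs), replace = TRUE)
        do.call(rbind, lapply(seq_along(pick), function(j) {
          block <- pm[pm$condition == cc & pm$run == pick[j], ]
          block$run <- paste0(cc, "_", j)
          block
        }))
      }))
      .transfer_from_means(res, speed, center)
    }, numeric(1))
  }
  structure(list(speed = speed, estimate = estimate, boot = boot,
                 median = if (length(boot)) stats::median(boot) else estimate,
                 quartiles = if (length(boot))
                   stats::quantile(boot, c(0.25, 0.75), names = FALSE)
                 else c(NA_real_, NA_real_)),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("<transfer_result> %s speed: %.1f%% transfer", x$speed, x$estimate))
  if (length(x$boot)) {
    cat(sprintf(" (bootstrap median %.1f%%, IQR [%.1f, %.1f], %d resamples)",
                x$median, x$quartiles[1], x$quartiles[2], length(x$boot)))
  }
  cat("\n")
  invisible(x)
}

#' RMSE and BIC of model game means against reference means
#'
#' Compares two vectors of game means (conventionally the 60 means of 4
#' conditions x 15 games). RMSE is the root mean squared difference; BIC is
#' `n * log(RSS / n)` with the parameter-count term dropped (all models
#' under comparison share their parameterisation, so `k = 0`). Ranking by
#' BIC therefore equals ranking by RMSE. A perfect fit has RMSE 0 and an
#' unbounded-below BIC; it is returned as `-Inf` with `perfect = TRUE`.
#'
#' @param model_means numeric vector of model game means.
#' @param reference_means numeric vector of the same length.
#' @return object of class `fit_result`: list with `rmse`, `bic`, `rss`,
#'   `n`, `perfect`.
#' @export
fit_scores <- function(model_means, reference_means) {
  if (length(model_means) != length(reference_means)) {
    stop("length mismatch: ", length(model_means), " vs ", length(reference_means))
  }
  ok <- is.finite(model_means) & is.finite(reference_means)
  d <- model_means[ok] - reference_means[ok]
  n <- length(d)
  if (n == 0) stop("no finite pairs to compare")
  rss <- sum(d^2)
  rmse <- sqrt(rss / n)
  bic <- if (rss == 0) -Inf else n * log(rss / n)
  structure(list(rmse = rmse, bic = bic, rss = rss, n = n,
                 perfect = rss == 0),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> n = %d: RMSE = %.4g, BIC = %.4g%s\n",
              x$n, x$rmse, x$bic, if (x$perfect) " (perfect fit)" else ""))
  invisible(x)
}
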