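#' Production utility with difference learning
#'
#' Utilities of competing productions are learned by the difference rule
#' `U <- U + alpha * (R - U)`: each update moves the utility a fraction
#' `alpha` of the way toward the obtained reward, so with constant reward the
#' utility converges geometrically to it at rate `1 - alpha`.
#'
#' @param U0 initial utility.
#' @param alpha learning rate in (0, 1].
#' @return object of class `production_utility` with fields `U`, `alpha`,
#'   and `n_updates`.
#' @examples
#' p <- production_utility(alpha = 0.05)
#' p <- update_utility(p, 20)
#' p$U  # 1.0
#' @export
production_utility <- function(U0 = 0, alpha = 0.05) {
  stopifnot(alpha > 0, alpha <= 1, is.finite(U0))
  structure(list(U = U0, alpha = alpha, n_updates = 0L),
            class = "production_utility")
}

#' @rdname production_utility
#' @param p a `production_utility`.
#' @param R reward for this update (finite).
#' @export
update_utility <- function(p, R) {
  if (!is.finite(R)) stop("reward must be finite")
  p$U <- p$U + p$alpha * (R - p$U)
  p$n_updates <- p$n_updates + 1L
  p
}
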