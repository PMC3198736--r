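#' Storey pFDR q-values
#'
#' Positive-false-discovery-rate q-values. The proportion of true nulls
#' `pi0` is estimated on a lambda grid as
#' `pi0(lambda) = mean(p > lambda) / (1 - lambda)` and read off at
#' `lambda = 0.95` by linear interpolation, capped into (0, 1]. With
#' `pi0 = 1` the q-values reduce exactly to Benjamini-Hochberg adjusted
#' p-values. q-values are enforced monotone non-decreasing in p.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param pi0 optional fixed null proportion; overrides estimation.
#'   `pi0 = 1` gives Benjamini-Hochberg.
#' @param lambda grid used for the `pi0` estimate.
#' @return numeric vector of q-values, same order as `p`. Empty input
#'   returns an empty vector. The `pi0` used is attached as attribute
#'   `"pi0"`.
#' @examples
#' p <- c(0.001, 0.02, 0.5, 0.9)
#' pfdr_qvalues(p, pi0 = 1)            # equals p.adjust(p, "BH")
#' @export
pfdr_qvalues <- function(p, pi0 = NULL, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    pi0 <- if (length(lambda) == 1L) pi0_l else
      stats::approx(lambda, pi0_l, xout = 0.95, rule = 2)$y
    pi0 <- min(1, pi0)
    if (pi0 <= 0) pi0 <- 1 / m     # degenerate grid (all p small)
  } else {
    if (pi0 <= 0 || pi0 > 1) stop("'pi0' must lie in (0, 1]")
  }
  o <- order(p)
  qraw <- pi0 * m * p[o] / seq_len(m)
  q <- rev(cummin(rev(pmin(qraw, 1))))
  out <- numeric(m)
  out[o] <- q
  attr(out, "pi0") <- pi0
  out
}
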