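#' Storey q-values (positive false discovery rate)
#'
#' `q_i = min_{t >= p_i} pi0 * m * t / #(p <= t)` with the null proportion
#' `pi0` estimated on the lambda grid `0, 0.05, ..., 0.90` and smoothed
#' with a cubic spline (the estimate at the largest lambda, capped at 1).
#' Forcing `pi0 = 1` makes the output identical to Benjamini-Hochberg
#' step-up adjusted p-values.
#'
#' @param p_values Vector of p-values in (0, 1].
#' @param lambda Grid for the pi0 estimate.
#' @param pi0 Optional fixed null proportion (e.g. 1 for BH).
#' @return Vector of q-values in the input order.
#' @examples
#' storey_qvalues(c(0.01, 0.02, 0.03, 0.04), pi0 = 1)  # all 0.04
#' @export
storey_qvalues <- function(p_values, lambda = seq(0, 0.90, by = 0.05),
                           pi0 = NULL) {
  p <- p_values
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  m <- length(p)
  if (is.null(pi0)) {
    pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    if (m >= 10L && length(unique(pi0_lambda)) > 3L) {
      fit <- smooth.spline(lambda, pi0_lambda, df = 3)
      pi0 <- predict(fit, x = max(lambda))$y
    } else {
      pi0 <- min(pi0_lambda[length(pi0_lambda)], 1)
    }
    pi0 <- min(max(pi0, 1 / m), 1)
  }
  ord <- order(p)
  ranked <- pi0 * m * p[ord] / seq_len(m)
  q_sorted <- rev(cummin(rev(ranked)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}
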