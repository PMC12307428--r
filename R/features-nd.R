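#' Poincare plot descriptors of a signal
#'
#' The Poincare plot scatters `x[i + lag]` against `x[i]`; an ellipse fitted
#' to the cloud has width SD1 (short-term variability) and length SD2
#' (long-term variability). These are computed with the standard identities
#' `SD1 = sd((x[i+lag] - x[i]) / sqrt(2))` and
#' `SD2 = sd((x[i+lag] + x[i]) / sqrt(2))` (sample standard deviation,
#' denominator N-1), equivalently `SD1^2 = SDSD^2 / 2` where SDSD is the
#' standard deviation of successive lagged differences. The ratio SD1/SD2 is
#' defined as 0 when SD2 = 0.
#'
#' @param signal numeric vector of length > lag + 1.
#' @param lag positive integer lag (conventional default 1).
#' @return A `poincare_measures` list: `sd1`, `sd2`, `product`, `ratio`,
#'   `lag`.
#' @export
#' @examples
#' p <- poincare(sin(2 * pi * 10 * (0:999) / 1000))
#' p$product == p$sd1 * p$sd2
poincare <- function(signal, lag = 1L) {
  if (length(lag) != 1L || lag < 1L || lag != round(lag))
    stop("lag must be a positive integer")
  n <- length(signal)
  if (n <= lag + 1L) stop("signal must be longer than lag + 1")
  lead <- signal[(1L + lag):n]
  base <- signal[1:(n - lag)]
  sd1 <- sd((lead - base) / sqrt(2))
  sd2 <- sd((lead + base) / sqrt(2))
  structure(list(sd1 = sd1, sd2 = sd2, product = sd1 * sd2,
                 ratio = if (sd2 > 0) sd1 / sd2 else 0,
                 lag = as.integer(lag)),
            class = "poincare_measures")
}

#' Nonlinear-domain feature extraction for one segment
#'
#' Four Poincare descriptors per channel at lag 1 — ND1 = SD1, ND2 = SD2,
#' ND3 = SD1*SD2, ND4 = SD1/SD2 — for 76 features per segment,
#' channel-major.
#'
#' @param segment an `eeg_segment`.
#' @param lag Poincare lag (default 1).
#' @return Named numeric vector of length 76.
#' @export
extract_nd <- function(segment, lag = 1L) {
  validate_segment(segment)
  X <- segment$data
  n <- ncol(X)
  lead <- X[, (1L + lag):n, drop = FALSE]
  base <- X[, 1:(n - lag), drop = FALSE]
  m <- ncol(lead)
  row_sd <- function(M) {
    mu <- rowMeans(M)
    sqrt(rowSums((M - mu)^2) / (ncol(M) - 1))
  }
  sd1 <- row_sd((lead - base) / sqrt(2))
  sd2 <- row_sd((lead + base) / sqrt(2))
  feats <- rbind(ND1 = sd1, ND2 = sd2, ND3 = sd1 * sd2,
                 ND4 = ifelse(sd2 > 0, sd1 / sd2, 0))
  ids <- make_feature_ids("ND", paste0("ND", 1:4), seq_len(N_CHANNELS))
  stats::setNames(as.vector(feats), ids)
}
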