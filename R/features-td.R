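#' The 24-slot time-domain feature catalog
#'
#' Fixed catalog of the 24 temporal descriptors computed per channel. The
#' assignment of codes to features is a package convention, except that
#' TD10-TD12 and TD24 are pinned to waveform length, average amplitude
#' change, difference absolute standard deviation value and slope-sign
#' change (the four descriptors that behave as a block in channel-selection
#' maps of this analysis family).
#'
#' @return data.frame with columns `code`, `name`.
#' @export
td_catalog <- function() {
  data.frame(
    code = paste0("TD", 1:24),
    name = c("mean", "mean absolute value", "median", "root mean square",
             "standard deviation", "variance", "integrated EEG",
             "simple square integral", "log detector", "waveform length",
             "average amplitude change",
             "difference absolute standard deviation value",
             "maximum", "minimum", "peak to peak", "skewness", "kurtosis",
             "zero crossings", "Hjorth activity", "Hjorth mobility",
             "Hjorth complexity", "Willison amplitude",
             "myopulse percentage rate", "slope sign changes"),
    stringsAsFactors = FALSE
  )
}

#' Waveform length of a signal
#'
#' Sum of absolute successive differences, `sum(|x[i+1] - x[i]|)`.
#'
#' @param signal numeric vector, length >= 2.
#' @return Non-negative scalar.
#' @export
#' @examples
#' waveform_length(c(0, 1, 2, 3))  # 3
waveform_length <- function(signal) {
  if (length(signal) < 2L) stop("signal must have length >= 2")
  sum(abs(diff(signal)))
}

#' Zero crossings with optional amplitude deadband
#'
#' Counts consecutive sample pairs with strictly opposite signs whose
#' amplitude jump exceeds `deadband` (a noise guard; 0 disables it).
#'
#' @param signal numeric vector, length >= 2.
#' @param deadband non-negative threshold on `|x[i+1] - x[i]|`.
#' @return Non-negative integer count.
#' @export
zero_crossings <- function(signal, deadband = 0) {
  if (length(signal) < 2L) stop("signal must have length >= 2")
  stopifnot(deadband >= 0)
  a <- signal[-length(signal)]
  b <- signal[-1L]
  sum(a * b < 0 & abs(b - a) > deadband)
}

#' Slope sign changes with optional deadband
#'
#' Counts interior samples that are local extrema:
#' `(x[i] - x[i-1]) * (x[i] - x[i+1]) > deadband`.
#'
#' @param signal numeric vector, length >= 3.
#' @param deadband non-negative product threshold; 0 counts strict extrema.
#' @return Non-negative integer count.
#' @export
slope_sign_changes <- function(signal, deadband = 0) {
  if (length(signal) < 3L) stop("signal must have length >= 3")
  stopifnot(deadband >= 0)
  n <- length(signal)
  mid <- signal[2:(n - 1L)]
  sum((mid - signal[1:(n - 2L)]) * (mid - signal[3:n]) > deadband)
}

#' Hjorth parameters of a signal
#'
#' Activity is the signal variance; mobility the square root of the variance
#' ratio of the first derivative to the signal; complexity the mobility of
#' the derivative over the mobility of the signal. A zero-variance input
#' returns (0, 0, 0) by convention.
#'
#' @param signal numeric vector, length >= 3.
#' @return Named numeric vector `c(activity, mobility, complexity)`.
#' @export
hjorth_parameters <- function(signal) {
  if (length(signal) < 3L) stop("signal must have length >= 3")
  v0 <- var(signal)
  if (!is.finite(v0) || v0 == 0) {
    return(c(activity = 0, mobility = 0, complexity = 0))
  }
  d1 <- diff(signal)
  d2 <- diff(d1)
  v1 <- var(d1)
  v2 <- var(d2)
  mob <- sqrt(v1 / v0)
  comp <- if (v1 == 0) 0 else sqrt(v2 / v1) / mob
  c(activity = v0, mobility = mob, complexity = comp)
}

#' Time-domain feature extraction for one segment
#'
#' Computes the 24 catalog descriptors for each of the 19 channels
#' (456 features), ordered channel-major (channel 1's TD1..TD24 first).
#' Skewness and kurtosis use population moments (kurtosis is the raw Pearson
#' moment ratio, 3 for a Gaussian); both are 0 for a flat channel. The log
#' detector is `exp(mean(log |x|))` and collapses to 0 whenever a sample is
#' exactly zero.
#'
#' @param segment an `eeg_segment`.
#' @param deadband_zc,deadband_ssc deadbands for TD18 / TD24 (default 0).
#' @param wamp_threshold,myop_threshold amplitude thresholds (microvolts) for
#'   Willison amplitude (TD22) and myopulse percentage rate (TD23).
#' @return Named numeric vector of length 456; names are feature ids
#'   `TD:<code>:ch<k>`.
#' @export
extract_td <- function(segment, deadband_zc = 0, deadband_ssc = 0,
                       wamp_threshold = 10, myop_threshold = 10) {
  validate_segment(segment)
  X <- segment$data                       # 19 x 1000
  n <- ncol(X)
  A <- abs(X)
  D <- X[, -1L, drop = FALSE] - X[, -n, drop = FALSE]   # successive diffs
  AD <- abs(D)

  mu <- rowMeans(X)
  cx <- X - mu
  m2 <- rowMeans(cx^2)
  m3 <- rowMeans(cx^3)
  m4 <- rowMeans(cx^4)
  v_s <- rowSums(cx^2) / (n - 1)          # sample variance
  sd_s <- sqrt(v_s)

  # derivative moments for Hjorth
  d2 <- D[, -1L, drop = FALSE] - D[, -ncol(D), drop = FALSE]
  vd1 <- apply(D, 1, var)
  vd2 <- apply(d2, 1, var)
  mob <- ifelse(v_s > 0, sqrt(vd1 / v_s), 0)
  comp <- ifelse(v_s > 0 & vd1 > 0, sqrt(vd2 / vd1) / sqrt(vd1 / v_s), 0)

  sgn <- X[, -n, drop = FALSE] * X[, -1L, drop = FALSE]
  zc <- rowSums(sgn < 0 & AD > deadband_zc)
  mid <- X[, 2:(n - 1L), drop = FALSE]
  ssc <- rowSums((mid - X[, 1:(n - 2L), drop = FALSE]) *
                 (mid - X[, 3:n, drop = FALSE]) > deadband_ssc)

  wl <- rowSums(AD)
  feats <- rbind(
    TD1 = mu,
    TD2 = rowMeans(A),
    TD3 = apply(X, 1, median),
    TD4 = sqrt(rowMeans(X^2)),
    TD5 = sd_s,
    TD6 = v_s,
    TD7 = rowSums(A),
    TD8 = rowSums(X^2),
    TD9 = exp(rowMeans(log(A))),
    TD10 = wl,
    TD11 = wl / (n - 1),
    TD12 = sqrt(rowSums(D^2) / (n - 1)),
    TD13 = apply(X, 1, max),
    TD14 = apply(X, 1, min),
    TD15 = apply(X, 1, max) - apply(X, 1, min),
    TD16 = ifelse(m2 > 0, m3 / m2^1.5, 0),
    TD17 = ifelse(m2 > 0, m4 / m2^2, 0),
    TD18 = zc,
    TD19 = v_s,
    TD20 = mob,
    TD21 = comp,
    TD22 = rowSums(AD > wamp_threshold),
    TD23 = rowMeans(A > myop_threshold),
    TD24 = ssc
  )
  feats[!is.finite(feats)] <- 0           # log detector of a zero sample
  ids <- make_feature_ids("TD", td_catalog()$code, seq_len(N_CHANNELS))
  stats::setNames(as.vector(feats), ids)
}
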