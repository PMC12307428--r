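#' One-sided band spectrum of a 1 s signal
#'
#' Discrete Fourier magnitudes of a 1000-sample signal at 1000 Hz (1 Hz bin
#' resolution), restricted to the bins whose frequency lies in the half-open
#' interval `[f_lo, f_hi)`. DC is never included; the delta band therefore
#' retains bins 1, 2, 3 Hz.
#'
#' @param signal numeric vector of length 1000.
#' @param fs sampling rate; must be 1000 Hz.
#' @param band one row of [band_definitions()] (or any list with `name`,
#'   `f_lo`, `f_hi`).
#' @return A `band_spectrum`: list with magnitudes `y`, `frequencies` (Hz),
#'   bin count `M` and the band.
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * (0:999) / 1000)
#' sp <- band_spectrum(x, 1000, band_definitions()[3, ])  # alpha
#' sp$frequencies[which.max(sp$y)]  # 10
band_spectrum <- function(signal, fs = FS, band) {
  if (fs != FS) stop("fs must be 1000 Hz")
  if (length(signal) != N_SAMPLES) stop("signal must have length 1000")
  f <- 0:(N_SAMPLES / 2)                  # one-sided grid, 1 Hz steps
  keep <- f >= band$f_lo & f < band$f_hi & f > 0
  if (!any(keep)) stop("band ", band$name, " retains no frequency bins")
  y <- Mod(fft(signal))[seq_len(N_SAMPLES / 2 + 1)]
  structure(list(y = y[keep], frequencies = f[keep], M = sum(keep),
                 band = band), class = "band_spectrum")
}

#' Band energy, variance and spectral entropy
#'
#' Three statistics of a [band_spectrum()]: energy is the sum of squared
#' magnitudes over the band's `M` bins; variance is the sample variance
#' (denominator `M - 1`) of the magnitudes; spectral entropy is the Shannon
#' entropy of the normalized within-band power distribution
#' `P(i) = |y(i)|^2 / sum |y(j)|^2`, divided by `log(M)` so it lies in
#' [0, 1] (1 for flat power, 0 for a single active bin; 0 by convention for
#' an all-zero band).
#'
#' @param spec a `band_spectrum`.
#' @return A non-negative scalar (`band_energy`, `band_variance`) or a value
#'   in [0, 1] (`band_spectral_entropy`).
#' @export
band_energy <- function(spec) {
  stopifnot(inherits(spec, "band_spectrum"))
  sum(spec$y^2)
}

#' @rdname band_energy
#' @export
band_variance <- function(spec) {
  stopifnot(inherits(spec, "band_spectrum"))
  if (spec$M < 2L) stop("band variance needs at least 2 bins")
  var(spec$y)
}

#' @rdname band_energy
#' @export
band_spectral_entropy <- function(spec) {
  stopifnot(inherits(spec, "band_spectrum"))
  if (spec$M < 2L) stop("spectral entropy needs at least 2 bins")
  p <- spec$y^2
  tot <- sum(p)
  if (tot == 0) return(0)
  p <- p / tot
  nz <- p > 0
  -sum(p[nz] * log(p[nz])) / log(spec$M)
}

# indices (into the 0..500 Hz one-sided grid, position = Hz + 1) per band
.fd_band_bins <- function(bands = band_definitions()) {
  f <- 0:(N_SAMPLES / 2)
  lapply(seq_len(nrow(bands)), function(b) {
    which(f >= bands$f_lo[b] & f < bands$f_hi[b] & f > 0)
  })
}

#' Frequency-domain feature extraction for one segment
#'
#' 15 features per channel: FD1-FD5 band energies (delta..gamma), FD6-FD10
#' band variances, FD11-FD15 band spectral entropies, for 285 features per
#' segment. No window or detrend is applied before the FFT unless requested.
#'
#' @param segment an `eeg_segment`.
#' @param demean subtract the channel mean before the FFT (default FALSE; DC
#'   is excluded from every band either way).
#' @return Named numeric vector of length 285 (channel-major).
#' @export
extract_fd <- function(segment, demean = FALSE) {
  validate_segment(segment)
  X <- segment$data
  if (demean) X <- X - rowMeans(X)
  mags <- Mod(mvfft(t(X)))[seq_len(N_SAMPLES / 2 + 1), , drop = FALSE]
  bins <- .fd_band_bins()
  feats <- matrix(0, nrow = 15L, ncol = N_CHANNELS)
  for (b in seq_len(5L)) {
    Y <- mags[bins[[b]], , drop = FALSE]
    P <- Y^2
    en <- colSums(P)
    M <- nrow(Y)
    vr <- colSums((Y - rep(colMeans(Y), each = M))^2) / (M - 1)
    Pn <- sweep(P, 2, ifelse(en > 0, en, 1), "/")
    ent <- -colSums(ifelse(Pn > 0, Pn * log(Pn), 0)) / log(M)
    ent[en == 0] <- 0
    feats[b, ] <- en
    feats[b + 5L, ] <- vr
    feats[b + 10L, ] <- ent
  }
  ids <- make_feature_ids("FD", paste0("FD", 1:15), seq_len(N_CHANNELS))
  stats::setNames(as.vector(feats), ids)
}
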