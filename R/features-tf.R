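#' Haar wavelet packet decomposition
#'
#' Full binary wavelet packet tree of a 1 s signal using the orthonormal Haar
#' pair `a = (x1 + x2)/sqrt(2)`, `d = (x1 - x2)/sqrt(2)`. The 1000-sample
#' input is padded to 1024 (default: zero padding, which leaves the total
#' coefficient energy exactly equal to the original signal energy; symmetric
#' reflection is available as an option). At the default level 9 there are
#' 512 terminal nodes of 2 coefficients each, returned in frequency
#' (sequency) order: the Gray-code correction is applied so node k tiles
#' `[(k-1), k) * 500/512` Hz.
#'
#' @param signal numeric vector of length 1000.
#' @param level decomposition depth (default and maximum for this length: 9).
#' @param wavelet mother wavelet name; only "haar" is supported.
#' @param padding "zero" (default) or "symmetric".
#' @return A `wp_decomposition`: list with `coef` (matrix, one terminal node
#'   per column, frequency order), `f_lo`/`f_hi`/`center` per node (Hz),
#'   `level`, `wavelet`, `n_orig`, `n_pad`.
#' @export
#' @examples
#' dec <- wpd_decompose(sin(2 * pi * 10 * (0:999) / 1000))
#' dec$center[which.max(colSums(dec$coef^2))]  # ~10 Hz
wpd_decompose <- function(signal, level = 9L, wavelet = "haar",
                          padding = c("zero", "symmetric")) {
  if (!identical(tolower(wavelet), "haar"))
    stop("unsupported wavelet: ", wavelet, " (only \"haar\" is implemented)")
  padding <- match.arg(padding)
  if (length(signal) != N_SAMPLES) stop("signal must have length 1000")
  stopifnot(level >= 1L, level <= 10L)
  x <- .wpd_pad(signal, padding)
  X <- matrix(x, ncol = 1L)
  for (l in seq_len(level)) X <- .haar_step(X, n_channels = 1L)
  K <- 2L^level
  ord <- .sequency_order(level)           # natural index (0-based) per freq pos
  X <- X[, ord + 1L, drop = FALSE]
  width <- (FS / 2) / K
  structure(list(coef = X, level = as.integer(level), wavelet = "haar",
                 n_orig = N_SAMPLES, n_pad = length(x), padding = padding,
                 f_lo = (seq_len(K) - 1) * width,
                 f_hi = seq_len(K) * width,
                 center = (seq_len(K) - 0.5) * width),
            class = "wp_decomposition")
}

.wpd_pad <- function(x, padding) {
  n_pad <- 2L^ceiling(log2(length(x)))
  extra <- n_pad - length(x)
  if (extra == 0L) return(x)
  if (padding == "zero") return(c(x, numeric(extra)))
  left <- extra %/% 2L
  right <- extra - left
  c(rev(x[seq_len(left)]), x, rev(x)[seq_len(right)])
}

# one Haar analysis level; X has node-major columns, n_channels per node
.haar_step <- function(X, n_channels) {
  m <- nrow(X)
  odd <- X[seq(1L, m, by = 2L), , drop = FALSE]
  even <- X[seq(2L, m, by = 2L), , drop = FALSE]
  a <- (odd + even) / sqrt(2)
  d <- (odd - even) / sqrt(2)
  K <- ncol(X) / n_channels
  out <- matrix(0, nrow = m / 2L, ncol = 2L * K * n_channels)
  blk <- seq_len(n_channels)
  for (k in seq_len(K)) {
    src <- (k - 1L) * n_channels + blk
    out[, (2L * k - 2L) * n_channels + blk] <- a[, src]
    out[, (2L * k - 1L) * n_channels + blk] <- d[, src]
  }
  out
}

# natural (Paley) node index, 0-based, for each frequency-ordered position.
# Children of a node at even frequency position keep (approx -> low,
# detail -> high); at odd positions the spectral image is mirrored and the
# assignment swaps. This is the standard Gray-code/sequency correction.
.sequency_order <- function(level) {
  ord <- 0L
  for (l in seq_len(level)) {
    nxt <- integer(2L * length(ord))
    for (p in seq_along(ord)) {
      lo <- 2L * ord[p]
      hi <- lo + 1L
      if ((p - 1L) %% 2L == 0L) {
        nxt[2L * p - 1L] <- lo; nxt[2L * p] <- hi
      } else {
        nxt[2L * p - 1L] <- hi; nxt[2L * p] <- lo
      }
    }
    ord <- nxt
  }
  ord
}

#' Assign wavelet-packet terminal nodes to EEG bands
#'
#' Each terminal node goes to at most one band, decided by its interval's
#' center frequency against the half-open band ranges `[f_lo, f_hi)`.
#' Nodes below delta (the 0-0.5 Hz node) and above gamma (100-500 Hz) stay
#' unassigned.
#'
#' @param dec a [wpd_decompose()] result.
#' @param bands band table as from [band_definitions()].
#' @return Named list of `band_coefficients` (band row, node indices,
#'   concatenated coefficient vector), one entry per band.
#' @export
map_nodes_to_bands <- function(dec, bands = band_definitions()) {
  stopifnot(inherits(dec, "wp_decomposition"))
  out <- lapply(seq_len(nrow(bands)), function(b) {
    nodes <- which(dec$center >= bands$f_lo[b] & dec$center < bands$f_hi[b])
    if (!length(nodes))
      stop("band ", bands$name[b], " captured no wavelet-packet nodes")
    structure(list(band = bands[b, ], nodes = nodes,
                   coeffs = as.vector(dec$coef[, nodes, drop = FALSE])),
              class = "band_coefficients")
  })
  stats::setNames(out, bands$name)
}

#' Wavelet-band energy, variance and entropy
#'
#' Statistics of a band's concatenated terminal coefficients d_j: energy is
#' `sum(d_j^2)`; variance is the sample variance (denominator N-1); entropy
#' is the unnormalized log-energy form `sum(d_j^2 * log(d_j^2))` with
#' `0*log(0) = 0` — note the convention carries no minus sign, so values can
#' be negative; `shannon = TRUE` flips the sign.
#'
#' @param bc a `band_coefficients` entry from [map_nodes_to_bands()].
#' @param shannon use the sign-flipped (Shannon-style) entropy variant.
#' @return A scalar.
#' @export
tf_band_energy <- function(bc) {
  stopifnot(inherits(bc, "band_coefficients"))
  sum(bc$coeffs^2)
}

#' @rdname tf_band_energy
#' @export
tf_band_variance <- function(bc) {
  stopifnot(inherits(bc, "band_coefficients"))
  if (length(bc$coeffs) < 2L) stop("band variance needs >= 2 coefficients")
  var(bc$coeffs)
}

#' @rdname tf_band_energy
#' @export
tf_band_entropy <- function(bc, shannon = FALSE) {
  stopifnot(inherits(bc, "band_coefficients"))
  p <- bc$coeffs^2
  val <- sum(ifelse(p > 0, p * log(p), 0))
  if (shannon) -val else val
}

#' Time-frequency feature extraction for one segment
#'
#' 15 features per channel from the 9-level Haar wavelet packet transform:
#' TF1-TF5 band energies (delta..gamma), TF6-TF10 band variances, TF11-TF15
#' band entropies; 285 features per segment, channel-major. All 19 channels
#' are decomposed in one multi-channel pass; the result matches the
#' single-channel [wpd_decompose()] route exactly.
#'
#' @param segment an `eeg_segment`.
#' @param padding passed to the decomposition ("zero" default).
#' @param shannon_entropy sign-flipped entropy variant (default FALSE:
#'   the raw `sum(d^2 log d^2)` convention).
#' @return Named numeric vector of length 285.
#' @export
extract_tf <- function(segment, padding = "zero", shannon_entropy = FALSE) {
  validate_segment(segment)
  level <- 9L
  X <- apply(segment$data, 1, .wpd_pad, padding = padding)  # 1024 x 19
  for (l in seq_len(level)) X <- .haar_step(X, n_channels = N_CHANNELS)
  K <- 2L^level
  ord <- .sequency_order(level)
  bands <- band_definitions()
  width <- (FS / 2) / K
  centers <- (seq_len(K) - 0.5) * width
  feats <- matrix(0, nrow = 15L, ncol = N_CHANNELS)
  for (b in seq_len(5L)) {
    nodes <- which(centers >= bands$f_lo[b] & centers < bands$f_hi[b])
    nat <- ord[nodes]                     # natural 0-based node indices
    cols <- as.vector(outer(seq_len(N_CHANNELS), nat * N_CHANNELS, "+"))
    # reshape so each column holds one channel's concatenated band coeffs
    C <- matrix(aperm(array(X[, cols], c(nrow(X), N_CHANNELS, length(nat))),
                      c(1, 3, 2)),
                nrow = nrow(X) * length(nat), ncol = N_CHANNELS)
    en <- colSums(C^2)
    N <- nrow(C)
    vr <- colSums((C - rep(colMeans(C), each = N))^2) / (N - 1)
    P <- C^2
    ent <- colSums(ifelse(P > 0, P * log(P), 0))
    if (shannon_entropy) ent <- -ent
    feats[b, ] <- en
    feats[b + 5L, ] <- vr
    feats[b + 10L, ] <- ent
  }
  ids <- make_feature_ids("TF", paste0("TF", 1:15), seq_len(N_CHANNELS))
  stats::setNames(as.vector(feats), ids)
}
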