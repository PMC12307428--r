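#' Effect configuration for the synthetic EEG generator
#'
#' Describes the stochastic world the generator draws from: a 1/f-shaped
#' Gaussian background plus five band-limited oscillations per channel, with
#' class-dependent multiplicative band-power modulation on a subset of
#' channels (an ERD/ERS-style effect) and one log-normal gain per subject.
#'
#' @param multipliers 6 x 5 numeric matrix of band-power multipliers,
#'   rows = classes 1..6 (class 6 = NoMT baseline, must be all 1),
#'   columns = bands delta..gamma. All entries must be positive.
#' @param affected_channels integer channel indices (1-19) the class effect
#'   applies to; elsewhere the multiplier is 1.
#' @param subject_gain_sd sdlog of the per-subject log-normal gain.
#' @param background_exponent slope of the 1/f^exponent background spectrum.
#' @param background_scale standard deviation (microvolts) of the background.
#' @param band_scales length-5 vector of oscillation standard deviations
#'   (microvolts) for delta..gamma at multiplier 1.
#' @param band_defs band table as from [band_definitions()].
#'
#' @return An object of class `effect_config`.
#' @export
#' @examples
#' cfg <- effect_config()        # the default, class-separable world
#' cfg0 <- null_effect_config()  # global null: no class effect at all
effect_config <- function(multipliers = default_multipliers(),
                          affected_channels = c(8L, 9L, 10L),
                          subject_gain_sd = 0.2,
                          background_exponent = 1,
                          background_scale = 10,
                          band_scales = c(delta = 6, theta = 4, alpha = 5,
                                          beta = 3, gamma = 1.5),
                          band_defs = band_definitions()) {
  multipliers <- as.matrix(multipliers)
  if (!all(dim(multipliers) == c(N_CLASSES, 5L)))
    stop("multipliers must be a 6 x 5 matrix (classes x bands)")
  if (any(!is.finite(multipliers)) || any(multipliers <= 0))
    stop("multipliers must be finite and > 0")
  if (any(multipliers[N_CLASSES, ] != 1))
    stop("NoMT class (row 6) multipliers must all be 1 (baseline)")
  if (length(affected_channels) < 1L ||
      any(affected_channels < 1L | affected_channels > N_CHANNELS))
    stop("affected_channels must be channel indices in 1..19")
  stopifnot(subject_gain_sd >= 0, background_exponent >= 0,
            background_scale > 0, length(band_scales) == 5L,
            all(band_scales > 0))
  structure(list(
    multipliers = multipliers,
    affected_channels = as.integer(affected_channels),
    subject_gain_sd = subject_gain_sd,
    background_exponent = background_exponent,
    background_scale = background_scale,
    band_scales = unname(band_scales),
    band_defs = band_defs
  ), class = "effect_config")
}

#' @rdname effect_config
#' @details `default_multipliers()` encodes the package's stated world for the
#'   five finger classes: distinct alpha/beta modulation patterns over the
#'   central channels, with NoMT as the untouched baseline.
#' @export
default_multipliers <- function() {
  m <- matrix(1, nrow = N_CLASSES, ncol = 5,
              dimnames = list(paste0("class", 1:6),
                              c("delta", "theta", "alpha", "beta", "gamma")))
  # per-class (alpha, beta) power modulation; classes 1..5 get distinct patterns
  m[1, c("alpha", "beta")] <- c(1.8, 1.0)
  m[2, c("alpha", "beta")] <- c(1.4, 1.5)
  m[3, c("alpha", "beta")] <- c(0.6, 1.1)
  m[4, c("alpha", "beta")] <- c(0.8, 0.5)
  m[5, c("alpha", "beta")] <- c(1.0, 1.9)
  m
}

#' @rdname effect_config
#' @param ... passed on to `effect_config()`.
#' @export
null_effect_config <- function(...) {
  effect_config(multipliers = matrix(1, N_CLASSES, 5), ...)
}

# frequency grid (Hz) of the length-1000 DFT, bins 0..999
.fft_freqs <- function(n = N_SAMPLES, fs = FS) (seq_len(n) - 1) * fs / n

# Gaussian noise with the given two-sided spectral amplitude profile, drawn
# directly in the frequency domain (the DFT of white Gaussian noise is
# complex Gaussian, so this matches filtering white noise exactly in law).
# Returns n x n_channels columns normalized to unit standard deviation.
.spectral_noise <- function(n_channels, n, amp) {
  half <- n / 2
  re <- matrix(rnorm(n * n_channels), nrow = n)
  im <- matrix(rnorm(n * n_channels), nrow = n)
  sp <- matrix(0 + 0i, n, n_channels)
  idx <- 2:half                           # positive frequencies below Nyquist
  sp[idx, ] <- (re[idx, ] + 1i * im[idx, ]) / sqrt(2)
  sp[half + 1L, ] <- re[half + 1L, ]      # Nyquist bin is real
  sp[n:(half + 2L), ] <- Conj(sp[idx, ])  # Hermitian symmetry
  sp <- sp * amp
  w <- Re(mvfft(sp, inverse = TRUE)) / sqrt(n)
  mu <- colMeans(w)
  sds <- sqrt(colSums((w - rep(mu, each = n))^2) / (n - 1))
  sweep(w, 2, ifelse(sds > 0, sds, 1), "/")
}

# colored-noise channels shaped to 1/f^exponent power, sd = scale
.background_noise <- function(n_channels, n, exponent, scale) {
  f_fold <- pmin(.fft_freqs(n), FS - .fft_freqs(n))
  amp <- if (exponent > 0) ifelse(f_fold > 0, f_fold^(-exponent / 2), 0)
         else rep(1, n)
  .spectral_noise(n_channels, n, amp) * scale
}

# band-limited unit-variance noise, one column per channel
.band_noise <- function(n_channels, n, f_lo, f_hi) {
  f_fold <- pmin(.fft_freqs(n), FS - .fft_freqs(n))
  .spectral_noise(n_channels, n, as.numeric(f_fold >= f_lo & f_fold < f_hi))
}

#' Generate one synthetic EEG segment
#'
#' Builds a 19 x 1000 epoch as
#' `subject_gain * (background + sum_bands multiplier-scaled oscillation)`,
#' where the band multiplier applies (as a power factor, i.e. sqrt on
#' amplitude) only on the configured affected channels of the given class.
#'
#' @param class_id class label in 1..6 (1-5 fingers, 6 NoMT).
#' @param subject_gain positive multiplicative gain for the subject.
#' @param cfg an [effect_config()].
#' @param seed integer seed, or NULL to consume the current RNG stream
#'   (used by [generate_dataset()]).
#' @param subject,segment_id metadata carried on the segment.
#'
#' @return An `eeg_segment`: list with `data` (19 x 1000 matrix, microvolts),
#'   `fs`, `label`, `subject`, `segment_id`.
#' @export
generate_segment <- function(class_id, subject_gain = 1, cfg = effect_config(),
                             seed = NULL, subject = "S1", segment_id = 1L) {
  if (!inherits(cfg, "effect_config")) stop("cfg must be an effect_config")
  if (length(class_id) != 1L || !class_id %in% 1:N_CLASSES)
    stop("class_id must be a single value in 1..6")
  if (!is.finite(subject_gain) || subject_gain <= 0)
    stop("subject_gain must be a positive number")
  class_id <- as.integer(class_id)
  data <- with_seed(seed, {
    x <- .background_noise(N_CHANNELS, N_SAMPLES,
                           cfg$background_exponent, cfg$background_scale)
    for (b in seq_len(5L)) {
      bd <- cfg$band_defs[b, ]
      osc <- .band_noise(N_CHANNELS, N_SAMPLES, bd$f_lo, bd$f_hi)
      amp <- rep(cfg$band_scales[b], N_CHANNELS)
      amp[cfg$affected_channels] <- amp[cfg$affected_channels] *
        sqrt(cfg$multipliers[class_id, b])
      x <- x + sweep(osc, 2, amp, "*")
    }
    t(x) * subject_gain                     # channels x samples
  })
  new_eeg_segment(data, class_id, subject, segment_id)
}

new_eeg_segment <- function(data, label, subject, segment_id) {
  structure(list(data = data, fs = FS, label = as.integer(label),
                 subject = as.character(subject),
                 segment_id = as.integer(segment_id)),
            class = "eeg_segment")
}

#' Validate an EEG segment
#' @param x object to check.
#' @return `x`, invisibly; errors if invalid.
#' @export
validate_segment <- function(x) {
  if (!inherits(x, "eeg_segment")) stop("not an eeg_segment")
  if (!is.matrix(x$data) || nrow(x$data) != N_CHANNELS ||
      ncol(x$data) != N_SAMPLES)
    stop("segment data must be a 19 x 1000 matrix")
  if (any(!is.finite(x$data))) stop("segment contains non-finite values")
  if (x$fs != FS) stop("sampling rate must be 1000 Hz")
  if (!x$label %in% 1:N_CLASSES) stop("label must be in 1..6")
  invisible(x)
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> subject %s, class %d, id %d: %d ch x %d samples @ %d Hz\n",
              x$subject, x$label, x$segment_id, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

new_segment_collection <- function(segments, channel_names = eeg_channels()) {
  labels <- vapply(segments, `[[`, integer(1), "label")
  counts <- integer(N_CLASSES)
  tb <- table(factor(labels, levels = 1:N_CLASSES))
  counts[] <- as.integer(tb)
  structure(list(segments = segments, channel_names = channel_names,
                 class_counts = stats::setNames(counts, 1:N_CLASSES)),
            class = "segment_collection")
}

#' @export
print.segment_collection <- function(x, ...) {
  cat(sprintf("<segment_collection> %d segments, subjects: %s; class counts: %s\n",
              length(x$segments),
              paste(unique(vapply(x$segments, `[[`, "", "subject")), collapse = ","),
              paste(x$class_counts, collapse = "/")))
  invisible(x)
}

#' Generate a multi-subject synthetic EEG dataset
#'
#' One collection per subject, balanced over the six classes. Subject gains
#' are drawn once per subject from a log-normal with sdlog
#' `cfg$subject_gain_sd`; all randomness comes from `seed`.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param n_per_class segments per class per subject (>= 2).
#' @param cfg an [effect_config()].
#' @param seed integer seed.
#' @return List of `segment_collection`, one per subject, named S1, S2, ...
#' @export
#' @examples
#' ds <- generate_dataset(1, 2, effect_config(), seed = 1)
#' length(ds[[1]]$segments)  # 12
generate_dataset <- function(n_subjects, n_per_class, cfg = effect_config(),
                             seed = 1L) {
  stopifnot(n_subjects >= 1, n_per_class >= 2)
  with_seed(seed, {
    gains <- rlnorm(n_subjects, meanlog = 0, sdlog = cfg$subject_gain_sd)
    out <- vector("list", n_subjects)
    sid <- 0L
    for (s in seq_len(n_subjects)) {
      subj <- paste0("S", s)
      segs <- vector("list", N_CLASSES * n_per_class)
      i <- 0L
      for (cl in 1:N_CLASSES) {
        for (r in seq_len(n_per_class)) {
          i <- i + 1L; sid <- sid + 1L
          segs[[i]] <- generate_segment(cl, gains[s], cfg, seed = NULL,
                                        subject = subj, segment_id = sid)
        }
      }
      out[[s]] <- new_segment_collection(segs)
    }
    names(out) <- paste0("S", seq_len(n_subjects))
    out
  })
}

#' Write / read a segment collection as plain text
#'
#' Layout: `<stem>_meta.csv` with one row per segment (segment_id, subject,
#' label, fs) plus the channel names as a header attribute row, and
#' `<stem>_signals.csv` holding the signal matrix with `19 * n_segments`
#' rows (segment-major, channels in montage order) and 1000 columns.
#'
#' @param collection a `segment_collection`.
#' @param stem path stem (no extension) for the two CSV files.
#' @return `write_collection` returns the two paths invisibly;
#'   `read_collection` returns a `segment_collection`.
#' @export
write_collection <- function(collection, stem) {
  stopifnot(inherits(collection, "segment_collection"))
  meta <- data.frame(
    segment_id = vapply(collection$segments, `[[`, integer(1), "segment_id"),
    subject = vapply(collection$segments, `[[`, "", "subject"),
    label = vapply(collection$segments, `[[`, integer(1), "label"),
    fs = vapply(collection$segments, `[[`, integer(1), "fs"),
    stringsAsFactors = FALSE
  )
  meta$channels <- paste(collection$channel_names, collapse = "|")
  meta_path <- paste0(stem, "_meta.csv")
  sig_path <- paste0(stem, "_signals.csv")
  write.csv(meta, meta_path, row.names = FALSE)
  sig <- do.call(rbind, lapply(collection$segments, `[[`, "data"))
  write.table(round(sig, 6), sig_path, sep = ",",
              row.names = FALSE, col.names = FALSE)
  invisible(c(meta_path, sig_path))
}

#' @rdname write_collection
#' @export
read_collection <- function(stem) {
  meta_path <- paste0(stem, "_meta.csv")
  sig_path <- paste0(stem, "_signals.csv")
  if (!file.exists(meta_path)) stop("missing metadata file: ", meta_path)
  if (!file.exists(sig_path)) stop("missing signal file: ", sig_path)
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  need <- c("segment_id", "subject", "label", "fs")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("collection metadata missing field(s): ",
                         paste(miss, collapse = ", "))
  sig <- as.matrix(read.csv(sig_path, header = FALSE))
  dimnames(sig) <- NULL
  if (nrow(sig) != nrow(meta) * N_CHANNELS || ncol(sig) != N_SAMPLES)
    stop("signal matrix has wrong shape for ", nrow(meta), " segments")
  channels <- strsplit(meta$channels[1], "|", fixed = TRUE)[[1]]
  segs <- lapply(seq_len(nrow(meta)), function(i) {
    rows <- ((i - 1L) * N_CHANNELS + 1L):(i * N_CHANNELS)
    new_eeg_segment(sig[rows, , drop = FALSE], meta$label[i],
                    meta$subject[i], meta$segment_id[i])
  })
  new_segment_collection(segs, channels)
}

#' Read an external source container (optional adapter)
#'
#' Adapter slot for the published finger motor-imagery recordings, which ship
#' as MATLAB matrix containers. This offline build has no .mat reader, so
#' only the package's own CSV collection layout (see [write_collection()]) is
#' supported; .mat paths raise a format error naming what is missing.
#'
#' @param path path to a collection: either the `_meta.csv` file or the stem.
#' @return A `segment_collection`.
#' @export
read_source_container <- function(path) {
  if (!file.exists(path) && !file.exists(paste0(path, "_meta.csv")))
    stop("no such file: ", path)
  if (grepl("\\.mat$", path, ignore.case = TRUE))
    stop("format error: MATLAB container support requires a .mat reader, ",
         "which is not available in this installation; convert the ",
         "recording to the CSV collection layout (\"o.data\" signal matrix ",
         "and \"o.marker\" codes) documented in ?write_collection")
  stem <- sub("_meta\\.csv$", "", path)
  coll <- read_collection(stem)
  bad <- vapply(coll$segments, function(s) ncol(s$data) != N_SAMPLES, logical(1))
  if (any(bad)) stop("format error: epochs must be exactly 1000 samples (1 s)")
  coll
}
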