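test_that("wpd_decompose: structure, constants and energy conservation", {
  expect_error(wpd_decompose(rnorm(1000), wavelet = "db4"), "unsupported")
  x <- rep(3, 1000)
  dec <- wpd_decompose(x, padding = "symmetric")
  expect_equal(ncol(dec$coef), 512L)
  # a constant signal leaves everything except the lowest node (near) zero
  en <- colSums(dec$coef^2)
  expect_gt(en[1] / sum(en), 1 - 1e-12)
  # orthonormality: terminal energy equals (padded) input energy
  set.seed(12)
  for (r in 1:20) {
    v <- rnorm(1000)
    d0 <- wpd_decompose(v)                # zero padding: original energy
    expect_equal(sum(d0$coef^2), sum(v^2), tolerance = 1e-10)
    ds <- wpd_decompose(v, padding = "symmetric")
    vp <- fingereeg:::.wpd_pad(v, "symmetric")
    expect_equal(sum(ds$coef^2), sum(vp^2), tolerance = 1e-10)
  }
})

test_that("sequency ordering puts node energy at the tone frequency", {
  for (f0 in c(5, 10, 21, 40, 77)) {
    x <- sin(2 * pi * f0 * (0:999) / 1000)
    dec <- wpd_decompose(x)
    peak <- dec$center[which.max(colSums(dec$coef^2))]
    expect_lt(abs(peak - f0), 1.0)        # within one node width of the tone
  }
})

test_that("white-noise band energies are proportional to band widths", {
  set.seed(13)
  counts <- c(3L, 4L, 5L, 18L, 71L)       # nodes per band at level 9
  fracs <- matrix(0, 40, 5)
  for (r in 1:40) {
    dec <- wpd_decompose(rnorm(1000))
    bc <- map_nodes_to_bands(dec)
    tot <- sum(dec$coef^2)
    fracs[r, ] <- vapply(bc, tf_band_energy, numeric(1)) / tot
  }
  expect_equal(colMeans(fracs), counts / 512, tolerance = 0.1)
})

test_that("node-to-band mapping is a partition with the expected gaps", {
  dec <- wpd_decompose(rnorm(1000))
  bc <- map_nodes_to_bands(dec)
  nodes <- unlist(lapply(bc, `[[`, "nodes"))
  expect_equal(anyDuplicated(nodes), 0L)          # no node in two bands
  expect_lt(length(nodes), 512L)                  # sub-delta + >100 Hz free
  expect_equal(length(nodes), sum(c(3, 4, 5, 18, 71)))
  # node width 500/512; the node centered at 10.25 Hz belongs to alpha
  k <- which.min(abs(dec$center - 10.25))
  expect_true(k %in% bc$alpha$nodes)
  # half-open band edges: center 29.79 -> beta, 30.76 -> gamma
  expect_true(which.min(abs(dec$center - 29.79)) %in% bc$beta$nodes)
  expect_true(which.min(abs(dec$center - 30.76)) %in% bc$gamma$nodes)
})

test_that("wavelet band statistics follow their printed forms", {
  mk <- function(co) structure(list(band = band_definitions()[3, ],
                                    nodes = integer(0), coeffs = co),
                               class = "band_coefficients")
  expect_equal(tf_band_energy(mk(c(1, 2, 2))), 9)
  expect_equal(tf_band_energy(mk(numeric(3))), 0)
  expect_equal(tf_band_variance(mk(c(0, 2))), 2)
  expect_equal(tf_band_variance(mk(rep(5, 4))), 0)
  expect_error(tf_band_variance(mk(1)), ">= 2")
  # entropy: single coefficient with d^2 = e gives e * log(e) = e
  expect_equal(tf_band_entropy(mk(exp(0.5))), exp(1))
  expect_equal(tf_band_entropy(mk(numeric(5))), 0)   # 0 * log 0 convention
  set.seed(14)
  for (r in 1:50) {
    co <- rnorm(25)
    expect_equal(tf_band_entropy(mk(co)), sum(co^2 * log(co^2)))
    expect_equal(tf_band_entropy(mk(co), shannon = TRUE),
                 -sum(co^2 * log(co^2)))
    expect_equal(tf_band_variance(mk(co)),
                 sum((co - mean(co))^2) / (length(co) - 1))
  }
})

test_that("wavelet alpha energy tracks FFT alpha energy for a 10 Hz tone", {
  x <- sin(2 * pi * 10 * (0:999) / 1000)
  wpt_alpha <- tf_band_energy(map_nodes_to_bands(wpd_decompose(x))$alpha)
  # Eq-style FFT band energy, rescaled to signal units by Parseval (1/N)
  fft_alpha <- band_energy(band_spectrum(x, 1000, band_definitions()[3, ])) / 1000
  expect_lt(abs(wpt_alpha - fft_alpha) / fft_alpha, 0.25)
})

test_that("extract_tf yields 285 features and matches the scalar route", {
  seg <- fix_segment()
  tf <- extract_tf(seg)
  expect_length(tf, 285L)
  expect_true(all(is.finite(tf)))
  ids <- parse_feature_ids(names(tf))
  expect_equal(unname(table(ids$type_code)), rep(19L, 15L), ignore_attr = TRUE)
  expect_equal(unname(table(ids$channel)), rep(15L, 19L), ignore_attr = TRUE)
  expect_true(all(extract_tf(zero_segment()) == 0))
  for (ch in c(1L, 12L)) {
    bc <- map_nodes_to_bands(wpd_decompose(seg$data[ch, ]))
    for (b in 1:5) {
      expect_equal(tf[[paste0("TF:TF", b, ":ch", ch)]],
                   tf_band_energy(bc[[b]]))
      expect_equal(tf[[paste0("TF:TF", b + 5, ":ch", ch)]],
                   tf_band_variance(bc[[b]]))
      expect_equal(tf[[paste0("TF:TF", b + 10, ":ch", ch)]],
                   tf_band_entropy(bc[[b]]))
    }
  }
})
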