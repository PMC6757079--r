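# Frozen single-level coefficients for x = 1..8 (periodized boundary mode),
# computed once with an independent wavelet implementation (PyWavelets
# 1.9.0) and used here as an external oracle for the filter bank.
pywt_db4_ca <- c(11.20225481, 3.26486322, 4.33504706, 6.65367903)
pywt_db4_cd <- c(-0.10111225, -0.08477921, 1.84302251, 1.17129609)
pywt_db2_ca <- c(4.76027878, 3.72500260, 6.55342972, 10.41713303)
pywt_db2_cd <- c(-1.03527618, 0, 0, 3.86370331)

test_that("single-level decomposition matches the independent wavelet oracle", {
  co4 <- dwt_decompose(1:8, wavelet_spec(fs = 8, family = "db4", n_levels = 1))
  expect_equal(co4$approx, pywt_db4_ca, tolerance = 1e-7)
  expect_equal(co4$details[[1]], pywt_db4_cd, tolerance = 1e-7)
  co2 <- dwt_decompose(1:8, wavelet_spec(fs = 8, family = "db2", n_levels = 1))
  expect_equal(co2$approx, pywt_db2_ca, tolerance = 1e-7)
  expect_equal(co2$details[[1]], pywt_db2_cd, tolerance = 1e-7)
})

test_that("decompose/reconstruct is a perfect-reconstruction identity", {
  set.seed(10)
  for (n in c(256, 768, 1536, 1537)) {   # includes an odd length
    x <- rnorm(n)
    spec <- wavelet_spec(fs = 256, n_levels = 5)
    expect_lt(max(abs(dwt_reconstruct(dwt_decompose(x, spec)) - x)) /
                max(abs(x)), 1e-8)
  }
  # zero in, zero out (linearity)
  co0 <- dwt_decompose(numeric(64), wavelet_spec(fs = 64, n_levels = 3))
  expect_true(all(abs(unlist(co0$details)) == 0) && all(co0$approx == 0))
})

test_that("the orthonormal transform conserves energy (Parseval)", {
  imp <- c(1, rep(0, 255))
  co <- dwt_decompose(imp, wavelet_spec(fs = 256, n_levels = 3))
  energy <- sum(co$approx^2) + sum(vapply(co$details,
                                          function(d) sum(d^2), 0))
  expect_equal(energy, 1, tolerance = 1e-12)
})

test_that("decomposition depth is validated against signal length", {
  expect_error(dwt_decompose(rnorm(16), wavelet_spec(fs = 256, n_levels = 5)),
               "maximum feasible depth is 4")
})

test_that("band-to-level mapping follows the dyadic arithmetic at fs = 256", {
  spec <- wavelet_spec(256)
  expect_equal(spec$n_levels, 5)
  bands <- default_bands(256)
  expect_equal(band_level_map(bands$theta, spec)$details, 5L)  # 4-8 Hz
  expect_equal(band_level_map(bands$alpha, spec)$details, 4L)  # 8-16 Hz
  expect_equal(band_level_map(bands$beta, spec)$details, 3L)   # 16-32 Hz
  expect_equal(band_level_map(bands$gamma, spec)$details, c(1L, 2L)) # 32-128
  dl <- band_level_map(bands$delta, spec)
  expect_true(dl$approx)                                       # 0-4 Hz
  expect_error(band_level_map(band_definition("x", 200, 300), spec),
               "Nyquist")
})

test_that("the five band reconstructions sum back to the input", {
  set.seed(11)
  x <- raw_eeg(matrix(rnorm(2 * 1536), nrow = 2), fs = 256)
  recs <- lapply(names(default_bands(256)), function(b)
    extract_rhythm(x, b)$data)
  total <- Reduce(`+`, recs)
  expect_lt(max(abs(total - x$data)) / max(abs(x$data)), 1e-6)
})

test_that("band extraction is selective for in-band tones", {
  t <- (0:1535) / 256
  x <- raw_eeg(matrix(sin(2 * pi * 10 * t), nrow = 1), fs = 256)
  v <- vapply(names(default_bands(256)), function(b)
    var(as.numeric(extract_rhythm(x, b)$data)), 0)
  v <- v / var(as.numeric(x$data))
  expect_gt(v["alpha"], 0.80)   # 10 Hz belongs to alpha
  expect_lt(v["gamma"], 0.10)
  expect_equal(names(which.max(v)), "alpha")
  # a tone at each band's center is captured best by its own band
  centers <- c(delta = 2, theta = 6, alpha = 10, beta = 22, gamma = 40)
  for (b in names(centers)) {
    xs <- raw_eeg(matrix(sin(2 * pi * centers[[b]] * t), nrow = 1), fs = 256)
    vv <- vapply(names(default_bands(256)), function(bb)
      var(as.numeric(extract_rhythm(xs, bb)$data)), 0)
    expect_equal(names(which.max(vv)), b)
  }
})

test_that("extraction is linear and shape-preserving", {
  set.seed(12)
  a <- raw_eeg(matrix(rnorm(3 * 512), nrow = 3), fs = 256)
  b <- raw_eeg(matrix(rnorm(3 * 512), nrow = 3), fs = 256)
  mix <- raw_eeg(2 * a$data - 3 * b$data, fs = 256)
  ra <- extract_rhythm(a, "theta")
  expect_equal(dim(ra$data), dim(a$data))
  rb <- extract_rhythm(b, "theta")
  rmix <- extract_rhythm(mix, "theta")
  expect_equal(rmix$data, 2 * ra$data - 3 * rb$data, tolerance = 1e-10)
})

test_that("white-noise band variance tracks relative bandwidth", {
  set.seed(13)
  x <- raw_eeg(matrix(rnorm(4 * 4096), nrow = 4), fs = 256)
  v_in <- mean(apply(x$data, 1, var))
  v_theta <- mean(apply(extract_rhythm(x, "theta")$data, 1, var))
  expected <- (8 - 4) / 128  # dyadic theta width over Nyquist
  ratio <- (v_theta / v_in) / expected
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("unknown band names and mismatched specs are rejected", {
  x <- raw_eeg(matrix(rnorm(256), nrow = 1), fs = 256)
  expect_error(extract_rhythm(x, "sigma"), "valid names")
  expect_error(extract_rhythm(x, "theta", spec = wavelet_spec(128)),
               "does not match")
  expect_error(wavelet_spec(256, family = "morlet"), "unknown wavelet")
})

test_that("exact-edge mode sharpens band edges with zero phase", {
  t <- (0:2047) / 256
  # 14.5 Hz: inside printed beta (14-30) but in the dyadic alpha level (8-16)
  x <- raw_eeg(matrix(sin(2 * pi * 14.5 * t), nrow = 1), fs = 256)
  dyadic <- extract_rhythm(x, "beta")
  exact <- extract_rhythm(x, "beta", exact_edges = TRUE)
  v_in <- var(as.numeric(x$data))
  expect_lt(var(as.numeric(dyadic$data)) / v_in, 0.5)  # dyadic misses it
  expect_gt(var(as.numeric(exact$data)) / v_in, 0.9)   # exact edges catch it
  # zero phase: in-band tone reconstructed in phase
  expect_gt(cor(as.numeric(exact$data), as.numeric(x$data)), 0.95)
})
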