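test_that("band-pass decomposition isolates band energy (FFT-mask oracle)", {
  set.seed(11)
  rec <- sine_recording(freq = 10, rate = 200, seconds = 5, noise_sd = 0.01)
  stack <- bandpass_decompose(rec, default_bands())
  v_in <- stats::var(rec$data[1, ])
  v_alpha <- stats::var(stack[1, , "alpha"])
  v_delta <- stats::var(stack[1, , "delta"])
  expect_gt(v_alpha / v_in, 0.9)
  expect_lt(v_delta / v_in, 0.05)
  # agree with an independent FFT mask filter on retained variance
  v_oracle <- oracle_fft_bandpass_var(rec$data[1, ], 200, 8, 13)
  expect_lt(abs(v_alpha - v_oracle) / v_oracle, 0.1)
})

test_that("band-pass decomposition is linear and validates bands", {
  rec <- raw_recording(matrix(0, 2, 1000), 200, c("E01", "E02"), "s", "t", 1L)
  stack <- bandpass_decompose(rec, default_bands())
  expect_true(all(stack == 0))
  expect_error(resolve_band(band_spec("bad", 100, 200), 200), "Nyquist")
})

test_that("windowing follows the floor rule and warns on short signals", {
  m <- matrix(rnorm(2 * 400), 2, 400)
  expect_length(segment_windows(m, 200, 1, 1), 2L)
  expect_length(segment_windows(m[, 1:399, drop = FALSE], 200, 1, 1), 1L)
  expect_length(segment_windows(matrix(rnorm(2 * 600), 2, 600), 200, 1, 0.5), 5L)
  expect_warning(res <- segment_windows(m[, 1:100, drop = FALSE], 200, 1, 1),
                 "shorter")
  expect_length(res, 0L)
})

test_that("differential entropy matches the Gaussian closed form and scale rule", {
  set.seed(7)
  w <- rnorm(10000)
  expect_lt(abs(differential_entropy(w) - 0.5 * log(2 * pi * exp(1))), 0.05)
  # exact scale rule DE(aX) = DE(X) + log(a)
  for (a in c(0.5, 2, 7)) {
    expect_equal(differential_entropy(a * w), differential_entropy(w) + log(a),
                 tolerance = 1e-12)
  }
  expect_warning(de0 <- differential_entropy(rep(1, 50)), "degenerate")
  expect_equal(de0, 0.5 * log(2 * pi * exp(1) * 1e-12))
})

test_that("band power follows an FFT oracle and handles degenerate input", {
  set.seed(8)
  rate <- 200
  t <- seq(0, 1 - 1 / rate, by = 1 / rate)
  w <- sin(2 * pi * 10 * t)
  alpha <- power_spectral_density(w, rate, band_spec("alpha", 8, 13), log = FALSE)
  beta <- power_spectral_density(w, rate, band_spec("beta", 14, 30), log = FALSE)
  expect_gt(alpha / beta, 10)
  # white noise: roughly flat across bands (long window)
  w2 <- rnorm(10000)
  p <- vapply(default_bands()[1:4], function(b) {
    power_spectral_density(w2, rate, b, log = FALSE)
  }, numeric(1))
  expect_lt(max(p) / min(p), 2)
  expect_equal(power_spectral_density(rep(0, 256), rate, band_spec("alpha", 8, 13)),
               log(1e-12))
  expect_error(power_spectral_density(w[1:16], rate, band_spec("x", 10, 10.5)),
               "no frequency bin")
})

test_that("asymmetry features obey symmetry, antisymmetry and substitution", {
  mont <- make_montage(6)
  de <- array(rnorm(4 * 6 * 5), c(4, 6, 5))
  sym <- de
  for (p in seq_len(nrow(mont$symmetric_pairs))) {
    sym[, mont$symmetric_pairs[p, 2], ] <- sym[, mont$symmetric_pairs[p, 1], ]
  }
  expect_true(all(asymmetry_features(sym, mont, "DASM") == 0))
  expect_true(all(abs(asymmetry_features(sym, mont, "RASM") - 1) < 1e-12))
  # swapping left/right negates DASM and inverts RASM
  mont_sw <- mont
  mont_sw$symmetric_pairs <- mont$symmetric_pairs[, c(2, 1)]
  d1 <- asymmetry_features(de, mont, "DASM")
  d2 <- asymmetry_features(de, mont_sw, "DASM")
  expect_equal(d2, -d1, tolerance = 1e-12)
  r1 <- asymmetry_features(de, mont, "RASM")
  r2 <- asymmetry_features(de, mont_sw, "RASM")
  expect_equal(r2, 1 / r1, tolerance = 1e-9)
  # direct substitution
  de2 <- array(0, c(1, 6, 1)); de2[1, mont$symmetric_pairs[1, 1], 1] <- 2
  de2[1, mont$symmetric_pairs[1, 2], 1] <- 0.5
  expect_equal(asymmetry_features(de2, mont, "DASM")[1, 1, 1], 1.5)
  expect_equal(asymmetry_features(de2, mont, "RASM")[1, 1, 1], 4.0)
  expect_equal(dim(asymmetry_features(de, mont, "ASM"))[2], 6L)
})

test_that("feature extraction has the contracted shape and is deterministic", {
  set.seed(12)
  spec <- micro_spec()
  truth <- sample_class_graphs(spec, 5)
  rec <- generate_recording(1, 1, 1, spec, truth, seed = 5)
  ft <- extract_features(rec, feature_config("DE"))
  expect_equal(dim(ft$values), c(20L, 8L, 5L))
  ft2 <- extract_features(rec, feature_config("DE"))
  expect_identical(ft$values, ft2$values)
  mont <- make_montage(8)
  fd <- extract_features(rec, feature_config("DASM"), mont)
  expect_equal(dim(fd$values), c(20L, 4L, 5L))
})
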