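test_that("MLS lengths and the circular autocorrelation identity", {
  expect_equal(length(generate_mls(14)$values), 16383)
  expect_error(generate_mls(30), "unsupported")
  # brute-force autocorrelation for the 7-sample sequence
  v <- generate_mls(3)$values
  brute <- sapply(0:6, function(lag) sum(v * v[(((0:6) + lag) %% 7) + 1]))
  expect_equal(brute, c(7, rep(-1, 6)))
  # identity and the +/-1 balance for all small orders
  for (ord in 3:14) {
    v <- generate_mls(ord)$values
    L <- length(v)
    expect_equal(L, 2^ord - 1)
    ac <- circular_autocorrelation(v)
    expect_equal(ac[1], L, tolerance = 1e-9)
    expect_equal(max(abs(ac[-1] + 1)), 0, tolerance = 1e-6)
    expect_equal(abs(sum(v)), 1)
  }
})

test_that("period accounting: 2 s at 500 kHz holds 61 whole / 60 usable", {
  pc <- mls_period_count(2, 14, 5e5)
  expect_equal(pc$whole, 61)
  expect_equal(pc$usable, 60)
  expect_equal(pc$period_samples, 16383)
})

test_that("deconvolution: identity, round trip, period-count guard", {
  mls <- generate_mls(14)
  rec <- simulate_recording(c(1, numeric(10)), mls, duration_s = 2)
  ir <- deconvolve(rec, mls, n_average = 50)
  expect_equal(which.max(abs(ir)), 1)
  expect_equal(ir[1], 1, tolerance = 1e-3)
  expect_lte(max(abs(ir[-1])), 1 / 16383 + 1e-9)
  expect_error(deconvolve(rec[1:100000], mls, n_average = 50), "periods")
  # planted two-spike IR at 40 dB SNR: delays exact, amplitudes within 1%
  planted <- numeric(600)
  planted[101] <- 0.2
  planted[130] <- 0.1
  rec2 <- simulate_recording(planted, mls, duration_s = 2, snr_db = 40,
                             seed = 3)
  got <- deconvolve(rec2, mls, n_average = 50)
  expect_equal(which.max(abs(got)), 101)
  expect_equal(got[101], 0.2, tolerance = 0.01)
  expect_equal(got[130], 0.1, tolerance = 0.01)
})

test_that("averaging 50 periods cuts residual noise by ~17 dB", {
  mls <- generate_mls(10)  # short sequence keeps the Monte Carlo cheap
  L <- length(mls$values)
  planted <- numeric(50)
  planted[11] <- 1
  dur <- 52 * L / mls$sample_rate
  noise_power <- function(n_avg, seed) {
    rec <- simulate_recording(planted, mls, duration_s = dur, snr_db = 10,
                              seed = seed)
    ir <- deconvolve(rec, mls, n_avg)
    mean((ir[-11])^2)  # off-peak residual
  }
  p1 <- mean(sapply(1:8, function(s) noise_power(1, s)))
  p50 <- mean(sapply(1:8, function(s) noise_power(50, s)))
  expect_equal(10 * log10(p1 / p50), 10 * log10(50), tolerance = 1.5)
})

test_that("echo extraction: peak capture, two spikes, noise-only error", {
  ir <- numeric(8000)
  ir[5000] <- 1
  e <- extract_echo(ir, sample_rate = 5e5)
  expect_equal(attr(e, "peak"), 5000)
  expect_gte(sum(e^2) / sum(ir^2), 0.999)
  ir2 <- ir
  ir2[5100] <- 0.5
  e2 <- extract_echo(ir2, sample_rate = 5e5)
  s <- attr(e2, "start")
  expect_true(all(c(5000, 5100) %in% s:(s + 1023)))
  # false-positive rate below 1% on pure noise at the 5-sigma threshold
  set.seed(42)
  hits <- sum(sapply(1:200, function(i) {
    tryCatch({extract_echo(rnorm(4000), sample_rate = 5e5); 1},
             error = function(e) 0)
  }))
  expect_lt(hits / 200, 0.05)
})

test_that("power spectrum: impulse, tone bin, Parseval", {
  x <- numeric(1024)
  x[1] <- 1
  ps <- power_spectrum(x, 5e5)
  expect_equal(length(ps$power), 513)
  sel <- ps$frequency > 0 & ps$frequency < 2.5e5
  expect_lt(diff(range(ps$power[sel])), 1e-12)
  tone <- sin(2 * pi * 68e3 * (0:1023) / 5e5)
  pt <- power_spectrum(tone, 5e5)
  expect_lt(abs(pt$frequency[which.max(pt$power)] - 68e3), 5e5 / 1024)
  for (seed in 1:3) {
    set.seed(seed)
    y <- rnorm(1024)
    expect_equal(sum(power_spectrum(y, 5e5)$power), sum(y^2),
                 tolerance = 1e-9)
  }
})

test_that("plate calibration: self-calibration, ratios, coloration", {
  x <- numeric(1024)
  x[100] <- 1
  ps <- power_spectrum(x, 5e5)
  ts <- calibrate_ts(ps, ps)
  expect_true(all(abs(ts$ts_db) < 1e-12))
  ps2 <- ps
  ps2$power <- ps$power / 100
  expect_true(all(abs(calibrate_ts(ps2, ps)$ts_db + 20) < 1e-9))
  # a smooth emitter/receiver coloration common to both spectra cancels
  set.seed(7)
  f <- ps$frequency
  colr <- exp(0.5 * sin(2 * pi * f / 2.5e5 * 3) + 0.2 * cos(2 * pi * f /
              2.5e5 * 7))
  flower <- ps
  flower$power <- ps$power * 0.03
  base <- calibrate_ts(flower, ps)
  flower2 <- flower
  plate2 <- ps
  flower2$power <- flower$power * colr
  plate2$power <- ps$power * colr
  expect_equal(calibrate_ts(flower2, plate2)$ts_db, base$ts_db,
               tolerance = 1e-9)
})

test_that("band averaging: flat, half-silent, band membership", {
  n <- 513
  ts <- structure(list(frequency = seq(0, 2.5e5, length.out = n),
                       ts_db = rep(-20, n), reliable = rep(TRUE, n)),
                  class = "ts_spectrum")
  expect_equal(band_ts(ts, list(f_low = 40e3, f_high = 160e3)), -20)
  # half the bins at 0 dB, half fully cancelled -> 10 log10(0.5)
  ts2 <- ts
  ts2$ts_db <- rep(c(0, -Inf), length.out = n)
  got <- band_ts(ts2, list(f_low = 0, f_high = 2.5e5))
  expect_equal(got, 10 * log10(sum(is.finite(ts2$ts_db) &
               ts2$ts_db == 0) / n), tolerance = 1e-9)
  # 45 kHz +/- 20%: membership is the closed interval [36, 54] kHz
  b45 <- ts_bands()[ts_bands()$name == "f45", ]
  expect_equal(c(b45$f_low, b45$f_high), c(36e3, 54e3))
  expect_error(band_ts(ts, list(f_low = 1, f_high = 2)), "no frequency")
})

test_that("overall TS: delog plane averaging and betweenness", {
  expect_equal(overall_ts(rep(-20, 101), rep(-20, 101)), -20)
  got <- overall_ts(rep(-10, 101), rep(-20, 101))
  expect_equal(got, 10 * log10((0.1 + 0.01) / 2), tolerance = 1e-12)
  expect_equal(overall_ts(rep(-15, 101)), -15)
  expect_error(overall_ts(), "at least one")
  # monotone betweenness of delog averaging
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(11, -20, 6)
    m <- delog_mean(x)
    expect_gte(m, min(x))
    expect_lte(m, max(x))
  }
})

test_that("directional spectrum: shape, notch movement, angle-independence", {
  cfg <- fix_cfg()
  truth <- acoustic_truth()
  fl <- fix_flower_depth(15)
  scan <- simulate_scan(fl, "azimuth", truth, cfg)
  plate <- plate_impulse_response(cfg)
  ds <- directional_spectrum(scan, plate)
  expect_equal(dim(ds), c(101, 513))
  expect_equal(length(attr(ds, "frequency")), 513)
  # interference pattern varies across angles ("spotted" plot):
  # row-to-row correlation over the analysis band stays below 1
  sel <- attr(ds, "frequency") >= 40e3 & attr(ds, "frequency") <= 160e3
  cc <- cor(ds[26, sel], ds[51, sel])
  expect_lt(cc, 0.999)
  # an angle-independent reflector gives identical rows
  truth0 <- acoustic_truth(angle_kappa = 0, two_path_ratio = 0)
  scan0 <- simulate_scan(fl, "azimuth", truth0, cfg)
  ds0 <- directional_spectrum(scan0, plate)
  expect_lt(max(abs(sweep(ds0, 2, ds0[1, ]))), 1e-9)
})

test_that("batched scan processing equals the per-angle reference chain", {
  cfg <- fix_small_cfg()
  truth <- acoustic_truth()
  fl <- fix_flowers(1)[3, , drop = FALSE]
  scan <- simulate_scan(fl, "azimuth", truth, cfg)
  plate <- plate_impulse_response(cfg)
  bt <- scan_band_ts(scan, plate)
  b <- ts_bands()
  for (i in c(1, 11, 21)) {
    e <- extract_echo(scan$irs[i, ], sample_rate = cfg$sample_rate)
    p <- extract_echo(plate, sample_rate = cfg$sample_rate)
    ts <- calibrate_ts(power_spectrum(as.numeric(e), cfg$sample_rate),
                       power_spectrum(as.numeric(p), cfg$sample_rate))
    for (j in seq_len(nrow(b)))
      expect_equal(unname(bt[i, j]), band_ts(ts, b[j, ]),
                   tolerance = 1e-9)
  }
})

test_that("scan containers round-trip through the text format", {
  cfg <- fix_small_cfg(n_angles = 5, ir_length = 1200)
  fl <- fix_flowers(1)[1, , drop = FALSE]
  scan <- simulate_scan(fl, "azimuth", cfg = cfg)
  dir <- withr::local_tempdir()
  write_scan(scan, dir)
  back <- read_scan(dir, fl$flower_id, "azimuth")
  expect_equal(back$irs, scan$irs, tolerance = 1e-12)
  expect_equal(back$angles, scan$angles)
  expect_equal(back$species, scan$species)
})

test_that("WAV files round-trip in float and PCM", {
  set.seed(3)
  x <- runif(1000, -0.9, 0.9)
  p <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, p, 5e5, bits = 32)
  got <- read_wav(p)
  expect_equal(got$sample_rate, 5e5)
  expect_equal(got$samples, x, tolerance = 1e-6)
  write_wav(x, p, 192000, bits = 16)
  got16 <- read_wav(p)
  expect_equal(got16$sample_rate, 192000)
  expect_equal(got16$samples, x, tolerance = 1e-3)
})
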