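test_that("echo synthesis: identity IR, linearity, comb transfer", {
  cfg <- fix_cfg()
  call <- synthesize_call(cfg)
  hp <- highpass_call(call)
  # unit-impulse IR returns the filtered call itself
  e <- make_echo(c(1, numeric(50)), hp, length_out = 1024)
  expect_equal(e[seq_along(hp)], as.numeric(hp), tolerance = 1e-9)
  # linearity: halving the IR halves the echo
  e2 <- make_echo(c(0.5, numeric(50)), hp, length_out = 1024)
  expect_equal(e2, e / 2, tolerance = 1e-12)
  expect_error(make_echo(numeric(0), hp), "empty")
  expect_error(make_echo(numeric(10), hp), "empty")
  # two-path IR: echo spectrum = call spectrum x IR transfer function
  ir <- numeric(200)
  ir[1] <- 0.8
  ir[30] <- 0.4
  e3 <- make_echo(ir, hp, length_out = 1024)
  ps_e <- power_spectrum(e3, cfg$sample_rate)
  ps_c <- power_spectrum(c(as.numeric(hp), numeric(1024 - length(hp))),
                         cfg$sample_rate)
  sel <- ps_e$frequency >= 45e3 & ps_e$frequency <= 155e3
  H2 <- Mod(0.8 + 0.4 * exp(-2i * pi * ps_e$frequency[sel] * 29 /
            cfg$sample_rate))^2
  expect_equal(power_to_db(ps_e$power[sel]) - power_to_db(ps_c$power[sel]),
               power_to_db(H2), tolerance = 0.2)
})

test_that("spectrogram: frame count, tone row, silence, normalisation", {
  for (N in c(768, 1024, 1280)) {
    sp <- echo_spectrogram(rnorm(N))
    expect_equal(ncol(sp), (N - 256) %/% 26 + 1)
    expect_equal(nrow(sp), 129)
    expect_gte(min(sp), 0)
    expect_lte(max(sp), 1)
  }
  tone <- sin(2 * pi * 68e3 * (0:1023) / 5e5)
  sp <- echo_spectrogram(tone)
  rows <- apply(sp, 1, mean)
  expect_equal(which.max(rows), round(68e3 / (5e5 / 256)) + 1,
               tolerance = 1)
  expect_true(all(echo_spectrogram(numeric(600)) == 0))
  expect_error(echo_spectrogram(rnorm(100)), "shorter")
})

test_that("random chunking: counts, determinism, label consistency", {
  entry <- fix_chunk_entry()
  ch10 <- chunk_random(entry, 10, seed = 1)
  expect_equal(length(ch10), 20)  # floor(202 / 10)
  ch1 <- chunk_random(entry, 1, seed = 1)
  expect_equal(length(ch1), 202)
  expect_identical(chunk_random(entry, 10, seed = 1),
                   chunk_random(entry, 10, seed = 1))
  # every chunk from the same flower, no echo reused within a chunking
  used <- do.call(rbind, lapply(ch10, `[[`, "rows"))
  expect_equal(nrow(unique(used)), 200)
  expect_true(all(vapply(ch10, `[[`, character(1), "flower_id") == "F_01"))
})

test_that("interval chunking: arithmetic progressions within one plane", {
  entry <- fix_chunk_entry()
  ch <- chunk_interval(entry, 10, seed = 2)
  expect_equal(length(ch), 20)  # matched to the random scheme's count
  for (c1 in ch) {
    expect_equal(length(unique(c1$rows$plane)), 1)
    d <- diff(c1$rows$angle_idx)
    expect_equal(length(unique(d)), 1)
    expect_true(d[1] %in% 2:8)
    expect_true(all(c1$rows$angle_idx >= 1 & c1$rows$angle_idx <= 101))
  }
  expect_error(chunk_interval(fix_chunk_entry(n_angles = 15), 10, seed = 1),
               "cannot fit")
  # interval chunks are less angularly diverse than random chunks
  chr <- chunk_random(entry, 10, seed = 3)
  expect_lt(chunk_angle_spread(ch, entry$angles),
            chunk_angle_spread(chr, entry$angles))
})

test_that("flower-level split: counts, disjointness, coverage", {
  fl <- fix_flowers(n_per_species = 14)
  sp <- split_by_flower(fl, seed = 4)
  expect_equal(length(sp$train), 8 * 12)
  expect_equal(length(sp$validation), 2 * 12)
  expect_equal(length(sp$test), 2 * 12)
  all_ids <- c(sp$train, sp$validation, sp$test)
  expect_equal(anyDuplicated(all_ids), 0)   # no flower-ID leakage
  for (part in sp) {
    species <- fl$species[match(part, fl$flower_id)]
    expect_equal(length(unique(species)), 12)
  }
  expect_error(split_by_flower(fix_flowers(n_per_species = 5), seed = 1),
               "need")
})

test_that("network: probabilities, shared-branch parameters, chance level", {
  spec1 <- echonet_spec(k = 1, input_shape = c(40, 20), n_classes = 12,
                        dense = c(64, 32))
  spec10 <- echonet_spec(k = 10, input_shape = c(40, 20), n_classes = 12,
                         dense = c(64, 32))
  p1 <- build_echonet(spec1, seed = 5)
  p10 <- build_echonet(spec10, seed = 5)
  # branch parameter count independent of k (weights shared across inputs)
  expect_equal(dim(p1$w1), dim(p10$w1))
  expect_equal(length(p1$b1), length(p10$b1))
  x <- array(runif(40 * 20 * 1 * 7), dim = c(40, 20, 1, 7))
  probs <- floralecho:::.echonet_forward(p1, spec1, x)$probs
  expect_equal(colSums(probs), rep(1, 7), tolerance = 1e-12)
  expect_true(all(probs > 0))
  # untrained network on balanced inputs scores at chance level
  set.seed(6)
  xb <- array(runif(40 * 20 * 1 * 240), dim = c(40, 20, 1, 240))
  yb <- rep(1:12, 20)
  pb <- floralecho:::.echonet_forward(p1, spec1, xb)$probs
  acc <- mean(max.col(t(pb)) == yb)
  expect_lt(abs(acc - 1 / 12), 0.12)
})

test_that("training learns a separable toy problem deterministically", {
  cfg <- fix_small_cfg(n_angles = 11, ir_length = 1536)
  cat2 <- make_catalog(seed = 1)
  cat2 <- cat2[cat2$code %in% c("Cj", "Ws"), ]
  fl <- sample_flowers(cat2, 6, seed = 3)
  scans <- scan_set(fl, cfg = cfg, seed = 4)
  split <- split_by_flower(fl, counts = c(4, 1, 1), seed = 5)
  call <- synthesize_call(cfg)
  fit <- train_echonet(scans, split, call, k = 1, epochs = 5, patience = 5,
                       echo_length = 768, seed = 7)
  h <- fit$history
  # loss decreases over the first epochs on learnable data
  expect_lt(h$train_loss[5], h$train_loss[1])
  # determinism: same seed reproduces the epoch-1 loss exactly
  fit2 <- train_echonet(scans, split, call, k = 1, epochs = 1, patience = 5,
                        echo_length = 768, seed = 7)
  expect_equal(fit2$history$train_loss[1], h$train_loss[1],
               tolerance = 1e-12)
  # evaluation plumbing: confusion matrix rows sum to per-class counts
  ev <- evaluate_echonet(fit, scans, split$test, call, seed = 8)
  expect_equal(sum(ev$confusion), ev$n_chunks)
  expect_equal(nrow(ev$per_syndrome), 2)
  expect_true(all(ev$per_syndrome$ci_low <= ev$per_syndrome$accuracy))
  expect_true(all(ev$per_syndrome$ci_high >= ev$per_syndrome$accuracy))
})

test_that("Clopper-Pearson interval matches beta quantiles and binom.test", {
  ci <- clopper_pearson(73, 100)
  bt <- binom.test(73, 100)$conf.int
  expect_equal(ci, as.numeric(bt), tolerance = 1e-10)
  expect_equal(ci[1], qbeta(0.025, 73, 28), tolerance = 1e-12)
  expect_equal(ci[2], qbeta(0.975, 74, 27), tolerance = 1e-12)
  expect_equal(clopper_pearson(0, 10)[1], 0)
  expect_equal(clopper_pearson(10, 10)[2], 1)
  # width shrinks roughly as 1/sqrt(n)
  w1 <- diff(clopper_pearson(73, 100))
  w4 <- diff(clopper_pearson(292, 400))
  expect_equal(w4 / w1, 0.5, tolerance = 0.1)
})
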