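test_that("fractal generator hits the white-noise and Brownian limits", {
  # white-noise limit, against the known exponent 0.5
  expect_lt(abs(mean_recovered_alpha(0.5, 2^13, 1:10) - 0.5), 0.05)
  # Brownian limit, against a brute-force oracle: cumulative sum of iid noise
  brownian <- vapply(1:10, function(s) {
    set.seed(s); dfa(cumsum(rnorm(2^13)))$alpha
  }, numeric(1))
  expect_lt(abs(mean(brownian) - 1.5), 0.07)
  expect_lt(abs(mean_recovered_alpha(1.5, 2^13, 1:10) - 1.5), 0.07)
})

test_that("fractal generator round-trips intermediate exponents through dfa", {
  for (a in c(0.6, 1.0, 1.2, 1.4)) {
    expect_lt(abs(mean_recovered_alpha(a, 2^13, 1:20) - a), 0.08)
  }
})

test_that("fractal series are zero-mean, unit-SD, reproducible, and validated", {
  x <- generate_fractal_series(1024, 1.2, seed = 4)
  expect_length(x, 1024)
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(sd(x), 1, tolerance = 1e-12)
  expect_identical(x, generate_fractal_series(1024, 1.2, seed = 4))
  expect_error(generate_fractal_series(100, 1.2, seed = 1), "256")
  expect_error(generate_fractal_series(1024, 1.9, seed = 1), "alpha")
})

test_that("session design satisfies the block and stimulus constraints", {
  for (s in 1:25) {
    d <- session_design(seed = s)
    expect_identical(nrow(d), 30L)
    expect_true(all(table(d$condition) == 10))
    expect_true(all(table(d$stimulus) == 15))
    # no-task trials split 4 / 2 / 4 around the two task blocks
    none_blocks <- table(d$block[d$condition == "None"])
    expect_identical(as.integer(none_blocks[c("baseline_start", "baseline_mid",
                                              "baseline_end")]), c(4L, 2L, 4L))
    # task blocks are contiguous
    for (cc in c("Easy", "Hard")) {
      idx <- which(d$condition == cc)
      expect_identical(idx, idx[1]:(idx[1] + 9L))
    }
  }
})

test_that("config validation rejects impossible cell targets", {
  expect_error(sway_model_config(rs_effects = c(intercept = 1, noise = -2,
                                                easy = 0, hard = 0,
                                                easy_noise = 0, hard_noise = 0)),
               "non.positive|not positive")
  expect_error(sway_model_config(alpha_effects = c(intercept = 1.6, noise = 0,
                                                   easy = 0, hard = 0,
                                                   easy_noise = 0, hard_noise = 0)),
               "anti-persistent")
  expect_error(sway_model_config(trials_per_condition = 0), "at least 1")
})

test_that("single trials are calibrated exactly to the target mean radial sway", {
  cfg <- sway_model_config(trial_duration = 30)
  for (s in 1:5) {
    tr <- generate_cop_trial(cfg, 0, "None", "Silent", seed = s)
    expect_equal(radial_sway(tr)$mean_rs, 5.726, tolerance = 1e-9)
    trn <- generate_cop_trial(cfg, 0, "None", "Noise", seed = s)
    expect_equal(radial_sway(trn)$mean_rs, 5.726 - 1.273, tolerance = 1e-9)
  }
  # offsets shift the target additively
  tro <- generate_cop_trial(cfg, 0.5, "None", "Silent", seed = 1, trial_offset = 0.25)
  expect_equal(radial_sway(tro)$mean_rs, 6.476, tolerance = 1e-9)
})

test_that("doubling the configured amplitude doubles RS and leaves alpha unchanged", {
  cfg <- sway_model_config(trial_duration = 30)
  cfg2 <- cfg
  cfg2$rs_effects <- cfg$rs_effects * 2
  t1 <- generate_cop_trial(cfg, 0, "Easy", "Noise", seed = 8)
  t2 <- generate_cop_trial(cfg2, 0, "Easy", "Noise", seed = 8)
  expect_equal(t2$x, 2 * t1$x, tolerance = 1e-12)
  expect_equal(radial_sway(t2)$mean_rs, 2 * radial_sway(t1)$mean_rs,
               tolerance = 1e-12)
  a1 <- dfa(radial_sway(t1)$rs)$alpha
  a2 <- dfa(radial_sway(t2)$rs)$alpha
  expect_lt(abs(a1 - a2), 1e-9)
})

test_that("cohort generation honours the design arithmetic and the seed contract", {
  cfg <- sway_model_config(n_subjects = 3, trials_per_condition = 2,
                           trial_duration = 10, seed = 21)
  co <- generate_cohort(cfg)
  expect_length(co$trials, 3 * 6)
  expect_identical(nrow(co$design), 18L)
  co2 <- generate_cohort(cfg)
  expect_identical(co$trials, co2$trials)
  expect_identical(co$design, co2$design)
  # a trial regenerates in isolation from its design-table seed and offsets
  row <- co$design[7, ]
  s <- match(row$subject, co$subjects$subject)
  rebuilt <- generate_cop_trial(
    cfg, co$subjects$rs_offset[s],
    as.character(row$condition), as.character(row$stimulus), seed = row$seed,
    trial_offset = row$trial_rs_offset,
    alpha_offset = co$subjects$alpha_offset[s] + row$trial_alpha_offset)
  expect_identical(co$trials[[7]]$x, rebuilt$x)
  expect_identical(co$trials[[7]]$y, rebuilt$y)
})

test_that("zero variance components give identical cell targets for every subject", {
  cfg <- sway_model_config(n_subjects = 3, trials_per_condition = 2,
                           trial_duration = 10, subject_sd = 0, trial_sd = 0,
                           alpha_subject_sd = 0, alpha_trial_sd = 0, seed = 2)
  co <- generate_cohort(cfg)
  expect_true(all(co$subjects$rs_offset == 0))
  m <- vapply(co$trials, function(t) radial_sway(t)$mean_rs, numeric(1))
  tg <- cell_targets(cfg)
  for (i in seq_along(co$trials)) {
    cell <- tg[tg$condition == co$design$condition[i] &
                 tg$stimulus == co$design$stimulus[i], ]
    expect_equal(unname(m[i]), cell$rs_mean, tolerance = 1e-9)
  }
})

test_that("cell-mean calibration holds within 3% over 50 seeds in every cell", {
  cfg <- sway_model_config(trial_duration = 30, seed = 1)
  tg <- cell_targets(cfg)
  for (i in seq_len(nrow(tg))) {
    means <- vapply(1:50, function(s) {
      radial_sway(generate_cop_trial(cfg, 0, as.character(tg$condition[i]),
                                     as.character(tg$stimulus[i]),
                                     seed = 1000 + s))$mean_rs
    }, numeric(1))
    expect_lt(abs(mean(means) - tg$rs_mean[i]) / tg$rs_mean[i], 0.03)
  }
})

test_that("white-noise audio is flat across octave bands and reproducible", {
  a <- generate_white_noise_audio(2, 44100, seed = 6)
  expect_length(a$samples, 88200)
  expect_identical(a$samples, generate_white_noise_audio(2, 44100, seed = 6)$samples)
  # Welch-style averaged periodogram, octave bands 100 Hz .. Nyquist/2
  x <- a$samples
  nseg <- 32L; L <- length(x) %/% nseg
  psd <- rowMeans(vapply(seq_len(nseg), function(k) {
    seg <- x[((k - 1) * L + 1):(k * L)]
    Mod(fft(seg))[1:(L %/% 2)]^2
  }, numeric(L %/% 2)))
  freq <- (seq_len(L %/% 2) - 1) / L * 44100
  edges <- 100 * 2^(0:8)
  edges <- edges[edges <= 44100 / 4]
  band_power <- vapply(seq_len(length(edges) - 1), function(b) {
    mean(psd[freq >= edges[b] & freq < edges[b + 1]])
  }, numeric(1))
  ratio_db <- 10 * log10(max(band_power) / min(band_power))
  expect_lt(ratio_db, 3)
})

test_that("WAV export writes a well-formed 16-bit PCM mono header", {
  a <- generate_white_noise_audio(0.1, 8000, seed = 2)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(a, path)
  con <- file(path, "rb")
  on.exit(close(con))
  expect_identical(readChar(con, 4), "RIFF")
  invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
  expect_identical(readChar(con, 8), "WAVEfmt ")
  invisible(readBin(con, integer(), 2, size = 4, endian = "little"))  # fmtsize+fmt/channels
  rate <- readBin(con, integer(), 1, size = 4, endian = "little")
  expect_identical(rate, 8000L)
  expect_identical(file.info(path)$size, 44 + 2 * 800)
})

test_that("configs round-trip through YAML", {
  cfg <- sway_model_config(n_subjects = 5, seed = 99, trial_sd = 1.1)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sway_config(cfg, path)
  back <- read_sway_config(path)
  expect_equal(back$rs_effects, cfg$rs_effects)
  expect_equal(back$alpha_effects, cfg$alpha_effects)
  expect_identical(back$n_subjects, 5L)
  expect_equal(back$trial_sd, 1.1)
})
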