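test_that("band-pass filter passes in-band tones and rejects out-of-band", {
  fs <- 512
  t <- seq_len(fs * 10) / fs
  tone <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1), "A", fs)
  core <- (fs + 1):(fs * 9)  # discard 1 s edges
  inband <- bandpass_filter(tone, "alpha_low")
  gain_in <- sd(inband$data[1, core]) / sd(tone$data[1, core])
  expect_gt(gain_in, 0.9)
  expect_lte(gain_in, 1.0)
  outband <- bandpass_filter(tone, "delta")
  expect_lt(sd(outband$data[1, core]) / sd(tone$data[1, core]), 0.1)
  # zero-phase: the peak of an in-band burst is not shifted
  burst <- numeric(fs * 4)
  burst[fs * 2 + seq_len(fs)] <- sin(2 * pi * 9 * seq_len(fs) / fs) *
    exp(-((seq_len(fs) - fs / 2) / 80)^2)
  rec_b <- eeg_recording(matrix(burst, 1), "A", fs)
  filt_b <- bandpass_filter(rec_b, "alpha_low")
  env_raw <- which.max(abs(burst))
  env_filt <- which.max(abs(filt_b$data[1, ]))
  expect_lte(abs(env_raw - env_filt), 1)
  # above-Nyquist band is rejected
  lowfs <- eeg_recording(matrix(rnorm(100), 1), "A", 40)
  expect_error(bandpass_filter(lowfs, "gamma"), "Nyquist")
})

test_that("noiseless full-column-rank estimation recovers the truth exactly", {
  L <- fx_leadfield()
  ori <- fx_orientations()
  set.seed(9)
  # oriented seeding: 28 columns, full column rank
  truth <- matrix(rnorm(28 * 200), 28)
  Leff <- vapply(seq_len(28), function(s) {
    as.vector(L$matrix[, 3 * (s - 1) + 1:3] %*% ori[s, ])
  }, numeric(64))
  d <- Leff %*% truth
  swf <- estimate_source_waveforms(d, L, lambda = 0, orientations = ori)
  expect_lt(max(abs(swf$magnitude[1, , ] - abs(truth))) / max(abs(truth)), 1e-6)
  expect_lt(swf$residual_variance, 1e-10)
  # free 3-component sources with a reduced model (full column rank)
  sub <- L$matrix[, 1:15]  # 5 regional sources
  s_true <- matrix(rnorm(15 * 100), 15)
  d2 <- sub %*% s_true
  swf2 <- estimate_source_waveforms(d2, sub, lambda = 0)
  expect_lt(max(abs(swf2$components[1, , ] - s_true)) / max(abs(s_true)), 1e-6)
})

test_that("ridge solution matches an independent normal-equations solver", {
  L <- fx_leadfield()
  set.seed(10)
  d <- matrix(rnorm(64 * 50), 64)
  swf <- estimate_source_waveforms(d, L)
  lam <- swf$lambda
  # brute-force oracle: solve the stacked normal equations directly
  A <- rbind(L$matrix, diag(sqrt(lam), 84))
  b <- rbind(d, matrix(0, 84, 50))
  s_ref <- qr.solve(A, b)
  expect_lt(max(abs(swf$components[1, , ] - s_ref)), 1e-8)
  rv <- swf$residual_variance
  expect_gt(rv, 0)
  expect_lt(rv, 100)
  # zero data: flagged, residual variance 0
  swf0 <- estimate_source_waveforms(matrix(0, 64, 10), L)
  expect_equal(swf0$residual_variance, 0)
  expect_true(swf0$zero_data)
  # rank-deficient lead field without regularization is refused
  expect_error(estimate_source_waveforms(d, L, lambda = 0), "rank deficient")
})

test_that("estimation is linear in the data", {
  L <- fx_leadfield()
  set.seed(12)
  d1 <- matrix(rnorm(64 * 30), 64)
  d2 <- matrix(rnorm(64 * 30), 64)
  lam <- 0.01
  s1 <- estimate_source_waveforms(d1, L, lambda = lam)$components[1, , ]
  s2 <- estimate_source_waveforms(d2, L, lambda = lam)$components[1, , ]
  s12 <- estimate_source_waveforms(d1 + d2, L, lambda = lam)$components[1, , ]
  expect_equal(s12, s1 + s2, tolerance = 1e-10)
})

test_that("residual variance reflects constructed decompositions", {
  L <- fx_leadfield()
  set.seed(13)
  s <- matrix(rnorm(84 * 40), 84)
  fit <- L$matrix %*% s
  expect_equal(residual_variance(fit, L, s), 0, tolerance = 1e-20)
  expect_equal(residual_variance(fit, L, 0 * s), 100)
  # orthogonal residual of equal energy -> 50%
  r0 <- matrix(rnorm(64 * 40), 64)
  sv <- svd(L$matrix)
  U <- sv$u[, sv$d > 1e-8 * sv$d[1], drop = FALSE]
  r_orth <- r0 - U %*% (t(U) %*% r0)
  r_orth <- r_orth * sqrt(sum(fit^2) / sum(r_orth^2))
  expect_equal(residual_variance(fit + r_orth, L, s), 50, tolerance = 0.1)
  z <- residual_variance(matrix(0, 64, 4), L, matrix(0, 84, 4))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "zero_data"))
})

test_that("2-SD rejection flags spiking epochs and only those", {
  # 21 calm epochs (bounded smooth oscillation around 5), 3 sources; one
  # epoch carries a 10x spike on one source
  phase <- array(rep(seq_len(64), each = 21 * 3), dim = c(21, 3, 64))
  mag <- 5 + 0.5 * sin(2 * pi * phase / 64)
  mag[7, 2, 30] <- 10 * mean(mag[, 2, ])
  swf <- structure(list(magnitude = mag, components = array(0, c(21, 9, 64)),
                        residual_variance = numeric(21),
                        zero_data = logical(21), source_short = NULL,
                        band = "theta", fs = 64), class = "swf_set")
  out <- reject_epochs_sd(swf, k = 2)
  rej <- attr(out, "rejected")
  expect_true(rej[7])
  expect_equal(sum(rej), 1)
  expect_equal(dim(out$magnitude)[1], 20)
  # identical constant epochs: SD = 0, strict inequality keeps everything
  magc <- array(3, dim = c(4, 2, 8))
  swfc <- structure(list(magnitude = magc, components = array(0, c(4, 6, 8)),
                         residual_variance = numeric(4), zero_data = logical(4),
                         source_short = NULL, band = NULL, fs = 8),
                    class = "swf_set")
  outc <- reject_epochs_sd(swfc, k = 2)
  expect_false(any(attr(outc, "rejected")))
  # k = Inf never rejects
  expect_false(any(attr(reject_epochs_sd(swf, k = Inf), "rejected")))
  # rejection is invariant under epoch permutation
  perm <- sample(21)
  swfp <- swf
  swfp$magnitude <- mag[perm, , , drop = FALSE]
  expect_equal(attr(reject_epochs_sd(swfp, 2), "rejected"), rej[perm])
})

test_that("mean moments equal the flat mean over surviving samples", {
  mag <- array(0, dim = c(2, 2, 4))
  mag[1, , ] <- 1
  mag[2, , ] <- 3
  swf <- structure(list(magnitude = mag, components = array(0, c(2, 6, 4)),
                        residual_variance = numeric(2), zero_data = logical(2),
                        source_short = c("A", "B"), band = NULL, fs = 4),
                   class = "swf_set")
  expect_equal(mean_rs_moments(swf), c(A = 2, B = 2))
  # oracle identity: flat recomputation over concatenated samples
  set.seed(15)
  mag2 <- array(abs(rnorm(3 * 2 * 5)), dim = c(3, 2, 5))
  swf$magnitude <- mag2
  swf$source_short <- NULL
  flat <- apply(mag2, 2, function(x) mean(as.vector(x)))
  expect_equal(mean_rs_moments(swf), flat)
})
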