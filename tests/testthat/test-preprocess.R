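test_that("average re-referencing zeroes the channel mean and is idempotent", {
  set.seed(4)
  rec <- eeg_recording(matrix(rnorm(64 * 1000), 64),
                       standard_montage(bremen_channels())$labels, 512)
  avg <- rereference_average(rec)
  expect_lt(max(abs(colMeans(avg$data))), 1e-12 * max(abs(rec$data)))
  # idempotence
  expect_equal(rereference_average(avg)$data, avg$data, tolerance = 1e-14)
  # common-mode rejection: adding a constant to all channels changes nothing
  shifted <- eeg_recording(rec$data + 42, rec$labels, rec$fs)
  expect_equal(rereference_average(shifted)$data, avg$data, tolerance = 1e-10)
  expect_error(rereference_average(eeg_recording(matrix(0, 1, 5), "A", 512)),
               "at least 2")
})

test_that("spherical-spline interpolation reproduces constants and smooth maps", {
  mont <- fx_montage()
  n <- length(mont$labels)
  # constant across channels stays constant
  rec_const <- eeg_recording(matrix(5, n, 10), mont$labels, 512)
  out <- interpolate_channels(rec_const, "Cz", mont)
  expect_equal(out$data[match("Cz", mont$labels), ], rep(5, 10),
               tolerance = 1e-6)
  # empty bad list is the identity
  expect_identical(interpolate_channels(rec_const, character(0), mont),
                   rec_const)
  # hold-out on lead-field topographies: smooth maps are recovered;
  # correlation across several held-out (channel, topography) pairs
  L <- fx_leadfield()$matrix
  held <- c("CP1", "Fz", "C3", "PO3", "P2", "FC4")
  for (col in c(20, 40)) {
    topo <- L[, col]
    est <- vapply(held, function(ch) {
      i <- match(ch, mont$labels)
      spoiled <- eeg_recording(matrix(topo, n, 1), mont$labels, 512)
      spoiled$data[i, ] <- 0
      interpolate_channels(spoiled, ch, mont)$data[i, 1]
    }, numeric(1))
    expect_gt(cor(est, topo[match(held, mont$labels)]), 0.95)
  }
  # warning above five channels, error when everything is bad
  rec <- eeg_recording(matrix(rnorm(n * 4), n), mont$labels, 512)
  expect_warning(interpolate_channels(rec, mont$labels[1:6], mont),
                 "more than five")
  expect_error(suppressWarnings(interpolate_channels(rec, mont$labels, mont)))
})

test_that("blink template averaging recovers injected time courses", {
  mont <- fx_montage()
  n <- length(mont$labels)
  fs <- 512
  topo <- exp(-seq_len(n) / 15)
  pulse <- 50 * sin(pi * seq_len(154) / 154)^2
  data <- matrix(0, n, fs * 30)
  events <- seq(300, fs * 30 - 300, length.out = 30) |> round()
  for (e in events) {
    data[, e:(e + 153)] <- data[, e:(e + 153)] + outer(topo, pulse)
  }
  rec <- eeg_recording(data, mont$labels, fs)
  tpl <- build_blink_template(rec, events + 77, window_ms = 400)
  expect_equal(tpl$n_averaged, 30)
  expect_equal(sqrt(sum(tpl$topography^2)), 1, tolerance = 1e-12)
  expect_gt(abs(cor(tpl$topography, topo)), 0.999)
  # injected pulse is recovered in the averaged time course
  peak_region <- which(tpl$time_course > 0.5 * max(tpl$time_course))
  expect_gt(length(peak_region), 40)
  # single event: template equals that window's first principal direction
  one <- build_blink_template(rec, events[1] + 77, window_ms = 400)
  expect_equal(one$n_averaged, 1)
  expect_error(build_blink_template(rec, integer(0)), "at least one")
})

test_that("template amplitude in pure noise shrinks like 1/sqrt(n)", {
  mont <- fx_montage()
  set.seed(11)
  rec <- eeg_recording(matrix(rnorm(64 * 30 * 512), 64), mont$labels, 512)
  amp <- function(nev, seed) {
    set.seed(seed)
    ev <- sample(300:(30 * 512 - 300), nev)
    sqrt(mean(build_blink_template(rec, ev, 400)$time_course^2))
  }
  a10 <- mean(vapply(1:4, function(s) amp(10, s), numeric(1)))
  a40 <- mean(vapply(5:8, function(s) amp(40, s), numeric(1)))
  expect_gt(a10 / a40, 2 * 0.7)
  expect_lt(a10 / a40, 2 * 1.3)
})

test_that("PCA blink correction removes injected blinks from frontal channels", {
  mont <- fx_montage()
  L <- fx_leadfield()
  ori <- fx_orientations()
  truth <- simulate_source_activity(fx_model(), "alpha_low", NULL, age = 24,
                                    n_epochs = 60, seed = 7)
  clean <- project_to_scalp(truth, L, mont, ori, sensor_noise_sd = 0,
                            blink_rate = 0, seed = 8)
  dirty <- project_to_scalp(truth, L, mont, ori, sensor_noise_sd = 0,
                            blink_rate = 30, seed = 8)
  ev <- attr(dirty, "blink_samples")
  tpl <- build_blink_template(dirty, ev, window_ms = 400)
  # rich synthetic brain activity needs a permissive variance cutoff for
  # the brain subspace (28 sources spread over many small components)
  corr <- correct_blinks_pca(dirty, tpl, var_threshold = 0.001)
  fidx <- match(c("FP1", "FP2"), mont$labels)
  err_before <- sqrt(mean((dirty$data[fidx, ] - clean$data[fidx, ])^2))
  err_after <- sqrt(mean((corr$data[fidx, ] - clean$data[fidx, ])^2))
  expect_lt(err_after, 0.2 * err_before)
  expect_gt(attr(corr, "n_artifact_windows"), 0)
  # dimensions never change
  expect_equal(dim(corr$data), dim(dirty$data))
})

test_that("correction leaves data untouched when nothing crosses thresholds", {
  mont <- fx_montage()
  set.seed(3)
  rec <- eeg_recording(matrix(rnorm(64 * 2048, 0, 5), 64), mont$labels, 512)
  # a non-constant template, thresholds no window can cross
  tpl <- structure(list(topography = rep(c(1, -1) / 8, 32),
                        time_course = numeric(10),
                        labels = mont$labels, n_averaged = 1),
                   class = "blink_template")
  out <- correct_blinks_pca(rec, tpl, corr_threshold = 0.999,
                            amp_threshold = 1e6)
  expect_equal(out$data, rec$data, tolerance = 1e-10)
  expect_equal(attr(out, "n_artifact_windows"), 0L)
})

test_that("event files parse with comments and reject junk", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("100", "300  # second blink", "", "200"), f)
  expect_equal(read_event_file(f), c(100L, 200L, 300L))
  writeLines(c("12", "abc"), f)
  expect_error(read_event_file(f), "non-integer")
  file.remove(f)
  expect_error(read_event_file(f), "not found")
})

test_that("epoch segmentation follows the count formula", {
  rec <- sine_recording(n_channels = 2, seconds = 30)
  ep <- segment_epochs(rec, 1, 0)
  expect_equal(dim(ep$data), c(30, 2, 512))
  ep2 <- segment_epochs(rec, 2, 0.5)
  expect_equal(dim(ep2$data)[1], 29)
  short <- sine_recording(n_channels = 2, seconds = 1)
  short$data <- short$data[, 1:256]
  expect_warning(ep3 <- segment_epochs(short, 1), "shorter")
  expect_equal(dim(ep3$data)[1], 0)
})
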