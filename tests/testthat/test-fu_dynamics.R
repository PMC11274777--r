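test_that("the per-band bin-rate table is honored verbatim", {
  rates <- c(delta = 8.0, theta = 16, alpha_low = 22.0, alpha_high = 26.0,
             beta_low = 43, beta_high = 60, gamma = 70)
  for (b in names(rates)) expect_equal(downsample_rate(b), unname(rates[b]))
  # custom bands fall back to twice the upper edge
  expect_equal(downsample_rate(data.frame(name = "custom", low = 0, high = 17)),
               34)
  expect_error(downsample_rate(data.frame(name = "custom")), "upper edge")
})

test_that("bin summation partitions epochs by equal time edges", {
  mag <- array(1, dim = c(2, 3, 512))
  swf <- structure(list(magnitude = mag, fs = 512, band = "delta",
                        source_short = c("A", "B", "C")), class = "swf_set")
  b8 <- bin_and_sum(swf, 8)
  expect_equal(dim(b8$values), c(2, 3, 8))
  expect_equal(unique(as.vector(b8$values)), 64)  # 512/8 samples per bin
  b43 <- bin_and_sum(swf, 43)
  counts <- b43$values[1, 1, ]
  expect_true(all(counts %in% c(11, 12)))
  expect_equal(sum(counts), 512)
  # constant magnitude c with integer samples per bin gives c * m
  swf$magnitude <- array(2.5, dim = c(1, 3, 512))
  expect_equal(unique(as.vector(bin_and_sum(swf, 16)$values)), 2.5 * 32)
  expect_error(bin_and_sum(swf, 1000), "exceeds")
})

test_that("epoch-max normalization scales every source to peak 100", {
  v <- array(0, dim = c(1, 2, 3))
  v[1, 1, ] <- c(2, 4, 8)
  v[1, 2, ] <- c(1, 5, 2)
  binned <- structure(list(values = v, rate = 3, source_short = NULL,
                           normalized = FALSE), class = "binned_activity")
  normed <- normalize_epoch_max(binned)
  expect_equal(normed$values[1, 1, ], c(25, 50, 100))
  expect_equal(max(normed$values[1, 2, ]), 100)
  # per-source scale invariance
  v2 <- v
  v2[1, 1, ] <- v[1, 1, ] * 17
  v2[1, 2, ] <- v[1, 2, ] * 0.3
  binned2 <- binned; binned2$values <- v2
  expect_equal(normalize_epoch_max(binned2)$values, normed$values)
  # an all-zero source flags the epoch degenerate
  v3 <- array(1, dim = c(2, 2, 3)); v3[2, 1, ] <- 0
  binned3 <- binned; binned3$values <- v3
  out <- normalize_epoch_max(binned3)
  expect_equal(attr(out, "degenerate"), c(FALSE, TRUE))
  expect_equal(dim(out$values)[1], 1)
})

test_that("share binarization uses a strict threshold", {
  mk <- function(vals) {
    v <- array(0, dim = c(1, length(vals), 1))
    v[1, , 1] <- vals
    structure(list(values = v, rate = 1, source_short = NULL,
                   normalized = TRUE), class = "binned_activity")
  }
  # equality is not 'more than': all-equal bins are entirely inactive
  expect_equal(as.vector(binarize_share(mk(rep(4, 28)))$values), rep(0L, 28))
  # a single dominant source
  one <- c(100, rep(0, 27))
  expect_equal(as.vector(binarize_share(mk(one))$values), c(1L, rep(0L, 27)))
  # 3-source toy: only the first exceeds a third of the sum
  expect_equal(as.vector(binarize_share(mk(c(50, 30, 20)))$values),
               c(1L, 0L, 0L))
  expect_error(binarize_share(mk(c(1, 2)), n = 5), "must equal")
})

test_that("follow-up counting matches hand enumeration and the brute force", {
  # worked 2-source example: A = [1,1,0], B = [0,1,1]
  v <- array(0L, dim = c(1, 2, 3))
  v[1, 1, ] <- c(1L, 1L, 0L)
  v[1, 2, ] <- c(0L, 1L, 1L)
  bin <- structure(list(values = v, source_short = c("A", "B")),
                   class = "binary_activity")
  fu <- count_followups(bin)
  expect_equal(unclass(fu), matrix(c(1, 0, 2, 1), 2,
                                   dimnames = list(c("A", "B"), c("A", "B"))),
               ignore_attr = TRUE)
  # all-zero and single-source cases
  v0 <- array(0L, dim = c(2, 3, 5))
  bin0 <- structure(list(values = v0, source_short = NULL),
                    class = "binary_activity")
  expect_equal(max(count_followups(bin0)), 0)
  v1 <- array(0L, dim = c(1, 3, 6)); v1[1, 2, ] <- 1L
  bin1 <- structure(list(values = v1, source_short = NULL),
                    class = "binary_activity")
  fu1 <- count_followups(bin1)
  expect_equal(fu1[2, 2], 5)
  expect_equal(sum(fu1), 5)
  # random matrices against the nested-loop oracle
  set.seed(31)
  for (rep in 1:50) {
    ne <- sample(1:3, 1); ns <- sample(2:5, 1); nb <- sample(2:10, 1)
    arr <- array(rbinom(ne * ns * nb, 1, 0.4), dim = c(ne, ns, nb))
    binr <- structure(list(values = arr, source_short = NULL),
                      class = "binary_activity")
    expect_equal(unclass(count_followups(binr)), fu_bruteforce(arr),
                 ignore_attr = TRUE)
  }
  expect_error(count_followups(structure(list(values = array(1L, c(1, 2, 1)),
                                              source_short = NULL),
                                         class = "binary_activity")),
               "at least 2 bins")
})

test_that("FU totals match the active-count identity and scale invariance", {
  set.seed(32)
  mag <- array(abs(rnorm(4 * 5 * 64, 2)), dim = c(4, 5, 64))
  swf <- structure(list(magnitude = mag, fs = 64, band = NULL,
                        source_short = letters[1:5]), class = "swf_set")
  binned <- bin_and_sum(swf, 16)
  normed <- normalize_epoch_max(binned)
  bin <- binarize_share(normed)
  fu <- count_followups(bin)
  # FU total per epoch = sum_t (#active at t) * (#active at t+1)
  v <- bin$values
  tot <- 0
  for (e in 1:4) {
    act <- colSums(v[e, , ])
    tot <- tot + sum(act[-length(act)] * act[-1])
  }
  expect_equal(sum(unclass(fu)) * 4, tot)
  # multiplying one source's raw magnitudes by a constant changes nothing
  mag2 <- mag; mag2[, 3, ] <- mag[, 3, ] * 123.4
  swf2 <- swf; swf2$magnitude <- mag2
  fu2 <- count_followups(binarize_share(normalize_epoch_max(
    bin_and_sum(swf2, 16))))
  expect_equal(unclass(fu2), unclass(fu))
})

test_that("a lagged copy drives the follow-up asymmetry in the right direction", {
  band <- get_band("alpha_low")
  fs <- 512; nt <- fs; ne <- 20; lag <- 23  # about one alpha-low bin
  wins <- 0L
  n_seeds <- 20
  for (seed in seq_len(n_seeds)) {
    set.seed(seed)
    a <- bl_noise(ne * nt + lag, band, fs)
    mags <- array(0, c(ne, 4, nt))
    for (e in seq_len(ne)) {
      idx <- lag + ((e - 1) * nt + 1):(e * nt)
      mags[e, 1, ] <- abs(a[idx])        # leader
      mags[e, 2, ] <- abs(a[idx - lag])  # follower: delayed copy of A
      mags[e, 3, ] <- abs(bl_noise(nt, band, fs))
      mags[e, 4, ] <- abs(bl_noise(nt, band, fs))
    }
    swf <- structure(list(magnitude = mags, fs = fs, band = "alpha_low",
                          source_short = c("A", "B", "C", "D")),
                     class = "swf_set")
    fu <- fu_matrix(swf)
    if (fu["A", "B"] > fu["B", "A"]) wins <- wins + 1L
  }
  expect_gte(wins, 0.9 * n_seeds)
})

test_that("a perfect lagged copy without noise follows exactly", {
  # strength-1 coupling: the target equals the shifted driver
  model <- fx_model()
  cpl <- coupling_spec(1, 2, lag = 40, strength = 1, age_slope = 0)
  tr <- simulate_source_activity(model, "theta", cpl, age = 24, n_epochs = 2,
                                 fs = 128, seed = 5)
  flat <- function(s) as.vector(t(matrix(tr[, s, ], 2, 128)))
  a <- flat(1); b <- flat(2)
  expect_equal(b[41:256], a[1:216], tolerance = 1e-12)
})
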