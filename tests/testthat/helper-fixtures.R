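# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

fx_montage <- function() {
  if (is.null(fixture_env$montage)) {
    fixture_env$montage <- standard_montage(bremen_channels())
  }
  fixture_env$montage
}

fx_model <- function() {
  if (is.null(fixture_env$model)) fixture_env$model <- load_dmnsm()
  fixture_env$model
}

fx_leadfield <- function() {
  if (is.null(fixture_env$leadfield)) {
    fixture_env$leadfield <- compute_leadfield(fx_model(), fx_montage())
  }
  fixture_env$leadfield
}

fx_orientations <- function() source_orientations(28)

# a deterministic sine-mixture recording for i/o and spectral tests
sine_recording <- function(n_channels = 4, fs = 512, seconds = 30,
                           freq = 10, amp = 20, noise_sd = 0, seed = 1) {
  set.seed(seed)
  t <- seq_len(fs * seconds) / fs
  data <- t(vapply(seq_len(n_channels), function(ch) {
    amp * sin(2 * pi * freq * t + ch) + stats::rnorm(length(t), 0, noise_sd)
  }, numeric(length(t))))
  eeg_recording(data, paste0("CH", seq_len(n_channels)), fs)
}

# independent closed-form oracle: surface potential of a dipole inside a
# homogeneous conducting sphere with insulating boundary (series summed
# analytically via Legendre generating functions)
single_sphere_potential <- function(elec, pos_mm, u, R_mm, sigma) {
  b <- sqrt(sum(pos_mm^2))
  f <- b / R_mm
  bhat <- pos_mm / b
  cg <- as.vector(elec %*% bhat)
  Fq <- sqrt(1 - 2 * f * cg + f^2)
  mr <- sum(u * bhat)
  qt <- as.vector((elec - outer(cg, bhat)) %*% u)
  S1 <- (cg - f) / Fq^3
  S2 <- (1 / f) * (1 / Fq - 1)
  S3 <- 1 / Fq^3
  S4 <- (Fq + 1) / (Fq * (1 - f * cg + Fq))
  Rm <- R_mm / 1000
  V <- (mr * (2 * S1 + S2) + qt * (2 * S3 + S4)) / (4 * pi * sigma * Rm^2)
  V * 1e-3  # microvolts per nAm
}

# brute-force nested-loop follow-up counter (oracle for count_followups)
fu_bruteforce <- function(binary_arr) {
  ne <- dim(binary_arr)[1]; ns <- dim(binary_arr)[2]; nb <- dim(binary_arr)[3]
  acc <- matrix(0, ns, ns)
  for (e in seq_len(ne)) {
    for (t in seq_len(nb - 1)) {
      for (a in seq_len(ns)) {
        if (binary_arr[e, a, t] == 1) {
          for (b in seq_len(ns)) {
            if (binary_arr[e, b, t + 1] == 1) acc[a, b] <- acc[a, b] + 1
          }
        }
      }
    }
  }
  acc / ne
}

# band-limited unit-RMS noise for small fixtures
bl_noise <- function(n, band, fs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bf <- signal::butter(4, c(band$low, band$high) / (fs / 2), type = "pass")
  pad <- min(2 * fs, n)
  x <- signal::filtfilt(bf, stats::rnorm(n + 2 * pad))[(pad + 1):(pad + n)]
  x / stats::sd(x)
}
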