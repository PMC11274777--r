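## Topographical FFT power spectra and cluster-averaged band powers.

#' The seven classical frequency bands
#'
#' Delta through gamma, tiling 1.0-35.0 Hz. Shared edges are resolved by
#' the half-open convention `[low, high)`, so adjacent bands never double
#' count a frequency bin and the seven relative powers partition unity.
#'
#' @return data.frame with columns `name`, `low`, `high` (Hz).
#' @export
frequency_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha_low", "alpha_high",
             "beta_low", "beta_high", "gamma"),
    low  = c(1.0, 4.0, 8.0, 10.5, 13.0, 21.5, 30.0),
    high = c(4.0, 8.0, 10.5, 13.0, 21.5, 30.0, 35.0),
    stringsAsFactors = FALSE
  )
}

#' Look up one band definition
#'
#' @param name band name (`"delta"`, ..., `"gamma"`).
#' @return one-row data.frame with `name`, `low`, `high`.
#' @export
get_band <- function(name) {
  bands <- frequency_bands()
  hit <- bands[bands$name == name, ]
  if (nrow(hit) == 0) stop("unknown frequency band: ", name)
  hit
}

#' Average power spectrum of a recording
#'
#' Welch-style estimate: the recording is cut into moving segments of
#' `segment_ms` with 50% overlap, each segment is multiplied by a
#' cosine-squared (Hann) window and Fourier transformed, and the one-sided
#' power spectra are averaged. The 50% overlap together with the cos^2
#' taper makes every time point contribute with equal total weight. Powers
#' are corrected for the window's power gain so that the sum of the
#' spectrum over the frequency grid equals the mean square of the signal
#' (Parseval), in microvolts squared.
#'
#' @param rec an [eeg_recording()].
#' @param segment_ms segment length in ms; 2000 ms gives a 0.5 Hz grid.
#' @param overlap fractional overlap between segments.
#' @return a `power_spectrum`: list with `freq` (Hz), `power`
#'   (channels x frequencies, uV^2), `labels`, `n_segments`.
#' @export
compute_fft_spectrum <- function(rec, segment_ms = 2000, overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  nseg <- round(segment_ms / 1000 * rec$fs)
  if (n_samples(rec) < nseg) {
    stop("recording shorter than one FFT segment")
  }
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq.int(1L, n_samples(rec) - nseg + 1L, by = step)
  w <- cos(pi * (seq_len(nseg) - (nseg + 1) / 2) / nseg)^2  # cos^2 taper
  wgain <- mean(w^2)
  nfreq <- nseg %/% 2 + 1
  freq <- (seq_len(nfreq) - 1) * rec$fs / nseg
  acc <- matrix(0, n_channels(rec), nfreq)
  for (s in starts) {
    seg <- rec$data[, s:(s + nseg - 1L), drop = FALSE]
    seg <- sweep(seg, 2, w, `*`)
    X <- t(stats::mvfft(t(seg)))
    p <- Mod(X[, seq_len(nfreq), drop = FALSE])^2
    # fold the negative frequencies into the one-sided spectrum
    p[, 2:(nfreq - 1)] <- 2 * p[, 2:(nfreq - 1)]
    if (nseg %% 2 == 1) p[, nfreq] <- 2 * p[, nfreq]
    acc <- acc + p
  }
  power <- acc / (length(starts) * nseg^2 * wgain)
  structure(list(freq = freq, power = power, labels = rec$labels,
                 n_segments = length(starts)),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d channels, %.2f-%.2f Hz in %.3g Hz steps (%d segments)\n",
              nrow(x$power), min(x$freq), max(x$freq), x$freq[2] - x$freq[1],
              x$n_segments))
  invisible(x)
}

# frequency-band denominator: the union of the seven analyzed bands
whole_spectrum_range <- function() c(1.0, 35.0)

#' Band-integrated power per channel
#'
#' Sums spectral power over grid bins with `low <= f < high`. In
#' `"relative"` mode the band power is divided by the power over the whole
#' analyzed spectrum (1.0-35.0 Hz, same half-open convention), so the seven
#' canonical bands sum to exactly one.
#'
#' @param spec a [compute_fft_spectrum()] result.
#' @param band one-row data.frame (`low`, `high`) or a band name.
#' @param mode `"absolute"` (uV^2) or `"relative"` (fraction).
#' @return named numeric vector, one value per channel.
#' @export
band_power <- function(spec, band, mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "power_spectrum"))
  if (is.character(band)) band <- get_band(band)
  if (band$low < min(spec$freq) - 1e-9 || band$high > max(spec$freq) + 1e-9) {
    stop("band [", band$low, ", ", band$high, ") outside the spectral grid")
  }
  sel <- spec$freq >= band$low - 1e-9 & spec$freq < band$high - 1e-9
  absolute <- rowSums(spec$power[, sel, drop = FALSE])
  if (mode == "absolute") {
    out <- absolute
  } else {
    rng <- whole_spectrum_range()
    tot <- spec$freq >= rng[1] - 1e-9 & spec$freq < rng[2] - 1e-9
    out <- absolute / rowSums(spec$power[, tot, drop = FALSE])
  }
  names(out) <- spec$labels
  out
}

#' Average channel values over electrode clusters
#'
#' @param values named numeric vector (per channel), e.g. a [band_power()]
#'   result.
#' @param clusters cluster definitions from [electrode_clusters()].
#' @return named numeric vector, one value per cluster (arithmetic mean of
#'   the member channels). Cluster member tokens are alias-resolved against
#'   the available channel names; a member with no matching channel is an
#'   error.
#' @export
cluster_average <- function(values, clusters = electrode_clusters()) {
  if (is.null(names(values))) stop("`values` must be named by channel")
  have <- names(values)
  norm <- function(x) toupper(x)
  # alias-resolved key: maps both directions (e.g. channel FC7 and cluster
  # token FT7 share one key; P10 resolves to PO10 on caps without P10)
  canon_key <- function(x) {
    x <- norm(x)
    ali <- .label_aliases[x]
    ifelse(is.na(ali), x, norm(ali))
  }
  vapply(names(clusters), function(cl) {
    members <- clusters[[cl]]
    if (length(members) == 0) stop("cluster '", cl, "' is empty")
    idx <- match(norm(members), norm(have))          # literal names first
    miss <- is.na(idx)
    idx[miss] <- match(canon_key(members[miss]), canon_key(have))
    if (anyNA(idx)) {
      stop("cluster '", cl, "' has members missing from the data: ",
           paste(members[is.na(idx)], collapse = ", "))
    }
    mean(values[idx])
  }, numeric(1))
}

#' Tidy band-power table for a set of participants
#'
#' Computes, for each participant's recording, the spectrum, the seven
#' absolute and relative band powers, and their cluster averages, returning
#' one tidy data.frame.
#'
#' @param recordings named list of [eeg_recording()] objects (names are
#'   participant ids).
#' @param clusters cluster set, default [electrode_clusters()].
#' @param segment_ms,overlap forwarded to [compute_fft_spectrum()].
#' @return data.frame with columns `participant`, `cluster`, `band`,
#'   `absolute`, `relative`.
#' @export
band_power_table <- function(recordings, clusters = electrode_clusters(),
                             segment_ms = 2000, overlap = 0.5) {
  bands <- frequency_bands()
  rows <- lapply(names(recordings), function(id) {
    spec <- compute_fft_spectrum(recordings[[id]], segment_ms, overlap)
    do.call(rbind, lapply(seq_len(nrow(bands)), function(b) {
      ab <- cluster_average(band_power(spec, bands[b, ], "absolute"), clusters)
      re <- cluster_average(band_power(spec, bands[b, ], "relative"), clusters)
      data.frame(participant = id, cluster = names(ab),
                 band = bands$name[b], absolute = unname(ab),
                 relative = unname(re), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
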