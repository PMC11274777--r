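## Preprocessing: average re-referencing, spherical-spline channel
## interpolation, blink-template construction and adaptive PCA-based
## ocular artifact correction.

#' Re-reference a recording to the common average
#'
#' Subtracts, at every sample, the mean over all channels, so that the
#' channel mean is zero everywhere. Idempotent, and removes any
#' common-mode offset.
#'
#' @param rec an [eeg_recording()].
#' @return the re-referenced recording, with `reference = "average"`.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_channels(rec) < 2) stop("average reference needs at least 2 channels")
  data <- sweep(rec$data, 2, colMeans(rec$data))
  eeg_recording(data, rec$labels, rec$fs, reference = "average")
}

# spherical-spline kernel g(cos(angle)) of Perrin-style order m
spline_g <- function(cosang, m = 4, nmax = 50) {
  n <- seq_len(nmax)
  coef <- (2 * n + 1) / (n^m * (n + 1)^m)
  P <- legendre_table(nmax, cosang)$P
  as.vector(crossprod(coef, P)) / (4 * pi)
}

#' Interpolate bad channels by spherical splines
#'
#' Replaces the listed channels with spherical-spline estimates from the
#' remaining good channels, using their positions on the montage sphere.
#' Interpolating more than five channels is allowed but triggers a warning,
#' mirroring the conventional quality bound for 64-channel recordings.
#'
#' @param rec an [eeg_recording()].
#' @param bad character vector of channel labels to replace.
#' @param montage a [standard_montage()] covering the recording's labels.
#' @param m spline order (smoothness), default 4.
#' @param lambda ridge regularization added to the spline system.
#' @return the recording with bad channels replaced; good channels are
#'   untouched.
#' @export
interpolate_channels <- function(rec, bad, montage, m = 4, lambda = 1e-5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(bad) == 0) return(rec)
  if (!all(bad %in% rec$labels)) {
    stop("bad channel(s) not present in recording: ",
         paste(setdiff(bad, rec$labels), collapse = ", "))
  }
  if (length(bad) > 5) {
    warning("interpolating more than five channels; topography may degrade")
  }
  good <- setdiff(rec$labels, bad)
  if (length(good) == 0) stop("cannot interpolate: all channels are bad")
  pos_good <- montage_positions(montage, good)
  pos_bad <- montage_positions(montage, bad)
  ng <- length(good)
  G <- matrix(spline_g(tcrossprod(pos_good)), ng, ng)
  A <- rbind(cbind(G + diag(lambda, ng), rep(1, ng)),
             c(rep(1, ng), 0))
  rhs <- rbind(rec$data[match(good, rec$labels), , drop = FALSE], 0)
  sol <- solve(A, rhs)
  Gb <- matrix(spline_g(tcrossprod(pos_bad, pos_good)),
               nrow(pos_bad), ng)
  est <- Gb %*% sol[seq_len(ng), , drop = FALSE] +
    matrix(sol[ng + 1, ], nrow(pos_bad), ncol(rec$data), byrow = TRUE)
  data <- rec$data
  data[match(bad, rec$labels), ] <- est
  eeg_recording(data, rec$labels, rec$fs, rec$reference)
}

#' Build a blink artifact template
#'
#' Averages event-locked windows around the supplied blink onsets and
#' extracts the topography as the first principal direction (left singular
#' vector) of the averaged window, normalized to unit norm.
#'
#' @param rec an [eeg_recording()].
#' @param blink_events sample indices of blink onsets (window centers).
#' @param window_ms window length around each event, in ms.
#' @return a `blink_template`: list with unit-norm `topography`,
#'   averaged `time_course` (samples), and `n_averaged`.
#' @export
build_blink_template <- function(rec, blink_events, window_ms = 400) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(blink_events) < 1) stop("need at least one blink event")
  half <- round(window_ms / 1000 * rec$fs / 2)
  keep <- blink_events - half >= 1 & blink_events + half <= n_samples(rec)
  ev <- blink_events[keep]
  if (length(ev) < 1) stop("no blink window fits inside the recording")
  acc <- matrix(0, n_channels(rec), 2 * half + 1)
  for (e in ev) acc <- acc + rec$data[, (e - half):(e + half)]
  avg <- acc / length(ev)
  sv <- svd(avg, nu = 1, nv = 1)
  topo <- sv$u[, 1]
  # orient so the dominant-amplitude channel loads positively
  peak <- which.max(abs(topo))
  if (topo[peak] < 0) topo <- -topo
  tc <- as.vector(crossprod(topo, avg))
  structure(list(topography = topo / sqrt(sum(topo^2)), time_course = tc,
                 labels = rec$labels, n_averaged = length(ev)),
            class = "blink_template")
}

#' Detect blink events on frontal channels
#'
#' Simple amplitude-threshold detector intended for template building:
#' marks peaks of the mean frontopolar signal exceeding `threshold`
#' microvolts, separated by at least `refractory_ms`.
#'
#' @param rec an [eeg_recording()].
#' @param channels frontal channels carrying the ocular far field.
#' @param threshold detection threshold in microvolts.
#' @param refractory_ms minimum separation between events.
#' @return integer sample indices of detected blink peaks.
#' @export
detect_blinks <- function(rec, channels = c("FP1", "FP2"), threshold = 75,
                          refractory_ms = 250) {
  idx <- match(channels, rec$labels)
  idx <- idx[!is.na(idx)]
  if (!length(idx)) stop("none of the requested frontal channels is present")
  x <- colMeans(rec$data[idx, , drop = FALSE])
  above <- which(x > threshold)
  if (!length(above)) return(integer(0))
  refr <- round(refractory_ms / 1000 * rec$fs)
  events <- integer(0)
  i <- 1
  while (i <= length(above)) {
    run <- above[above >= above[i] & above < above[i] + refr]
    events <- c(events, run[which.max(x[run])])
    i <- match(run[length(run)], above) + 1L
  }
  events
}

#' Read an event list from a plain-text file
#'
#' One sample index per line (comments after `#` allowed); used to
#' override automatic blink detection with manually curated events.
#'
#' @param path text file of 1-based sample indices.
#' @return sorted integer vector of sample indices.
#' @export
read_event_file <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path)
  lines <- sub("#.*$", "", readLines(path, warn = FALSE))
  vals <- suppressWarnings(as.integer(trimws(lines[nzchar(trimws(lines))])))
  if (anyNA(vals)) stop("event file contains non-integer entries: ", path)
  sort(vals)
}

#' Adaptive PCA-based blink correction
#'
#' Scans the recording in short windows; windows whose dominant topography
#' correlates with the blink template above `corr_threshold`, or whose
#' amplitude exceeds `amp_threshold`, are classified as artifact. A PCA of
#' the remaining (brain) data yields the brain topographies (components
#' explaining more than `var_threshold` of the variance). The data are then
#' decomposed in the joint basis of artifact and brain topographies and the
#' artifact contribution is subtracted, leaving dimensions unchanged.
#'
#' @param rec an [eeg_recording()].
#' @param template a [build_blink_template()] result.
#' @param corr_threshold topography correlation above which a window counts
#'   as artifact, in (0, 1).
#' @param amp_threshold absolute amplitude bound in microvolts.
#' @param var_threshold minimum variance fraction for a brain PCA
#'   component, in (0, 1).
#' @param window_ms classification window length.
#' @return the corrected recording; an attribute `n_artifact_windows`
#'   reports how many windows were classified as artifact.
#' @export
correct_blinks_pca <- function(rec, template, corr_threshold = 0.8,
                               amp_threshold = 150, var_threshold = 0.01,
                               window_ms = 200) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(template, "blink_template"))
  if (length(template$topography) != n_channels(rec)) {
    stop("template channel count does not match the recording")
  }
  if (corr_threshold <= 0 || corr_threshold >= 1) {
    stop("`corr_threshold` must be in (0, 1)")
  }
  if (var_threshold <= 0 || var_threshold >= 1) {
    stop("`var_threshold` must be in (0, 1)")
  }
  a <- template$topography
  wlen <- max(2L, round(window_ms / 1000 * rec$fs))
  nwin <- ceiling(n_samples(rec) / wlen)
  artifact <- logical(nwin)
  for (w in seq_len(nwin)) {
    sel <- ((w - 1) * wlen + 1):min(w * wlen, n_samples(rec))
    seg <- rec$data[, sel, drop = FALSE]
    # dominant topography of the window
    topo <- svd(seg, nu = 1, nv = 0)$u[, 1]
    artifact[w] <- abs(stats::cor(topo, a)) > corr_threshold ||
      max(abs(seg)) > amp_threshold
  }
  if (!any(artifact)) {
    attr(rec, "n_artifact_windows") <- 0L
    return(rec)
  }
  clean_idx <- unlist(lapply(which(!artifact), function(w) {
    ((w - 1) * wlen + 1):min(w * wlen, n_samples(rec))
  }))
  if (length(clean_idx) < n_channels(rec)) {
    stop("not enough artifact-free data to estimate brain topographies")
  }
  clean <- rec$data[, clean_idx, drop = FALSE]
  sv <- svd(clean)
  varfrac <- sv$d^2 / sum(sv$d^2)
  nb <- max(1L, sum(varfrac > var_threshold))
  B <- sv$u[, seq_len(nb), drop = FALSE]
  # joint basis [artifact | brain]; least-squares coefficients per sample
  basis <- cbind(a, B)
  coefs <- qr.solve(basis, rec$data)
  corrected <- rec$data - a %*% coefs[1, , drop = FALSE]
  out <- eeg_recording(corrected, rec$labels, rec$fs, rec$reference)
  attr(out, "n_artifact_windows") <- sum(artifact)
  out
}
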