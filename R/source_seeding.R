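## Seeded source-waveform estimation.
##
## The source model is seeded into band-pass-filtered scalp data: per time
## sample, the dipole component moments solve a ridge-regularized least
## squares problem against the lead field, and each regional source's
## waveform is the Euclidean norm of its three component moments (a
## non-negative "nAm" magnitude, orientation-free). With a full-column-rank
## lead field (e.g. orientation-constrained sources) and lambda -> 0 the
## estimate is the exact inverse of the forward projection.

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth band-pass of order
#' `order` per pass, with corner frequencies at the band edges.
#'
#' @param rec an [eeg_recording()].
#' @param band band name or one-row data.frame (`low`, `high` in Hz).
#' @param order Butterworth order per pass.
#' @return the filtered recording.
#' @export
bandpass_filter <- function(rec, band, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.character(band)) band <- get_band(band)
  if (band$high >= rec$fs / 2) {
    stop("band upper edge ", band$high, " Hz is at or above Nyquist (",
         rec$fs / 2, " Hz)")
  }
  bf <- signal::butter(order, c(band$low, band$high) / (rec$fs / 2),
                       type = "pass")
  data <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  eeg_recording(data, rec$labels, rec$fs, rec$reference)
}

# ridge solve operator for a lead field: returns the matrix M with
# s = M %*% d solving min ||d - L s||^2 + lambda ||s||^2
ridge_operator <- function(L, lambda) {
  p <- ncol(L)
  if (lambda <= 0) {
    if (qr(L)$rank < p) {
      stop("lead field is rank deficient; use lambda > 0 (regularization)")
    }
    return(solve(crossprod(L), t(L)))
  }
  solve(crossprod(L) + diag(lambda, p), t(L))
}

#' Estimate source waveforms by seeded least squares
#'
#' Solves, per time sample, `min ||d - L s||^2 + lambda ||s||^2` for the
#' source component moments `s`, then reduces each regional source to a
#' moment-magnitude waveform (Euclidean norm of its three components).
#'
#' @param epochs an `eeg_epochs` object ([segment_epochs()]), a single
#'   channels x samples matrix, or an [eeg_recording()].
#' @param leadfield a [compute_leadfield()] result (or a plain matrix).
#' @param lambda ridge penalty; the default is 0.01 times the mean
#'   singular value of the lead field. Use `lambda = 0` only with a
#'   full-column-rank lead field.
#' @param orientations optional n_sources x 3 matrix of fixed unit dipole
#'   orientations; when given, estimation is constrained to one oriented
#'   dipole per source (n columns instead of 3n), and the waveform is the
#'   absolute value of the oriented moment.
#' @param band optional band name stored with the result.
#' @param fs sampling rate stored with the result (taken from `epochs`
#'   when available).
#' @return a `swf_set`: list with `magnitude` (epochs x sources x samples,
#'   nAm), `components` (epochs x 3n (or n) x samples), `residual_variance`
#'   (percent, per epoch), `source_short`, `band`, `fs`, `lambda`.
#' @export
estimate_source_waveforms <- function(epochs, leadfield, lambda = NULL,
                                      orientations = NULL, band = NULL,
                                      fs = NULL) {
  L <- if (inherits(leadfield, "leadfield")) leadfield$matrix else leadfield
  src <- if (inherits(leadfield, "leadfield")) leadfield$source_short else NULL
  if (inherits(epochs, "eeg_recording")) {
    fs <- fs %||% epochs$fs
    epochs <- list(epochs$data)
  } else if (inherits(epochs, "eeg_epochs")) {
    fs <- fs %||% epochs$fs
    arr <- epochs$data
    epochs <- lapply(seq_len(dim(arr)[1]), function(i) {
      matrix(arr[i, , ], dim(arr)[2], dim(arr)[3])
    })
  } else if (is.matrix(epochs)) {
    epochs <- list(epochs)
  }
  nsrc <- ncol(L) / 3
  if (!is.null(orientations)) {
    stopifnot(nrow(orientations) == nsrc, ncol(orientations) == 3)
    # collapse each source's three columns onto its fixed orientation
    L <- vapply(seq_len(nsrc), function(s) {
      L[, 3 * (s - 1) + 1:3, drop = FALSE] %*% orientations[s, ]
    }, numeric(nrow(L)))
    percomp <- 1L
  } else {
    percomp <- 3L
  }
  if (any(vapply(epochs, nrow, 0L) != nrow(L))) {
    stop("epoch channel count does not match the lead field")
  }
  if (is.null(lambda)) lambda <- 0.01 * mean(svd(L, nu = 0, nv = 0)$d)
  M <- ridge_operator(L, lambda)
  ne <- length(epochs)
  nt <- ncol(epochs[[1]])
  mag <- array(0, dim = c(ne, nsrc, nt))
  comp <- array(0, dim = c(ne, ncol(L), nt))
  rv <- numeric(ne)
  zero_flag <- logical(ne)
  for (e in seq_len(ne)) {
    d <- epochs[[e]]
    s <- M %*% d
    comp[e, , ] <- s
    if (percomp == 1L) {
      mag[e, , ] <- abs(s)
    } else {
      for (k in seq_len(nsrc)) {
        mag[e, k, ] <- sqrt(colSums(s[3 * (k - 1) + 1:3, , drop = FALSE]^2))
      }
    }
    denom <- sum(d^2)
    if (denom == 0) {
      rv[e] <- 0
      zero_flag[e] <- TRUE
    } else {
      rv[e] <- 100 * sum((d - L %*% s)^2) / denom
    }
  }
  structure(list(magnitude = mag, components = comp, residual_variance = rv,
                 zero_data = zero_flag, source_short = src,
                 band = band, fs = fs, lambda = lambda),
            class = "swf_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.swf_set <- function(x, ...) {
  d <- dim(x$magnitude)
  cat(sprintf("<swf_set> %d epochs x %d sources x %d samples%s; residual variance %.2f%% (mean)\n",
              d[1], d[2], d[3],
              if (!is.null(x$band)) paste0(" [", x$band, "]") else "",
              mean(x$residual_variance)))
  invisible(x)
}

#' Residual variance of a source fit
#'
#' Percentage of scalp-data energy left unexplained by the source
#' reconstruction: `100 * sum((d - L s)^2) / sum(d^2)`.
#'
#' @param d channels x samples data matrix.
#' @param leadfield lead field (object or matrix).
#' @param s source component moments, columns matching `d`.
#' @return residual variance in percent; all-zero data yields 0 with an
#'   attribute `zero_data = TRUE`.
#' @export
residual_variance <- function(d, leadfield, s) {
  L <- if (inherits(leadfield, "leadfield")) leadfield$matrix else leadfield
  stopifnot(nrow(d) == nrow(L), ncol(d) == ncol(s), nrow(s) == ncol(L))
  denom <- sum(d^2)
  if (denom == 0) {
    return(structure(0, zero_data = TRUE))
  }
  100 * sum((d - L %*% s)^2) / denom
}

#' Reject epochs with outlying source magnitudes
#'
#' For each source, the mean and standard deviation of its moment
#' magnitude are pooled over all time bins of all epochs; an epoch is
#' rejected when any source exceeds `mean + k * SD` (strictly) at any bin
#' inside it.
#'
#' @param swf a `swf_set` from [estimate_source_waveforms()].
#' @param k SD multiplier, conventionally 2.
#' @return the `swf_set` restricted to surviving epochs, with a logical
#'   attribute `rejected` (length = original epoch count).
#' @export
reject_epochs_sd <- function(swf, k = 2) {
  stopifnot(inherits(swf, "swf_set"))
  ne <- dim(swf$magnitude)[1]
  if (ne < 2) stop("epoch rejection needs at least 2 epochs")
  nsrc <- dim(swf$magnitude)[2]
  rejected <- rep(FALSE, ne)
  if (is.finite(k)) {
    for (s in seq_len(nsrc)) {
      v <- swf$magnitude[, s, ]
      thr <- mean(v) + k * stats::sd(as.vector(v))
      rejected <- rejected | apply(v > thr, 1, any)
    }
  }
  if (all(rejected)) {
    stop("all epochs rejected (k = ", k, "); per-source magnitude means: ",
         paste(sprintf("%.3g", apply(swf$magnitude, 2, mean)), collapse = ", "))
  }
  out <- swf
  keep <- !rejected
  out$magnitude <- swf$magnitude[keep, , , drop = FALSE]
  out$components <- swf$components[keep, , , drop = FALSE]
  out$residual_variance <- swf$residual_variance[keep]
  out$zero_data <- swf$zero_data[keep]
  attr(out, "rejected") <- rejected
  out
}

#' Mean regional-source moments
#'
#' Grand mean of the moment magnitude over all surviving epochs and
#' samples, per source.
#'
#' @param swf a `swf_set`.
#' @return named numeric vector of mean nAm values, one per source.
#' @export
mean_rs_moments <- function(swf) {
  stopifnot(inherits(swf, "swf_set"))
  if (dim(swf$magnitude)[1] < 1) stop("no surviving epochs")
  out <- apply(swf$magnitude, 2, mean)
  if (!is.null(swf$source_short)) names(out) <- swf$source_short
  out
}
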