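#' Construct a multi-channel EEG recording
#'
#' The basic container used throughout the package: a channels-by-samples
#' matrix of voltages in microvolts, channel labels, a sampling rate and a
#' reference flag.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param labels character vector of channel labels, one per row of `data`.
#' @param fs sampling rate in Hz.
#' @param reference reference scheme, `"average"` or `"other"`.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, labels, fs, reference = c("other", "average")) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  if (length(labels) != nrow(data)) {
    stop("`labels` must have one entry per data row (channel)")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  if (anyNA(data)) stop("recording data must not contain NA/NaN")
  structure(
    list(data = data, labels = as.character(labels), fs = fs,
         reference = reference),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%s reference)\n",
              nrow(x$data), ncol(x$data), x$fs, x$reference))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_channels <- function(rec) nrow(rec$data)
n_samples  <- function(rec) ncol(rec$data)

#' Cut a recording into fixed-length epochs
#'
#' Splits a continuous recording into consecutive windows of `length`
#' seconds with fractional `overlap`. The number of epochs for a recording
#' of duration `T >= length` is
#' `floor((T - length) / (length * (1 - overlap))) + 1`.
#'
#' @param rec an [eeg_recording()].
#' @param length epoch length in seconds (default 1 s).
#' @param overlap fractional overlap between consecutive epochs in `[0, 1)`.
#' @return an `eeg_epochs` object: a list with a 3-d `data` array
#'   (epochs x channels x samples), `labels` and `fs`. A recording shorter
#'   than one epoch yields zero epochs with a warning.
#' @export
segment_epochs <- function(rec, length = 1, overlap = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)")
  len <- round(length * rec$fs)
  if (len < 2) stop("epoch length must cover at least 2 samples")
  total <- n_samples(rec)
  if (total < len) {
    warning("recording shorter than one epoch; returning zero epochs")
    arr <- array(numeric(0), dim = c(0L, n_channels(rec), len))
    return(structure(list(data = arr, labels = rec$labels, fs = rec$fs),
                     class = "eeg_epochs"))
  }
  step <- max(1L, round(len * (1 - overlap)))
  starts <- seq.int(1L, total - len + 1L, by = step)
  arr <- array(0, dim = c(length(starts), n_channels(rec), len))
  for (i in seq_along(starts)) {
    arr[i, , ] <- rec$data[, starts[i]:(starts[i] + len - 1L)]
  }
  structure(list(data = arr, labels = rec$labels, fs = rec$fs),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  invisible(x)
}

n_epochs <- function(ep) dim(ep$data)[1]
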