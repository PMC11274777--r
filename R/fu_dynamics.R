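## The follow-up (FU) statistic: band-dependent down-sampling by bin
## summation, per-epoch source-wise max normalization, share-based
## binarization, and directed transition counting.

# printed per-band bin rates; the Nyquist doubling rule is the fallback
.fu_rate_table <- c(delta = 8.0, theta = 16, alpha_low = 22.0,
                    alpha_high = 26.0, beta_low = 43, beta_high = 60,
                    gamma = 70)

#' Down-sampling rate for the FU analysis
#'
#' Returns the per-band bin rate used to temporally coarse-grain source
#' waveforms before binarization. The seven canonical bands use a fixed
#' rate table (delta 8, theta 16, alpha-low 22, alpha-high 26, beta-low
#' 43, beta-high 60, gamma 70 Hz); any other band falls back to twice its
#' upper edge, the minimal rate by the Nyquist criterion. Note the table
#' is honored verbatim even where it departs from the doubling rule
#' (alpha-low: 22 rather than 21 Hz).
#'
#' @param band band name or one-row data.frame with `name`/`high`.
#' @return bin rate in Hz.
#' @export
downsample_rate <- function(band) {
  if (is.character(band)) {
    if (band %in% names(.fu_rate_table)) return(unname(.fu_rate_table[band]))
    band <- get_band(band)
  }
  nm <- if (!is.null(band$name)) band$name else NA_character_
  if (!is.na(nm) && nm %in% names(.fu_rate_table)) {
    return(unname(.fu_rate_table[nm]))
  }
  if (is.null(band$high)) stop("unknown band and no upper edge to double")
  2 * band$high
}

#' Sum source magnitudes into coarse time bins
#'
#' Partitions each one-second epoch into `floor(rate)` bins by equal time
#' edges (sample counts may differ by one when `fs/rate` is not an
#' integer) and sums the non-negative moment magnitudes within each bin.
#'
#' @param swf a `swf_set` (or a plain epochs x sources x samples array
#'   with `fs` supplied).
#' @param rate bin rate in Hz, at most `fs`.
#' @param fs sampling rate; taken from `swf` when it is a `swf_set`.
#' @return a `binned_activity`: list with `values` (epochs x sources x
#'   bins), `rate`, `source_short`.
#' @export
bin_and_sum <- function(swf, rate, fs = NULL) {
  if (inherits(swf, "swf_set")) {
    mag <- swf$magnitude
    fs <- fs %||% swf$fs
    src <- swf$source_short
  } else {
    mag <- swf
    src <- NULL
  }
  if (is.null(fs)) stop("sampling rate `fs` required")
  if (rate > fs) stop("bin rate ", rate, " Hz exceeds the sampling rate")
  nt <- dim(mag)[3]
  nbin <- floor(rate)
  edges <- floor((0:nbin) * nt / nbin)
  binidx <- rep(seq_len(nbin), times = diff(edges))
  ne <- dim(mag)[1]; nsrc <- dim(mag)[2]
  out <- array(0, dim = c(ne, nsrc, nbin))
  for (e in seq_len(ne)) {
    m <- matrix(mag[e, , ], nsrc, nt)
    out[e, , ] <- t(rowsum(t(m), binidx))
  }
  structure(list(values = out, rate = rate, source_short = src,
                 normalized = FALSE),
            class = "binned_activity")
}

#' Normalize binned activity to the epoch maximum
#'
#' Divides each source's bins by that source's maximum within the epoch
#' and scales to percent, so every source peaks at exactly 100 in every
#' epoch. Epochs in which some source is identically zero carry no share
#' information for that source and are flagged degenerate and excluded.
#'
#' @param binned a [bin_and_sum()] result.
#' @return the normalized `binned_activity` (percent of epoch max);
#'   attribute `degenerate` flags excluded epochs (relative to the input).
#' @export
normalize_epoch_max <- function(binned) {
  stopifnot(inherits(binned, "binned_activity"))
  v <- binned$values
  ne <- dim(v)[1]; nsrc <- dim(v)[2]
  degenerate <- logical(ne)
  for (e in seq_len(ne)) {
    mx <- apply(matrix(v[e, , ], nsrc), 1, max)
    if (any(mx <= 0)) {
      degenerate[e] <- TRUE
      next
    }
    v[e, , ] <- 100 * v[e, , ] / mx
  }
  out <- binned
  out$values <- v[!degenerate, , , drop = FALSE]
  out$normalized <- TRUE
  attr(out, "degenerate") <- degenerate
  out
}

#' Binarize activity by the equal-share criterion
#'
#' A source is labeled active (1) in a time bin when its normalized value
#' strictly exceeds one nth of the summed value of all `n` sources at that
#' bin; ties and equality yield 0. Bins where all sources are zero are
#' entirely inactive.
#'
#' @param normed a [normalize_epoch_max()] result.
#' @param n the share divisor; must equal the source count of the model.
#' @return a `binary_activity` list with `values` (epochs x sources x
#'   bins, 0/1) and `source_short`.
#' @export
binarize_share <- function(normed, n = dim(normed$values)[2]) {
  stopifnot(inherits(normed, "binned_activity"))
  v <- normed$values
  if (n != dim(v)[2]) {
    stop("share divisor n = ", n, " must equal the source count ", dim(v)[2])
  }
  ne <- dim(v)[1]
  out <- array(0L, dim = dim(v))
  for (e in seq_len(ne)) {
    m <- matrix(v[e, , ], dim(v)[2])
    share <- matrix(colSums(m) / n, dim(v)[2], ncol(m), byrow = TRUE)
    out[e, , ] <- (m > share) * 1L
  }
  structure(list(values = out, source_short = normed$source_short),
            class = "binary_activity")
}

#' Count directed follow-up transitions
#'
#' For every consecutive bin pair (t, t+1) of every epoch, the counter
#' `FU[A, B]` is incremented for each source A active at t and each source
#' B active at t+1; A = B is allowed, so the diagonal carries steady-state
#' (self-persisting) activation. Per-epoch counts are averaged over
#' epochs, giving mean follow-up counts per second for one-second epochs.
#'
#' @param bin a [binarize_share()] result.
#' @return an `fu_matrix`: n x n numeric matrix (rows = source active at
#'   t, columns = source active at t+1) with attribute `n_epochs`.
#' @export
count_followups <- function(bin) {
  stopifnot(inherits(bin, "binary_activity"))
  v <- bin$values
  ne <- dim(v)[1]; nsrc <- dim(v)[2]; nbin <- dim(v)[3]
  if (nbin < 2) stop("follow-up counting needs at least 2 bins per epoch")
  if (ne < 1) stop("no epochs to count")
  acc <- matrix(0, nsrc, nsrc)
  for (e in seq_len(ne)) {
    m <- matrix(v[e, , ], nsrc, nbin)
    acc <- acc + m[, 1:(nbin - 1), drop = FALSE] %*%
      t(m[, 2:nbin, drop = FALSE])
  }
  fu <- acc / ne
  if (!is.null(bin$source_short)) {
    dimnames(fu) <- list(bin$source_short, bin$source_short)
  }
  structure(fu, class = c("fu_matrix", "matrix"), n_epochs = ne)
}

#' Full FU pipeline for one source-waveform set
#'
#' Convenience wrapper chaining [downsample_rate()], [bin_and_sum()],
#' [normalize_epoch_max()], [binarize_share()] and [count_followups()].
#'
#' @param swf a `swf_set` with its `band` field set (or pass `band`).
#' @param band band name overriding `swf$band`.
#' @return an `fu_matrix`.
#' @export
fu_matrix <- function(swf, band = swf$band) {
  if (is.null(band)) stop("band unknown; set `swf$band` or pass `band`")
  rate <- downsample_rate(band)
  binned <- bin_and_sum(swf, rate)
  normed <- normalize_epoch_max(binned)
  binar <- binarize_share(normed)
  count_followups(binar)
}
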