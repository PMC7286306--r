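#' Multichannel ROI time series
#'
#' Container for continuous per-region signals: a numeric matrix with one row
#' per sample and one column per region of interest, plus the sampling rate.
#'
#' @param data Numeric matrix (or data frame), rows = samples, columns = ROIs.
#'   Must contain no missing values and at least 2 rows and 2 columns.
#' @param fs Sampling rate in Hz (> 0).
#' @param roi_names Optional character vector of column labels; defaults to
#'   the matrix column names or `ROI1..ROIN`.
#' @param band Optional [frequency_band()] tag recording the band the signal
#'   is limited to.
#' @return A `roi_timeseries` object.
#' @export
roi_timeseries <- function(data, fs, roi_names = NULL, band = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (anyNA(data)) stop("roi_timeseries: data contains missing values")
  if (nrow(data) < 2L) stop("roi_timeseries: need at least 2 samples")
  if (ncol(data) < 2L) stop("roi_timeseries: need at least 2 ROIs")
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  if (is.null(roi_names)) {
    roi_names <- colnames(data)
    if (is.null(roi_names)) roi_names <- paste0("ROI", seq_len(ncol(data)))
  }
  stopifnot(length(roi_names) == ncol(data))
  colnames(data) <- roi_names
  if (!is.null(band)) stopifnot(inherits(band, "frequency_band"))
  structure(list(data = data, fs = fs, roi_names = roi_names, band = band),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %d samples x %d ROIs @ %g Hz%s\n",
              nrow(x$data), ncol(x$data), x$fs,
              if (is.null(x$band)) "" else paste0(" [", x$band$name, "]")))
  invisible(x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass filter forward and backward
#' (zero phase lag) to every ROI column. The default order is 4.
#'
#' @param x A [roi_timeseries()].
#' @param band A [frequency_band()]; both edges must lie strictly below the
#'   Nyquist frequency `fs/2`.
#' @param order Filter order (>= 1), default 4.
#' @return A filtered `roi_timeseries` tagged with `band`.
#' @export
bandpass_filter <- function(x, band, order = 4L) {
  stopifnot(inherits(x, "roi_timeseries"), inherits(band, "frequency_band"))
  if (order < 1L) stop("bandpass_filter: order must be >= 1")
  nyq <- x$fs / 2
  if (band$hi >= nyq || band$lo <= 0)
    stop(sprintf(
      "bandpass_filter: band %g-%g Hz invalid for fs = %g Hz (Nyquist %g Hz)",
      band$lo, band$hi, x$fs, nyq))
  # filtfilt needs enough samples for its edge padding (3 * filter length)
  if (nrow(x$data) <= 3 * (2 * order + 1))
    stop("bandpass_filter: signal too short for zero-phase filtering at this order")
  bf <- signal::butter(order, c(band$lo, band$hi) / nyq, type = "pass")
  filt <- apply(x$data, 2, function(col) signal::filtfilt(bf, col))
  roi_timeseries(filt, x$fs, x$roi_names, band = band)
}

#' Hilbert amplitude envelope
#'
#' Computes, per ROI, the absolute value of the analytic representation of
#' the signal (FFT construction: double the positive frequencies, zero the
#' negative ones), i.e. the instantaneous amplitude of band-limited
#' oscillatory activity.
#'
#' @param x A [roi_timeseries()] of real-valued signals.
#' @return A `roi_timeseries` of non-negative envelopes, same shape. An
#'   all-zero input column yields an all-zero envelope (a message is emitted).
#' @export
hilbert_envelope <- function(x) {
  stopifnot(inherits(x, "roi_timeseries"))
  n <- nrow(x$data)
  # multiplier for the analytic signal: 1 at DC (and Nyquist when n even),
  # 2 on positive frequencies, 0 on negative frequencies
  mult <- numeric(n)
  if (n %% 2 == 0) {
    mult[c(1, n / 2 + 1)] <- 1
    mult[2:(n / 2)] <- 2
  } else {
    mult[1] <- 1
    mult[2:((n + 1) / 2)] <- 2
  }
  env <- apply(x$data, 2, function(col) {
    if (all(col == 0)) return(col)
    Mod(stats::fft(stats::fft(col) * mult, inverse = TRUE) / n)
  })
  if (any(apply(x$data, 2, function(col) all(col == 0))))
    message("hilbert_envelope: all-zero column(s); envelope is zero there")
  roi_timeseries(env, x$fs, x$roi_names, band = x$band)
}

#' Binary state series
#'
#' A matrix of +1/-1 entries, one row per sample and one column per region:
#' +1 marks high oscillatory power, -1 low.
#'
#' @param states Numeric/integer matrix with entries exactly +1 or -1.
#' @param roi_names Optional column labels.
#' @return A `binary_states` object.
#' @export
binary_states <- function(states, roi_names = NULL) {
  states <- as.matrix(states)
  storage.mode(states) <- "double"
  if (!all(states %in% c(-1, 1)))
    stop("binary_states: entries must be exactly +1 or -1")
  if (is.null(roi_names)) {
    roi_names <- colnames(states)
    if (is.null(roi_names)) roi_names <- paste0("ROI", seq_len(ncol(states)))
  }
  colnames(states) <- roi_names
  structure(list(states = states, roi_names = roi_names),
            class = "binary_states")
}

#' @export
print.binary_states <- function(x, ...) {
  cat(sprintf("<binary_states> %d samples x %d ROIs (+1 fraction %.3f)\n",
              nrow(x$states), ncol(x$states), mean(x$states > 0)))
  invisible(x)
}

#' Median-split binarization of amplitude envelopes
#'
#' Thresholds each ROI's envelope at the median of its amplitude over the full
#' series: samples strictly above the median become +1 (high oscillatory
#' power), all others -1. Ties at the median therefore map to -1, which makes
#' the rule deterministic; for even-length columns of distinct values each
#' column ends up with exactly half +1.
#'
#' @param env A [roi_timeseries()] of (envelope) values.
#' @param edge_trim Fraction of samples (default 0) dropped from each end
#'   before binarization, to discard filter/envelope edge distortion.
#' @return A [binary_states()] object with attribute `"thresholds"` holding
#'   the per-ROI medians. Constant columns binarize to all -1 with a warning.
#' @export
binarize_median <- function(env, edge_trim = 0) {
  stopifnot(inherits(env, "roi_timeseries"),
            edge_trim >= 0, edge_trim < 0.5)
  m <- env$data
  if (edge_trim > 0) {
    n <- nrow(m)
    drop <- floor(n * edge_trim)
    if (n - 2 * drop < 1) stop("binarize_median: edge_trim leaves no samples")
    m <- m[(drop + 1):(n - drop), , drop = FALSE]
  }
  med <- apply(m, 2, stats::median)
  if (any(apply(m, 2, function(col) length(unique(col)) == 1L)))
    warning("binarize_median: constant column(s) binarize to all -1")
  states <- sweep(m, 2, med, function(a, b) ifelse(a > b, 1, -1))
  out <- binary_states(states, env$roi_names)
  attr(out, "thresholds") <- stats::setNames(med, env$roi_names)
  out
}

#' Empirical state statistics of a binary series
#'
#' Computes the sufficient statistics that constrain the pairwise maximum
#' entropy model: per-region mean activation `<r_i> = (1/T) sum_t r_i(t)`,
#' pairwise co-occurrence `<r_i r_j> = (1/T) sum_t r_i(t) r_j(t)`, and the
#' empirical occurrence probability of each observed network state.
#'
#' @param b A [binary_states()] object.
#' @return An `empirical_stats` object: `mean_activation` (length `N`),
#'   `cooccurrence` (`N x N`, symmetric, unit diagonal), `state_probs`
#'   (named numeric; names are state indices, see [state_index()]), and `T`.
#' @export
empirical_stats <- function(b) {
  stopifnot(inherits(b, "binary_states"))
  S <- b$states
  T_n <- nrow(S)
  m <- colMeans(S)
  cooc <- crossprod(S) / T_n
  diag(cooc) <- 1
  idx <- state_index(S)
  tab <- table(idx) / T_n
  probs <- stats::setNames(as.numeric(tab), names(tab))
  structure(list(mean_activation = stats::setNames(m, b$roi_names),
                 cooccurrence = cooc,
                 state_probs = probs,
                 T = T_n,
                 roi_names = b$roi_names),
            class = "empirical_stats")
}

#' @export
print.empirical_stats <- function(x, ...) {
  cat(sprintf("<empirical_stats> N = %d ROIs, T = %d samples, %d observed states\n",
              length(x$mean_activation), x$T, length(x$state_probs)))
  invisible(x)
}
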