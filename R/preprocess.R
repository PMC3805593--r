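#' Cognitive sub-stage windows
#'
#' The three post-stimulus analysis windows: Beginning (visual stimulus
#' encoding, 0-300 ms), Middle (mental rotation, 300-800 ms) and End
#' (response, 800-1200 ms). Windows are half-open `[start, end)` in both
#' milliseconds and sample indices.
#'
#' @param starts_ms,ends_ms numeric vectors of window edges (ms).
#' @param names window names.
#' @return list of `sub_stage_window` objects (`name`, `start_ms`,
#'   `end_ms`).
#' @export
sub_stage_windows <- function(starts_ms = c(0, 300, 800),
                              ends_ms = c(300, 800, 1200),
                              names = c("Beginning", "Middle", "End")) {
  if (length(starts_ms) != length(ends_ms) ||
      length(starts_ms) != length(names))
    stop("starts_ms, ends_ms and names must have equal length")
  if (any(starts_ms >= ends_ms))
    stop("each window must satisfy start < end")
  ord <- order(starts_ms)
  if (any(ends_ms[ord][-length(ord)] > starts_ms[ord][-1] + 1e-9))
    stop("windows must not overlap")
  mapply(function(nm, s, e)
    structure(list(name = nm, start_ms = s, end_ms = e),
              class = "sub_stage_window"),
    names, starts_ms, ends_ms, SIMPLIFY = FALSE)
}

# Sample index range (1-based, half-open [start, end) in 0-based samples)
window_samples <- function(window, fs) {
  i0 <- floor(window$start_ms * fs / 1000) + 1L
  i1 <- floor(window$end_ms * fs / 1000)
  i0:i1
}

# Squared-magnitude response of an order-`order` Butterworth band-pass,
# evaluated at digital frequencies (radians/sample) with bilinear
# pre-warping so the -3 dB points land exactly on (low, high). Applying
# this squared response once equals a forward-backward (zero-phase) pass
# of the order-4 filter: effective order 8, no phase distortion.
butter_bp_gain2 <- function(w, low, high, fs, order = 4) {
  W  <- tan(w / 2)
  W1 <- tan(pi * low / fs)
  W2 <- tan(pi * high / fs)
  u <- (W^2 - W1 * W2) / ((W2 - W1) * W)
  g2 <- 1 / (1 + u^(2 * order))^2
  g2[!is.finite(u)] <- 0 # DC and Nyquist
  g2
}

# Zero-phase band-pass of one channels x samples matrix via FFT, with
# odd-reflection padding against circular wrap-around.
bandpass_matrix <- function(x, low, high, fs, order = 4, pad = NULL) {
  n <- ncol(x)
  if (is.null(pad)) pad <- min(n - 1L, max(50L, round(0.2 * fs)))
  left  <- 2 * x[, 1] - x[, (pad + 1):2, drop = FALSE]
  right <- 2 * x[, n] - x[, (n - 1):(n - pad), drop = FALSE]
  xp <- cbind(left, x, right)
  np <- ncol(xp)
  w <- 2 * pi * (seq_len(np) - 1) / np
  g2 <- butter_bp_gain2(w, low, high, fs, order)
  X <- t(stats::mvfft(t(xp)))
  y <- Re(t(stats::mvfft(t(X * rep(g2, each = nrow(xp))), inverse = TRUE))) / np
  y[, (pad + 1):(pad + n), drop = FALSE]
}

#' Band-pass filter epochs into the beta band
#'
#' Applies a zero-phase band-pass (squared magnitude response of a
#' 4th-order Butterworth, i.e. the magnitude characteristic of a
#' forward-backward pass) to every channel of every trial. Output length is
#' unchanged. Filtering is done on the full trial, before segmentation, so
#' edge transients never fall inside the short sub-stage windows.
#'
#' @param epochs an [epoch_set].
#' @param low,high band edges in Hz (defaults 13 and 30, the beta band).
#' @param order analog prototype order (default 4).
#' @return the filtered [epoch_set].
#' @export
bandpass_beta <- function(epochs, low = 13, high = 30, order = 4) {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- epochs$fs
  if (low <= 0 || high >= fs / 2 || low >= high)
    stop("band edges must satisfy 0 < low < high < fs/2")
  out <- epochs
  dm <- dim(epochs$data)[2:3]
  for (i in seq_len(dim(epochs$data)[1]))
    out$data[i, , ] <- bandpass_matrix(
      array(epochs$data[i, , , drop = FALSE], dm), low, high, fs, order)
  out
}

#' Split epochs into sub-stage segments
#'
#' Cuts every trial into the given half-open windows. At 1000 Hz the three
#' default windows give segments of 300, 500 and 400 samples. Call this
#' after [bandpass_beta()]; segmentation itself is pure slicing.
#'
#' @param epochs an [epoch_set].
#' @param windows list from [sub_stage_windows()].
#' @return named list (window name -> [epoch_set] restricted to the
#'   window's samples).
#' @export
segment_epochs <- function(epochs, windows = sub_stage_windows()) {
  stopifnot(inherits(epochs, "epoch_set"))
  nsamp <- dim(epochs$data)[3]
  out <- lapply(windows, function(w) {
    idx <- window_samples(w, epochs$fs)
    if (max(idx) > nsamp || min(idx) < 1)
      stop("window ", w$name, " falls outside the trial")
    seg <- epochs
    seg$data <- epochs$data[, , idx, drop = FALSE]
    seg
  })
  names(out) <- vapply(windows, `[[`, character(1), "name")
  out
}
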