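#' Event-related epoch container
#'
#' Holds one subject's stack of fixed-length multichannel trials together
#' with the stimulus metadata needed downstream: hand, rotation angle and
#' the correct-response flag per trial.
#'
#' @param data numeric array, trials x channels x samples.
#' @param fs sampling rate in Hz.
#' @param montage a [montage]; its length must match `dim(data)[2]`.
#' @param meta data.frame with one row per trial; must contain columns
#'   `hand` and `angle`, and normally `correct` (logical) and `block`.
#' @param subject_id subject identifier string.
#' @param group `"control"` or `"patient"`.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, montage, meta,
                      subject_id = "S01", group = "control") {
  if (length(dim(data)) != 3)
    stop("data must be a trials x channels x samples array")
  if (dim(data)[2] != length(montage$labels))
    stop("channel dimension (", dim(data)[2], ") does not match montage (",
         length(montage$labels), " labels)")
  if (nrow(meta) != dim(data)[1])
    stop("meta must have one row per trial")
  if (!all(c("hand", "angle") %in% names(meta)))
    stop("meta must contain 'hand' and 'angle' columns")
  if (fs <= 0) stop("fs must be positive")
  structure(list(data = data, fs = fs, montage = montage, meta = meta,
                 subject_id = subject_id, group = group),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %s (%s): %d trials x %d channels x %d samples @ %g Hz\n",
    x$subject_id, x$group, d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' Number of trials in an epoch set
#' @param epochs an [epoch_set].
#' @return integer trial count.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

#' Keep only correctly answered trials
#'
#' Drops every trial whose `correct` flag is `FALSE`, keeping the metadata
#' aligned. If some (hand, angle) cell loses all its trials a warning is
#' emitted and the cell is recorded in the `missing_cells` attribute so
#' downstream averaging can flag the gap.
#'
#' @param epochs an [epoch_set] whose `meta` has a logical `correct` column.
#' @return The filtered [epoch_set]; attribute `missing_cells` is a
#'   data.frame of now-empty (hand, angle) cells (zero rows if none).
#' @export
select_correct <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(epochs$meta$correct))
    stop("meta has no 'correct' column")
  before <- unique(epochs$meta[, c("hand", "angle")])
  keep <- which(as.logical(epochs$meta$correct))
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  out$meta <- epochs$meta[keep, , drop = FALSE]
  rownames(out$meta) <- NULL
  after <- unique(out$meta[, c("hand", "angle")])
  key <- function(d) paste(d$hand, d$angle)
  lost <- before[!key(before) %in% key(after), , drop = FALSE]
  if (nrow(lost) > 0)
    warning(sprintf("%s: no correct trials left in %d (hand, angle) cell(s): %s",
                    epochs$subject_id, nrow(lost),
                    paste(key(lost), collapse = "; ")))
  attr(out, "missing_cells") <- lost
  out
}
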