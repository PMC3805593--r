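#' Analytic signal via the Hilbert transform
#'
#' Frequency-domain construction: positive frequencies doubled, negative
#' frequencies zeroed, so that `analytic = x + i * H(x)`.
#'
#' @param x numeric vector or channels x samples matrix (one row per
#'   channel).
#' @return complex vector/matrix of the same shape.
#' @export
analytic_signal <- function(x) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1) else x
  n <- ncol(m)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- t(stats::mvfft(t(m)))
  a <- t(stats::mvfft(t(X * rep(h, each = nrow(m))), inverse = TRUE)) / n
  if (vec) as.vector(a) else a
}

#' Instantaneous phase of every trial and channel
#'
#' Computes the argument of the analytic signal over the FULL trial (the
#' transform's edge artifacts are then diluted over the whole 1200 ms
#' rather than a 300-sample window); segment the resulting phases
#' afterwards with [segment_epochs()]. All-zero channels have no defined
#' phase and are returned as `NA`, which propagates to a missing pair flag
#' in the association matrices.
#'
#' @param epochs an [epoch_set] (normally band-passed).
#' @return an [epoch_set] whose `data` holds phases in radians, wrapped to
#'   (-pi, pi].
#' @export
analytic_phase <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  out <- epochs
  dm <- dim(epochs$data)[2:3]
  for (i in seq_len(dim(epochs$data)[1])) {
    m <- array(epochs$data[i, , , drop = FALSE], dm)
    ph <- Arg(analytic_signal(m))
    dead <- rowSums(abs(m)) == 0
    if (any(dead)) ph[dead, ] <- NA_real_
    out$data[i, , ] <- ph
  }
  out
}

#' Mean phase coherence of two phase sequences
#'
#' The modulus of the time-averaged unit phasor of the phase difference:
#' 1 for a perfectly constant difference, near 0 for independent phases.
#'
#' @param phi1,phi2 numeric phase vectors (radians) of equal length >= 2.
#' @return scalar in `[0, 1]`, or `NA` if either input contains `NA`.
#' @examples
#' p <- seq(0, 10, by = 0.1)
#' mpc(p, p + 0.7)   # 1
#' @export
mpc <- function(phi1, phi2) {
  if (length(phi1) != length(phi2))
    stop("phase sequences must have equal length")
  if (length(phi1) < 2) stop("need at least 2 samples")
  if (anyNA(phi1) || anyNA(phi2)) return(NA_real_)
  Mod(mean(exp(1i * (phi1 - phi2))))
}

#' Association (PSI) matrix of one trial
#'
#' Fills every unordered channel pair with the mean phase coherence of the
#' two phase rows over the segment's samples. Symmetric by construction;
#' the diagonal is fixed at 0 (self-synchrony is excluded from every
#' average and from top-k thresholding).
#'
#' @param phases channels x samples numeric matrix of phases (radians);
#'   rows may be named.
#' @return channels x channels symmetric matrix, entries in `[0, 1]`
#'   (or `NA` for pairs involving a flagged channel), zero diagonal.
#' @export
psi_matrix <- function(phases) {
  if (is.null(dim(phases)) || nrow(phases) < 2)
    stop("need a channels x samples matrix with >= 2 channels")
  n <- nrow(phases)
  M <- matrix(0, n, n, dimnames = list(rownames(phases), rownames(phases)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      M[i, j] <- M[j, i] <- mpc(phases[i, ], phases[j, ])
    }
  }
  M
}

# Vectorised PSI for a trials x channels x samples phase array: one complex
# crossproduct per trial. Numerically identical to psi_matrix() per trial
# (asserted in the test suite); used by the pipeline for speed.
psi_matrices_fast <- function(phase_array) {
  stopifnot(length(dim(phase_array)) == 3)
  ntr <- dim(phase_array)[1]
  lapply(seq_len(ntr), function(i) {
    ph <- phase_array[i, , , drop = TRUE]
    E <- exp(1i * ph)
    nan <- rowSums(is.na(ph)) > 0
    E[nan, ] <- 0
    M <- Mod(E %*% Conj(t(E))) / ncol(ph)
    if (any(nan)) {
      M[nan, ] <- NA_real_
      M[, nan] <- NA_real_
    }
    diag(M) <- 0
    dimnames(M) <- list(dimnames(phase_array)[[2]],
                        dimnames(phase_array)[[2]])
    M
  })
}

#' Average per-trial association matrices by stimulus type
#'
#' Element-wise mean of all per-trial matrices sharing the same
#' (hand, angle) cell: one averaged matrix per stimulus type (12 for the
#' full 2 x 6 design). Empty cells yield `NULL` with a warning.
#'
#' @param matrices list of per-trial association matrices.
#' @param meta data.frame with `hand` and `angle` per trial (same order).
#' @param hands,angles the full factor levels defining the design cells.
#' @return named list `"<hand>_<angle>"` -> averaged matrix (or `NULL` for
#'   a missing cell); attribute `n_trials` gives per-cell trial counts.
#' @export
average_by_type <- function(matrices, meta,
                            hands = c("left", "right"),
                            angles = c(0, 60, 120, 180, 240, 300)) {
  if (length(matrices) != nrow(meta))
    stop("one metadata row per matrix required")
  cells <- expand.grid(hand = hands, angle = angles,
                       stringsAsFactors = FALSE)
  cells <- cells[order(match(cells$hand, hands), cells$angle), ]
  out <- vector("list", nrow(cells))
  names(out) <- paste(cells$hand, cells$angle, sep = "_")
  counts <- stats::setNames(integer(nrow(cells)), names(out))
  for (k in seq_len(nrow(cells))) {
    sel <- which(meta$hand == cells$hand[k] & meta$angle == cells$angle[k])
    counts[k] <- length(sel)
    if (length(sel) == 0) next
    out[[k]] <- Reduce(`+`, matrices[sel]) / length(sel)
  }
  if (any(counts == 0))
    warning("no trials for cell(s) ",
            paste(names(out)[counts == 0], collapse = ", "),
            "; matrices missing")
  attr(out, "n_trials") <- counts
  out
}

#' Hemispheric PSI summary of an association matrix
#'
#' Means of the left intra-hemispheric, right intra-hemispheric and
#' inter-hemispheric channel-pair classes. Pairs involving midline
#' channels belong to no class and are excluded from all three, keeping
#' the classes disjoint.
#'
#' @param M symmetric association matrix (labels in montage order).
#' @param montage the [montage] describing `M`'s channels.
#' @return named numeric vector `c(left = , right = , inter = )`.
#' @export
hemispheric_summary <- function(M, montage) {
  if (nrow(M) != length(montage$labels))
    stop("matrix size does not match montage")
  if (!is.null(rownames(M)) && !identical(rownames(M), montage$labels))
    stop("matrix labels do not match montage order")
  hp <- hemisphere_pairs(montage)
  val <- M[cbind(hp$i, hp$j)]
  c(left  = mean(val[hp$class == "left"]),
    right = mean(val[hp$class == "right"]),
    inter = mean(val[hp$class == "inter"]))
}
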