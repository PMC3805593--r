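# Batched connectivity fast path.
#
# One FFT round per subject: all trials and channels are laid out as
# columns of a single samples x (channels * trials) matrix, odd-reflection
# padded, and the zero-phase band-pass gain and the analytic-signal
# (Hilbert) multiplier are applied in the same frequency-domain pass. The
# result is the unit phasor exp(i * phase) per channel and sample, which is
# all the mean phase coherence needs. Numerically equivalent to
# bandpass_beta() -> analytic_phase() -> psi_matrix() up to edge handling
# (asserted against the modular path in the test suite).

fast_phasors <- function(es, low = 13, high = 30, pad = NULL) {
  d <- es$data
  ntr <- dim(d)[1]; nch <- dim(d)[2]; n <- dim(d)[3]
  fs <- es$fs
  if (is.null(pad)) {
    # pad to a 5-smooth FFT length (>= 50 samples each side)
    np <- stats::nextn(n + 100L, c(2, 3, 5))
    pad <- (np - n) %/% 2L
  }
  pad <- min(n - 1L, pad)
  X <- matrix(aperm(d, c(3, 2, 1)), nrow = n) # samples x (ch*trials)
  nc <- ncol(X)
  left <- 2 * matrix(X[1, ], pad, nc, byrow = TRUE) -
    X[(pad + 1):2, , drop = FALSE]
  right <- 2 * matrix(X[n, ], pad, nc, byrow = TRUE) -
    X[(n - 1):(n - pad), , drop = FALSE]
  XP <- rbind(left, X, right)
  np <- n + 2L * pad
  w <- 2 * pi * (seq_len(np) - 1) / np
  g2 <- butter_bp_gain2(w, low, high, fs)
  h <- numeric(np)
  if (np %% 2 == 0) {
    h[c(1, np / 2 + 1)] <- 1
    h[2:(np / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((np + 1) / 2)] <- 2
  }
  A <- stats::mvfft(XP) * (g2 * h)
  a <- stats::mvfft(A, inverse = TRUE)[(pad + 1):(pad + n), ,
                                       drop = FALSE] / np
  mod <- Mod(a)
  mod[mod == 0] <- NA_real_
  E <- a / mod
  # samples x (channels * trials) unit phasors; trial i occupies columns
  # (i-1)*nch + 1 ... i*nch
  structure(E, nch = nch, ntr = ntr)
}

# Averaged association matrices and hemispheric PSI rows for one subject.
# Returns list(avg = window -> named list of 12 cell matrices,
#              hemi = long data.frame).
compute_subject_connectivity <- function(es, windows = sub_stage_windows(),
                                         band = c(13, 30),
                                         sweep_window = FALSE,
                                         hemi_windows = NULL) {
  E <- fast_phasors(es, band[1], band[2])
  nch <- attr(E, "nch"); ntr <- attr(E, "ntr")
  wins <- windows
  if (sweep_window) {
    total <- dim(es$data)[3] * 1000 / es$fs
    wins <- c(wins, sub_stage_windows(0, total, "Whole"))
  }
  hp <- hemisphere_pairs(es$montage)
  avg <- list(); hemi_rows <- list()
  for (w in wins) {
    idx <- window_samples(w, es$fs)
    mats <- lapply(seq_len(ntr), function(i) {
      Ew <- E[idx, (i - 1L) * nch + seq_len(nch), drop = FALSE]
      M <- Mod(t(Ew) %*% Conj(Ew)) / length(idx)
      diag(M) <- 0
      M
    })
    am <- average_by_type(mats, es$meta)
    for (cell in names(am)) {
      if (is.null(am[[cell]])) next
      dimnames(am[[cell]]) <- list(es$montage$labels, es$montage$labels)
    }
    avg[[w$name]] <- am
    if (w$name != "Whole" &&
        (is.null(hemi_windows) || w$name %in% hemi_windows)) {
      for (cell in names(am)) {
        if (is.null(am[[cell]])) next
        val <- am[[cell]][cbind(hp$i, hp$j)]
        hemi_rows[[length(hemi_rows) + 1]] <- data.frame(
          subject = es$subject_id, group = es$group, substage = w$name,
          hand = sub("_.*", "", cell),
          angle = as.numeric(sub(".*_", "", cell)),
          hemisphere = c("left", "right", "inter"),
          value = c(mean(val[hp$class == "left"]),
                    mean(val[hp$class == "right"]),
                    mean(val[hp$class == "inter"])),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(avg = avg, hemi = do.call(rbind, hemi_rows))
}
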