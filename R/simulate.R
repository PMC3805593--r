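#' Coupling specification for the synthetic generator
#'
#' Describes how tightly channels phase-lock in each cognitive sub-stage.
#' The signal model is a shared beta-band oscillator plus independent
#' von Mises phase jitter per channel: larger `kappa` means tighter
#' coupling. The effective concentration for a trial with rotation angle
#' `a`, group `g` and sub-stage `s` is
#' `kappa[s] * angle_gain[a] * group_gain[g, s]` (times the per-subject and
#' optional per-channel gains).
#'
#' @param kappa nonnegative numeric, one value per sub-stage (recycled to
#'   the three default windows). Jitter concentration.
#' @param carrier_freq carrier frequency in Hz, strictly inside (13, 30).
#' @param carrier_jitter half-width (Hz) of the uniform per-subject carrier
#'   perturbation.
#' @param noise_sd standard deviation of additive white broadband noise.
#' @param angle_gain named numeric map, angle (degrees) -> multiplicative
#'   modifier of `kappa`. The default peaks at 180 degrees, emulating the
#'   angle effect of mental rotation.
#' @param group_gain named list `control`/`patient`, each a numeric vector
#'   of per-sub-stage multiplicative modifiers.
#' @param inter_hemi_kappa concentration of the per-hemisphere phase-offset
#'   process; finite values make inter-hemispheric pairs less coherent than
#'   intra-hemispheric ones. `Inf` switches the offset off.
#' @param channel_gain optional named numeric map, channel label ->
#'   multiplicative modifier of `kappa` (nodal asymmetry hook); unnamed
#'   channels get 1.
#' @param jitter_ms length (ms) of the piecewise-constant jitter blocks;
#'   each block gets an independent von Mises draw per channel.
#' @param blend_ms width (ms) of the raised-cosine ramp that blends the
#'   concentration profile across sub-stage boundaries.
#' @param drift_rate standard deviation (rad / sqrt(s)) of the shared slow
#'   random-walk phase drift (common to all channels, cancels in pairwise
#'   coherence).
#' @param subject_sd log-normal sd of the per-subject kappa multiplier.
#' @param accuracy probability that a trial is answered correctly.
#' @return An object of class `coupling_spec`.
#' @seealso [control_coupling()], [patient_coupling()]
#' @export
coupling_spec <- function(kappa = c(1.5, 2, 1.5),
                          carrier_freq = 20,
                          carrier_jitter = 0.5,
                          noise_sd = 0.3,
                          angle_gain = default_angle_gain(),
                          group_gain = list(control = c(1, 1, 1),
                                            patient = c(1, 1, 1)),
                          inter_hemi_kappa = Inf,
                          channel_gain = NULL,
                          jitter_ms = 20,
                          blend_ms = 20,
                          drift_rate = 1,
                          subject_sd = 0.1,
                          accuracy = 0.97) {
  kappa <- rep_len(as.numeric(kappa), 3)
  if (any(kappa < 0)) stop("kappa must be nonnegative")
  if (carrier_freq <= 13 || carrier_freq >= 30)
    stop("carrier_freq must lie strictly inside (13, 30) Hz")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (any(unlist(angle_gain) < 0)) stop("angle_gain must be nonnegative")
  if (!all(c("control", "patient") %in% names(group_gain)))
    stop("group_gain must name 'control' and 'patient'")
  group_gain <- lapply(group_gain, function(g) rep_len(as.numeric(g), 3))
  structure(list(kappa = kappa, carrier_freq = carrier_freq,
                 carrier_jitter = carrier_jitter, noise_sd = noise_sd,
                 angle_gain = angle_gain, group_gain = group_gain,
                 inter_hemi_kappa = inter_hemi_kappa,
                 channel_gain = channel_gain,
                 jitter_ms = jitter_ms, blend_ms = blend_ms,
                 drift_rate = drift_rate, subject_sd = subject_sd,
                 accuracy = accuracy),
            class = "coupling_spec")
}

#' Default angle-gain map (peaks at 180 degrees)
#'
#' `1 + 0.15 * (1 - cos(angle)) / 2`: unity at 0 degrees, maximum 1.15 at
#' 180 degrees, symmetric about 180.
#' @return named numeric vector over the six stimulus angles.
#' @export
default_angle_gain <- function() {
  a <- c(0, 60, 120, 180, 240, 300)
  stats::setNames(1 + 0.15 * (1 - cos(pi * a / 180)) / 2, a)
}

#' Preset coupling for the control cohort
#' @return a [coupling_spec] with full coupling in all sub-stages.
#' @export
control_coupling <- function() {
  coupling_spec(kappa = c(1.5, 2, 1.5), inter_hemi_kappa = 1.5,
                accuracy = 0.97)
}

#' Preset coupling for the patient cohort
#'
#' Identical to [control_coupling()] except that coupling is reduced
#' (gain 0.6) in the Middle (mental rotation) sub-stage only, emulating a
#' group effect confined to that window, and response accuracy is lower.
#' @return a [coupling_spec].
#' @export
patient_coupling <- function() {
  coupling_spec(kappa = c(1.5, 2, 1.5), inter_hemi_kappa = 1.5,
                group_gain = list(control = c(1, 1, 1),
                                  patient = c(1, 0.6, 1)),
                accuracy = 0.90)
}

#' Cohort specification
#'
#' @param n_per_group subjects per group (default 11).
#' @param blocks_per_subject named integer vector: blocks of 96 stimuli per
#'   subject, by group (default controls 6, patients 2).
#' @param block_size trials per block.
#' @param seed master cohort seed; every subject, block and trial stream is
#'   derived from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 11,
                        blocks_per_subject = c(control = 6, patient = 2),
                        block_size = 96,
                        seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be at least 2")
  if (any(blocks_per_subject < 1)) stop("blocks must be at least 1")
  if (!all(c("control", "patient") %in% names(blocks_per_subject)))
    stop("blocks_per_subject must name 'control' and 'patient'")
  structure(list(n_per_group = n_per_group,
                 blocks_per_subject = blocks_per_subject,
                 block_size = block_size, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Per-sample effective concentration profile over the trial, raised-cosine
# blended across sub-stage boundaries.
kappa_profile <- function(coupling, n, fs, windows, angle, group,
                          kappa_scale = 1) {
  prof <- numeric(n)
  ag <- coupling$angle_gain[[as.character(angle)]]
  if (is.null(ag)) ag <- 1
  gg <- coupling$group_gain[[group]]
  for (w in seq_along(windows)) {
    i0 <- floor(windows[[w]]$start_ms * fs / 1000) + 1
    i1 <- min(n, ceiling(windows[[w]]$end_ms * fs / 1000))
    prof[i0:i1] <- coupling$kappa[w] * ag * gg[w] * kappa_scale
  }
  blend <- max(1L, round(coupling$blend_ms * fs / 1000))
  if (blend > 1) {
    kern <- 0.5 * (1 - cos(2 * pi * seq_len(blend) / (blend + 1)))
    kern <- kern / sum(kern)
    padded <- c(rep(prof[1], blend), prof, rep(prof[n], blend))
    sm <- stats::filter(padded, kern, sides = 2)
    prof <- as.numeric(sm[(blend + 1):(blend + n)])
  }
  prof
}

#' Generate one synthetic multichannel epoch
#'
#' Channel `i` carries `sin(2 pi f t + theta(t) + delta_h(t) + eps_i(t))`
#' plus white noise, where `theta` is a shared slowly drifting phase,
#' `delta_h` a per-hemisphere offset process (midline channels carry none)
#' and `eps_i` independent von Mises jitter, piecewise constant over
#' `jitter_ms` blocks with concentration following the blended sub-stage
#' profile. Coupled pairs therefore have analytically predictable expected
#' coherence (see [vm_pair_mpc()]).
#'
#' @param hand `"left"` or `"right"` (metadata only; does not alter
#'   coupling).
#' @param angle stimulus rotation angle in degrees.
#' @param coupling a [coupling_spec].
#' @param montage a [montage].
#' @param fs sampling rate (Hz).
#' @param duration_ms trial length (ms); must cover all sub-stage windows.
#' @param group `"control"` or `"patient"`.
#' @param seed integer seed for this trial's draws.
#' @param windows list of sub-stage windows, see [sub_stage_windows()].
#' @param carrier_freq optional per-subject carrier override (Hz).
#' @param kappa_scale per-subject concentration multiplier.
#' @return channels x samples numeric matrix (rows named by montage), with
#'   attribute `phase`: the ground-truth per-channel phase matrix (unwrapped
#'   radians) before noise.
#' @export
generate_epoch <- function(hand, angle, coupling,
                           montage = default_montage(),
                           fs = 1000, duration_ms = 1200,
                           group = "control", seed = 1L,
                           windows = sub_stage_windows(),
                           carrier_freq = NULL, kappa_scale = 1) {
  if (fs <= 0 || duration_ms <= 0) stop("fs and duration_ms must be positive")
  n <- round(duration_ms * fs / 1000)
  if (max(vapply(windows, `[[`, numeric(1), "end_ms")) > duration_ms + 1e-9)
    stop("duration_ms does not cover the sub-stage windows")
  nch <- length(montage$labels)
  f <- if (is.null(carrier_freq)) coupling$carrier_freq else carrier_freq
  tt <- (seq_len(n) - 1) / fs
  prof <- kappa_profile(coupling, n, fs, windows, angle, group, kappa_scale)
  L <- max(1L, round(coupling$jitter_ms * fs / 1000))
  nblk <- ceiling(n / L)
  centers <- pmin(n, round((seq_len(nblk) - 0.5) * L))
  kblk <- prof[centers]
  cg <- rep(1, nch)
  if (!is.null(coupling$channel_gain)) {
    hit <- match(names(coupling$channel_gain), montage$labels)
    cg[hit[!is.na(hit)]] <- coupling$channel_gain[!is.na(hit)]
  }
  with_seed(seed, {
    # per-channel jitter, block-constant
    eps_blk <- matrix(rvonmises(rep(kblk, each = nch) * rep(cg, nblk)),
                      nrow = nch)
    eps <- eps_blk[, rep(seq_len(nblk), each = L)[seq_len(n)], drop = FALSE]
    # per-hemisphere offset
    delta <- matrix(0, 3, n,
                    dimnames = list(c("left", "right", "midline"), NULL))
    if (is.finite(coupling$inter_hemi_kappa)) {
      for (h in c("left", "right")) {
        d <- rvonmises(rep(coupling$inter_hemi_kappa, nblk))
        delta[h, ] <- d[rep(seq_len(nblk), each = L)[seq_len(n)]]
      }
    }
    theta <- cumsum(stats::rnorm(n, 0, coupling$drift_rate / sqrt(fs)))
    phase0 <- stats::runif(1, -pi, pi)
    base <- 2 * pi * f * tt + phase0 + theta
    phase <- sweep(eps + delta[montage$hemisphere, , drop = FALSE], 2,
                   base, "+")
    sig <- sin(phase)
    if (coupling$noise_sd > 0)
      sig <- sig + matrix(stats::rnorm(nch * n, 0, coupling$noise_sd),
                          nch, n)
    rownames(sig) <- montage$labels
    attr(sig, "phase") <- phase
    sig
  })
}

#' Generate one synthetic subject
#'
#' Draws the subject-level parameters (carrier perturbation, concentration
#' multiplier, correct-response flags) from a seed derived from the cohort
#' seed, then generates `blocks` blocks of scheduled trials, each trial from
#' its own derived seed.
#'
#' @param spec a [cohort_spec].
#' @param coupling a [coupling_spec].
#' @param group `"control"` or `"patient"`.
#' @param index subject index within the group (1-based).
#' @param montage a [montage].
#' @param fs,duration_ms sampling rate and trial length.
#' @return an [epoch_set].
#' @export
generate_subject <- function(spec, coupling, group, index,
                             montage = default_montage(),
                             fs = 1000, duration_ms = 1200) {
  gi <- match(group, c("control", "patient"))
  if (is.na(gi)) stop("group must be 'control' or 'patient'")
  sseed <- derive_seed(spec$seed, gi, index)
  blocks <- spec$blocks_per_subject[[group]]
  subj <- with_seed(sseed, list(
    carrier = coupling$carrier_freq +
      stats::runif(1, -coupling$carrier_jitter, coupling$carrier_jitter),
    kscale = exp(stats::rnorm(1, 0, coupling$subject_sd))))
  meta <- do.call(rbind, lapply(seq_len(blocks), function(b) {
    s <- make_schedule(spec$block_size, seed = derive_seed(sseed, 1000L, b))
    data.frame(block = b, hand = s$hand, angle = s$angle,
               stringsAsFactors = FALSE)
  }))
  meta$trial <- seq_len(nrow(meta))
  meta$correct <- with_seed(derive_seed(sseed, 2000L, 0L),
                            stats::runif(nrow(meta)) < coupling$accuracy)
  n <- round(duration_ms * fs / 1000)
  data <- array(0, c(nrow(meta), length(montage$labels), n))
  for (i in seq_len(nrow(meta))) {
    data[i, , ] <- generate_epoch(
      meta$hand[i], meta$angle[i], coupling, montage, fs, duration_ms,
      group = group, seed = derive_seed(sseed, 3000L + meta$block[i], i),
      carrier_freq = subj$carrier, kappa_scale = subj$kscale)
  }
  id <- sprintf("%s%02d", if (group == "control") "C" else "P", index)
  epoch_set(data, fs, montage, meta, subject_id = id, group = group)
}

#' Generate a two-group synthetic cohort
#'
#' @param spec a [cohort_spec].
#' @param control_coupling,patient_coupling [coupling_spec]s for the two
#'   groups.
#' @param montage a [montage].
#' @param fs,duration_ms sampling rate and trial length.
#' @return named list of [epoch_set]s (controls first). For the full
#'   default design this is large (~2 GB); prefer streaming per subject via
#'   [generate_subject()] as [run_pipeline()] does.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            control_coupling = synchnet::control_coupling(),
                            patient_coupling = synchnet::patient_coupling(),
                            montage = default_montage(),
                            fs = 1000, duration_ms = 1200) {
  subjects <- list()
  for (group in c("control", "patient")) {
    cp <- if (group == "control") control_coupling else patient_coupling
    for (i in seq_len(spec$n_per_group)) {
      es <- generate_subject(spec, cp, group, i, montage, fs, duration_ms)
      subjects[[es$subject_id]] <- es
    }
  }
  subjects
}
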