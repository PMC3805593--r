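# Small in-code fixtures shared across test files.

tiny_montage <- function(n = 4) {
  montage(paste0("ch", seq_len(n)),
          rep(c("left", "right"), length.out = n))
}

# epoch_set with deterministic, fully controllable contents
tiny_epochs <- function(n_trials = 4, n_channels = 4, n_samples = 100,
                        fs = 1000, fill = function(t, c, s) s,
                        correct = rep(TRUE, n_trials),
                        hands = rep(c("left", "right"),
                                    length.out = n_trials),
                        angles = rep(0, n_trials)) {
  data <- array(0, c(n_trials, n_channels, n_samples))
  for (tr in seq_len(n_trials)) for (ch in seq_len(n_channels))
    data[tr, ch, ] <- fill(tr, ch, seq_len(n_samples))
  epoch_set(data, fs, tiny_montage(n_channels),
            data.frame(trial = seq_len(n_trials), hand = hands,
                       angle = angles, correct = correct,
                       stringsAsFactors = FALSE))
}

# balanced long table for the factorial statistics
balanced_table <- function(n_subj = 22, within = list(
                             hemisphere = c("left", "right", "inter"),
                             angle = c(0, 60, 120, 180, 240, 300),
                             hand = c("left", "right")),
                           effect = function(d) 0, seed = 1) {
  d <- do.call(expand.grid, c(list(subject = sprintf("s%02d",
                                                     seq_len(n_subj))),
                              within,
                              list(stringsAsFactors = FALSE)))
  d$subject <- as.character(d$subject)
  d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= n_subj / 2,
                    "control", "patient")
  set.seed(seed)
  d$value <- rnorm(nrow(d), sd = 1) + effect(d)
  d
}

# one-block coupling with everything neutral except kappa (for recovery
# tests): no angle/group modulation, no hemisphere offset, no noise
flat_coupling <- function(kappa, noise_sd = 0, inter = Inf) {
  coupling_spec(kappa = kappa, noise_sd = noise_sd,
                angle_gain = setNames(rep(1, 6),
                                      c(0, 60, 120, 180, 240, 300)),
                inter_hemi_kappa = inter, subject_sd = 0)
}
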