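#' Build a randomized stimulus schedule
#'
#' Constructs the exact multiset of (hand, angle) stimulus types implied by a
#' block size and a table of angle probabilities, balances hands within every
#' angle, and returns a seeded random permutation of it. Counts are exact by
#' construction; only the presentation order is random.
#'
#' The default probabilities reproduce the mental-rotation block design:
#' 96 stimuli per block, angles 0 and 180 degrees at 25%, the four oblique
#' angles at 12.5% each, half the trials per hand.
#'
#' @param block_size number of trials in one block (default 96).
#' @param probabilities named numeric vector, angle (degrees) -> fraction.
#'   Must sum to 1 and give integer expected counts; each angle count must
#'   be even so hands can be balanced exactly.
#' @param seed integer seed for the permutation.
#' @return An object of class `stimulus_schedule`: a data.frame with columns
#'   `trial`, `hand` (`"left"`/`"right"`) and `angle` (degrees), plus
#'   attribute `block_size`.
#' @examples
#' s <- make_schedule(seed = 1)
#' table(s$hand)              # 48 / 48
#' table(s$angle)[c("0","180")] # 24 / 24
#' @export
make_schedule <- function(block_size = 96,
                          probabilities = c("0" = 0.25, "60" = 0.125,
                                            "120" = 0.125, "180" = 0.25,
                                            "240" = 0.125, "300" = 0.125),
                          seed = 1L) {
  if (block_size < 1) stop("block_size must be positive")
  if (abs(sum(probabilities) - 1) > 1e-9)
    stop("probabilities must sum to 1 (got ", sum(probabilities), ")")
  counts <- block_size * probabilities
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("block_size * probability must be an integer for every angle; ",
         "offending angle(s): ",
         paste(names(counts)[abs(counts - round(counts)) > 1e-9],
               collapse = ", "))
  counts <- round(counts)
  if (any(counts %% 2 != 0))
    stop("per-angle counts must be even to balance left/right hands; ",
         "offending angle(s): ",
         paste(names(counts)[counts %% 2 != 0], collapse = ", "))
  angles <- as.numeric(names(probabilities))
  hand <- unlist(lapply(seq_along(angles), function(k)
    rep(c("left", "right"), each = counts[k] / 2)))
  angle <- rep(angles, counts)
  ord <- with_seed(seed, sample.int(length(angle)))
  out <- data.frame(trial = seq_along(angle),
                    hand = hand[ord], angle = angle[ord],
                    stringsAsFactors = FALSE)
  attr(out, "block_size") <- block_size
  class(out) <- c("stimulus_schedule", "data.frame")
  out
}
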