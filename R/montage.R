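#' Electrode montage
#'
#' A montage is an ordered set of channel labels together with a hemisphere
#' assignment (`left`, `right` or `midline`) for every channel. Hemisphere
#' membership drives the intra-/inter-hemispheric summaries of the
#' association matrices.
#'
#' @param labels character vector of unique channel labels.
#' @param hemisphere character vector, same length as `labels`, each element
#'   one of `"left"`, `"right"`, `"midline"`. If `NULL`, hemispheres are
#'   inferred from the 10-20 naming convention: odd digit suffix = left,
#'   even digit = right, trailing `z` = midline.
#' @return An object of class `montage`: a list with `labels` and
#'   `hemisphere` (named character vector).
#' @seealso [default_montage()]
#' @export
montage <- function(labels, hemisphere = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels))
    stop("montage labels must be unique")
  if (is.null(hemisphere)) {
    hemisphere <- vapply(labels, infer_hemisphere, character(1))
  } else {
    hemisphere <- as.character(hemisphere)
    if (length(hemisphere) != length(labels))
      stop("hemisphere must have one entry per label")
  }
  bad <- !hemisphere %in% c("left", "right", "midline")
  if (any(bad))
    stop("unmapped hemisphere for channel(s): ",
         paste(labels[bad], collapse = ", "))
  names(hemisphere) <- labels
  structure(list(labels = labels, hemisphere = hemisphere),
            class = "montage")
}

# 10-20 convention: trailing z -> midline, odd final digit -> left, even -> right
infer_hemisphere <- function(label) {
  if (grepl("z$", label, ignore.case = TRUE)) return("midline")
  d <- regmatches(label, regexpr("[0-9]+$", label))
  if (length(d) == 0) stop("cannot infer hemisphere for channel ", label)
  if (as.integer(d) %% 2 == 1) "left" else "right"
}

#' Default 28-channel 10-20 montage
#'
#' The default scalp layout used throughout the package: a 32-electrode cap
#' minus reference, mastoid and ocular leads, leaving 28 analysis channels
#' (12 left, 12 right, 4 midline). User-supplied montages are accepted by
#' every function that takes one, so this reconstruction is overridable.
#'
#' @return A [montage] with 28 channels.
#' @examples
#' m <- default_montage()
#' length(m$labels)            # 28
#' m$hemisphere[["Fz"]]        # "midline"
#' @export
default_montage <- function() {
  montage(c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
            "FC5", "FC1", "FC2", "FC6",
            "T7", "C3", "Cz", "C4", "T8",
            "CP5", "CP1", "CP2", "CP6",
            "P7", "P3", "Pz", "P4", "P8",
            "O1", "Oz", "O2"))
}

#' Hemispheric channel-pair classes
#'
#' Enumerates the unordered channel pairs of a montage and classifies each
#' as left intra-hemispheric, right intra-hemispheric or inter-hemispheric.
#' Pairs that involve a midline channel belong to no class (midline channels
#' are excluded from the hemispheric summaries).
#'
#' @param montage a [montage].
#' @return A data.frame with columns `i`, `j` (1-based channel indices,
#'   `i < j`) and `class` (`"left"`, `"right"`, `"inter"` or `"none"`).
#' @export
hemisphere_pairs <- function(montage) {
  stopifnot(inherits(montage, "montage"))
  n <- length(montage$labels)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  hi <- montage$hemisphere[i]; hj <- montage$hemisphere[j]
  cls <- rep("none", length(i))
  cls[hi == "left"  & hj == "left"]  <- "left"
  cls[hi == "right" & hj == "right"] <- "right"
  cls[(hi == "left" & hj == "right") | (hi == "right" & hj == "left")] <- "inter"
  data.frame(i = i, j = j, class = cls, stringsAsFactors = FALSE)
}

#' @export
print.montage <- function(x, ...) {
  tab <- table(factor(x$hemisphere, c("left", "right", "midline")))
  cat(sprintf("<montage> %d channels (%d left, %d right, %d midline)\n",
              length(x$labels), tab[["left"]], tab[["right"]],
              tab[["midline"]]))
  cat(" ", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}
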