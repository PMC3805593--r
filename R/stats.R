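#' Mixed-design repeated-measures ANOVA
#'
#' Fits the study's factorial model: one between-subjects factor (GROUP)
#' and one or more within-subjects factors, using the classical balanced
#' sums-of-squares decomposition (each within effect and its GROUP
#' interaction tested against the subject-within-group x effect stratum
#' -- the same partition `aov()` produces with
#' `Error(subject/(w1*w2*...))`, but in O(n) time). The design must be
#' complete and balanced within subjects (exactly one value per subject per
#' within-cell); aggregate replicate records before calling. No sphericity
#' correction is applied (the df are the uncorrected integers of the
#' design).
#'
#' @param table data.frame in long format.
#' @param dv name of the dependent-variable column (default `"value"`).
#' @param between name of the between-subjects factor column (default
#'   `"group"`).
#' @param within character vector of within-subjects factor columns.
#' @param subject name of the subject-identifier column.
#' @return data.frame of class `anova_result` with columns `effect`, `df1`,
#'   `df2`, `F`, `p` (main effects, between x within interactions and
#'   within-only interactions). Zero-variance strata yield `NA` F/p and a
#'   `degenerate` attribute.
#' @examples
#' d <- expand.grid(subject = paste0("s", 1:6), hemi = c("L", "R", "I"))
#' d$group <- ifelse(d$subject %in% paste0("s", 1:3), "control", "patient")
#' d$value <- rnorm(nrow(d))
#' rm_anova(d, within = "hemi")
#' @export
rm_anova <- function(table, dv = "value", between = "group",
                     within, subject = "subject") {
  need <- c(dv, between, within, subject)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- data.frame(
    .y = as.numeric(table[[dv]]),
    .subj = factor(table[[subject]]),
    .grp = factor(table[[between]]),
    stringsAsFactors = FALSE)
  for (w in within) df[[w]] <- factor(table[[w]])
  if (nlevels(df$.grp) < 2) stop("need at least 2 groups")
  # every subject must have exactly one record per within-cell
  cell <- interaction(df[within], drop = FALSE)
  tab <- table(df$.subj, cell)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    lab <- apply(bad, 1, function(r)
      paste0(rownames(tab)[r[1]], ":", colnames(tab)[r[2]],
             " (n=", tab[r[1], r[2]], ")"))
    stop("unbalanced design; offending subject:cell entries: ",
         paste(utils::head(lab, 10), collapse = ", "),
         if (length(lab) > 10) ", ..." else "")
  }
  # subjects nested in exactly one group
  gtab <- table(df$.subj, df$.grp) > 0
  if (any(rowSums(gtab) != 1))
    stop("each subject must belong to exactly one group")
  if (any(colSums(gtab) < 2)) stop("need >= 2 subjects per group")
  res <- balanced_mixed_anova(df, within, label = toupper(between))
  class(res) <- c("anova_result", "data.frame")
  res
}

# Classical sums-of-squares decomposition for a balanced mixed design
# (one observation per subject x within-cell, subjects nested in groups).
# Exact for balanced data -- identical to the aov()/Error() fit, which the
# test suite uses as an independent oracle -- but runs in O(n) instead of
# a large QR, which matters for the 28-level channel factor.
balanced_mixed_anova <- function(df, within, label = "GROUP") {
  y <- df$.y
  N <- length(y)
  grand <- sum(y)^2 / N
  raw <- function(cols) {
    # sum over cells of (cell sum)^2 / cell size
    if (length(cols) == 0) return(grand)
    f <- interaction(df[cols], drop = TRUE)
    s <- rowsum(y, f)
    n <- tabulate(f)
    sum(s^2 / n[n > 0])
  }
  nlev <- vapply(within, function(w) nlevels(df[[w]]), integer(1))
  names(nlev) <- within
  nsub <- nlevels(df$.subj)
  ngrp <- nlevels(df$.grp)
  subsets <- unlist(lapply(0:length(within), function(k)
    utils::combn(within, k, simplify = FALSE)), recursive = FALSE)
  keyof <- function(A) if (length(A) == 0) ".empty" else
    paste(A, collapse = ":")
  ssW <- list(); ssG <- list(); ssE <- list()
  for (A in subsets) {
    k <- keyof(A)
    subs <- Filter(function(U) length(U) < length(A) &&
                     all(U %in% A), subsets)
    ssW[[k]] <- if (length(A) == 0) 0 else
      raw(A) - grand - sum(vapply(subs, function(U)
        ssW[[keyof(U)]], numeric(1)))
    ssG[[k]] <- raw(c(".grp", A)) - grand -
      sum(vapply(subs, function(U)
        ssW[[keyof(U)]] + ssG[[keyof(U)]], numeric(1))) - ssW[[k]]
    ssE[[k]] <- raw(c(".subj", A)) - grand -
      sum(vapply(subs, function(U)
        ssW[[keyof(U)]] + ssG[[keyof(U)]] + ssE[[keyof(U)]],
        numeric(1))) - ssW[[k]] - ssG[[k]]
  }
  scale0 <- sum(y^2) / N + 1e-300
  rows <- list(); degen <- character(0)
  push <- function(effect, ss1, df1, ss2, df2) {
    ms1 <- ss1 / df1; ms2 <- ss2 / df2
    if (ms2 <= scale0 * 1e-12) {
      degen <<- c(degen, effect)
      Fv <- NA_real_; pv <- NA_real_
    } else {
      Fv <- ms1 / ms2
      pv <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    }
    rows[[length(rows) + 1]] <<- data.frame(
      effect = effect, df1 = df1, df2 = df2, F = Fv, p = pv,
      stringsAsFactors = FALSE)
  }
  for (A in subsets) {
    k <- keyof(A)
    dfA <- prod(nlev[A] - 1) # empty product = 1
    dfE <- (nsub - ngrp) * dfA
    if (length(A) == 0) {
      push(label, ssG[[k]], ngrp - 1, ssE[[k]], nsub - ngrp)
    } else {
      nm <- paste(A, collapse = " x ")
      push(nm, ssW[[k]], dfA, ssE[[k]], dfE)
      push(paste(label, "x", nm), ssG[[k]], (ngrp - 1) * dfA,
           ssE[[k]], dfE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "degenerate") <- degen
  res
}

#' Per-key two-sample t-tests
#'
#' Runs one two-sided two-sample t-test (control vs patient) for every
#' level of a grouping key, e.g. per threshold k or per channel, and
#' returns the p-values ready for FDR correction. Pooled-variance by
#' default (Welch selectable).
#'
#' @param table long data.frame.
#' @param dv dependent-variable column name.
#' @param between two-level group column name.
#' @param by column whose levels index the tests.
#' @param var_equal `TRUE` for the pooled-variance test (default),
#'   `FALSE` for Welch.
#' @return data.frame with one row per key: `key`, `t`, `df`, `p`,
#'   `mean_1`, `mean_2` (group order = factor level order). Degenerate
#'   (zero-variance) keys get `NA` with a warning.
#' @export
posthoc_t <- function(table, dv = "value", between = "group", by,
                      var_equal = TRUE) {
  g <- factor(table[[between]])
  if (nlevels(g) != 2) stop("between factor must have exactly 2 levels")
  keys <- unique(table[[by]])
  rows <- lapply(keys, function(k) {
    sel <- table[[by]] == k
    y <- as.numeric(table[[dv]][sel]); gg <- g[sel]
    if (min(table(gg)) < 2)
      stop("need >= 2 observations per group for key ", k)
    tt <- tryCatch(stats::t.test(y ~ gg, var.equal = var_equal),
                   error = function(e) NULL)
    if (is.null(tt)) {
      warning("degenerate (zero-variance) samples for key ", k)
      return(data.frame(key = k, t = NA_real_, df = NA_real_, p = NA_real_,
                        mean_1 = mean(y[gg == levels(gg)[1]]),
                        mean_2 = mean(y[gg == levels(gg)[2]])))
    }
    data.frame(key = k, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               mean_1 = unname(tt$estimate[1]),
               mean_2 = unname(tt$estimate[2]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR step-up procedure
#'
#' Sorts the p-values ascending, finds the largest rank `i` with
#' `p_(i) <= (i/m) q`, and rejects every hypothesis with p-value up to
#' `p_(i)`. The rejection set is returned as a mask in the original input
#' order together with the adaptive cutoff.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return object of class `fdr_result`: list with `p`, `q`, `reject`
#'   (logical mask), `cutoff` (largest rejected p-value; 0 if none) and
#'   `n_reject`.
#' @examples
#' fdr_bh(c(0.001, 0.2, 0.9))$reject  # TRUE FALSE FALSE
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (length(p) == 0) stop("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= (seq_len(m) / m) * q)
  cutoff <- if (length(ok)) ps[max(ok)] else 0
  reject <- p <= cutoff & length(ok) > 0
  structure(list(p = p, q = q, reject = reject, cutoff = cutoff,
                 n_reject = sum(reject)),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("<fdr_result> %d/%d rejected at q = %g (cutoff %.4g)\n",
              x$n_reject, length(x$p), x$q, x$cutoff))
  invisible(x)
}
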