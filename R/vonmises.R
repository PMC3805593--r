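#' Sample von Mises phase angles
#'
#' Draws one angle per element of `kappa` from the von Mises distribution
#' with mean 0 and the given concentration, using the Best-Fisher (1979)
#' rejection sampler. `kappa = 0` falls back to the circular uniform,
#' `kappa = Inf` to a point mass at 0.
#'
#' @param kappa numeric vector of nonnegative concentrations (recycled
#'   against `n` if `n` is given).
#' @param n optional number of draws; default `length(kappa)`.
#' @return numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(kappa, n = length(kappa)) {
  kappa <- rep_len(as.numeric(kappa), n)
  if (any(kappa < 0)) stop("kappa must be nonnegative")
  out <- numeric(n)
  inf <- is.infinite(kappa)
  out[inf] <- 0
  unif <- !inf & kappa < 1e-7
  out[unif] <- stats::runif(sum(unif), -pi, pi)
  todo <- which(!inf & !unif)
  if (length(todo)) {
    k <- kappa[todo]
    tau <- 1 + sqrt(1 + 4 * k^2)
    rho <- (tau - sqrt(2 * tau)) / (2 * k)
    r <- (1 + rho^2) / (2 * rho)
    theta <- numeric(length(todo))
    pend <- seq_along(todo)
    while (length(pend)) {
      u1 <- stats::runif(length(pend))
      u2 <- stats::runif(length(pend))
      z <- cos(pi * u1)
      f <- (1 + r[pend] * z) / (r[pend] + z)
      cc <- k[pend] * (r[pend] - f)
      ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
      if (any(ok)) {
        u3 <- stats::runif(sum(ok))
        theta[pend[ok]] <- sign(u3 - 0.5) * acos(pmax(-1, pmin(1, f[ok])))
      }
      pend <- pend[!ok]
    }
    out[todo] <- theta
  }
  out
}

#' Mean resultant length of the von Mises distribution
#'
#' `A(kappa) = I1(kappa) / I0(kappa)`, the expected value of `cos(theta)`
#' for a von Mises angle. Computed with exponentially scaled Bessel
#' functions so large concentrations do not overflow.
#'
#' @param kappa nonnegative concentration(s).
#' @param nu harmonic order: `vm_resultant(kappa, nu)` returns
#'   `I_nu(kappa) / I0(kappa)`, i.e. `E cos(nu * theta)`.
#' @return numeric vector in `[0, 1]`.
#' @export
vm_resultant <- function(kappa, nu = 1) {
  out <- ifelse(is.infinite(kappa), 1,
                besselI(kappa, nu, expon.scaled = TRUE) /
                  besselI(kappa, 0, expon.scaled = TRUE))
  out[kappa == 0] <- as.numeric(nu == 0)
  out
}

#' Asymptotic expected pairwise coherence of the jitter model
#'
#' Under the shared-oscillator model two channels with independent von
#' Mises jitter (concentrations `kappa1`, `kappa2`) have phase-difference
#' mean resultant length `A(kappa1) * A(kappa2)`; an inter-hemispheric pair
#' additionally picks up the resultant of the hemisphere offset difference.
#' This is the infinite-sample limit of the mean phase coherence; the
#' finite-sample estimator is biased upward by O(n^-1/2).
#'
#' @param kappa1,kappa2 channel jitter concentrations.
#' @param inter_kappa hemisphere-offset concentration for inter-hemispheric
#'   pairs (`Inf` = same hemisphere, the default).
#' @return expected asymptotic MPC in `[0, 1]`.
#' @export
vm_pair_mpc <- function(kappa1, kappa2, inter_kappa = Inf) {
  vm_resultant(kappa1) * vm_resultant(kappa2) * vm_resultant(inter_kappa)^2
}
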