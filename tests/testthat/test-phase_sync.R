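fs <- 1000
tt <- (0:1199) / fs

test_that("analytic phase advances at the carrier rate", {
  x <- cos(2 * pi * 20 * tt)
  ph <- Arg(analytic_signal(x))
  d <- diff(ph[200:1000])
  d <- (d + pi) %% (2 * pi) - pi
  slope <- mean(d) * fs
  expect_lt(abs(slope - 2 * pi * 20) / (2 * pi * 20), 0.01)
})

test_that("sin and cos phases differ by a constant pi/2", {
  pc <- Arg(analytic_signal(cos(2 * pi * 20 * tt)))
  ps <- Arg(analytic_signal(sin(2 * pi * 20 * tt)))
  off <- (pc - ps)[300:900]
  off <- (off + pi) %% (2 * pi) - pi
  expect_lt(max(abs(off - pi / 2)), 1e-6)
})

test_that("phase is amplitude-invariant", {
  x <- sin(2 * pi * 17 * tt) + 0.3 * sin(2 * pi * 25 * tt)
  expect_equal(Arg(analytic_signal(x)), Arg(analytic_signal(7.3 * x)),
               tolerance = 1e-12)
})

test_that("mpc matches its defining examples", {
  p <- seq(0, 30, by = 0.01)
  expect_equal(mpc(p, p + 0.7), 1)
  expect_equal(mpc(p, p - 2.3), 1)
  alt <- rep(c(0, pi), 50)
  expect_lt(mpc(rep(0, 100), alt), 1e-12)
  # {0, pi/2} alternating difference -> |(1 + i)/2| = sqrt(2)/2
  d <- rep(c(0, pi / 2), 50)
  expect_equal(mpc(d, rep(0, 100)), sqrt(2) / 2, tolerance = 1e-12)
  expect_error(mpc(1:3, 1:4), "equal length")
  expect_error(mpc(1, 1), "at least 2")
})

test_that("mpc is invariant to global offsets and time reversal", {
  set.seed(2)
  for (i in 1:20) {
    a <- runif(200, -pi, pi); b <- runif(200, -pi, pi)
    v <- mpc(a, b)
    expect_equal(mpc(a + 1.1, b), v, tolerance = 1e-12)
    expect_equal(mpc(a, b + 5), v, tolerance = 1e-12)
    expect_equal(mpc(rev(a), rev(b)), v, tolerance = 1e-12)
  }
})

test_that("empirical mpc of von Mises jitter matches integration oracle", {
  set.seed(31)
  for (k in c(0.5, 2)) {
    v <- replicate(200, mpc(rvonmises(rep(k, 500)),
                            rvonmises(rep(k, 500))))
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - oracle_expected_mpc(k, k, 500)), 3 * se)
  }
})

test_that("psi_matrix fills all pairs symmetrically with zero diagonal", {
  set.seed(3)
  ph <- matrix(runif(5 * 300, -pi, pi), 5,
               dimnames = list(paste0("c", 1:5), NULL))
  ph[2, ] <- ph[1, ] # identical channels
  M <- psi_matrix(ph)
  expect_equal(M[1, 2], 1)
  expect_identical(M, t(M))
  expect_equal(diag(M), setNames(rep(0, 5), paste0("c", 1:5)))
  expect_true(all(M >= 0 & M <= 1))
  # relabeling equivariance
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(unname(psi_matrix(ph[perm, ])), unname(M[perm, perm]),
               tolerance = 1e-12)
})

test_that("independent uniform phases give near-zero entries", {
  set.seed(4)
  vals <- replicate(100, {
    ph <- matrix(runif(4 * 500, -pi, pi), 4)
    M <- psi_matrix(ph)
    mean(M[upper.tri(M)])
  })
  expect_lt(mean(vals), 0.15)
})

test_that("psi_matrix performs exactly n(n-1)/2 mpc evaluations", {
  calls <- 0L
  local_mocked_bindings(
    mpc = function(phi1, phi2) {
      calls <<- calls + 1L
      Mod(mean(exp(1i * (phi1 - phi2))))
    },
    .package = "synchnet")
  ph <- matrix(runif(6 * 50, -pi, pi), 6)
  psi_matrix(ph)
  expect_equal(calls, 6 * 5 / 2)
})

test_that("the vectorised PSI path equals the per-pair path", {
  set.seed(6)
  arr <- array(runif(3 * 5 * 200, -pi, pi), c(3, 5, 200))
  fast <- synchnet:::psi_matrices_fast(arr)
  for (i in 1:3) {
    slow <- psi_matrix(arr[i, , ])
    expect_equal(unname(fast[[i]]), unname(slow), tolerance = 1e-12)
  }
})

test_that("all-zero channels propagate as missing pairs", {
  es <- tiny_epochs(1, 3, 400, fill = function(t, c, s)
    if (c == 2) 0 else sin(2 * pi * 20 * (s - 1) / 1000))
  ph <- analytic_phase(es)
  expect_true(all(is.na(ph$data[1, 2, ])))
  M <- psi_matrix(ph$data[1, , ])
  expect_true(is.na(M[1, 2]) && is.na(M[2, 3]))
  expect_false(is.na(M[1, 3]))
  fastM <- synchnet:::psi_matrices_fast(ph$data)[[1]]
  expect_true(is.na(fastM[1, 2]) && !is.na(fastM[1, 3]))
})

test_that("average_by_type averages within the 12 design cells", {
  m1 <- matrix(0.2, 3, 3); m2 <- matrix(0.4, 3, 3)
  meta <- data.frame(hand = c("left", "left"), angle = c(0, 0))
  avg <- suppressWarnings(average_by_type(list(m1, m2), meta))
  expect_equal(avg[["left_0"]], matrix(0.3, 3, 3))
  expect_equal(sum(!vapply(avg, is.null, logical(1))), 1)
  expect_length(avg, 12)
  # idempotence
  avg2 <- suppressWarnings(average_by_type(list(m1, m1), meta))
  expect_equal(avg2[["left_0"]], m1)
  # a full synthetic block covers all 12 cells
  s <- make_schedule(seed = 8)
  mats <- lapply(seq_len(96), function(i) matrix(i / 96, 2, 2))
  full <- average_by_type(mats, s)
  expect_length(full, 12)
  expect_true(all(!vapply(full, is.null, logical(1))))
  expect_equal(unname(attr(full, "n_trials")[c("left_0", "right_180")]),
               c(12L, 12L))
})

test_that("empty cells warn and stay missing", {
  meta <- data.frame(hand = "left", angle = 0)
  expect_warning(avg <- average_by_type(list(matrix(1, 2, 2)), meta),
                 "right_0")
  expect_null(avg[["right_0"]])
  expect_error(average_by_type(list(matrix(1, 2, 2)),
                               data.frame(hand = c("l", "r"),
                                          angle = c(0, 0))),
               "one metadata row")
})

test_that("hemispheric summary averages the three disjoint pair classes", {
  m <- default_montage()
  M <- matrix(0.37, 28, 28, dimnames = list(m$labels, m$labels))
  diag(M) <- 0
  h <- hemispheric_summary(M, m)
  expect_equal(unname(h), rep(0.37, 3))
  # indicator: left-left pairs 1, everything else 0
  hp <- hemisphere_pairs(m)
  M2 <- matrix(0, 28, 28, dimnames = list(m$labels, m$labels))
  ll <- hp[hp$class == "left", ]
  M2[cbind(ll$i, ll$j)] <- 1
  M2 <- M2 + t(M2)
  expect_equal(unname(hemispheric_summary(M2, m)), c(1, 0, 0))
  expect_error(hemispheric_summary(matrix(0, 3, 3), m), "size")
})
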