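test_that("rm_anova reproduces the aov()/Error() fit exactly", {
  d <- balanced_table(n_subj = 8,
                      within = list(hemisphere = c("L", "R", "I"),
                                    hand = c("l", "r")),
                      effect = function(d)
                        0.5 * (d$hemisphere == "I") +
                        0.3 * (d$group == "patient") *
                          (d$hand == "r"),
                      seed = 21)
  a <- rm_anova(d, within = c("hemisphere", "hand"))
  d2 <- d
  for (cc in c("subject", "group", "hemisphere", "hand"))
    d2[[cc]] <- factor(d2[[cc]])
  fit <- suppressWarnings(stats::aov(
    value ~ group * hemisphere * hand +
      Error(subject / (hemisphere * hand)), data = d2))
  oracle <- list()
  for (st in summary(fit)) {
    tb <- st[[1]]
    rn <- trimws(rownames(tb))
    for (r in which(rn != "Residuals")) {
      key <- gsub(":", " x ", gsub("group", "GROUP", rn[r]))
      oracle[[key]] <- c(tb[r, "F value"], tb[r, "Pr(>F)"],
                         tb[r, "Df"], tb[rn == "Residuals", "Df"])
    }
  }
  expect_equal(nrow(a), length(oracle))
  for (i in seq_len(nrow(a))) {
    o <- oracle[[a$effect[i]]]
    expect_false(is.null(o), info = a$effect[i])
    expect_equal(a$F[i], o[1], tolerance = 1e-10, info = a$effect[i])
    expect_equal(a$p[i], o[2], tolerance = 1e-10, info = a$effect[i])
    expect_equal(a$df1[i], o[3])
    expect_equal(a$df2[i], o[4])
  }
})

test_that("design df match the printed 22-subject patterns", {
  d <- balanced_table(n_subj = 22)
  a <- rm_anova(d, within = c("hemisphere", "angle", "hand"))
  get <- function(e) unlist(a[a$effect == e, c("df1", "df2")])
  expect_equal(unname(get("GROUP")), c(1, 20))
  expect_equal(unname(get("hemisphere")), c(2, 40))
  expect_equal(unname(get("angle")), c(5, 100))
  expect_equal(unname(get("hand")), c(1, 20))
  expect_equal(unname(get("GROUP x hemisphere")), c(2, 40))
  # 28-level channel factor -> (27, 540)
  dc <- balanced_table(n_subj = 22,
                       within = list(hand = c("l", "r"),
                                     angle = c(0, 60, 120, 180, 240, 300),
                                     channel = sprintf("c%02d", 1:28)))
  ac <- rm_anova(dc, within = c("hand", "angle", "channel"))
  expect_equal(unname(unlist(
    ac[ac$effect == "channel", c("df1", "df2")])), c(27, 540))
})

test_that("unbalanced or malformed designs fail loudly", {
  d <- balanced_table(n_subj = 6, within = list(hand = c("l", "r")))
  expect_error(rm_anova(d[-1, ], within = "hand"), "unbalanced")
  expect_error(rm_anova(d, within = "hand", dv = "nope"), "missing column")
  d2 <- d; d2$group[1] <- "patient" # subject in two groups
  expect_error(rm_anova(d2, within = "hand"), "exactly one group")
  d3 <- d; d3$group <- "control"
  expect_error(rm_anova(d3, within = "hand"), "2 groups")
})

test_that("zero-variance designs degrade to flagged NA", {
  d <- balanced_table(n_subj = 6, within = list(hand = c("l", "r")))
  d$value <- 3.14
  a <- rm_anova(d, within = "hand")
  expect_true(all(is.na(a$F)))
  expect_true(length(attr(a, "degenerate")) > 0)
})

test_that("GROUP test keeps its nominal level on null data", {
  hits <- 0
  for (s in 1:200) {
    d <- balanced_table(n_subj = 22,
                        within = list(hemisphere = c("L", "R", "I")),
                        seed = 500 + s)
    a <- rm_anova(d, within = "hemisphere")
    if (a$p[a$effect == "GROUP"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.02)
  expect_lte(hits / 200, 0.08)
})

test_that("posthoc_t matches the textbook pooled t", {
  set.seed(22)
  tab <- data.frame(
    group = rep(c("control", "patient"), each = 11, times = 7),
    k = rep(seq(90, 180, 15), each = 22),
    value = rnorm(154))
  res <- posthoc_t(tab, by = "k")
  expect_equal(nrow(res), 7) # one test per threshold
  for (i in seq_len(7)) {
    kk <- res$key[i]
    x <- tab$value[tab$k == kk & tab$group == "control"]
    y <- tab$value[tab$k == kk & tab$group == "patient"]
    o <- oracle_t_pooled(x, y)
    expect_equal(res$t[i], o$t, tolerance = 1e-12)
    expect_equal(res$p[i], o$p, tolerance = 1e-12)
    expect_equal(res$df[i], o$df)
  }
})

test_that("posthoc_t handles identical, separated and degenerate input", {
  base <- data.frame(group = rep(c("a", "b"), each = 5), key = 1,
                     value = c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5))
  r <- posthoc_t(base, by = "key")
  expect_equal(r$p, 1, tolerance = 1e-12)
  # 5 pooled SDs apart, n = 11 per group
  set.seed(23)
  x <- rnorm(11); y <- rnorm(11) + 5 * sd(c(x, rnorm(11)))
  tab <- data.frame(group = rep(c("a", "b"), each = 11), key = "t",
                    value = c(x, y))
  expect_lt(posthoc_t(tab, by = "key")$p, 0.001)
  # Welch differs from pooled under unequal variance
  set.seed(24)
  tab2 <- data.frame(group = rep(c("a", "b"), c(6, 12)), key = 1,
                     value = c(rnorm(6, sd = 4), rnorm(12, sd = 0.5)))
  expect_false(isTRUE(all.equal(
    posthoc_t(tab2, by = "key")$p,
    posthoc_t(tab2, by = "key", var_equal = FALSE)$p)))
  const <- data.frame(group = rep(c("a", "b"), each = 3), key = 1,
                      value = rep(2, 6))
  expect_warning(rc <- posthoc_t(const, by = "key"), "degenerate")
  expect_true(is.na(rc$p))
  expect_error(posthoc_t(base[1:6, ], by = "key"), ">= 2 observations")
})

test_that("fdr_bh implements the exact step-up rule", {
  r <- fdr_bh(c(0.001, 0.2, 0.9), 0.05)
  expect_identical(r$reject, c(TRUE, FALSE, FALSE))
  expect_equal(r$cutoff, 0.001)
  expect_identical(fdr_bh(rep(1, 5))$reject, rep(FALSE, 5))
  expect_identical(fdr_bh(rep(0, 5))$reject, rep(TRUE, 5))
  expect_error(fdr_bh(numeric(0)), "empty")
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(25)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_identical(fdr_bh(p, 0.05)$reject, oracle_bh(p, 0.05))
    expect_identical(fdr_bh(p, 0.2)$reject, oracle_bh(p, 0.2))
  }
})

test_that("BH rejections are monotone in q and componentwise in p", {
  set.seed(26)
  for (i in 1:20) {
    p <- runif(15)^2
    r1 <- fdr_bh(p, 0.01)$reject
    r2 <- fdr_bh(p, 0.05)$reject
    r3 <- fdr_bh(p, 0.2)$reject
    expect_true(all(r2[r1]))
    expect_true(all(r3[r2]))
    # shrinking any single p-value never removes rejections (m fixed)
    j <- sample(15, 1)
    p2 <- p; p2[j] <- p2[j] / 2
    expect_true(all(fdr_bh(p2, 0.05)$reject[r2]))
  }
})
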