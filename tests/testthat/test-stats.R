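# independent oracle: Kruskal-Wallis H from the rank formula with mid-rank
# ties and the standard tie correction
kw_rank_oracle <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(v) length(v) * (mean(v) - (N + 1) / 2)^2))
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

test_that("Kruskal-Wallis matches the hand rank computation", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  kt <- kruskal_wallis(v, g)
  expect_equal(kt$H, 7.2, tolerance = 1e-12)
  expect_equal(kt$H, kw_rank_oracle(v, g), tolerance = 1e-12)
  expect_equal(kt$df, 2L)
  expect_equal(kt$p, stats::pchisq(7.2, 2, lower.tail = FALSE), tolerance = 1e-12)
  # with ties, wrapper and oracle still agree
  set.seed(3)
  vt <- sample(1:5, 30, replace = TRUE)
  gt <- rep(c("a", "b", "c"), 10)
  expect_equal(kruskal_wallis(vt, gt)$H, kw_rank_oracle(vt, gt), tolerance = 1e-12)
})

test_that("Kruskal-Wallis degenerate and invariance behaviour", {
  expect_equal(kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))$H, 0)
  d <- kruskal_wallis(rep(4, 8), rep(c("a", "b"), each = 4))
  expect_true(d$degenerate)
  expect_equal(d$p, 1)
  # permutations within groups leave H unchanged
  set.seed(9)
  v <- rnorm(18); g <- rep(c("a", "b", "c"), each = 6)
  h0 <- kruskal_wallis(v, g)$H
  vperm <- v
  for (gg in unique(g)) vperm[g == gg] <- sample(v[g == gg])
  expect_equal(kruskal_wallis(vperm, g)$H, h0, tolerance = 1e-12)
  expect_error(kruskal_wallis(1:3, c("a", "a", "b")), "n >= 2")
})

test_that("Holm-Sidak step-down adjustment", {
  # frozen references: 1-(1-0.01)^3 = 0.029701; 1-(1-0.03)^2 = 0.0591;
  # 1-(1-0.04)^1 = 0.04 lifted to 0.0591 by the step-down maximum
  adj <- holm_sidak_adjust(c(0.01, 0.04, 0.03))
  expect_equal(adj, c(0.029701, 0.0591, 0.0591), tolerance = 1e-12)
  expect_equal(holm_sidak_adjust(0.2), 0.2)
  expect_equal(holm_sidak_adjust(rep(1, 4)), rep(1, 4))
  # order invariance and sorted monotonicity
  p <- c(0.2, 0.001, 0.05, 0.5, 0.049)
  a1 <- holm_sidak_adjust(p)
  o <- sample(length(p))
  expect_equal(holm_sidak_adjust(p[o]), a1[o])
  expect_true(all(diff(a1[order(p)]) >= -1e-15))
  expect_true(all(a1 >= p))
  expect_true(all(a1 <= 1))
})

test_that("Dunn post hoc z statistics follow the pooled-rank formula", {
  set.seed(12)
  v <- c(rnorm(8, 0), rnorm(8, 1), rnorm(8, 2))
  g <- rep(c("a", "b", "c"), each = 8)
  tab <- dunn_posthoc(v, g, adjust = "none")
  # hand computation for one pair
  N <- length(v); r <- rank(v)
  z_ab <- (mean(r[g == "a"]) - mean(r[g == "b"])) /
    sqrt((N * (N + 1) / 12) * (1 / 8 + 1 / 8))
  expect_equal(tab$z[tab$group1 == "a" & tab$group2 == "b"], z_ab,
               tolerance = 1e-12)
  expect_true(all(tab$p_raw >= 0 & tab$p_raw <= 1))
  # adjusted p never smaller than raw, for both procedures
  for (adj in c("holm_sidak", "bonferroni")) {
    tt <- dunn_posthoc(v, g, adjust = adj)
    expect_true(all(tt$p_adj >= tt$p_raw - 1e-15))
    expect_true(all(tt$p_adj <= 1))
  }
})

test_that("group summaries report mean and SEM", {
  s <- summarize_groups(c(1, 2, 3), rep("g", 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(summarize_groups(rep(7, 5), rep("g", 5))$sem, 0)
  expect_warning(s1 <- summarize_groups(c(1, 2, 3), c("a", "b", "b")), "n = 1")
  expect_true(is.na(s1$sem[s1$group == "a"]))
  # SEM agrees with a bootstrap estimate within 10% on a large fixture
  set.seed(4)
  x <- rnorm(1000, 5, 2)
  sem <- summarize_groups(x, rep("g", 1000))$sem
  boots <- replicate(400, mean(sample(x, replace = TRUE)))
  expect_lt(abs(sem - stats::sd(boots)) / sem, 0.1)
})

test_that("null calibration: rejection rate near the nominal level", {
  set.seed(2024)
  n_sim <- 2000
  rej <- 0L
  for (i in seq_len(n_sim)) {
    v <- rnorm(30)
    if (kruskal_wallis(v, rep(c("a", "b", "c"), each = 10))$p < 0.05)
      rej <- rej + 1L
  }
  rate <- rej / n_sim
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("group_compare assembles summaries, omnibus and pairwise tables", {
  set.seed(5)
  pooled <- data.frame(
    cell_id = sprintf("c%02d", 1:30), sample_id = rep(c("s1", "s2", "s3"), 10),
    condition = rep(c("x", "y", "z"), each = 10),
    segment_count = c(rnorm(10, 20, 2), rnorm(10, 12, 2), rnorm(10, 6, 2)),
    sholl_auc = c(rnorm(10, 200, 20), rnorm(10, 110, 15), rnorm(10, 60, 10)))
  gc <- group_compare(pooled, metrics = c("segment_count", "sholl_auc"),
                      posthoc = "holm_sidak")
  expect_s3_class(gc, "group_comparison")
  expect_named(gc, c("segment_count", "sholl_auc"))
  expect_lt(gc$segment_count$omnibus$p, 0.01)
  expect_equal(nrow(gc$sholl_auc$pairwise), 3L)
  td <- withr::local_tempdir()
  p <- file.path(td, "stats.csv")
  write_stats_csv(gc, p)
  out <- read.csv(p)
  expect_equal(nrow(out), 6L)
  expect_true(all(c("metric", "H", "omnibus_p", "p_adj") %in% names(out)))
})
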