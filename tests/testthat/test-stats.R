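anova_fixture <- function() {
  data.frame(value = c(1, 2, 1, 2, 3, 4, 3, 4),
             factor_a = rep(c("A1", "A2"), each = 4),
             factor_b = rep(c("B1", "B2", "B1", "B2"), each = 2))
}

test_that("balanced 2x2 ANOVA matches the hand-computed partition", {
  fit <- two_way_anova(anova_fixture())
  tab <- tidy(fit)
  expect_equal(tab$sumsq, c(8, 0, 0, 2), tolerance = 1e-9)
  expect_equal(tab$df, c(1, 1, 1, 4))
  expect_equal(tab$statistic[1], 16, tolerance = 1e-9)
  # cross-check the full table against base R aov
  ref <- aov_two_way(anova_fixture())
  expect_equal(tab$sumsq, ref$`Sum Sq`, tolerance = 1e-9)
  expect_equal(tab$p.value[1], ref$`Pr(>F)`[1], tolerance = 1e-9)
})

test_that("balanced SS partition identity holds on random tables", {
  for (s in 1:5) {
    df <- withr::with_seed(s, data.frame(
      value = rnorm(24),
      factor_a = rep(c("a1", "a2", "a3"), each = 8),
      factor_b = rep(c("b1", "b2"), times = 12)))
    fit <- two_way_anova(df)
    tab <- tidy(fit)
    ss_tot <- sum((df$value - mean(df$value))^2)
    expect_equal(sum(tab$sumsq), ss_tot, tolerance = 1e-8)
  }
})

test_that("unbalanced designs use Type-II SS and agree with car::Anova", {
  df <- withr::with_seed(2, data.frame(
    value = rnorm(30),
    factor_a = rep(c("a1", "a2"), times = c(18, 12)),
    factor_b = c(rep(c("b1", "b2"), times = c(10, 8)),
                 rep(c("b1", "b2"), times = c(5, 7)))))
  fit <- two_way_anova(df)
  expect_equal(fit$type, "II")
  ref <- car::Anova(stats::lm(value ~ factor_a * factor_b, data = df),
                    type = 2)
  expect_equal(tidy(fit)$sumsq, ref$`Sum Sq`, tolerance = 1e-9)
})

test_that("degenerate all-equal tables report undefined F with p = 1", {
  df <- anova_fixture()
  df$value <- 5
  fit <- two_way_anova(df)
  expect_true(fit$degenerate)
  expect_true(all(is.na(tidy(fit)$statistic)))
  expect_equal(tidy(fit)$p.value[1:3], rep(1, 3))
})

test_that("ANOVA output is invariant to row permutation", {
  df <- anova_fixture()
  fit1 <- two_way_anova(df)
  fit2 <- withr::with_seed(1, two_way_anova(df[sample(nrow(df)), ]))
  expect_equal(tidy(fit1), tidy(fit2), tolerance = 1e-12)
  expect_equal(fit1$comparisons$p.adj, fit2$comparisons$p.adj,
               tolerance = 1e-12)
})

test_that("empty cells are reported by name", {
  df <- anova_fixture()[1:6, ]
  expect_error(two_way_anova(df), "A2:B2")
})

test_that("Holm-Sidak matches the worked step-down example", {
  hs <- holm_sidak(c(0.01, 0.04, 0.03))
  expect_equal(hs$p_adj, c(1 - 0.99^3, 0.0591, 0.0591), tolerance = 1e-4)
  expect_equal(hs$p_adj[1], 0.029701, tolerance = 1e-6)
  expect_equal(holm_sidak(0.02)$p_adj, 0.02)
  expect_equal(holm_sidak(c(0, 0, 0))$p_adj, c(0, 0, 0))
  expect_error(holm_sidak(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Holm-Sidak adjustments are valid and never exceed Bonferroni", {
  for (s in 1:10) {
    p <- withr::with_seed(s, runif(7)^2)
    hs <- holm_sidak(p)
    expect_true(all(hs$p_adj >= p))
    expect_true(all(hs$p_adj <= 1))
    expect_true(all(diff(hs$p_adj[order(p)]) >= -1e-12))
    bonf <- p.adjust(p, method = "bonferroni")
    expect_true(all(hs$p_adj <= bonf + 1e-12))
  }
})

test_that("the F-test holds its nominal type-I error rate under the null", {
  n_rep <- 1000
  rejects <- withr::with_seed(99, vapply(seq_len(n_rep), function(i) {
    df <- data.frame(value = rnorm(120),
                     factor_a = rep(c("g1", "g2"), each = 60),
                     factor_b = rep(c("t1", "t2"), times = 60))
    fit <- two_way_anova(df, comparisons = FALSE)
    tidy(fit)$p.value[1] < 0.05
  }, logical(1)))
  rate <- mean(rejects)
  bounds <- qbinom(c(0.005, 0.995), n_rep, 0.05) / n_rep
  expect_gte(rate, bounds[1])
  expect_lte(rate, bounds[2])
})

test_that("two-group t-test matches the closed-form pooled statistic", {
  df <- data.frame(value = c(1, 2, 3, 4, 5, 6),
                   group = rep(c("g1", "g2"), each = 3))
  tt <- t_test_groups(df)
  # closed form: pooled SD 1, SE = sqrt(2/3), t = -3/SE
  t_exact <- -3 / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(tt$statistic, t_exact, tolerance = 1e-9)
  expect_equal(tt$df, 4)
  expect_equal(tt$p.value, 2 * pt(t_exact, 4), tolerance = 1e-9)
  expect_equal(tt$p.value, 0.0214, tolerance = 1e-2)
  # identical groups: t = 0, p = 1
  df2 <- data.frame(value = c(1, 2, 3, 1, 2, 3),
                    group = rep(c("g1", "g2"), each = 3))
  tt2 <- t_test_groups(df2)
  expect_equal(tt2$statistic, 0)
  expect_equal(tt2$p.value, 1)
})

test_that("one-way ANOVA with two groups satisfies F = t^2", {
  df <- withr::with_seed(5, data.frame(
    value = rnorm(20), group = rep(c("g1", "g2"), each = 10)))
  f_stat <- tidy(one_way_anova(df))$statistic[1]
  t_stat <- t_test_groups(df)$statistic
  expect_equal(f_stat, t_stat^2, tolerance = 1e-9)
})

test_that("group summaries report mean, SEM and n", {
  df <- data.frame(value = c(2, 4, 7), g = c("a", "a", "b"))
  sm <- summarize_groups(df, value, g)
  expect_equal(sm$mean, c(3, 7))
  expect_equal(sm$sem, c(1, NA))
  expect_equal(sm$n, c(2L, 1L))
  # permutation invariance
  sm2 <- summarize_groups(df[c(3, 1, 2), ], value, g)
  expect_equal(sm, sm2)
})

test_that("ddCt fold changes follow the stated arithmetic", {
  ct <- tibble::tibble(
    sample = c("s1", "s1", "s2", "s2"),
    group = c("treated", "treated", "ctl", "ctl"),
    gene = c("tg", "ref", "tg", "ref"),
    ct = c(20, 15, 22, 15))
  res <- ddct(ct, "tg", "ref", "ctl")
  expect_equal(res$fold[res$sample == "s1"], 4)
  expect_equal(res$fold[res$sample == "s2"], 1)
  # dCt invariance: adding a constant to both genes of one sample
  ct2 <- ct
  ct2$ct[ct2$sample == "s1"] <- ct2$ct[ct2$sample == "s1"] + 3
  expect_equal(ddct(ct2, "tg", "ref", "ctl")$fold,
               res$fold)
  # calibrator group's geometric mean fold is 1
  ct3 <- tibble::tibble(
    sample = rep(c("c1", "c2", "t1"), each = 2),
    group = rep(c("ctl", "ctl", "tr"), each = 2),
    gene = rep(c("tg", "ref"), 3),
    ct = c(21, 15, 22, 15, 19, 15))
  res3 <- ddct(ct3, "tg", "ref", "ctl")
  expect_equal(exp(mean(log(res3$fold[res3$group == "ctl"]))), 1,
               tolerance = 1e-12)
  expect_error(ddct(ct[-2, ], "tg", "ref", "ctl"), "missing Ct")
})

test_that("technical replicates are averaged before dCt", {
  ct <- tibble::tibble(
    sample = rep(c("s1", "s2"), each = 6),
    group = rep(c("tr", "ctl"), each = 6),
    gene = rep(rep(c("tg", "ref"), each = 3), 2),
    ct = c(19.9, 20.0, 20.1, 14.9, 15.0, 15.1,
           21.9, 22.0, 22.1, 14.9, 15.0, 15.1))
  res <- ddct(ct, "tg", "ref", "ctl")
  expect_equal(res$fold[res$sample == "s1"], 4, tolerance = 1e-9)
})
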