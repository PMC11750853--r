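test_that("one-way ANOVA matches hand computation and degenerate cases", {
  y <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  an <- one_way_anova(y, g)
  expect_equal(an$F, 27)           # SSB = 54 over 2 df, SSW = 6 over 6 df
  expect_equal(c(an$df1, an$df2), c(2L, 6L))
  expect_equal(an$p, stats::pf(27, 2, 6, lower.tail = FALSE))
  expect_equal(an$msw, 1)

  same <- one_way_anova(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  flat <- one_way_anova(rep(5, 9), g)
  expect_true(is.na(flat$F))
  expect_match(flat$note, "zero total variance")

  expect_error(one_way_anova(1:4, c("a", "a", "a", "b")), "at least 2")
  expect_error(one_way_anova(1:3, c("a", "b", "c")), "at least 2")
})

test_that("LSD equals unadjusted pooled-variance pairwise t tests", {
  y <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- factor(rep(c("a", "b", "c"), each = 3))
  lsd <- pairwise_posthoc(y, g, method = "LSD")
  # hand computation: MSW = 1, se = sqrt(2/3)
  t13 <- -6 / sqrt(2 / 3)
  expect_equal(lsd$statistic[lsd$group1 == "a" & lsd$group2 == "c"], t13)
  expect_lt(lsd$p.value[lsd$group1 == "a" & lsd$group2 == "c"], 0.01)
  expect_equal(unique(lsd$df), 6)

  # base R's pooled pairwise t tests are an independent oracle
  base_p <- stats::pairwise.t.test(y, g, p.adjust.method = "none",
                                   pool.sd = TRUE)$p.value
  expect_equal(lsd$p.value[1], base_p["b", "a"])
  expect_equal(lsd$p.value[2], base_p["c", "a"])
  expect_equal(lsd$p.value[3], base_p["c", "b"])

  ident <- pairwise_posthoc(rep(c(1, 2, 3), 3),
                            rep(c("a", "b", "c"), each = 3), method = "LSD")
  expect_equal(ident$p.value, rep(1, 3))
})

test_that("Games-Howell reduces to Welch df and approaches Tukey HSD asymptotically", {
  # two groups: Welch-Satterthwaite df must equal t.test's
  set.seed(8)
  x <- rnorm(12, sd = 1); z <- rnorm(20, sd = 3)
  gh <- pairwise_posthoc(c(x, z), rep(c("a", "b"), c(12, 20)),
                         method = "Games-Howell")
  wt <- stats::t.test(x, z)
  expect_equal(gh$df, unname(wt$parameter), tolerance = 1e-10)
  expect_equal(abs(gh$statistic), abs(unname(wt$statistic)),
               tolerance = 1e-10)

  # equal variances, large n: Games-Howell ~ Tukey HSD
  set.seed(9)
  y <- rnorm(600) + rep(c(0, 0.12, 0.3), each = 200)
  g <- factor(rep(c("a", "b", "c"), each = 200))
  gh3 <- pairwise_posthoc(y, g, method = "Games-Howell")
  tk <- stats::TukeyHSD(stats::aov(y ~ g))$g
  expect_equal(gh3$p.value, unname(tk[c("b-a", "c-a", "c-b"), "p adj"]),
               tolerance = 0.02)

  expect_error(pairwise_posthoc(y, g, method = "Bonferroni"))
})

test_that("Levene gate: null p values are uniform and scaled variance is caught", {
  set.seed(10)
  ps <- replicate(300, {
    homogeneity_test(rnorm(60), rep(c("a", "b", "c"), each = 20))
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.001)

  set.seed(11)
  hits <- replicate(100, {
    y <- c(rnorm(50), rnorm(50) * 10, rnorm(50))
    homogeneity_test(y, rep(c("a", "b", "c"), each = 50)) < 0.01
  })
  expect_gte(mean(hits), 0.95)

  degen <- homogeneity_test(rep(c(3, 3, 7, 7), each = 2),
                            rep(c("a", "b", "c", "d"), each = 2))
  expect_true(is.na(degen))
  expect_match(attr(degen, "note"), "not applicable")
})

test_that("post hoc method is LSD exactly when Levene p >= alpha", {
  set.seed(12)
  for (i in 1:20) {
    hetero <- i %% 2 == 0
    y <- c(rnorm(40), rnorm(40, sd = if (hetero) 6 else 1), rnorm(40))
    g <- rep(c("a", "b", "c"), each = 40)
    res <- compare_groups(y, g, parameter = "x")
    expect_equal(res$posthoc_method,
                 if (res$homogeneity_p >= 0.05) "LSD" else "Games-Howell")
  }
})

test_that("results are invariant to group label order", {
  set.seed(13)
  y <- rnorm(90) + rep(c(0, 1, 2), each = 30)
  g1 <- factor(rep(c("a", "b", "c"), each = 30))
  g2 <- factor(g1, levels = c("c", "a", "b"))
  r1 <- compare_groups(y, g1)
  r2 <- compare_groups(y, g2)
  expect_equal(r1$anova$F, r2$anova$F)
  expect_equal(r1$anova$p, r2$anova$p)
  expect_equal(r1$homogeneity_p, r2$homogeneity_p)
  expect_setequal(round(r1$posthoc$p.value, 12),
                  round(r2$posthoc$p.value, 12))
})

test_that("run_table renders one row per parameter with mean ± SD cells", {
  toy <- data.frame(group = rep(c("GDM", "PC", "NC"), each = 2),
                    VWT = c(12, 13, 11, 12, 10, 11))
  out <- run_table(toy, parameters = "VWT")
  expect_length(out$results, 1)
  expect_equal(out$table$parameter, "VWT")
  expect_match(out$table$GDM, "^12\\.5000 ± 0\\.7071$")
  expect_error(run_table(toy, parameters = "NOPE"), "unknown parameter")

  coh <- generate_cohort(reference_group_specs(), seed = 21)
  full <- run_table(coh)
  expect_equal(nrow(full$table), 11)
  expect_true(all(c("GDM", "PC", "NC", "P") %in% names(full$table)))
  # missing values drop listwise per parameter
  coh$AVR[c(3, 70)] <- NA
  res <- run_table(coh, parameters = "AVR")$results$AVR
  expect_equal(sum(res$anova$ns), 158)
})
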