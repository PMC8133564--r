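test_that("heritability follows its defining formula and limits", {
  expect_identical(heritability(3, 6, 6), 0.75)
  expect_equal(heritability(0, 6, 6), 0)
  expect_gt(heritability(1, 1e-9, 6), 0.999)
  expect_error(heritability(1, 1, 0), "positive")
  expect_error(heritability(-1, 1, 6), "non-negative")
  # monotone: increasing in sigma_g2 and r, decreasing in sigma_e2
  expect_true(all(diff(heritability(c(1, 2, 3), 6, 6)) > 0))
  expect_true(all(diff(heritability(3, c(9, 6, 3), 6)) > 0))
  expect_true(all(diff(heritability(3, 6, c(2, 4, 8))) > 0))
})

test_that("mean squares match a direct sums-of-squares computation", {
  # brute-force oracle on a 3-genotype x 2-rep toy table
  df <- tibble::tibble(
    genotype = rep(c("A", "B", "C"), each = 2),
    y = c(10, 12, 15, 17, 20, 24)
  )
  gm <- tapply(df$y, df$genotype, mean)
  grand <- mean(df$y)
  ss_g <- 2 * sum((gm - grand)^2)
  ss_e <- sum((df$y - gm[df$genotype])^2)
  vc <- variance_components(df, "y")
  expect_equal(vc$ms_genotype, ss_g / 2)
  expect_equal(vc$ms_residual, ss_e / 3)
  expect_equal(vc$sigma_e2, ss_e / 3)
  expect_equal(vc$sigma_g2, (ss_g / 2 - ss_e / 3) / 2)
  expect_equal(vc$r, 2)
})

test_that("moment estimates recover generating variances at the study scale", {
  set.seed(123)
  est <- t(replicate(120, {
    d <- simulate_trait_values(26, 6, sigma_g2 = 3, sigma_e2 = 6)
    vc <- variance_components(d, "value")
    c(vc$sigma_g2, vc$sigma_e2)
  }))
  # Monte-Carlo error of the mean ~ sd/sqrt(120)
  expect_equal(mean(est[, 1]), 3, tolerance = 0.15)
  expect_equal(mean(est[, 2]), 6, tolerance = 0.05)
})

test_that("flat genotype means truncate the genetic variance at zero", {
  df <- tibble::tibble(genotype = rep(c("A", "B", "C"), each = 4),
                       y = rep(c(1, 2, 3, 4), 3))
  vc <- variance_components(df, "y")
  expect_equal(vc$sigma_g2, 0)
  expect_lt(vc$sigma_g2_raw, 0)
  expect_equal(vc$h2, 0)
})

test_that("REML and moments agree on balanced data", {
  d <- simulate_trait_values(20, 6, sigma_g2 = 2, sigma_e2 = 4, seed = 7)
  m <- variance_components(d, "value", method = "moments")
  r <- variance_components(d, "value", method = "reml")
  expect_equal(r$sigma_g2, m$sigma_g2, tolerance = 0.02)
  expect_equal(r$sigma_e2, m$sigma_e2, tolerance = 0.02)
})

test_that("variance components reject degenerate inputs", {
  expect_error(variance_components(tibble::tibble(genotype = "A", y = 1:4 * 0 + 2), "y"),
               "2 genotypes")
  expect_error(
    variance_components(tibble::tibble(genotype = rep(c("A", "B"), 3), y = 1), "y"),
    "zero total variance"
  )
})

test_that("genotype x concentration ANOVA matches hand-computed F statistics", {
  # balanced 2 x 2 x 3 layout: Type II equals the classic two-way table
  set.seed(31)
  df <- tidyr::expand_grid(genotype = c("A", "B"), treatment = c("hi", "lo"),
                           rep = 1:3)
  df$y <- 2 + (df$genotype == "B") * 1.5 + (df$treatment == "lo") * -1 +
    (df$genotype == "B" & df$treatment == "lo") * 0.8 + rnorm(12, 0, 0.3)
  out <- anova_gxc(df, "y")
  # independent oracle: direct sums of squares on the balanced layout
  cell <- tapply(df$y, list(df$genotype, df$treatment), mean)
  g <- rowMeans(cell); c_ <- colMeans(cell); grand <- mean(df$y)
  ss_g <- 6 * sum((g - grand)^2)
  ss_c <- 6 * sum((c_ - grand)^2)
  ss_gc <- 3 * sum((sweep(sweep(cell, 1, g), 2, c_) + grand)^2)
  fitted <- cell[cbind(df$genotype, df$treatment)]
  ss_e <- sum((df$y - fitted)^2)
  expect_equal(out$sumsq[out$term == "genotype"], ss_g, tolerance = 1e-10)
  expect_equal(out$sumsq[out$term == "concentration"], ss_c, tolerance = 1e-10)
  expect_equal(out$sumsq[out$term == "genotype:concentration"], ss_gc, tolerance = 1e-10)
  expect_equal(out$statistic[out$term == "genotype"], (ss_g / 1) / (ss_e / 8),
               tolerance = 1e-10)
})

test_that("ANOVA power detects a planted interaction at the study scale", {
  set.seed(77)
  hits <- replicate(200, {
    df <- tidyr::expand_grid(genotype = sprintf("G%02d", 1:26),
                             treatment = c("hi", "lo"), rep = 1:6)
    inter <- rnorm(26) # interaction SD = residual SD = 1
    gi <- inter[match(df$genotype, sprintf("G%02d", 1:26))]
    df$y <- rnorm(nrow(df)) + ifelse(df$treatment == "lo", gi, -gi)
    out <- anova_gxc(df, "y")
    out$p.value[out$term == "genotype:concentration"] < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("ANOVA rejects degenerate designs", {
  df <- tidyr::expand_grid(genotype = c("A", "B"), treatment = c("hi", "lo"), rep = 1:2)
  df$y <- 1
  expect_error(anova_gxc(df, "y"), "zero variance")
  df$y <- rnorm(8)
  df1 <- df; df1$treatment <- "hi"
  expect_error(anova_gxc(df1, "y"), "2 levels")
})

test_that("correlations reproduce hand-computed cases", {
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1, z = -(1:10))
  cm <- correlation_matrix(d, c("x", "y", "z"))
  expect_equal(cm$r[cm$trait_a == "x" & cm$trait_b == "y"], 1)
  expect_equal(cm$r[cm$trait_a == "x" & cm$trait_b == "z"], -1)
  # hand computation of Pearson r for (0,0),(1,2),(2,1)
  d2 <- tibble::tibble(x = c(0, 1, 2), y = c(0, 2, 1))
  cm2 <- correlation_matrix(d2, c("x", "y"))
  expect_equal(cm2$r, 0.5)
  # constant trait: flagged missing, not an error
  d3 <- tibble::tibble(x = 1:5, y = rep(2, 5))
  cm3 <- correlation_matrix(d3, c("x", "y"))
  expect_true(is.na(cm3$r) && cm3$flagged)
})

test_that("PCA summaries normalize variance and find shared axes", {
  d <- tibble::tibble(x = 1:20, y = 3 * (1:20) + 2)
  p <- pca_summary(d, c("x", "y"))
  expect_equal(p$variance$prop_variance[1], 1, tolerance = 1e-12)
  expect_equal(sum(p$variance$prop_variance), 1, tolerance = 1e-12)

  set.seed(5)
  iso <- tibble::tibble(x = rnorm(1e4), y = rnorm(1e4))
  p2 <- pca_summary(iso, c("x", "y"))
  expect_equal(p2$variance$prop_variance[1], 0.5, tolerance = 0.02)

  expect_error(pca_summary(d[1, ], c("x", "y")), "fewer than 2")
})
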