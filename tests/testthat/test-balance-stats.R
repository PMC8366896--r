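test_that("standardize gives mean 0, sd 1, and rejects constants", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(3)
  z <- standardize(rnorm(50, 10, 4))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_error(standardize(rep(2, 10)), "constant")
})

test_that("isometry test matches the closed-form OLS oracle", {
  x <- c(-1.5, -0.5, 0.5, 1.5)
  y <- c(-1.2, -0.8, 0.4, 1.6)
  oracle <- ols_by_hand(y, x)
  fit <- isometry_test(y, x, standardize = FALSE)
  expect_equal(fit$slope, oracle$slope)
  expect_equal(fit$intercept, oracle$intercept)
  expect_equal(fit$slope_se, oracle$se)
  expect_equal(fit$r_squared, oracle$r_squared)
  expect_equal(fit$df, 2)
  expect_equal(fit$t_vs_one, (oracle$slope - 1) / oracle$se)
})

test_that("perfect identity fit is handled as slope 1 with t_vs_one 0", {
  x <- 1:10
  fit <- isometry_test(x, x, standardize = FALSE)
  expect_equal(fit$slope, 1)
  expect_equal(fit$t_vs_one, 0)
  expect_equal(fit$r_squared, 1)
})

test_that("on standardized data slope equals Pearson r and R2 its square", {
  set.seed(21)
  for (rep in 1:10) {
    x <- rnorm(40)
    y <- 0.6 * x + rnorm(40)
    fit <- isometry_test(y, x)   # standardizes internally
    r <- cor(x, y)
    expect_equal(fit$slope, r, tolerance = 1e-12)
    expect_equal(fit$r_squared, r^2, tolerance = 1e-12)
  }
})

test_that("ratio-fiber simple fit recovers an exact linear law", {
  fiber <- seq(20, 70, length.out = 60)
  ratio <- 2 - 0.02 * fiber
  fit <- ratio_fiber_model(ratio, fiber, standardize = FALSE)
  expect_equal(fit$slope, -0.02)
  expect_equal(fit$r_squared, 1)
})

test_that("interaction model recovers per-type slopes from known truth", {
  set.seed(5)
  types <- c("broadleaf", "shrub_sugar", "conifer")
  true_slopes <- c(broadleaf = -0.9, shrub_sugar = -0.6, conifer = -0.8)
  n <- 300
  df <- do.call(rbind, lapply(types, function(tt) {
    fiber <- runif(n, 30, 70)
    data.frame(diet = tt, fiber = fiber,
               ratio = 60 + true_slopes[tt] * fiber + rnorm(n, 0, 2))
  }))
  fit <- ratio_fiber_model(df$ratio, df$fiber, df$diet, standardize = FALSE)
  # per-type slope se here is ~0.01 (n = 300/type, sd 2, fiber range 40)
  for (tt in types) {
    est <- fit$per_type$slope[fit$per_type$diet_type == tt]
    expect_lt(abs(est - true_slopes[tt]), 0.04)
  }
  expect_error(ratio_fiber_model(df$ratio, df$fiber, rep("a", nrow(df))),
               "at least 2 diet types")
})

test_that("quasi-binomial variant agrees with the linear fit in sign", {
  set.seed(6)
  fiber <- runif(400, 30, 70)
  ratio <- pmax(0.05, 1.4 - 0.015 * fiber + rnorm(400, 0, 0.08))
  lin <- ratio_fiber_model(ratio, fiber, standardize = FALSE)
  qb <- ratio_fiber_model(ratio, fiber, standardize = FALSE,
                          family = "quasibinomial")
  expect_lt(lin$slope, 0)
  expect_lt(qb$slope, 0)
  expect_lt(qb$p_two_sided, 0.001)
})

test_that("pearson matrix matches hand computation and flags constants", {
  tab <- data.frame(a = c(1, 2, 4), b = c(2, 1, 3))
  pm <- pearson_matrix(tab)
  r_hand <- sum(scale(tab$a) * scale(tab$b)) / 2
  expect_equal(pm$r["a", "b"], r_hand)
  expect_equal(diag(pm$r), c(a = 1, b = 1))
  expect_equal(pm$r, t(pm$r))
  # p-value from the t distribution with n - 2 df
  tstat <- r_hand * sqrt(1 / (1 - r_hand^2))
  expect_equal(pm$p["a", "b"], 2 * pt(abs(tstat), 1, lower.tail = FALSE))

  ident <- pearson_matrix(data.frame(u = 1:5, v = 1:5))
  expect_equal(ident$r["u", "v"], 1)
  expect_equal(ident$p["u", "v"], 0)

  flagged <- pearson_matrix(data.frame(u = 1:5, k = rep(3, 5)))
  expect_equal(flagged$flagged, "k")
  expect_true(is.na(flagged$r["u", "k"]))
})

test_that("two-group ANOVA F equals the squared pooled t", {
  set.seed(8)
  v <- c(rnorm(12, 10), rnorm(15, 11))
  g <- rep(c("a", "b"), c(12, 15))
  at <- anova_tukey(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(at$F, unname(tt$statistic)^2)
  expect_equal(at$p, tt$p.value)
  expect_equal(at$df_between, 1)
})

test_that("ANOVA F matches brute-force sums of squares", {
  set.seed(12)
  v <- rnorm(30)
  g <- rep(c("a", "b", "c"), each = 10)
  at <- anova_tukey(v, g)
  gm <- tapply(v, g, mean)
  ssb <- sum(10 * (gm - mean(v))^2)
  ssw <- sum((v - gm[g])^2)
  f_hand <- (ssb / 2) / (ssw / 27)
  expect_equal(at$F, f_hand)
  expect_equal(at$df_between, 2)
  expect_equal(at$df_within, 27)
})

test_that("Tukey comparisons flag a shifted group with high power", {
  set.seed(13)
  hits <- 0
  for (rep in 1:40) {
    v <- c(rnorm(50), rnorm(50), rnorm(50, 2))  # one mean 2 sd away
    g <- rep(c("a", "b", "c"), each = 50)
    at <- anova_tukey(v, g)
    ca <- at$tukey[at$tukey$comparison == "c-a", ]
    cb <- at$tukey[at$tukey$comparison == "c-b", ]
    if (ca$significant && cb$significant) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
})

test_that("ANOVA type-I error is near nominal under the null", {
  set.seed(14)
  rejects <- vapply(1:300, function(i) {
    v <- rnorm(60)
    anova_tukey(v, rep(c("a", "b", "c"), 20))$p < 0.05
  }, logical(1))
  # binomial 99% band around 0.05 at 300 reps
  expect_gt(mean(rejects), 0.05 - 2.58 * sqrt(0.05 * 0.95 / 300))
  expect_lt(mean(rejects), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 300))
})

test_that("subpopulation regression: exact line, null, and errors", {
  sub <- data.frame(mmu = sprintf("U%02d", 1:10),
                    mean_ratio = seq(0.3, 0.75, length.out = 10))
  sub$mean_calf_bm <- 40 + 50 * sub$mean_ratio
  fit <- subpop_ratio_vs_bodymass(sub)
  expect_equal(fit$slope, 50)
  expect_equal(fit$df, 8)
  expect_lt(fit$p_two_sided, 1e-10)

  set.seed(15)
  ps <- replicate(60, {
    s2 <- data.frame(mmu = 1:30, mean_ratio = rnorm(30),
                     mean_calf_bm = rnorm(30, 65, 5))
    subpop_ratio_vs_bodymass(s2)$p_two_sided
  })
  expect_gt(mean(ps > 0.05), 0.8)   # null p-values roughly uniform
  expect_error(subpop_ratio_vs_bodymass(
    data.frame(mmu = 1:2, mean_ratio = 1:2, mean_calf_bm = 1:2)),
    "at least 3")
})

test_that("per-sample aggregation averages ratios within subpopulation", {
  df <- data.frame(mmu = rep(c("U1", "U2", "U3"), each = 4),
                   ratio = c(1, 2, 3, 4, 2, 2, 2, 2, 1, 1, 3, 3),
                   calf_body_mass = c(60, NA, 62, NA, 70, 71, NA, NA,
                                      55, 56, 57, NA))
  fit <- subpop_ratio_vs_bodymass(df)
  expect_equal(sort(fit$subpops$mean_ratio), c(2, 2, 2.5))
  expect_equal(fit$n, 3)
})
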