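# Oracle cross-checks for the statistics engine: hand computations, brute
# force enumeration written independently here, and the corresponding base-R
# reference implementations.

test_that("one-way ANOVA reproduces the hand-computed decomposition", {
  at <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(at$ss, c(1.5, 4))
  expect_equal(at$df, c(1, 4))
  expect_equal(at$f[1], 1.5)
  expect_equal(at$p[1], stats::pf(1.5, 1, 4, lower.tail = FALSE))

  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$f[1], 0)
  expect_equal(same$p[1], 1)

  expect_warning(one_way_anova(list(c(2, 2), c(2, 2))), "undefined")
})

test_that("one-way ANOVA agrees with aov on random data", {
  set.seed(10)
  for (i in 1:5) {
    y <- rnorm(24)
    g <- rep(letters[1:3], each = 8)
    ours <- one_way_anova(y, g)
    ref <- summary(stats::aov(y ~ g))[[1]]
    expect_equal(ours$ss, ref$`Sum Sq`, tolerance = 1e-10)
    expect_equal(ours$f[1], ref$`F value`[1], tolerance = 1e-10)
    expect_equal(ours$p[1], ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("balanced two-way ANOVA matches hand computation and aov", {
  # cells: open/A {1,2}, open/B {3,4}, shaded/A {5,6}, shaded/B {7,8}
  y <- c(1, 2, 3, 4, 5, 6, 7, 8)
  hab <- c("open", "open", "open", "open", "shaded", "shaded", "shaded", "shaded")
  pop <- c("A", "A", "B", "B", "A", "A", "B", "B")
  at <- two_way_anova_balanced(y, hab, pop)
  expect_equal(at$ss, c(32, 8, 0, 2))
  expect_equal(at$df, c(1, 1, 1, 4))
  expect_equal(at$f[1:3], c(64, 16, 0))

  set.seed(11)
  for (i in 1:5) {
    y <- rnorm(40)
    hab <- rep(c("open", "shaded"), each = 20)
    pop <- rep(rep(c("Dune", "Woods"), each = 10), 2)
    ours <- two_way_anova_balanced(y, hab, pop)
    ref <- summary(stats::aov(y ~ hab * pop))[[1]]
    expect_equal(ours$ss, ref$`Sum Sq`, tolerance = 1e-9)
    expect_equal(ours$p[1:3], ref$`Pr(>F)`[1:3], tolerance = 1e-9)
  }
})

test_that("two-way SS bookkeeping is exact and unbalance is refused", {
  set.seed(12)
  y <- rlnorm(24)
  hab <- rep(c("open", "shaded"), each = 12)
  pop <- rep(rep(c("Dune", "Woods"), each = 6), 2)
  at <- two_way_anova_balanced(y, hab, pop)
  sst <- sum((y - mean(y))^2)
  expect_equal(sum(at$ss), sst, tolerance = 1e-9 * sst)
  expect_equal(sum(at$df), length(y) - 1)
  # one-way between-SS on a marginal factor equals the balanced two-way SS
  expect_equal(one_way_anova(y, hab)$ss[1], at$ss[1], tolerance = 1e-10)

  expect_error(two_way_anova_balanced(y[-1], hab[-1], pop[-1]), "nbalanced")
  expect_warning(two_way_anova_balanced(rep(1, 8),
                                        rep(c("a", "b"), each = 4),
                                        rep(c("x", "x", "y", "y"), 2)),
                 "constant")
})

test_that("variance-ratio F-test is two-sided and order-faithful", {
  a <- c(1, 3, 5, 7)        # var = 20/3
  b <- c(1, 2, 3, 4)        # var = 5/3
  res <- variance_ratio_test(a, b)
  expect_equal(res$statistic, var(a) / var(b))
  expect_equal(res$statistic, 4)
  ref <- stats::var.test(a, b)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)

  same <- variance_ratio_test(a, a)
  expect_equal(same$statistic, 1)
  expect_equal(same$p_value, 1)

  fwd <- variance_ratio_test(a, b)
  rev <- variance_ratio_test(b, a)
  expect_equal(rev$statistic, 1 / fwd$statistic)
  expect_equal(rev$p_value, fwd$p_value, tolerance = 1e-12)

  expect_warning(variance_ratio_test(a, c(2, 2, 2)), "zero variance")
})

test_that("exact Wilcoxon equals full enumeration for all n1, n2 <= 6", {
  res <- wilcoxon_rank_sum(c(1, 2), c(3, 4), mode = "exact")
  expect_equal(res$p_value, 1 / 3)   # two-sided; one-sided would be 1/6

  set.seed(13)
  for (n1 in 2:6) {
    for (n2 in 2:6) {
      a <- rnorm(n1)
      b <- rnorm(n2, 0.5)
      ours <- wilcoxon_rank_sum(a, b, mode = "exact")
      expect_equal(ours$p_value, brute_wilcoxon_p(a, b), tolerance = 1e-12)
      ref <- stats::wilcox.test(a, b, exact = TRUE)
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("Wilcoxon handles identity, ties and the normal approximation", {
  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  set.seed(14)
  a <- rnorm(25); b <- rnorm(30, 0.4)
  ours <- wilcoxon_rank_sum(a, b, mode = "normal_approx")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)

  a <- c(1, 2, 2, 3); b <- c(2, 3, 3, 4)
  expect_warning(tied <- wilcoxon_rank_sum(a, b, mode = "exact"), "ties")
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                             correct = TRUE))
  expect_equal(tied$p_value, ref$p.value, tolerance = 1e-10)
  expect_true(tied$ties)
})

test_that("Pearson correlation matches its closed form and cor.test", {
  x <- c(1, 2, 3, 4, 5)
  res <- pearson_corr(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_equal(res$p_value, 0)

  y_orth <- c(1, -1, 0, -1, 1)   # orthogonal to centered x
  res0 <- pearson_corr(x, y_orth)
  expect_equal(res0$r, 0, tolerance = 1e-15)
  expect_equal(res0$p_value, 1, tolerance = 1e-12)

  set.seed(15)
  x <- rnorm(20); y <- rnorm(20)
  ours <- pearson_corr(x, y)
  ref <- stats::cor.test(x, y)
  expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  expect_warning(pearson_corr(x, rep(1, 20)), "zero variance")
})

test_that("Spearman rho is Pearson on ranks with exact enumeration p", {
  x <- c(0.5, 1.2, 2.0, 3.1, 4.8)
  expect_equal(spearman_corr(x, x^3)$rho, 1)

  set.seed(16)
  for (i in 1:3) {
    x <- rnorm(5); y <- rnorm(5)
    ours <- spearman_corr(x, y)
    expect_true(ours$exact)
    expect_equal(ours$rho, stats::cor(rank(x), rank(y)), tolerance = 1e-12)
    expect_equal(ours$p_value, brute_spearman_p(x, y), tolerance = 1e-12)
  }

  x <- rnorm(15); y <- rnorm(15)
  approx <- spearman_corr(x, y)
  expect_false(approx$exact)
  expect_equal(approx$rho, unname(stats::cor.test(x, y,
                                                  method = "spearman")$estimate),
               tolerance = 1e-12)
})

test_that("correlation matrices are symmetric with unit diagonal", {
  sim <- default_sim(seed = 31)
  sub <- as.data.frame(sim$table)[sim$table$population == "Dune" &
                                    sim$table$habitat == "open",
                                  c("SLA", "LDMC", "POD", "GR")]
  for (method in c("pearson", "spearman")) {
    cm <- corr_matrix(sub, method)
    expect_equal(cm$r, t(cm$r))
    expect_equal(unname(diag(cm$r)), rep(1, 4))
    expect_true(all(abs(cm$r) <= 1))
    expect_true(all(cm$p[upper.tri(cm$p)] > 0 & cm$p[upper.tri(cm$p)] <= 1))
  }
})

test_that("Mantel exact enumeration equals the brute-force oracle", {
  m1 <- rand_sym(4, 41)
  self <- mantel_test(m1, m1, exact = TRUE)
  expect_equal(self$r_observed, 1)

  for (seed in 42:44) {
    m2 <- rand_sym(4, seed)
    ours <- mantel_test(m1, m2, exact = TRUE)
    expect_equal(ours$p_value, brute_mantel_p(m1, m2), tolerance = 1e-12)
  }
})

test_that("Mantel permutation p is seeded, reproducible and consistent", {
  m1 <- rand_sym(6, 45)
  m2 <- rand_sym(6, 46)
  a <- mantel_test(m1, m2, n_perm = 499, seed = 1)
  b <- mantel_test(m1, m2, n_perm = 499, seed = 1)
  expect_identical(a$p_value, b$p_value)
  expect_gte(a$p_value, 1 / 500)

  # permutation estimate agrees with full enumeration within 3 binomial SE
  m1s <- rand_sym(5, 47); m2s <- rand_sym(5, 48)
  exact <- mantel_test(m1s, m2s, exact = TRUE)
  perm <- mantel_test(m1s, m2s, n_perm = 999, seed = 2)
  se <- sqrt(exact$p_value * (1 - exact$p_value) / 999)
  expect_lt(abs(perm$p_value - exact$p_value), 3 * se + 1e-3)

  expect_error(mantel_test(m1, rand_sym(5, 49)), "equal dimension")
  expect_warning(mantel_test(matrix(1, 4, 4), m2[1:4, 1:4]), "constant")
})

test_that("Mantel statistic matches the vegan implementation", {
  skip_if_not_installed("vegan")
  m1 <- rand_sym(7, 50); m2 <- rand_sym(7, 51)
  ours <- mantel_test(m1, m2, n_perm = 999, seed = 3)
  ref <- vegan::mantel(as.dist(m1), as.dist(m2), permutations = 999)
  expect_equal(ours$r_observed, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p_value - ref$signif), 0.05)
})

test_that("standardized OLS reports comparable effect sizes", {
  x <- rnorm(20)
  fit <- standardized_ols(x * 2 + 5, data.frame(x = x))
  expect_equal(fit$coefficients$estimate, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # orthogonal standardized predictors: coefficients = simple correlations
  set.seed(17)
  x1 <- rep(c(-1, 1), 10)
  x2 <- rep(c(-1, 1), each = 10)
  y <- rnorm(20)
  fit2 <- standardized_ols(y, data.frame(x1, x2))
  expect_equal(fit2$coefficients$estimate[1], stats::cor(y, x1),
               tolerance = 1e-10)
  expect_equal(fit2$coefficients$estimate[2], stats::cor(y, x2),
               tolerance = 1e-10)

  # location shifts never move standardized coefficients
  fit3 <- standardized_ols(y + 100, data.frame(x1 = x1 + 7, x2))
  expect_equal(fit3$coefficients$estimate, fit2$coefficients$estimate,
               tolerance = 1e-10)

  # cross-check SEs and p-values against lm on scaled data
  set.seed(18)
  x <- rnorm(15); z <- rnorm(15); y <- x + rnorm(15)
  ours <- standardized_ols(y, data.frame(x, z))
  ref <- summary(stats::lm(scale(y) ~ scale(x) + scale(z)))
  expect_equal(ours$coefficients$estimate, unname(coef(ref)[2:3, 1]),
               tolerance = 1e-10)
  expect_equal(ours$coefficients$p, unname(coef(ref)[2:3, 4]),
               tolerance = 1e-10)
  expect_equal(ours$r_squared, ref$r.squared, tolerance = 1e-10)

  expect_error(standardized_ols(y, data.frame(x, x2 = 2 * x)), "collinear")
})

test_that("null p-values are uniform for the ANOVA engine", {
  set.seed(19)
  ps <- replicate(400, {
    y <- rnorm(20)
    one_way_anova(y, rep(c("a", "b"), each = 10))$p[1]
  })
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("significance stars follow the documented strict boundaries", {
  expect_equal(significance_stars(c(0.2, 0.049, 0.01, 0.009, 0.0009)),
               c("ns", "*", "*", "**", "***"))
})
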