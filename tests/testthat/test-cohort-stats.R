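test_that("Kruskal-Wallis handles identical groups and tiny samples", {
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "degenerate")
  same <- list(c(1, 5, 9), c(9, 1, 5))
  kw <- kruskal_wallis(same)
  expect_equal(unname(kw$statistic), 0)
  expect_equal(kw$p.value, 1)

  # chi-square p within 0.02 of the permutation distribution
  set.seed(21)
  for (i in 1:5) {
    x <- sample(100, 9)
    g <- split(x, rep(1:3, c(3, 3, 3)))
    kw2 <- kruskal_wallis(g)
    dist <- oracle_perm_dist(x, c(3, 3, 3), oracle_kw_h)
    p_perm <- mean(dist >= unname(kw2$statistic) - 1e-9)
    expect_lt(abs(kw2$p.value - p_perm), 0.02)
  }
})

test_that("two-group Kruskal-Wallis agrees with the rank-sum normal p", {
  set.seed(22)
  a <- rnorm(25)
  b <- rnorm(30, 0.5)
  kw <- kruskal_wallis(list(a, b))
  w <- wilcoxon_rank_sum(a, b)
  expect_lt(abs(kw$p.value - w$p.value), 0.01)
})

test_that("Wilcoxon rank-sum matches exact small-sample enumeration", {
  # extreme case: one-sided p = 1/20 over the 20 orderings
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(w$p.value, 1 / 20)
  # permutation-oracle agreement on the two-sided p
  set.seed(23)
  for (i in 1:5) {
    x <- sample(100, 8)
    a <- x[1:4]; b <- x[5:8]
    got <- wilcoxon_rank_sum(a, b)$p.value
    dist <- oracle_perm_dist(x, c(4, 4), oracle_rank_sum)
    obs <- oracle_rank_sum(list(a, b))
    mu <- mean(dist)
    p_perm <- mean(abs(dist - mu) >= abs(obs - mu) - 1e-9)
    expect_lt(abs(got - p_perm), 0.02)
  }
  # symmetry and identity
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p.value,
               wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3))$p.value)
  expect_gte(wilcoxon_rank_sum(c(1, 2, 5), c(5, 1, 2))$p.value, 0.99)
})

test_that("chi-square matches the printed sex-by-cancer table and hand sums", {
  sex <- rbind(man = c(AEGJ = 152, GAC = 189, ESCC = 492),
               woman = c(62, 67, 260))
  ct <- chi_square_test(sex)
  expect_equal(round(ct$p.value, 3), 0.027)  # the printed precision
  expect_equal(ct$df, 2)

  prop <- rbind(c(10, 20), c(30, 60))        # perfectly proportional
  ct2 <- chi_square_test(prop)
  expect_equal(unname(ct2$statistic), 0)
  expect_equal(ct2$p.value, 1)

  tab <- rbind(c(10, 20), c(20, 10))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(unname(chi_square_test(tab)$statistic),
               sum((tab - e)^2 / e))
  expect_error(chi_square_test(rbind(c(0, 0), c(1, 2))), "degenerate")
})

test_that("Bonferroni multiplies and caps", {
  expect_equal(bonferroni_adjust(0.04), 0.04)
  expect_equal(bonferroni_adjust(0.02, m = 3), 0.06)
  expect_equal(bonferroni_adjust(c(0.5, 0.01), m = 3), c(1, 0.03))
  expect_true(all(bonferroni_adjust(runif(10)) >= runif(0)))
})

test_that("Spearman is rank-then-Pearson", {
  expect_equal(spearman(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman(1:10, -(1:10)^3)$rho, -1)
  x <- c(1, 2, 2, 4, 5)
  y <- c(3, 1, 4, 4, 9)
  rx <- rank(x); ry <- rank(y)
  r_hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman(x, y)$rho, r_hand)
  expect_error(spearman(c(1, 1, 1), c(2, 3, 4)), "zero rank variance")
})

test_that("OLS equals the normal-equations solution", {
  des <- data.frame(x1 = c(0.1, 1.3, 2.2, 3.1, 4.7, 5.2),
                    x2 = c(1, 0, 1, 0, 1, 0))
  y <- c(2.1, 3.9, 6.3, 7.8, 11.0, 11.9)
  fit <- fit_linear_model(des, y)
  X <- cbind(1, des$x1, des$x2)
  b_hand <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$coefficients$B, as.vector(b_hand), tolerance = 1e-8)
  # adjusted R2 identity
  n <- length(y); p <- 2
  expect_equal(fit$adj_r_squared,
               1 - (1 - fit$r_squared) * (n - 1) / (n - p - 1))
  # exact linear response
  fit2 <- suppressWarnings(fit_linear_model(des, 2 + 3 * des$x1 - des$x2))
  expect_equal(fit2$r_squared, 1)
  # standardised coefficient of a variable on itself is 1
  z <- scale(rnorm(20))[, 1]
  fit3 <- suppressWarnings(fit_linear_model(data.frame(x = z), z))
  expect_equal(fit3$coefficients$Beta[fit3$coefficients$term == "x"], 1)
  # collinearity is reported, naming the term
  expect_error(fit_linear_model(cbind(des, x3 = des$x1 * 2), y),
               "collinearity")
})

test_that("cancer-type effects on TIL are recovered in the published order", {
  # simulate AEGJ > GAC > ESCC TIL offsets (standardised effects 0.36/0.28
  # serve as the simulation truth) and check the fitted Betas keep the order
  set.seed(30)
  n <- 1500
  type <- factor(sample(c("ESCC", "GAC", "AEGJ"), n, replace = TRUE),
                 levels = c("ESCC", "GAC", "AEGJ"))
  age <- rnorm(n, 65, 8)
  y <- 2 + 8.28 * (type == "AEGJ") + 6.07 * (type == "GAC") +
    0.01 * age + rnorm(n, sd = 8)
  fit <- fit_linear_model(data.frame(cancer_type = type, age = age), y,
                          reference = list(cancer_type = "ESCC"))
  cf <- fit$coefficients
  b_aegj <- cf$Beta[cf$term == "cancer_typeAEGJ"]
  b_gac <- cf$Beta[cf$term == "cancer_typeGAC"]
  expect_gt(b_aegj, 0)
  expect_gt(b_gac, 0)
  expect_gt(b_aegj, b_gac)
})

test_that("Kruskal-Wallis H is invariant under monotone transforms", {
  set.seed(24)
  g <- list(rnorm(12), rnorm(10, 1), rnorm(15, 2))
  h1 <- unname(kruskal_wallis(g)$statistic)
  h2 <- unname(kruskal_wallis(lapply(g, function(v) exp(v)))$statistic)
  expect_equal(h1, h2)
})
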