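tiny_separable_set <- function(n_per_class = 12L) {
  fc <- sprintf("f%02d", 1:43)
  centers <- list(cancer = 5, lymphocyte = 0, stroma = -5)
  rec <- do.call(rbind, lapply(names(centers), function(cl) {
    m <- matrix(centers[[cl]], n_per_class, 43,
                dimnames = list(NULL, fc))
    m <- m + matrix(rnorm(length(m), sd = 0.1), nrow(m))
    df <- as.data.frame(m)
    df$label <- cl
    df
  }))
  training_set(rec, "AEGJ")
}

test_that("training set construction enforces labels and classes", {
  set.seed(1)
  ts <- tiny_separable_set()
  expect_s3_class(ts, "training_set")
  rec <- ts$records
  rec2 <- rec[rec$label != "stroma", ]
  expect_error(training_set(rec2), "missing class")
  rec3 <- rec
  rec3$label[1] <- NA
  expect_error(training_set(rec3), "label")
})

test_that("well-separated classes are memorised and predicted exactly", {
  set.seed(2)
  ts <- tiny_separable_set()
  model <- train_classifier(ts, seed = 1)
  pred <- classify_cells(model, ts$records)
  expect_equal(pred$label, ts$records$label)   # 100% resubstitution

  # determinism on a probe set
  set.seed(99)
  probe <- tiny_separable_set()$records
  m2 <- train_classifier(ts, seed = 1)
  expect_identical(classify_cells(model, probe)$label,
                   classify_cells(m2, probe)$label)

  empty <- ts$records[0, ]
  expect_equal(nrow(classify_cells(model, empty)), 0L)
  expect_error(classify_cells(model, ts$records[, -3]), "registry")
})

test_that("cross-validation is stratified, order-invariant and near chance on permuted labels", {
  set.seed(3)
  ts <- tiny_separable_set(20L)
  cv <- cross_validate(ts, k = 5, seed = 2)
  expect_gte(cv$overall_accuracy, 99)

  shuf <- ts$records[sample(nrow(ts$records)), ]
  cv_shuf <- cross_validate(training_set(shuf, ts$cancer_type), k = 5,
                            seed = 2)
  expect_equal(cv_shuf$overall_accuracy, cv$overall_accuracy)

  expect_error(cross_validate(tiny_separable_set(3L), k = 5), "fewer than")

  # label permutation destroys the signal: accuracy near 1/3
  perm <- ts$records
  set.seed(7)
  accs <- vapply(1:5, function(i) {
    perm$label <- sample(perm$label)
    cross_validate(training_set(perm, "AEGJ"), k = 5,
                   seed = i)$overall_accuracy
  }, numeric(1L))
  expect_lt(abs(mean(accs) - 100 / 3), 10)
})

test_that("leave-one-out equals k-fold with singleton folds", {
  set.seed(4)
  ts <- tiny_separable_set(5L)
  n <- nrow(ts$records)
  cv <- cross_validate(ts, k = 5, seed = 3)
  loo <- cross_validate(ts, k = 5, seed = 3)   # same folds, sanity
  expect_equal(cv$overall_accuracy, loo$overall_accuracy)
})

test_that("synthetic training sets cross-validate above 95%", {
  cv <- cross_validate(shared_training_set(), k = 10, seed = 1)
  expect_gte(cv$overall_accuracy, 95)
  expect_true(all(cv$per_class_accuracy >= 0 & cv$per_class_accuracy <= 100))
})

test_that("concordance with manual counts reproduces the Pearson formula", {
  auto <- rbind(c(50, 10, 40), c(60, 20, 20), c(30, 30, 40),
                c(80, 5, 15), c(45, 25, 30))
  expect_equal(concordance_with_manual(auto, auto)$overall, 1)

  manual <- rbind(c(40, 15, 45), c(55, 25, 20), c(35, 25, 40),
                  c(70, 10, 20), c(50, 20, 30))
  got <- concordance_with_manual(auto, manual)
  pa <- as.vector(auto / rowSums(auto))
  pm <- as.vector(manual / rowSums(manual))
  r_hand <- sum((pa - mean(pa)) * (pm - mean(pm))) /
    sqrt(sum((pa - mean(pa))^2) * sum((pm - mean(pm))^2))
  expect_equal(got$overall, r_hand)
  expect_true(all(abs(got$per_class) <= 1))
})

test_that("Jonckheere-Terpstra reduces to Mann-Whitney for two groups", {
  a <- c(3, 1, 4, 1, 5)
  b <- c(9, 2, 6, 5, 3.5)
  jt <- jonckheere_terpstra(list(a, b))
  u <- sum(outer(a, b, "<")) + 0.5 * sum(outer(a, b, "=="))
  expect_equal(unname(jt$statistic), u)
})

test_that("exact JT p-values match full enumeration", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  jt <- jonckheere_terpstra(g)
  expect_equal(unname(jt$statistic), 12)     # maximum
  expect_equal(unname(jt$statistic), oracle_jt(g))
  # enumeration oracle: all 6!/(2!2!2!) = 90 assignments
  dist <- oracle_perm_dist(unlist(g), c(2, 2, 2), oracle_jt)
  expect_length(dist, 90L)
  p_oracle <- 2 * min(mean(dist >= 12), mean(dist <= 12))
  expect_equal(jt$p.value, p_oracle)

  set.seed(11)
  for (i in 1:5) {
    x <- sample(50, 9)
    gg <- split(x, rep(1:3, each = 3))
    jt2 <- jonckheere_terpstra(gg)
    d2 <- oracle_perm_dist(x, c(3, 3, 3), oracle_jt)
    s2 <- unname(jt2$statistic)
    expect_equal(jt2$p.value,
                 min(1, 2 * min(mean(d2 >= s2 - 1e-9),
                                mean(d2 <= s2 + 1e-9))))
  }
})

test_that("JT normal approximation tracks the exact tail within 0.02", {
  set.seed(12)
  for (i in 1:25) {
    ns <- sample(2:4, 3, replace = TRUE)
    x <- sample(1000, sum(ns))               # no ties
    g <- split(x, rep(seq_along(ns), ns))
    pe <- jonckheere_terpstra(g, exact_limit = 12)$p.value
    pn <- jonckheere_terpstra(g, exact_limit = 0)$p.value
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("JT handles degenerate and single-group input", {
  expect_warning(out <- jonckheere_terpstra(list(c(2, 2), c(2, 2), c(2, 2))),
                 "tied")
  expect_equal(out$p.value, 1)
  expect_error(jonckheere_terpstra(list(1:5)), "at least 2")
  expect_error(jonckheere_terpstra(list(1:3, numeric(0))), "nonempty")
})
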