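#' Kruskal-Wallis H test across groups
#'
#' Tie-corrected Kruskal-Wallis rank test. For small pooled samples (total
#' n at most `exact_limit`) the p-value comes from full enumeration of the
#' permutation distribution of H; otherwise from the chi-square distribution
#' with `g - 1` degrees of freedom.
#'
#' @param groups List of numeric vectors (>= 2 nonempty groups), or a
#'   numeric vector plus a grouping factor via `g`.
#' @param g Optional grouping factor when `groups` is a vector.
#' @param exact_limit Largest pooled n for which the permutation
#'   distribution is enumerated (default 12).
#' @return A `test_result` list: `statistic` (H), `df`, `p.value` and
#'   per-group `summaries` (n, median, IQR).
#' @export
kruskal_wallis <- function(groups, g = NULL, exact_limit = 12L) {
  groups <- as_group_list(groups, g)
  if (length(groups) < 2L || any(!lengths(groups)))
    stopf("need at least 2 nonempty groups")
  x <- unlist(groups)
  if (length(unique(x)) == 1L)
    stopf("degenerate data: all observations tied across all groups")
  fac <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- suppressWarnings(kruskal.test(x, fac))
  h <- unname(kt$statistic)
  n <- length(x)
  if (n <= exact_limit) {
    dist <- kw_perm_dist(x, lengths(groups))
    p <- mean(dist >= h - 1e-9)
    method <- "Kruskal-Wallis H test (exact permutation)"
  } else {
    p <- kt$p.value
    method <- "Kruskal-Wallis H test"
  }
  test_result(statistic = c(H = h), df = unname(kt$parameter), p.value = p,
              method = method, summaries = group_summaries(groups))
}

# Permutation distribution of the tie-corrected H: the ranks are fixed, so
# each assignment only needs group rank sums.
kw_perm_dist <- function(x, sizes) {
  r <- rank(x)
  n <- length(x)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h_of <- function(groups) {
    (12 / (n * (n + 1)) *
       sum(vapply(groups, function(ii) length(ii) * mean(r[ii])^2, 0)) -
       3 * (n + 1)) / corr
  }
  out <- numeric(0)
  recurse <- function(avail, sz, acc) {
    if (length(sz) == 1L) {
      out[length(out) + 1L] <<- h_of(c(acc, list(avail)))
      return(invisible())
    }
    picks <- combn(length(avail), sz[1L])
    for (i in seq_len(ncol(picks))) {
      sel <- picks[, i]
      recurse(avail[-sel], sz[-1L], c(acc, list(avail[sel])))
    }
  }
  recurse(seq_len(n), sizes, list())
  out
}

#' Wilcoxon rank-sum test
#'
#' Two-sided by default; exact when the smaller sample has at most 8
#' observations and there are no ties, otherwise the tie-corrected normal
#' approximation (without continuity correction, so that identical samples
#' give p = 1).
#'
#' @param a,b Numeric vectors.
#' @param alternative Passed to [stats::wilcox.test()].
#' @return A `test_result` list with `statistic` (W), `p.value`.
#' @export
wilcoxon_rank_sum <- function(a, b, alternative = "two.sided") {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && min(length(a), length(b)) <= 8L
  wt <- suppressWarnings(wilcox.test(a, b, alternative = alternative,
                                     exact = exact, correct = FALSE))
  test_result(statistic = c(W = unname(wt$statistic)), df = NA_real_,
              p.value = wt$p.value,
              method = paste0("Wilcoxon rank-sum test (",
                              if (exact) "exact" else "normal approximation",
                              ")"),
              summaries = group_summaries(list(a = a, b = b)))
}

#' Pearson chi-square test of a contingency table
#'
#' @param table Matrix of counts, at least 2 x 2, without zero marginals.
#' @return A `test_result` list with `statistic` (X2), `df`, `p.value`.
#' @examples
#' sex_by_cancer <- rbind(man = c(152, 189, 492), woman = c(62, 67, 260))
#' chi_square_test(sex_by_cancer)$p.value  # 0.027
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) >= 2L, ncol(table) >= 2L)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stopf("degenerate table: zero marginal")
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  test_result(statistic = c(X2 = unname(ct$statistic)),
              df = unname(ct$parameter), p.value = ct$p.value,
              method = "Pearson chi-square test", summaries = NULL)
}

#' Bonferroni adjustment
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param m Number of comparisons (default `length(pvals)`).
#' @return Adjusted p-values `min(1, m * p)`.
#' @export
bonferroni_adjust <- function(pvals, m = length(pvals)) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  pmin(1, m * pvals)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks, with the asymptotic t-based p-value.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return List with `rho`, `p.value`, `n`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stopf("undefined correlation: zero rank variance")
  rho <- cor(rx, ry)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = rho, p.value = ct$p.value, n = length(x))
}

#' Multivariable linear regression of TIL proportion
#'
#' Ordinary least squares of `y` on the covariate table (complete cases;
#' factors dummy-coded against their stated reference levels). Reports per
#' term the unstandardised coefficient B, its SE, normal-approximation 95%
#' CI, standardised coefficient Beta = B * SD(x) / SD(y), and p, plus R-squared
#' and adjusted R-squared.
#'
#' @param design Data frame of covariates (factors and numerics).
#' @param y Numeric response (TIL %).
#' @param reference Optional named list of reference levels, e.g.
#'   `list(cancer_type = "ESCC")`.
#' @return A list of class `regression_fit` with `coefficients` (data
#'   frame), `r_squared`, `adj_r_squared`, `n`.
#' @export
fit_linear_model <- function(design, y, reference = NULL) {
  stopifnot(is.data.frame(design), nrow(design) == length(y))
  ok <- complete.cases(design) & is.finite(y)
  design <- design[ok, , drop = FALSE]
  y <- y[ok]
  for (nm in names(reference)) {
    design[[nm]] <- stats::relevel(factor(design[[nm]]),
                                   ref = reference[[nm]])
  }
  dat <- cbind(design, .y = y)
  fit <- lm(.y ~ ., data = dat)
  X <- model.matrix(fit)
  if (qr(X)$rank < ncol(X)) {
    al <- is.na(coef(fit))
    stopf("collinearity error: terms not estimable: %s",
          paste(names(coef(fit))[al], collapse = ", "))
  }
  sm <- summary(fit)
  ce <- sm$coefficients
  terms_x <- rownames(ce)
  sdx <- apply(X, 2L, sd)[terms_x]
  beta_std <- ce[, 1L] * sdx / sd(y)
  z <- qnorm(0.975)
  coefs <- data.frame(term = terms_x, B = ce[, 1L], SE = ce[, 2L],
                      ci_lo = ce[, 1L] - z * ce[, 2L],
                      ci_hi = ce[, 1L] + z * ce[, 2L],
                      Beta = beta_std, p.value = ce[, 4L],
                      row.names = NULL)
  coefs$Beta[terms_x == "(Intercept)"] <- NA_real_
  structure(list(coefficients = coefs, r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared, n = length(y),
                 fit = fit),
            class = "regression_fit")
}

# --- helpers -----------------------------------------------------------------

as_group_list <- function(groups, g) {
  if (!is.null(g)) return(split(groups, g))
  if (!is.list(groups)) stopf("groups must be a list (or supply g)")
  groups
}

group_summaries <- function(groups) {
  do.call(rbind, lapply(seq_along(groups), function(i) {
    v <- groups[[i]]
    data.frame(group = if (is.null(names(groups))) as.character(i)
               else names(groups)[i],
               n = length(v), median = median(v),
               q1 = unname(quantile(v, 0.25)),
               q3 = unname(quantile(v, 0.75)))
  }))
}

test_result <- function(statistic, df, p.value, method, summaries) {
  structure(list(statistic = statistic, df = df, p.value = p.value,
                 method = method, summaries = summaries),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  %s = %.4g%s, p = %.4g\n", names(x$statistic), x$statistic,
              if (!is.na(x$df)) sprintf(", df = %g", x$df) else "",
              x$p.value))
  invisible(x)
}
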