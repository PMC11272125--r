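#' Jonckheere-Terpstra test for an ordered trend
#'
#' Tests a monotone location trend across `g >= 2` groups given in a stated
#' order. The statistic is the sum of pairwise Mann-Whitney counts
#' \eqn{JT = \sum_{i<j} U_{ij}} (ties counted 1/2). The p-value comes from
#' full enumeration of group assignments when the total sample size is at
#' most `exact_limit`, otherwise from a normal approximation with the
#' tie-corrected variance.
#'
#' @param samples List of numeric vectors, one per group, in increasing
#'   hypothesised order.
#' @param alternative `"two.sided"` (default), `"increasing"` or
#'   `"decreasing"`.
#' @param exact_limit Largest total n for which the exact permutation
#'   distribution is enumerated (default 12).
#' @return An `htest`-style list with `statistic` (JT), `p.value`, `method`
#'   and the null mean/sd.
#' @examples
#' jonckheere_terpstra(list(c(1, 2), c(3, 4), c(5, 6)))
#' @export
jonckheere_terpstra <- function(samples,
                                alternative = c("two.sided", "increasing",
                                                "decreasing"),
                                exact_limit = 12L) {
  alternative <- match.arg(alternative)
  if (!is.list(samples) || length(samples) < 2L)
    stopf("test undefined: need at least 2 ordered groups")
  if (any(!vapply(samples, length, 1L)))
    stopf("test undefined: every group must be nonempty")
  x <- unlist(samples)
  ni <- vapply(samples, length, 1L)
  g <- factor(rep(seq_along(samples), ni))
  N <- length(x)

  jt <- jt_statistic(x, g)
  mu <- (N^2 - sum(ni^2)) / 4

  if (length(unique(x)) == 1L) {
    warnf("all observations tied: no trend information")
    return(jt_result(jt, mu, 0, 1, "degenerate"))
  }

  if (N <= exact_limit) {
    dist <- jt_exact_distribution(x, ni)
    p <- switch(alternative,
      increasing = sum(dist$prob[dist$jt >= jt - 1e-9]),
      decreasing = sum(dist$prob[dist$jt <= jt + 1e-9]),
      two.sided = min(1, 2 * min(sum(dist$prob[dist$jt >= jt - 1e-9]),
                                 sum(dist$prob[dist$jt <= jt + 1e-9]))))
    sig <- sqrt(sum(dist$prob * (dist$jt - mu)^2))
    return(jt_result(jt, mu, sig, p, "exact"))
  }

  # tie-corrected null variance (counts t_j of each distinct value)
  tj <- as.numeric(table(x))
  v1 <- (N * (N - 1) * (2 * N + 5) -
           sum(ni * (ni - 1) * (2 * ni + 5)) -
           sum(tj * (tj - 1) * (2 * tj + 5))) / 72
  v2 <- sum(ni * (ni - 1) * (ni - 2)) * sum(tj * (tj - 1) * (tj - 2)) /
    (36 * N * (N - 1) * (N - 2))
  v3 <- sum(ni * (ni - 1)) * sum(tj * (tj - 1)) / (8 * N * (N - 1))
  sig <- sqrt(v1 + v2 + v3)
  if (sig == 0) {
    warnf("degenerate variance: no trend information")
    return(jt_result(jt, mu, 0, 1, "degenerate"))
  }
  # continuity-corrected normal approximation
  p <- switch(alternative,
              increasing = pnorm((jt - mu - 0.5) / sig, lower.tail = FALSE),
              decreasing = pnorm((jt - mu + 0.5) / sig),
              two.sided = min(1, 2 * pnorm((abs(jt - mu) - 0.5) / sig,
                                           lower.tail = FALSE)))
  jt_result(jt, mu, sig, p, "normal")
}

jt_statistic <- function(x, g) {
  lev <- levels(g)
  jt <- 0
  for (i in seq_along(lev)[-length(lev)])
    for (j in (i + 1L):length(lev)) {
      a <- x[g == lev[i]]
      b <- x[g == lev[j]]
      cmp <- outer(a, b, "<")
      eq <- outer(a, b, "==")
      jt <- jt + sum(cmp) + 0.5 * sum(eq)
    }
  jt
}

# Exact null distribution by enumerating all distinct assignments of the
# pooled observations to the groups. The pairwise comparison matrix
# C[a, b] = 1(x_a < x_b) + 0.5 * 1(x_a = x_b) is precomputed once so each
# assignment costs only submatrix sums.
jt_exact_distribution <- function(x, ni) {
  C <- outer(x, x, "<") + 0.5 * outer(x, x, "==")
  ng <- length(ni)
  jt_of <- function(groups) {
    s <- 0
    for (i in seq_len(ng - 1L))
      for (j in (i + 1L):ng)
        s <- s + sum(C[groups[[i]], groups[[j]]])
    s
  }
  res <- new.env()
  res$jt <- numeric(0)
  res$cnt <- numeric(0)
  recurse <- function(avail, sizes, assigned) {
    if (length(sizes) == 1L) {
      v <- jt_of(c(assigned, list(avail)))
      key <- match(v, res$jt)
      if (is.na(key)) {
        res$jt <- c(res$jt, v)
        res$cnt <- c(res$cnt, 1)
      } else res$cnt[key] <- res$cnt[key] + 1
      return(invisible())
    }
    picks <- combn(length(avail), sizes[1L])
    for (ci in seq_len(ncol(picks))) {
      sel <- picks[, ci]
      recurse(avail[-sel], sizes[-1L], c(assigned, list(avail[sel])))
    }
  }
  recurse(seq_along(x), ni, list())
  list(jt = res$jt, prob = res$cnt / sum(res$cnt))
}

jt_result <- function(jt, mu, sig, p, method) {
  structure(list(statistic = c(JT = jt), p.value = p,
                 null_mean = mu, null_sd = sig,
                 method = paste("Jonckheere-Terpstra trend test,", method)),
            class = "htest")
}
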