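# Independent oracles used by the tests. These deliberately re-derive each
# quantity by brute force or first principles, never through the package's
# own code paths.

# Exhaustive between-class-variance scan over all candidate bin boundaries.
oracle_otsu <- function(gray, n_bins = 256L) {
  v <- as.vector(gray)
  bin <- pmin(floor(v * n_bins), n_bins - 1L) + 1L
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  best_k <- NA_integer_
  best_s <- -Inf
  for (k in seq_len(n_bins - 1L)) {
    lo <- bin <= k
    w0 <- mean(lo)
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- mean(mids[bin[lo]])
    mu1 <- mean(mids[bin[!lo]])
    s <- w0 * w1 * (mu0 - mu1)^2
    if (s > best_s + 1e-15) {
      best_s <- s
      best_k <- k
    }
  }
  best_k / n_bins
}

# All distinct assignments of the pooled sample to groups of the given
# sizes; returns the permutation distribution of statfun(list_of_groups).
oracle_perm_dist <- function(x, sizes, statfun) {
  out <- numeric(0)
  recurse <- function(avail, sz, acc) {
    if (length(sz) == 1L) {
      out[length(out) + 1L] <<- statfun(c(acc, list(x[avail])))
      return(invisible())
    }
    picks <- utils::combn(length(avail), sz[1L])
    for (i in seq_len(ncol(picks))) {
      sel <- picks[, i]
      recurse(avail[-sel], sz[-1L], c(acc, list(x[avail[sel]])))
    }
  }
  recurse(seq_along(x), sizes, list())
  out
}

# Direct double-loop Jonckheere-Terpstra count.
oracle_jt <- function(groups) {
  s <- 0
  g <- length(groups)
  for (i in seq_len(g - 1L))
    for (j in (i + 1L):g)
      for (a in groups[[i]])
        for (b in groups[[j]])
          s <- s + (a < b) + 0.5 * (a == b)
  s
}

# Kruskal-Wallis H computed from first principles (tie-corrected).
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  r <- rank(x)
  N <- length(x)
  idx <- split(seq_len(N), rep(seq_along(groups), lengths(groups)))
  h <- 12 / (N * (N + 1)) *
    sum(vapply(idx, function(ii) length(ii) * mean(r[ii])^2, 0)) -
    3 * (N + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Rank sum of the first group (Wilcoxon W plus offset).
oracle_rank_sum <- function(groups) sum(rank(unlist(groups))[
  seq_along(groups[[1L]])])

# Cox log partial likelihood for a single covariate without ties.
oracle_cox_logpl <- function(beta, x, times, events) {
  ll <- 0
  for (i in which(events == 1L)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Log-rank observed-minus-expected via an explicit risk-set tabulation.
oracle_logrank_oe <- function(group, times, events) {
  group <- factor(group)
  lev <- levels(group)
  o <- e <- setNames(numeric(length(lev)), lev)
  for (t in sort(unique(times[events == 1L]))) {
    at_risk <- times >= t
    d <- events == 1L & times == t
    for (l in lev) {
      o[l] <- o[l] + sum(d & group == l)
      e[l] <- e[l] + sum(d) * sum(at_risk & group == l) / sum(at_risk)
    }
  }
  o - e
}
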