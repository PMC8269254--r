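# Independent oracles used across the suite.  Each is a deliberately
# naive re-derivation (brute force, closed form, or enumeration) of a
# quantity the package computes by its own path.

# Benjamini-Hochberg by direct sort / (i/m) scaling / cummin
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# leading eigenvector of the covariance of the z-scored panel
eigen_pc1_oracle <- function(m) {
  s <- scale(m)
  eigen(stats::cov(s), symmetric = TRUE)$vectors[, 1]
}

# OLS y ~ x evaluated at x0, by the closed-form slope/intercept
ols_at_oracle <- function(x, y, x0) {
  b <- stats::cov(x, y) / stats::var(x)
  a <- mean(y) - b * mean(x)
  a + b * x0
}

# SparCC basis variances by building the full linear system explicitly
# from pairwise log-ratio variances and solving it densely
sparcc_basis_oracle <- function(counts, pseudocount = 1) {
  x <- log(counts + pseudocount)
  d <- nrow(x)
  Tm <- matrix(0, d, d)
  for (i in seq_len(d)) {
    for (j in seq_len(d)) {
      if (i != j) Tm[i, j] <- stats::var(x[i, ] - x[j, ])
    }
  }
  A <- matrix(1, d, d) + diag(rep(d - 2, d))
  qr.solve(A, rowSums(Tm))
}

# maximal qualifying subtrees by recursing over the dendrogram object
# (a different tree representation than the package's merge-matrix walk)
smd_oracle <- function(corr, min_r, r_is_squared = FALSE) {
  hc <- stats::hclust(stats::as.dist(1 - corr), method = "complete")
  dend <- stats::as.dendrogram(hc)
  ok <- function(tips) {
    sub <- corr[tips, tips]
    v <- sub[upper.tri(sub)]
    if (r_is_squared) all(v > 0 & v^2 >= min_r) else all(v >= min_r)
  }
  found <- list()
  walk <- function(node) {
    tips <- labels(node)
    if (length(tips) >= 2 && ok(tips)) {
      found[[length(found) + 1]] <<- sort(tips)
      return(invisible())          # maximal: do not descend further
    }
    if (!is.leaf(node)) for (k in seq_along(node)) walk(node[[k]])
  }
  walk(dend)
  found[order(vapply(found, `[`, character(1), 1))]
}

# all permutations of 1..n by the choose-first-element recursion
perms_oracle <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (sub in perms_oracle(n - 1)) {
      out[[length(out) + 1]] <- c(first, rest[sub])
    }
  }
  out
}

# exact two-sided Mantel p by enumerating every relabeling
mantel_exact_oracle <- function(m1, m2) {
  n <- nrow(m1)
  ut <- upper.tri(m1)
  r_obs <- stats::cor(m1[ut], m2[ut])
  hits <- 0
  for (pm in perms_oracle(n)) {
    if (abs(stats::cor(m1[ut], m2[pm, pm][ut])) >= abs(r_obs) - 1e-12) {
      hits <- hits + 1
    }
  }
  hits / factorial(n)
}

# small random marker panel on plausible scales
toy_marker_panel <- function(n = 10, seed = 1) {
  set.seed(seed)
  nm <- metsys:::marker_names()
  m <- sapply(c(130, 95, 12, 110, 50, 8, 10), function(mu) {
    abs(stats::rnorm(n, mu, mu / 4))
  })
  colnames(m) <- nm
  rownames(m) <- sprintf("S%02d", seq_len(n))
  m
}

# four-gene toy reaction map with overlapping product sets
toy_map <- function() {
  list(
    genes = list(g1 = "r1", g2 = c("r1", "r2"), g3 = "r3", g4 = "r4"),
    reactions = list(
      r1 = list(substrates = "S1", products = c("C1", "C2")),
      r2 = list(substrates = "S2", products = "C3"),
      r3 = list(substrates = c("S3", "C3"), products = c("C2", "C4")),
      r4 = list(substrates = "C4", products = "C5")))
}
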