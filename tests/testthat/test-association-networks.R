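test_that("a strictly monotone pair forms a perfect-rho edge", {
  set.seed(1)
  x <- rnorm(20)
  f <- data.frame(a = x, b = exp(x), c = rnorm(20), d = rnorm(20))
  net <- spearman_network(f, fdr_threshold = 0.25)
  e <- subset(net$edges, feature_a == "a" & feature_b == "b")
  expect_equal(e$rho, 1)
  # Spearman is invariant under strictly monotone transforms
  all_ab <- subset(net$all_pairs, feature_a == "a" & feature_b == "b")
  f2 <- f; f2$a <- qlogis(pnorm(f2$a))
  net2 <- spearman_network(f2, fdr_threshold = 0.25)
  expect_equal(subset(net2$all_pairs, feature_a == "a" &
                        feature_b == "b")$rho, all_ab$rho)
})

test_that("q-values equal the brute-force BH oracle and are monotone", {
  set.seed(2)
  f <- data.frame(matrix(rnorm(30 * 10), 30))
  f$X2 <- f$X1 + rnorm(30, sd = 0.4)
  net <- spearman_network(f, fdr_threshold = 0.25)
  tbl <- net$all_pairs
  expect_equal(tbl$q, brute_bh(tbl$p))
  expect_true(all(tbl$q >= tbl$p))
  o <- order(tbl$p)
  expect_true(all(diff(tbl$q[o]) >= -1e-15))
  # edges are exactly the below-threshold pairs
  expect_setequal(paste(net$edges$feature_a, net$edges$feature_b),
                  paste(tbl$feature_a, tbl$feature_b)[tbl$q < 0.25])
})

test_that("a hub's subnetwork is exactly its incident edges", {
  set.seed(3)
  hub <- rnorm(40)
  f <- data.frame(hub = hub, a = hub + rnorm(40, sd = .3),
                  b = -hub + rnorm(40, sd = .3), c = rnorm(40), d = rnorm(40))
  net <- spearman_network(f, fdr_threshold = 0.25)
  sn <- subnetwork(net, "hub")
  expect_true(all(sn$feature_a == "hub" | sn$feature_b == "hub"))
  expect_true(all(c("a", "b") %in% c(sn$feature_a, sn$feature_b)))
  inc <- net$edges$feature_a == "hub" | net$edges$feature_b == "hub"
  expect_equal(nrow(sn), sum(inc))
})

test_that("outcome correlations flag planted associations at the preset FDR", {
  set.seed(4)
  out <- rnorm(44)
  f <- data.frame(matrix(rnorm(44 * 20), 44))
  f$self <- out
  oc <- outcome_correlations(f, out, fdr_threshold = 0.05)
  expect_equal(oc$rho[oc$feature == "self"], 1)
  expect_equal(unname(which.min(oc$q)), which(oc$feature == "self"))
  expect_true(oc$pass[oc$feature == "self"])
  expect_error(outcome_correlations(f, out[-1]), "schema")
})

test_that("planted score-tracking metabolites are mostly recovered at study n", {
  rec <- vapply(1:20, function(s) {
    set.seed(s)
    z <- rnorm(44)
    n_sig <- 10
    Y <- cbind(
      sapply(seq_len(n_sig), function(i) 0.5 * z + sqrt(.75) * rnorm(44)),
      matrix(rnorm(44 * 190), 44))
    colnames(Y) <- paste0("c", seq_len(ncol(Y)))
    oc <- outcome_correlations(as.data.frame(Y), z, fdr_threshold = 0.05)
    sum(oc$pass[1:n_sig])
  }, numeric(1))
  # rho = 0.5 at n = 44 against a 200-test BH family: a clear majority of
  # the planted compounds pass, never the noise-level handful
  expect_gte(median(rec), 6)
  expect_lt(mean(vapply(1:20, function(s) {
    set.seed(1000 + s)
    Y <- as.data.frame(matrix(rnorm(44 * 200), 44))
    sum(outcome_correlations(Y, rnorm(44), fdr_threshold = 0.05)$pass)
  }, numeric(1))), 1)
})

test_that("Kruskal-Wallis matches hand-computed rank sums", {
  v <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  g <- rep(c("a", "b", "c"), each = 3)
  # no ties: H = 12/(N(N+1)) sum R_j^2/n_j - 3(N+1)
  R <- tapply(rank(v), g, sum)
  H <- 12 / (9 * 10) * sum(R^2 / 3) - 3 * 10
  kw <- kruskal_wallis(v, g)
  expect_equal(kw$H, H, tolerance = 1e-10)
  expect_equal(kw$df, 2)
  # widely separated groups
  set.seed(5)
  v2 <- c(rnorm(15), rnorm(15, 50), rnorm(15, 100))
  expect_lt(kruskal_wallis(v2, rep(1:3, each = 15))$p, 0.001)
  expect_warning(kw0 <- kruskal_wallis(rep(1, 6), rep(1:2, 3)), "tied")
  expect_equal(kw0$p, 1)
})

test_that("Fisher enumeration matches the 2x2 closed form and base R", {
  t22 <- rbind(c(1, 9), c(11, 3))
  # closed-form hypergeometric two-sided p
  x <- 0:10
  probs <- dhyper(x, 10, 14, 12)
  oracle <- sum(probs[probs <= dhyper(1, 10, 14, 12) * (1 + 1e-7)])
  expect_equal(fisher_exact_rxc(t22), oracle, tolerance = 1e-12)
  t23 <- rbind(c(3, 1, 4), c(1, 5, 9))
  expect_equal(fisher_exact_rxc(t23), fisher.test(t23)$p.value,
               tolerance = 1e-9)
})

test_that("enumeration probabilities over fixed margins sum to one", {
  tab <- rbind(c(4, 2, 3), c(1, 5, 2), c(2, 2, 4))
  total <- 0
  metsys:::enumerate_tables(rowSums(tab), colSums(tab), function(t2) {
    total <<- total + exp(metsys:::log_table_prob(t2))
  }, cap = 1e6)
  expect_equal(total, 1, tolerance = 1e-9)
})

test_that("degenerate tables and the enumeration cap behave as documented", {
  expect_equal(fisher_exact_rxc(rbind(c(0, 0), c(3, 5))), 1)
  big <- matrix(200L, 4, 4)
  expect_error(fisher_exact_rxc(big, max_tables = 1000), "monte_carlo")
  expect_error(fisher_exact_rxc(rbind(c(-1, 2), c(3, 4))), "non-negative")
})

test_that("Monte Carlo mode approximates the enumerated p-value", {
  tab <- rbind(c(2, 7, 3), c(8, 2, 5))
  p_exact <- fisher_exact_rxc(tab)
  p_mc <- fisher_exact_rxc(tab, monte_carlo = TRUE, n_mc = 20000, seed = 1)
  expect_lt(abs(p_exact - p_mc), 0.02)
  expect_identical(p_mc, fisher_exact_rxc(tab, monte_carlo = TRUE,
                                          n_mc = 20000, seed = 1))
})
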