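test_that("producibility is single-step product union and monotone", {
  map <- toy_map()
  expect_equal(producible_compounds(character(0), map), character(0))
  expect_equal(producible_compounds("g1", map), c("C1", "C2"))
  # monotone under gene-set union, brute-forced over all 16 subsets
  genes <- names(map$genes)
  subsets <- lapply(0:15, function(k) genes[bitwAnd(k, 2^(0:3)) > 0])
  prods <- lapply(subsets, producible_compounds, map = map)
  for (i in seq_along(subsets)) {
    for (j in seq_along(subsets)) {
      if (all(subsets[[i]] %in% subsets[[j]])) {
        expect_true(all(prods[[i]] %in% prods[[j]]))
      }
    }
  }
  expect_message(out <- producible_compounds(c("g1", "gX"), map), "unknown")
  expect_equal(out, c("C1", "C2"))
})

test_that("reachability mode extends products transitively", {
  map <- toy_map()
  # single-step from g3,g4: r3 products + r4 products need C4 first
  expect_equal(producible_compounds(c("g3", "g4"), map),
               c("C2", "C4", "C5"))
  # from g2 alone, C3 enables nothing without r3 access
  expect_equal(producible_compounds("g2", map, reachability = TRUE),
               c("C1", "C2", "C3"))
})

test_that("origin combination implements the two-pronged rule exactly", {
  set.seed(1)
  ids <- sprintf("C%03d", 1:100)
  pr <- sample(ids, 30)
  df <- sample(ids, 25)
  hu <- sample(ids, 60)
  out <- combine_origin(pr, df, hu)
  for (i in seq_len(nrow(out))) {
    cid <- out$compound[i]
    expect_identical(out$microbiome_associated[i],
                     (cid %in% pr || cid %in% df) && cid %in% hu)
  }
  both <- out$producible_by_microbes & out$mouse_differential
  expect_true(all(out$provenance[both] == "both"))
  # neither prong -> never associated
  neither <- !out$producible_by_microbes & !out$mouse_differential
  expect_true(all(out$provenance[neither] == "none"))
  expect_false(any(out$microbiome_associated[neither]))
})

test_that("identical mouse arms yield no differential compounds", {
  any_hit <- vapply(1:20, function(s) {
    set.seed(s)
    m <- list(intensities = matrix(exp(rnorm(20 * 16, 8)), 20,
                                   dimnames = list(sprintf("C%d", 1:20))),
              design = rep(c("germfree", "colonized"), each = 8))
    any(mouse_differential(m)$stats$significant)
  }, logical(1))
  expect_lte(mean(any_hit), 0.10)
})

test_that("planted fold changes are recovered and prevalence-filtered out", {
  set.seed(2)
  logm <- matrix(rnorm(50 * 16, sd = 0.5), 50)  # mouse-like variability
  logm[1:10, 9:16] <- logm[1:10, 9:16] + 2      # LFC 2 in colonized arm
  m <- list(intensities = exp(8 + logm),
            design = rep(c("germfree", "colonized"), each = 8))
  rownames(m$intensities) <- sprintf("C%d", 1:50)
  res <- mouse_differential(m)
  expect_gte(sum(sprintf("C%d", 1:10) %in% res$differential), 8)
  # a compound absent from >80% of samples is dropped before testing
  m$intensities["C50", ] <- 0
  m$intensities["C50", 1:2] <- 5
  res2 <- mouse_differential(m)
  expect_false("C50" %in% res2$stats$compound)
  expect_error(mouse_differential(list(
    intensities = m$intensities[, c(1, 9)],
    design = c("germfree", "colonized"))), "replication")
})

test_that("rank regression fits an exact line with zero dispersion", {
  set.seed(3)
  x <- rnorm(30)
  fit <- rank_regression(2 * x, cbind(x = x))
  expect_equal(unname(fit$coefficients["x"]), 2, tolerance = 1e-6)
  expect_lt(fit$dispersion, 1e-8)
  expect_lte(fit$dispersion, fit$dispersion0)
})

test_that("the rank slope matches a dispersion-grid oracle", {
  set.seed(4)
  x <- rnorm(8)
  y <- 1 + 0.7 * x + rt(8, df = 3) * 0.5
  fit <- rank_regression(y, cbind(x = x))
  grid <- seq(-2, 3, by = 1e-4)
  disp <- vapply(grid, function(b) {
    e <- y - b * x
    n <- length(e)
    a <- sqrt(12) * (rank(e) / (n + 1) - 0.5)
    sum(a * e)
  }, numeric(1))
  expect_equal(unname(fit$coefficients["x"]), grid[which.min(disp)],
               tolerance = 1e-3)
})

test_that("rank and OLS slopes agree on clean Gaussian data", {
  set.seed(5)
  x <- rnorm(100)
  y <- 2 + 0.8 * x + rnorm(100)
  fit <- rank_regression(y, cbind(x = x))
  ols <- summary(lm(y ~ x))$coefficients
  expect_lt(abs(fit$coefficients[["x"]] - ols[2, 1]), 2 * ols[2, 2])
  # scale equivariance: slopes double when y doubles
  fit2 <- rank_regression(2 * y, cbind(x = x))
  expect_equal(unname(fit2$coefficients["x"]),
               2 * unname(fit$coefficients["x"]), tolerance = 1e-3)
})

test_that("rank regression rejects deficient designs", {
  set.seed(6)
  x <- rnorm(20)
  expect_error(rank_regression(rnorm(20), cbind(x, 2 * x)), "singular")
  expect_error(rank_regression(rnorm(3), cbind(x = rnorm(3))), "n > p")
})

test_that("the with/without-age screen reports overlap correctly", {
  set.seed(7)
  n <- 44
  score <- rnorm(n)
  age <- rnorm(n, 45, 10)
  Y <- rbind(
    t(sapply(1:6, function(i) 2 * score + rnorm(n, sd = 0.8))),
    matrix(rnorm(14 * n), 14))
  rownames(Y) <- sprintf("C%d", 1:20)
  sc <- rank_metabolite_screen(exp(Y), score, age)
  expect_setequal(sc$overlap, intersect(sc$significant_without_age,
                                        sc$significant_with_age))
  expect_gte(length(sc$overlap), 5)
  expect_true(all(sprintf("C%d", 1:6) %in% sc$significant_without_age))
})
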