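fast_vsurf <- list(n_forests = 8, n_trees = 100, n_forests_nested = 3,
                   n_trees_nested = 100)

test_that("a deterministic signal dominates forest importance", {
  set.seed(1)
  X <- data.frame(matrix(rnorm(200 * 51), 200))
  names(X) <- c("x1", paste0("noise_", 1:50))
  y <- X$x1
  fit <- random_forest_regress(X, y, n_trees = 300, seed = 1)
  expect_identical(names(which.max(fit$importance)), "x1")
  expect_gte(fit$oob_r2, 80)
  expect_lte(fit$oob_r2, 100)
})

test_that("a null response gives near-zero variance explained", {
  r2 <- vapply(1:3, function(s) {
    set.seed(s)
    X <- data.frame(matrix(rnorm(120 * 20), 120))
    random_forest_regress(X, rnorm(120), n_trees = 200, seed = s)$oob_r2
  }, numeric(1))
  expect_true(all(r2 <= 10))
})

test_that("forest fits are bit-reproducible under a fixed seed", {
  set.seed(2)
  X <- data.frame(matrix(rnorm(60 * 5), 60))
  y <- X$X1 + rnorm(60)
  f1 <- random_forest_regress(X, y, n_trees = 100, seed = 42)
  f2 <- random_forest_regress(X, y, n_trees = 100, seed = 42)
  expect_identical(f1$importance, f2$importance)
  expect_identical(f1$oob_r2, f2$oob_r2)
})

test_that("duplicated signal columns share importance but both beat noise", {
  set.seed(3)
  X <- data.frame(matrix(rnorm(200 * 10), 200))
  names(X) <- paste0("noise_", 1:10)
  X$dup1 <- rnorm(200)
  X$dup2 <- X$dup1
  y <- X$dup1
  fit <- random_forest_regress(X, y, n_trees = 300, seed = 3)
  noise_max <- max(fit$importance[paste0("noise_", 1:10)])
  expect_gt(fit$importance[["dup1"]], noise_max)
  expect_gt(fit$importance[["dup2"]], noise_max)
})

test_that("three planted features land in the interpretation set", {
  sp <- simulate_selection_problem(n = 200, n_noise = 50,
                                   n_informative = 3, r2 = 0.3, seed = 1)
  vs <- do.call(vsurf_select, c(list(X = sp$X, y = sp$y, seed = 1),
                                fast_vsurf))
  expect_true(all(sp$informative %in% vs$interpretation_set))
  # nesting invariant
  expect_true(all(vs$prediction_set %in% vs$interpretation_set))
  expect_true(all(vs$interpretation_set %in% vs$threshold_set))
  expect_true(all(vs$threshold_set %in% vs$ranked))
})

test_that("selection content is stable under feature reordering", {
  sp <- simulate_selection_problem(n = 150, n_noise = 20,
                                   n_informative = 3, r2 = 0.35, seed = 2)
  vs1 <- do.call(vsurf_select, c(list(X = sp$X, y = sp$y, seed = 7),
                                 fast_vsurf))
  perm <- rev(seq_len(ncol(sp$X)))
  vs2 <- do.call(vsurf_select,
                 c(list(X = sp$X[, perm], y = sp$y, seed = 7), fast_vsurf))
  expect_true(all(sp$informative %in% vs1$interpretation_set))
  expect_true(all(sp$informative %in% vs2$interpretation_set))
})

test_that("pure-noise selection keeps only a handful of features", {
  sizes <- vapply(1:5, function(s) {
    set.seed(s)
    X <- data.frame(matrix(rnorm(100 * 20), 100))
    vs <- do.call(vsurf_select,
                  c(list(X = X, y = rnorm(100), seed = s), fast_vsurf))
    length(vs$interpretation_set)
  }, numeric(1))
  expect_lte(median(sizes), 3)
})

test_that("the permutation p-value matches its closed form and add-one floor", {
  sp <- simulate_selection_problem(n = 100, n_noise = 10,
                                   n_informative = 2, r2 = 0.5, seed = 3)
  pn <- permutation_null(sp$X, sp$y, B = 19, seed = 1,
                         vsurf_params = list(n_forests = 4, n_trees = 50,
                                             n_forests_nested = 2,
                                             n_trees_nested = 50),
                         n_trees_final = 100)
  expect_equal(pn$p, (1 + sum(pn$permuted >= pn$observed)) / (pn$B + 1))
  expect_gt(pn$p, 0)
  expect_lte(pn$p, 1)
  expect_length(pn$permuted, 19)
  # strong planted signal: no permutation reaches the observed r2
  expect_equal(pn$p, 1 / 20)
})

test_that("invalid selection inputs raise the documented errors", {
  X <- data.frame(a = c(1:9, NA), b = 1:10)
  expect_error(random_forest_regress(X, 1:10), "missing data.*a")
  expect_error(random_forest_regress(data.frame(a = 1:20), rep(1, 20)),
               "degenerate outcome")
  expect_error(vsurf_select(data.frame(a = 1:20), rnorm(20)), ">= 2 features")
  expect_error(permutation_null(data.frame(a = 1:20, b = 1:20), rnorm(20),
                                B = 5), "B < 19")
})
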