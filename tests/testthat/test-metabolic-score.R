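test_that("PC1 loadings match a brute-force eigendecomposition", {
  for (n in c(6, 25, 50)) {
    m <- toy_marker_panel(n, seed = n)
    model <- fit_score_model(m)
    v <- eigen_pc1_oracle(m)
    if (sum(v * model$loadings) < 0) v <- -v
    expect_equal(unname(model$loadings), v, tolerance = 1e-8)
    expect_equal(sum(model$loadings^2), 1, tolerance = 1e-10)
    # orientation makes the triglycerides loading positive
    expect_gt((model$orientation * model$loadings)[["triglycerides"]], 0)
  }
})

test_that("the fitting panel's minimum subject scores exactly 0", {
  m <- toy_marker_panel(20, seed = 2)
  model <- fit_score_model(m)
  s <- score_subjects(model, m)
  expect_equal(min(s$score), 0, tolerance = 1e-12)
  # re-scoring the argmin subject alone still gives 0
  i <- which.min(s$score)
  expect_equal(score_subjects(model, m[c(i, i), , drop = FALSE])$score[1], 0,
               tolerance = 1e-12)
})

test_that("scores are invariant to per-marker affine transforms", {
  m <- toy_marker_panel(15, seed = 3)
  model <- fit_score_model(m)
  s1 <- score_subjects(model, m)$score
  m2 <- sweep(sweep(m, 2, c(2, 3, 0.5, 1, 4, 1, 2), `*`), 2,
              c(10, -5, 1, 0, 20, 2, 0), `+`)
  s2 <- score_subjects(fit_score_model(m2), m2)$score
  expect_equal(s1, s2, tolerance = 1e-8)
  # adding a constant to glucose changes nothing
  m3 <- m; m3[, "glucose"] <- m3[, "glucose"] + 57
  s3 <- score_subjects(fit_score_model(m3), m3)$score
  expect_equal(s1, s3, tolerance = 1e-8)
})

test_that("classification thresholds at the impairment cutoff", {
  # transparent hand-built model: score = log(triglycerides)
  model <- structure(list(
    center = setNames(rep(0, 7), metsys:::marker_names()),
    scale = setNames(rep(1, 7), metsys:::marker_names()),
    loadings = setNames(c(1, 0, 0, 0, 0, 0, 0), metsys:::marker_names()),
    orientation = 1, shift = 0, log_base = exp(1), cutoff = 1.4,
    clinical_thresholds = NULL), class = "score_model")
  m <- toy_marker_panel(2, seed = 4)
  m[, "triglycerides"] <- exp(c(1.5, 1.3))
  s <- score_subjects(model, m)
  expect_equal(s$score, c(1.5, 1.3), tolerance = 1e-12)
  expect_equal(as.character(s$class), c("impaired", "normal"))
})

test_that("the score recovers the latent metabolic factor", {
  cors <- vapply(1:20, function(s) {
    cfg <- synth_config(n_per_cohort = setNames(rep(30, 5), letters[1:5]),
                        seed = s)
    co <- generate_cohort(cfg)
    cor(score_subjects(fit_score_model(co$markers), co$markers)$score,
        co$latent)
  }, numeric(1))
  expect_gte(median(cors), 0.9)
})

test_that("derived cutoff equals the mean of OLS threshold intersections", {
  m <- toy_marker_panel(10, seed = 5)
  scores <- score_subjects(fit_score_model(m), m)$score
  thr <- list(triglycerides = 200, glucose = 100, hdl = 40, ldl = 160)
  oracle <- mean(vapply(names(thr), function(mk) {
    ols_at_oracle(m[, mk], scores, thr[[mk]])
  }, numeric(1)))
  expect_equal(derive_cutoff(scores, m, thr), oracle, tolerance = 1e-10)
  # defaults include the printed 200 mg/dl triglyceride threshold
  expect_equal(fit_score_model(m)$clinical_thresholds$triglycerides, 200)
})

test_that("cutoff construction returns 1.4 when every regression hits 1.4", {
  set.seed(6)
  s <- runif(12, 0, 2.5)
  m <- toy_marker_panel(12, seed = 6)
  m[, "triglycerides"] <- 200 + (s - 1.4) * 50
  m[, "glucose"] <- 100 + (s - 1.4) * 20
  m[, "hdl"] <- 40 - (s - 1.4) * 15
  m[, "ldl"] <- 160 + (s - 1.4) * 40
  expect_equal(derive_cutoff(s, m), 1.4, tolerance = 1e-10)
})

test_that("age-by-cohort slopes match a hand-solved normal-equations fit", {
  set.seed(7)
  age <- c(25, 30, 35, 40, 45, 50, 28, 33, 38, 43, 48, 53)
  cohort <- rep(c("a", "b"), each = 6)
  y <- 0.3 + 0.02 * age + 0.05 * (cohort == "b") * age + rnorm(12, sd = .05)
  D <- cbind(1, age, cohort == "b", age * (cohort == "b"))
  beta <- solve(t(D) %*% D, t(D) %*% y)
  fit <- age_cohort_model(y, age, cohort)
  expect_equal(fit$slope[fit$cohort == "a"], beta[2], tolerance = 1e-8)
  expect_equal(fit$slope[fit$cohort == "b"], beta[2] + beta[4],
               tolerance = 1e-8)
  expect_true(all(fit$p >= 0 & fit$p <= 1))
})

test_that("a cohort-free age effect yields equal per-cohort slopes", {
  set.seed(8)
  age <- runif(90, 25, 65)
  cohort <- rep(c("a", "b", "c"), each = 30)
  y <- 0.02 * age + rnorm(90, sd = 0.02)
  fit <- age_cohort_model(y, age, cohort)
  expect_equal(fit$slope, rep(0.02, 3), tolerance = 0.01)
})

test_that("degenerate inputs raise the documented errors", {
  m <- toy_marker_panel(10, seed = 9)
  expect_error(fit_score_model(m[1:2, ]), "insufficient")
  m2 <- m; m2[, "hdl"] <- 50
  expect_error(fit_score_model(m2), "degenerate scale")
  expect_error(score_subjects(fit_score_model(m), m[, 1:5]), "schema")
  expect_error(age_cohort_model(1:6, 1:6, rep("a", 6)), "2 cohorts")
})
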