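#' Random-forest regression with OOB variance explained
#'
#' Standard random forest (CART regression trees on bootstrap samples,
#' via the randomForest package) reporting out-of-bag percent variance
#' explained, `r2 = 100 * (1 - OOB-MSE / Var(y))`, and per-feature
#' permutation importance (mean decrease in accuracy) with its
#' between-tree standard deviation.
#'
#' @param X data frame or matrix of predictors (no missing values).
#' @param y numeric response.
#' @param n_trees number of trees (default 500).
#' @param mtry variables tried per split; default `ceiling(p / 3)`.
#' @param seed seed; fits are reproducible bit-for-bit under a fixed
#'   seed.
#' @return a `forest_fit` list: `importance`, `importance_sd`,
#'   `oob_r2`, `oob_predicted`, `params`.
#' @export
random_forest_regress <- function(X, y, n_trees = 500L, mtry = NULL,
                                  seed = NULL) {
  X <- as.data.frame(X)
  nas <- vapply(X, anyNA, logical(1))
  if (any(nas)) {
    stop("missing data in column(s): ",
         paste(names(X)[nas], collapse = ", "),
         " (random forests do not allow gaps in data)", call. = FALSE)
  }
  if (anyNA(y)) stop("missing data in response", call. = FALSE)
  if (length(y) < 10L) stop("need n >= 10", call. = FALSE)
  if (stats::var(y) == 0) stop("degenerate outcome: constant y", call. = FALSE)
  p <- ncol(X)
  mtry <- mtry %||% max(1L, ceiling(p / 3))
  rf <- with_seed(seed, {
    randomForest::randomForest(x = X, y = y, ntree = n_trees, mtry = mtry,
                               importance = TRUE)
  })
  pred <- rf$predicted
  r2 <- 100 * (1 - sum((y - pred)^2) / sum((y - mean(y))^2))
  structure(list(importance = rf$importance[, "%IncMSE"],
                 importance_sd = rf$importanceSD,
                 oob_r2 = r2, oob_predicted = pred,
                 params = list(n_trees = n_trees, mtry = mtry, seed = seed)),
            class = "forest_fit")
}

# mean OOB MSE over `reps` forests on a fixed predictor subset
oob_mse_reps <- function(X, y, vars, reps, n_trees, seed) {
  vapply(seq_len(reps), function(r) {
    fit <- with_seed(derive_seed(seed, paste0("nested", r, vars[1],
                                              length(vars))), {
      randomForest::randomForest(x = X[, vars, drop = FALSE], y = y,
                                 ntree = n_trees,
                                 mtry = max(1L, ceiling(length(vars) / 3)))
    })
    mean((y - fit$predicted)^2)
  }, numeric(1))
}

#' Three-phase random-forest variable selection
#'
#' Follows the published VSURF scheme for regression:
#' \enumerate{
#'   \item Thresholding: features are ranked by mean permutation
#'     importance over `n_forests` forests; a CART model is fitted to
#'     the curve of importance standard deviations versus rank, and
#'     features whose mean importance exceeds the minimum CART
#'     prediction are retained.
#'   \item Interpretation: nested forests are grown over growing
#'     prefixes of the ranked retained features; the smallest prefix
#'     whose mean OOB error is within one standard deviation of the
#'     minimum is kept (the analysis set of "important" variables).
#'   \item Prediction: interpretation variables are added stepwise,
#'     keeping those that reduce OOB error by more than a data-driven
#'     tolerance (the mean absolute jump of the tail of the
#'     interpretation error curve), yielding a parsimonious predictive
#'     subset.
#' }
#' The three sets are nested: prediction within interpretation within
#' threshold.
#'
#' @param X predictors (no missing values), >= 2 features.
#' @param y numeric response.
#' @param n_forests forests averaged in the thresholding phase
#'   (published default 25).
#' @param n_trees trees per thresholding forest (default 500).
#' @param n_forests_nested forests averaged per nested model in phases
#'   2-3 (smaller values trade stability for speed).
#' @param n_trees_nested trees per nested forest; defaults to
#'   `n_trees`.
#' @param seed root seed for all forests.
#' @return a `selection_result` list: `ranked`, `threshold_set`,
#'   `interpretation_set`, `prediction_set`, `importance` (tibble of
#'   mean/sd importance), `oob_errors` (phase-2 curve), `params`.
#' @export
vsurf_select <- function(X, y, n_forests = 25L, n_trees = 500L,
                         n_forests_nested = 10L, n_trees_nested = NULL,
                         seed = 1L) {
  X <- as.data.frame(X)
  if (ncol(X) < 2L) stop("invalid input: need >= 2 features", call. = FALSE)
  nas <- vapply(X, anyNA, logical(1))
  if (any(nas)) {
    stop("missing data in column(s): ",
         paste(names(X)[nas], collapse = ", "), call. = FALSE)
  }
  n_trees_nested <- n_trees_nested %||% n_trees
  p <- ncol(X)
  mtry <- max(1L, ceiling(p / 3))

  # -- phase 1: thresholding ------------------------------------------
  VI <- vapply(seq_len(n_forests), function(k) {
    rf <- with_seed(derive_seed(seed, paste0("thresh", k)), {
      randomForest::randomForest(x = X, y = y, ntree = n_trees, mtry = mtry,
                                 importance = TRUE)
    })
    rf$importance[, "%IncMSE"]
  }, numeric(p))
  mean_vi <- rowMeans(VI)
  sd_vi <- apply(VI, 1, stats::sd)
  ord <- order(mean_vi, decreasing = TRUE)
  ranked <- names(X)[ord]
  cart <- rpart::rpart(sd ~ rank,
                       data = data.frame(rank = seq_len(p), sd = sd_vi[ord]),
                       minsplit = 2)
  vi_threshold <- min(stats::predict(cart))
  keep <- mean_vi[ord] > vi_threshold
  threshold_set <- ranked[keep]

  importance_tbl <- tibble::tibble(feature = ranked,
                                   mean_importance = mean_vi[ord],
                                   sd_importance = sd_vi[ord])
  empty <- function() {
    structure(list(ranked = ranked, threshold_set = character(0),
                   interpretation_set = character(0),
                   prediction_set = character(0),
                   importance = importance_tbl,
                   oob_errors = numeric(0), vi_threshold = vi_threshold,
                   params = list(n_forests = n_forests, n_trees = n_trees,
                                 n_forests_nested = n_forests_nested,
                                 n_trees_nested = n_trees_nested,
                                 seed = seed)),
              class = "selection_result")
  }
  if (!length(threshold_set)) return(empty())

  # -- phase 2: interpretation ----------------------------------------
  m <- length(threshold_set)
  err_runs <- lapply(seq_len(m), function(j) {
    oob_mse_reps(X, y, threshold_set[seq_len(j)], n_forests_nested,
                 n_trees_nested, derive_seed(seed, paste0("interp", j)))
  })
  err_mean <- vapply(err_runs, mean, numeric(1))
  jmin <- which.min(err_mean)
  sd_min <- if (n_forests_nested > 1L) stats::sd(err_runs[[jmin]]) else 0
  j_interp <- which(err_mean <= err_mean[jmin] + sd_min)[1]
  interpretation_set <- threshold_set[seq_len(j_interp)]

  # -- phase 3: prediction --------------------------------------------
  tol <- if (m > j_interp) mean(abs(diff(err_mean[j_interp:m]))) else 0
  current <- interpretation_set[1]
  err_cur <- mean(oob_mse_reps(X, y, current, n_forests_nested,
                               n_trees_nested,
                               derive_seed(seed, "pred1")))
  if (j_interp > 1L) {
    for (k in 2:j_interp) {
      cand <- c(current, interpretation_set[k])
      err_new <- mean(oob_mse_reps(X, y, cand, n_forests_nested,
                                   n_trees_nested,
                                   derive_seed(seed, paste0("pred", k))))
      if (err_cur - err_new > tol) {
        current <- cand
        err_cur <- err_new
      }
    }
  }
  res <- empty()
  res$threshold_set <- threshold_set
  res$interpretation_set <- interpretation_set
  res$prediction_set <- current
  res$oob_errors <- err_mean
  res
}

#' Permutation null for selection-plus-forest variance explained
#'
#' The observed statistic is the OOB percent variance explained of a
#' standard forest fitted on the interpretation set selected by
#' [vsurf_select()].  The response is then permuted `B` times; each
#' permutation is passed through the full selection and a forest is fit
#' on the resulting set (a run selecting nothing contributes 0, the
#' intercept-only value).  The one-tailed p-value uses the add-one
#' convention, `p = (1 + #\{permuted >= observed\}) / (B + 1)`, so it is
#' never 0.
#'
#' @param X,y as in [vsurf_select()].
#' @param B number of permutations; the study-fidelity value is 1000, a
#'   reduced `B = 99` is practical for exploration.  `B < 19` is
#'   refused.
#' @param seed root seed.
#' @param vsurf_params named list of arguments forwarded to
#'   [vsurf_select()] (forest sizes etc.).
#' @param n_trees_final trees in the forest evaluated on each selected
#'   set.
#' @return a `permutation_null` list: `observed`, `permuted` (length
#'   `B`), `p`, `B`, `selected` (the observed interpretation set).
#' @export
permutation_null <- function(X, y, B = 1000L, seed = 1L,
                             vsurf_params = list(), n_trees_final = 500L) {
  if (B < 19L) {
    stop("B < 19 gives too little p-value resolution", call. = FALSE)
  }
  X <- as.data.frame(X)
  eval_once <- function(yy, s) {
    vs <- do.call(vsurf_select,
                  c(list(X = X, y = yy, seed = s), vsurf_params))
    sel <- vs$interpretation_set
    if (!length(sel)) return(list(r2 = 0, sel = sel))
    fit <- random_forest_regress(X[, sel, drop = FALSE], yy,
                                 n_trees = n_trees_final, seed = s)
    list(r2 = fit$oob_r2, sel = sel)
  }
  obs <- eval_once(y, derive_seed(seed, "observed"))
  permuted <- vapply(seq_len(B), function(b) {
    sb <- derive_seed(seed, paste0("perm", b))
    yp <- with_seed(sb, sample(y))
    eval_once(yp, sb)$r2
  }, numeric(1))
  p <- (1 + sum(permuted >= obs$r2)) / (B + 1)
  structure(list(observed = obs$r2, permuted = permuted, p = p, B = B,
                 selected = obs$sel),
            class = "permutation_null")
}
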