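#' Iterated, importance-weighted forest interactions
#'
#' Fits a sequence of random forests in which iterations after the
#' first bias split-candidate sampling by the previous iteration's
#' (non-negative, normalized) importances, with a floor of `1 / (10 p)`
#' so no feature is permanently excluded.  From the final forest, a
#' feature pair counts as "proximate" in a tree when the two features
#' split adjacent (parent-child) internal nodes anywhere in that tree;
#' adjacency is counted at most once per tree, so edge prevalence (the
#' fraction of trees with the adjacency) is always in `[0, 1]`.  Edges
#' with prevalence at or above `min_prevalence` are reported.
#'
#' @param X predictors (no missing values).
#' @param y numeric response.
#' @param n_iterations number of forest iterations (default 3).
#' @param n_trees trees per forest.
#' @param min_prevalence edge threshold; 0.30 = an interaction present
#'   in 30% or more of trees.
#' @param max_depth tree depth limit (default 4).  Adjacency is read
#'   from the upper levels of each tree, where nodes still carry enough
#'   samples for splits to be signal-driven; unlimited-depth trees
#'   accumulate so many deep, noise-dominated adjacencies that pair
#'   prevalence saturates and stops discriminating.  Set to `NULL` for
#'   unlimited depth.
#' @param seed seed (forests run single-threaded for reproducibility).
#' @return an `interaction_graph` list: `edges` (tibble `feature_a`,
#'   `feature_b`, `prevalence`, filtered at the threshold), `all_pairs`
#'   (unfiltered tibble), `threshold`, `n_trees`, `weights` (final
#'   split-sampling weights).
#' @export
iterative_forest_interactions <- function(X, y, n_iterations = 3L,
                                          n_trees = 500L,
                                          min_prevalence = 0.30,
                                          max_depth = 4L,
                                          seed = 1L) {
  if (n_iterations < 1L) {
    stop("invalid argument: n_iterations must be >= 1", call. = FALSE)
  }
  X <- as.data.frame(X)
  if (anyNA(X) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  p <- ncol(X)
  dat <- data.frame(.y = y, X, check.names = FALSE)
  weights <- NULL
  rf <- NULL
  for (it in seq_len(n_iterations)) {
    # ranger warns that importances are not comparable across unequal
    # split weights; expected here, the weights ARE the iteration device
    rf <- withCallingHandlers(
      ranger::ranger(
        dependent.variable.name = ".y", data = dat,
        num.trees = n_trees, importance = "impurity",
        split.select.weights = weights, max.depth = max_depth,
        num.threads = 1L, verbose = FALSE,
        seed = derive_seed(seed, paste0("irf", it))),
      warning = function(w) {
        if (grepl("Split select weights", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    imp <- pmax(rf$variable.importance, 0)
    if (sum(imp) == 0) imp <- rep(1, p)
    w <- imp / sum(imp)
    w <- pmax(w, 1 / (10 * p))
    weights <- w / sum(w)
  }
  tallies <- new.env(hash = TRUE)
  for (tr in seq_len(n_trees)) {
    ti <- ranger::treeInfo(rf, tr)
    for (pair in tree_adjacent_pairs(ti)) {
      key <- paste(pair, collapse = "\r")
      tallies[[key]] <- (tallies[[key]] %||% 0) + 1
    }
  }
  keys <- ls(tallies)
  if (length(keys)) {
    parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    all_pairs <- tibble::tibble(
      feature_a = parts[, 1], feature_b = parts[, 2],
      prevalence = vapply(keys, function(k) tallies[[k]], numeric(1)) /
        n_trees)
    all_pairs <- all_pairs[order(-all_pairs$prevalence), ]
  } else {
    all_pairs <- tibble::tibble(feature_a = character(0),
                                feature_b = character(0),
                                prevalence = numeric(0))
  }
  structure(list(edges = all_pairs[all_pairs$prevalence >= min_prevalence, ],
                 all_pairs = all_pairs, threshold = min_prevalence,
                 n_trees = n_trees, weights = weights),
            class = "interaction_graph")
}

# unique unordered feature pairs in parent-child internal nodes of one
# ranger treeInfo data frame
tree_adjacent_pairs <- function(ti) {
  internal <- !ti$terminal
  if (sum(internal) < 2L) return(list())
  var_of <- stats::setNames(as.character(ti$splitvarName), ti$nodeID)
  pairs <- character(0)
  for (i in which(internal)) {
    for (child in c(ti$leftChild[i], ti$rightChild[i])) {
      cr <- match(child, ti$nodeID)
      if (!is.na(cr) && internal[cr]) {
        a <- var_of[[as.character(ti$nodeID[i])]]
        b <- var_of[[as.character(child)]]
        if (a != b) {
          pr <- sort(c(a, b))
          pairs <- c(pairs, paste(pr, collapse = "\r"))
        }
      }
    }
  }
  lapply(unique(pairs), function(k) strsplit(k, "\r", fixed = TRUE)[[1]])
}
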