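#' Shared-minimum-distance (SMD) co-occurrence modules
#'
#' Builds a complete-linkage dendrogram on the distance `1 - r` and
#' defines modules as maximal subtrees in which EVERY pairwise
#' correlation between tips meets the threshold: `r >= min_r`, or, with
#' `r_is_squared = TRUE` (the diet convention), `r > 0` and
#' `r^2 >= min_r` (summing anti-correlated features would not be
#' meaningful).  Maximality makes modules pairwise disjoint; features in
#' no qualifying subtree remain singletons and are not modules.
#'
#' @param corr symmetric correlation matrix (e.g. from [sparcc()]'s
#'   `$rho` or [cor_matrix()]).
#' @param min_r threshold in (0, 1): minimum R (default 0.35, the
#'   microbiome setting) or minimum r-squared when `r_is_squared`
#'   (0.75 is the diet setting).
#' @param r_is_squared interpret `min_r` on the r-squared scale.
#' @return a `module_set` list: `modules` (named list of member id
#'   vectors, ordered as in the dendrogram), `method`, `threshold`,
#'   `r_is_squared`, `linkage`.
#' @export
smd_modules <- function(corr, min_r = 0.35, r_is_squared = FALSE) {
  if (inherits(corr, "sparcc_fit")) corr <- corr$rho
  r <- as_num_matrix(corr, "correlation matrix")
  if (nrow(r) != ncol(r) || !isTRUE(all.equal(r, t(r), tolerance = 1e-8))) {
    stop("invalid matrix: correlation matrix must be symmetric",
         call. = FALSE)
  }
  if (min_r <= 0 || min_r >= 1) stop("min_r must be in (0, 1)", call. = FALSE)
  n <- nrow(r)
  ids <- rownames(r) %||% sprintf("F%d", seq_len(n))
  out <- structure(list(modules = list(),
                        method = attr(corr, "method") %||% "unknown",
                        threshold = min_r, r_is_squared = r_is_squared,
                        linkage = "complete"),
                   class = "module_set")
  if (n < 2L) return(out)

  qual_pair <- if (r_is_squared) {
    function(v) all(v > 0 & v^2 >= min_r)
  } else {
    function(v) all(v >= min_r)
  }
  hc <- stats::hclust(stats::as.dist(1 - r), method = "complete")
  nm <- n - 1L
  tips <- vector("list", nm)
  qual <- logical(nm)
  for (k in seq_len(nm)) {
    get_side <- function(v) if (v < 0) -v else tips[[v]]
    tips[[k]] <- c(get_side(hc$merge[k, 1]), get_side(hc$merge[k, 2]))
    sub <- r[tips[[k]], tips[[k]]]
    qual[k] <- qual_pair(sub[upper.tri(sub)])
  }
  parent <- rep(NA_integer_, nm)
  for (k in seq_len(nm)) {
    for (s in 1:2) {
      v <- hc$merge[k, s]
      if (v > 0) parent[v] <- k
    }
  }
  maximal <- which(qual & (is.na(parent) | !qual[parent]))
  # tip order within each subtree follows the dendrogram ordering
  mods <- lapply(maximal, function(k) ids[tips[[k]][order(match(tips[[k]], hc$order))]])
  mods <- mods[order(vapply(mods, function(x) min(match(x, ids)), numeric(1)))]
  names(mods) <- sprintf("module_%d", seq_along(mods))
  out$modules <- mods
  out
}

#' Summarize module members by summation
#'
#' Replaces each module's member rows with a single row equal to their
#' elementwise sum; non-member features pass through unchanged.
#' Per-sample totals are conserved exactly, and the feature count drops
#' by `sum(size - 1)` over modules.
#'
#' @param table feature-by-sample matrix.
#' @param modules a [smd_modules()] result (or a named list of member
#'   id vectors).
#' @return reduced matrix with module rows first, then the remaining
#'   features in original order.
#' @export
summarize_modules <- function(table, modules) {
  m <- as_num_matrix(table, "feature table")
  mods <- if (inherits(modules, "module_set")) modules$modules else modules
  members <- unlist(mods, use.names = FALSE)
  missing <- setdiff(members, rownames(m))
  if (length(missing)) {
    stop("inconsistent input: module member(s) not in table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(members)) {
    stop("inconsistent input: modules are not disjoint", call. = FALSE)
  }
  if (!length(mods)) return(m)
  modrows <- t(vapply(mods, function(ids) {
    colSums(m[ids, , drop = FALSE])
  }, numeric(ncol(m))))
  rest <- m[setdiff(rownames(m), members), , drop = FALSE]
  out <- rbind(modrows, rest)
  colnames(out) <- colnames(m)
  out
}
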