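#' Rarefy a count table to even depth
#'
#' Samples with fewer total reads than `depth` are dropped (with a
#' message); the rest are subsampled without replacement to exactly
#' `depth` reads, so rarefied counts never exceed the originals.
#' Subsampling is delegated to [vegan::rrarefy()].
#'
#' @param table integer matrix, features (rows) by samples (columns).
#' @param depth target depth; the default 19986 is the study depth.
#' @param seed optional seed for the subsampling.
#' @return rarefied count matrix (possibly fewer columns).
#' @export
rarefy_counts <- function(table, depth = 19986L, seed = NULL) {
  m <- as_num_matrix(table, "count table")
  if (length(depth) != 1L || depth <= 0) {
    stop("invalid argument: depth must be a positive integer", call. = FALSE)
  }
  totals <- colSums(m)
  drop <- totals < depth
  if (any(drop)) {
    message("dropping ", sum(drop), " sample(s) below depth ", depth)
    m <- m[, !drop, drop = FALSE]
  }
  if (ncol(m) == 0L) return(m)
  with_seed(seed, {
    # vegan heuristically warns when the smallest count is not 1; our
    # synthetic tables legitimately have large minimum counts
    r <- withCallingHandlers(
      t(vegan::rrarefy(t(m), sample = depth)),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  })
  storage.mode(r) <- "integer"
  r
}

#' Prevalence filter
#'
#' Keeps features with nonzero counts in strictly more than
#' `min_fraction` of samples (a feature present in exactly 20% of
#' samples is removed at the default).
#'
#' @param table feature-by-sample matrix.
#' @param min_fraction prevalence fraction in (0, 1); default 0.2.
#' @return filtered matrix.
#' @export
prevalence_filter <- function(table, min_fraction = 0.2) {
  m <- as_num_matrix(table, "count table")
  if (ncol(m) == 0L || nrow(m) == 0L) {
    stop("empty input table", call. = FALSE)
  }
  if (min_fraction <= 0 || min_fraction >= 1) {
    stop("min_fraction must be in (0, 1)", call. = FALSE)
  }
  prev <- rowMeans(m > 0)
  m[prev > min_fraction, , drop = FALSE]
}

#' Normalize diet features per 1,000 kcal
#'
#' @param diet numeric matrix/data frame, subjects by diet features.
#' @param kcal numeric vector of daily energy intake per subject.
#' @return matrix of `value * 1000 / kcal`.
#' @export
normalize_per_kcal <- function(diet, kcal) {
  m <- as_num_matrix(diet, "diet table")
  stopifnot(length(kcal) == nrow(m))
  if (any(!is.finite(kcal)) || any(kcal <= 0)) {
    stop("invalid data: kcal must be positive for every subject",
         call. = FALSE)
  }
  sweep(m, 1, 1000 / kcal, `*`)
}
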