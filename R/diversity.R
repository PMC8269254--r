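#' Alpha diversity per sample
#'
#' Shannon entropy `H = -sum p_i ln p_i` over nonzero proportions
#' (via [vegan::diversity()]), observed features (nonzero count), and
#' Pielou's evenness `J = H / ln(observed)`.  A single-feature sample
#' has undefined evenness (`ln 1 = 0`); `J` is reported as 0 by
#' convention with a warning so degenerate synthetic samples do not
#' break pipelines.  All-zero samples are an error.
#'
#' @param counts feature-by-sample count matrix (or a single sample
#'   vector).
#' @return tibble `sample`, `shannon`, `pielou`, `observed`.
#' @export
alpha_diversity <- function(counts) {
  m <- if (is.null(dim(counts))) matrix(counts, ncol = 1) else
    as_num_matrix(counts, "count table")
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(colSums(m) == 0)) {
    stop("undefined diversity: all-zero sample(s)", call. = FALSE)
  }
  H <- vegan::diversity(t(m), index = "shannon")
  obs <- colSums(m > 0)
  J <- ifelse(obs > 1, H / log(obs), 0)
  if (any(obs == 1)) {
    warning("single-feature sample(s): Pielou evenness reported as 0")
  }
  tibble::tibble(sample = colnames(m) %||% sprintf("sample_%d", seq_len(ncol(m))),
                 shannon = unname(H), pielou = unname(J),
                 observed = unname(obs))
}

# all permutations of 1..n (n small)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in all_permutations(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries, with a
#' permutation p-value obtained by simultaneous row/column shuffling of
#' the second matrix; two-sided,
#' `p = (1 + #\{|r_perm| >= |r_obs|\}) / (B + 1)`.
#'
#' @param d1,d2 `dist` objects or symmetric matrices with zero
#'   diagonal over the same samples.
#' With `exact = TRUE` (feasible for n <= 8) all `n!` relabelings are
#' enumerated instead and `p = #\{|r_perm| >= |r_obs|\} / n!` (the
#' identity permutation counts itself, so p is never 0).
#'
#' @param n_permutations number of permutations B.
#' @param seed permutation seed.
#' @param exact enumerate all permutations instead of sampling.
#' @return list with `r`, `p`, `n_permutations`.
#' @export
mantel_test <- function(d1, d2, n_permutations = 999L, seed = NULL,
                        exact = FALSE) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!all(dim(m1) == dim(m2))) {
    stop("schema error: distance matrices have different sizes",
         call. = FALSE)
  }
  check_dist <- function(m) {
    if (!isTRUE(all.equal(m, t(m))) || any(diag(m) != 0) || any(m < 0)) {
      stop("distance matrices must be symmetric, non-negative, with ",
           "zero diagonal", call. = FALSE)
    }
  }
  check_dist(m1); check_dist(m2)
  n <- nrow(m1)
  if (n < 4L) stop("need >= 4 samples", call. = FALSE)
  ut <- upper.tri(m1)
  r_obs <- stats::cor(m1[ut], m2[ut])
  if (exact) {
    if (n > 8L) stop("exact enumeration limited to n <= 8", call. = FALSE)
    perms <- all_permutations(n)
    hits <- sum(vapply(perms, function(pm) {
      abs(stats::cor(m1[ut], m2[pm, pm][ut])) >= abs(r_obs) - 1e-12
    }, logical(1)))
    return(list(r = r_obs, p = hits / length(perms),
                n_permutations = length(perms)))
  }
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(b) {
      pm <- sample.int(n)
      abs(stats::cor(m1[ut], m2[pm, pm][ut])) >= abs(r_obs)
    }, logical(1)))
  })
  list(r = r_obs, p = (1 + hits) / (n_permutations + 1),
       n_permutations = n_permutations)
}
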