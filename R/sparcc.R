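#' SparCC compositional correlation
#'
#' Friedman-Alm estimator of correlations between components of
#' compositional count data.  With a pseudocount added, per-pair
#' log-ratio variances `t_ij = Var(log(x_i / x_j))` are computed; the
#' linear system `sum_j t_ij = (d - 2) w_i^2 + sum_j w_j^2` (the sparse
#' approximation dropping cross terms) is solved for the basis variances
#' `w_i^2`; correlations follow as
#' `rho_ij = (w_i^2 + w_j^2 - t_ij) / (2 w_i w_j)`, clipped to `[-1, 1]`.
#' Strongly correlated pairs above `exclusion_threshold` are then
#' iteratively removed from the system and the basis re-solved, for up
#' to `n_exclusion_rounds` rounds, which de-biases the sparse
#' approximation.  If `n_resamples > 1`, the whole estimate is averaged
#' over Dirichlet-perturbed fraction draws (the original algorithm's
#' stochastic variant); the default is a single deterministic estimate.
#'
#' @param table count matrix, features (rows) by samples (columns).
#' @param n_exclusion_rounds maximum strong-pair exclusion rounds.
#' @param exclusion_threshold absolute correlation above which a pair is
#'   excluded from the basis system.
#' @param pseudocount added to all counts before taking logs.
#' @param n_resamples number of Dirichlet resamples (1 = deterministic).
#' @param seed seed for the resampling variant.
#' @return a `sparcc_fit` list: `rho` (correlation matrix, method tag
#'   "sparcc"), `basis_var`, `excluded` (2-column matrix of excluded
#'   pair indices), `params`.
#' @export
sparcc <- function(table, n_exclusion_rounds = 10L,
                   exclusion_threshold = 0.8, pseudocount = 1,
                   n_resamples = 1L, seed = NULL) {
  m <- as_num_matrix(table, "count table")
  d <- nrow(m)
  if (d < 4L) {
    stop("SparCC needs >= 4 features for basis-variance identifiability",
         call. = FALSE)
  }
  x0 <- m + pseudocount
  if (any(x0 <= 0)) {
    stop("degenerate variance: nonpositive values after pseudocount; ",
         "use a positive pseudocount", call. = FALSE)
  }
  run_once <- function(x) {
    sparcc_from_logx(log(x), n_exclusion_rounds, exclusion_threshold)
  }
  if (n_resamples <= 1L) {
    est <- run_once(x0)
  } else {
    est <- with_seed(seed, {
      acc_rho <- 0; acc_w <- 0
      for (b in seq_len(n_resamples)) {
        fr <- apply(x0, 2, function(col) {
          g <- stats::rgamma(d, shape = col)
          g / sum(g)
        })
        e <- run_once(fr)
        acc_rho <- acc_rho + e$rho
        acc_w <- acc_w + e$basis_var
      }
      list(rho = acc_rho / n_resamples, basis_var = acc_w / n_resamples,
           excluded = e$excluded)
    })
  }
  dimnames(est$rho) <- list(rownames(m), rownames(m))
  names(est$basis_var) <- rownames(m)
  structure(list(rho = est$rho, basis_var = est$basis_var,
                 excluded = est$excluded,
                 params = list(method = "sparcc",
                               n_exclusion_rounds = n_exclusion_rounds,
                               exclusion_threshold = exclusion_threshold,
                               pseudocount = pseudocount,
                               n_resamples = n_resamples)),
            class = "sparcc_fit")
}

# core estimator on a log-abundance matrix (features x samples)
sparcc_from_logx <- function(logx, n_rounds, excl_thr) {
  d <- nrow(logx)
  V <- stats::cov(t(logx))
  v <- diag(V)
  Tm <- outer(v, rep(1, d)) + outer(rep(1, d), v) - 2 * V  # t_ij
  diag(Tm) <- 0

  M <- matrix(1, d, d) + diag(rep(d - 2, d))
  t_vec <- rowSums(Tm)
  n_incl <- rep(d - 1L, d)   # included partners per feature
  excluded <- matrix(integer(0), ncol = 2)

  solve_basis <- function() {
    w2 <- solve(M, t_vec)
    pmax(w2, 1e-12)
  }
  rho_from <- function(w2) {
    w <- sqrt(w2)
    r <- (outer(w2, rep(1, d)) + outer(rep(1, d), w2) - Tm) /
      (2 * outer(w, w))
    r <- pmin(pmax(r, -1), 1)
    diag(r) <- 1
    r
  }
  w2 <- solve_basis()
  rho <- rho_from(w2)
  for (round in seq_len(n_rounds)) {
    cand <- abs(rho)
    diag(cand) <- 0
    if (nrow(excluded)) cand[excluded] <- 0
    cand[cbind(excluded[, 2], excluded[, 1])] <- 0
    mx <- max(cand)
    if (mx <= excl_thr) break
    ij <- which(cand == mx, arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    if (n_incl[i] <= 2L || n_incl[j] <= 2L) break  # keep system solvable
    t_vec[i] <- t_vec[i] - Tm[i, j]
    t_vec[j] <- t_vec[j] - Tm[i, j]
    M[i, i] <- M[i, i] - 1; M[j, j] <- M[j, j] - 1
    M[i, j] <- M[i, j] - 1; M[j, i] <- M[j, i] - 1
    n_incl[i] <- n_incl[i] - 1L; n_incl[j] <- n_incl[j] - 1L
    excluded <- rbind(excluded, c(i, j))
    w2 <- solve_basis()
    rho <- rho_from(w2)
  }
  list(rho = rho, basis_var = w2, excluded = excluded)
}

#' Plain correlation matrix with a method tag
#'
#' Pearson or Spearman correlation across features (rows of `table`),
#' in the same shape [sparcc()] returns, for use with [smd_modules()]
#' (e.g. Pearson for diet features).
#'
#' @param table features (rows) by samples (columns).
#' @param method "pearson" or "spearman".
#' @return correlation matrix with a `method` attribute.
#' @export
cor_matrix <- function(table, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- as_num_matrix(table, "feature table")
  r <- stats::cor(t(m), method = method)
  attr(r, "method") <- method
  r
}
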