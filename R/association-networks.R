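# Spearman rho with average ranks, two-sided p via the t approximation
spearman_test <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  rho <- suppressWarnings(stats::cor(x[ok], y[ok], method = "spearman"))
  if (is.na(rho)) return(c(rho = NA_real_, p = NA_real_, n = n))
  if (abs(rho) >= 1) return(c(rho = rho, p = 0, n = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p = 2 * stats::pt(-abs(tstat), n - 2), n = n)
}

#' FDR-thresholded Spearman correlation network
#'
#' All pairwise Spearman rank correlations among the supplied features
#' (average ranks for ties, two-sided p via the t approximation), with
#' Benjamini-Hochberg correction over all tested pairs as one family.
#' Edges are pairs with adjusted `q` below `fdr_threshold` (the network
#' preset is 0.25).  Constant features are skipped with a warning.
#'
#' @param features data frame/matrix, subjects by features.
#' @param fdr_threshold BH threshold for edges.
#' @param layers optional named character vector tagging each feature
#'   with its data layer (clinical/diet/immune/microbe), carried into
#'   the node table.
#' @return an `assoc_network` list: `edges` (tibble `feature_a`,
#'   `feature_b`, `rho`, `p`, `q`), `all_pairs`, `nodes`,
#'   `fdr_threshold`.
#' @export
spearman_network <- function(features, fdr_threshold = 0.25, layers = NULL) {
  f <- as.data.frame(features)
  const <- vapply(f, function(col) stats::sd(col, na.rm = TRUE) == 0,
                  logical(1))
  if (any(const)) {
    warning("skipping constant feature(s): ",
            paste(names(f)[const], collapse = ", "))
    f <- f[, !const, drop = FALSE]
  }
  p <- ncol(f)
  if (p < 2L) stop("need >= 2 non-constant features", call. = FALSE)
  idx <- utils::combn(p, 2)
  rows <- apply(idx, 2, function(ij) {
    st <- spearman_test(f[[ij[1]]], f[[ij[2]]])
    c(ij, st)
  })
  tbl <- tibble::tibble(feature_a = names(f)[rows[1, ]],
                        feature_b = names(f)[rows[2, ]],
                        rho = rows[3, ], p = rows[4, ], n = rows[5, ])
  tbl$q <- stats::p.adjust(tbl$p, method = "BH")
  nodes <- tibble::tibble(feature = names(f),
                          layer = if (is.null(layers)) NA_character_ else
                            unname(layers[names(f)]))
  structure(list(edges = tbl[!is.na(tbl$q) & tbl$q < fdr_threshold, ],
                 all_pairs = tbl, nodes = nodes,
                 fdr_threshold = fdr_threshold),
            class = "assoc_network")
}

#' Nearest-neighbor subnetwork of a node
#'
#' Returns exactly the edges incident to `node` (its one-hop
#' neighborhood) from a fitted network.
#' @param network an [spearman_network()] result.
#' @param node feature id.
#' @export
subnetwork <- function(network, node) {
  stopifnot(inherits(network, "assoc_network"))
  e <- network$edges
  e[e$feature_a == node | e$feature_b == node, ]
}

#' Per-feature Spearman correlation with an outcome
#'
#' Spearman rho of every feature against the outcome with BH correction
#' across the supplied feature set (the multiple-testing family is the
#' set as given).  Preset thresholds used in the analysis: 0.1 for
#' selected features against the disease score, 0.05 for metabolites,
#' 0.25 for networks.
#'
#' @param features subjects-by-features table.
#' @param outcome numeric outcome vector.
#' @param fdr_threshold BH threshold for the `pass` flag.
#' @return tibble `feature`, `rho`, `p`, `q`, `pass`.
#' @export
outcome_correlations <- function(features, outcome, fdr_threshold = 0.1) {
  f <- as.data.frame(features)
  if (nrow(f) != length(outcome)) {
    stop("schema error: features and outcome lengths differ", call. = FALSE)
  }
  st <- t(vapply(f, function(col) spearman_test(col, outcome), numeric(3)))
  out <- tibble::tibble(feature = names(f), rho = unname(st[, 1]),
                        p = unname(st[, 2]))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$pass <- !is.na(out$q) & out$q < fdr_threshold
  out
}

#' Kruskal-Wallis rank-sum test
#'
#' Rank-based H statistic with tie correction and chi-squared p-value
#' on k-1 degrees of freedom (delegates to [stats::kruskal.test()]).
#' All-tied values yield p = 1 with a warning.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) {
    stop("need >= 2 groups", call. = FALSE)
  }
  if (length(unique(values)) == 1L) {
    warning("all values tied; p = 1")
    return(list(H = 0, df = nlevels(droplevels(groups)) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

# log-probability of a table under the fixed-margins hypergeometric model
log_table_prob <- function(tab) {
  (sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1))
   - lgamma(sum(tab) + 1) - sum(lgamma(tab + 1)))
}

# enumerate all r x c tables with given margins, calling fn(table)
enumerate_tables <- function(rs, cs, fn, cap) {
  r <- length(rs); cc <- length(cs)
  count <- 0L
  tab <- matrix(0L, r, cc)
  rec_row <- function(i, colrem) {
    if (i == r) {
      tab[r, ] <<- colrem
      count <<- count + 1L
      if (count > cap) {
        stop("table too large: enumeration exceeds cap; use monte_carlo ",
             "mode", call. = FALSE)
      }
      fn(tab)
      return(invisible())
    }
    rec_cell <- function(j, left, rem) {
      if (j == cc) {
        if (left <= rem[cc]) {
          tab[i, cc] <<- left
          rec_row(i + 1L, rem - tab[i, ])
        }
        return(invisible())
      }
      upper <- min(left, rem[j])
      for (x in 0:upper) {
        tab[i, j] <<- x
        rec_cell(j + 1L, left - x, rem)
      }
    }
    rec_cell(1L, rs[i], colrem)
  }
  rec_row(1L, cs)
  count
}

#' Fisher exact test for r x c contingency tables
#'
#' Exact p-value by full enumeration of all tables sharing the observed
#' margins, summing the hypergeometric probabilities of tables at most
#' as probable as the observed one (with a `1 + 1e-7` relative
#' tolerance absorbing float jitter).  All-zero rows or columns are
#' dropped first.  When the enumeration would exceed `max_tables`, an
#' error suggests the seeded Monte Carlo mode
#' (`monte_carlo = TRUE`, tables drawn with [stats::r2dtable()]).
#'
#' @param table non-negative integer matrix, at least 2 x 2 after
#'   dropping empty rows/columns (a degenerate single row or column
#'   gives p = 1).
#' @param max_tables enumeration cap.
#' @param monte_carlo use Monte Carlo estimation instead of
#'   enumeration.
#' @param n_mc Monte Carlo table draws.
#' @param seed Monte Carlo seed.
#' @return p-value in (0, 1].
#' @export
fisher_exact_rxc <- function(table, max_tables = 2e6, monte_carlo = FALSE,
                             n_mc = 1e5, seed = 1L) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table must contain non-negative integers", call. = FALSE)
  }
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(1)
  lp_obs <- log_table_prob(tab)
  thresh <- lp_obs + log(1 + 1e-7)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (monte_carlo) {
    draws <- with_seed(seed, stats::r2dtable(n_mc, rs, cs))
    hits <- sum(vapply(draws, function(d) log_table_prob(d) <= thresh,
                       logical(1)))
    return((1 + hits) / (n_mc + 1))
  }
  psum <- 0
  enumerate_tables(rs, cs, function(t2) {
    lp <- log_table_prob(t2)
    if (lp <= thresh) psum <<- psum + exp(lp)
  }, cap = max_tables)
  min(psum, 1)
}
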