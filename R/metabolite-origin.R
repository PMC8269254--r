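#' Compounds producible from a gene set
#'
#' Single-step product logic over a gene-to-reaction-to-compound map:
#' the result is the union of product compounds over all reactions
#' linked to any gene in the set.  (Producibility is therefore monotone
#' in the gene set.)  Unknown gene ids are ignored with a message.  A
#' transitive-reachability mode, which additionally fires reactions
#' whose substrates become available, exists behind `reachability` for
#' exploration and is off by default.
#'
#' @param gene_set character vector of gene (KO-style) ids.
#' @param map reaction map: `list(genes = list(gene -> reaction ids),
#'   reactions = list(reaction -> list(substrates, products)))`.
#' @param reachability if TRUE, iterate product closure.
#' @return sorted character vector of compound ids.
#' @export
producible_compounds <- function(gene_set, map, reachability = FALSE) {
  check_reaction_map(map)
  gene_set <- unique(gene_set)
  unknown <- setdiff(gene_set, names(map$genes))
  if (length(unknown)) {
    message("ignoring ", length(unknown), " unknown gene id(s)")
    gene_set <- setdiff(gene_set, unknown)
  }
  if (!length(gene_set)) return(character(0))
  rxns <- unique(unlist(map$genes[gene_set], use.names = FALSE))
  rxns <- intersect(rxns, names(map$reactions))
  products <- function(rs) {
    sort(unique(unlist(lapply(map$reactions[rs], `[[`, "products"),
                       use.names = FALSE)))
  }
  out <- products(rxns)
  if (reachability) {
    repeat {
      avail <- out
      can_fire <- vapply(rxns, function(r) {
        all(map$reactions[[r]]$substrates %in% avail)
      }, logical(1))
      new <- products(rxns[can_fire])
      if (all(new %in% out)) break
      out <- sort(unique(c(out, new)))
    }
  }
  out
}

check_reaction_map <- function(map) {
  if (!is.list(map) || !all(c("genes", "reactions") %in% names(map))) {
    stop("reaction map must have $genes and $reactions", call. = FALSE)
  }
  for (r in map$reactions) {
    if (!length(r$products) || !length(r$substrates)) {
      stop("reaction map: every reaction needs substrates and products",
           call. = FALSE)
    }
  }
  invisible(map)
}

#' Germfree-versus-colonized differential metabolites
#'
#' Compounds present (nonzero) in fewer than `min_prev` of samples are
#' filtered out; the rest are compared between arms with a two-sided
#' pooled-variance Student t test on (by default) log-transformed
#' intensities, followed by BH correction.  Compounds with `q < alpha`
#' form the differential set.  Aqueous and lipid fractions can be
#' passed as separate calls.
#'
#' @param mouse list with `intensities` (compound x sample matrix,
#'   values >= 0) and `design` (factor with levels germfree/colonized).
#' @param min_prev keep compounds with prevalence at or above this
#'   fraction (the study filter removes those below 20%).
#' @param alpha FDR significance level.
#' @param log_transform log-transform intensities (log(x + 1)) before
#'   testing; standard for LC-MS intensity scales.
#' @return list: `stats` (tibble compound, group means, lfc, t, p, q,
#'   significant) and `differential` (compound ids at `q < alpha`).
#' @export
mouse_differential <- function(mouse, min_prev = 0.2, alpha = 0.05,
                               log_transform = TRUE) {
  m <- as_num_matrix(mouse$intensities, "mouse intensities")
  design <- as.factor(mouse$design)
  stopifnot(ncol(m) == length(design), nlevels(design) == 2L)
  if (any(table(design) < 2L)) {
    stop("insufficient replication: need >= 2 samples per arm",
         call. = FALSE)
  }
  keep <- rowMeans(m > 0) >= min_prev
  m <- m[keep, , drop = FALSE]
  v <- if (log_transform) log(m + 1) else m
  g1 <- design == levels(design)[1]
  res <- t(apply(v, 1, function(row) {
    if (stats::sd(row) == 0) return(c(NA, NA))
    tt <- stats::t.test(row[!g1], row[g1], var.equal = TRUE)
    c(tt$statistic, tt$p.value)
  }))
  stats_tbl <- tibble::tibble(
    compound = rownames(m),
    mean_gf = rowMeans(v[, g1, drop = FALSE]),
    mean_colonized = rowMeans(v[, !g1, drop = FALSE]))
  stats_tbl$lfc <- stats_tbl$mean_colonized - stats_tbl$mean_gf
  stats_tbl$t <- res[, 1]
  stats_tbl$p <- res[, 2]
  stats_tbl$q <- stats::p.adjust(stats_tbl$p, method = "BH")
  stats_tbl$significant <- !is.na(stats_tbl$q) & stats_tbl$q < alpha
  list(stats = stats_tbl,
       differential = stats_tbl$compound[stats_tbl$significant])
}

#' Combine origin evidence into microbiome-association calls
#'
#' Applies the two-pronged rule: a compound is microbiome-associated
#' when it is (producible by the microbial gene set OR differential in
#' germfree-versus-colonized mice) AND present in the human table.
#' Per-compound provenance records which prong(s) fired, and an
#' optional host-producibility flag supports identifying compounds
#' explainable exclusively by microbial production.
#'
#' @param producible compound ids producible by microbial genes.
#' @param differential compound ids differential in the mouse contrast.
#' @param human_compounds compound ids observed in human plasma.
#' @param host_producible optional compound ids producible by host
#'   genes.
#' @return tibble with logical flags `producible_by_microbes`,
#'   `mouse_differential`, `present_in_human`, `producible_by_host`,
#'   `microbiome_associated`, and a `provenance` string.
#' @export
combine_origin <- function(producible, differential, human_compounds,
                           host_producible = NULL) {
  ids <- sort(unique(c(producible, differential, human_compounds)))
  pr <- ids %in% producible
  df <- ids %in% differential
  hu <- ids %in% human_compounds
  ho <- if (is.null(host_producible)) rep(NA, length(ids)) else
    ids %in% host_producible
  prov <- ifelse(pr & df, "both", ifelse(pr, "producible",
                                         ifelse(df, "mouse", "none")))
  tibble::tibble(compound = ids,
                 producible_by_microbes = pr,
                 mouse_differential = df,
                 present_in_human = hu,
                 producible_by_host = ho,
                 microbiome_associated = (pr | df) & hu,
                 provenance = prov)
}

# Jaeckel dispersion with Wilcoxon scores a(i) = sqrt(12) (i/(n+1) - 1/2)
jaeckel_dispersion <- function(e) {
  n <- length(e)
  a <- sqrt(12) * (rank(e, ties.method = "average") / (n + 1) - 0.5)
  sum(a * e)
}

#' Rank-based linear regression (Wilcoxon scores)
#'
#' Estimates slopes by minimizing Jaeckel's dispersion
#' `D(b) = sum a(R(e_i)) e_i` over residuals `e = y - X b`, with
#' Wilcoxon scores `a(i) = sqrt(12) (i/(n+1) - 1/2)` -- a convex,
#' piecewise-linear objective.  The intercept is the median residual.
#' Coefficient standard errors use the standard rank-based asymptotic
#' variance `tau^2 (Xc' Xc)^-1` with the scale `tau = 1 / (sqrt(12)
#' integral f^2)` estimated by a kernel-density plug-in on the
#' residuals; p-values are two-sided normal.
#'
#' @param y numeric response.
#' @param X predictors (vector, matrix, or data frame); no missing
#'   values, `n > p + 2`.
#' @return a `rank_fit` list: `coefficients` (intercept + slopes),
#'   `dispersion` (at the optimum), `dispersion0` (at the zero slope
#'   vector), `tau`, `se`, `p`, `residuals`.
#' @export
rank_regression <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y); p <- ncol(X)
  if (anyNA(y) || anyNA(X)) stop("missing values not allowed", call. = FALSE)
  if (n <= p + 2) stop("need n > p + 2", call. = FALSE)
  if (qr(cbind(1, X))$rank < p + 1) {
    stop("singular design", call. = FALSE)
  }
  obj <- function(b) jaeckel_dispersion(y - X %*% b)
  b0 <- stats::coef(stats::lm(y ~ X))[-1]        # OLS start
  opt <- if (p == 1L) {
    se0 <- suppressWarnings(summary(stats::lm(y ~ X))$coefficients[2, 2])
    width <- max(20 * se0, 1e-3 * max(abs(b0), 1), .Machine$double.eps)
    stats::optimize(function(b) obj(b), interval = b0 + c(-1, 1) * width)
  } else {
    o <- stats::optim(b0, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
    list(minimum = o$par, objective = o$value)
  }
  beta <- if (p == 1L) opt$minimum else opt$minimum
  e <- drop(y - X %*% beta)
  intercept <- stats::median(e)
  # tau = 1 / (sqrt(12) * integral f^2), integral f^2 ~ mean f_hat(e_i)
  dens <- stats::density(e)
  f_at <- stats::approx(dens$x, dens$y, xout = e, rule = 2)$y
  tau <- 1 / (sqrt(12) * mean(f_at))
  Xc <- sweep(X, 2, colMeans(X))
  V <- tau^2 * solve(crossprod(Xc))
  se <- sqrt(diag(V))
  zstat <- beta / se
  structure(list(
    coefficients = c("(Intercept)" = unname(intercept),
                     stats::setNames(as.numeric(beta), colnames(X))),
    dispersion = opt$objective, dispersion0 = obj(rep(0, p)),
    tau = tau, se = stats::setNames(se, colnames(X)),
    p = stats::setNames(2 * stats::pnorm(-abs(zstat)), colnames(X)),
    residuals = e - intercept),
    class = "rank_fit")
}

#' Rank-regression metabolite screen, with and without age adjustment
#'
#' For every compound (row of `Y`), fits `compound ~ score` and
#' `compound ~ score + age` by [rank_regression()], BH-adjusts the
#' score-coefficient p-values within each model, and reports the two
#' significant sets and their overlap -- the comparison used to judge
#' whether age confounds score-metabolite associations.
#'
#' @param Y compound-by-subject intensity matrix (log-transformed
#'   internally).
#' @param score metabolic disease score per subject.
#' @param age age per subject.
#' @param alpha FDR level (default 0.05).
#' @param log_transform log(x + 1)-transform intensities first.
#' @return list: `stats` (tibble with per-model p and q),
#'   `significant_without_age`, `significant_with_age`, `overlap`.
#' @export
rank_metabolite_screen <- function(Y, score, age, alpha = 0.05,
                                   log_transform = TRUE) {
  m <- as_num_matrix(Y, "metabolite table")
  stopifnot(ncol(m) == length(score), length(age) == length(score))
  v <- if (log_transform) log(m + 1) else m
  res <- t(apply(v, 1, function(row) {
    p1 <- rank_regression(row, cbind(score = score))$p[["score"]]
    p2 <- rank_regression(row, cbind(score = score, age = age))$p[["score"]]
    c(p1, p2)
  }))
  out <- tibble::tibble(compound = rownames(m),
                        p_without_age = res[, 1], p_with_age = res[, 2])
  out$q_without_age <- stats::p.adjust(out$p_without_age, method = "BH")
  out$q_with_age <- stats::p.adjust(out$p_with_age, method = "BH")
  s1 <- out$compound[out$q_without_age < alpha]
  s2 <- out$compound[out$q_with_age < alpha]
  list(stats = out, significant_without_age = s1,
       significant_with_age = s2, overlap = intersect(s1, s2))
}
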