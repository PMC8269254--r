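#' Configuration for the synthetic multi-omic cohort
#'
#' The generator emulates the data layers of a five-cohort human study:
#' subject metadata (cohort, age, BMI, GI symptoms), a seven-marker
#' fasting blood panel, a 21-analyte plasma immune panel, 29 per-1,000-kcal
#' diet features, an OTU count table, and a plasma metabolome with a
#' companion germfree-versus-colonized mouse experiment plus a toy
#' gene-to-reaction-to-compound map.
#'
#' A single latent metabolic-health factor `z ~ N(0, 1)` per subject
#' drives the blood markers (triglycerides/glucose/insulin load
#' positively, HDL/adiponectin negatively), the LBP analyte, and any
#' planted-informative OTUs, so downstream stages have recoverable
#' signal.  OTU counts follow a logistic-normal/multinomial model, the
#' standard compositional benchmark for SparCC-style estimators, with
#' planted correlated log-abundance blocks as co-occurrence modules.
#'
#' @param n_per_cohort named integer vector, subjects per cohort.
#'   Defaults mirror the study design: 22 HIV-negative MSW, 32
#'   HIV-negative MSM, 14 HIV-positive untreated MSM, 20 HIV-positive
#'   treated MSM, 25 HIV-positive treated MSM with lipodystrophy.
#' @param seed root seed; all layers derive named sub-streams from it.
#' @param latent_effect named loadings of the latent factor on the seven
#'   markers (unitless, in `[-1, 1]`).
#' @param lbp_effect loading of the latent factor on LBP.
#' @param n_otus,n_immune,n_diet layer sizes (21 immune analytes and 29
#'   diet features by default, matching the study's panels).
#' @param planted_modules list of `list(size =, r =)` co-occurring OTU
#'   blocks; `r` is the within-module log-abundance correlation in (0,1).
#' @param planted_informative named numeric vector: OTU index (by id
#'   `OTU_k`) to effect of the latent factor on its log abundance.
#' @param depth_range 2-vector of per-sample sequencing depths, drawn
#'   uniformly; the default keeps every sample at or above the 19,986
#'   read rarefaction depth used downstream.
#' @param mouse_n_per_arm mice per arm in the gnotobiotic experiment.
#' @param planted_metabolite_shifts named numeric vector: compound id to
#'   log-fold-change between germfree and colonized arms.
#' @param n_compounds number of human plasma compounds.
#' @param n_score_metabolites,score_metabolite_r number and target
#'   correlation of compounds planted to track the latent factor.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_per_cohort = c("HIV-negative MSW" = 22,
                                          "HIV-negative MSM" = 32,
                                          "HIV-positive untreated MSM" = 14,
                                          "HIV-positive treated MSM" = 20,
                                          "HIV-positive treated MSM LD" = 25),
                         seed = 1L,
                         latent_effect = c(triglycerides = 0.85,
                                           glucose = 0.75,
                                           insulin = 0.80,
                                           ldl = 0.55,
                                           hdl = -0.75,
                                           leptin = 0.65,
                                           adiponectin = -0.65),
                         lbp_effect = 0.70,
                         n_otus = 60L,
                         n_immune = 21L,
                         n_diet = 29L,
                         planted_modules = list(list(size = 3L, r = 0.9)),
                         planted_informative = c(OTU_1 = 0.8, OTU_2 = -0.8,
                                                 OTU_3 = 0.6),
                         depth_range = c(20000L, 30000L),
                         mouse_n_per_arm = 8L,
                         planted_metabolite_shifts = stats::setNames(
                           rep(2, 10), sprintf("C%05d", 1:10)),
                         n_compounds = 200L,
                         n_score_metabolites = 10L,
                         score_metabolite_r = 0.5) {
  cfg <- list(n_per_cohort = n_per_cohort, seed = as.integer(seed),
              latent_effect = latent_effect, lbp_effect = lbp_effect,
              n_otus = as.integer(n_otus), n_immune = as.integer(n_immune),
              n_diet = as.integer(n_diet),
              planted_modules = planted_modules,
              planted_informative = planted_informative,
              depth_range = depth_range,
              mouse_n_per_arm = as.integer(mouse_n_per_arm),
              planted_metabolite_shifts = planted_metabolite_shifts,
              n_compounds = as.integer(n_compounds),
              n_score_metabolites = as.integer(n_score_metabolites),
              score_metabolite_r = score_metabolite_r)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (length(cfg$n_per_cohort) < 1L || any(cfg$n_per_cohort <= 0)) {
    stop("invalid config: cohort sizes must be positive", call. = FALSE)
  }
  if (is.null(names(cfg$n_per_cohort))) {
    stop("invalid config: cohorts must be named", call. = FALSE)
  }
  if (!setequal(names(cfg$latent_effect), marker_names())) {
    stop("invalid config: latent_effect must name the seven markers",
         call. = FALSE)
  }
  if (any(abs(cfg$latent_effect) > 1)) {
    stop("invalid config: marker loadings must lie in [-1, 1]", call. = FALSE)
  }
  for (m in cfg$planted_modules) {
    if (m$size > cfg$n_otus) {
      stop("invalid config: module member count exceeds n_otus", call. = FALSE)
    }
    if (m$r <= 0 || m$r >= 1) {
      stop("invalid config: within-module correlation must be in (0, 1)",
           call. = FALSE)
    }
  }
  if (any(cfg$n_otus <= 0, cfg$n_immune <= 0, cfg$n_diet <= 0,
          cfg$mouse_n_per_arm < 2, cfg$n_compounds <= 0)) {
    stop("invalid config: layer sizes must be positive (>= 2 mice per arm)",
         call. = FALSE)
  }
  invisible(cfg)
}

marker_names <- function() {
  c("triglycerides", "glucose", "insulin", "ldl", "hdl", "leptin",
    "adiponectin")
}

# Plausible fasting-panel location/spread per marker (mg/dl except insulin
# uIU/ml, leptin/adiponectin ng/ml-scale); only used to put synthetic values
# on familiar scales -- the score z-scores them away.
marker_scales <- function() {
  data.frame(marker = marker_names(),
             mean = c(130, 95, 12, 110, 50, 8, 10),
             sd   = c(45, 12, 5, 30, 12, 4, 4))
}

# Cohort age medians echo the study design (treated cohorts older).
cohort_age_medians <- function(labels) {
  defaults <- c(33, 34, 34, 46, 60)
  stats::setNames(defaults[pmin(seq_along(labels), 5L)], labels)
}

#' Generate the subject-level cohort layers
#'
#' Draws metadata, the seven-marker fasting panel, the immune panel
#' (first analyte LBP), and diet features for all cohorts.  Each marker
#' is `location + scale * (loading * z + sqrt(1 - loading^2) * noise)`
#' with `z` the latent metabolic factor; LBP is driven analogously via
#' `lbp_effect`.  Ages are cohort-specific normals so treated cohorts
#' are older.  The latent draw is retained in the result (`$latent`) so
#' recovery can be verified.
#'
#' @param config a [synth_config()].
#' @return a `cohort_data` list: `metadata` (tibble), `markers`,
#'   `immune`, `diet` (numeric matrices, subjects as rows), `latent`.
#' @export
generate_cohort <- function(config) {
  validate_synth_config(config)
  with_seed(derive_seed(config$seed, "cohort"), {
    ns <- config$n_per_cohort
    n <- sum(ns)
    cohort <- factor(rep(names(ns), ns), levels = names(ns))
    subject <- sprintf("S%03d", seq_len(n))
    z <- stats::rnorm(n)

    med <- cohort_age_medians(names(ns))
    age <- round(stats::rnorm(n, mean = med[as.character(cohort)], sd = 6), 1)
    age <- pmax(age, 18)
    bmi <- round(24 + 0.8 * z + stats::rnorm(n, sd = 2), 1)
    bmi <- pmin(pmax(bmi, 17), 30)    # obese subjects excluded by design
    bloating <- pmin(pmax(round(1 + 0.6 * z + stats::rnorm(n, sd = 0.9)), 0), 4)

    sc <- marker_scales()
    markers <- sapply(seq_len(nrow(sc)), function(i) {
      l <- config$latent_effect[[sc$marker[i]]]
      v <- sc$mean[i] + sc$sd[i] * (l * z + sqrt(1 - l^2) * stats::rnorm(n))
      pmax(v, 0.5)
    })
    colnames(markers) <- sc$marker
    rownames(markers) <- subject

    immune_names <- c("LBP", "sCD14", "sCD163", "FABP2", "IL-6", "IL-10",
                      "TNF-a", "MCP-1", "IL-22", "SAA", "VCAM-1", "ICAM-1",
                      "CRP", "GM-CSF", "IL-7", "IL-12p40", "IL-15", "IL-16",
                      "IL-17A", "TNF-b", "VEGF")[seq_len(config$n_immune)]
    le <- config$lbp_effect
    immune <- matrix(stats::rnorm(n * config$n_immune), nrow = n)
    immune[, 1] <- le * z + sqrt(max(1 - le^2, 0)) * immune[, 1]
    immune <- sweep(sweep(immune, 2, rep(5, config$n_immune), `*`),
                    2, rep(20, config$n_immune), `+`)
    immune <- pmax(immune, 0.1)
    dimnames(immune) <- list(subject, immune_names)

    diet <- matrix(stats::rgamma(n * config$n_diet, shape = 4, rate = 0.5),
                   nrow = n)
    dimnames(diet) <- list(subject, sprintf("diet_%02d", seq_len(config$n_diet)))

    structure(list(
      metadata = tibble::tibble(subject = subject, cohort = cohort,
                                age = age, bmi = bmi, bloating = bloating),
      markers = markers, immune = immune, diet = diet, latent = z
    ), class = "cohort_data")
  })
}

#' Generate a compositional OTU count table
#'
#' Logistic-normal log-abundances with planted correlated blocks
#' (members of a planted module share a latent component at the
#' configured correlation) and planted-informative OTUs tracking the
#' cohort latent factor, converted to proportions and sampled
#' multinomially at per-sample depths drawn from `depth_range`.
#'
#' @param config a [synth_config()].
#' @param cohort optional [generate_cohort()] result; when supplied, its
#'   subjects and latent factor are reused so tables are join-consistent.
#' @return integer matrix, OTUs (rows) by samples (columns), with a
#'   `planted_modules` attribute listing member ids per planted block.
#' @export
generate_count_table <- function(config, cohort = NULL) {
  validate_synth_config(config)
  with_seed(derive_seed(config$seed, "counts"), {
    if (is.null(cohort)) {
      n <- sum(config$n_per_cohort)
      samples <- sprintf("S%03d", seq_len(n))
      z <- stats::rnorm(n)
    } else {
      samples <- cohort$metadata$subject
      z <- cohort$latent
      n <- length(samples)
    }
    p <- config$n_otus
    otus <- sprintf("OTU_%d", seq_len(p))
    mu <- stats::rnorm(p, sd = 1.2)              # uneven base abundances
    loga <- matrix(stats::rnorm(n * p), nrow = p) # p x n noise
    # planted co-occurrence blocks: members share a latent component
    planted <- list()
    used <- integer(0)
    free <- setdiff(seq_len(p), seq_along(config$planted_informative))
    for (k in seq_along(config$planted_modules)) {
      m <- config$planted_modules[[k]]
      members <- free[!(free %in% used)][seq_len(m$size)]
      if (any(is.na(members))) {
        stop("invalid config: not enough OTUs for planted modules",
             call. = FALSE)
      }
      used <- c(used, members)
      w <- stats::rnorm(n)
      for (i in members) {
        loga[i, ] <- sqrt(m$r) * w + sqrt(1 - m$r) * loga[i, ]
      }
      planted[[paste0("planted_", k)]] <- otus[members]
    }
    # informative OTUs track the cohort latent factor
    inf_idx <- match(names(config$planted_informative), otus)
    if (anyNA(inf_idx)) {
      stop("invalid config: planted_informative names unknown OTUs",
           call. = FALSE)
    }
    for (j in seq_along(inf_idx)) {
      loga[inf_idx[j], ] <- loga[inf_idx[j], ] +
        config$planted_informative[j] * z
    }
    loga <- loga + mu
    prop <- apply(exp(loga), 2, function(x) x / sum(x))
    depth <- round(stats::runif(n, config$depth_range[1], config$depth_range[2]))
    counts <- sapply(seq_len(n), function(j) {
      stats::rmultinom(1, size = depth[j], prob = prop[, j])
    })
    dimnames(counts) <- list(otus, samples)
    attr(counts, "planted_modules") <- planted
    attr(counts, "informative") <- otus[inf_idx]
    counts
  })
}

#' Generate metabolome layers and a toy gene-reaction-compound map
#'
#' Produces (i) a human plasma compound intensity table whose first
#' compounds carry KEGG-style ids and a planted subset tracks the cohort
#' latent factor, (ii) a germfree-versus-colonized mouse intensity table
#' with planted log-fold-change shifts in the colonized arm, and (iii) a
#' toy gene-to-reaction-to-compound map in which a known compound subset
#' is producible from the microbial gene set, with partial overlap
#' between the producible, mouse-shifted, and human-observed sets.
#'
#' @param config a [synth_config()].
#' @param cohort optional cohort (latent factor reuse, as in
#'   [generate_count_table()]).
#' @return list with `human` (compound x subject matrix), `mouse`
#'   (`intensities`, `design`, `compound_ids`), `map` (a reaction map,
#'   see [read_reaction_map()]), and `gene_sets` (`microbial`, `host`).
#' @export
generate_metabolome_and_map <- function(config, cohort = NULL) {
  validate_synth_config(config)
  with_seed(derive_seed(config$seed, "metabolome"), {
    if (is.null(cohort)) {
      n <- sum(config$n_per_cohort)
      subjects <- sprintf("S%03d", seq_len(n))
      z <- stats::rnorm(n)
    } else {
      subjects <- cohort$metadata$subject
      z <- cohort$latent
      n <- length(subjects)
    }
    nc <- config$n_compounds
    compounds <- sprintf("C%05d", seq_len(nc))
    bad <- setdiff(names(config$planted_metabolite_shifts), compounds)
    if (length(bad)) {
      stop("invalid config: planted shift references unknown compound: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    # human table: log-normal intensities; a planted block tracks z
    logi <- matrix(stats::rnorm(nc * n), nrow = nc)
    r <- config$score_metabolite_r
    ns <- config$n_score_metabolites
    if (ns > 0) {
      idx <- (nc - ns + 1):nc   # last compounds track the latent factor
      for (i in idx) logi[i, ] <- r * z + sqrt(1 - r^2) * logi[i, ]
    } else {
      idx <- integer(0)
    }
    human <- exp(10 + logi)
    dimnames(human) <- list(compounds, subjects)

    # mouse experiment: balanced arms, planted shifts in the colonized arm;
    # genetically identical mice on a fixed diet vary less than free-living
    # humans, hence the smaller log-intensity spread
    m <- config$mouse_n_per_arm
    design <- factor(rep(c("germfree", "colonized"), each = m),
                     levels = c("germfree", "colonized"))
    mouse_samples <- sprintf("M%02d", seq_len(2 * m))
    logm <- matrix(stats::rnorm(nc * 2 * m, sd = 0.5), nrow = nc)
    sh <- config$planted_metabolite_shifts
    shi <- match(names(sh), compounds)
    logm[shi, design == "colonized"] <- logm[shi, design == "colonized"] + sh
    mouse <- exp(8 + logm)
    dimnames(mouse) <- list(compounds, mouse_samples)

    # toy reaction map: microbial genes produce the first 30 compounds in
    # pairs; host genes produce compounds 21..50, so origins overlap
    mk_map <- function(prefix, comp_idx) {
      rxns <- list(); genes <- list()
      blocks <- split(comp_idx, ceiling(seq_along(comp_idx) / 2))
      for (b in seq_along(blocks)) {
        rid <- sprintf("R_%s_%03d", prefix, b)
        gid <- sprintf("K_%s_%03d", prefix, b)
        rxns[[rid]] <- list(substrates = sprintf("C9%04d", b),
                            products = compounds[blocks[[b]]])
        genes[[gid]] <- rid
      }
      list(genes = genes, reactions = rxns)
    }
    micro <- mk_map("m", seq_len(min(30, nc)))
    host <- mk_map("h", intersect(21:50, seq_len(nc)))
    map <- list(genes = c(micro$genes, host$genes),
                reactions = c(micro$reactions, host$reactions))

    list(human = human,
         mouse = list(intensities = mouse, design = design,
                      compound_ids = compounds),
         map = map,
         gene_sets = list(microbial = names(micro$genes),
                          host = names(host$genes)),
         score_tracking = compounds[idx])
  })
}

#' Simulate a regression problem with planted informative features
#'
#' A small stand-alone generator for feature-selection benchmarking:
#' `n_informative` features each correlated with the response at
#' pairwise R-squared `r2`, plus independent noise features.
#'
#' @return list with `X` (data frame), `y`, and `informative` (names).
#' @export
simulate_selection_problem <- function(n = 200, n_noise = 50,
                                       n_informative = 3, r2 = 0.3,
                                       seed = 1L) {
  with_seed(seed, {
    y <- stats::rnorm(n)
    r <- sqrt(r2)
    Xi <- sapply(seq_len(n_informative), function(i) {
      r * y + sqrt(1 - r2) * stats::rnorm(n)
    })
    Xn <- matrix(stats::rnorm(n * n_noise), nrow = n)
    X <- data.frame(Xi, Xn)
    names(X) <- c(sprintf("signal_%d", seq_len(n_informative)),
                  sprintf("noise_%d", seq_len(n_noise)))
    list(X = X, y = y, informative = names(X)[seq_len(n_informative)])
  })
}

#' Simulate an XOR-style pairwise interaction problem
#'
#' `y = sign(x1) * sign(x2) + noise`: neither variable is marginally
#' informative, only their interaction is.
#' @export
simulate_interaction_problem <- function(n = 400, n_noise = 8,
                                         noise_sd = 0.5, seed = 1L) {
  with_seed(seed, {
    x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
    Xn <- matrix(stats::rnorm(n * n_noise), nrow = n)
    y <- sign(x1) * sign(x2) + stats::rnorm(n, sd = noise_sd)
    X <- data.frame(x1 = x1, x2 = x2, Xn)
    names(X)[-(1:2)] <- sprintf("noise_%d", seq_len(n_noise))
    list(X = X, y = y, interacting = c("x1", "x2"))
  })
}
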