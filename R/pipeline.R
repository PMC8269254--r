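#' Pipeline configuration
#'
#' Collects every stage threshold of the end-to-end analysis together
#' with the synthetic-cohort configuration and the forest-size knobs.
#' Stage thresholds default to the study settings: rarefaction depth
#' 19,986 reads; prevalence filter 0.2; SparCC minimum R 0.35 for
#' microbiome modules; Pearson r-squared 0.75 for diet modules; outcome
#' FDR 0.1; network FDR 0.25; metabolite FDR 0.05; interaction
#' prevalence 0.30; 1,000 permutations for the selection null.
#'
#' @param synth a [synth_config()] (defines the generated cohort).
#' @param seed root seed for the run.
#' @param rarefaction_depth,prevalence_min,sparcc_min_r,diet_r2
#'   preprocessing/module thresholds.
#' @param outcome_fdr,network_fdr,metabolite_fdr,interaction_prevalence
#'   FDR and prevalence thresholds per stage.
#' @param n_permutations permutations for the selection null (B).
#' @param selection forest-size knobs forwarded to [vsurf_select()].
#' @param n_trees_interactions,n_iterations iterated-forest sizes.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(), seed = 1L,
                            rarefaction_depth = 19986L,
                            prevalence_min = 0.2,
                            sparcc_min_r = 0.35,
                            diet_r2 = 0.75,
                            outcome_fdr = 0.1,
                            network_fdr = 0.25,
                            metabolite_fdr = 0.05,
                            interaction_prevalence = 0.30,
                            n_permutations = 1000L,
                            selection = list(n_forests = 15L,
                                             n_trees = 300L,
                                             n_forests_nested = 5L,
                                             n_trees_nested = 100L),
                            n_trees_interactions = 300L,
                            n_iterations = 3L) {
  stopifnot(rarefaction_depth >= 1, prevalence_min > 0, prevalence_min < 1,
            sparcc_min_r > 0, sparcc_min_r < 1, diet_r2 > 0, diet_r2 < 1,
            interaction_prevalence > 0, interaction_prevalence <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis end-to-end
#'
#' Stage order: generate the synthetic layers; fit and apply the
#' metabolic disease score (plus impairment cutoff and age-by-cohort
#' model); rarefy, prevalence-filter, and module-summarize the OTU
#' table (SparCC + SMD) and the diet table (Pearson r-squared + SMD);
#' select score-predictive features with three-phase forest selection
#' and the permutation null; build the FDR correlation network,
#' outcome correlations, and the iterated-forest interaction graph;
#' attribute metabolites to the microbiome (producibility + mouse
#' differential) and screen them with age-adjusted rank regression;
#' compute alpha diversity and the Mantel association.  All stage
#' outputs are written under `out_dir` along with `manifest.json`
#' recording every effective parameter and seed.  The run is
#' deterministic given the config's seeds.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param run_permutation_null run the (expensive) permutation null
#'   stage; when FALSE a reduced placeholder is skipped entirely.
#' @return (invisibly) a list with every stage result.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         run_permutation_null = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  # --- layers ---------------------------------------------------------
  cohort <- generate_cohort(config$synth)
  counts <- generate_count_table(config$synth, cohort)
  metab <- generate_metabolome_and_map(config$synth, cohort)
  write_cohort(cohort, file.path(out_dir, "layers"))
  write_feature_table(counts, file.path(out_dir, "layers", "otu_counts.tsv"))
  write_reaction_map(metab$map, file.path(out_dir, "layers",
                                          "reaction_map.json"))

  # --- metabolic disease score ---------------------------------------
  model <- fit_score_model(cohort$markers)
  scored <- score_subjects(model, cohort$markers)
  cutoff <- derive_cutoff(scored$score, cohort$markers,
                          model$clinical_thresholds)
  agefit <- age_cohort_model(scored$score, cohort$metadata$age,
                             cohort$metadata$cohort)
  write_score_model(model, file.path(out_dir, "score_model.json"))
  utils::write.table(scored, file.path(out_dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- microbiome preprocessing and modules --------------------------
  rare <- rarefy_counts(counts, depth = config$rarefaction_depth,
                        seed = derive_seed(seed, "rarefy"))
  filt <- prevalence_filter(rare, config$prevalence_min)
  sp <- sparcc(filt, seed = derive_seed(seed, "sparcc"))
  micro_mods <- smd_modules(sp$rho, min_r = config$sparcc_min_r)
  micro_sum <- summarize_modules(filt, micro_mods)
  write_module_set(micro_mods, file.path(out_dir, "microbiome_modules.tsv"))

  diet_cor <- cor_matrix(t(cohort$diet), method = "pearson")
  diet_mods <- smd_modules(diet_cor, min_r = config$diet_r2,
                           r_is_squared = TRUE)
  diet_sum <- summarize_modules(t(cohort$diet), diet_mods)
  write_module_set(diet_mods, file.path(out_dir, "diet_modules.tsv"))

  # --- feature matrix and selection ----------------------------------
  rel <- sweep(micro_sum, 2, colSums(micro_sum), `/`)
  subj <- scored$subject
  features <- data.frame(
    age = cohort$metadata$age, bmi = cohort$metadata$bmi,
    bloating = cohort$metadata$bloating,
    cohort$immune[subj, , drop = FALSE],
    t(diet_sum)[subj, , drop = FALSE],
    t(rel)[subj, , drop = FALSE], check.names = FALSE)
  layers <- stats::setNames(
    rep(c("clinical", "immune", "diet", "microbe"),
        c(3, ncol(cohort$immune), nrow(diet_sum), nrow(rel))),
    names(features))
  sel <- do.call(vsurf_select,
                 c(list(X = features, y = scored$score,
                        seed = derive_seed(seed, "vsurf")),
                   config$selection))
  fit <- if (length(sel$interpretation_set)) {
    random_forest_regress(features[, sel$interpretation_set, drop = FALSE],
                          scored$score,
                          seed = derive_seed(seed, "forest"))
  }
  perm <- if (run_permutation_null) {
    permutation_null(features, scored$score, B = config$n_permutations,
                     seed = derive_seed(seed, "perm"),
                     vsurf_params = config$selection)
  }
  jsonlite::write_json(
    list(threshold_set = sel$threshold_set,
         interpretation_set = sel$interpretation_set,
         prediction_set = sel$prediction_set,
         oob_r2 = if (!is.null(fit)) fit$oob_r2 else NA,
         permutation_p = if (!is.null(perm)) perm$p else NA),
    file.path(out_dir, "selection.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  utils::write.table(sel$importance, file.path(out_dir, "importance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- networks and interactions -------------------------------------
  selset <- if (length(sel$interpretation_set) >= 2) {
    sel$interpretation_set
  } else {
    utils::head(sel$ranked, 10)
  }
  net <- spearman_network(features[, selset, drop = FALSE],
                          fdr_threshold = config$network_fdr,
                          layers = layers[selset])
  oc <- outcome_correlations(features[, selset, drop = FALSE], scored$score,
                             fdr_threshold = config$outcome_fdr)
  inter <- iterative_forest_interactions(
    features[, selset, drop = FALSE], scored$score,
    n_iterations = config$n_iterations,
    n_trees = config$n_trees_interactions,
    min_prevalence = config$interaction_prevalence,
    seed = derive_seed(seed, "interactions"))
  utils::write.table(net$edges, file.path(out_dir, "network_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(oc, file.path(out_dir, "outcome_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(inter$all_pairs,
                     file.path(out_dir, "interaction_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- metabolite origin ---------------------------------------------
  producible <- producible_compounds(metab$gene_sets$microbial, metab$map)
  host_prod <- producible_compounds(metab$gene_sets$host, metab$map)
  diffres <- mouse_differential(metab$mouse, alpha = config$metabolite_fdr)
  origin <- combine_origin(producible, diffres$differential,
                           rownames(metab$human), host_prod)
  met_oc <- outcome_correlations(t(log(metab$human)), scored$score,
                                 fdr_threshold = config$metabolite_fdr)
  screen <- rank_metabolite_screen(metab$human, scored$score,
                                   cohort$metadata$age,
                                   alpha = config$metabolite_fdr)
  utils::write.table(origin, file.path(out_dir, "metabolite_origin.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- community-level measures --------------------------------------
  adiv <- alpha_diversity(rare)
  bray <- vegan::vegdist(t(rare), method = "bray")
  dscore <- stats::dist(scored$score)
  mant <- mantel_test(bray, dscore, n_permutations = 199L,
                      seed = derive_seed(seed, "mantel"))
  utils::write.table(adiv, file.path(out_dir, "alpha_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("metsys")),
    seed = seed,
    thresholds = config[c("rarefaction_depth", "prevalence_min",
                          "sparcc_min_r", "diet_r2", "outcome_fdr",
                          "network_fdr", "metabolite_fdr",
                          "interaction_prevalence", "n_permutations")],
    selection_params = config$selection,
    stage_sizes = list(
      n_subjects = nrow(cohort$metadata),
      n_otus_filtered = nrow(filt),
      n_microbiome_modules = length(micro_mods$modules),
      n_diet_modules = length(diet_mods$modules),
      n_selected = length(sel$interpretation_set),
      n_network_edges = nrow(net$edges),
      n_interaction_edges = nrow(inter$edges),
      n_microbiome_associated = sum(origin$microbiome_associated),
      mantel_r = mant$r, mantel_p = mant$p))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(cohort = cohort, counts = counts, metabolome = metab,
                 score_model = model, scores = scored,
                 derived_cutoff = cutoff, age_model = agefit,
                 microbiome_modules = micro_mods, diet_modules = diet_mods,
                 selection = sel, forest = fit, permutation = perm,
                 network = net, outcome = oc, interactions = inter,
                 origin = origin, metabolite_correlations = met_oc,
                 rank_screen = screen, alpha = adiv, mantel = mant,
                 manifest = manifest))
}
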