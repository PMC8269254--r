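# Association structure among selected features: Spearman network at
# FDR < 0.25, outcome correlations with the score at FDR < 0.1, the LBP
# neighborhood, and the iterated-forest interaction graph at 30% tree
# prevalence.

source("analysis/00_config.R")

L <- layers()
co <- L$cohort
scored <- score_subjects(fit_score_model(co$markers), co$markers)

sel_path <- file.path(OUT, "selection.json")
if (!file.exists(sel_path)) stop("run analysis/04_selection.R first")
sel <- jsonlite::read_json(sel_path, simplifyVector = TRUE)

rare <- rarefy_counts(L$counts, depth = 19986,
                      seed = metsys:::derive_seed(ROOT_SEED, "rarefy"))
filt <- prevalence_filter(rare, 0.2)
micro_sum <- summarize_modules(filt, smd_modules(sparcc(filt)$rho, 0.35))
rel <- sweep(micro_sum, 2, colSums(micro_sum), `/`)
features <- data.frame(age = co$metadata$age, bmi = co$metadata$bmi,
                       bloating = co$metadata$bloating,
                       co$immune, t(rel)[scored$subject, ],
                       check.names = TRUE)

vars <- sel$interpretation_set
net <- spearman_network(features[, vars], fdr_threshold = 0.25)
oc <- outcome_correlations(features[, vars], scored$score,
                           fdr_threshold = 0.1)
ig <- iterative_forest_interactions(features[, vars], scored$score,
                                    n_trees = 300,
                                    seed = metsys:::derive_seed(ROOT_SEED,
                                                                "irf"))

utils::write.table(net$edges, file.path(OUT, "network_edges.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(oc, file.path(OUT, "outcome_correlations.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(ig$all_pairs, file.path(OUT, "interaction_edges.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

message(nrow(net$edges), " network edges at FDR < 0.25 among ",
        length(vars), " selected features")
message(sum(oc$pass), " of ", nrow(oc),
        " selected features correlate with the score at FDR < 0.1")
if ("LBP" %in% vars) {
  nb <- subnetwork(net, "LBP")
  message("LBP neighborhood: ", nrow(nb), " incident edge(s)")
}
message(nrow(ig$edges), " interaction edge(s) at >= 30% tree prevalence")
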