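# Feature selection: three-phase forest selection of score predictors
# over clinical + immune + diet-module + microbe-module features, a
# standard forest on the selected set, and the permutation null for the
# OOB variance explained (reduced B = 99 here; B = 1000 reproduces the
# study's resolution).

source("analysis/00_config.R")

L <- layers()
co <- L$cohort
scored <- score_subjects(fit_score_model(co$markers), co$markers)

rare <- rarefy_counts(L$counts, depth = 19986,
                      seed = metsys:::derive_seed(ROOT_SEED, "rarefy"))
filt <- prevalence_filter(rare, 0.2)
micro_sum <- summarize_modules(filt, smd_modules(sparcc(filt)$rho, 0.35))
rel <- sweep(micro_sum, 2, colSums(micro_sum), `/`)

features <- data.frame(age = co$metadata$age, bmi = co$metadata$bmi,
                       bloating = co$metadata$bloating,
                       co$immune, t(rel)[scored$subject, ],
                       check.names = TRUE)

sel <- do.call(vsurf_select,
               c(list(X = features, y = scored$score,
                      seed = metsys:::derive_seed(ROOT_SEED, "vsurf")),
                 SELECTION))
fit <- random_forest_regress(features[, sel$interpretation_set], scored$score,
                             seed = metsys:::derive_seed(ROOT_SEED, "rf"))
pn <- permutation_null(features, scored$score, B = 99,
                       seed = metsys:::derive_seed(ROOT_SEED, "perm"),
                       vsurf_params = SELECTION)

utils::write.table(sel$importance, file.path(OUT, "importance.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(threshold_set = sel$threshold_set,
                          interpretation_set = sel$interpretation_set,
                          prediction_set = sel$prediction_set,
                          oob_r2 = fit$oob_r2, permutation_p = pn$p),
                     file.path(OUT, "selection.json"), auto_unbox = TRUE,
                     pretty = TRUE, digits = NA)

message("selected ", length(sel$interpretation_set),
        " interpretation variables (",
        length(sel$prediction_set), " predictive): ",
        paste(utils::head(sel$interpretation_set, 8), collapse = ", "),
        if (length(sel$interpretation_set) > 8) ", ...")
message("top importance: ", sel$importance$feature[1])
message(sprintf("forest on selected set: OOB r2 = %.1f%%; permutation p = %.3g (B = %d)",
                fit$oob_r2, pn$p, pn$B))
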