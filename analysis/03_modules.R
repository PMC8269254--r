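# Count-table preprocessing and co-occurrence modules: rarefaction to
# 19,986 reads, >20% prevalence filter, SparCC correlations, SMD module
# detection (min R 0.35 microbiome; Pearson r^2 0.75 diet), summation
# summarization.

source("analysis/00_config.R")

L <- layers()

rare <- rarefy_counts(L$counts, depth = 19986,
                      seed = metsys:::derive_seed(ROOT_SEED, "rarefy"))
filt <- prevalence_filter(rare, 0.2)
sp <- sparcc(filt)
micro_mods <- smd_modules(sp$rho, min_r = 0.35)
micro_sum <- summarize_modules(filt, micro_mods)

diet_cor <- cor_matrix(t(L$cohort$diet), method = "pearson")
diet_mods <- smd_modules(diet_cor, min_r = 0.75, r_is_squared = TRUE)

write_module_set(micro_mods, file.path(OUT, "microbiome_modules.tsv"))
write_module_set(diet_mods, file.path(OUT, "diet_modules.tsv"))
write_feature_table(micro_sum, file.path(OUT, "otu_summarized.tsv"))

message(nrow(filt), " of ", nrow(rare), " OTUs pass the prevalence filter")
sizes <- lengths(micro_mods$modules)
message(length(micro_mods$modules), " microbiome module(s) of sizes ",
        paste(sizes, collapse = ", "),
        "; features ", nrow(filt), " -> ", nrow(micro_sum),
        " after summarization (drop = sum(size - 1) = ",
        sum(sizes - 1), ")")
planted <- attr(L$counts, "planted_modules")[[1]]
hit <- any(vapply(micro_mods$modules, function(m) all(planted %in% m),
                  logical(1)))
message("planted 3-OTU block recovered as a module: ", hit)
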