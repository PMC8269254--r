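# Generate the synthetic multi-omic cohort: metadata, fasting markers,
# immune panel, diet, OTU counts, human/mouse metabolomes, reaction map.
# Everything downstream re-derives from the same root seed.

source("analysis/00_config.R")

L <- layers()
write_cohort(L$cohort, file.path(OUT, "layers"))
write_feature_table(L$counts, file.path(OUT, "layers", "otu_counts.tsv"))
write_feature_table(L$metab$human,
                    file.path(OUT, "layers", "human_metabolome.tsv"))
write_feature_table(L$metab$mouse$intensities,
                    file.path(OUT, "layers", "mouse_metabolome.tsv"))
write_reaction_map(L$metab$map, file.path(OUT, "layers", "reaction_map.json"))

message("cohort: ", nrow(L$cohort$metadata), " subjects in ",
        nlevels(L$cohort$metadata$cohort), " cohorts")
message("counts: ", nrow(L$counts), " OTUs x ", ncol(L$counts),
        " samples (min depth ", min(colSums(L$counts)), ")")
message("metabolome: ", nrow(L$metab$human), " compounds; mouse ",
        ncol(L$metab$mouse$intensities), " samples")
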