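# Microbiome-origin attribution of plasma metabolites (gene-set
# producibility + germfree-vs-colonized differential at FDR < 0.05),
# score correlations of metabolites at FDR < 0.05, and the age-adjusted
# rank-regression screen with its with/without-age overlap.

source("analysis/00_config.R")

L <- layers()
co <- L$cohort
scored <- score_subjects(fit_score_model(co$markers), co$markers)
gm <- L$metab

producible <- producible_compounds(gm$gene_sets$microbial, gm$map)
host_prod <- producible_compounds(gm$gene_sets$host, gm$map)
diff <- mouse_differential(gm$mouse, alpha = 0.05)
origin <- combine_origin(producible, diff$differential, rownames(gm$human),
                         host_prod)

met_oc <- outcome_correlations(as.data.frame(t(log(gm$human))),
                               scored$score, fdr_threshold = 0.05)
screen <- rank_metabolite_screen(gm$human, scored$score, co$metadata$age,
                                 alpha = 0.05)

utils::write.table(origin, file.path(OUT, "metabolite_origin.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(screen$stats, file.path(OUT, "rank_screen.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(met_oc, file.path(OUT, "metabolite_correlations.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

message(length(diff$differential), " compounds differ between germfree ",
        "and colonized mice at FDR < 0.05 (",
        length(intersect(diff$differential,
                         names(cfg$planted_metabolite_shifts))),
        " of the 10 planted)")
message(length(producible), " compounds producible from the microbial ",
        "gene set; ", sum(origin$microbiome_associated),
        " microbiome-associated overall")
excl <- origin$microbiome_associated & origin$producible_by_microbes &
  !origin$producible_by_host
message(sum(excl), " associated compound(s) producible exclusively by ",
        "microbes")
message(sum(met_oc$pass), " metabolites correlate with the score at ",
        "FDR < 0.05")
message("rank screen: ", length(screen$significant_without_age),
        " significant without age, ", length(screen$significant_with_age),
        " with age, overlap ", length(screen$overlap))
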