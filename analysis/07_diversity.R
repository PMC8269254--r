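# Community-level associations: alpha diversity (Shannon, Pielou,
# observed features) against the score, and a Mantel test between
# community dissimilarity and score differences.

source("analysis/00_config.R")

L <- layers()
scored <- score_subjects(fit_score_model(L$cohort$markers),
                         L$cohort$markers)
rare <- rarefy_counts(L$counts, depth = 19986,
                      seed = metsys:::derive_seed(ROOT_SEED, "rarefy"))

adiv <- alpha_diversity(rare)
utils::write.table(adiv, file.path(OUT, "alpha_diversity.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

for (metric in c("shannon", "pielou", "observed")) {
  ct <- suppressWarnings(cor.test(adiv[[metric]], scored$score,
                                  method = "spearman"))
  message(sprintf("score vs %s: rho = %.3f, p = %.3f", metric,
                  ct$estimate, ct$p.value))
}

bray <- vegan::vegdist(t(rare), method = "bray")
mt <- mantel_test(bray, dist(scored$score), n_permutations = 999,
                  seed = metsys:::derive_seed(ROOT_SEED, "mantel"))
message(sprintf("Mantel (Bray-Curtis vs score distance): r = %.3f, p = %.3f",
                mt$r, mt$p))
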