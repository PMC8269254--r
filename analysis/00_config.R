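# Shared configuration for the analysis scripts.  Each numbered script
# is standalone: it regenerates the synthetic layers deterministically
# from ROOT_SEED through the package and writes its tables under
# results/analysis/.

library(metsys)

ROOT_SEED <- 20260101L
OUT <- "results/analysis"
dir.create(OUT, showWarnings = FALSE, recursive = TRUE)

# study-shaped cohort: 22/32/14/20/25 subjects, 60 OTUs, one planted
# 3-member co-occurrence block, three OTUs tracking the latent factor
cfg <- synth_config(seed = ROOT_SEED)

layers <- function() {
  co <- generate_cohort(cfg)
  list(cohort = co,
       counts = generate_count_table(cfg, co),
       metab = generate_metabolome_and_map(cfg, co))
}

# forest sizes used throughout the analysis (reduced from the package
# defaults; stable at this problem size and quick on one CPU)
SELECTION <- list(n_forests = 10, n_trees = 150, n_forests_nested = 4,
                  n_trees_nested = 100)
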