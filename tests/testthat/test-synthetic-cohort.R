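test_that("cohort layers have the study's shape and are join-consistent", {
  cfg <- synth_config()
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$metadata), 113)
  expect_equal(nlevels(co$metadata$cohort), 5)
  expect_equal(ncol(co$markers), 7)
  expect_equal(ncol(co$immune), 21)
  expect_equal(ncol(co$diet), 29)
  expect_false(anyNA(co$markers) || anyNA(co$immune) || anyNA(co$diet))
  # same subject set across all tables
  expect_identical(rownames(co$markers), co$metadata$subject)
  expect_identical(rownames(co$immune), co$metadata$subject)
  expect_identical(rownames(co$diet), co$metadata$subject)
  ct <- generate_count_table(cfg, co)
  expect_identical(colnames(ct), co$metadata$subject)
  # treated cohorts are older by design
  med <- tapply(co$metadata$age, co$metadata$cohort, median)
  expect_gt(med[5], med[2])
})

test_that("a fixed seed gives identical output; different seeds differ", {
  cfg <- synth_config(seed = 7)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_identical(generate_count_table(cfg), generate_count_table(cfg))
  expect_identical(generate_metabolome_and_map(cfg),
                   generate_metabolome_and_map(cfg))
  cfg2 <- synth_config(seed = 8)
  expect_false(identical(generate_cohort(cfg)$markers,
                         generate_cohort(cfg2)$markers))
})

test_that("zero latent effect leaves markers uncorrelated", {
  le <- setNames(rep(0, 7), metsys:::marker_names())
  cfg <- synth_config(n_per_cohort = c(all = 500), latent_effect = le,
                      lbp_effect = 0, seed = 3)
  co <- generate_cohort(cfg)
  cm <- cor(co$markers)
  expect_lte(max(abs(cm[upper.tri(cm)])), 0.2)
})

test_that("the latent factor drives triglycerides at default effects", {
  cfg <- synth_config(n_per_cohort = setNames(rep(30, 5), letters[1:5]),
                      seed = 1)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$markers), 150)
  expect_gte(cor(co$latent, co$markers[, "triglycerides"]), 0.5)
})

test_that("count table depths support the study rarefaction depth", {
  ct <- generate_count_table(synth_config(seed = 2))
  expect_true(all(colSums(ct) >= 19986))
  expect_true(all(ct >= 0) && all(ct == round(ct)))
})

test_that("without planted structure no OTU pair co-occurs strongly", {
  cfg <- synth_config(n_per_cohort = c(all = 500), planted_modules = list(),
                      planted_informative = numeric(0), seed = 5)
  ct <- generate_count_table(cfg)
  prop <- sweep(ct + 1, 2, colSums(ct + 1), "/")
  cl <- cor(t(log(prop)))
  expect_lte(max(abs(cl[upper.tri(cl)])), 0.5)
})

test_that("a planted 3-member block is recovered by SparCC at 0.35", {
  cfg <- synth_config(planted_modules = list(list(size = 3, r = 0.9)),
                      seed = 11)
  ct <- generate_count_table(cfg)
  members <- attr(ct, "planted_modules")[[1]]
  rho <- sparcc(ct)$rho[members, members]
  expect_true(all(rho[upper.tri(rho)] >= 0.35))
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_per_cohort = c(a = 0)), "positive")
  expect_error(synth_config(planted_modules = list(list(size = 99, r = .5))),
               "exceeds n_otus")
  expect_error(synth_config(planted_modules = list(list(size = 3, r = 1))),
               "correlation")
  expect_error(synth_config(planted_metabolite_shifts = c(ZZZ = 2)) |>
                 generate_metabolome_and_map(), "unknown compound")
  expect_error(generate_count_table(
    synth_config(planted_informative = c(OTU_999 = 1))), "unknown OTUs")
})

test_that("metabolome layers carry the planted overlap structure", {
  cfg <- synth_config(seed = 4)
  gm <- generate_metabolome_and_map(cfg, generate_cohort(cfg))
  producible <- producible_compounds(gm$gene_sets$microbial, gm$map)
  shifted <- names(cfg$planted_metabolite_shifts)
  human <- rownames(gm$human)
  # producible and shifted sets overlap partially within the human set
  expect_gt(length(intersect(producible, shifted)), 0)
  expect_lt(length(intersect(producible, shifted)), length(producible))
  expect_true(all(producible %in% human))
  expect_equal(ncol(gm$mouse$intensities), 2 * cfg$mouse_n_per_arm)
  expect_true(all(gm$mouse$intensities >= 0))
})

test_that("planted mouse shifts drive the differential test, absent shifts do not", {
  hits_null <- vapply(1:3, function(s) {
    cfg <- synth_config(planted_metabolite_shifts = numeric(0), seed = s)
    gm <- generate_metabolome_and_map(cfg)
    length(mouse_differential(gm$mouse)$differential)
  }, numeric(1))
  expect_true(all(hits_null == 0))
  cfg <- synth_config(seed = 1)
  gm <- generate_metabolome_and_map(cfg)
  rec <- intersect(mouse_differential(gm$mouse)$differential,
                   names(cfg$planted_metabolite_shifts))
  expect_gte(length(rec), 8)
})
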