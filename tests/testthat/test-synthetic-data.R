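test_that("planted DE features are exact in number and seeded runs are identical", {
  cfg <- synthetic_config(seed = 1, n_features = 300, n_lncrna_probes = 60,
                          probes_per_symbol = 1, n_de_features = 10,
                          de_effect = 2, n_tfs = 2, targets_per_tf = 3,
                          n_pathways = 4, pathway_size = 10)
  a <- generate_expression(cfg)
  expect_length(a$truth$de_features, 10)
  expect_true(all(a$truth$de_features %in% rownames(a$data$values)))
  expect_setequal(names(a$truth$de_direction), a$truth$de_features)

  b <- generate_expression(cfg)
  expect_identical(a$data$values, b$data$values)
  expect_identical(generate_interaction_tables(cfg, a$truth),
                   generate_interaction_tables(cfg, b$truth))
  expect_identical(generate_pathways(cfg, a$truth),
                   generate_pathways(cfg, b$truth))
})

test_that("non-DE features carry no group signal: pooled-t p-values are uniform", {
  cfg <- synthetic_config(seed = 1, n_minority = 10, n_majority = 20,
                          n_features = 1500, n_lncrna_probes = 300,
                          probes_per_symbol = 1, n_de_features = 50,
                          de_effect = 2, n_tfs = 0)
  gen <- generate_expression(cfg)
  v <- gen$data$values
  non_de <- setdiff(rownames(v), gen$truth$de_features)
  lab <- gen$data$sample_labels
  pvals <- apply(v[non_de, ], 1, function(x) {
    t.test(x[lab == "CAF"], x[lab == "NOF"], var.equal = TRUE)$p.value
  })
  expect_gt(length(pvals), 1000)
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("planted module members correlate more than random feature pairs", {
  sim <- fixture_sim()
  v <- sim$data$values
  ann <- sim$data$annotation
  mean_pair_cor <- function(feats) {
    cm <- cor(t(v[feats, ]))
    mean(cm[upper.tri(cm)])
  }
  set.seed(10)
  non_module <- setdiff(rownames(v), unlist(lapply(sim$truth$tf_modules,
                                                   `[[`, "features")))
  random_cor <- mean_pair_cor(sample(non_module, 20))
  for (tf in names(sim$truth$tf_modules)) {
    expect_gt(mean_pair_cor(sim$truth$tf_modules[[tf]]$features), random_cor)
  }
})

test_that("generated files round-trip through the package readers", {
  sim <- fixture_sim()
  d <- withr::local_tempdir()
  write_expression_tsv(sim$data, file.path(d, "e.tsv"), file.path(d, "l.tsv"),
                       file.path(d, "a.tsv"))
  back <- read_expression_tsv(file.path(d, "e.tsv"), file.path(d, "l.tsv"),
                              file.path(d, "a.tsv"))
  expect_equal(back$values, sim$data$values)
  expect_identical(back$sample_labels, sim$data$sample_labels)
  expect_identical(back$annotation, sim$data$annotation)

  write_interactions_tsv(sim$tf_tg, file.path(d, "tg.tsv"))
  expect_identical(read_interactions_tsv(file.path(d, "tg.tsv")), sim$tf_tg)

  write_gmt(sim$pathways, file.path(d, "p.gmt"))
  expect_identical(read_gmt(file.path(d, "p.gmt")), sim$pathways)
})

test_that("interaction tables split module members by biotype and honour zero TFs", {
  cfg <- synthetic_config(seed = 2, n_features = 400, n_lncrna_probes = 100,
                          probes_per_symbol = 1, n_de_features = 20,
                          n_tfs = 2, targets_per_tf = 10, decoys_per_tf = 0)
  gen <- generate_expression(cfg)
  tabs <- generate_interaction_tables(cfg, gen$truth)
  for (tf in names(gen$truth$tf_modules)) {
    m <- gen$truth$tf_modules[[tf]]
    expect_length(m$lncrna, 3)  # ~30% of a 10-member module
    expect_length(m$coding, 7)
    expect_setequal(tabs$tf_lncrna$target_symbol[tabs$tf_lncrna$tf_symbol == tf],
                    m$lncrna)
    expect_setequal(tabs$tf_tg$target_symbol[tabs$tf_tg$tf_symbol == tf],
                    m$coding)
  }

  cfg0 <- synthetic_config(seed = 2, n_features = 100, n_lncrna_probes = 20,
                           probes_per_symbol = 1, n_de_features = 4, n_tfs = 0)
  tabs0 <- generate_interaction_tables(cfg0, generate_expression(cfg0)$truth)
  expect_identical(nrow(tabs0$tf_lncrna), 0L)
  expect_identical(nrow(tabs0$tf_tg), 0L)
  expect_named(tabs0$tf_tg, c("tf_symbol", "target_symbol", "rank"))
})

test_that("pathway planting honours the enrichment fraction", {
  cfg <- synthetic_config(seed = 3, n_features = 600, n_lncrna_probes = 120,
                          probes_per_symbol = 1, n_de_features = 30,
                          n_tfs = 2, targets_per_tf = 10,
                          n_pathways = 4, pathway_size = 20,
                          planted_enrichment_fraction = 1)
  gen <- generate_expression(cfg)
  pws <- generate_pathways(cfg, gen$truth)
  pt <- gen$truth$pathway_truth
  for (i in seq_len(nrow(pt))) {
    cod <- gen$truth$tf_modules[[pt$tf[i]]]$coding
    expect_true(all(cod %in% pws[[pt$pathway_id[i]]]))
  }
  # too-small pathways cannot hold the planted overlap
  cfg_bad <- synthetic_config(seed = 3, n_features = 600, n_lncrna_probes = 120,
                              probes_per_symbol = 1, n_de_features = 30,
                              n_tfs = 2, targets_per_tf = 10,
                              n_pathways = 4, pathway_size = 5,
                              planted_enrichment_fraction = 1)
  expect_error(generate_pathways(cfg_bad, generate_expression(cfg_bad)$truth),
               "pathway_size")
})

test_that("unplanted pathway overlap follows the hypergeometric null", {
  # with planted_enrichment_fraction = 0 a pathway is a uniform draw of
  # coding symbols, so its overlap with a fixed module should follow the
  # hypergeometric distribution
  base <- list(n_features = 400, n_lncrna_probes = 100, probes_per_symbol = 1,
               n_de_features = 30, n_tfs = 2, targets_per_tf = 10,
               n_pathways = 1, pathway_size = 20,
               planted_enrichment_fraction = 0)
  cfg1 <- do.call(synthetic_config, c(base, seed = 1))
  gen <- generate_expression(cfg1)
  cod <- gen$truth$tf_modules[["TF01"]]$coding
  n_coding <- length(gen$truth$symbols_coding)
  overlaps <- vapply(1:1000, function(s) {
    cfg <- do.call(synthetic_config, c(base, seed = s))
    length(intersect(generate_pathways(cfg, gen$truth)[[1]], cod))
  }, numeric(1))
  ks <- seq(0, length(cod))
  expected <- dhyper(ks, length(cod), n_coding - length(cod), 20) * 1000
  observed <- tabulate(overlaps + 1L, nbins = length(ks))
  keep <- expected > 1
  chi <- sum((observed[keep] - expected[keep])^2 / expected[keep])
  expect_gt(pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE), 0.001)
})

test_that("configuration invariants are validated", {
  expect_error(synthetic_config(n_de_features = 5000, n_features = 100),
               "exceeds")
  expect_error(synthetic_config(noise_sd = 0), "noise_sd")
  expect_error(synthetic_config(n_de_features = 7, probes_per_symbol = 2),
               "multiple")
  expect_error(synthetic_config(n_tfs = 5, targets_per_tf = 10,
                                n_de_features = 20, probes_per_symbol = 1),
               "not enough planted DE symbols")
})
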