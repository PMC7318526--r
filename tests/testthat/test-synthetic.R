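test_that("identical seeds give identical bundles; different seeds differ", {
  a <- simulate_dataset(small_config(seed = 30))
  b <- simulate_dataset(small_config(seed = 30))
  expect_identical(a$bundle$beta, b$bundle$beta)
  expect_identical(a$bundle$detp, b$bundle$detp)
  expect_equal(a$bundle$drug, b$bundle$drug)
  expect_identical(a$bundle$expression$values, b$bundle$expression$values)
  expect_equal(a$truth$lineage, b$truth$lineage)
  c <- simulate_dataset(small_config(seed = 31))
  expect_false(identical(a$bundle$beta, c$bundle$beta))
})

test_that("generated bundles satisfy the loader's validation contract", {
  sim <- simulate_dataset(small_config(seed = 32))
  expect_true(all(sim$bundle$beta >= 0 & sim$bundle$beta <= 1))
  expect_true(all(sim$bundle$detp >= 0 & sim$bundle$detp <= 1))
  expect_true(all(sim$bundle$drug$ic50 > 0))
  # every planted entity exists in the bundle
  tr <- sim$truth
  expect_true(all(tr$planted_probes$probe_id %in% rownames(sim$bundle$beta)))
  expect_true(all(tr$planted_regions$gene %in% sim$bundle$assignments$gene))
  expect_true(all(tr$agents$agent %in% sim$bundle$drug$agent))
  # loads without error after a disk round trip
  dir <- withr::local_tempdir()
  expect_no_error(load_dataset(write_dataset(sim$bundle, dir)))
})

test_that("manifest simulation plants SNP flags at the configured binomial rate", {
  cfg <- sim_config(n_genes = 544L, snp_rate = 0.1, seed = 33,
    archetypes = c(canonical_repressive = 0L, positive_coupled = 0L,
      cn_driven = 0L, lineage_linked = 0L))
  man <- simulate_manifest(cfg)
  n <- nrow(man)
  expect_gte(n, 9900L)
  flagged <- sum(man$snp_masked)
  bounds <- qbinom(c(0.005, 0.995), n, 0.1)
  expect_gte(flagged, bounds[1])
  expect_lte(flagged, bounds[2])
  # multi-assignment fraction zero keeps the reverse index single-valued
  cfg0 <- small_config(seed = 33, multi_gene_rate = 0)
  asn <- probe_assignments(simulate_manifest(cfg0))
  expect_equal(max(table(asn$probe_id)), 1L)
  # one probe per class, one gene -> six probes, six region keys
  cfg1 <- sim_config(n_genes = 1L, n_intergenic = 0L, multi_gene_rate = 0,
    probes_per_class = c(TSS1500 = 1L, TSS200 = 1L, `5UTR` = 1L,
      `1stExon` = 1L, Body = 1L, `3UTR` = 1L),
    archetypes = c(canonical_repressive = 0L, positive_coupled = 0L,
      cn_driven = 0L, lineage_linked = 0L),
    n_agents = 3L, n_constant_agents = 0L, seed = 1)
  asn1 <- probe_assignments(simulate_manifest(cfg1))
  expect_equal(nrow(asn1), 6L)
  expect_equal(dplyr::n_distinct(asn1$region), 6L)
})

test_that("planted repressive coupling reaches the configured strength", {
  sim <- simulate_dataset(small_config(seed = 34))
  qc <- run_probe_qc(sim$bundle)
  idx <- build_region_index(sim$bundle$assignments, qc$retained_probes)
  reg <- average_region_betas(qc$beta, idx)
  gt <- sim$truth$genes
  for (g in gt$gene[gt$archetype == "canonical_repressive"]) {
    rho <- spearman_cor(
      reg$values[paste0(g, "|TSS200"), ],
      sim$bundle$expression$values[paste0("TX_", g, "_1"), ]
    )$coefficient
    expect_lt(rho, -0.5)
  }
})

test_that("null genes show calibrated type-I behaviour for methylation-expression tests", {
  pvals <- c()
  for (s in 40:44) {
    sim <- simulate_dataset(small_config(seed = s))
    qc <- run_probe_qc(sim$bundle)
    idx <- build_region_index(sim$bundle$assignments, qc$retained_probes)
    reg <- average_region_betas(qc$beta, idx)
    gt <- sim$truth$genes
    nulls <- gt$gene[gt$archetype == "null"]
    keys <- reg$keys$key[reg$keys$gene %in% nulls]
    me <- methylation_expression_correlations(
      reg$values[keys, , drop = FALSE], sim$bundle$expression,
      dplyr::select(dplyr::filter(reg$keys, key %in% keys), feature_id = key, gene))
    pvals <- c(pvals, me$p_value)
  }
  frac <- mean(pvals < 0.05, na.rm = TRUE)
  n <- sum(!is.na(pvals))
  bounds <- qbinom(c(0.005, 0.995), n, 0.05) / n
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})

test_that("recovery metrics equal brute-force set arithmetic", {
  sim <- simulate_dataset(small_config(seed = 35))
  planted <- sim$truth$planted_regions
  # calls exactly equal to the planted set
  perfect <- tibble::tibble(
    feature_id = planted$key, agent = planted$agent, p_fdr = 1e-6)
  m <- evaluate_recovery(perfect, sim$truth, tier = 0.1, level = "region")
  expect_equal(m$tpr, 1)
  expect_equal(m$fdp, 0)
  # empty call set: zero calls, FDP reported as NA
  m0 <- evaluate_recovery(perfect[0, ], sim$truth, tier = 0.1, level = "region")
  expect_equal(m0$n_calls, 0L)
  expect_true(is.na(m0$fdp))
  expect_equal(m0$tpr, 0)
  # random call set matches independent set-intersection counts
  withr::with_seed(99, {
    random <- tibble::tibble(
      feature_id = sample(planted$key, 20, replace = TRUE),
      agent = sample(sim$truth$agents$agent, 20, replace = TRUE),
      p_fdr = 1e-6
    )
    random <- dplyr::distinct(random)
  })
  m2 <- evaluate_recovery(random, sim$truth, tier = 0.1, level = "region")
  key_p <- paste(planted$key, planted$agent)
  key_c <- paste(random$feature_id, random$agent)
  expect_equal(m2$n_true_calls, length(intersect(key_c, key_p)))
  expect_equal(m2$tpr, length(intersect(key_c, key_p)) / length(key_p))
  expect_equal(m2$fdp, length(setdiff(key_c, key_p)) / length(key_c))
})

test_that("recovery is monotone in the planted effect size", {
  tprs <- vapply(c(0.35, 0.55, 0.75), function(rho) {
    tp <- 0; tc <- 0
    for (s in 50:52) {
      sim <- simulate_dataset(small_config(seed = s, target_rho = rho))
      qc <- run_probe_qc(sim$bundle)
      idx <- build_region_index(sim$bundle$assignments, qc$retained_probes)
      reg <- average_region_betas(qc$beta, idx)
      fv <- filter_variable_agents(median_log_ic50(sim$bundle$drug))
      rec <- correlate_features_with_response(reg, fv$response, "epigenome_region")
      rec <- methylscreen:::add_fdr(rec, 0.1)
      m <- evaluate_recovery(rec, sim$truth, tier = 0.1, level = "region")
      tp <- tp + m$n_true_calls; tc <- tc + m$n_planted
    }
    tp / tc
  }, numeric(1))
  expect_true(all(diff(tprs) >= 0))
  expect_gt(tprs[3], tprs[1])
})
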