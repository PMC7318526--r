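test_that("methylation-expression correlations recover planted repression", {
  sim <- simulate_dataset(small_config(seed = 20))
  qc <- run_probe_qc(sim$bundle)
  idx <- build_region_index(sim$bundle$assignments, qc$retained_probes)
  reg <- average_region_betas(qc$beta, idx)
  me <- methylation_expression_correlations(reg, sim$bundle$expression, NULL)
  planted <- sim$truth$genes$gene[sim$truth$genes$archetype == "canonical_repressive"]
  rep_rows <- me[me$gene %in% planted & grepl("TSS200", me$feature_id) &
    grepl("_1$", me$transcript_id), ]
  expect_true(all(rep_rows$coefficient < -0.5))
  expect_true(all(rep_rows$p_value < 1e-4))
  # unrelated transcripts stay weak
  nulls <- sim$truth$genes$gene[sim$truth$genes$archetype == "null"]
  null_rows <- me[me$gene %in% nulls & grepl("_1$", me$transcript_id), ]
  expect_lt(stats::median(abs(null_rows$coefficient)), 0.2)
})

test_that("a feature tracking a transcript monotonically correlates perfectly", {
  sim <- simulate_dataset(small_config(seed = 21))
  ex <- sim$bundle$expression
  tx <- ex$tx_map$transcript_id[1]
  g <- ex$tx_map$gene[1]
  feat <- matrix(stats::plogis(ex$values[tx, ]), 1,
    dimnames = list("probeX", colnames(ex$values)))
  me <- methylation_expression_correlations(
    feat, ex, tibble::tibble(feature_id = "probeX", gene = g))
  expect_equal(me$coefficient[me$transcript_id == tx], 1)
})

test_that("expression-response correlations recover planted coupling", {
  sim <- simulate_dataset(small_config(seed = 22))
  fv <- filter_variable_agents(median_log_ic50(sim$bundle$drug))
  er <- expression_response_correlations(sim$bundle$expression, fv$response)
  planted <- sim$truth$genes[!is.na(sim$truth$genes$agent), ]
  rows <- dplyr::inner_join(er,
    dplyr::transmute(planted, gene, agent, transcript_id = paste0("TX_", gene, "_1")),
    by = c("gene", "agent", "transcript_id"))
  expect_equal(nrow(rows), nrow(planted))
  expect_true(all(abs(rows$coefficient) > 0.5))
  # a transcript equal to the response correlates at exactly 1
  ex2 <- list(
    values = matrix(fv$response[1, ], 1,
      dimnames = list("TXresp", colnames(fv$response))),
    tx_map = tibble::tibble(transcript_id = "TXresp", gene = "GX")
  )
  er2 <- expression_response_correlations(ex2, fv$response)
  expect_equal(er2$coefficient[er2$agent == rownames(fv$response)[1]], 1)
  # constant transcripts are logged, not emitted
  ex3 <- list(
    values = matrix(1, 1, ncol(fv$response),
      dimnames = list("TXflat", colnames(fv$response))),
    tx_map = tibble::tibble(transcript_id = "TXflat", gene = "GX")
  )
  er3 <- expression_response_correlations(ex3, fv$response)
  expect_equal(nrow(er3), 0L)
  expect_gt(nrow(attr(er3, "exclusions")), 0L)
})

test_that("regulatory pattern classification follows the three-leg rules", {
  leg <- function(coefficient, p_value) tibble::tibble(coefficient = coefficient, p_value = p_value)
  # repression chain: meth-expr strongly negative, expr-drug opposite to meth-drug
  expect_equal(
    classify_regulatory_pattern(leg(-0.65, 1e-8), leg(-0.84, 1e-10), leg(0.5, 2e-5)),
    "canonical_repression"
  )
  # positive coupling: all legs aligned positive
  expect_equal(
    classify_regulatory_pattern(leg(0.63, 1e-8), leg(0.68, 1e-9), leg(0.40, 9e-4)),
    "expression_coupled_positive"
  )
  expect_equal(
    classify_regulatory_pattern(leg(0.05, 0.6), leg(-0.08, 0.5), leg(0.02, 0.9)),
    "undetermined"
  )
  # strong legs whose sign pattern fits neither model
  expect_equal(
    classify_regulatory_pattern(leg(0.65, 1e-8), leg(-0.84, 1e-10), leg(0.5, 2e-5)),
    "inconsistent"
  )
  # relabeling resistance as sensitivity flips meth-drug and expr-drug together
  expect_equal(
    classify_regulatory_pattern(leg(0.65, 1e-8), leg(-0.84, 1e-10), leg(-0.5, 2e-5)),
    "canonical_repression"
  )
  # vectorized row-wise
  out <- classify_regulatory_pattern(
    leg(c(-0.65, 0.63), c(1e-8, 1e-8)),
    leg(c(-0.84, 0.68), c(1e-10, 1e-9)),
    leg(c(0.5, 0.40), c(2e-5, 9e-4))
  )
  expect_equal(out, c("canonical_repression", "expression_coupled_positive"))
})

test_that("linked reports classify planted archetypes correctly", {
  sim <- simulate_dataset(small_config(seed = 23))
  qc <- run_probe_qc(sim$bundle)
  idx <- build_region_index(sim$bundle$assignments, qc$retained_probes)
  reg <- average_region_betas(qc$beta, idx)
  fv <- filter_variable_agents(median_log_ic50(sim$bundle$drug))
  epi <- epigenome_wide_analysis(qc$beta, reg, fv$response)
  top <- dplyr::filter(epi$region_records, p_fdr < 0.15)
  me <- methylation_expression_correlations(
    reg$values[unique(top$feature_id), , drop = FALSE],
    sim$bundle$expression,
    dplyr::select(dplyr::filter(reg$keys, key %in% top$feature_id),
      feature_id = key, gene))
  er <- expression_response_correlations(sim$bundle$expression, fv$response)
  linked <- build_linked_reports(top, me, er)
  truth <- sim$truth
  planted_canonical <- dplyr::semi_join(
    linked,
    dplyr::filter(truth$planted_regions,
      gene %in% truth$genes$gene[truth$genes$archetype == "canonical_repressive"]),
    by = c("feature_id" = "key", "agent")
  )
  expect_gt(nrow(planted_canonical), 0L)
  expect_true(all(planted_canonical$pattern == "canonical_repression"))
  planted_positive <- dplyr::semi_join(
    linked,
    dplyr::filter(truth$planted_regions,
      gene %in% truth$genes$gene[truth$genes$archetype == "positive_coupled"]),
    by = c("feature_id" = "key", "agent")
  )
  expect_gt(nrow(planted_positive), 0L)
  expect_true(all(planted_positive$pattern == "expression_coupled_positive"))
})

test_that("copy-number screen separates cn-driven from cn-independent coupling", {
  sim <- simulate_dataset(small_config(seed = 24))
  qc <- run_probe_qc(sim$bundle)
  idx <- build_region_index(sim$bundle$assignments, qc$retained_probes)
  reg <- average_region_betas(qc$beta, idx)
  fv <- filter_variable_agents(median_log_ic50(sim$bundle$drug))
  gt <- sim$truth$genes
  cn_gene <- gt$gene[gt$archetype == "cn_driven"][1]
  pos_gene <- gt$gene[gt$archetype == "positive_coupled"][1]
  targets <- tibble::tibble(
    gene = c(cn_gene, pos_gene),
    feature_id = paste0(c(cn_gene, pos_gene), "|Body"),
    transcript_id = paste0("TX_", c(cn_gene, pos_gene), "_1"),
    agent = gt$agent[match(c(cn_gene, pos_gene), gt$gene)]
  )
  scr <- copy_number_screen(sim$bundle$cn, reg, sim$bundle$expression, fv$response, targets)
  cn_row <- scr[scr$gene == cn_gene, ]
  expect_gt(cn_row$rho_cn_meth, 0.4)
  expect_gt(cn_row$rho_cn_expr, 0.4)
  expect_false(cn_row$cn_unexplained)
  # positively coupled but copy-number-independent gene gets flagged
  expect_true(scr$cn_unexplained[scr$gene == pos_gene])
  # cn identical to expression correlates at exactly 1
  ex <- sim$bundle$expression
  cn2 <- matrix(ex$values[paste0("TX_", pos_gene, "_1"), ], 1,
    dimnames = list(pos_gene, colnames(ex$values)))
  scr2 <- copy_number_screen(cn2, reg, ex, fv$response, targets[2, ])
  expect_equal(scr2$rho_cn_expr, 1)
  # genes missing from the cn table are skipped and logged
  scr3 <- copy_number_screen(sim$bundle$cn[1, , drop = FALSE], reg, ex, fv$response, targets)
  expect_equal(nrow(attr(scr3, "skipped")), 2L)
})

test_that("UPGMA lineage clustering recovers planted clusters deterministically", {
  sim <- simulate_dataset(small_config(seed = 25))
  lc <- lineage_clustering(sim$bundle$expression, k = 2)
  truth <- sim$truth$lineage
  tab <- table(lc$assignments[truth$sample_id], truth$cluster)
  # planted labels recovered exactly, up to label permutation
  expect_equal(sum(diag(tab)) == sum(tab) || sum(tab) - sum(diag(tab)) == sum(tab), TRUE)
  agreement <- max(sum(diag(tab)), sum(tab) - sum(diag(tab)))
  expect_equal(agreement, nrow(truth))
  # sample relabeling only permutes assignments
  ex2 <- sim$bundle$expression
  perm <- rev(seq_len(ncol(ex2$values)))
  ex2$values <- ex2$values[, perm]
  lc2 <- lineage_clustering(ex2, k = 2)
  tab2 <- table(lc2$assignments[truth$sample_id], lc$assignments[truth$sample_id])
  expect_equal(max(sum(diag(tab2)), sum(tab2) - sum(diag(tab2))), nrow(truth))
  # duplicated samples merge first at height zero
  ex3 <- sim$bundle$expression
  ex3$values[, 2] <- ex3$values[, 1]
  lc3 <- lineage_clustering(ex3, k = 2)
  expect_equal(min(lc3$hclust$height), 0)
  expect_setequal(abs(lc3$hclust$merge[1, ]), c(1, 2))
  # missing markers are named in the error
  ex4 <- sim$bundle$expression
  keep <- ex4$tx_map$gene != "YAP1"
  ex4$values <- ex4$values[keep, ]
  ex4$tx_map <- ex4$tx_map[keep, ]
  expect_error(lineage_clustering(ex4), "YAP1", class = "methylscreen_validation_error")
})

test_that("average linkage differs from single linkage on a chain and matches hand heights", {
  # four points on a line at 0, 1, 3, 7
  ex <- list(
    values = matrix(rep(c(0, 1, 3, 7), each = 6), 6,
      dimnames = list(paste0("TX_", c("ASCL1", "ASCL2", "NEUROD1", "INSM1", "YAP1", "POU2F3"), "_1"),
        paste0("S", 1:4))) / sqrt(6),
    tx_map = tibble::tibble(
      transcript_id = paste0("TX_", c("ASCL1", "ASCL2", "NEUROD1", "INSM1", "YAP1", "POU2F3"), "_1"),
      gene = c("ASCL1", "ASCL2", "NEUROD1", "INSM1", "YAP1", "POU2F3")
    )
  )
  lc <- lineage_clustering(ex, k = 2)
  # hand-computed UPGMA heights: 1, then avg(2, 3) = 2.5, then avg(7, 6, 4) = 17/3
  expect_equal(sort(lc$hclust$height), c(1, 2.5, 17 / 3))
  single <- stats::hclust(stats::dist(t(lc$markers)), method = "single")
  expect_equal(sort(single$height), c(1, 2, 4))
  expect_false(isTRUE(all.equal(sort(lc$hclust$height), sort(single$height))))
})

test_that("marker correlations report both flavours and detect lineage-linked methylation", {
  sim <- simulate_dataset(small_config(seed = 26))
  ex <- sim$bundle$expression
  # a profile equal to ASCL1 expression correlates at exactly 1 with ASCL1
  ascl1 <- ex$values["TX_ASCL1_1", ]
  mc <- marker_correlations(ascl1, ex)
  self <- mc[mc$marker == "ASCL1", ]
  expect_equal(self$coefficient, c(1, 1))
  expect_setequal(self$method, c("spearman", "pearson"))
  # planted lineage-linked methylation tracks the cluster-defining markers
  qc <- run_probe_qc(sim$bundle)
  idx <- build_region_index(sim$bundle$assignments, qc$retained_probes)
  reg <- average_region_betas(qc$beta, idx)
  lin_gene <- sim$truth$genes$gene[sim$truth$genes$archetype == "lineage_linked"][1]
  prof <- reg$values[paste0(lin_gene, "|TSS200"), ]
  mc2 <- marker_correlations(prof, ex)
  sp <- mc2[mc2$method == "spearman", ]
  expect_true(any(sp$p_value < 1e-3 & abs(sp$coefficient) > 0.4))
})
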