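test_that("median log10(IC50) follows the replicate-median convention", {
  tbl <- tibble::tibble(
    agent = "A",
    cell_line = c("S1", "S2", "S2", "S2", "S3", "S3"),
    replicate = c(1L, 1L, 2L, 3L, 1L, 2L),
    ic50 = c(1e-6, 1e-7, 1e-6, 1e-4, 1e-7, 1e-5)
  )
  m <- median_log_ic50(tbl)
  expect_equal(m["A", "S1"], -6)            # single replicate of 1 uM
  expect_equal(m["A", "S2"], -6)            # odd count: middle of -7, -6, -4
  expect_equal(m["A", "S3"], -6)            # even count: mean of -7 and -5
  expect_error(median_log_ic50(dplyr::mutate(tbl, ic50 = -ic50)),
    class = "methylscreen_validation_error")
})

test_that("agent variability filter excludes constants and matches planted truth", {
  resp <- rbind(
    flat = rep(-5, 6),
    ok = c(-5, -6, -5, -6, -5, -6),
    gappy = c(-5, NA, NA, NA, NA, NA)
  )
  colnames(resp) <- paste0("S", 1:6)
  got <- filter_variable_agents(resp)
  expect_setequal(rownames(got$response), "ok")
  expect_setequal(got$excluded$agent, c("flat", "gappy"))
  sim <- simulate_dataset(small_config(seed = 12))
  fv <- filter_variable_agents(median_log_ic50(sim$bundle$drug))
  expect_setequal(fv$excluded$agent, sim$truth$agents$agent[sim$truth$agents$constant])
})

test_that("feature-response correlation emits defined records and logs exclusions", {
  resp <- matrix(c(1, 3, 2, 5, 4, 6), 1, dimnames = list("A", paste0("S", 1:6)))
  feats <- rbind(
    same = resp[1, ],
    const = rep(0.5, 6),
    other = 7 - resp[1, ]
  )
  colnames(feats) <- colnames(resp)
  rec <- correlate_features_with_response(feats, resp, "epigenome_probe")
  expect_equal(rec$coefficient[rec$feature_id == "same"], 1)
  expect_equal(rec$coefficient[rec$feature_id == "other"], -1)
  expect_false("const" %in% rec$feature_id)
  excl <- attr(rec, "exclusions")
  expect_equal(excl$feature_id, "const")
  expect_equal(excl$reason, "constant_ranks")
})

test_that("every emitted p_o is reproducible from its coefficient and n_used", {
  sim <- simulate_dataset(small_config(seed = 13))
  qc <- run_probe_qc(sim$bundle)
  fv <- filter_variable_agents(median_log_ic50(sim$bundle$drug))
  rec <- correlate_features_with_response(qc$beta, fv$response, "epigenome_probe")
  expect_equal(rec$p_o, spearman_p_from_rho(rec$coefficient, rec$n_used),
    tolerance = 1e-12)
})

test_that("epigenome-wide analysis applies the two-tier probe thresholds and one region family", {
  sim <- simulate_dataset(small_config(seed = 14))
  qc <- run_probe_qc(sim$bundle)
  idx <- build_region_index(sim$bundle$assignments, qc$retained_probes)
  reg <- average_region_betas(qc$beta, idx)
  fv <- filter_variable_agents(median_log_ic50(sim$bundle$drug))
  epi <- epigenome_wide_analysis(qc$beta, reg, fv$response)
  pr <- epi$probe_records
  # strict implies liberal, and no probe-level FDR column
  expect_true(all(!pr$passes_strict | pr$passes_liberal))
  expect_false("p_fdr" %in% names(pr))
  # strict records satisfy the critical-coefficient geometry
  strict <- pr[pr$passes_strict, ]
  if (nrow(strict)) {
    crit <- critical_rho(strict$n_used[1], epi$thresholds$strict)
    expect_true(all(abs(strict$coefficient) >= crit))
  }
  rr <- epi$region_records
  expect_true(all(rr$p_fdr >= rr$p_o))
  expect_equal(attr(bh_adjust(rr$p_o), "family_size"), nrow(rr))
  # shuffling record order never changes any adjusted p-value
  perm <- sample(nrow(rr))
  shuffled <- bh_adjust(rr$p_o[perm])$adjusted
  expect_equal(shuffled[order(perm)], rr$p_fdr)
  expect_error(
    epigenome_wide_analysis(qc$beta, reg, fv$response, strict = 1e-6, liberal = 1e-7),
    class = "methylscreen_validation_error"
  )
})

test_that("Spearman records are invariant to the log base of the response", {
  sim <- simulate_dataset(small_config(seed = 15))
  qc <- run_probe_qc(sim$bundle)
  fv <- filter_variable_agents(median_log_ic50(sim$bundle$drug))
  r10 <- correlate_features_with_response(qc$beta[1:30, ], fv$response, "epigenome_probe")
  rln <- correlate_features_with_response(qc$beta[1:30, ], fv$response * log(10), "epigenome_probe")
  expect_equal(r10$coefficient, rln$coefficient)
  expect_equal(r10$p_o, rln$p_o)
})

test_that("candidate families are independent of the epigenome-wide family", {
  sim <- simulate_dataset(small_config(seed = 16))
  qc <- run_probe_qc(sim$bundle)
  idx <- build_region_index(sim$bundle$assignments, qc$retained_probes)
  reg <- average_region_betas(qc$beta, idx)
  fv <- filter_variable_agents(median_log_ic50(sim$bundle$drug))
  cand <- candidate_analysis(
    qc$beta, reg, fv$response,
    sim$bundle$candidates$genes, sim$bundle$candidates$agents,
    sim$bundle$assignments
  )
  # family size bookkeeping: probes x agents when no test is undefined
  n_probes <- length(unique(cand$probe_records$feature_id))
  n_agents <- length(unique(cand$probe_records$agent))
  n_excluded <- nrow(cand$exclusions$probe)
  expect_equal(nrow(cand$probe_records) + n_excluded, n_probes * n_agents)
  expect_equal(cand$families$candidate_probe, nrow(cand$probe_records))
  # the same test carries a different p_FDR under the candidate family
  epi <- epigenome_wide_analysis(qc$beta, reg, fv$response)
  joint <- dplyr::inner_join(
    dplyr::select(cand$region_records, feature_id, agent, p_o, p_fdr),
    dplyr::select(epi$region_records, feature_id, agent, p_o, p_fdr),
    by = c("feature_id", "agent"), suffix = c("_cand", "_epi")
  )
  expect_equal(joint$p_o_cand, joint$p_o_epi)
  expect_gt(sum(joint$p_fdr_cand != joint$p_fdr_epi), 0)
  expect_error(
    candidate_analysis(qc$beta, reg, fv$response, "NOSUCHGENE",
      sim$bundle$candidates$agents, sim$bundle$assignments),
    class = "methylscreen_validation_error"
  )
})

test_that("singleton-probe regions reproduce the probe-level coefficient exactly", {
  sim <- simulate_dataset(small_config(seed = 17))
  qc <- run_probe_qc(sim$bundle)
  idx <- build_region_index(sim$bundle$assignments, qc$retained_probes)
  reg <- average_region_betas(qc$beta, idx)
  fv <- filter_variable_agents(median_log_ic50(sim$bundle$drug))
  singles <- reg$keys$key[reg$keys$n_probes == 1L]
  expect_gt(length(singles), 0L)
  key <- singles[1]
  probe <- idx$probe_id[idx$key == key]
  rr <- correlate_features_with_response(
    reg$values[key, , drop = FALSE], fv$response, "epigenome_region")
  pr <- correlate_features_with_response(
    qc$beta[probe, , drop = FALSE], fv$response, "epigenome_probe")
  expect_equal(rr$coefficient[order(rr$agent)], pr$coefficient[order(pr$agent)])
  expect_equal(rr$p_o[order(rr$agent)], pr$p_o[order(pr$agent)])
})

test_that("gene-level summary picks best probes and expression-coupled transcripts", {
  sim <- simulate_dataset(small_config(seed = 18))
  qc <- run_probe_qc(sim$bundle)
  fv <- filter_variable_agents(median_log_ic50(sim$bundle$drug))
  probe_info <- dplyr::select(sim$bundle$assignments,
    feature_id = probe_id, gene, region)
  rec <- correlate_features_with_response(qc$beta, fv$response, "epigenome_probe",
    feature_info = probe_info)
  # use a permissive threshold so the small fixture yields summary rows
  summ <- gene_level_summary(rec, qc$beta, sim$bundle$expression, fv$response,
    liberal = 1e-6)
  expect_gt(nrow(summ), 0L)
  # planted genes select their coupled transcript (TX_<gene>_1), not the decoy
  planted <- sim$truth$genes$gene[sim$truth$genes$archetype == "canonical_repressive"]
  hits <- summ[summ$gene %in% planted, ]
  expect_gt(nrow(hits), 0L)
  expect_true(all(hits$best_transcript == paste0("TX_", hits$gene, "_1")))
  # methylation-expression leg is strongly negative for repressive genes
  expect_true(all(hits$rho_meth_expr < -0.5))
  # best probe is the group's smallest p_o
  for (i in seq_len(min(3, nrow(summ)))) {
    grp <- rec[rec$gene == summ$gene[i] & rec$agent == summ$agent[i] & rec$p_o < 1e-6, ]
    expect_equal(summ$p_o[i], min(grp$p_o))
  }
})
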