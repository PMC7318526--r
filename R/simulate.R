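#' Simulation configuration
#'
#' Assembles and validates the configuration of the synthetic-data generator.
#' Defaults emulate the structure of a 66-cell-line methylation /
#' expression / drug-response panel at desk scale: ~4,000 EPIC-style probes
#' over 200 genes with the six region classes, 30 agents with replicate
#' IC50s, planted regulatory archetypes, detection failures and SNP-flagged
#' probes.
#'
#' Archetypes plant a recoverable causal chain
#' (methylation -> expression -> response) so the three-way integration can
#' be validated end-to-end:
#' * `canonical_repressive`: upstream-region methylation represses a
#'   transcript whose expression drives response to one agent (net
#'   methylation-sensitivity association);
#' * `positive_coupled`: gene-body methylation and expression share a latent
#'   factor positively, expression drives response (net resistance
#'   association);
#' * `cn_driven`: a copy-number gain in a sample subset raises body
#'   methylation measure and expression jointly;
#' * `lineage_linked`: two sample clusters differ in the six lineage markers
#'   and in a planted upstream-methylation offset (no drug coupling);
#' * remaining genes are null.
#'
#' @param n_samples Number of cell lines (default 66).
#' @param n_genes Number of annotated genes (default 200).
#' @param probes_per_class Named integer vector of probes per region class
#'   per gene.
#' @param n_intergenic Number of intergenic probes (default 200).
#' @param multi_gene_rate Fraction of gene probes additionally assigned to a
#'   second gene/region (default 0.02).
#' @param snp_rate Per-probe SNP-mask flag rate (default 0.01).
#' @param n_bad_probes Probes planted with failing median detection p
#'   (default 5).
#' @param detection_fail_rate Per-cell detection-failure rate (default
#'   0.002).
#' @param n_agents,n_constant_agents,n_replicates Drug panel shape (default
#'   30 agents of which 2 constant, 3 replicates).
#' @param archetypes Named counts for `canonical_repressive`,
#'   `positive_coupled`, `cn_driven`, `lineage_linked`.
#' @param target_rho Planted end-to-end |Spearman rho| between region
#'   methylation and response for canonical/positive archetypes (default
#'   0.75).
#' @param meth_expr_pearson Latent Pearson magnitude of the
#'   methylation-expression leg (default 0.9).
#' @param probe_noise_sd Per-probe noise on the logit scale (default 0.25).
#' @param latent_sd Between-sample sd of region latents (default 1).
#' @param lineage_offset Methylation logit offset between lineage clusters
#'   (default 1.5).
#' @param marker_separation,marker_noise_sd Lineage-marker expression
#'   separation and noise (log2 units; defaults 2 and 0.6).
#' @param cn_amp_fraction,cn_gain,cn_noise_sd Copy-number archetype: fraction
#'   of amplified samples, log2 gain, latent noise.
#' @param response_mean,response_sd Location/scale of log10(IC50) (molar;
#'   defaults -6 and 0.6).
#' @param replicate_sd Replicate noise in log10 units (default 0.05).
#' @param expression_base,expression_scale Location/scale of log2 expression.
#' @param seed Integer seed; identical seeds give identical bundles.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 66L,
                       n_genes = 200L,
                       probes_per_class = c(
                         TSS1500 = 3L, TSS200 = 3L, `5UTR` = 2L,
                         `1stExon` = 2L, Body = 6L, `3UTR` = 2L
                       ),
                       n_intergenic = 200L,
                       multi_gene_rate = 0.02,
                       snp_rate = 0.01,
                       n_bad_probes = 5L,
                       detection_fail_rate = 0.002,
                       n_agents = 30L,
                       n_constant_agents = 2L,
                       n_replicates = 3L,
                       archetypes = c(
                         canonical_repressive = 14L, positive_coupled = 7L,
                         cn_driven = 4L, lineage_linked = 5L
                       ),
                       target_rho = 0.75,
                       meth_expr_pearson = 0.9,
                       probe_noise_sd = 0.25,
                       latent_sd = 1,
                       lineage_offset = 1.5,
                       marker_separation = 2,
                       marker_noise_sd = 0.6,
                       cn_amp_fraction = 0.25,
                       cn_gain = 1,
                       cn_noise_sd = 0.3,
                       response_mean = -6,
                       response_sd = 0.6,
                       replicate_sd = 0.05,
                       expression_base = 7,
                       expression_scale = 1.2,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (!setequal(names(probes_per_class), REGION_CLASSES)) {
    abort_validation("`probes_per_class` must name exactly the six region classes.")
  }
  if (any(probes_per_class < 1L)) {
    abort_validation("Every region class needs at least one probe per gene (planted effects need probes).")
  }
  rates <- c(multi_gene_rate, snp_rate, detection_fail_rate, cn_amp_fraction)
  if (any(rates < 0 | rates > 1)) abort_validation("Rates must be in [0, 1].")
  if (sum(archetypes) > n_genes) {
    abort_validation("Archetype counts exceed `n_genes`.")
  }
  n_effect <- sum(archetypes[c("canonical_repressive", "positive_coupled", "cn_driven")])
  if (n_effect > n_agents - n_constant_agents) {
    abort_validation("Need at least one variable agent per drug-coupled effect gene.")
  }
  if (target_rho <= 0 || target_rho >= 1) abort_validation("`target_rho` must be in (0, 1).")
  structure(cfg, class = "sim_config")
}

#' Simulate an EPIC-style probe manifest
#'
#' Generates probe annotations for `n_genes` genes laid along a
#' pseudo-chromosome, with the configured number of probes per region class
#' and positions ordered TSS1500 < TSS200 < 5UTR < 1stExon < Body < 3UTR
#' within each gene, a configured fraction of probes additionally assigned
#' to the following gene, intergenic probes, and SNP-mask flags planted at
#' `snp_rate`.
#'
#' @param config A `sim_config`.
#' @return A manifest tibble in the [read_probe_manifest()] dialect.
#' @export
simulate_manifest <- function(config = sim_config()) {
  withr::with_seed(config$seed, simulate_manifest_impl(config))
}

simulate_manifest_impl <- function(config) {
  genes <- sprintf("G%03d", seq_len(config$n_genes))
  ppc <- config$probes_per_class[REGION_CLASSES]
  per_gene <- sum(ppc)
  gene_idx <- rep(seq_len(config$n_genes), each = per_gene)
  region <- rep(rep(REGION_CLASSES, times = ppc), times = config$n_genes)
  offset <- rep(seq_len(per_gene) * 100L, times = config$n_genes)
  gene_start <- (gene_idx - 1L) * 10000L + 1L
  n_gene_probes <- length(gene_idx)
  n_total <- n_gene_probes + config$n_intergenic
  probe_id <- sprintf("cg%06d", seq_len(n_total))
  manifest <- tibble::tibble(
    probe_id = probe_id,
    chromosome = "chr1",
    position = c(gene_start + offset,
      config$n_genes * 10000L + seq_len(config$n_intergenic) * 500L),
    cytoband = paste0("1q", c((gene_idx - 1L) %/% 10L + 1L,
      rep((config$n_genes - 1L) %/% 10L + 2L, config$n_intergenic))),
    gene_names = c(genes[gene_idx], rep("", config$n_intergenic)),
    region_classes = c(region, rep("", config$n_intergenic)),
    snp_masked = stats::runif(n_total) < config$snp_rate
  )
  # secondary assignments: a fraction of gene probes also annotated to the
  # next gene, in a random region class (mirrors multi-gene manifest rows)
  extra <- which(stats::runif(n_gene_probes) < config$multi_gene_rate)
  if (length(extra)) {
    second_gene <- genes[gene_idx[extra] %% config$n_genes + 1L]
    second_region <- sample(REGION_CLASSES, length(extra), replace = TRUE)
    manifest$gene_names[extra] <- paste(manifest$gene_names[extra], second_gene, sep = ";")
    manifest$region_classes[extra] <- paste(manifest$region_classes[extra], second_region, sep = ";")
  }
  manifest
}

#' Simulate a complete analysis bundle with known ground truth
#'
#' Draws per-gene region latents on the logit scale, maps member-probe
#' beta-values through the logistic function (probe noise added on the logit
#' scale, so values stay inside (0, 1)), couples expression and replicate
#' drug response through the archetype chains described in [sim_config()],
#' plants detection failures, failing-median probes, SNP flags, constant
#' agents and lineage clusters, and returns both the loadable bundle and the
#' truth tables needed for recovery scoring.
#'
#' @param config A `sim_config`.
#' @return A `methyl_sim` list: `bundle` (a `methyl_bundle`) and `truth`
#'   (gene/region/probe/agent/QC/lineage truth tables).
#' @export
simulate_dataset <- function(config = sim_config()) {
  withr::with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(config) {
  ns <- config$n_samples
  samples <- sprintf("S%03d", seq_len(ns))
  genes <- sprintf("G%03d", seq_len(config$n_genes))
  manifest <- simulate_manifest_impl(config)
  assignments <- probe_assignments(manifest)

  # archetype assignment (leading blocks; remaining genes are null)
  arch <- rep("null", config$n_genes)
  pos <- 1L
  for (a in names(config$archetypes)) {
    k <- config$archetypes[[a]]
    if (k > 0L) arch[pos:(pos + k - 1L)] <- a
    pos <- pos + k
  }

  # lineage clusters
  n1 <- ceiling(0.55 * ns)
  cluster <- sample(c(rep(1L, n1), rep(2L, ns - n1)))

  # agents: constant agents last; drug-coupled genes take the leading agents
  agents <- sprintf("AGT%02d", seq_len(config$n_agents))
  constant_agents <- utils::tail(agents, config$n_constant_agents)
  variable_agents <- setdiff(agents, constant_agents)
  coupled <- which(arch %in% c("canonical_repressive", "positive_coupled", "cn_driven"))
  target_agent <- rep(NA_character_, config$n_genes)
  target_agent[coupled] <- variable_agents[seq_along(coupled)]

  w_total <- 2 * sin(pi * config$target_rho / 6)  # Spearman -> Pearson, bivariate normal
  w_me <- config$meth_expr_pearson
  w_er <- w_total / w_me
  stopifnot(w_er < 1)

  znorm <- function(v) (v - mean(v)) / stats::sd(v)
  mix <- function(z, w) w * znorm(z) + sqrt(1 - w^2) * stats::rnorm(length(z))

  # per-gene latents: upstream (TSS1500/TSS200/5UTR/1stExon), body, 3'UTR
  upstream <- matrix(NA_real_, config$n_genes, ns, dimnames = list(genes, samples))
  body <- matrix(NA_real_, config$n_genes, ns, dimnames = list(genes, samples))
  utr3 <- matrix(NA_real_, config$n_genes, ns, dimnames = list(genes, samples))
  expr_z <- matrix(NA_real_, config$n_genes, ns, dimnames = list(genes, samples))
  amp_mat <- matrix(0, config$n_genes, ns, dimnames = list(genes, samples))
  mu <- stats::rnorm(config$n_genes, 0, 1)

  for (g in seq_len(config$n_genes)) {
    base_up <- stats::rnorm(ns, 0, config$latent_sd)
    base_body <- stats::rnorm(ns, 0, config$latent_sd)
    utr3[g, ] <- mu[g] + stats::rnorm(ns, 0, config$latent_sd)
    switch(arch[g],
      canonical_repressive = {
        upstream[g, ] <- mu[g] + base_up
        body[g, ] <- mu[g] + base_body
        expr_z[g, ] <- mix(-base_up, w_me)
      },
      positive_coupled = {
        upstream[g, ] <- mu[g] + base_up
        body[g, ] <- mu[g] + base_body
        expr_z[g, ] <- mix(base_body, w_me)
      },
      cn_driven = {
        # per-gene amplification event shared by methylation measure and
        # expression (independent across cn-driven genes)
        amp_mat[g, ] <- (stats::runif(ns) < config$cn_amp_fraction) * config$cn_gain
        cn_z <- znorm(amp_mat[g, ] + stats::rnorm(ns, 0, config$cn_noise_sd))
        upstream[g, ] <- mu[g] + base_up
        body[g, ] <- mu[g] + config$latent_sd * mix(cn_z, w_me)
        expr_z[g, ] <- mix(cn_z, w_me)
      },
      lineage_linked = {
        upstream[g, ] <- mu[g] + base_up + config$lineage_offset * (cluster == 2L)
        body[g, ] <- mu[g] + base_body
        expr_z[g, ] <- stats::rnorm(ns)
      },
      {
        upstream[g, ] <- mu[g] + base_up
        body[g, ] <- mu[g] + base_body
        expr_z[g, ] <- stats::rnorm(ns)
      }
    )
  }

  # probe betas: logistic of (region latent + probe noise); probes with a
  # secondary gene assignment are generated from their primary gene's region
  prim_gene <- sub(";.*$", "", manifest$gene_names)
  prim_region <- sub(";.*$", "", manifest$region_classes)
  beta <- matrix(NA_real_, nrow(manifest), ns,
    dimnames = list(manifest$probe_id, samples))
  for (i in seq_len(nrow(manifest))) {
    if (manifest$gene_names[i] == "") {
      lat <- stats::rnorm(1, 0, 1) + stats::rnorm(ns, 0, config$latent_sd)
    } else {
      g <- match(prim_gene[i], genes)
      lat <- switch(prim_region[i],
        Body = body[g, ],
        `3UTR` = utr3[g, ],
        upstream[g, ]
      )
    }
    beta[i, ] <- stats::plogis(lat + stats::rnorm(ns, 0, config$probe_noise_sd))
  }

  # expression: two transcripts per gene (coupled + decoy) and six lineage
  # markers split across the two clusters
  marker_high <- c("ASCL1", "ASCL2", "NEUROD1", "INSM1")
  marker_low <- c("YAP1", "POU2F3")
  tx_map <- tibble::tibble(
    transcript_id = c(
      paste0("TX_", rep(genes, each = 2L), "_", rep(1:2, config$n_genes)),
      paste0("TX_", c(marker_high, marker_low), "_1")
    ),
    gene = c(rep(genes, each = 2L), marker_high, marker_low)
  )
  expr <- matrix(NA_real_, nrow(tx_map), ns,
    dimnames = list(tx_map$transcript_id, samples))
  for (g in seq_len(config$n_genes)) {
    expr[2L * g - 1L, ] <- config$expression_base + config$expression_scale * expr_z[g, ]
    expr[2L * g, ] <- config$expression_base + config$expression_scale * stats::rnorm(ns)
  }
  for (m in marker_high) {
    expr[paste0("TX_", m, "_1"), ] <- config$expression_base +
      config$marker_separation * (cluster == 1L) +
      stats::rnorm(ns, 0, config$marker_noise_sd)
  }
  for (m in marker_low) {
    expr[paste0("TX_", m, "_1"), ] <- config$expression_base +
      config$marker_separation * (cluster == 2L) +
      stats::rnorm(ns, 0, config$marker_noise_sd)
  }

  # response: log10(IC50) per agent; coupled agents follow their driver
  # transcript, constant agents are flat
  resp_log10 <- matrix(NA_real_, config$n_agents, ns,
    dimnames = list(agents, samples))
  for (a in seq_len(config$n_agents)) {
    ag <- agents[a]
    if (ag %in% constant_agents) {
      resp_log10[a, ] <- config$response_mean
    } else {
      g <- match(ag, target_agent)
      z <- if (is.na(g)) stats::rnorm(ns) else mix(expr_z[g, ], w_er)
      resp_log10[a, ] <- config$response_mean + config$response_sd * znorm(z)
    }
  }
  replicates <- tidyr::expand_grid(
    agent = agents, cell_line = samples, replicate = seq_len(config$n_replicates)
  )
  rep_noise <- ifelse(replicates$agent %in% constant_agents, 0,
    stats::rnorm(nrow(replicates), 0, config$replicate_sd))
  replicates$ic50 <- 10^(resp_log10[cbind(
    match(replicates$agent, agents), match(replicates$cell_line, samples)
  )] + rep_noise)

  # detection p-values: clean base, planted bad-median probes, planted
  # per-cell failures on otherwise clean, unflagged probes
  detp <- matrix(10^stats::runif(length(beta), -8, -6.2),
    nrow(beta), ncol(beta), dimnames = dimnames(beta))
  eligible <- manifest$probe_id[!manifest$snp_masked]
  bad_probes <- sample(eligible, config$n_bad_probes)
  detp[bad_probes, ] <- 10^stats::runif(config$n_bad_probes * ns, -4, -1)
  clean_probes <- setdiff(eligible, bad_probes)
  cell_grid <- expand.grid(probe = clean_probes, sample = samples,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fail_idx <- which(stats::runif(nrow(cell_grid)) < config$detection_fail_rate)
  failed_cells <- tibble::as_tibble(cell_grid[fail_idx, ]) %>%
    dplyr::rename(probe_id = "probe") %>%
    dplyr::arrange(.data$probe_id, .data$sample)
  detp[cbind(
    match(failed_cells$probe_id, rownames(detp)),
    match(failed_cells$sample, colnames(detp))
  )] <- 10^stats::runif(nrow(failed_cells), -2.5, -0.3)

  # truth tables
  upstream_regions <- c("TSS1500", "TSS200", "5UTR", "1stExon")
  gene_truth <- tibble::tibble(
    gene = genes, archetype = arch, agent = target_agent
  )
  planted_regions <- dplyr::bind_rows(
    tidyr::expand_grid(
      gene = genes[arch == "canonical_repressive"],
      region = upstream_regions
    ),
    tibble::tibble(gene = genes[arch == "positive_coupled"], region = "Body"),
    tibble::tibble(gene = genes[arch == "cn_driven"], region = "Body")
  ) %>%
    dplyr::left_join(gene_truth[, c("gene", "agent")], by = "gene") %>%
    dplyr::mutate(key = paste(.data$gene, .data$region, sep = "|"))
  planted_probes <- assignments %>%
    dplyr::semi_join(planted_regions, by = c("gene", "region")) %>%
    dplyr::left_join(gene_truth[, c("gene", "agent")], by = "gene") %>%
    dplyr::distinct(.data$probe_id, .data$agent)

  # copy number: mild noise everywhere, planted gains for cn-driven genes
  cn <- matrix(stats::rnorm(config$n_genes * ns, 0, 0.15), config$n_genes, ns,
    dimnames = list(genes, samples)) + amp_mat

  candidates <- list(
    genes = sort(c(
      genes[arch != "null"],
      utils::head(genes[arch == "null"], 20L)
    )),
    agents = sort(unique(c(
      stats::na.omit(target_agent),
      utils::head(setdiff(variable_agents, target_agent), 2L)
    )))
  )

  bundle <- new_methyl_bundle(
    beta = beta, detp = detp, manifest = manifest,
    drug = replicates, expression = list(values = expr, tx_map = tx_map),
    cn = cn, candidates = candidates
  )
  bundle$samples_report <- sample_report(bundle)
  truth <- list(
    genes = gene_truth,
    planted_regions = planted_regions,
    planted_probes = planted_probes,
    qc = list(
      failed_cells = failed_cells,
      bad_probes = sort(bad_probes),
      snp_probes = manifest$probe_id[manifest$snp_masked]
    ),
    agents = tibble::tibble(
      agent = agents,
      constant = agents %in% constant_agents,
      target_gene = genes[match(agents, target_agent)]
    ),
    lineage = tibble::tibble(sample_id = samples, cluster = cluster),
    config = config
  )
  structure(list(bundle = bundle, truth = truth), class = "methyl_sim")
}

#' @export
print.methyl_sim <- function(x, ...) {
  cat("<methyl_sim>\n")
  print(x$bundle)
  cat("  archetypes: ")
  print(table(x$truth$genes$archetype))
  invisible(x)
}

#' Score recovery of planted effects
#'
#' Compares association records against the generator's truth tables at a
#' significance tier. A call is a record passing the tier; the true-positive
#' rate is computed over planted (feature, agent) pairs and the false
#' discovery proportion over calls.
#'
#' @param records Association record tibble (probe- or region-level).
#' @param truth Truth list from [simulate_dataset()].
#' @param tier `"strict"` / `"liberal"` (probe threshold flags) or a numeric
#'   FDR cutoff applied to `p_fdr`.
#' @param level `"region"` or `"probe"`: which planted set to score against.
#' @return A one-row tibble with `n_planted`, `n_calls`, `n_true_calls`,
#'   `tpr`, `fdp` plus a `by_archetype` attribute with the per-archetype
#'   breakdown.
#' @export
evaluate_recovery <- function(records, truth, tier = 0.1,
                              level = c("region", "probe")) {
  level <- match.arg(level)
  planted <- if (level == "region") {
    truth$planted_regions %>%
      dplyr::transmute(feature_id = .data$key, agent = .data$agent, gene = .data$gene)
  } else {
    truth$planted_probes %>%
      dplyr::transmute(feature_id = .data$probe_id, agent = .data$agent)
  }
  bad <- setdiff(planted$agent, c(records$agent, truth$agents$agent))
  if (length(bad)) {
    abort_validation("Truth and records do not come from the same bundle.")
  }
  calls <- if (identical(tier, "strict")) {
    dplyr::filter(records, .data$passes_strict)
  } else if (identical(tier, "liberal")) {
    dplyr::filter(records, .data$passes_liberal)
  } else {
    dplyr::filter(records, .data$p_fdr < tier)
  }
  hit <- dplyr::semi_join(planted, calls, by = c("feature_id", "agent"))
  false_calls <- dplyr::anti_join(calls, planted, by = c("feature_id", "agent"))
  out <- tibble::tibble(
    n_planted = nrow(planted),
    n_calls = nrow(calls),
    n_true_calls = nrow(hit),
    tpr = nrow(hit) / nrow(planted),
    fdp = if (nrow(calls) == 0L) NA_real_ else nrow(false_calls) / nrow(calls)
  )
  if (level == "region") {
    by_arch <- planted %>%
      dplyr::left_join(truth$genes[, c("gene", "archetype")], by = "gene") %>%
      dplyr::mutate(hit = paste(.data$feature_id, .data$agent) %in%
        paste(hit$feature_id, hit$agent)) %>%
      dplyr::group_by(.data$archetype) %>%
      dplyr::summarise(n_planted = dplyr::n(), tpr = mean(.data$hit), .groups = "drop")
    attr(out, "by_archetype") <- by_arch
  }
  out
}
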