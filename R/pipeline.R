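#' Run the full association pipeline
#'
#' Executes load -> QC -> region aggregation -> response preparation ->
#' epigenome-wide and candidate association -> expression/response
#' integration -> lineage clustering, writing every artifact into `out_dir`
#' and returning a manifest of the written files with content hashes.
#' Identical inputs and configuration give byte-identical outputs.
#'
#' Output files (all TSV/JSON/newick text): `qc_report.json`,
#' `probe_associations.tsv`, `region_associations.tsv`, candidate analogues
#' when a candidate spec is present, `gene_summary.tsv`,
#' `linked_reports.tsv`, `overlap_genes.tsv`, `overlap_agents.tsv`,
#' `lineage_clusters.tsv`, `lineage_dendrogram.nwk`, `excluded_agents.tsv`
#' and `run_manifest.json`. Result TSVs carry `#` provenance comment lines
#' echoing the thresholds.
#'
#' @param bundle A `methyl_bundle` (from [load_dataset()] or
#'   [simulate_dataset()]`$bundle`), or a path list / YAML path accepted by
#'   [load_dataset()].
#' @param out_dir Output directory (created if needed).
#' @param strict,liberal Fixed probe thresholds (defaults `9.42e-8`,
#'   `5e-7`).
#' @param fdr_tiers Region/candidate FDR tiers, default `c(0.05, 0.1,
#'   0.15)`.
#' @param overlap_tier FDR tier used for the gene/agent overlap summary,
#'   default 0.1.
#' @param value_threshold,median_threshold QC thresholds, see
#'   [run_probe_qc()].
#' @param min_distinct,min_range Agent-variability filter, see
#'   [filter_variable_agents()].
#' @param sig_alpha,min_abs Regulatory-pattern thresholds, see
#'   [classify_regulatory_pattern()].
#' @param lineage_k Cluster count for the lineage cut, default 2.
#' @return A `pipeline_result` list: `manifest` (tibble `file`, `md5`),
#'   `qc_report`, `epigenome` and `candidate` (`methyl_assoc`), `summary`
#'   tibble, `lineage` (`lineage_clust` or `NULL`), returned invisibly.
#' @export
run_pipeline <- function(bundle, out_dir,
                         strict = 9.42e-8, liberal = 5e-7,
                         fdr_tiers = c(0.05, 0.1, 0.15),
                         overlap_tier = 0.1,
                         value_threshold = 1e-3, median_threshold = 1e-6,
                         min_distinct = 2L, min_range = 0,
                         sig_alpha = 0.05, min_abs = 0.3,
                         lineage_k = 2L) {
  if (!inherits(bundle, "methyl_bundle")) {
    bundle <- load_dataset(bundle)
  }
  if (strict >= liberal) abort_validation("`strict` must be smaller than `liberal`.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- c(
    sprintf("strict_threshold: %g", strict),
    sprintf("liberal_threshold: %g", liberal),
    sprintf("fdr_tiers: %s", paste(fdr_tiers, collapse = ",")),
    sprintf("detection_value_threshold: %g", value_threshold),
    sprintf("detection_median_threshold: %g", median_threshold)
  )

  qc <- run_probe_qc(bundle, value_threshold, median_threshold)
  write_qc_report(qc$report, file.path(out_dir, "qc_report.json"))

  index <- build_region_index(bundle$assignments, qc$retained_probes)
  regions <- average_region_betas(qc$beta, index)
  write_region_matrix(regions, file.path(out_dir, "region_methylation.tsv"))

  response_all <- median_log_ic50(bundle$drug)
  filt <- filter_variable_agents(response_all, min_distinct, min_range)
  response <- filt$response
  if (nrow(response) == 0L) {
    rlang::abort("No agent shows variable response; all association tests are undefined.",
      class = "methylscreen_degenerate_error")
  }
  readr::write_tsv(filt$excluded, file.path(out_dir, "excluded_agents.tsv"), progress = FALSE)

  probe_info <- bundle$assignments %>%
    dplyr::select(feature_id = "probe_id", "gene", "region")
  epi <- epigenome_wide_analysis(qc$beta, regions, response,
    strict = strict, liberal = liberal, fdr_tiers = fdr_tiers,
    probe_info = probe_info
  )
  write_results(epi$probe_records, file.path(out_dir, "probe_associations.tsv"), comments = prov)
  write_results(epi$region_records, file.path(out_dir, "region_associations.tsv"), comments = prov)

  cand <- NULL
  if (!is.null(bundle$candidates) &&
      length(bundle$candidates$genes) && length(bundle$candidates$agents)) {
    cand <- candidate_analysis(
      qc$beta, regions, response,
      bundle$candidates$genes, bundle$candidates$agents, bundle$assignments,
      fdr_tiers = fdr_tiers
    )
    write_results(cand$probe_records,
      file.path(out_dir, "candidate_probe_associations.tsv"), comments = prov)
    write_results(cand$region_records,
      file.path(out_dir, "candidate_region_associations.tsv"), comments = prov)
  }

  summary_tbl <- gene_level_summary(
    epi$probe_records, qc$beta, bundle$expression, response, liberal = liberal
  )
  readr::write_tsv(summary_tbl, file.path(out_dir, "gene_summary.tsv"), progress = FALSE)

  # integration over regions with an FDR-tier hit (plus all candidate hits)
  top_regions <- epi$region_records %>%
    dplyr::filter(.data$p_fdr < max(fdr_tiers))
  linked <- tibble::tibble()
  if (nrow(top_regions)) {
    feature_genes <- regions$keys %>%
      dplyr::filter(.data$key %in% top_regions$feature_id) %>%
      dplyr::select(feature_id = "key", "gene")
    me <- methylation_expression_correlations(
      regions$values[unique(top_regions$feature_id), , drop = FALSE],
      bundle$expression, feature_genes
    )
    er <- expression_response_correlations(bundle$expression, response)
    linked <- build_linked_reports(top_regions, me, er,
      sig_alpha = sig_alpha, min_abs = min_abs)
  }
  readr::write_tsv(linked, file.path(out_dir, "linked_reports.tsv"), progress = FALSE)

  ov <- overlap_summary(epi$region_records, tier = overlap_tier)
  readr::write_tsv(ov$genes, file.path(out_dir, "overlap_genes.tsv"), progress = FALSE)
  readr::write_tsv(ov$agents, file.path(out_dir, "overlap_agents.tsv"), progress = FALSE)

  lineage <- NULL
  if (all(LINEAGE_MARKERS %in% bundle$expression$tx_map$gene)) {
    lineage <- lineage_clustering(bundle$expression, k = lineage_k)
    readr::write_tsv(tidy(lineage), file.path(out_dir, "lineage_clusters.tsv"), progress = FALSE)
    if (requireNamespace("ape", quietly = TRUE)) {
      write_newick(lineage, file.path(out_dir, "lineage_dendrogram.nwk"))
    }
  }

  files <- sort(list.files(out_dir, full.names = FALSE))
  files <- setdiff(files, "run_manifest.json")
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)

  invisible(structure(
    list(
      manifest = manifest, qc_report = qc$report, epigenome = epi,
      candidate = cand, summary = summary_tbl, lineage = lineage,
      out_dir = out_dir
    ),
    class = "pipeline_result"
  ))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d artifacts in %s\n", nrow(x$manifest), x$out_dir))
  print(x$qc_report)
  print(x$epigenome)
  invisible(x)
}

#' Gene/agent overlap summary at a significance tier
#'
#' The bipartite structure behind a Venn-style figure: genes associated with
#' two or more agents and agents associated with two or more genes at the
#' requested tier, as sorted adjacency lists.
#'
#' @param records Association records carrying `gene`, `agent` and either
#'   `p_fdr` or threshold flags.
#' @param tier Numeric FDR cutoff (applied to `p_fdr`) or `"strict"` /
#'   `"liberal"`.
#' @return List of two tibbles: `genes` (`gene`, `n_agents`, `agents`) and
#'   `agents` (`agent`, `n_genes`, `genes`), adjacency lists joined with
#'   `";"`.
#' @export
overlap_summary <- function(records, tier = 0.1) {
  calls <- if (identical(tier, "strict")) {
    dplyr::filter(records, .data$passes_strict)
  } else if (identical(tier, "liberal")) {
    dplyr::filter(records, .data$passes_liberal)
  } else {
    dplyr::filter(records, .data$p_fdr < tier)
  }
  calls <- dplyr::distinct(calls[!is.na(calls$gene), c("gene", "agent")])
  genes <- calls %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(
      n_agents = dplyr::n_distinct(.data$agent),
      agents = paste(sort(unique(.data$agent)), collapse = ";"),
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$n_agents >= 2L) %>%
    dplyr::arrange(dplyr::desc(.data$n_agents), .data$gene)
  agents <- calls %>%
    dplyr::group_by(.data$agent) %>%
    dplyr::summarise(
      n_genes = dplyr::n_distinct(.data$gene),
      genes = paste(sort(unique(.data$gene)), collapse = ";"),
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$n_genes >= 2L) %>%
    dplyr::arrange(dplyr::desc(.data$n_genes), .data$agent)
  list(genes = genes, agents = agents)
}
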