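#' Median log10(IC50) drug-response matrix
#'
#' Per (agent, cell line): takes log10 of each replicate IC50 (molar), then
#' the median across replicates (even counts average the two central values).
#' Spearman-based association downstream is invariant to the log base; base
#' 10 is used so response values read directly as orders of magnitude of
#' molar concentration.
#'
#' @param replicates Tibble `(agent, cell_line, replicate, ic50)` from
#'   [read_drug_replicates()].
#' @return An agent x cell-line numeric matrix of median log10(IC50); `NA`
#'   where a pair has no replicates.
#' @export
median_log_ic50 <- function(replicates) {
  if (any(replicates$ic50 <= 0, na.rm = TRUE)) {
    abort_validation("IC50 values must be strictly positive.")
  }
  med <- replicates %>%
    dplyr::group_by(.data$agent, .data$cell_line) %>%
    dplyr::summarise(value = stats::median(log10(.data$ic50)), .groups = "drop")
  agents <- sort(unique(med$agent))
  lines <- sort(unique(med$cell_line))
  m <- matrix(NA_real_, length(agents), length(lines), dimnames = list(agents, lines))
  m[cbind(match(med$agent, agents), match(med$cell_line, lines))] <- med$value
  m
}

#' Restrict to agents with variable response
#'
#' Keeps agents whose response vector has at least `min_distinct` distinct
#' non-missing values and a range exceeding `min_range` log units. Agents
#' screened at concentrations that never modulated growth produce constant
#' response vectors, which carry no rank information and would make every
#' correlation undefined.
#'
#' @param response Agent x cell-line response matrix from [median_log_ic50()].
#' @param min_distinct Minimum number of distinct non-missing values
#'   (default 2, the weakest reading of "variable").
#' @param min_range Minimum response range in log units (default 0,
#'   exclusive).
#' @return List with `response` (subset matrix) and `excluded` (tibble
#'   `agent`, `reason`).
#' @export
filter_variable_agents <- function(response, min_distinct = 2L, min_range = 0) {
  reasons <- purrr::map_chr(seq_len(nrow(response)), function(i) {
    v <- response[i, ]
    v <- v[!is.na(v)]
    if (length(unique(v)) < min_distinct) return("too_few_distinct_values")
    if (length(v) && (max(v) - min(v)) <= min_range) return("range_below_minimum")
    NA_character_
  })
  keep <- is.na(reasons)
  list(
    response = response[keep, , drop = FALSE],
    excluded = tibble::tibble(agent = rownames(response)[!keep], reason = reasons[!keep])
  )
}

#' Correlate methylation features with drug response
#'
#' One Spearman test per (feature, agent) pair on their pairwise-complete
#' samples, emitting a record only when the correlation is defined (at least
#' 3 complete pairs, neither rank vector constant). Undefined tests are
#' logged in the `exclusions` attribute, never silently discarded and never
#' counted into FDR families. The sign convention follows the response
#' scale: positive coefficients mean higher methylation with higher
#' log(IC50), i.e. resistance; negative means sensitivity.
#'
#' @param features Feature x sample matrix (probe betas, or the `values` of a
#'   `region_matrix`), or a `region_matrix`.
#' @param response Agent x cell-line response matrix (pre-filtered for
#'   variability).
#' @param family Family tag recorded on each record, e.g.
#'   `"epigenome_probe"`.
#' @param feature_info Optional tibble `(feature_id, gene, region)` used to
#'   annotate records (for probes, gene labels collapse multi-gene
#'   assignments with `";"`).
#' @return Tibble of association records with columns `feature_id`,
#'   `feature_kind`, `gene`, `region`, `agent`, `coefficient`, `p_o`,
#'   `n_used`, `family`; attribute `exclusions` logs undefined tests.
#' @export
correlate_features_with_response <- function(features, response, family,
                                             feature_info = NULL) {
  kind <- if (inherits(features, "region_matrix")) "region" else "probe"
  if (inherits(features, "region_matrix")) {
    if (is.null(feature_info)) {
      feature_info <- features$keys %>%
        dplyr::select(feature_id = "key", "gene", "region")
    }
    features <- features$values
  }
  shared <- intersect(colnames(features), colnames(response))
  if (length(shared) < 3L) {
    abort_validation("Fewer than 3 samples shared between features and response.")
  }
  cors <- cor_rows(features[, shared, drop = FALSE], response[, shared, drop = FALSE],
    method = "spearman"
  )
  long <- tibble::tibble(
    feature_id = rep(rownames(features), times = nrow(response)),
    agent = rep(rownames(response), each = nrow(features)),
    coefficient = as.vector(cors$coefficient),
    n_used = as.vector(cors$n_used)
  )
  defined <- !is.na(long$coefficient)
  records <- long[defined, ]
  records$p_o <- spearman_p_from_rho(records$coefficient, records$n_used)
  records$feature_kind <- kind
  records$family <- family
  if (!is.null(feature_info)) {
    info <- feature_info %>%
      dplyr::group_by(.data$feature_id) %>%
      dplyr::summarise(
        gene = paste(sort(unique(.data$gene)), collapse = ";"),
        region = paste(sort(unique(.data$region)), collapse = ";"),
        .groups = "drop"
      )
    records <- dplyr::left_join(records, info, by = "feature_id")
  } else {
    records$gene <- NA_character_
    records$region <- NA_character_
  }
  records <- records %>%
    dplyr::select(
      "feature_id", "feature_kind", "gene", "region", "agent",
      "coefficient", "p_o", "n_used", "family"
    ) %>%
    dplyr::arrange(.data$p_o, .data$feature_id, .data$agent)
  attr(records, "exclusions") <- long[!defined, c("feature_id", "agent", "n_used")] %>%
    dplyr::mutate(reason = ifelse(.data$n_used < 3L, "fewer_than_3_pairs", "constant_ranks"))
  records
}

#' Epigenome-wide association of methylation with drug response
#'
#' Runs the two-tier epigenome-wide screen. Probe-level records are judged
#' against fixed per-probe thresholds only (`passes_strict`,
#' `passes_liberal`) -- no probe-level FDR. Region-level records receive
#' Benjamini-Hochberg adjusted p-values from a single family spanning every
#' defined region x agent test, with significance tiers flagged at the
#' `fdr_tiers` cutoffs.
#'
#' @param beta QC-filtered probe x sample beta matrix.
#' @param regions A `region_matrix` from [average_region_betas()].
#' @param response Variable-agent response matrix.
#' @param strict Fixed strict probe threshold on the raw p-value
#'   (default `9.42e-8`, the single-EPIC-probe recommendation).
#' @param liberal Liberal probe threshold (default `5e-7`).
#' @param fdr_tiers Region FDR tiers to flag, default `c(0.05, 0.1, 0.15)`.
#' @param probe_info Optional `(feature_id, gene, region)` tibble annotating
#'   probes (pass `probe_assignments()` output renamed accordingly).
#' @return A `methyl_assoc` object; `tidy()` extracts the record tibbles and
#'   `glance()` the tally of tests and hits.
#' @export
epigenome_wide_analysis <- function(beta, regions, response,
                                    strict = 9.42e-8, liberal = 5e-7,
                                    fdr_tiers = c(0.05, 0.1, 0.15),
                                    probe_info = NULL) {
  if (strict >= liberal) {
    abort_validation("`strict` must be smaller than `liberal`.")
  }
  probe_records <- correlate_features_with_response(
    beta, response, "epigenome_probe", feature_info = probe_info
  ) %>%
    dplyr::mutate(
      passes_strict = .data$p_o < strict,
      passes_liberal = .data$p_o < liberal
    )
  region_records <- correlate_features_with_response(
    regions, response, "epigenome_region"
  )
  region_records <- add_fdr(region_records, fdr_tiers)
  new_methyl_assoc(
    probe_records = probe_records,
    region_records = region_records,
    thresholds = list(strict = strict, liberal = liberal, fdr_tiers = fdr_tiers),
    families = list(
      epigenome_probe = nrow(probe_records),
      epigenome_region = nrow(region_records)
    ),
    exclusions = list(
      probe = attr(probe_records, "exclusions"),
      region = attr(region_records, "exclusions")
    )
  )
}

add_fdr <- function(records, fdr_tiers) {
  if (nrow(records) == 0L) {
    records$p_fdr <- numeric()
  } else {
    records$p_fdr <- bh_adjust(records$p_o)$adjusted
  }
  for (tier in fdr_tiers) {
    records[[sprintf("fdr_lt_%s", format(tier))]] <- records$p_fdr < tier
  }
  records
}

#' Candidate-gene association with selected agents
#'
#' Tests candidate-gene probes and regions against a candidate agent panel,
#' with two Benjamini-Hochberg families fully independent of each other and
#' of the epigenome-wide families: (candidate probes x candidate agents) and
#' (candidate regions x candidate agents). The same raw p-value therefore
#' generally carries a different adjusted value here than in the
#' epigenome-wide screen.
#'
#' @param beta QC-filtered probe x sample beta matrix.
#' @param regions A `region_matrix`.
#' @param response Variable-agent response matrix.
#' @param candidate_genes,candidate_agents Character vectors (non-empty
#'   intersections with the data are required).
#' @param assignments Probe assignment tibble `(probe_id, gene, region)` used
#'   to select candidate probes.
#' @param fdr_tiers FDR tiers to flag, default `c(0.05, 0.1, 0.15)`.
#' @return A `methyl_assoc` object with families `candidate_probe` and
#'   `candidate_region`.
#' @export
candidate_analysis <- function(beta, regions, response,
                               candidate_genes, candidate_agents, assignments,
                               fdr_tiers = c(0.05, 0.1, 0.15)) {
  cand_probes <- assignments %>%
    dplyr::filter(.data$gene %in% candidate_genes) %>%
    dplyr::pull("probe_id") %>%
    unique()
  cand_probes <- intersect(rownames(beta), cand_probes)
  agents <- intersect(rownames(response), candidate_agents)
  keep_keys <- regions$keys$gene %in% candidate_genes
  if (length(cand_probes) == 0L || length(agents) == 0L || !any(keep_keys)) {
    abort_validation("Empty candidate intersection: no candidate probes, regions or agents present.")
  }
  probe_info <- assignments %>%
    dplyr::filter(.data$probe_id %in% cand_probes) %>%
    dplyr::select(feature_id = "probe_id", "gene", "region")
  probe_records <- correlate_features_with_response(
    beta[cand_probes, , drop = FALSE],
    response[agents, , drop = FALSE],
    "candidate_probe",
    feature_info = probe_info
  ) %>% add_fdr(fdr_tiers)
  cand_regions <- structure(
    list(
      values = regions$values[regions$keys$key[keep_keys], , drop = FALSE],
      keys = regions$keys[keep_keys, ]
    ),
    class = "region_matrix"
  )
  region_records <- correlate_features_with_response(
    cand_regions, response[agents, , drop = FALSE], "candidate_region"
  ) %>% add_fdr(fdr_tiers)
  new_methyl_assoc(
    probe_records = probe_records,
    region_records = region_records,
    thresholds = list(fdr_tiers = fdr_tiers),
    families = list(
      candidate_probe = nrow(probe_records),
      candidate_region = nrow(region_records)
    ),
    exclusions = list(
      probe = attr(probe_records, "exclusions"),
      region = attr(region_records, "exclusions")
    )
  )
}

new_methyl_assoc <- function(probe_records, region_records, thresholds,
                             families, exclusions) {
  structure(
    list(
      probe_records = probe_records,
      region_records = region_records,
      thresholds = thresholds,
      families = families,
      exclusions = exclusions
    ),
    class = "methyl_assoc"
  )
}

#' @export
print.methyl_assoc <- function(x, ...) {
  cat("<methyl_assoc>\n")
  for (fam in names(x$families)) {
    cat(sprintf("  %s: %d tests\n", fam, x$families[[fam]]))
  }
  if (!is.null(x$thresholds$strict)) {
    cat(sprintf(
      "  probe hits: %d strict (p < %g), %d liberal (p < %g)\n",
      sum(x$probe_records$passes_strict), x$thresholds$strict,
      sum(x$probe_records$passes_liberal), x$thresholds$liberal
    ))
  }
  if ("p_fdr" %in% names(x$region_records)) {
    for (tier in x$thresholds$fdr_tiers) {
      cat(sprintf("  regions with p_FDR < %g: %d\n", tier,
        sum(x$region_records$p_fdr < tier)))
    }
  }
  invisible(x)
}

#' @rdname epigenome_wide_analysis
#' @param x,object A `methyl_assoc`.
#' @param level `"region"` or `"probe"`: which record table to extract.
#' @param ... Unused.
#' @export
tidy.methyl_assoc <- function(x, level = c("region", "probe"), ...) {
  level <- match.arg(level)
  out <- if (level == "region") x$region_records else x$probe_records
  tibble::as_tibble(out)
}

#' @rdname epigenome_wide_analysis
#' @export
glance.methyl_assoc <- function(x, ...) {
  out <- tibble::tibble(
    n_probe_tests = nrow(x$probe_records),
    n_region_tests = nrow(x$region_records)
  )
  if (!is.null(x$thresholds$strict)) {
    out$n_probe_strict <- sum(x$probe_records$passes_strict)
    out$n_probe_liberal <- sum(x$probe_records$passes_liberal)
  }
  if ("p_fdr" %in% names(x$region_records)) {
    for (tier in x$thresholds$fdr_tiers) {
      out[[sprintf("n_region_fdr_%s", format(tier))]] <-
        sum(x$region_records$p_fdr < tier)
    }
  }
  out
}

#' Gene-level summary of top probe associations
#'
#' For every (gene, agent) pair holding at least one qualifying probe record
#' (raw p below `liberal`), reports the best probe (smallest p, ties broken
#' by larger coefficient magnitude then lexicographic id) and links it to
#' transcript expression: among transcripts whose gene symbol matches, the
#' transcript whose log2 expression has the smallest Spearman p against any
#' qualifying probe's methylation is selected, and its Pearson correlation
#' with the agent's response is reported alongside. Probes assigned to
#' several genes form combined multi-gene rows (gene symbols joined by
#' `";"`); genes with no matching transcript keep `NA` expression columns.
#'
#' @param probe_records Probe-level association records (with `gene` labels).
#' @param beta QC-filtered beta matrix (for methylation-expression tests).
#' @param expression Expression list (`values`, `tx_map`) from
#'   [read_expression()].
#' @param response Response matrix.
#' @param liberal Qualifying raw-p threshold, default `5e-7`.
#' @return A tibble with one row per (gene label, agent).
#' @export
gene_level_summary <- function(probe_records, beta, expression, response,
                               liberal = 5e-7) {
  qual <- probe_records %>%
    dplyr::filter(.data$p_o < liberal, !is.na(.data$gene), .data$gene != "")
  if (nrow(qual) == 0L) {
    return(tibble::tibble(
      gene = character(), agent = character(), n_probes_qualifying = integer(),
      best_probe = character(), coefficient = numeric(), p_o = numeric(),
      best_transcript = character(), rho_meth_expr = numeric(),
      p_meth_expr = numeric(), r_expr_drug = numeric(), p_expr_drug = numeric()
    ))
  }
  groups <- qual %>%
    dplyr::group_by(.data$gene, .data$agent) %>%
    dplyr::group_split()
  purrr::map_dfr(groups, function(g) {
    best <- g %>%
      dplyr::arrange(.data$p_o, dplyr::desc(abs(.data$coefficient)), .data$feature_id) %>%
      dplyr::slice(1L)
    symbols <- strsplit(best$gene, ";", fixed = TRUE)[[1L]]
    txs <- expression$tx_map$transcript_id[expression$tx_map$gene %in% symbols]
    out <- tibble::tibble(
      gene = best$gene, agent = best$agent,
      n_probes_qualifying = nrow(g),
      best_probe = best$feature_id,
      coefficient = best$coefficient, p_o = best$p_o,
      best_transcript = NA_character_, rho_meth_expr = NA_real_,
      p_meth_expr = NA_real_, r_expr_drug = NA_real_, p_expr_drug = NA_real_
    )
    if (length(txs) == 0L) {
      return(out)
    }
    # best transcript: smallest methylation-expression Spearman p over any
    # qualifying probe of this (gene, agent) group
    cand <- tidyr::expand_grid(probe = unique(g$feature_id), tx = txs) %>%
      dplyr::mutate(purrr::map2_dfr(.data$probe, .data$tx, function(pr, tx) {
        shared <- intersect(colnames(beta), colnames(expression$values))
        spearman_cor(beta[pr, shared], expression$values[tx, shared])[, c("coefficient", "p_value")]
      })) %>%
      dplyr::filter(!is.na(.data$coefficient)) %>%
      dplyr::arrange(.data$p_value, dplyr::desc(abs(.data$coefficient)), .data$tx)
    if (nrow(cand) == 0L) {
      return(out)
    }
    top <- cand[1L, ]
    out$best_transcript <- top$tx
    out$rho_meth_expr <- top$coefficient
    out$p_meth_expr <- top$p_value
    shared <- intersect(colnames(expression$values), colnames(response))
    pear <- pearson_cor(expression$values[top$tx, shared], response[best$agent, shared])
    out$r_expr_drug <- pear$coefficient
    out$p_expr_drug <- pear$p_value
    out
  }) %>%
    dplyr::arrange(.data$p_o, .data$gene, .data$agent)
}
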