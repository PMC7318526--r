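LINEAGE_MARKERS <- c("ASCL1", "ASCL2", "NEUROD1", "INSM1", "YAP1", "POU2F3")

#' Spearman correlation of methylation features with matching transcripts
#'
#' For every feature (probe or gene region) and every transcript whose gene
#' symbol matches the feature's annotated gene(s), the Spearman correlation
#' between methylation and log2 expression on shared samples. Features with
#' no matching transcript are logged in the `unmatched` attribute.
#'
#' @param features Feature x sample matrix, or a `region_matrix`.
#' @param expression Expression list (`values`, `tx_map`).
#' @param feature_genes Tibble `(feature_id, gene)`; one row per annotated
#'   gene symbol (not collapsed).
#' @return Tibble `(feature_id, gene, transcript_id, coefficient, p_value,
#'   n_used)`.
#' @export
methylation_expression_correlations <- function(features, expression, feature_genes) {
  if (inherits(features, "region_matrix")) {
    if (missing(feature_genes) || is.null(feature_genes)) {
      feature_genes <- features$keys %>% dplyr::select(feature_id = "key", "gene")
    }
    features <- features$values
  }
  pairs <- feature_genes %>%
    dplyr::inner_join(expression$tx_map, by = "gene", relationship = "many-to-many") %>%
    dplyr::filter(.data$feature_id %in% rownames(features))
  unmatched <- feature_genes %>%
    dplyr::anti_join(expression$tx_map, by = "gene")
  shared <- intersect(colnames(features), colnames(expression$values))
  if (length(shared) < 3L) {
    abort_validation("Fewer than 3 samples shared between features and expression.")
  }
  res <- purrr::map2_dfr(pairs$feature_id, pairs$transcript_id, function(f, tx) {
    spearman_cor(features[f, shared], expression$values[tx, shared])
  })
  out <- dplyr::bind_cols(pairs[, c("feature_id", "gene", "transcript_id")], res) %>%
    dplyr::select(-"method")
  attr(out, "unmatched") <- unmatched
  out
}

#' Pearson correlation of transcript expression with drug response
#'
#' One Pearson test per (transcript, agent) on pairwise-complete samples.
#' Constant transcripts yield no record and are logged in the `exclusions`
#' attribute.
#'
#' @param expression Expression list (`values`, `tx_map`).
#' @param response Agent x cell-line response matrix.
#' @return Tibble `(transcript_id, gene, agent, coefficient, p_value,
#'   n_used)`.
#' @export
expression_response_correlations <- function(expression, response) {
  shared <- intersect(colnames(expression$values), colnames(response))
  if (length(shared) < 3L) {
    abort_validation("Fewer than 3 samples shared between expression and response.")
  }
  cors <- cor_rows(expression$values[, shared, drop = FALSE],
    response[, shared, drop = FALSE],
    method = "pearson"
  )
  long <- tibble::tibble(
    transcript_id = rep(rownames(expression$values), times = nrow(response)),
    agent = rep(rownames(response), each = nrow(expression$values)),
    coefficient = as.vector(cors$coefficient),
    n_used = as.vector(cors$n_used)
  )
  defined <- !is.na(long$coefficient)
  out <- long[defined, ]
  out$p_value <- spearman_p_from_rho(out$coefficient, out$n_used)
  out$gene <- expression$tx_map$gene[match(out$transcript_id, expression$tx_map$transcript_id)]
  out <- out[, c("transcript_id", "gene", "agent", "coefficient", "p_value", "n_used")]
  attr(out, "exclusions") <- long[!defined, c("transcript_id", "agent")]
  out
}

#' Classify the regulatory pattern of a methylation-expression-response triple
#'
#' Given the three legs linking one (gene, feature, agent) triple --
#' methylation vs response (Spearman), methylation vs expression (Spearman),
#' expression vs response (Pearson) -- assigns one of four tags:
#'
#' * `canonical_repression`: methylation-expression significantly negative
#'   and the expression-response sign opposite to the methylation-response
#'   sign (direct epigenetic silencing driving the drug association);
#' * `expression_coupled_positive`: methylation-expression significantly
#'   positive with expression-response matching the methylation-response
#'   sign (e.g. copy-number-driven co-elevation);
#' * `undetermined`: any leg not significant at `sig_alpha` or with
#'   coefficient magnitude below `min_abs`;
#' * `inconsistent`: all legs strong but the sign pattern fits neither model.
#'
#' Vectorized row-wise over the three input tibbles.
#'
#' @param meth_drug,meth_expr,expr_drug Tibbles with columns `coefficient`
#'   and `p_value` (e.g. from [spearman_cor()] / [pearson_cor()]), all the
#'   same number of rows.
#' @param sig_alpha Per-leg significance level, default 0.05.
#' @param min_abs Minimum coefficient magnitude per leg, default 0.3.
#' @return Character vector of pattern tags.
#' @export
classify_regulatory_pattern <- function(meth_drug, meth_expr, expr_drug,
                                        sig_alpha = 0.05, min_abs = 0.3) {
  n <- nrow(meth_drug)
  stopifnot(nrow(meth_expr) == n, nrow(expr_drug) == n)
  strong <- function(leg) {
    !is.na(leg$coefficient) & !is.na(leg$p_value) &
      leg$p_value < sig_alpha & abs(leg$coefficient) >= min_abs
  }
  all_strong <- strong(meth_drug) & strong(meth_expr) & strong(expr_drug)
  out <- rep("undetermined", n)
  canonical <- all_strong & meth_expr$coefficient < 0 &
    sign(expr_drug$coefficient) == -sign(meth_drug$coefficient)
  positive <- all_strong & meth_expr$coefficient > 0 &
    sign(expr_drug$coefficient) == sign(meth_drug$coefficient)
  out[all_strong] <- "inconsistent"
  out[canonical] <- "canonical_repression"
  out[positive] <- "expression_coupled_positive"
  out
}

#' Build linked gene reports across the three association legs
#'
#' Joins methylation-response records with methylation-expression and
#' expression-response correlations and classifies each triple with
#' [classify_regulatory_pattern()]. For each (feature, agent) record the
#' matching transcript with the smallest methylation-expression p-value is
#' used.
#'
#' @param records Methylation-response association records (probe or region).
#' @param meth_expr Output of [methylation_expression_correlations()].
#' @param expr_drug Output of [expression_response_correlations()].
#' @param sig_alpha,min_abs Classification thresholds, see
#'   [classify_regulatory_pattern()].
#' @return A tibble, one row per (feature, agent) with all three legs and a
#'   `pattern` column.
#' @export
build_linked_reports <- function(records, meth_expr, expr_drug,
                                 sig_alpha = 0.05, min_abs = 0.3) {
  best_tx <- meth_expr %>%
    dplyr::filter(!is.na(.data$coefficient)) %>%
    dplyr::group_by(.data$feature_id) %>%
    dplyr::arrange(.data$p_value, dplyr::desc(abs(.data$coefficient)),
      .data$transcript_id, .by_group = TRUE) %>%
    dplyr::slice(1L) %>%
    dplyr::ungroup() %>%
    dplyr::select("feature_id",
      transcript_id = "transcript_id",
      rho_meth_expr = "coefficient", p_meth_expr = "p_value"
    )
  linked <- records %>%
    dplyr::inner_join(best_tx, by = "feature_id") %>%
    dplyr::left_join(
      expr_drug %>% dplyr::select("transcript_id", "agent",
        r_expr_drug = "coefficient", p_expr_drug = "p_value"),
      by = c("transcript_id", "agent")
    )
  linked$pattern <- classify_regulatory_pattern(
    tibble::tibble(coefficient = linked$coefficient, p_value = linked$p_o),
    tibble::tibble(coefficient = linked$rho_meth_expr, p_value = linked$p_meth_expr),
    tibble::tibble(coefficient = linked$r_expr_drug, p_value = linked$p_expr_drug),
    sig_alpha = sig_alpha, min_abs = min_abs
  )
  linked
}

#' Copy-number screen for positively coupled genes
#'
#' For each requested (gene, feature, transcript, agent) target, Spearman
#' correlations of the gene's copy-number profile with methylation,
#' expression and response. When all three coefficient magnitudes stay below
#' `flag_threshold`, the `cn_unexplained` flag is set: the positive
#' methylation-expression coupling is not attributable to copy number.
#'
#' @param cn Gene x sample copy-number matrix (log2 ratios).
#' @param features Feature x sample methylation matrix, or a
#'   `region_matrix`.
#' @param expression Expression list (`values`, `tx_map`).
#' @param response Response matrix.
#' @param targets Tibble `(gene, feature_id, transcript_id, agent)` naming
#'   the triples to screen.
#' @param flag_threshold Magnitude below which copy number is deemed
#'   uninformative, default 0.2.
#' @return Tibble with the three correlations and the `cn_unexplained` flag;
#'   genes absent from `cn` are skipped and logged in the `skipped`
#'   attribute.
#' @export
copy_number_screen <- function(cn, features, expression, response, targets,
                               flag_threshold = 0.2) {
  if (inherits(features, "region_matrix")) features <- features$values
  present <- targets$gene %in% rownames(cn)
  skipped <- targets[!present, ]
  targets <- targets[present, ]
  out <- purrr::pmap_dfr(targets, function(gene, feature_id, transcript_id, agent, ...) {
    cng <- cn[gene, ]
    sm <- intersect(names(cng)[!is.na(cng)], colnames(features))
    meth <- spearman_cor(cng[sm], features[feature_id, sm])
    se <- intersect(names(cng)[!is.na(cng)], colnames(expression$values))
    expr <- spearman_cor(cng[se], expression$values[transcript_id, se])
    sr <- intersect(names(cng)[!is.na(cng)], colnames(response))
    resp <- spearman_cor(cng[sr], response[agent, sr])
    tibble::tibble(
      gene = gene, feature_id = feature_id, transcript_id = transcript_id,
      agent = agent,
      rho_cn_meth = meth$coefficient, p_cn_meth = meth$p_value,
      rho_cn_expr = expr$coefficient, p_cn_expr = expr$p_value,
      rho_cn_resp = resp$coefficient, p_cn_resp = resp$p_value,
      n_used = min(meth$n_used, expr$n_used, resp$n_used),
      cn_unexplained = all(abs(c(
        meth$coefficient, expr$coefficient, resp$coefficient
      )) < flag_threshold, na.rm = TRUE)
    )
  })
  attr(out, "skipped") <- skipped
  out
}

#' UPGMA clustering of samples on lineage-marker expression
#'
#' Agglomerative average-linkage (UPGMA) clustering of samples on Euclidean
#' distances over the log2 expression of the six lineage markers (ASCL1,
#' ASCL2, NEUROD1, INSM1, YAP1, POU2F3 by default). Genes represented by
#' several transcripts are averaged to one gene-level profile. The merge
#' order is deterministic given the input sample order ([stats::hclust()]
#' merges the lowest-index pair among equals first).
#'
#' @param expression Expression list (`values`, `tx_map`).
#' @param markers Marker gene symbols; all must be present (missing markers
#'   raise an error listing them).
#' @param k Number of clusters for the reported cut, default 2.
#' @return A `lineage_clust` object: `hclust`, `assignments` (named integer
#'   vector), `markers` (marker x sample matrix), `k`.
#' @export
lineage_clustering <- function(expression, markers = LINEAGE_MARKERS, k = 2L) {
  have <- markers %in% expression$tx_map$gene
  if (!all(have)) {
    abort_validation(sprintf(
      "Lineage markers missing from expression data: %s.",
      paste(markers[!have], collapse = ", ")
    ))
  }
  if (ncol(expression$values) < 2L) {
    abort_validation("At least 2 samples are required for clustering.")
  }
  mat <- t(vapply(markers, function(g) {
    txs <- expression$tx_map$transcript_id[expression$tx_map$gene == g]
    colMeans(expression$values[txs, , drop = FALSE])
  }, numeric(ncol(expression$values))))
  rownames(mat) <- markers
  hc <- stats::hclust(stats::dist(t(mat), method = "euclidean"), method = "average")
  assignments <- stats::cutree(hc, k = k)
  structure(
    list(hclust = hc, assignments = assignments, markers = mat, k = k),
    class = "lineage_clust"
  )
}

#' @export
print.lineage_clust <- function(x, ...) {
  cat("<lineage_clust>\n")
  cat(sprintf("  %d samples, UPGMA on %d markers, cut at k = %d\n",
    length(x$assignments), nrow(x$markers), x$k))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' @rdname lineage_clustering
#' @param x,object A `lineage_clust`.
#' @param ... Unused.
#' @export
tidy.lineage_clust <- function(x, ...) {
  tibble::tibble(
    sample_id = names(x$assignments),
    cluster = unname(x$assignments)
  )
}

#' @rdname lineage_clustering
#' @export
glance.lineage_clust <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$assignments),
    k = x$k,
    n_markers = nrow(x$markers),
    max_height = max(x$hclust$height)
  )
}

#' Export a lineage dendrogram as Newick text
#'
#' @param clustering A `lineage_clust`.
#' @param path Output path for the newick file.
#' @export
write_newick <- function(clustering, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort_validation("Package 'ape' is required for newick export.")
  }
  phy <- ape::as.phylo(clustering$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Correlate one profile with the six lineage markers
#'
#' Both Spearman and Pearson correlations of a per-sample profile (a probe's
#' beta-values, a region average, or a transcript) against gene-level
#' expression of each lineage marker.
#'
#' @param x Named numeric vector over samples.
#' @param expression Expression list (`values`, `tx_map`).
#' @param markers Marker gene symbols, default the six lineage markers.
#' @return Tibble `(marker, method, coefficient, p_value, n_used)`.
#' @export
marker_correlations <- function(x, expression, markers = LINEAGE_MARKERS) {
  have <- markers %in% expression$tx_map$gene
  if (!all(have)) {
    abort_validation(sprintf(
      "Lineage markers missing from expression data: %s.",
      paste(markers[!have], collapse = ", ")
    ))
  }
  purrr::map_dfr(markers, function(g) {
    txs <- expression$tx_map$transcript_id[expression$tx_map$gene == g]
    prof <- colMeans(expression$values[txs, , drop = FALSE])
    shared <- intersect(names(x), names(prof))
    dplyr::bind_rows(
      spearman_cor(x[shared], prof[shared]),
      pearson_cor(x[shared], prof[shared])
    ) %>%
      dplyr::mutate(marker = g, .before = 1L)
  }) %>%
    dplyr::select("marker", "method", "coefficient", "p_value", "n_used")
}
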