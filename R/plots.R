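#' Volcano plot of association records
#'
#' Coefficient against \eqn{-\log_{10} p_O} for one record table of a
#' `methyl_assoc`, colored by the significance tier reached (fixed probe
#' thresholds for probe records, FDR tiers for region records).
#'
#' @param object A `methyl_assoc`.
#' @param level `"region"` or `"probe"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.methyl_assoc <- function(object, level = c("region", "probe"), ...) {
  level <- match.arg(level)
  rec <- tidy(object, level = level)
  if (level == "probe" && !is.null(object$thresholds$strict)) {
    rec$tier <- dplyr::case_when(
      rec$passes_strict ~ sprintf("p < %g", object$thresholds$strict),
      rec$passes_liberal ~ sprintf("p < %g", object$thresholds$liberal),
      TRUE ~ "not significant"
    )
  } else if ("p_fdr" %in% names(rec)) {
    tiers <- sort(object$thresholds$fdr_tiers)
    rec$tier <- "not significant"
    for (t in rev(tiers)) {
      rec$tier[rec$p_fdr < t] <- sprintf("FDR < %g", t)
    }
  } else {
    rec$tier <- "test"
  }
  ggplot2::ggplot(rec, ggplot2::aes(
    x = .data$coefficient, y = -log10(.data$p_o), colour = .data$tier
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(
      x = "Spearman correlation with log(IC50)",
      y = expression(-log[10] ~ p[O]),
      colour = NULL,
      title = sprintf("%s-level methylation-response associations", level)
    ) +
    ggplot2::theme_minimal()
}

#' Dendrogram of a lineage clustering
#'
#' Draws the UPGMA dendrogram as segments, with leaves colored by the
#' reported cluster cut.
#'
#' @param object A `lineage_clust`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lineage_clust <- function(object, ...) {
  seg <- hclust_segments(object$hclust)
  leaves <- tibble::tibble(
    x = seq_along(object$hclust$order),
    sample_id = object$hclust$labels[object$hclust$order]
  )
  leaves$cluster <- factor(object$assignments[leaves$sample_id])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend)
    ) +
    ggplot2::geom_text(
      data = leaves,
      ggplot2::aes(x = .data$x, y = -0.02 * max(seg$y), label = .data$sample_id,
        colour = .data$cluster),
      angle = 90, hjust = 1, size = 2.5
    ) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.25, 0.05))) +
    ggplot2::labs(x = NULL, y = "UPGMA merge height", colour = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_blank(),
      panel.grid.major.x = ggplot2::element_blank()
    )
}

# segment table for an hclust dendrogram (x positions follow leaf order)
hclust_segments <- function(hc) {
  n <- length(hc$order)
  leaf_x <- integer(n)
  leaf_x[hc$order] <- seq_len(n)
  node_x <- numeric(nrow(hc$merge))
  node_h <- hc$height
  seg <- vector("list", nrow(hc$merge))
  pos <- function(id) if (id < 0) leaf_x[-id] else node_x[id]
  hei <- function(id) if (id < 0) 0 else node_h[id]
  for (i in seq_len(nrow(hc$merge))) {
    a <- hc$merge[i, 1L]
    b <- hc$merge[i, 2L]
    xa <- pos(a); xb <- pos(b)
    node_x[i] <- (xa + xb) / 2
    seg[[i]] <- tibble::tibble(
      x = c(xa, xb, xa), xend = c(xa, xb, xb),
      y = c(hei(a), hei(b), node_h[i]), yend = c(node_h[i], node_h[i], node_h[i])
    )
  }
  dplyr::bind_rows(seg)
}

#' Scatter plot of region methylation against drug response
#'
#' One (gene region, agent) pair: average beta against median log10(IC50),
#' annotated with the Spearman coefficient and its t-approximation p-value.
#'
#' @param regions A `region_matrix`.
#' @param response Agent x cell-line response matrix.
#' @param key Region key `"GENE|REGION"`.
#' @param agent Agent identifier.
#' @return A ggplot object.
#' @export
plot_region_response <- function(regions, response, key, agent) {
  if (!key %in% rownames(regions$values)) {
    abort_validation(sprintf("Region key %s not found.", key))
  }
  if (!agent %in% rownames(response)) {
    abort_validation(sprintf("Agent %s not found.", agent))
  }
  shared <- intersect(colnames(regions$values), colnames(response))
  df <- tibble::tibble(
    beta = regions$values[key, shared],
    response = response[agent, shared]
  )
  ct <- spearman_cor(df$beta, df$response)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$response)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("%s average methylation (beta)", key),
      y = sprintf("%s median log10(IC50)", agent),
      subtitle = sprintf("Spearman rho = %.3f, p = %.3g (n = %d)",
        ct$coefficient, ct$p_value, ct$n_used)
    ) +
    ggplot2::theme_minimal()
}
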