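#' Build the gene-region probe index
#'
#' Maps each (gene, region-class) key to its QC-retained member probes, with
#' region classes drawn from the six-class manifest vocabulary (TSS1500,
#' TSS200, 5UTR, 1stExon, Body, 3UTR). Probes annotated to several genes
#' and/or regions appear under each of their keys; intergenic probes appear
#' under none. Keys left with no retained probes are omitted (and can be
#' audited via the dropped-key attribute).
#'
#' @param assignments Tibble `(probe_id, gene, region)` from
#'   [probe_assignments()], or a manifest tibble (expanded automatically).
#' @param retained_probes Character vector of QC-retained probe ids.
#' @return A `region_index` tibble `(key, gene, region, probe_id)` where
#'   `key = "GENE|REGION"`; attribute `n_keys` counts distinct keys.
#' @export
build_region_index <- function(assignments, retained_probes) {
  if (!all(c("probe_id", "gene", "region") %in% names(assignments))) {
    assignments <- probe_assignments(assignments)
  }
  all_keys <- dplyr::distinct(assignments[, c("gene", "region")])
  idx <- assignments %>%
    dplyr::filter(.data$probe_id %in% retained_probes) %>%
    dplyr::mutate(key = paste(.data$gene, .data$region, sep = "|")) %>%
    dplyr::select("key", "gene", "region", "probe_id") %>%
    dplyr::arrange(.data$key, .data$probe_id)
  kept_keys <- dplyr::distinct(idx[, c("gene", "region")])
  dropped <- dplyr::anti_join(all_keys, kept_keys, by = c("gene", "region"))
  structure(idx,
    class = c("region_index", class(idx)),
    n_keys = nrow(kept_keys),
    dropped_keys = dropped
  )
}

#' Average beta-values within gene regions
#'
#' For every (gene, region-class) key and sample, the unweighted arithmetic
#' mean of the non-missing member-probe beta-values; missing only when every
#' member probe is missing in that sample. Region classes are never pooled
#' with each other, and a probe belonging to several keys contributes to each
#' of them.
#'
#' @param beta Probe x sample beta matrix (QC output).
#' @param index A `region_index` from [build_region_index()].
#' @return A `region_matrix` list: `values` (region x sample matrix with
#'   rownames `"GENE|REGION"`), `keys` (tibble `key`, `gene`, `region`,
#'   `n_probes`).
#' @export
average_region_betas <- function(beta, index) {
  miss <- setdiff(index$probe_id, rownames(beta))
  if (length(miss)) {
    abort_validation(sprintf("Index probe %s not present in the beta matrix.", miss[1L]))
  }
  # canonical accumulation order: averages are bit-identical however the
  # index rows were arranged
  index <- dplyr::arrange(tibble::as_tibble(index), .data$key, .data$probe_id)
  B <- beta[index$probe_id, , drop = FALSE]
  grp <- index$key
  present <- !is.na(B)
  B0 <- B
  B0[!present] <- 0
  sums <- rowsum(B0, grp)
  counts <- rowsum(present + 0L, grp)
  values <- sums / counts
  values[counts == 0L] <- NA_real_
  keys <- index %>%
    dplyr::count(.data$key, .data$gene, .data$region, name = "n_probes") %>%
    dplyr::arrange(.data$key)
  values <- values[keys$key, , drop = FALSE]
  structure(list(values = values, keys = keys), class = "region_matrix")
}

#' @export
print.region_matrix <- function(x, ...) {
  cat("<region_matrix>\n")
  cat(sprintf("  %d gene regions x %d samples\n", nrow(x$values), ncol(x$values)))
  cat(sprintf("  probes per region: %s\n",
    paste(range(x$keys$n_probes), collapse = "-")))
  invisible(x)
}

#' Write a region methylation matrix as TSV
#'
#' Rows are composite `"GENE|REGION"` identifiers.
#'
#' @param regions A `region_matrix`.
#' @param path Output path.
#' @export
write_region_matrix <- function(regions, path) {
  write_matrix_tsv(regions$values, path, id_col = "region_key")
}
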