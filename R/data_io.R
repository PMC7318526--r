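#' @importFrom rlang .data
NULL

REGION_CLASSES <- c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "3UTR")

abort_validation <- function(msg) {
  rlang::abort(msg, class = "methylscreen_validation_error")
}

abort_parse <- function(msg) {
  rlang::abort(msg, class = "methylscreen_parse_error")
}

#' Read a numeric matrix from TSV (rows = features, columns = samples)
#'
#' The first column holds feature identifiers; remaining columns are samples.
#' Missing values are encoded as the `na` literal. Lines starting with `#` are
#' treated as provenance comments and skipped.
#'
#' @param path Path to a TSV file.
#' @param na Missing-value literal, default `"NA"`.
#' @return A numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path, na = "NA") {
  df <- read_delim_precise(path, sep = "\t", na = na, char_cols = 1L)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    abort_validation(sprintf("Duplicate row identifiers in %s (e.g. %s).",
      path, ids[duplicated(ids)][1L]))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  m
}

# Base-R delimited reader: strtod parsing is correctly rounded, so values
# written by readr (shortest round-trippable representation) reload exactly.
# The leading `char_cols` columns stay character; the rest must be numeric.
read_delim_precise <- function(path, sep, na = "NA", char_cols = 1L) {
  df <- utils::read.delim(path,
    sep = sep, quote = "", comment.char = "#", header = TRUE,
    colClasses = "character", check.names = FALSE, na.strings = na,
    stringsAsFactors = FALSE
  )
  for (j in setdiff(seq_along(df), seq_len(char_cols))) {
    raw <- df[[j]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw))
    if (length(bad)) {
      abort_parse(sprintf(
        "Non-numeric cell in %s at row %d, column %s (got '%s').",
        path, bad[1L], names(df)[j], raw[bad[1L]]
      ))
    }
    df[[j]] <- num
  }
  tibble::as_tibble(df)
}

#' Write a numeric matrix as TSV
#'
#' Inverse of [read_matrix_tsv()]; values round-trip exactly (shortest
#' round-trippable decimal representation).
#'
#' @param m Numeric matrix with rownames and colnames.
#' @param path Output path.
#' @param id_col Name of the identifier column, default `"id"`.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- tibble::as_tibble(m, rownames = id_col)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read an EPIC-manifest-like probe annotation
#'
#' Expects a CSV with columns `probe_id`, `chromosome`, `position` (1-based,
#' Illumina manifest convention), `cytoband`, `gene_names` and
#' `region_classes` (semicolon-delimited lists, paired positionally, as in the
#' manifest's UCSC RefGene columns), and `snp_masked` (0/1). Empty gene lists
#' denote intergenic probes.
#'
#' @param path Path to the CSV manifest.
#' @return A tibble with one row per probe; list parsing is deferred to
#'   [probe_assignments()].
#' @export
read_probe_manifest <- function(path) {
  df <- readr::read_csv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      probe_id = readr::col_character(),
      chromosome = readr::col_character(),
      position = readr::col_integer(),
      cytoband = readr::col_character(),
      gene_names = readr::col_character(),
      region_classes = readr::col_character(),
      snp_masked = readr::col_integer()
    )
  )
  need <- c("probe_id", "chromosome", "position", "cytoband",
            "gene_names", "region_classes", "snp_masked")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_parse(sprintf("Manifest %s is missing columns: %s.",
      path, paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(df$probe_id)) {
    abort_validation("Duplicate probe ids in manifest.")
  }
  df$gene_names[is.na(df$gene_names)] <- ""
  df$region_classes[is.na(df$region_classes)] <- ""
  df$snp_masked <- as.logical(df$snp_masked)
  # validate pairing now so malformed rows fail at load time, naming the probe
  invisible(probe_assignments(df))
  df
}

#' Expand manifest gene/region lists into (probe, gene, region) assignments
#'
#' Splits the semicolon-delimited `gene_names` and `region_classes` columns
#' positionally: the i-th gene pairs with the i-th region class. Lists of
#' unequal length are a parse error naming the probe. Duplicate (gene, region)
#' pairs for one probe (transcript-level duplicates in real manifests) are
#' deduplicated. Intergenic probes (empty lists) contribute no rows.
#'
#' @param manifest Manifest tibble from [read_probe_manifest()].
#' @return A tibble with columns `probe_id`, `gene`, `region`.
#' @export
probe_assignments <- function(manifest) {
  genes <- stringr::str_split(manifest$gene_names, stringr::fixed(";"))
  regions <- stringr::str_split(manifest$region_classes, stringr::fixed(";"))
  ng <- lengths(genes)
  nr <- lengths(regions)
  empty <- manifest$gene_names == ""
  ng[empty] <- 0L
  genes[empty] <- list(character())
  empty_r <- manifest$region_classes == ""
  nr[empty_r] <- 0L
  regions[empty_r] <- list(character())
  bad <- which(ng != nr)
  if (length(bad)) {
    abort_parse(sprintf(
      "Probe %s: gene list has %d entries but region list has %d.",
      manifest$probe_id[bad[1L]], ng[bad[1L]], nr[bad[1L]]
    ))
  }
  out <- tibble::tibble(
    probe_id = rep(manifest$probe_id, ng),
    gene = unlist(genes),
    region = unlist(regions)
  )
  blank <- out$gene == "" | out$region == ""
  if (any(blank)) {
    abort_parse(sprintf("Probe %s: blank gene or region-class entry.",
      out$probe_id[blank][1L]))
  }
  unknown <- !out$region %in% REGION_CLASSES
  if (any(unknown)) {
    abort_parse(sprintf(
      "Probe %s: region class '%s' is not one of %s.",
      out$probe_id[unknown][1L], out$region[unknown][1L],
      paste(REGION_CLASSES, collapse = ", ")
    ))
  }
  dplyr::distinct(out)
}

#' Read a drug-response replicate table
#'
#' CSV with header `agent,cell_line,replicate,ic50`; IC50 values are molar
#' concentrations and must be strictly positive.
#'
#' @param path Path to the CSV file.
#' @return A tibble with the four columns above.
#' @export
read_drug_replicates <- function(path) {
  df <- read_delim_precise(path, sep = ",", char_cols = 2L)
  need <- c("agent", "cell_line", "replicate", "ic50")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_parse(sprintf("Drug table %s is missing columns: %s.",
      path, paste(miss, collapse = ", ")))
  }
  df$replicate <- as.integer(df$replicate)
  if (any(!is.finite(df$ic50)) || any(df$ic50 <= 0)) {
    bad <- which(!is.finite(df$ic50) | df$ic50 <= 0)[1L]
    abort_validation(sprintf(
      "Non-positive IC50 at row %d (agent %s, cell line %s).",
      bad, df$agent[bad], df$cell_line[bad]
    ))
  }
  df
}

#' Read a transcript expression matrix with its gene map
#'
#' TSV whose first two columns are `transcript_id` and `gene`, followed by one
#' column per sample of log2 normalized expression.
#'
#' @param path Path to the TSV file.
#' @return A list with `values` (transcripts x samples matrix) and `tx_map`
#'   (tibble `transcript_id`, `gene`).
#' @export
read_expression <- function(path) {
  df <- read_delim_precise(path, sep = "\t", char_cols = 2L)
  if (!all(c("transcript_id", "gene") %in% names(df))) {
    abort_parse(sprintf("%s must start with transcript_id and gene columns.", path))
  }
  if (anyDuplicated(df$transcript_id)) {
    abort_validation("Duplicate transcript ids in expression table.")
  }
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$transcript_id
  list(values = m, tx_map = tibble::tibble(transcript_id = df$transcript_id, gene = df$gene))
}

write_expression <- function(expression, path) {
  df <- tibble::as_tibble(expression$values, rownames = "transcript_id")
  df <- dplyr::bind_cols(
    df[, "transcript_id"],
    tibble::tibble(gene = expression$tx_map$gene[match(df$transcript_id, expression$tx_map$transcript_id)]),
    df[, -1L, drop = FALSE]
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Load a complete analysis bundle
#'
#' Reads all tables the pipeline touches, validates cross-table consistency
#' (beta/detection-p axes identical, beta-values inside `[0, 1]`, manifest
#' covers the beta probes), and computes the sample intersection across the
#' required tables. With `align = TRUE` all tables are subset to the shared
#' samples in a canonical order; named samples are never dropped silently —
#' the intersection is recorded in the returned `samples_report`.
#'
#' @param paths Named list of file paths with elements `beta`, `detection_p`,
#'   `manifest`, `drug_response`, `expression`, and optionally `copy_number`,
#'   `candidate_genes`, `candidate_agents`; alternatively the path of a YAML
#'   file holding that named list.
#' @param align Subset all tables to the shared sample set (default `TRUE`).
#' @return A `methyl_bundle` list: `beta`, `detp`, `manifest`, `assignments`,
#'   `drug`, `expression`, `cn`, `candidates`, `samples_report`.
#' @export
load_dataset <- function(paths, align = TRUE) {
  if (is.character(paths) && length(paths) == 1L) {
    paths <- yaml::read_yaml(paths)
  }
  need <- c("beta", "detection_p", "manifest", "drug_response", "expression")
  miss <- setdiff(need, names(paths))
  if (length(miss)) {
    abort_validation(sprintf("Missing input paths: %s.", paste(miss, collapse = ", ")))
  }
  for (p in unlist(paths[need])) {
    if (!file.exists(p)) abort_validation(sprintf("Input file does not exist: %s", p))
  }
  beta <- read_matrix_tsv(paths$beta)
  check_beta_range(beta, paths$beta)
  detp <- read_matrix_tsv(paths$detection_p)
  if (!identical(dim(beta), dim(detp)) ||
      !identical(rownames(beta), rownames(detp)) ||
      !identical(colnames(beta), colnames(detp))) {
    abort_validation("Beta and detection-p matrices must share identical probe and sample axes.")
  }
  manifest <- read_probe_manifest(paths$manifest)
  missing_probes <- setdiff(rownames(beta), manifest$probe_id)
  if (length(missing_probes)) {
    abort_validation(sprintf(
      "%d beta probes absent from the manifest (e.g. %s).",
      length(missing_probes), missing_probes[1L]
    ))
  }
  drug <- read_drug_replicates(paths$drug_response)
  expression <- read_expression(paths$expression)
  cn <- if (!is.null(paths$copy_number)) read_matrix_tsv(paths$copy_number) else NULL
  candidates <- NULL
  if (!is.null(paths$candidate_genes) || !is.null(paths$candidate_agents)) {
    candidates <- list(
      genes = if (!is.null(paths$candidate_genes)) readLines(paths$candidate_genes) else character(),
      agents = if (!is.null(paths$candidate_agents)) readLines(paths$candidate_agents) else character()
    )
  }
  bundle <- new_methyl_bundle(beta, detp, manifest, drug, expression, cn, candidates)
  if (align) bundle <- align_samples(bundle) else bundle$samples_report <- sample_report(bundle)
  bundle
}

check_beta_range <- function(beta, label = "beta") {
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    abort_validation(sprintf(
      "Beta value %.4g outside [0, 1] in %s at probe %s, sample %s.",
      beta[bad[1L, 1L], bad[1L, 2L]], label,
      rownames(beta)[bad[1L, 1L]], colnames(beta)[bad[1L, 2L]]
    ))
  }
  invisible(TRUE)
}

new_methyl_bundle <- function(beta, detp, manifest, drug, expression, cn = NULL,
                              candidates = NULL, samples_report = NULL) {
  structure(
    list(
      beta = beta, detp = detp, manifest = manifest,
      assignments = probe_assignments(manifest),
      drug = drug, expression = expression, cn = cn,
      candidates = candidates, samples_report = samples_report
    ),
    class = "methyl_bundle"
  )
}

sample_report <- function(bundle) {
  sets <- list(
    methylation = colnames(bundle$beta),
    drug_response = unique(bundle$drug$cell_line),
    expression = colnames(bundle$expression$values)
  )
  if (!is.null(bundle$cn)) sets$copy_number <- colnames(bundle$cn)
  shared <- Reduce(intersect, sets[c("methylation", "drug_response", "expression")])
  list(per_table = lapply(sets, length), shared = sort(shared))
}

#' Align a bundle to the shared sample set
#'
#' Subsets methylation, expression and response tables to the intersection of
#' their sample ids, in sorted order, so downstream associations are invariant
#' to input column order. Copy-number samples may be a subset and are aligned
#' to their own intersection with the shared set.
#'
#' @param bundle A `methyl_bundle`.
#' @return The aligned bundle with a populated `samples_report`.
#' @export
align_samples <- function(bundle) {
  rep <- sample_report(bundle)
  shared <- rep$shared
  if (length(shared) < 3L) {
    abort_validation("Fewer than 3 samples shared across methylation, response and expression tables.")
  }
  bundle$beta <- bundle$beta[, shared, drop = FALSE]
  bundle$detp <- bundle$detp[, shared, drop = FALSE]
  bundle$expression$values <- bundle$expression$values[, shared, drop = FALSE]
  bundle$drug <- dplyr::filter(bundle$drug, .data$cell_line %in% shared)
  if (!is.null(bundle$cn)) {
    keep <- intersect(shared, colnames(bundle$cn))
    bundle$cn <- bundle$cn[, keep, drop = FALSE]
  }
  bundle$samples_report <- rep
  bundle
}

#' Write a bundle back to disk
#'
#' Inverse of [load_dataset()]; writes each table in its declared dialect into
#' `dir` and returns the path list, suitable for reloading.
#'
#' @param bundle A `methyl_bundle`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths (invisibly usable with [load_dataset()]).
#' @export
write_dataset <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    beta = file.path(dir, "beta.tsv"),
    detection_p = file.path(dir, "detection_p.tsv"),
    manifest = file.path(dir, "manifest.csv"),
    drug_response = file.path(dir, "drug_replicates.csv"),
    expression = file.path(dir, "expression.tsv")
  )
  write_matrix_tsv(bundle$beta, paths$beta, id_col = "probe_id")
  write_matrix_tsv(bundle$detp, paths$detection_p, id_col = "probe_id")
  readr::write_csv(bundle$manifest %>%
    dplyr::mutate(snp_masked = as.integer(.data$snp_masked)), paths$manifest, progress = FALSE)
  readr::write_csv(bundle$drug, paths$drug_response, progress = FALSE)
  write_expression(bundle$expression, paths$expression)
  if (!is.null(bundle$cn)) {
    paths$copy_number <- file.path(dir, "copy_number.tsv")
    write_matrix_tsv(bundle$cn, paths$copy_number, id_col = "gene")
  }
  if (!is.null(bundle$candidates)) {
    paths$candidate_genes <- file.path(dir, "candidate_genes.txt")
    paths$candidate_agents <- file.path(dir, "candidate_agents.txt")
    writeLines(bundle$candidates$genes, paths$candidate_genes)
    writeLines(bundle$candidates$agents, paths$candidate_agents)
  }
  paths
}

RESULT_COLUMNS <- c(
  "feature_id", "feature_kind", "gene", "region", "agent",
  "coefficient", "p_o", "p_fdr", "passes_strict", "passes_liberal",
  "n_used", "family"
)

#' Write association records as TSV
#'
#' Stable column order and deterministic row order (ascending `p_o`, ties
#' broken by `feature_id` then `agent`). Header comment lines (`#`) may carry
#' provenance such as thresholds.
#'
#' @param records Association record tibble.
#' @param path Output path.
#' @param comments Optional character vector of provenance lines (written with
#'   a leading `#`).
#' @export
write_results <- function(records, path, comments = NULL) {
  for (col in RESULT_COLUMNS) {
    if (!col %in% names(records)) {
      records[[col]] <- if (col %in% c("coefficient", "p_o", "p_fdr")) {
        NA_real_
      } else if (col %in% c("passes_strict", "passes_liberal")) {
        NA
      } else if (col == "n_used") NA_integer_ else NA_character_
    }
  }
  records <- records[, RESULT_COLUMNS]
  records <- dplyr::arrange(records, .data$p_o, .data$feature_id, .data$agent)
  if (!is.null(comments)) {
    writeLines(paste0("# ", comments), path)
    readr::write_tsv(records, path, append = TRUE, col_names = TRUE, progress = FALSE)
  } else {
    readr::write_tsv(records, path, progress = FALSE)
  }
  invisible(path)
}

#' Read association records written by [write_results()]
#'
#' @param path Path to a results TSV.
#' @return The record tibble with its stable column set.
#' @export
read_results <- function(path) {
  readr::read_tsv(path,
    comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      feature_id = readr::col_character(),
      feature_kind = readr::col_character(),
      gene = readr::col_character(),
      region = readr::col_character(),
      agent = readr::col_character(),
      coefficient = readr::col_double(),
      p_o = readr::col_double(),
      p_fdr = readr::col_double(),
      passes_strict = readr::col_logical(),
      passes_liberal = readr::col_logical(),
      n_used = readr::col_integer(),
      family = readr::col_character()
    )
  )
}

#' @export
print.methyl_bundle <- function(x, ...) {
  cat("<methyl_bundle>\n")
  cat(sprintf("  beta:       %d probes x %d samples\n", nrow(x$beta), ncol(x$beta)))
  cat(sprintf("  expression: %d transcripts x %d samples\n",
    nrow(x$expression$values), ncol(x$expression$values)))
  cat(sprintf("  drug:       %d replicate rows, %d agents\n",
    nrow(x$drug), dplyr::n_distinct(x$drug$agent)))
  if (!is.null(x$cn)) cat(sprintf("  copy number: %d genes\n", nrow(x$cn)))
  invisible(x)
}
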