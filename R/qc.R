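#' Mask beta-values with failed detection p-values
#'
#' Sets to missing every beta cell whose detection p-value is at or above
#' `value_threshold` (exclusion at equality, following the convention that
#' detection p >= 1e-3 marks an unreliable measurement). All other cells are
#' unchanged; cells already missing stay missing.
#'
#' @param beta Probe x sample beta matrix.
#' @param detp Detection p-value matrix on identical axes.
#' @param value_threshold Per-cell detection p cutoff, default `1e-3`.
#' @return List with `beta` (masked matrix) and `n_values_masked` (count of
#'   newly masked cells).
#' @export
mask_low_quality_values <- function(beta, detp, value_threshold = 1e-3) {
  check_axes(beta, detp)
  fail <- detp >= value_threshold
  newly <- fail & !is.na(beta)
  beta[fail] <- NA_real_
  list(beta = beta, n_values_masked = sum(newly))
}

#' Drop probes with unreliable median detection p or SNP overlap
#'
#' A probe is removed when its median detection p-value across all samples is
#' at or above `median_threshold` (exclusion at equality), or when the
#' manifest flags it as overlapping a SNP (the external probe-masking
#' recommendation carried as the `snp_masked` flag). The two removal reasons
#' are counted separately; a probe failing both is counted under the median
#' rule.
#'
#' @param detp Detection p-value matrix.
#' @param manifest Probe annotation tibble with `probe_id` and `snp_masked`.
#' @param median_threshold Median detection p cutoff, default `1e-6`.
#' @return List with `retained` (character vector of probe ids, input order),
#'   `dropped_detp`, `dropped_snp` (probe id vectors) and their counts.
#' @export
drop_unreliable_probes <- function(detp, manifest, median_threshold = 1e-6) {
  miss <- setdiff(rownames(detp), manifest$probe_id)
  if (length(miss)) {
    abort_validation(sprintf("Probes absent from manifest (e.g. %s).", miss[1L]))
  }
  med <- apply(detp, 1L, stats::median)
  bad_med <- med >= median_threshold
  snp <- manifest$snp_masked[match(rownames(detp), manifest$probe_id)]
  bad_snp <- snp & !bad_med
  list(
    retained = rownames(detp)[!bad_med & !snp],
    dropped_detp = rownames(detp)[bad_med],
    dropped_snp = rownames(detp)[bad_snp],
    n_probes_dropped_detp = sum(bad_med),
    n_probes_dropped_snp = sum(bad_snp)
  )
}

#' Run the full probe quality-control chain
#'
#' Composition of [mask_low_quality_values()] and [drop_unreliable_probes()]:
#' per-cell masking of detection failures, then removal of probes with bad
#' median detection p or SNP flags. The two steps are per-cell/per-probe
#' local, so their order does not change the retained probe set, and the
#' chain is idempotent.
#'
#' @param bundle A `methyl_bundle` from [load_dataset()] or
#'   [simulate_dataset()].
#' @param value_threshold Per-cell detection p cutoff, default `1e-3`.
#' @param median_threshold Median detection p cutoff, default `1e-6`.
#' @return List with `beta` (filtered, masked matrix), `retained_probes`, and
#'   `report` (a `qc_report`).
#' @export
run_probe_qc <- function(bundle, value_threshold = 1e-3, median_threshold = 1e-6) {
  masked <- mask_low_quality_values(bundle$beta, bundle$detp, value_threshold)
  dropped <- drop_unreliable_probes(bundle$detp, bundle$manifest, median_threshold)
  beta <- masked$beta[dropped$retained, , drop = FALSE]
  report <- structure(
    list(
      n_probes_input = nrow(bundle$beta),
      n_values_masked = masked$n_values_masked,
      n_probes_dropped_detp = dropped$n_probes_dropped_detp,
      n_probes_dropped_snp = dropped$n_probes_dropped_snp,
      n_probes_retained = length(dropped$retained),
      value_threshold = value_threshold,
      median_threshold = median_threshold
    ),
    class = "qc_report"
  )
  stopifnot(report$n_probes_retained + report$n_probes_dropped_detp +
    report$n_probes_dropped_snp == report$n_probes_input)
  list(beta = beta, retained_probes = dropped$retained, report = report)
}

check_axes <- function(a, b) {
  if (!identical(dim(a), dim(b)) ||
      !identical(rownames(a), rownames(b)) ||
      !identical(colnames(a), colnames(b))) {
    abort_validation("Matrices must share identical row and column axes.")
  }
  invisible(TRUE)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  probes in:        %d\n", x$n_probes_input))
  cat(sprintf("  cells masked:     %d (detection p >= %g)\n", x$n_values_masked, x$value_threshold))
  cat(sprintf("  probes dropped:   %d (median detection p >= %g), %d (SNP mask)\n",
    x$n_probes_dropped_detp, x$median_threshold, x$n_probes_dropped_snp))
  cat(sprintf("  probes retained:  %d\n", x$n_probes_retained))
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param report A `qc_report`.
#' @param path Output path for the JSON file.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
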