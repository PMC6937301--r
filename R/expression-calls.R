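#' Presence call from raw read counts
#'
#' A gene is called `expressed` when strictly more than `min_reads` raw
#' reads are observed in at least `min_samples` of its samples, and
#' `not_expressed` otherwise. The strict inequality matters at the
#' boundary: with the default cutoff of 5 reads, a sample with exactly 5
#' reads does not count as detection.
#'
#' @param counts Non-empty vector of non-negative integer raw counts, one
#'   per sample.
#' @param thresholds A [threshold_config()].
#' @return `"expressed"` or `"not_expressed"`.
#' @examples
#' call_expressed_counts(c(0, 0, 0, 0, 0, 6))  # one sample above 5
#' call_expressed_counts(c(5, 5, 5, 5, 5, 5))  # exactly 5 never qualifies
#' @export
call_expressed_counts <- function(counts, thresholds = threshold_config()) {
  thresholds <- .as_thresholds(thresholds)
  if (length(counts) == 0) abort("`counts` must be non-empty")
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    abort("`counts` must be non-negative integers")
  }
  if (sum(counts > thresholds$min_reads) >= thresholds$min_samples) {
    "expressed"
  } else {
    "not_expressed"
  }
}

#' Presence call from microarray raw intensities
#'
#' A gene is `expressed` when any of its probes reaches the minimum raw
#' intensity (inclusive — a minimum threshold of 40 units means an
#' intensity of exactly 40 qualifies). Probes are redundant detectors of
#' the same transcript, so one passing probe suffices. A gene with no
#' probes on the array is `not_measured`.
#'
#' @param intensities Numeric vector of probe intensities for one gene
#'   (replicate-averaged); may be empty.
#' @inheritParams call_expressed_counts
#' @return `"expressed"`, `"not_expressed"` or `"not_measured"`.
#' @examples
#' call_expressed_microarray(40)            # the minimum qualifies
#' call_expressed_microarray(c(39.9, 12))   # all below
#' call_expressed_microarray(numeric(0))    # not on the array
#' @export
call_expressed_microarray <- function(intensities,
                                      thresholds = threshold_config()) {
  thresholds <- .as_thresholds(thresholds)
  if (length(intensities) == 0) return("not_measured")
  if (anyNA(intensities) || any(intensities < 0)) {
    abort("intensities must be non-negative")
  }
  if (any(intensities >= thresholds$array_min_intensity)) {
    "expressed"
  } else {
    "not_expressed"
  }
}

#' Presence calls for every gene in a count table
#'
#' Applies [call_expressed_counts()] row-wise. Genes in `universe` but
#' absent from the table are reported `not_measured`.
#'
#' @param counts Wide count tibble (`gene_id` + one column per sample), as
#'   returned by [read_count_table()].
#' @param thresholds A [threshold_config()].
#' @param universe Optional character vector of gene ids defining the
#'   measured-plus-unmeasured universe; defaults to the table's genes.
#' @return A tibble `gene_id`, `status`.
#' @export
call_expression_counts <- function(counts, thresholds = threshold_config(),
                                   universe = NULL) {
  thresholds <- .as_thresholds(thresholds)
  .validate_counts(counts, "counts")
  mat <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  if (ncol(mat) == 0) abort("count table has no sample columns")
  hits <- rowSums(mat > thresholds$min_reads)
  calls <- tibble(
    gene_id = counts$gene_id,
    status = ifelse(hits >= thresholds$min_samples,
                    "expressed", "not_expressed")
  )
  .complete_universe(calls, universe)
}

#' Presence calls for every gene on a microarray
#'
#' Intensities are first averaged across arrays per probe (the default
#' replicate handling; set `average_replicates = FALSE` to let any single
#' array's intensity count), then a gene is `expressed` when any of its
#' mapped probes passes the intensity cutoff. Unmapped probes carry no gene
#' evidence and are ignored. Genes in `universe` without any probe are
#' `not_measured`.
#'
#' @param intensities Probe-level tibble from [read_intensity_table()].
#' @param thresholds A [threshold_config()].
#' @param universe Optional gene universe (character).
#' @param average_replicates Average intensities across arrays before
#'   thresholding (default) or threshold each array individually.
#' @return A tibble `gene_id`, `status`.
#' @export
call_expression_array <- function(intensities,
                                  thresholds = threshold_config(),
                                  universe = NULL,
                                  average_replicates = TRUE) {
  thresholds <- .as_thresholds(thresholds)
  value_cols <- setdiff(names(intensities), c("probe_id", "gene_id"))
  if (length(value_cols) == 0) abort("intensity table has no array columns")
  mat <- as.matrix(intensities[value_cols])
  probe_pass <- if (average_replicates) {
    rowMeans(mat) >= thresholds$array_min_intensity
  } else {
    rowSums(mat >= thresholds$array_min_intensity) > 0
  }
  calls <- tibble(gene_id = intensities$gene_id, pass = probe_pass) |>
    dplyr::filter(!is.na(.data$gene_id)) |>
    dplyr::summarise(pass = any(.data$pass), .by = "gene_id") |>
    dplyr::mutate(status = ifelse(.data$pass, "expressed", "not_expressed")) |>
    dplyr::select("gene_id", "status")
  .complete_universe(calls, universe)
}

.complete_universe <- function(calls, universe) {
  if (is.null(universe)) return(calls)
  missing <- setdiff(universe, calls$gene_id)
  dplyr::bind_rows(
    calls[calls$gene_id %in% universe, ],
    tibble(gene_id = missing, status = "not_measured")
  ) |>
    dplyr::arrange(match(.data$gene_id, universe))
}

#' Consensus of the two oocyte reference datasets
#'
#' The oocyte side of the origin classifier rests on two independent
#' references (a microarray study and an RNA-seq study). Their tri-state
#' calls are combined per gene: both expressed is a confident `expressed`;
#' expressed in exactly one (whether the other says `not_expressed` or was
#' never measured) is `ambiguous`, which downstream becomes the
#' `provisional` origin label; anything else is `not_expressed`. Treating
#' `not_measured` as not-found means absence of evidence on one platform
#' never silently upgrades a single detection to a confident call.
#'
#' @param call_a,call_b Status vectors (`expressed` / `not_expressed` /
#'   `not_measured`), recycled to a common length.
#' @return Character vector in `expressed`, `not_expressed`, `ambiguous`.
#' @examples
#' oocyte_consensus("expressed", "expressed")
#' oocyte_consensus("expressed", "not_expressed")   # provisional evidence
#' oocyte_consensus("not_measured", "not_expressed")
#' @export
oocyte_consensus <- function(call_a, call_b) {
  .assert_status(call_a, "call_a")
  .assert_status(call_b, "call_b")
  n <- max(length(call_a), length(call_b))
  a <- rep_len(call_a, n) == "expressed"
  b <- rep_len(call_b, n) == "expressed"
  dplyr::case_when(
    a & b ~ "expressed",
    xor(a, b) ~ "ambiguous",
    .default = "not_expressed"
  )
}

#' Consensus calls across a gene universe
#'
#' Joins two per-gene call tables (genes absent from one table are treated
#' as `not_measured` there) and applies [oocyte_consensus()].
#'
#' @param calls_a,calls_b Tibbles `gene_id`, `status`.
#' @param universe Gene universe; defaults to the union of both tables.
#' @return A tibble `gene_id`, `status_a`, `status_b`, `consensus`.
#' @export
consensus_calls <- function(calls_a, calls_b, universe = NULL) {
  if (is.null(universe)) universe <- union(calls_a$gene_id, calls_b$gene_id)
  a <- .complete_universe(calls_a, universe)
  b <- .complete_universe(calls_b, universe)
  tibble(
    gene_id = universe,
    status_a = a$status[match(universe, a$gene_id)],
    status_b = b$status[match(universe, b$gene_id)]
  ) |>
    dplyr::mutate(consensus = oocyte_consensus(.data$status_a, .data$status_b))
}
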