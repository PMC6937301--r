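#' Paired t-test with degenerate-case conventions
#'
#' Two-sided paired t-test on differences `x - y`: `t = mean(d) / (sd(d) /
#' sqrt(n))` with `n - 1` degrees of freedom. Used both for the qPCR
#' normalized-expression (delta-CT) comparison and for the replicate-paired
#' embryo rate comparison. Degenerate inputs follow fixed conventions
#' rather than erroring: all-zero differences give t = 0, p = 1; constant
#' nonzero differences have zero variance and an unbounded statistic, which
#' is reported as t = +/-Inf, p = 0 with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 2 (replicate-paired).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_diff`.
#' @examples
#' paired_t_test(c(2, 3, 4), c(1, 1, 1))  # differences 1, 2, 3
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must be the same length")
  if (length(x) < 2) abort("paired t-test needs at least 2 pairs")
  if (anyNA(x) || anyNA(y)) abort("paired t-test inputs must not contain NA")
  d <- x - y
  n <- length(d)
  stderr <- sd(d) / sqrt(n)
  # same essentially-constant criterion t.test uses, resolved by convention
  # instead of an error
  if (stderr <= 10 * .Machine$double.eps * abs(mean(d)) || sd(d) == 0) {
    if (mean(d) == 0) {
      return(tibble(statistic = 0, df = n - 1, p_value = 1, mean_diff = 0))
    }
    warn("differences have zero variance; t statistic is unbounded, p reported as 0")
    return(tibble(statistic = sign(mean(d)) * Inf, df = n - 1,
                  p_value = 0, mean_diff = mean(d)))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, mean_diff = unname(ht$estimate))
}

#' Select the most stable qPCR reference gene
#'
#' Candidate housekeeping genes are ranked by the standard deviation of
#' their raw CT values across all quantifiable samples (CT at or below the
#' quantification limit); the gene with the smallest SD is the most stable
#' and is selected, ties broken lexicographically by gene id. Candidates
#' with fewer than 2 quantifiable CTs carry no stability information and
#' are excluded with a warning.
#'
#' @param qpcr A qPCR tibble from [read_qpcr_table()].
#' @param candidates Character vector (>= 2) of candidate gene ids.
#' @param thresholds A [threshold_config()] (supplies `ct_max`).
#' @return The selected gene id (length-1 character).
#' @export
select_reference_gene <- function(qpcr, candidates,
                                  thresholds = threshold_config()) {
  thresholds <- .as_thresholds(thresholds)
  if (length(candidates) < 2) abort("need at least 2 candidate reference genes")
  stab <- qpcr |>
    dplyr::filter(.data$gene_id %in% candidates,
                  !is.na(.data$ct), .data$ct <= thresholds$ct_max) |>
    dplyr::summarise(n_ct = dplyr::n(), ct_sd = sd(.data$ct),
                     .by = "gene_id")
  usable <- dplyr::filter(stab, .data$n_ct >= 2)
  excluded <- setdiff(candidates, usable$gene_id)
  if (length(excluded)) {
    warn(sprintf("candidate(s) excluded (< 2 quantifiable CTs): %s",
                 paste(excluded, collapse = ", ")))
  }
  if (nrow(usable) == 0) {
    abort("no candidate reference gene has >= 2 quantifiable CTs")
  }
  usable |>
    dplyr::arrange(.data$ct_sd, .data$gene_id) |>
    dplyr::pull("gene_id") |>
    head(1)
}

#' Relative fold change by the 2^-ddCT method
#'
#' Normalizes the target gene to the reference within each condition
#' (`dCT = CT_target - CT_reference`), takes the case-minus-control
#' difference (`ddCT`) and reports `fold = 2^-ddCT`. Any of the four input
#' CTs missing or above the quantification limit (`ct_max`, default 33
#' cycles) makes the replicate unquantifiable — a value, not an error,
#' since reactions past the limit are routinely reported as such.
#'
#' @param ct_target_case,ct_ref_case CT of target and reference gene in the
#'   case condition (may be `NA`).
#' @param ct_target_control,ct_ref_control Same for the control condition.
#' @param thresholds A [threshold_config()].
#' @return A one-row tibble: `fold`, `delta_ct_case`, `delta_ct_control`,
#'   `quantifiable`; `fold` and the dCTs are `NA` when unquantifiable.
#' @examples
#' fold_change_ddct(20, 15, 22, 15)  # ddCT = -2, fold = 4
#' fold_change_ddct(34, 15, 22, 15)  # beyond the limit of quantification
#' @export
fold_change_ddct <- function(ct_target_case, ct_ref_case,
                             ct_target_control, ct_ref_control,
                             thresholds = threshold_config()) {
  thresholds <- .as_thresholds(thresholds)
  cts <- c(ct_target_case, ct_ref_case, ct_target_control, ct_ref_control)
  if (length(cts) != 4) abort("each CT argument must be a single value")
  if (anyNA(cts) || any(cts > thresholds$ct_max)) {
    return(tibble(fold = NA_real_, delta_ct_case = NA_real_,
                  delta_ct_control = NA_real_, quantifiable = FALSE))
  }
  d_case <- unname(ct_target_case - ct_ref_case)
  d_ctrl <- unname(ct_target_control - ct_ref_control)
  tibble(fold = 2^(-(d_case - d_ctrl)), delta_ct_case = d_case,
         delta_ct_control = d_ctrl, quantifiable = TRUE)
}

#' Per-replicate fold changes for one gene from a qPCR table
#'
#' Pairs the target and reference CTs of each replicate across the two
#' conditions and applies [fold_change_ddct()].
#'
#' @param qpcr A qPCR tibble from [read_qpcr_table()].
#' @param gene Target gene id.
#' @param reference Reference gene id (see [select_reference_gene()]).
#' @param case_group,control_group Group labels forming the comparison
#'   (defaults: high vs low fertility).
#' @param thresholds A [threshold_config()].
#' @return A tibble with one row per replicate: `gene_id`, `replicate`,
#'   `fold`, `delta_ct_case`, `delta_ct_control`, `quantifiable`.
#' @export
compute_fold_changes <- function(qpcr, gene, reference,
                                 case_group = "high", control_group = "low",
                                 thresholds = threshold_config()) {
  thresholds <- .as_thresholds(thresholds)
  pick <- function(rep, grp, g) {
    v <- qpcr$ct[qpcr$replicate == rep & qpcr$group == grp & qpcr$gene_id == g]
    if (length(v) == 0) NA_real_ else v[1]
  }
  reps <- sort(unique(qpcr$replicate[qpcr$gene_id == gene]))
  if (length(reps) == 0) abort(sprintf("gene '%s' absent from qPCR table", gene))
  purrr::map_dfr(reps, function(r) {
    rec <- fold_change_ddct(pick(r, case_group, gene),
                            pick(r, case_group, reference),
                            pick(r, control_group, gene),
                            pick(r, control_group, reference),
                            thresholds)
    dplyr::bind_cols(tibble(gene_id = gene, replicate = r), rec)
  })
}

#' Summarize qPCR validation of a sequencing result
#'
#' A replicate individually validates the sequencing result when its fold
#' change exceeds the concordance cutoff in the sequencing direction: fold
#' >= `fold_validation` for an up-regulated gene, fold <= `1 /
#' fold_validation` for a down-regulated one (both boundaries inclusive).
#' The mean and SD of the quantifiable replicate folds are reported
#' (arithmetic mean of folds; see the vignette for the geometric
#' alternative), along with a two-sided paired t-test on the normalized
#' expression values (delta-CT case vs control) across quantifiable
#' replicates. When no replicate is quantifiable the summary carries the
#' unquantifiable flag and NA statistics.
#'
#' @param folds Per-replicate tibble from [compute_fold_changes()].
#' @param rnaseq_direction `"up"` or `"down"`: the sequencing direction the
#'   replicates are checked against.
#' @param thresholds A [threshold_config()].
#' @param mean_type `"arithmetic"` (default) or `"geometric"` mean of
#'   replicate folds.
#' @return A one-row tibble: `gene_id`, `rnaseq_direction`,
#'   `n_quantifiable`, `n_validated`, `mean_fold`, `sd_fold`,
#'   `paired_t_p`, `quantifiable`.
#' @export
summarize_validation <- function(folds, rnaseq_direction = c("up", "down"),
                                 thresholds = threshold_config(),
                                 mean_type = c("arithmetic", "geometric")) {
  rnaseq_direction <- match.arg(rnaseq_direction)
  mean_type <- match.arg(mean_type)
  thresholds <- .as_thresholds(thresholds)
  gene <- folds$gene_id[1]
  q <- dplyr::filter(folds, .data$quantifiable)
  if (nrow(q) == 0) {
    return(tibble(gene_id = gene, rnaseq_direction = rnaseq_direction,
                  n_quantifiable = 0L, n_validated = 0L,
                  mean_fold = NA_real_, sd_fold = NA_real_,
                  paired_t_p = NA_real_, quantifiable = FALSE))
  }
  validated <- if (rnaseq_direction == "up") {
    q$fold >= thresholds$fold_validation
  } else {
    q$fold <= 1 / thresholds$fold_validation
  }
  mean_fold <- if (mean_type == "arithmetic") {
    mean(q$fold)
  } else {
    exp(mean(log(q$fold)))
  }
  p <- if (nrow(q) >= 2) {
    paired_t_test(q$delta_ct_case, q$delta_ct_control)$p_value
  } else {
    NA_real_
  }
  tibble(gene_id = gene, rnaseq_direction = rnaseq_direction,
         n_quantifiable = nrow(q), n_validated = sum(validated),
         mean_fold = mean_fold, sd_fold = sd(q$fold),
         paired_t_p = p, quantifiable = TRUE)
}

#' Validate a panel of genes against sequencing directions
#'
#' Convenience driver over [compute_fold_changes()] and
#' [summarize_validation()] producing one summary row per gene — the shape
#' of a published validation table (gene, mean fold, SD, validated
#' replicates, p).
#'
#' @param qpcr A qPCR tibble.
#' @param directions Tibble `gene_id`, `direction` (`up`/`down`), typically
#'   derived from the sign of the DE log2 fold change.
#' @param reference Reference gene id.
#' @inheritParams compute_fold_changes
#' @return A tibble with one row per gene.
#' @export
validate_genes <- function(qpcr, directions, reference,
                           case_group = "high", control_group = "low",
                           thresholds = threshold_config()) {
  purrr::map2_dfr(directions$gene_id, directions$direction, function(g, d) {
    compute_fold_changes(qpcr, g, reference, case_group, control_group,
                         thresholds) |>
      summarize_validation(d, thresholds)
  })
}
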