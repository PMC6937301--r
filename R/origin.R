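#' Parental-origin label for embryo-expressed genes
#'
#' Given that a gene is expressed in the 2-4 cell embryo, its parental
#' origin follows from presence in the gamete datasets: detected in both
#' sperm and the oocyte consensus it is `sperm_and_oocyte`; in exactly one,
#' `sperm_only` or `oocyte_only`; in neither, `embryo_only` (a candidate
#' minor-EGA transcript). When the two oocyte references disagree the
#' consensus is ambiguous and the gene is labeled `provisional`, whatever
#' the sperm evidence — provisional genes are excluded from the confident
#' category counts.
#'
#' @param embryo Embryo status; must be `"expressed"` for every element
#'   (non-expressed genes are omitted from origin analysis upstream).
#' @param sperm Sperm status vector (`not_measured` counts as not found).
#' @param oocyte Oocyte consensus vector from [oocyte_consensus()].
#' @return Character vector of origin labels (see [origin_labels()]).
#' @examples
#' classify_origin("expressed", "expressed", "expressed")  # both gametes
#' classify_origin("expressed", "not_expressed", "not_expressed")
#' classify_origin("expressed", "expressed", "ambiguous")  # provisional
#' @export
classify_origin <- function(embryo, sperm, oocyte) {
  .assert_status(embryo, "embryo")
  .assert_status(sperm, "sperm")
  bad <- setdiff(unique(oocyte), .consensus_levels)
  if (length(bad)) {
    abort(sprintf("`oocyte` contains invalid consensus value(s): %s",
                  paste(bad, collapse = ", ")))
  }
  n <- max(length(embryo), length(sperm), length(oocyte))
  embryo <- rep_len(embryo, n)
  if (any(embryo != "expressed")) {
    abort("classify_origin() is defined only for embryo-expressed genes")
  }
  sp <- rep_len(sperm, n) == "expressed"
  oo <- rep_len(oocyte, n)
  dplyr::case_when(
    oo == "ambiguous" ~ "provisional",
    sp & oo == "expressed" ~ "sperm_and_oocyte",
    sp ~ "sperm_only",
    oo == "expressed" ~ "oocyte_only",
    .default = "embryo_only"
  )
}

#' Classify the parental origin of every embryo-expressed gene
#'
#' Runs the full origin assignment: genes not called expressed in the
#' embryo are omitted; the two oocyte references are merged into a
#' consensus; each remaining gene receives exactly one of the five labels.
#' Call tables are joined by exact `gene_id` match; genes absent from a
#' gamete call table are `not_measured` there.
#'
#' @param embryo_calls,sperm_calls Tibbles `gene_id`, `status`.
#' @param oocyte_calls_a,oocyte_calls_b Call tibbles for the two oocyte
#'   reference datasets.
#' @return An `origin_assignments` tibble: `gene_id`, per-dataset evidence
#'   columns (`embryo`, `sperm`, `oocyte_ref1`, `oocyte_ref2`,
#'   `oocyte_consensus`) and `label`.
#' @seealso [origin_summary()], [annotate_de_origins()],
#'   [ggplot2::autoplot()] for a category bar chart.
#' @export
classify_origins <- function(embryo_calls, sperm_calls,
                             oocyte_calls_a, oocyte_calls_b) {
  expressed <- embryo_calls$gene_id[embryo_calls$status == "expressed"]
  if (length(expressed) == 0) {
    warn("no gene is expressed in the embryo; returning an empty assignment table")
  }
  sperm <- .complete_universe(sperm_calls, expressed)
  oo <- consensus_calls(oocyte_calls_a, oocyte_calls_b, universe = expressed)
  out <- tibble(
    gene_id = expressed,
    embryo = "expressed",
    sperm = sperm$status[match(expressed, sperm$gene_id)],
    oocyte_ref1 = oo$status_a,
    oocyte_ref2 = oo$status_b,
    oocyte_consensus = oo$consensus
  )
  out$label <- if (nrow(out)) {
    classify_origin(out$embryo, out$sperm, out$oocyte_consensus)
  } else {
    character(0)
  }
  stopifnot(all(out$label != "provisional" | out$oocyte_consensus == "ambiguous"),
            !anyDuplicated(out$gene_id))
  class(out) <- c("origin_assignments", class(out))
  out
}

#' Summarize an origin assignment table
#'
#' Counts genes per confident category and provisionally-labeled genes.
#' The four confident counts sum to `total_confident`, and adding the
#' provisional count gives `total_embryo_expressed` — the partition
#' invariant of the classifier, asserted on every call.
#'
#' @param assignments An `origin_assignments` tibble, or any tibble with a
#'   `label` column drawn from [origin_labels()].
#' @return A one-row tibble with a count per label plus
#'   `total_confident` and `total_embryo_expressed`.
#' @export
origin_summary <- function(assignments) {
  bad <- setdiff(unique(assignments$label), .origin_labels)
  if (length(bad)) {
    abort(sprintf("unknown origin label(s): %s", paste(bad, collapse = ", ")))
  }
  counts <- table(factor(assignments$label, levels = .origin_labels))
  out <- as_tibble(as.list(counts)) |>
    dplyr::mutate(dplyr::across(dplyr::everything(), as.integer))
  out$total_confident <- sum(counts[.confident_labels])
  out$total_embryo_expressed <- out$total_confident + out$provisional
  stopifnot(out$total_embryo_expressed == nrow(assignments))
  out
}

#' Build an origin summary from per-category counts
#'
#' Reporting-layer constructor for when only category totals are known
#' (e.g. re-checking a published breakdown): returns the same one-row
#' summary as [origin_summary()], with the sum invariants recomputed from
#' the inputs.
#'
#' @param sperm_and_oocyte,oocyte_only,sperm_only,embryo_only,provisional
#'   Non-negative integer gene counts per category.
#' @return A one-row summary tibble.
#' @examples
#' origin_summary_from_counts(2675, 2575, 472, 663)
#' @export
origin_summary_from_counts <- function(sperm_and_oocyte, oocyte_only,
                                       sperm_only, embryo_only,
                                       provisional = 0L) {
  counts <- c(sperm_and_oocyte = sperm_and_oocyte, oocyte_only = oocyte_only,
              sperm_only = sperm_only, embryo_only = embryo_only,
              provisional = provisional)
  if (any(counts < 0 | counts != floor(counts))) {
    abort("category counts must be non-negative integers")
  }
  tibble(
    sperm_and_oocyte = as.integer(sperm_and_oocyte),
    oocyte_only = as.integer(oocyte_only),
    sperm_only = as.integer(sperm_only),
    embryo_only = as.integer(embryo_only),
    provisional = as.integer(provisional),
    total_confident = as.integer(sperm_and_oocyte + oocyte_only +
                                   sperm_only + embryo_only),
    total_embryo_expressed = as.integer(sperm_and_oocyte + oocyte_only +
                                          sperm_only + embryo_only + provisional)
  )
}

#' @method glance origin_assignments
#' @export
glance.origin_assignments <- function(x, ...) origin_summary(x)

#' Origin breakdown of significant differentially expressed genes
#'
#' Cross-tabulates the significant genes of a differential-expression
#' result by their parental-origin label. Every significant gene must be
#' present in the assignment table; the per-label counts sum to the number
#' of significant genes.
#'
#' @param de A `de_fit` from [run_de()] or its [tidy()] tibble (needs
#'   `gene_id` and `significant` columns).
#' @param assignments An `origin_assignments` tibble.
#' @return A one-row tibble: count per label, `total_resolved` (confident
#'   labels only) and `total_significant`.
#' @export
annotate_de_origins <- function(de, assignments) {
  if (inherits(de, "de_fit")) de <- tidy(de)
  sig <- de$gene_id[de$significant %in% TRUE]
  missing <- setdiff(sig, assignments$gene_id)
  if (length(missing)) {
    abort(sprintf("significant gene(s) missing from origin assignments: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  labels <- assignments$label[match(sig, assignments$gene_id)]
  counts <- table(factor(labels, levels = .origin_labels))
  out <- as_tibble(as.list(counts)) |>
    dplyr::mutate(dplyr::across(dplyr::everything(), as.integer))
  out$total_resolved <- sum(counts[.confident_labels])
  out$total_significant <- length(sig)
  stopifnot(out$total_resolved + out$provisional == out$total_significant)
  out
}

#' Bar chart of origin categories
#'
#' @param object An `origin_assignments` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot origin_assignments
#' @export
autoplot.origin_assignments <- function(object, ...) {
  smry <- origin_summary(object)
  df <- tidyr::pivot_longer(smry[.origin_labels], dplyr::everything(),
                            names_to = "label", values_to = "n_genes")
  df$label <- factor(df$label, levels = .origin_labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$n_genes,
                                   fill = .data$label == "provisional")) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_genes), vjust = -0.4,
                       size = 3) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey30",
                                          `TRUE` = "grey70")) +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Parental origin of embryo-expressed RNAs",
                  subtitle = sprintf("%d characterized, %d provisional",
                                     smry$total_confident, smry$provisional)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Write an origin assignment table as TSV
#'
#' Fixed column order: `gene_id`, `embryo`, `sperm`, `oocyte_ref1`,
#' `oocyte_ref2`, `oocyte_consensus`, `label`.
#'
#' @param assignments An `origin_assignments` tibble.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_origin_table <- function(assignments, file) {
  cols <- c("gene_id", "embryo", "sperm", "oocyte_ref1", "oocyte_ref2",
            "oocyte_consensus", "label")
  readr::write_tsv(assignments[cols], file, progress = FALSE)
  invisible(file)
}
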