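#' Build a sample sheet
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param tissue One of `"embryo"`, `"sperm"`, `"oocyte"` per sample.
#' @param fertility_group One of `"high"`, `"low"`, `"none"` per sample;
#'   must be `"none"` for non-embryo tissues.
#' @param replicate Positive integer replicate index per sample.
#'
#' @return A tibble with one row per sample.
#' @examples
#' sample_sheet(c("E1", "E2"), "embryo", c("high", "low"), 1)
#' @export
sample_sheet <- function(sample_id, tissue, fertility_group = "none",
                         replicate = 1L) {
  sheet <- tibble(
    sample_id = as.character(sample_id),
    tissue = tissue,
    fertility_group = fertility_group,
    replicate = as.integer(replicate)
  )
  if (anyDuplicated(sheet$sample_id)) {
    abort("sample identifiers must be unique")
  }
  bad_tissue <- setdiff(unique(sheet$tissue), c("embryo", "sperm", "oocyte"))
  if (length(bad_tissue)) {
    abort(sprintf("unknown tissue: %s", paste(bad_tissue, collapse = ", ")))
  }
  bad_grp <- setdiff(unique(sheet$fertility_group), c("high", "low", "none"))
  if (length(bad_grp)) {
    abort(sprintf("unknown fertility_group: %s", paste(bad_grp, collapse = ", ")))
  }
  off <- sheet$tissue != "embryo" & sheet$fertility_group != "none"
  if (any(off)) {
    abort(sprintf("fertility_group must be 'none' for non-embryo sample(s): %s",
                  paste(sheet$sample_id[off], collapse = ", ")))
  }
  if (any(sheet$replicate < 1L | is.na(sheet$replicate))) {
    abort("replicate must be a positive integer")
  }
  sheet
}

.validate_counts <- function(tbl, source = "counts") {
  if (anyDuplicated(tbl$gene_id)) {
    dup <- unique(tbl$gene_id[duplicated(tbl$gene_id)])
    abort(sprintf("duplicate gene_id in %s: %s", source,
                  paste(head(dup, 5), collapse = ", ")))
  }
  mat <- as.matrix(tbl[setdiff(names(tbl), "gene_id")])
  if (!is.numeric(mat)) abort(sprintf("non-numeric count in %s", source))
  bad <- which(!is.finite(mat) | mat < 0 | mat != floor(mat), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    g <- tbl$gene_id[bad[1, 1]]
    abort(sprintf(
      "invalid count for gene '%s', sample '%s' in %s: counts must be non-negative integers",
      g, colnames(mat)[bad[1, 2]], source))
  }
  invisible(tbl)
}

.drop_htseq_summary <- function(tbl, source) {
  summary_rows <- stringr::str_starts(tbl$gene_id, stringr::fixed("__"))
  if (any(summary_rows)) {
    inform(sprintf("dropped %d HTSeq summary row(s) from %s: %s",
                   sum(summary_rows), source,
                   paste(tbl$gene_id[summary_rows], collapse = ", ")))
    tbl <- tbl[!summary_rows, , drop = FALSE]
  }
  tbl
}

#' Read a gene-level read-count table
#'
#' Accepts either the two-column per-sample dialect written by HTSeq-count
#' (tab-separated `gene_id<TAB>count`, no header) or a wide multi-sample TSV
#' whose header starts with `gene_id` followed by one column per sample.
#' HTSeq summary rows (identifiers starting with a double underscore, e.g.
#' `__no_feature`) are dropped on read and their removal reported; they are
#' not genes and would corrupt presence calling. Counts must be raw
#' (unnormalized) non-negative integers — the presence thresholds are
#' defined on read counts, so normalized input is rejected.
#'
#' @param file Path to a wide multi-sample TSV, or (with `sample_id`) a
#'   single two-column HTSeq file.
#' @param sample_id Sample name to assign when `file` is a headerless
#'   two-column HTSeq file; leave `NULL` for wide input.
#'
#' @return A tibble with a `gene_id` column followed by one integer column
#'   per sample.
#' @seealso [read_count_files()] to assemble several HTSeq files,
#'   [write_count_table()] for the inverse.
#' @export
read_count_table <- function(file, sample_id = NULL) {
  if (!is.null(sample_id)) {
    tbl <- readr::read_tsv(file, col_names = c("gene_id", sample_id),
                           col_types = readr::cols(
                             gene_id = readr::col_character(),
                             .default = readr::col_double()),
                           progress = FALSE)
  } else {
    tbl <- readr::read_tsv(file, col_types = readr::cols(
      gene_id = readr::col_character(), .default = readr::col_double()),
      progress = FALSE)
    if (names(tbl)[1] != "gene_id") {
      abort("wide count tables must have a header starting with 'gene_id'")
    }
  }
  src <- if (is.character(file) && length(file) == 1 && !grepl("\n", file)) {
    file
  } else {
    "count input"
  }
  tbl <- .drop_htseq_summary(tbl, src)
  .validate_counts(tbl, src)
  dplyr::mutate(tbl, dplyr::across(-"gene_id", as.integer))
}

#' Read several HTSeq-count files into one count table
#'
#' @param files Named character vector of paths; names become sample ids.
#' @return A wide count tibble (`gene_id` + one column per sample).
#' @export
read_count_files <- function(files) {
  if (is.null(names(files)) || any(names(files) == "")) {
    abort("`files` must be a named character vector (names are sample ids)")
  }
  tabs <- purrr::imap(files, function(f, sid) read_count_table(f, sample_id = sid))
  out <- purrr::reduce(tabs, dplyr::full_join, by = "gene_id")
  if (anyNA(out)) {
    abort("samples disagree on the gene universe: every file must list every gene")
  }
  out
}

#' Write a count table as wide TSV
#'
#' Inverse of [read_count_table()]: `read_count_table(write_count_table(x))`
#' reproduces `x` byte-identically (summary rows having been removed on read).
#'
#' @param tbl Wide count tibble.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_count_table <- function(tbl, file) {
  .validate_counts(tbl, "counts")
  readr::write_tsv(tbl, file, progress = FALSE)
  invisible(file)
}

#' Read a microarray raw-intensity table and probe-to-gene map
#'
#' The intensity table is a TSV with a `probe_id` header column followed by
#' one raw-intensity column per array; the map is a two-column TSV
#' (`probe_id`, `gene_id`, no header). Many probes may map to one gene;
#' a probe mapped to several distinct genes is ambiguous and rejected.
#' Probes absent from the map are retained with `gene_id = NA` and counted
#' in a message, so that the measured universe is preserved.
#'
#' @param file Intensity TSV path or literal text.
#' @param map_file Probe-to-gene two-column TSV path or literal text.
#' @return A tibble: `probe_id`, `gene_id` (NA when unmapped), then one
#'   numeric intensity column per array.
#' @export
read_intensity_table <- function(file, map_file) {
  tbl <- readr::read_tsv(file, col_types = readr::cols(
    probe_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  if (names(tbl)[1] != "probe_id") {
    abort("intensity tables must have a header starting with 'probe_id'")
  }
  if (anyDuplicated(tbl$probe_id)) {
    abort(sprintf("duplicate probe_id: %s",
                  tbl$probe_id[duplicated(tbl$probe_id)][1]))
  }
  mat <- as.matrix(tbl[-1])
  bad <- which(!is.finite(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("invalid intensity for probe '%s': intensities must be finite and >= 0",
                  tbl$probe_id[bad[1, 1]]))
  }
  map <- readr::read_tsv(map_file, col_names = c("probe_id", "gene_id"),
                         col_types = "cc", progress = FALSE)
  amb <- map |>
    dplyr::distinct() |>
    dplyr::count(.data$probe_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(amb) > 0) {
    abort(sprintf("probe(s) mapped to multiple genes (ambiguous): %s",
                  paste(head(amb$probe_id, 5), collapse = ", ")))
  }
  missing_probe <- setdiff(map$probe_id, tbl$probe_id)
  if (length(missing_probe)) {
    abort(sprintf("probe(s) in map but absent from intensity table: %s",
                  paste(head(missing_probe, 5), collapse = ", ")))
  }
  out <- dplyr::left_join(tbl, dplyr::distinct(map), by = "probe_id") |>
    dplyr::relocate("probe_id", "gene_id")
  n_unmapped <- sum(is.na(out$gene_id))
  if (n_unmapped > 0) {
    inform(sprintf("%d probe(s) have no gene mapping and are flagged unmapped",
                   n_unmapped))
  }
  out
}

#' Read a qPCR cycle-threshold table
#'
#' CSV with header `replicate,group,gene_id,ct`. Empty CT cells are kept as
#' missing (`NA`): a missing CT means the reaction did not cross threshold,
#' which downstream analysis treats as unquantifiable, not as an error.
#' Group labels must come from the high/low (fertility comparison) or
#' treated/control (knockdown comparison) vocabularies.
#'
#' @param file CSV path or literal text.
#' @return A tibble: `replicate` (int), `group` (chr), `gene_id` (chr),
#'   `ct` (dbl, possibly NA).
#' @export
read_qpcr_table <- function(file) {
  tbl <- readr::read_csv(file, col_types = readr::cols(
    replicate = readr::col_integer(), group = readr::col_character(),
    gene_id = readr::col_character(), ct = readr::col_double()),
    progress = FALSE)
  if (!identical(names(tbl), c("replicate", "group", "gene_id", "ct"))) {
    abort("qPCR tables must have columns replicate, group, gene_id, ct")
  }
  bad_grp <- setdiff(unique(tbl$group), c("high", "low", "treated", "control"))
  if (length(bad_grp)) {
    abort(sprintf("unknown qPCR group label(s): %s",
                  paste(bad_grp, collapse = ", ")))
  }
  bad_ct <- !is.na(tbl$ct) & (!is.finite(tbl$ct) | tbl$ct <= 0)
  if (any(bad_ct)) {
    i <- which(bad_ct)[1]
    abort(sprintf("invalid CT for gene '%s' replicate %d: CT must be finite and > 0",
                  tbl$gene_id[i], tbl$replicate[i]))
  }
  tbl
}

#' Read an embryo tally table
#'
#' TSV with header `replicate, arm, n_oocytes, n_cleaved, n_blastocyst`
#' recording, per IVF replicate and treatment arm, how many oocytes were
#' inseminated, how many cleaved, and how many cleaved embryos reached
#' blastocyst. Enforces `n_blastocyst <= n_cleaved <= n_oocytes`.
#'
#' @param file TSV path or literal text.
#' @return A tibble of tallies; empty input yields an empty tibble with a
#'   warning.
#' @export
read_tally_table <- function(file) {
  tbl <- readr::read_tsv(file, col_types = readr::cols(
    replicate = readr::col_integer(), arm = readr::col_character(),
    n_oocytes = readr::col_integer(), n_cleaved = readr::col_integer(),
    n_blastocyst = readr::col_integer()), progress = FALSE)
  expected <- c("replicate", "arm", "n_oocytes", "n_cleaved", "n_blastocyst")
  if (!identical(names(tbl), expected)) {
    abort(sprintf("tally tables must have columns %s",
                  paste(expected, collapse = ", ")))
  }
  if (nrow(tbl) == 0) {
    warn("tally table is empty")
    return(tbl)
  }
  counts <- tbl[c("n_oocytes", "n_cleaved", "n_blastocyst")]
  if (anyNA(counts) || any(as.matrix(counts) < 0)) {
    abort("tally counts must be non-negative integers")
  }
  bad <- tbl$n_blastocyst > tbl$n_cleaved | tbl$n_cleaved > tbl$n_oocytes
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "replicate %d arm '%s': tallies must satisfy n_blastocyst <= n_cleaved <= n_oocytes",
      tbl$replicate[i], tbl$arm[i]))
  }
  tbl
}
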