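#' Detection and validation thresholds
#'
#' Bundles every cutoff the pipeline applies, with the defaults used in the
#' bovine pre-EGA study design this package implements:
#'
#' * a gene is called expressed in a count dataset when **more than**
#'   `min_reads` raw reads are seen in at least `min_samples` samples
#'   (strictly greater than; a count of exactly 5 does not qualify);
#' * a gene is called expressed on the microarray reference when any of its
#'   probes reaches `array_min_intensity` raw intensity units (inclusive: a
#'   minimum threshold of 40 means 40 qualifies);
#' * a qPCR cycle-threshold value above `ct_max` cycles is beyond the limit
#'   of quantification and the replicate is unquantifiable;
#' * a qPCR replicate validates a sequencing result when its fold change is
#'   at least `fold_validation` in the same direction (reciprocal
#'   `1/fold_validation` for down-regulation);
#' * a gene is differentially expressed when its Benjamini-Hochberg adjusted
#'   p-value is strictly below `fdr_cutoff`.
#'
#' @param min_reads Read-count cutoff (strict), default 5.
#' @param min_samples Minimum number of samples exceeding `min_reads`,
#'   default 1.
#' @param array_min_intensity Raw-intensity cutoff (inclusive), default 40.
#' @param ct_max Quantification limit in CT cycles (strict), default 33.
#' @param fold_validation Fold-concordance cutoff (inclusive), default 1.5.
#' @param fdr_cutoff FDR significance cutoff (strict), default 0.10.
#'
#' @return An object of class `threshold_config` (a named list).
#' @examples
#' threshold_config()
#' threshold_config(min_reads = 10)
#' @export
threshold_config <- function(min_reads = 5L, min_samples = 1L,
                             array_min_intensity = 40, ct_max = 33,
                             fold_validation = 1.5, fdr_cutoff = 0.10) {
  vals <- list(min_reads = min_reads, min_samples = min_samples,
               array_min_intensity = array_min_intensity, ct_max = ct_max,
               fold_validation = fold_validation, fdr_cutoff = fdr_cutoff)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a single positive finite number", nm))
    }
  }
  vals$min_reads <- as.integer(min_reads)
  vals$min_samples <- as.integer(min_samples)
  structure(vals, class = "threshold_config")
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("<threshold_config>\n")
  cat(sprintf("  expressed in counts : > %d reads in >= %d sample(s)\n",
              x$min_reads, x$min_samples))
  cat(sprintf("  expressed on array  : >= %g raw intensity units\n",
              x$array_min_intensity))
  cat(sprintf("  qPCR quantifiable   : CT <= %g cycles\n", x$ct_max))
  cat(sprintf("  replicate validated : fold >= %g (or <= %g down)\n",
              x$fold_validation, 1 / x$fold_validation))
  cat(sprintf("  DE significant      : BH q < %g\n", x$fdr_cutoff))
  invisible(x)
}

.as_thresholds <- function(thresholds) {
  if (is.null(thresholds)) return(threshold_config())
  if (!inherits(thresholds, "threshold_config")) {
    abort("`thresholds` must be created with threshold_config()")
  }
  thresholds
}
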