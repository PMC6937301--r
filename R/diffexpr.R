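#' Equalize library sizes by scaling to the geometric-mean depth
#'
#' The exact test conditions on group totals and therefore requires
#' exchangeable samples. Counts are scaled so every library has the
#' geometric mean of the observed depths, then rounded back to integers.
#' This is a deliberately simple, documented equalization: it makes the
#' per-sample means comparable without any model fitting.
#'
#' @param counts Integer matrix (genes x samples) or wide count tibble.
#' @return An integer matrix of equalized counts (same dimnames).
#' @export
equalize_library_sizes <- function(counts) {
  mat <- .count_matrix(counts)
  depth <- colSums(mat)
  if (any(depth == 0)) abort("cannot equalize a library with zero total counts")
  target <- exp(mean(log(depth)))
  out <- round(sweep(mat, 2, target / depth, `*`))
  storage.mode(out) <- "integer"
  out
}

.count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    storage.mode(counts) <- "integer"
    return(counts)
  }
  .validate_counts(counts, "counts")
  mat <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  rownames(mat) <- counts$gene_id
  storage.mode(mat) <- "integer"
  mat
}

# Log conditional likelihood of a common dispersion given per-gene group
# sums: for n iid NB(mean m, dispersion phi) counts conditioned on their
# sum s, the mean drops out and
#   log P(y | s) = sum_j lgamma(y_j + r) - n lgamma(r) + lgamma(n r)
#                  - lgamma(s + n r) + const,   r = 1/phi.
# Summed over genes and groups this is the conditional log-likelihood that
# the common-dispersion estimator maximizes.
.cond_loglik <- function(phi, mats) {
  r <- 1 / phi
  ll <- 0
  for (mat in mats) {
    n <- ncol(mat)
    s <- rowSums(mat)
    ll <- ll + sum(lgamma(mat + r)) - nrow(mat) * n * lgamma(r) +
      nrow(mat) * lgamma(n * r) - sum(lgamma(s + n * r))
  }
  ll
}

#' Estimate a common negative-binomial dispersion
#'
#' Fits a single overdispersion parameter shared across genes, under the
#' NB parameterization with variance \eqn{m + \phi m^2}. After library-size
#' equalization the per-gene mean is a nuisance that cancels from the
#' distribution of counts conditioned on the gene's group sum, so the
#' estimator maximizes the conditional log-likelihood over both fertility
#' groups — no per-gene mean is estimated, which avoids the downward bias
#' of plug-in profile likelihood at small replicate numbers. Genes with a
#' zero group sum contribute no information and are skipped.
#'
#' @param counts Wide count tibble or integer matrix (genes x samples).
#' @param groups Vector assigning each sample (column) to one of two
#'   groups; each group needs at least 2 samples.
#' @param interval Search interval for the dispersion.
#' @return A one-row tibble: `common_dispersion`, `method`, `n_genes_used`.
#' @export
estimate_common_dispersion <- function(counts, groups,
                                       interval = c(1e-6, 10)) {
  mat <- equalize_library_sizes(counts)
  groups <- as.character(groups)
  if (length(groups) != ncol(mat)) {
    abort("`groups` must have one entry per sample column")
  }
  lv <- unique(groups)
  if (length(lv) != 2) abort("exactly two groups are required")
  if (any(table(groups) < 2)) {
    abort("each group must contain at least 2 samples")
  }
  mats <- lapply(lv, function(g) {
    m <- mat[, groups == g, drop = FALSE]
    m[rowSums(m) > 0, , drop = FALSE]
  })
  n_used <- sum(vapply(mats, nrow, integer(1)))
  if (n_used == 0) abort("all-zero count matrix: no information to estimate dispersion")
  opt <- optimize(function(lphi) .cond_loglik(exp(lphi), mats),
                  interval = log(interval), maximum = TRUE, tol = 1e-8)
  phi <- exp(opt$maximum)
  # The likelihood is monotone decreasing in phi for Poisson-like data;
  # clamp estimates at the lower search bound to zero.
  if (phi <= interval[1] * 1.5) phi <- 0
  tibble(common_dispersion = phi, method = "conditional-ML",
         n_genes_used = n_used)
}

# NB pmf weights of the conditional split distribution. With equal
# per-sample means under the null and per-sample dispersion phi, the sum of
# n_a counts is NB(size n_a/phi, prob p) with p = 1/(1 + phi m) shared by
# both groups, so conditioning on the total t leaves a negative
# hypergeometric that is free of m:
#   w(s) proportional to C(s + r_a - 1, s) * C(t - s + r_b - 1, t - s).
# At phi = 0 the Poisson limit gives Binomial(t, n_a / (n_a + n_b)).
.split_log_weights <- function(t, n_a, n_b, dispersion) {
  s <- 0:t
  if (dispersion == 0) {
    lchoose(t, s) + s * log(n_a / (n_a + n_b)) + (t - s) * log(n_b / (n_a + n_b))
  } else {
    r_a <- n_a / dispersion
    r_b <- n_b / dispersion
    lchoose(s + r_a - 1, s) + lchoose(t - s + r_b - 1, t - s)
  }
}

#' Exact negative-binomial test for a two-group count difference
#'
#' Conditions on the total count of the gene across both groups and
#' computes the two-sided exact p-value as the summed probability of every
#' split of that total whose probability does not exceed the observed
#' split's (ties included, with a relative tolerance of 1e-12 so floating
#' point noise cannot drop an exactly tied outcome). Requires
#' library-size-equalized counts, as produced by
#' [equalize_library_sizes()]; at dispersion 0 the test reduces to the
#' conditional binomial (Poisson) exact test.
#'
#' @param counts_a,counts_b Non-negative integer count vectors for the two
#'   groups (one entry per sample).
#' @param dispersion Common NB dispersion (variance \eqn{m + \phi m^2});
#'   0 for Poisson.
#' @return Two-sided exact p-value in (0, 1].
#' @examples
#' nb_exact_test(c(10, 10, 10), c(10, 10, 10), 0.1)  # p = 1
#' nb_exact_test(c(0, 0, 0), c(4, 3, 3), 0)          # binomial tail
#' @export
nb_exact_test <- function(counts_a, counts_b, dispersion) {
  for (v in list(counts_a, counts_b)) {
    if (length(v) == 0 || anyNA(v) || any(v < 0) || any(v != floor(v))) {
      abort("counts must be non-empty non-negative integers")
    }
  }
  if (!is.numeric(dispersion) || length(dispersion) != 1 || dispersion < 0) {
    abort("`dispersion` must be a single non-negative number")
  }
  s_a <- sum(counts_a)
  t <- s_a + sum(counts_b)
  if (t == 0) return(1)
  lw <- .split_log_weights(t, length(counts_a), length(counts_b), dispersion)
  w <- exp(lw - max(lw))
  obs <- w[s_a + 1]
  min(1, sum(w[w <= obs * (1 + 1e-12)]) / sum(w))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR control: with p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} \min(1, p_{(j)} m / j)}, returned in the
#' input order. Written out explicitly so the adjustment is auditable
#' against an independent implementation.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  m <- length(pvalues)
  ord <- order(pvalues)
  scaled <- pmin(1, pvalues[ord] * m / seq_len(m))
  q_sorted <- rev(cummin(rev(scaled)))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Differential expression between fertility groups
#'
#' The full DE driver: restricts testing to genes that pass the embryo
#' presence call (the expressed-gene universe), equalizes library sizes to
#' the geometric-mean depth, estimates a common NB dispersion by
#' conditional maximum likelihood, applies the exact test per gene,
#' adjusts with Benjamini-Hochberg, and flags genes with q strictly below
#' the FDR cutoff. The log2 fold change is high-over-low on equalized
#' group means with a pseudo-count of 0.5 added to each mean so that zero
#' means stay finite.
#'
#' @param counts Wide embryo count tibble (`gene_id` + sample columns).
#' @param samples Sample sheet from [sample_sheet()] covering every count
#'   column, with `fertility_group` in high/low; at least 2 samples per
#'   group.
#' @param thresholds A [threshold_config()]; supplies the presence filter
#'   and the FDR cutoff.
#' @param dispersion Optional fixed common dispersion; estimated from the
#'   data when `NULL`.
#' @return A `de_fit` object. [tidy()] returns the per-gene table
#'   (`gene_id`, `tested`, `mean_norm_count`, `log2fc`, `pvalue`,
#'   `qvalue`, `significant`); [glance()] a one-row fit summary;
#'   [ggplot2::autoplot()] a volcano plot.
#' @export
run_de <- function(counts, samples, thresholds = threshold_config(),
                   dispersion = NULL) {
  thresholds <- .as_thresholds(thresholds)
  mat <- .count_matrix(counts)
  idx <- match(colnames(mat), samples$sample_id)
  if (anyNA(idx)) {
    abort(sprintf("sample(s) missing from sample sheet: %s",
                  paste(colnames(mat)[is.na(idx)], collapse = ", ")))
  }
  groups <- samples$fertility_group[idx]
  if (!all(groups %in% c("high", "low"))) {
    abort("every sample must be labeled fertility_group high or low")
  }
  if (any(table(groups) < 2)) abort("each group must contain at least 2 samples")

  calls <- call_expression_counts(counts, thresholds)
  tested <- calls$status == "expressed"
  eq <- equalize_library_sizes(mat)
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(
      mat[tested, , drop = FALSE], groups)$common_dispersion
  }
  hi <- eq[, groups == "high", drop = FALSE]
  lo <- eq[, groups == "low", drop = FALSE]
  mean_hi <- rowMeans(hi)
  mean_lo <- rowMeans(lo)
  pvals <- rep(NA_real_, nrow(eq))
  pvals[tested] <- vapply(which(tested), function(i) {
    nb_exact_test(hi[i, ], lo[i, ], dispersion)
  }, numeric(1))
  qvals <- rep(NA_real_, nrow(eq))
  qvals[tested] <- bh_adjust(pvals[tested])

  table <- tibble(
    gene_id = rownames(eq),
    tested = tested,
    mean_norm_count = (mean_hi + mean_lo) / 2,
    log2fc = log2((mean_hi + 0.5) / (mean_lo + 0.5)),
    pvalue = pvals,
    qvalue = qvals,
    significant = !is.na(qvals) & qvals < thresholds$fdr_cutoff
  )
  structure(
    list(table = table, dispersion = dispersion,
         fdr_cutoff = thresholds$fdr_cutoff,
         n_high = sum(groups == "high"), n_low = sum(groups == "low")),
    class = "de_fit"
  )
}

#' @export
print.de_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<de_fit> %d genes (%d tested), %d vs %d samples\n  common dispersion %.4g; %d significant at q < %g\n",
    g$n_genes, g$n_tested, x$n_high, x$n_low, g$common_dispersion,
    g$n_significant, x$fdr_cutoff))
  invisible(x)
}

#' @rdname run_de
#' @param x,object A `de_fit`.
#' @param ... Unused.
#' @method tidy de_fit
#' @export
tidy.de_fit <- function(x, ...) x$table

#' @rdname run_de
#' @method glance de_fit
#' @export
glance.de_fit <- function(x, ...) {
  tibble(
    n_genes = nrow(x$table),
    n_tested = sum(x$table$tested),
    n_significant = sum(x$table$significant),
    common_dispersion = x$dispersion,
    fdr_cutoff = x$fdr_cutoff
  )
}

#' @rdname run_de
#' @method autoplot de_fit
#' @export
autoplot.de_fit <- function(object, ...) {
  df <- dplyr::filter(object$table, .data$tested)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$pvalue),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (high / low fertility)",
                  y = expression(-log[10]~p),
                  colour = sprintf("q < %g", object$fdr_cutoff)) +
    ggplot2::theme_minimal()
}

#' Write a DE result table as TSV, sorted by q-value
#'
#' @param de A `de_fit` or its [tidy()] tibble.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_de_table <- function(de, file) {
  if (inherits(de, "de_fit")) de <- tidy(de)
  readr::write_tsv(dplyr::arrange(de, .data$qvalue), file, progress = FALSE)
  invisible(file)
}
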