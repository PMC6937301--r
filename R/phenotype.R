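#' Cleavage and blastocyst rates from embryo tallies
#'
#' The cleavage rate is the fraction of inseminated oocytes that divided
#' (`n_cleaved / n_oocytes`); the blastocyst rate is the fraction of
#' cleaved embryos that developed to the blastocyst stage
#' (`n_blastocyst / n_cleaved`) — note the different denominators. A zero
#' denominator is an error naming the affected rate.
#'
#' @param tallies Tally tibble from [read_tally_table()] or
#'   [simulate_tallies()].
#' @return The input with `cleavage_rate` and `blastocyst_rate` columns
#'   appended.
#' @examples
#' compute_rates(tibble::tibble(replicate = 1L, arm = "control",
#'   n_oocytes = 100L, n_cleaved = 80L, n_blastocyst = 20L))
#' @export
compute_rates <- function(tallies) {
  if (any(tallies$n_oocytes == 0)) {
    abort("cleavage rate undefined: n_oocytes is 0 in at least one tally")
  }
  if (any(tallies$n_cleaved == 0)) {
    abort("blastocyst rate undefined: n_cleaved is 0 in at least one tally")
  }
  bad <- tallies$n_blastocyst > tallies$n_cleaved |
    tallies$n_cleaved > tallies$n_oocytes
  if (any(bad)) {
    abort("tallies must satisfy n_blastocyst <= n_cleaved <= n_oocytes")
  }
  dplyr::mutate(tallies,
                cleavage_rate = .data$n_cleaved / .data$n_oocytes,
                blastocyst_rate = .data$n_blastocyst / .data$n_cleaved)
}

#' Replicate-paired comparison of two treatment arms
#'
#' Compares a development rate between two arms across replicate-matched
#' IVF runs: the relative percent change is computed on replicate-mean
#' rates, `100 * (mean treated - mean control) / mean control`, and
#' significance comes from a two-sided paired t-test on the per-replicate
#' rate pairs. The absolute difference in percentage points is reported
#' alongside, since "an X% increase" is ambiguous between the two readings.
#'
#' @param rates Rate tibble from [compute_rates()] containing both arms.
#' @param treated,control Arm labels to compare.
#' @param rate Which rate to compare: `"blastocyst"` (default) or
#'   `"cleavage"`.
#' @return A one-row tibble: `rate`, `mean_treated`, `mean_control`,
#'   `percent_change`, `percentage_point_change`, `statistic`, `df`,
#'   `p_value`, `n_replicates`.
#' @export
compare_arms_paired <- function(rates, treated = "treated",
                                control = "control",
                                rate = c("blastocyst", "cleavage")) {
  rate <- match.arg(rate)
  col <- paste0(rate, "_rate")
  if (!col %in% names(rates)) {
    abort("`rates` must come from compute_rates()")
  }
  tr <- dplyr::filter(rates, .data$arm == treated) |>
    dplyr::arrange(.data$replicate)
  ct <- dplyr::filter(rates, .data$arm == control) |>
    dplyr::arrange(.data$replicate)
  if (nrow(tr) == 0 || nrow(ct) == 0) {
    abort(sprintf("arm(s) not found: need '%s' and '%s'", treated, control))
  }
  if (!identical(tr$replicate, ct$replicate)) {
    abort("arms must share the same replicate set (replicate-matched design)")
  }
  if (nrow(tr) < 2) abort("paired comparison needs at least 2 replicates")
  x <- tr[[col]]
  y <- ct[[col]]
  tt <- paired_t_test(x, y)
  tibble(
    rate = rate,
    mean_treated = mean(x),
    mean_control = mean(y),
    percent_change = 100 * (mean(x) - mean(y)) / mean(y),
    percentage_point_change = 100 * (mean(x) - mean(y)),
    statistic = tt$statistic,
    df = tt$df,
    p_value = tt$p_value,
    n_replicates = nrow(tr)
  )
}
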