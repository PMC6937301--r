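# Shared fixtures and independent oracles, built in code at test time.

write_tmp <- function(lines, ext = ".tsv") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# A 6-gene toy universe covering all five origin outcomes.
toy_calls <- function() {
  list(
    embryo = tibble::tibble(
      gene_id = paste0("g", 1:6),
      status = c(rep("expressed", 5), "not_expressed")
    ),
    sperm = tibble::tibble(
      gene_id = paste0("g", 1:5),
      status = c("expressed", "not_expressed", "expressed",
                 "not_expressed", "expressed")
    ),
    oocyte_a = tibble::tibble(
      gene_id = paste0("g", 1:5),
      status = c("expressed", "expressed", "not_expressed",
                 "not_expressed", "expressed")
    ),
    oocyte_b = tibble::tibble(
      gene_id = paste0("g", 1:5),
      status = c("expressed", "expressed", "not_expressed",
                 "not_expressed", "not_expressed")
    ),
    # g1 both gametes; g2 oocyte only; g3 sperm only; g4 embryo only;
    # g5 oocyte references disagree -> provisional; g6 never classified.
    expected = c(g1 = "sperm_and_oocyte", g2 = "oocyte_only",
                 g3 = "sperm_only", g4 = "embryo_only", g5 = "provisional")
  )
}

# Independent brute-force oracle for the conditional exact test: enumerates
# every split of the total using NB (or Poisson) pmfs at an arbitrary mean,
# entirely separate from the package's negative-hypergeometric weights.
oracle_exact_p <- function(counts_a, counts_b, dispersion, mu = 7.3) {
  n_a <- length(counts_a)
  n_b <- length(counts_b)
  s_a <- sum(counts_a)
  t <- s_a + sum(counts_b)
  if (t == 0) return(1)
  s <- 0:t
  prob <- if (dispersion == 0) {
    stats::dpois(s, n_a * mu) * stats::dpois(t - s, n_b * mu)
  } else {
    stats::dnbinom(s, size = n_a / dispersion, mu = n_a * mu) *
      stats::dnbinom(t - s, size = n_b / dispersion, mu = n_b * mu)
  }
  prob <- prob / sum(prob)
  sum(prob[prob <= prob[s_a + 1] * (1 + 1e-12)])
}

# Independent step-up BH oracle: literal loop over ranks.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running_min <- 1
  for (i in m:1) {
    running_min <- min(running_min, p[ord[i]] * m / i)
    q[ord[i]] <- min(1, running_min)
  }
  q
}

random_count_table <- function(n_genes, n_samples, max_count = 500) {
  tbl <- tibble::tibble(gene_id = sprintf("g%04d", seq_len(n_genes)))
  for (j in seq_len(n_samples)) {
    tbl[[paste0("s", j)]] <- as.integer(sample.int(max_count + 1,
                                                   n_genes,
                                                   replace = TRUE) - 1L)
  }
  tbl
}
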