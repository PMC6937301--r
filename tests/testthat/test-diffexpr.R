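test_that("exact test closed forms: mode split, binomial tail, symmetry", {
  expect_equal(nb_exact_test(c(10, 10, 10), c(10, 10, 10), 0.3), 1)
  # Poisson conditional with equal group sizes: Binomial(10, 1/2) two tails.
  expect_equal(nb_exact_test(c(0, 0, 0), c(4, 3, 3), 0), 2 / 1024,
               tolerance = 1e-12)
  withr::local_seed(17)
  for (i in 1:20) {
    a <- sample(0:15, 3, replace = TRUE)
    b <- sample(0:15, 3, replace = TRUE)
    phi <- sample(c(0, 0.2, 0.7), 1)
    expect_equal(nb_exact_test(a, b, phi), nb_exact_test(b, a, phi),
                 tolerance = 1e-12)
  }
  expect_error(nb_exact_test(c(-1, 2), c(0, 1), 0), "non-negative")
  expect_error(nb_exact_test(c(1, 2), c(0, 1), -0.1), "non-negative")
})

test_that("exact test matches the brute-force enumeration oracle", {
  # Spot-check grid here; the exhaustive totals sweep runs in the
  # acceptance suite.
  for (phi in c(0, 0.5)) {
    for (t in c(1, 7, 18)) {
      for (s_a in 0:t) {
        a <- c(s_a, 0, 0)
        b <- c(t - s_a, 0, 0)
        expect_equal(nb_exact_test(a, b, phi), oracle_exact_p(a, b, phi),
                     tolerance = 1e-10)
      }
    }
  }
  # Unequal group sizes exercise the asymmetric conditional.
  expect_equal(nb_exact_test(c(9, 1), c(2, 0, 1), 0.5),
               oracle_exact_p(c(9, 1), c(2, 0, 1), 0.5), tolerance = 1e-10)
})

test_that("exact test agrees with the reference NB exact implementation", {
  skip_if_not_installed("edgeR")
  withr::local_seed(29)
  mat <- matrix(rnbinom(600, size = 5, mu = 40), ncol = 6)
  # equalize columns so both implementations condition identically
  mat <- equalize_library_sizes(mat)
  phi <- 0.2
  ours <- vapply(seq_len(nrow(mat)), function(i) {
    nb_exact_test(mat[i, 1:3], mat[i, 4:6], phi)
  }, numeric(1))
  ref <- edgeR::exactTestBySmallP(
    mat[, 1:3, drop = FALSE], mat[, 4:6, drop = FALSE], dispersion = phi)
  expect_equal(ours, as.numeric(ref), tolerance = 1e-6)
})

test_that("BH step-up matches hand computation and the independent oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::local_seed(41)
  for (i in 1:50) {
    p <- stats::runif(sample(1:60, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    expect_equal(bh_adjust(p), stats::p.adjust(p, method = "BH"),
                 tolerance = 1e-12)
  }
})

test_that("q-values are order-invariant and respect the raw-p ranking", {
  withr::local_seed(43)
  p <- stats::runif(40)
  perm <- sample(40)
  q <- bh_adjust(p)
  expect_equal(bh_adjust(p[perm]), q[perm])
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("common dispersion is recovered from simulated counts", {
  withr::local_seed(59)
  n <- 2000
  means <- stats::runif(n, 20, 200)
  poisson_mat <- vapply(1:6, function(j) rpois(n, means), numeric(n))
  groups <- rep(c("high", "low"), each = 3)
  est0 <- estimate_common_dispersion(poisson_mat, groups)
  expect_lt(est0$common_dispersion, 0.02)

  nb_mat <- vapply(1:6, function(j) rnbinom(n, size = 5, mu = means),
                   numeric(n))
  est <- estimate_common_dispersion(nb_mat, groups)
  expect_equal(est$common_dispersion, 0.2, tolerance = 0.25)
  expect_lt(abs(est$common_dispersion - 0.2), 0.05)

  zero <- matrix(0L, nrow = 5, ncol = 4)
  expect_error(estimate_common_dispersion(zero, rep(c("a", "b"), each = 2)),
               "zero")
  expect_error(estimate_common_dispersion(nb_mat, rep("high", 6)),
               "two groups")
  expect_error(estimate_common_dispersion(nb_mat[, 1:3],
                                          c("high", "high", "low")),
               "at least 2")
})

test_that("identical groups yield no significant genes", {
  withr::local_seed(61)
  base <- random_count_table(300, 3, max_count = 200)
  counts <- dplyr::bind_cols(
    base,
    setNames(base[, -1], c("d1", "d2", "d3"))
  )
  names(counts) <- c("gene_id", "h1", "h2", "h3", "l1", "l2", "l3")
  sheet <- sample_sheet(names(counts)[-1], "embryo",
                        rep(c("high", "low"), each = 3), rep(1:3, 2))
  fit <- run_de(counts, sheet)
  tbl <- tidy(fit)
  expect_true(all(tbl$pvalue[tbl$tested] == 1))
  expect_equal(sum(tbl$significant), 0)
  expect_true(all(abs(tbl$log2fc[tbl$tested]) < 1e-12))
})

test_that("run_de filters non-expressed genes and flags them untested", {
  withr::local_seed(63)
  stable <- random_count_table(40, 6, max_count = 300)
  names(stable) <- c("gene_id", "h1", "h2", "h3", "l1", "l2", "l3")
  counts <- dplyr::bind_rows(
    tibble::tibble(
      gene_id = c("g1", "g2"),
      h1 = c(100L, 1L), h2 = c(90L, 0L), h3 = c(110L, 2L),
      l1 = c(10L, 0L), l2 = c(12L, 1L), l3 = c(9L, 0L)),
    stable)
  sheet <- sample_sheet(names(counts)[-1], "embryo",
                        rep(c("high", "low"), each = 3), rep(1:3, 2))
  fit <- run_de(counts, sheet, dispersion = 0.05)
  tbl <- tidy(fit)
  expect_true(tbl$tested[1])
  expect_false(tbl$tested[2])
  expect_true(is.na(tbl$pvalue[2]))
  expect_false(tbl$significant[2])
  expect_gt(tbl$log2fc[1], 2)
  g <- glance(fit)
  expect_equal(g$n_tested, sum(tbl$tested))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})

test_that("planted DE genes are detected with high power and controlled FDP", {
  cfg <- sim_config(seed = 71, n_genes = 1000, nb_mean = 200,
                    nb_dispersion = 0.1, de_fraction = 0.05, de_log2fc = 3)
  sim <- simulate_dataset(cfg)
  fit <- run_de(sim$embryo, sim$samples)
  tbl <- tidy(fit)
  truth <- sim$truth
  flagged <- tbl$gene_id[tbl$significant]
  planted <- truth$gene_id[truth$is_de]
  power <- mean(planted %in% flagged)
  fdp <- if (length(flagged)) mean(!flagged %in% planted) else 0
  expect_gte(power, 0.9)
  expect_lte(fdp, 0.15)
})
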