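test_that("ddCT fold changes match closed forms and respect the CT limit", {
  rec <- fold_change_ddct(20, 15, 22, 15)
  expect_equal(rec$fold, 4)
  expect_equal(rec$delta_ct_case, 5)
  expect_equal(rec$delta_ct_control, 7)
  expect_equal(fold_change_ddct(24, 24, 24, 24)$fold, 1)
  # any CT past the quantification limit, or missing, is unquantifiable
  expect_false(fold_change_ddct(34, 15, 22, 15)$quantifiable)
  expect_false(fold_change_ddct(20, 15, 22, 33.01)$quantifiable)
  expect_false(fold_change_ddct(NA, 15, 22, 15)$quantifiable)
  expect_true(fold_change_ddct(33, 15, 22, 15)$quantifiable)
})

test_that("fold changes obey swap symmetry and global cycle-shift invariance", {
  withr::local_seed(13)
  for (i in 1:30) {
    cts <- stats::runif(4, 10, 32)
    fwd <- fold_change_ddct(cts[1], cts[2], cts[3], cts[4])
    rev <- fold_change_ddct(cts[3], cts[4], cts[1], cts[2])
    expect_equal(fwd$fold * rev$fold, 1, tolerance = 1e-12)
    shift <- fold_change_ddct(cts[1] + 1, cts[2] + 1, cts[3] + 1, cts[4] + 1)
    expect_equal(shift$fold, fwd$fold, tolerance = 1e-12)
  }
})

test_that("reference gene selection picks the most stable candidate", {
  qpcr <- tibble::tibble(
    replicate = rep(1:3, each = 4),
    group = rep(c("high", "low"), 6),
    gene_id = rep(c("ACTB", "ACTB", "B2M", "B2M"), 3),
    ct = c(20.0, 20.1, 22, 23, 20.05, 20.0, 24, 21, 20.1, 20.02, 20, 25)
  )
  expect_equal(select_reference_gene(qpcr, c("ACTB", "B2M")), "ACTB")
  # lexicographic tie-break on equal stability
  tie <- tibble::tibble(replicate = rep(1:2, 2),
                        group = "high",
                        gene_id = rep(c("B", "A"), each = 2),
                        ct = c(20, 21, 25, 26))
  expect_equal(select_reference_gene(tie, c("A", "B")), "A")
  # a candidate whose CTs all exceed the limit is excluded first
  hot <- tibble::tibble(replicate = rep(1:2, 2), group = "high",
                        gene_id = rep(c("CANX", "ACTB"), each = 2),
                        ct = c(34, 35, 20, 28))
  expect_warning(sel <- select_reference_gene(hot, c("CANX", "ACTB")),
                 "CANX")
  expect_equal(sel, "ACTB")
  expect_error(suppressWarnings(
    select_reference_gene(hot[hot$gene_id == "CANX", ], c("CANX", "X"))),
    "no candidate")
})

test_that("validation summaries count direction-concordant replicates", {
  folds_up <- tibble::tibble(
    gene_id = "g", replicate = 1:3, fold = c(2.0, 2.5, 2.9),
    delta_ct_case = c(4, 3.7, 3.5), delta_ct_control = c(5, 5, 5),
    quantifiable = TRUE)
  s_up <- summarize_validation(folds_up, "up")
  expect_equal(s_up$n_validated, 3L)
  expect_equal(s_up$mean_fold, mean(c(2.0, 2.5, 2.9)))

  folds_down <- dplyr::mutate(folds_up, fold = c(0.5, 0.6, 0.9))
  s_down <- summarize_validation(folds_down, "down")
  expect_equal(s_down$n_validated, 2L)  # 0.9 > 1/1.5 fails concordance

  # boundary: exactly 1.5 (up) and 1/1.5 (down) validate (inclusive rule)
  s_edge <- summarize_validation(
    dplyr::mutate(folds_up, fold = c(1.5, 1.49, 10)), "up")
  expect_equal(s_edge$n_validated, 2L)

  none <- dplyr::mutate(folds_up, quantifiable = FALSE,
                        fold = NA_real_)
  s_na <- summarize_validation(none, "up")
  expect_false(s_na$quantifiable)
  expect_true(is.na(s_na$mean_fold))
  expect_equal(s_na$n_validated, 0L)
})

test_that("validation rule is monotone in the fold cutoff", {
  withr::local_seed(19)
  folds <- tibble::tibble(gene_id = "g", replicate = 1:8,
                          fold = stats::runif(8, 0.3, 4),
                          delta_ct_case = stats::rnorm(8, 4),
                          delta_ct_control = 5, quantifiable = TRUE)
  nv <- vapply(seq(1.1, 3, by = 0.1), function(fv) {
    summarize_validation(folds, "up",
                         threshold_config(fold_validation = fv))$n_validated
  }, integer(1))
  expect_true(all(diff(nv) <= 0))
})

test_that("paired t-test matches its closed form and handles degeneracy", {
  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  res <- paired_t_test(c(2, 3, 4), c(1, 1, 1))  # differences 1, 2, 3
  expect_equal(res$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 2 * stats::pt(-res$statistic, 2),
               tolerance = 1e-10)
  expect_equal(round(res$p_value, 4), 0.0742)
  expect_warning(inf <- paired_t_test(c(2, 3, 4), c(1, 2, 3)),
                 "zero variance")
  expect_equal(inf$p_value, 0)
  expect_equal(inf$statistic, Inf)
  expect_error(paired_t_test(1, 2), "at least 2")
  expect_error(paired_t_test(c(1, 2), c(1, 2, 3)), "same length")
})

test_that("zero-noise simulated plates return planted folds exactly", {
  cfg <- sim_config(seed = 3, n_genes = 50, qpcr_noise_sd = 0,
                    de_fraction = 0.3, de_log2fc = 2)
  sim <- simulate_dataset(cfg)
  genes <- sim$truth$gene_id[1:10]
  plate <- simulate_qpcr(sim$truth, genes, cfg)
  for (g in genes) {
    fc <- compute_fold_changes(plate, g, "ACTB")
    planted <- 2^sim$truth$true_log2fc[sim$truth$gene_id == g]
    expect_equal(fc$fold, rep(planted, 3), tolerance = 1e-12)
  }
  # explicit fold override, closed-form inversion
  plate4 <- simulate_qpcr(sim$truth, genes[1], cfg,
                          folds = setNames(4, genes[1]))
  fc4 <- compute_fold_changes(plate4, genes[1], "ACTB")
  expect_equal(fc4$fold, rep(4, 3), tolerance = 1e-12)
})

test_that("noisy simulated folds are unbiased over many replicates", {
  cfg <- sim_config(seed = 27, n_genes = 400, qpcr_noise_sd = 0.5,
                    de_fraction = 0)
  sim <- simulate_dataset(cfg)
  genes <- sim$truth$gene_id[1:50]
  plate <- simulate_qpcr(sim$truth, genes, cfg, n_replicates = 50L)
  log_folds <- unlist(lapply(genes, function(g) {
    log2(compute_fold_changes(plate, g, "ACTB")$fold)
  }))
  # planted fold 1 (log2 = 0). Reference-gene noise is shared by every
  # target on a plate replicate, so the standard error has a per-replicate
  # component (2 sigma^2 / R) on top of the per-measurement one
  # (2 sigma^2 / (G R)).
  G <- 50; R <- 50; s2 <- 0.5^2
  se <- sqrt(2 * s2 / R + 2 * s2 / (G * R))
  expect_lt(abs(mean(log_folds)), 3 * se)
})

test_that("validate_genes produces one summary row per gene", {
  cfg <- sim_config(seed = 8, n_genes = 30, qpcr_noise_sd = 0,
                    de_fraction = 0.5, de_log2fc = 1.5)
  sim <- simulate_dataset(cfg)
  genes <- sim$truth$gene_id[1:4]
  plate <- simulate_qpcr(sim$truth, genes, cfg)
  dirs <- tibble::tibble(
    gene_id = genes,
    direction = ifelse(sim$truth$true_log2fc[1:4] >= 0, "up", "down"))
  out <- validate_genes(plate, dirs, "ACTB")
  expect_equal(out$gene_id, genes)
  expect_true(all(out$n_quantifiable == 3))
})
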