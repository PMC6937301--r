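test_that("a hand-labeled toy universe is classified gene by gene", {
  toy <- toy_calls()
  asn <- classify_origins(toy$embryo, toy$sperm, toy$oocyte_a, toy$oocyte_b)
  expect_equal(nrow(asn), 5)  # g6 is not embryo-expressed
  expect_equal(setNames(asn$label, asn$gene_id), toy$expected)
  smry <- origin_summary(asn)
  expect_equal(smry$total_confident, 4L)
  expect_equal(smry$total_embryo_expressed, 5L)
})

test_that("classification refuses genes not expressed in the embryo", {
  expect_error(classify_origin("not_expressed", "expressed", "expressed"),
               "embryo-expressed")
})

test_that("labels partition the embryo-expressed set for random inputs", {
  withr::local_seed(21)
  for (i in 1:5) {
    n <- 80
    genes <- sprintf("g%03d", 1:n)
    embryo <- tibble::tibble(
      gene_id = genes,
      status = sample(c("expressed", "not_expressed"), n, TRUE, c(0.8, 0.2)))
    rand_calls <- function() tibble::tibble(
      gene_id = sample(genes, 60),
      status = sample(c("expressed", "not_expressed", "not_measured"),
                      60, TRUE))
    asn <- classify_origins(embryo, rand_calls(), rand_calls(), rand_calls())
    expect_setequal(asn$gene_id, embryo$gene_id[embryo$status == "expressed"])
    expect_false(anyDuplicated(asn$gene_id) > 0)
    expect_true(all(asn$label %in% origin_labels()))
    smry <- origin_summary(asn)
    expect_equal(smry$total_confident + smry$provisional,
                 smry$total_embryo_expressed)
    # provisional exactly when the oocyte references disagree
    expect_equal(asn$label == "provisional",
                 asn$oocyte_consensus == "ambiguous")
  }
})

test_that("removing the sperm dataset demotes sperm evidence and nothing else", {
  withr::local_seed(33)
  sim <- simulate_dataset(sim_config(seed = 33, n_genes = 1500))
  with_sperm <- classify_sim(sim)
  no_sperm <- classify_origins(
    call_expression_counts(sim$embryo),
    tibble::tibble(gene_id = sim$truth$gene_id, status = "not_expressed"),
    call_expression_array(sim$oocyte_array, universe = sim$truth$gene_id),
    call_expression_counts(sim$oocyte_rnaseq, universe = sim$truth$gene_id)
  )
  expected <- dplyr::recode(with_sperm$label,
                            sperm_only = "embryo_only",
                            sperm_and_oocyte = "oocyte_only")
  expect_equal(no_sperm$label, expected)
})

test_that("noise-free synthetic data is recovered label for label", {
  cfg <- sim_config(seed = 5, n_genes = 2000, nb_dispersion = 0,
                    background_mean = 0, array_background_mean = 0,
                    de_fraction = 0)
  sim <- simulate_dataset(cfg)
  asn <- classify_sim(sim)
  expect_equal(nrow(asn), 2000)
  expect_equal(asn$label,
               sim$truth$true_origin[match(asn$gene_id, sim$truth$gene_id)])
})

test_that("a degenerate mixture classifies every gene into the planted label", {
  cfg <- sim_config(seed = 9, n_genes = 300, nb_dispersion = 0,
                    background_mean = 0, array_background_mean = 0,
                    origin_proportions = c(sperm_and_oocyte = 1, oocyte_only = 0,
                                           sperm_only = 0, embryo_only = 0,
                                           provisional = 0))
  asn <- classify_sim(simulate_dataset(cfg))
  expect_true(all(asn$label == "sperm_and_oocyte"))
})

test_that("DE-by-origin breakdown counts significant genes per label", {
  asn <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:30),
    label = rep(c("sperm_only", "embryo_only", "oocyte_only",
                  "sperm_and_oocyte", "provisional"),
                times = c(4, 2, 9, 9, 6))
  )
  de <- tibble::tibble(gene_id = asn$gene_id,
                       significant = c(rep(TRUE, 24), rep(FALSE, 6)))
  brk <- annotate_de_origins(de, asn)
  expect_equal(brk$sperm_only, 4L)
  expect_equal(brk$embryo_only, 2L)
  expect_equal(brk$oocyte_only, 9L)
  expect_equal(brk$sperm_and_oocyte, 9L)
  expect_equal(brk$total_resolved, 24L)
  expect_equal(brk$total_significant, 24L)

  empty <- annotate_de_origins(
    tibble::tibble(gene_id = character(0), significant = logical(0)), asn)
  expect_equal(empty$total_significant, 0L)
  expect_true(all(empty[origin_labels()] == 0))

  de_bad <- tibble::tibble(gene_id = "unknown_gene", significant = TRUE)
  expect_error(annotate_de_origins(de_bad, asn), "unknown_gene")
})

test_that("summary-from-counts reproduces the partition invariants", {
  smry <- origin_summary_from_counts(2675, 2575, 472, 663, provisional = 41)
  expect_equal(smry$total_confident, 6385L)
  expect_equal(smry$total_embryo_expressed, 6426L)
  expect_error(origin_summary_from_counts(-1, 0, 0, 0), "non-negative")
})

test_that("origin tables write with a fixed column order and autoplot works", {
  toy <- toy_calls()
  asn <- classify_origins(toy$embryo, toy$sperm, toy$oocyte_a, toy$oocyte_b)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_origin_table(asn, f)
  expect_equal(readLines(f)[1],
               "gene_id\tembryo\tsperm\toocyte_ref1\toocyte_ref2\toocyte_consensus\tlabel")
  p <- ggplot2::autoplot(asn)
  expect_s3_class(p, "ggplot")
})
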