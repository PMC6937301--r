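#' Configuration for the synthetic pre-EGA dataset generator
#'
#' Defines every knob of the planted-truth simulation. Defaults mirror the
#' experimental design the pipeline targets — 3 embryo RNA-seq replicates
#' per fertility group, 2 sperm samples, 2 oocyte RNA-seq replicates plus
#' one microarray oocyte reference — with origin-category proportions
#' patterned on the composition observed in pre-EGA bovine embryos (both
#' gametes and oocyte-only dominating, a small sperm-only class, a modest
#' embryo-exclusive class, and a provisional remainder). Count noise is
#' negative binomial with variance \eqn{m + \phi m^2}; a gene "not
#' expressed" in a gamete still receives NB background counts (default
#' mean 0.5) rather than structural zeros, so the detection thresholds are
#' genuinely exercised. Array intensities are log-normal around the
#' expressed / background means (`intensity = mean * exp(N(0, sdlog))`),
#' which keeps a zero background mean exactly at zero in noise-free
#' configurations.
#'
#' @param seed Integer master seed; one named random stream is derived per
#'   generator so adding a generator never perturbs the others.
#' @param n_genes Number of genes to simulate.
#' @param origin_proportions Named fractions over the five origin labels,
#'   summing to 1 (tolerance 1e-9).
#' @param nb_mean Expected raw count of an expressed gene.
#' @param nb_dispersion NB dispersion \eqn{\phi} (0 = Poisson).
#' @param background_mean Expected count of a non-expressed gene.
#' @param n_embryo_reps_per_group Embryo RNA-seq replicates per fertility
#'   group.
#' @param n_sperm_samples Sperm RNA-seq samples.
#' @param n_oocyte_rnaseq_reps Oocyte RNA-seq replicates.
#' @param de_fraction Fraction of genes planted as differentially
#'   expressed between fertility groups.
#' @param de_log2fc Magnitude of the planted log2 fold change (direction
#'   randomized per gene).
#' @param array_expressed_mean,array_background_mean Raw-intensity means
#'   for expressed / background probes on the microarray reference.
#' @param array_intensity_sdlog Log-normal sdlog of array intensities.
#' @param qpcr_noise_sd Gaussian noise SD, in CT cycles, added to every
#'   simulated CT.
#' @param rates Named list of per-arm development probabilities, each
#'   `c(cleavage =, blastocyst =)` in (0, 1).
#' @param n_tally_replicates Paired IVF replicates for the tally generator.
#' @param n_oocytes_per_arm Oocytes inseminated per arm and replicate.
#'
#' @return A `sim_config` object (named list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 10000L,
                       origin_proportions = c(sperm_and_oocyte = 0.356,
                                              oocyte_only = 0.343,
                                              sperm_only = 0.063,
                                              embryo_only = 0.088,
                                              provisional = 0.150),
                       nb_mean = 50,
                       nb_dispersion = 0.1,
                       background_mean = 0.5,
                       n_embryo_reps_per_group = 3L,
                       n_sperm_samples = 2L,
                       n_oocyte_rnaseq_reps = 2L,
                       de_fraction = 0.05,
                       de_log2fc = 3,
                       array_expressed_mean = 200,
                       array_background_mean = 10,
                       array_intensity_sdlog = 0.25,
                       qpcr_noise_sd = 0.3,
                       rates = list(control = c(cleavage = 0.8, blastocyst = 0.35),
                                    treated = c(cleavage = 0.8, blastocyst = 0.43)),
                       n_tally_replicates = 3L,
                       n_oocytes_per_arm = 300L) {
  if (!is.numeric(n_genes) || n_genes < 1) abort("`n_genes` must be >= 1")
  if (!setequal(names(origin_proportions), .origin_labels)) {
    abort(sprintf("`origin_proportions` must be named exactly: %s",
                  paste(.origin_labels, collapse = ", ")))
  }
  if (abs(sum(origin_proportions) - 1) > 1e-9) {
    abort("`origin_proportions` must sum to 1 (tolerance 1e-9)")
  }
  if (any(origin_proportions < 0)) abort("`origin_proportions` must be non-negative")
  if (nb_mean <= 0) abort("`nb_mean` must be > 0")
  if (nb_dispersion < 0) abort("`nb_dispersion` must be >= 0")
  if (background_mean < 0) abort("`background_mean` must be >= 0")
  if (de_fraction < 0 || de_fraction > 1) abort("`de_fraction` must be in [0, 1]")
  if (qpcr_noise_sd < 0) abort("`qpcr_noise_sd` must be >= 0")
  for (arm in names(rates)) {
    r <- rates[[arm]]
    if (!all(c("cleavage", "blastocyst") %in% names(r)) ||
        any(r <= 0) || any(r > 1)) {
      abort(sprintf("rates for arm '%s' must be cleavage/blastocyst probabilities in (0, 1]",
                    arm))
    }
  }
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    origin_proportions = origin_proportions[.origin_labels],
    nb_mean = nb_mean, nb_dispersion = nb_dispersion,
    background_mean = background_mean,
    n_embryo_reps_per_group = as.integer(n_embryo_reps_per_group),
    n_sperm_samples = as.integer(n_sperm_samples),
    n_oocyte_rnaseq_reps = as.integer(n_oocyte_rnaseq_reps),
    de_fraction = de_fraction, de_log2fc = de_log2fc,
    array_expressed_mean = array_expressed_mean,
    array_background_mean = array_background_mean,
    array_intensity_sdlog = array_intensity_sdlog,
    qpcr_noise_sd = qpcr_noise_sd, rates = rates,
    n_tally_replicates = as.integer(n_tally_replicates),
    n_oocytes_per_arm = as.integer(n_oocytes_per_arm)
  ), class = "sim_config")
}

# One named random stream per generator: substream seeds are drawn once
# from the master seed in a fixed name order, so adding a stream at the end
# never changes the draws of existing streams.
.stream_names <- c("truth", "embryo", "sperm", "oocyte_rnaseq",
                   "oocyte_array", "qpcr", "tallies")

.stream_seed <- function(config, stream) {
  stopifnot(stream %in% .stream_names)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, length(.stream_names))
  seeds[match(stream, .stream_names)]
}

.with_stream <- function(config, stream, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.stream_seed(config, stream))
  force(code)
}

# NB draws with mean m and dispersion phi (variance m + phi m^2); phi = 0
# degenerates to Poisson, m = 0 to structural zero.
.rnb <- function(n, mean, dispersion) {
  if (mean == 0) return(integer(n))
  if (dispersion == 0) return(rpois(n, mean))
  rnbinom(n, size = 1 / dispersion, mu = mean)
}

.rnb_matrix <- function(means, n_samples, dispersion) {
  n <- length(means)
  pos <- means > 0
  out <- vapply(seq_len(n_samples), function(j) {
    col <- integer(n)
    if (any(pos)) {
      col[pos] <- as.integer(if (dispersion == 0) {
        rpois(sum(pos), means[pos])
      } else {
        rnbinom(sum(pos), size = 1 / dispersion, mu = means[pos])
      })
    }
    col
  }, integer(n))
  matrix(out, nrow = n)
}

#' Simulate a full multi-platform dataset with planted ground truth
#'
#' Generates every input the origin pipeline consumes: an embryo count
#' table (3 high- plus 3 low-fertility replicates by default, with a
#' planted DE gene set), a sperm count table, an oocyte RNA-seq count
#' table, and an oocyte microarray intensity table with a probe-to-gene
#' map — plus the truth table recording each gene's planted origin label,
#' DE status and signed log2 fold change.
#'
#' Planting follows the origin semantics exactly: every gene is expressed
#' in the embryo; genes whose label includes sperm get expressed-level NB
#' counts in the sperm samples, others background counts; analogously for
#' the two oocyte references; a `provisional` gene is expressed in exactly
#' one of the two oocyte references (which one decided by coin flip, with
#' sperm evidence also randomized, since the provisional label overrides
#' sperm). The same seed always reproduces bit-identical tables.
#'
#' @param config A [sim_config()].
#' @return A list of class `origin_sim`: `truth`, `embryo`, `sperm`,
#'   `oocyte_rnaseq`, `oocyte_array` (probe-level tibble with
#'   `probe_id`, `gene_id` and one intensity column per array), and
#'   `samples` (embryo sample sheet).
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) abort("`config` must come from sim_config()")
  n <- config$n_genes
  gene_id <- sprintf("GENE%05d", seq_len(n))

  truth <- .with_stream(config, "truth", {
    lab <- sample(.origin_labels, n, replace = TRUE,
                  prob = config$origin_proportions)
    is_de <- stats::runif(n) < config$de_fraction
    sign <- sample(c(-1, 1), n, replace = TRUE)
    prov_in_array <- stats::runif(n) < 0.5
    prov_sperm <- stats::runif(n) < 0.5
    tibble(
      gene_id = gene_id,
      true_origin = lab,
      is_de = is_de,
      true_log2fc = ifelse(is_de, sign * config$de_log2fc, 0),
      sperm_expressed = ifelse(lab == "provisional", prov_sperm,
                               lab %in% c("sperm_and_oocyte", "sperm_only")),
      oocyte_array_expressed = ifelse(
        lab == "provisional", prov_in_array,
        lab %in% c("sperm_and_oocyte", "oocyte_only")),
      oocyte_rnaseq_expressed = ifelse(
        lab == "provisional", !prov_in_array,
        lab %in% c("sperm_and_oocyte", "oocyte_only"))
    )
  })

  embryo_mat <- .with_stream(config, "embryo", {
    k <- config$n_embryo_reps_per_group
    mean_hi <- config$nb_mean * 2^(truth$true_log2fc / 2)
    mean_lo <- config$nb_mean * 2^(-truth$true_log2fc / 2)
    cbind(.rnb_matrix(mean_hi, k, config$nb_dispersion),
          .rnb_matrix(mean_lo, k, config$nb_dispersion))
  })
  k <- config$n_embryo_reps_per_group
  colnames(embryo_mat) <- c(sprintf("embryo_high_%d", seq_len(k)),
                            sprintf("embryo_low_%d", seq_len(k)))
  samples <- sample_sheet(colnames(embryo_mat), "embryo",
                          rep(c("high", "low"), each = k),
                          rep(seq_len(k), 2))

  sperm_mat <- .with_stream(config, "sperm", {
    means <- ifelse(truth$sperm_expressed, config$nb_mean,
                    config$background_mean)
    .rnb_matrix(means, config$n_sperm_samples, config$nb_dispersion)
  })
  colnames(sperm_mat) <- sprintf("sperm_%d", seq_len(config$n_sperm_samples))

  oo_mat <- .with_stream(config, "oocyte_rnaseq", {
    means <- ifelse(truth$oocyte_rnaseq_expressed, config$nb_mean,
                    config$background_mean)
    .rnb_matrix(means, config$n_oocyte_rnaseq_reps, config$nb_dispersion)
  })
  colnames(oo_mat) <- sprintf("oocyte_%d", seq_len(config$n_oocyte_rnaseq_reps))

  array_tbl <- .with_stream(config, "oocyte_array", {
    means <- ifelse(truth$oocyte_array_expressed, config$array_expressed_mean,
                    config$array_background_mean)
    intensity <- means * exp(rnorm(n, 0, config$array_intensity_sdlog))
    tibble(probe_id = sprintf("PROBE%05d", seq_len(n)),
           gene_id = gene_id, array_1 = intensity)
  })

  as_counts <- function(mat) {
    dplyr::bind_cols(tibble(gene_id = gene_id), as_tibble(as.data.frame(mat)))
  }
  structure(list(
    truth = truth,
    embryo = as_counts(embryo_mat),
    sperm = as_counts(sperm_mat),
    oocyte_rnaseq = as_counts(oo_mat),
    oocyte_array = array_tbl,
    samples = samples,
    config = config
  ), class = "origin_sim")
}

#' @export
print.origin_sim <- function(x, ...) {
  cat(sprintf(
    "<origin_sim> %d genes; embryo %d+%d, sperm %d, oocyte RNA-seq %d, array 1\n",
    nrow(x$truth), x$config$n_embryo_reps_per_group,
    x$config$n_embryo_reps_per_group, x$config$n_sperm_samples,
    x$config$n_oocyte_rnaseq_reps))
  print(table(x$truth$true_origin))
  invisible(x)
}

#' Simulate a qPCR plate with planted fold changes
#'
#' For each requested gene, emits reference- and target-gene CT values for
#' three replicate case/control pairs such that in expectation
#' \eqn{\Delta\Delta CT = -\log_2 f} for the planted fold change `f`
#' (\eqn{2^{true\_log2fc}} for planted DE genes, 1 otherwise, unless
#' overridden via `folds`). Gaussian noise of SD `qpcr_noise_sd` cycles is
#' added to every CT. The reference gene (`ACTB`) is appended
#' automatically with zero planted effect.
#'
#' @param truth Truth tibble from [simulate_dataset()].
#' @param genes Character vector of target genes, a subset of
#'   `truth$gene_id`.
#' @param config A [sim_config()].
#' @param folds Optional named numeric vector overriding the planted fold
#'   per gene.
#' @param n_replicates Number of replicate pairs (default 3).
#' @param case_group,control_group Group labels to emit.
#' @return A qPCR tibble in the [read_qpcr_table()] layout.
#' @export
simulate_qpcr <- function(truth, genes, config = sim_config(), folds = NULL,
                          n_replicates = 3L, case_group = "high",
                          control_group = "low") {
  missing <- setdiff(genes, truth$gene_id)
  if (length(missing)) {
    abort(sprintf("gene(s) not in truth table: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  planted <- 2^truth$true_log2fc[match(genes, truth$gene_id)]
  names(planted) <- genes
  if (!is.null(folds)) planted[names(folds)] <- folds
  ref_gene <- "ACTB"
  ref_ct <- 15
  base_ct <- 25
  .with_stream(config, "qpcr", {
    rows <- purrr::map_dfr(seq_len(n_replicates), function(r) {
      dplyr::bind_rows(
        tibble(replicate = r, group = case_group, gene_id = genes,
               ct = base_ct - unname(log2(planted))),
        tibble(replicate = r, group = control_group, gene_id = genes,
               ct = base_ct),
        tibble(replicate = r, group = c(case_group, control_group),
               gene_id = ref_gene, ct = ref_ct)
      )
    })
    rows$ct <- rows$ct + rnorm(nrow(rows), 0, config$qpcr_noise_sd)
    rows$replicate <- as.integer(rows$replicate)
    rows
  })
}

#' Simulate paired embryo development tallies
#'
#' For each IVF replicate and each arm in `config$rates`, draws
#' `n_cleaved ~ Binomial(n_oocytes, cleavage rate)` and then
#' `n_blastocyst ~ Binomial(n_cleaved, blastocyst rate)` — the blastocyst
#' rate is conditional on cleavage, matching how the rates are defined
#' downstream.
#'
#' @param config A [sim_config()].
#' @return A tally tibble in the [read_tally_table()] layout.
#' @export
simulate_tallies <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) abort("`config` must come from sim_config()")
  .with_stream(config, "tallies", {
    purrr::map_dfr(seq_len(config$n_tally_replicates), function(r) {
      purrr::imap_dfr(config$rates, function(p, arm) {
        n_cleaved <- rbinom(1, config$n_oocytes_per_arm, p[["cleavage"]])
        n_blast <- rbinom(1, n_cleaved, p[["blastocyst"]])
        tibble(replicate = as.integer(r), arm = arm,
               n_oocytes = config$n_oocytes_per_arm,
               n_cleaved = as.integer(n_cleaved),
               n_blastocyst = as.integer(n_blast))
      })
    })
  })
}

#' Run the origin classifier on a simulated dataset
#'
#' Convenience wrapper chaining the presence callers, the oocyte consensus
#' and [classify_origins()] over the tables of an `origin_sim`, using the
#' simulated gene universe for every dataset (so nothing is
#' `not_measured` unless a table genuinely lacks the gene).
#'
#' @param sim An `origin_sim` from [simulate_dataset()].
#' @param thresholds A [threshold_config()].
#' @return An `origin_assignments` tibble.
#' @export
classify_sim <- function(sim, thresholds = threshold_config()) {
  universe <- sim$truth$gene_id
  classify_origins(
    embryo_calls = call_expression_counts(sim$embryo, thresholds),
    sperm_calls = call_expression_counts(sim$sperm, thresholds,
                                         universe = universe),
    oocyte_calls_a = call_expression_array(sim$oocyte_array, thresholds,
                                           universe = universe),
    oocyte_calls_b = call_expression_counts(sim$oocyte_rnaseq, thresholds,
                                            universe = universe)
  )
}

#' Audit classifier/truth disagreements on simulated data
#'
#' For each gene whose assigned label differs from its planted origin,
#' checks whether the disagreement is attributable to a threshold-boundary
#' event in the noisy measurements: a planted-expressed gene whose counts
#' all fell at or below the read cutoff (or whose probe fell below the
#' intensity cutoff), or a planted-background gene that fluctuated above
#' it. Since the callers are deterministic in the data, every disagreement
#' should be explained this way; an unexplained row would indicate a
#' classifier defect rather than sampling noise.
#'
#' @param sim An `origin_sim`.
#' @param assignments Output of [classify_sim()] on the same object.
#' @param thresholds The [threshold_config()] used for classification.
#' @return A tibble with one row per disagreeing gene: `gene_id`,
#'   `true_origin`, `label`, `boundary_dataset` (which measurement crossed
#'   the threshold against its planted level) and `explained` (logical).
#' @export
audit_disagreements <- function(sim, assignments,
                                thresholds = threshold_config()) {
  thresholds <- .as_thresholds(thresholds)
  joined <- dplyr::inner_join(
    dplyr::select(sim$truth, "gene_id", "true_origin", "sperm_expressed",
                  "oocyte_array_expressed", "oocyte_rnaseq_expressed"),
    dplyr::select(as_tibble(assignments), "gene_id", "label", "sperm",
                  "oocyte_ref1", "oocyte_ref2"),
    by = "gene_id"
  ) |>
    dplyr::filter(.data$true_origin != .data$label)
  if (nrow(joined) == 0) {
    return(tibble(gene_id = character(0), true_origin = character(0),
                  label = character(0), boundary_dataset = character(0),
                  explained = logical(0)))
  }
  flips <- joined |>
    dplyr::mutate(
      sperm_flip = (.data$sperm == "expressed") != .data$sperm_expressed,
      array_flip = (.data$oocyte_ref1 == "expressed") != .data$oocyte_array_expressed,
      rnaseq_flip = (.data$oocyte_ref2 == "expressed") != .data$oocyte_rnaseq_expressed
    )
  flips |>
    dplyr::mutate(
      boundary_dataset = purrr::pmap_chr(
        list(.data$sperm_flip, .data$array_flip, .data$rnaseq_flip),
        function(s, a, r) {
          paste(c("sperm", "oocyte_array", "oocyte_rnaseq")[c(s, a, r)],
                collapse = "+")
        }),
      explained = .data$sperm_flip | .data$array_flip | .data$rnaseq_flip
    ) |>
    dplyr::select("gene_id", "true_origin", "label", "boundary_dataset",
                  "explained")
}
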