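# Seeded synthetic-data generators. Every generator is a pure function of
# its configuration: identical config (including seed) gives bit-identical
# output. A single global seed is fanned out to independent per-generator
# streams with a counter-based derivation, so adding a generator never
# perturbs the streams of existing ones.

#' Simulation configuration
#'
#' Defaults emulate the study designs the pipeline was built around: 25
#' association signals, an LD block with geometrically decaying correlation,
#' evidence tables with per-category occurrence probabilities, and 3-group
#' expression data sized like the bronchial-epithelium design (20 control,
#' 50 mild-moderate, 38 severe). `blood_group_sizes()` gives the whole-blood
#' design (87/77/246).
#'
#' @param seed global integer seed, fanned out per generator.
#' @param n_signals number of simulated association signals.
#' @param n_genes_per_signal genes scored per signal (first gene of each
#'   signal is the designated true gene).
#' @param elevated_prob per-category evidence probability for the designated
#'   true gene.
#' @param background_prob per-category evidence probability for decoy genes.
#' @param ld_decay per-position allelic correlation decay in `(0, 1)`;
#'   r-squared between positions `i`, `j` is `ld_decay^(2|i-j|)`.
#' @param group_sizes named integer triple
#'   (control / mild_moderate / severe).
#' @param effect_sd_units additive group-mean shift for planted genes, in
#'   units of the gene's baseline standard deviation.
#' @param pi0 true-null proportion for p-value ensembles.
#' @param alt_beta_params shape parameters of the Beta alternative
#'   distribution for p-value ensembles.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_signals = 25L,
                       n_genes_per_signal = 5L,
                       elevated_prob = 0.8,
                       background_prob = 0.05,
                       ld_decay = 0.9,
                       group_sizes = c(control = 20L, mild_moderate = 50L,
                                       severe = 38L),
                       effect_sd_units = 2,
                       pi0 = 0.8,
                       alt_beta_params = c(0.1, 1)) {
  stopifnot(is_count(seed + 1), is_count(n_signals),
            is_count(n_genes_per_signal),
            is_fraction(elevated_prob), is_fraction(background_prob),
            is_fraction(ld_decay, open_left = TRUE, open_right = TRUE),
            length(group_sizes) == 3L, all(group_sizes >= 3L),
            effect_sd_units >= 0, is_fraction(pi0),
            length(alt_beta_params) == 2L, all(alt_beta_params > 0))
  structure(list(seed = as.integer(seed), n_signals = as.integer(n_signals),
                 n_genes_per_signal = as.integer(n_genes_per_signal),
                 elevated_prob = elevated_prob,
                 background_prob = background_prob, ld_decay = ld_decay,
                 group_sizes = group_sizes,
                 effect_sd_units = effect_sd_units, pi0 = pi0,
                 alt_beta_params = alt_beta_params),
            class = "sim_config")
}

#' Whole-blood design group sizes
#' @return named integer vector (87 control, 77 mild-moderate, 246 severe).
#' @export
blood_group_sizes <- function() {
  c(control = 87L, mild_moderate = 77L, severe = 246L)
}

#' Generate an LD block with geometric r-squared decay
#'
#' Deterministic closed form: `r2[i, j] = ld_decay^(2 * |i - j|)`, diagonal
#' 1, symmetric, all values in `[0, 1]`. The seed argument is accepted for
#' interface uniformity with the other generators; the block itself is a
#' pure function of `n_snps` and `ld_decay`.
#'
#' @param n_snps number of variants (>= 2).
#' @param ld_decay per-position correlation decay in `(0, 1)`.
#' @param seed unused, kept for generator-interface uniformity.
#' @return `n_snps x n_snps` symmetric r-squared matrix with rsid-style
#'   dimnames (`snp_1`, ...).
#' @export
gen_ld_block <- function(n_snps, ld_decay, seed = 1L) {
  stopifnot(is_count(n_snps), n_snps >= 2L,
            is_fraction(ld_decay, open_left = TRUE, open_right = TRUE))
  idx <- seq_len(n_snps)
  m <- ld_decay^(2 * abs(outer(idx, idx, `-`)))
  dimnames(m) <- list(paste0("snp_", idx), paste0("snp_", idx))
  m
}

#' Long-format LD pairs of a generated block
#'
#' @param block output of [gen_ld_block()].
#' @return data.frame `rsid_a`, `rsid_b`, `r2` (upper triangle only).
#' @export
ld_block_pairs <- function(block) {
  stopifnot(is.matrix(block))
  idx <- which(upper.tri(block), arr.ind = TRUE)
  data.frame(rsid_a = rownames(block)[idx[, 1L]],
             rsid_b = colnames(block)[idx[, 2L]],
             r2 = block[idx], stringsAsFactors = FALSE)
}

#' Generate an evidence table with planted true genes
#'
#' Per signal, one designated true gene receives each of the fourteen
#' evidence categories independently with probability
#' `config$elevated_prob`; decoy genes with `config$background_prob`.
#' Present records carry a significant p-value (uniform below 0.05 for
#' p-carrying categories), a signed effect, and, for the colocalization
#' category, an H4 above 0.8 — i.e. records emulate evidence that already
#' passed the upstream significance filters.
#'
#' @param config a [sim_config()].
#' @return list with `evidence` (data.frame in the evidence-record schema)
#'   and `truth` (data.frame `signal_rsid`, `true_gene`).
#' @export
gen_evidence <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "evidence"))
  cats <- evidence_categories()
  p_cats <- setdiff(cats, c("otg_v2g", "otg_coloc", "functional_variant_ld",
                            "literature"))
  rows <- list()
  truth <- data.frame(signal_rsid = character(), true_gene = character(),
                      stringsAsFactors = FALSE)
  for (s in seq_len(config$n_signals)) {
    rsid <- sprintf("rs_sim_%03d", s)
    genes <- sprintf("GENE_%03d_%d", s, seq_len(config$n_genes_per_signal))
    truth <- rbind(truth, data.frame(signal_rsid = rsid, true_gene = genes[1L],
                                     stringsAsFactors = FALSE))
    for (gi in seq_along(genes)) {
      prob <- if (gi == 1L) config$elevated_prob else config$background_prob
      present <- cats[stats::runif(length(cats)) < prob]
      if (!length(present)) next
      rows[[length(rows) + 1L]] <- data.frame(
        signal_rsid = rsid, gene = genes[gi], category = present,
        tissue = ifelse(grepl("blood", present), "whole_blood", "lung"),
        p_value = ifelse(present %in% p_cats,
                         stats::runif(length(present), 1e-8, 0.05), NA_real_),
        effect_b = stats::rnorm(length(present), 0, 0.3),
        h4 = ifelse(present == "otg_coloc",
                    stats::runif(length(present), 0.8, 1), NA_real_),
        stringsAsFactors = FALSE)
    }
  }
  evidence <- if (length(rows)) do.call(rbind, rows) else
    data.frame(signal_rsid = character(), gene = character(),
               category = character(), tissue = character(),
               p_value = numeric(), effect_b = numeric(), h4 = numeric(),
               stringsAsFactors = FALSE)
  rownames(evidence) <- NULL
  list(evidence = evidence, truth = truth)
}

#' Generate a 3-group expression dataset with planted DE genes
#'
#' Each gene gets a log-normal baseline (right-skewed, as microarray
#' intensities are; this also exercises the normality gate). Planted genes
#' receive additive group-mean shifts in units of the gene's baseline
#' standard deviation: the severe group is shifted by the full
#' `effect_sd_units`, the mild-moderate group by half of it (a graded
#' disease-severity pattern). `dist = "normal"` swaps the baseline for a
#' Gaussian with matching moments (useful to exercise the Welch path).
#'
#' @param config a [sim_config()].
#' @param n_genes total genes simulated.
#' @param n_de number of planted differentially expressed genes (the first
#'   `n_de` genes).
#' @param dist `"lognormal"` (default) or `"normal"` baseline noise.
#' @return list with `dataset` (an [expression_dataset()]) and `truth`
#'   (data.frame `gene`, `planted`).
#' @export
gen_expression <- function(config, n_genes = 100L, n_de = 10L,
                           dist = c("lognormal", "normal")) {
  stopifnot(inherits(config, "sim_config"), is_count(n_genes),
            n_de >= 0, n_de <= n_genes)
  dist <- match.arg(dist)
  set.seed(derive_seed(config$seed, paste0("expression_", dist)))
  sizes <- config$group_sizes
  groups <- factor(rep(names(sizes), sizes), levels = names(sizes))
  n <- sum(sizes)
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  values <- matrix(NA_real_, n_genes, n,
                   dimnames = list(genes, sprintf("sample_%03d", seq_len(n))))
  sdlog <- 0.5
  for (g in seq_len(n_genes)) {
    meanlog <- stats::runif(1L, 2, 4)
    base_sd <- sqrt((exp(sdlog^2) - 1) * exp(2 * meanlog + sdlog^2))
    x <- if (dist == "lognormal") {
      stats::rlnorm(n, meanlog, sdlog)
    } else {
      stats::rnorm(n, exp(meanlog + sdlog^2 / 2), base_sd)
    }
    if (g <= n_de && config$effect_sd_units > 0) {
      shift <- config$effect_sd_units * base_sd
      x[groups == "severe"] <- x[groups == "severe"] + shift
      x[groups == "mild_moderate"] <- x[groups == "mild_moderate"] + shift / 2
    }
    values[g, ] <- x
  }
  dataset <- expression_dataset(values,
                                stats::setNames(as.character(groups),
                                                colnames(values)))
  list(dataset = dataset,
       truth = data.frame(gene = genes, planted = seq_len(n_genes) <= n_de,
                          stringsAsFactors = FALSE))
}

#' Generate a labelled p-value ensemble
#'
#' `floor(pi0 * m)` true nulls drawn Uniform(0, 1); the remainder drawn from
#' a Beta alternative (small first shape parameter concentrates mass near
#' zero).
#'
#' @param m ensemble size (>= 1).
#' @param pi0 true-null proportion in `[0, 1]`.
#' @param alt_beta_params Beta shape pair for alternatives.
#' @param seed integer seed.
#' @return data.frame `p_value`, `is_null` (nulls first).
#' @export
gen_pvalues <- function(m, pi0 = 0.8, alt_beta_params = c(0.1, 1), seed = 1L) {
  stopifnot(is_count(m), is_fraction(pi0), length(alt_beta_params) == 2L,
            all(alt_beta_params > 0))
  set.seed(derive_seed(seed, "pvalues"))
  n_null <- floor(pi0 * m)
  p <- c(stats::runif(n_null),
         stats::rbeta(m - n_null, alt_beta_params[1L], alt_beta_params[2L]))
  data.frame(p_value = p,
             is_null = seq_len(m) <= n_null,
             stringsAsFactors = FALSE)
}

#' Write a complete simulated fixture directory
#'
#' Emits, in the same TSV dialects the pipeline reads: an LD pair table and
#' availability list, an evidence table with truth labels, an expression
#' matrix with its sample sheet and truth labels, and a PheWAS summary table
#' with planted significant associations.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written file paths.
#' @export
write_simulated_inputs <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    ld_pairs = file.path(dir, "ld_pairs.tsv"),
    available = file.path(dir, "available_rsids.txt"),
    evidence = file.path(dir, "evidence.tsv"),
    evidence_truth = file.path(dir, "evidence_truth.tsv"),
    expression = file.path(dir, "expression_matrix.tsv"),
    samples = file.path(dir, "samples.tsv"),
    expression_truth = file.path(dir, "expression_truth.tsv"),
    phewas = file.path(dir, "phewas.tsv"),
    phewas_truth = file.path(dir, "phewas_truth.tsv")
  )
  block <- gen_ld_block(20L, config$ld_decay)
  pairs <- ld_block_pairs(block)
  sentinel_pairs <- pairs[pairs$rsid_a == "snp_1" | pairs$rsid_b == "snp_1", ]
  write_table(sentinel_pairs, paths[["ld_pairs"]])
  writeLines(rownames(block)[seq(3L, 20L, by = 2L)], paths[["available"]])
  ev <- gen_evidence(config)
  write_table(ev$evidence, paths[["evidence"]])
  write_table(ev$truth, paths[["evidence_truth"]])
  ex <- gen_expression(config)
  mat <- data.frame(gene = rownames(ex$dataset$values),
                    ex$dataset$values, check.names = FALSE)
  write_table(mat, paths[["expression"]])
  write_table(data.frame(sample = colnames(ex$dataset$values),
                         group = as.character(ex$dataset$group)),
              paths[["samples"]])
  write_table(ex$truth, paths[["expression_truth"]])
  ph <- gen_phewas(config)
  write_table(ph[, setdiff(names(ph), "planted")], paths[["phewas"]])
  write_table(ph[, c("rsid", "trait", "planted")], paths[["phewas_truth"]])
  invisible(paths)
}

#' Generate a PheWAS summary table with planted associations
#'
#' For each simulated signal: one planted asthma association far below the
#' Bonferroni threshold, one planted blood-cell trait association, and a
#' panel of null traits with uniform p-values. Disease traits carry odds
#' ratios (protective for a subset).
#'
#' @param config a [sim_config()].
#' @param n_null_traits null traits per signal (default 20).
#' @return data.frame in the PheWAS record schema, plus a `planted` column.
#' @export
gen_phewas <- function(config, n_null_traits = 20L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "phewas"))
  rows <- list()
  null_traits <- sprintf("null trait %02d", seq_len(n_null_traits))
  for (s in seq_len(config$n_signals)) {
    rsid <- sprintf("rs_sim_%03d", s)
    or_asthma <- exp(stats::runif(1L, 0.05, 0.3))
    rows[[length(rows) + 1L]] <- data.frame(
      rsid = rsid,
      trait = c("asthma", "eosinophil count", null_traits),
      effect = c(log(or_asthma), stats::rnorm(1L, 0.05, 0.01),
                 stats::rnorm(n_null_traits, 0, 0.01)),
      p_value = c(10^stats::runif(2L, -30, -10),
                  stats::runif(n_null_traits)),
      odds_ratio = c(or_asthma, rep(NA_real_, 1L + n_null_traits)),
      planted = c(TRUE, TRUE, rep(FALSE, n_null_traits)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
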