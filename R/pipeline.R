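# End-to-end orchestration: a YAML config enables individual stages
# (proxy -> scoring/selection -> phewas -> de -> enrichment -> profiles ->
# coloc -> drugs), every stage reads/writes the package's TSV dialects, and
# the run is summarized in a machine-readable report. Re-running with an
# identical config and inputs is byte-identical in all outputs.

default_params <- function() {
  list(r2_min = 0.2, alpha = 0.05, n_traits = 778L, q = 0.05,
       gate_alpha = 0.05, enrichment_mode = "ease", fold = 4,
       coloc_cutoff = 0.8, min_score = 1.0, score_threshold = 3L)
}

#' Run the translational pipeline from a configuration
#'
#' Executes the enabled stages in order. Any stage can be disabled; a failed
#' stage aborts with the stage name in the error. With `simulate: true` the
#' synthetic generators write a complete input directory under
#' `out_dir/sim_inputs` first (seeded, so the whole run is reproducible).
#'
#' @param config path to a YAML configuration or an equivalent named list.
#'   Keys: `out_dir`, `seed`, `simulate`, `stages` (named logical),
#'   `inputs` (named paths, or `"fixture"` for packaged tables), `params`
#'   (see `default_params` in the source for names and defaults),
#'   `overrides` (signal -> gene literature overrides).
#' @return a `run_report` object (also written to `out_dir/run_report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% stop("config needs out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- utils::modifyList(default_params(), config$params %||% list())
  stages <- config$stages %||% list()
  inputs <- config$inputs %||% list()
  seed <- config$seed %||% 1L
  report <- list(
    package_version = as.character(utils::packageVersion("gwastrans")),
    config_hash = stable_hash(config),
    thresholds = params,
    stages = list(),
    annotations = character()
  )
  enabled <- function(name) isTRUE(stages[[name]])
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (isTRUE(config$simulate)) {
    sim_dir <- file.path(out_dir, "sim_inputs")
    cfg <- sim_config(seed = seed)
    paths <- write_simulated_inputs(cfg, sim_dir)
    defaults <- list(ld_pairs = paths[["ld_pairs"]],
                     available = paths[["available"]],
                     evidence = paths[["evidence"]],
                     phewas = paths[["phewas"]],
                     expression_matrix = paths[["expression"]],
                     samples = paths[["samples"]])
    inputs <- utils::modifyList(defaults, inputs)
  }

  cards <- NULL
  cands <- NULL

  if (enabled("proxy")) {
    run_stage("proxy", function() {
      pairs <- read_ld_pairs(inputs$ld_pairs)
      available <- read_availability(inputs$available)
      sentinels <- config$sentinels %||%
        unique(c(pairs$rsid_a, pairs$rsid_b))[1L]
      choices <- lapply(sentinels, function(s) {
        nb <- pairs[pairs$rsid_a == s | pairs$rsid_b == s, , drop = FALSE]
        ch <- tryCatch(select_proxy(s, nb, available, params$r2_min),
                       no_proxy = function(e) NULL)
        if (is.null(ch)) {
          data.frame(sentinel = s, chosen = NA_character_, r2 = NA_real_,
                     is_self = FALSE, stringsAsFactors = FALSE)
        } else {
          data.frame(sentinel = ch$sentinel, chosen = ch$chosen, r2 = ch$r2,
                     is_self = ch$is_self, stringsAsFactors = FALSE)
        }
      })
      out <- do.call(rbind, choices)
      write_table(out, file.path(out_dir, "proxies.tsv"))
      report$stages$proxy <<- list(n_sentinels = length(sentinels),
                                   n_resolved = sum(!is.na(out$chosen)))
    })
  }

  if (enabled("score")) {
    run_stage("score", function() {
      scheme <- weight_scheme(threshold = params$score_threshold)
      cards <<- if (!is.null(inputs$scorecards)) {
        src <- if (identical(inputs$scorecards, "fixture")) {
          load_fixture("evidence_scores")
        } else {
          read_table(inputs$scorecards, schema_scorecards())
        }
        as_scorecards(src, scheme)
      } else {
        score_evidence(read_evidence(inputs$evidence), scheme)
      }
      overrides <- unlist(config$overrides %||% NULL)
      reference <- if (identical(inputs$reference_genes, "fixture")) {
        load_fixture("candidate_genes")$gene
      } else if (!is.null(inputs$reference_genes)) {
        read_availability(inputs$reference_genes)
      }
      cands <<- select_candidates(cards, scheme, overrides = overrides,
                                  reference_genes = reference)
      write_table(as.data.frame(cards), file.path(out_dir, "scorecards.tsv"))
      write_candidates_json(cands, file.path(out_dir, "candidates.json"))
      by_rule <- unique(cands$per_signal[, c("signal_rsid", "rule")])
      report$stages$score <<- list(
        n_signals = length(unique(cards$signal_rsid)),
        n_pairs = nrow(cards),
        n_threshold_signals =
          sum(tapply(by_rule$rule == "threshold", by_rule$signal_rsid, any)),
        n_candidate_genes = length(cands$unique_genes),
        selection = stats::setNames(
          cands$per_signal$rule, paste(cands$per_signal$signal_rsid,
                                       cands$per_signal$gene)))
      report$annotations <<- c(report$annotations, cands$annotations)
    })
  }

  if (enabled("phewas")) {
    run_stage("phewas", function() {
      records <- read_phewas(inputs$phewas)
      groups <- if (!is.null(inputs$trait_groups)) {
        read_trait_groups(inputs$trait_groups)
      }
      threshold <- bonferroni_threshold(params$alpha, params$n_traits)
      screened <- screen_traits(records, threshold, groups)
      write_table(screened, file.path(out_dir, "phewas_significant.tsv"))
      m <- significance_matrix(screened)
      write_table(data.frame(rsid = rownames(m), m, check.names = FALSE),
                  file.path(out_dir, "phewas_matrix.tsv"))
      report$stages$phewas <<- list(
        n_records = nrow(records), n_significant = nrow(screened),
        threshold = threshold,
        threshold_display = display_threshold(threshold))
    })
  }

  if (enabled("de")) {
    run_stage("de", function() {
      dataset <- read_expression(inputs$expression_matrix, inputs$samples)
      de <- run_de(dataset, q = params$q, alpha_gate = params$gate_alpha,
                   force_test = config$force_test %||% NULL)
      write_table(as.data.frame(de), file.path(out_dir, "de_results.tsv"))
      report$stages$de <<- list(
        n_genes = nrow(de), n_significant = sum(de$significant),
        tests = as.list(table(de$test_used)))
    })
  }

  if (enabled("enrich")) {
    run_stage("enrich", function() {
      collection <- read_gmt(inputs$gmt)
      query <- if (!is.null(cands)) cands$unique_genes else
        read_availability(inputs$query_genes)
      enr <- term_enrichment(query, collection, mode = params$enrichment_mode)
      write_table(as.data.frame(enr), file.path(out_dir, "enrichment.tsv"))
      report$stages$enrich <<- list(
        n_terms = nrow(enr), n_significant = sum(enr$fdr_q < 0.05))
    })
  }

  if (enabled("profiles")) {
    run_stage("profiles", function() {
      profiles <- read_profiles(inputs$profiles)
      flags <- lapply(split(profiles, profiles$gene), function(d) {
        enriched <- enrichment_flag(stats::setNames(d$value, d$class),
                                    fold = params$fold)
        data.frame(gene = d$gene[1L],
                   enriched_in = paste(enriched, collapse = ","),
                   stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, flags)
      write_table(out, file.path(out_dir, "profile_flags.tsv"))
      report$stages$profiles <<- list(
        n_genes = length(unique(profiles$gene)),
        n_enriched = sum(out$enriched_in != ""))
    })
  }

  if (enabled("coloc")) {
    run_stage("coloc", function() {
      records <- read_coloc(inputs$coloc)
      summaries <- coloc_summarize(records, cutoff = params$coloc_cutoff)
      summaries$pattern <- vapply(unique(summaries$gene), function(g) {
        classify_coloc_pattern(summaries[summaries$gene == g, , drop = FALSE])
      }, character(1L))[summaries$gene]
      write_table(summaries, file.path(out_dir, "coloc_summary.tsv"))
      report$stages$coloc <<- list(
        n_records = nrow(records),
        n_gene_classes = nrow(summaries),
        n_linked = sum(summaries$linked))
    })
  }

  if (enabled("drugs")) {
    run_stage("drugs", function() {
      records <- if (identical(inputs$drugs, "fixture")) {
        load_fixture("drug_table")
      } else {
        read_drug_interactions(inputs$drugs)
      }
      channels <- filter_interactions(records, min_score = params$min_score)
      genes <- if (identical(inputs$drugs, "fixture")) drug_gene_universe()
               else unique(records$gene)
      summary <- summarize_druggability(
        rbind(channels$scored, channels$trials), genes = genes)
      write_table(channels$scored, file.path(out_dir, "drug_scored.tsv"))
      write_table(summary, file.path(out_dir, "drug_summary.tsv"))
      report$stages$drugs <<- list(
        n_records = nrow(records),
        n_scored_retained = nrow(channels$scored),
        n_genes_with_scored = sum(summary$n_scored > 0))
    })
  }

  report <- structure(report, class = "run_report")
  write_report_json(report, file.path(out_dir, "run_report.json"))
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a run report to JSON
#' @param report a `run_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run report back from JSON
#' @param path JSON path written by [write_report_json()].
#' @return a `run_report` object.
#' @export
read_report_json <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run (gwastrans %s, config %s)\n",
              x$package_version, x$config_hash))
  for (s in names(x$stages)) {
    counts <- x$stages[[s]]
    scalars <- counts[vapply(counts, function(v)
      is.atomic(v) && length(v) == 1L, logical(1L))]
    cat(sprintf("  %-9s %s\n", s,
                paste(names(scalars), unlist(scalars), sep = "=",
                      collapse = ", ")))
  }
  if (length(x$annotations)) {
    cat("  annotations:\n")
    for (a in x$annotations) cat("   -", a, "\n")
  }
  invisible(x)
}
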