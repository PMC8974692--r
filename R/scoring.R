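# Weighted evidence scoring and candidate-gene selection.
#
# Each signal:gene pair collects evidence across fourteen categories; a
# category contributes its weight at most once (presence/absence, never
# multiplicity: a gene with eQTLs in five respiratory tissues still scores
# one point for that category). The total score s drives selection: all
# genes with s >= threshold are candidates; a signal with none falls back to
# its single highest-scoring gene; a literature override replaces a signal's
# selection entirely.

#' Score one signal:gene evidence bundle
#'
#' @param evidence data.frame of evidence records for a single signal:gene
#'   pair (columns `signal_rsid`, `gene`, `category`; significance filtering
#'   is assumed done upstream). Must be non-empty and single-pair.
#' @param scheme a [weight_scheme()].
#' @return a one-row `data.frame` scorecard: `signal_rsid`, `gene`,
#'   `base_score` (number of weight-1 categories present), `ub_count`
#'   (distinct U-BIOPRED compartments present, 0-3), `total`
#'   (`base_score + 2 * ub_count` under the default scheme; in general the
#'   sum of weights over categories present).
#' @examples
#' ev <- data.frame(signal_rsid = "rs1", gene = "G",
#'                  category = c("gtex_resp_eqtl", "ub_brush_eqtl"))
#' score_pair(ev, weight_scheme())
#' @export
score_pair <- function(evidence, scheme = weight_scheme()) {
  stopifnot(inherits(scheme, "weight_scheme"), is.data.frame(evidence))
  if (nrow(evidence) == 0L) {
    gt_stop("empty evidence list: a pair must have at least one record",
            "validation_error")
  }
  if (length(unique(evidence$signal_rsid)) != 1L ||
      length(unique(evidence$gene)) != 1L) {
    gt_stop("evidence records must all share one (signal, gene) pair",
            "validation_error")
  }
  unknown <- setdiff(unique(evidence$category), evidence_categories())
  if (length(unknown)) {
    gt_stop(sprintf("unknown evidence category: %s",
                    paste(unknown, collapse = ", ")), "validation_error")
  }
  present <- unique(evidence$category)
  ub <- intersect(present, ub_categories())
  base_cats <- setdiff(present, ub_categories())
  data.frame(
    signal_rsid = evidence$signal_rsid[1L],
    gene = evidence$gene[1L],
    base_score = as.integer(sum(scheme$weights[base_cats])),
    ub_count = length(ub),
    total = as.integer(sum(scheme$weights[present])),
    stringsAsFactors = FALSE
  )
}

#' Score every signal:gene pair in an evidence table
#'
#' @param evidence data.frame of evidence records (as from
#'   [read_evidence()] or [gen_evidence()]).
#' @param scheme a [weight_scheme()].
#' @return data.frame of scorecards, one row per (signal, gene) pair, in
#'   first-appearance order, with class `scorecards`.
#' @export
score_evidence <- function(evidence, scheme = weight_scheme()) {
  stopifnot(is.data.frame(evidence))
  if (nrow(evidence) == 0L) {
    out <- data.frame(signal_rsid = character(), gene = character(),
                      base_score = integer(), ub_count = integer(),
                      total = integer(), stringsAsFactors = FALSE)
    class(out) <- c("scorecards", "data.frame")
    return(out)
  }
  key <- paste(evidence$signal_rsid, evidence$gene, sep = "\r")
  pieces <- split(evidence, factor(key, levels = unique(key)))
  out <- do.call(rbind, lapply(pieces, score_pair, scheme = scheme))
  rownames(out) <- NULL
  class(out) <- c("scorecards", "data.frame")
  out
}

#' Turn a packaged or external score table into scorecards
#'
#' Accepts a data.frame that already carries `signal_rsid`, `gene`,
#' `base_score`, `ub_count` (compartment counts) and computes the weighted
#' total under the given scheme's U-BIOPRED weight.
#'
#' @param scores data.frame with columns `signal_rsid`, `gene`, `base_score`,
#'   `ub_count`.
#' @param scheme a [weight_scheme()] (its U-BIOPRED weight is applied; the
#'   default doubles each compartment).
#' @return `scorecards` data.frame.
#' @export
as_scorecards <- function(scores, scheme = weight_scheme()) {
  needed <- c("signal_rsid", "gene", "base_score", "ub_count")
  missing_cols <- setdiff(needed, names(scores))
  if (length(missing_cols)) {
    gt_stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
            "schema_error")
  }
  ub_w <- unique(scheme$weights[ub_categories()])
  if (length(ub_w) != 1L) {
    gt_stop("as_scorecards needs a single shared U-BIOPRED weight",
            "validation_error")
  }
  out <- data.frame(
    signal_rsid = scores$signal_rsid,
    gene = scores$gene,
    base_score = as.integer(scores$base_score),
    ub_count = as.integer(scores$ub_count),
    total = as.integer(scores$base_score + ub_w * scores$ub_count),
    stringsAsFactors = FALSE
  )
  class(out) <- c("scorecards", "data.frame")
  out
}

#' Select candidate causal genes per signal
#'
#' Applies the selection rules: all genes with total score at or above the
#' scheme threshold are selected (`rule = "threshold"`); for a signal with
#' none, the unique highest-scoring gene is selected
#' (`rule = "fallback_highest"`; a tie among top scores with no override is
#' an `"ambiguity_error"`); an entry in `overrides` replaces that signal's
#' selection entirely (`rule = "literature_override"`).
#'
#' @param cards `scorecards` data.frame (one row per signal:gene pair).
#' @param scheme a [weight_scheme()] (supplies the threshold).
#' @param overrides named character vector, signal rsid -> gene symbol; the
#'   gene must appear among that signal's scored genes.
#' @param reference_genes optional character vector of an expected candidate
#'   set; selected genes outside it are annotated, not dropped.
#' @return an object of class `candidate_set`: list with
#'   `per_signal` (data.frame `signal_rsid`, `gene`, `total`, `rule`),
#'   `unique_genes` (deduplicated union, first-appearance order),
#'   `annotations` (character vector of mismatch notes, possibly empty).
#' @examples
#' cards <- as_scorecards(data.frame(
#'   signal_rsid = c("rs1", "rs1", "rs2"),
#'   gene = c("A", "B", "C"),
#'   base_score = c(7L, 2L, 2L), ub_count = c(0L, 0L, 0L)))
#' select_candidates(cards)
#' @export
select_candidates <- function(cards, scheme = weight_scheme(),
                              overrides = NULL, reference_genes = NULL) {
  stopifnot(is.data.frame(cards))
  if (nrow(cards) == 0L) gt_stop("no scorecards supplied", "validation_error")
  signals <- unique(cards$signal_rsid)
  if (!is.null(overrides)) {
    stopifnot(!is.null(names(overrides)))
    bad <- setdiff(names(overrides), signals)
    if (length(bad)) {
      gt_stop(sprintf("override for unknown signal(s): %s",
                      paste(bad, collapse = ", ")), "validation_error")
    }
  }
  rows <- lapply(signals, function(s) {
    sub <- cards[cards$signal_rsid == s, , drop = FALSE]
    if (!is.null(overrides) && s %in% names(overrides)) {
      gene <- overrides[[s]]
      if (!gene %in% sub$gene) {
        gt_stop(sprintf("override gene %s not scored for signal %s", gene, s),
                "validation_error")
      }
      return(data.frame(signal_rsid = s, gene = gene,
                        total = sub$total[sub$gene == gene][1L],
                        rule = "literature_override",
                        stringsAsFactors = FALSE))
    }
    hit <- sub$total >= scheme$threshold
    if (any(hit)) {
      return(data.frame(signal_rsid = s, gene = sub$gene[hit],
                        total = sub$total[hit], rule = "threshold",
                        stringsAsFactors = FALSE))
    }
    top <- which(sub$total == max(sub$total))
    if (length(top) > 1L) {
      gt_stop(sprintf(
        "signal %s: fallback tie between genes %s (no override given)",
        s, paste(sub$gene[top], collapse = ", ")),
        "ambiguity_error", signal = s, tied_genes = sub$gene[top])
    }
    data.frame(signal_rsid = s, gene = sub$gene[top], total = sub$total[top],
               rule = "fallback_highest", stringsAsFactors = FALSE)
  })
  per_signal <- do.call(rbind, rows)
  rownames(per_signal) <- NULL
  unique_genes <- unique(per_signal$gene)
  annotations <- character()
  if (!is.null(reference_genes)) {
    extra <- setdiff(unique_genes, reference_genes)
    missing_genes <- setdiff(reference_genes, unique_genes)
    if (length(extra)) {
      annotations <- c(annotations, sprintf(
        "published-set mismatch: selected but not in reference set: %s",
        paste(extra, collapse = ", ")))
    }
    if (length(missing_genes)) {
      annotations <- c(annotations, sprintf(
        "published-set mismatch: in reference set but not selected: %s",
        paste(missing_genes, collapse = ", ")))
    }
  }
  structure(list(per_signal = per_signal, unique_genes = unique_genes,
                 annotations = annotations),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  n_sig <- length(unique(x$per_signal$signal_rsid))
  by_rule <- table(unique(x$per_signal[, c("signal_rsid", "rule")])$rule)
  cat(sprintf("Candidate set: %d genes across %d signals\n",
              length(x$unique_genes), n_sig))
  for (r in names(by_rule)) cat(sprintf("  signals via %s: %d\n", r, by_rule[[r]]))
  if (length(x$annotations)) {
    cat("  annotations:\n")
    for (a in x$annotations) cat("   -", a, "\n")
  }
  invisible(x)
}

#' Write a candidate set as JSON (with per-gene rule provenance)
#' @param cands a `candidate_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidates_json <- function(cands, path) {
  stopifnot(inherits(cands, "candidate_set"))
  jsonlite::write_json(
    list(per_signal = cands$per_signal, unique_genes = cands$unique_genes,
         annotations = cands$annotations),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
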