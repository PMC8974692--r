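# Drug-gene interaction triage: keep scored database interactions above the
# score cutoff, route clinical-trial-only records to their own channel, and
# summarize per-gene druggability over the full queried universe.

#' Filter drug-gene interaction records
#'
#' Scored database records are retained when `interaction_score` is strictly
#' greater than `min_score` (a score of exactly `min_score` is excluded).
#' Clinical-trial records (no score) pass through untouched to a separate
#' channel and are never counted as scored interactions.
#'
#' @param records data.frame as from [read_drug_interactions()] or
#'   `load_fixture("drug_table")` (columns `gene`, `drug`,
#'   `interaction_score`, `trial_ids`, `source`).
#' @param min_score score cutoff (default 1.0).
#' @return list with `scored` (retained scored records) and `trials`
#'   (clinical-trial channel).
#' @export
filter_interactions <- function(records, min_score = 1.0) {
  stopifnot(is.data.frame(records), is.numeric(min_score), min_score >= 0)
  if (is.null(records$source)) {
    records$source <- ifelse(!is.na(records$interaction_score),
                             "scored_db", "clinical_trial")
  }
  scored <- records[records$source == "scored_db" &
                      !is.na(records$interaction_score) &
                      records$interaction_score > min_score, , drop = FALSE]
  trials <- records[records$source == "clinical_trial", , drop = FALSE]
  rownames(scored) <- rownames(trials) <- NULL
  list(scored = scored, trials = trials)
}

#' The 42-gene universe queried for drug interactions
#'
#' The 37 candidate causal genes plus the 5 predicted interaction partners
#' (CD274, IL37, IRAK4, PDCD1LG2, ZAP70).
#'
#' @return character vector of 42 gene symbols.
#' @export
drug_gene_universe <- function() {
  c(load_fixture("candidate_genes")$gene,
    sort(c("CD274", "IL37", "IRAK4", "PDCD1LG2", "ZAP70")))
}

#' Per-gene druggability summary
#'
#' One row per queried gene, including genes with no interactions at all.
#' Scored-interaction counts come only from the scored channel; trial
#' records only set the trial flag and identifiers.
#'
#' @param records interaction data.frame (see [filter_interactions()]);
#'   pass pre-filtered records to summarize above a cutoff.
#' @param genes character vector of queried genes (default: the bundled
#'   42-gene universe).
#' @return data.frame: `gene`, `n_scored`, `max_score`, `has_trials`,
#'   `trial_ids` (comma-separated).
#' @export
summarize_druggability <- function(records, genes = drug_gene_universe()) {
  stopifnot(is.data.frame(records))
  if (is.null(records$source)) {
    records$source <- ifelse(!is.na(records$interaction_score),
                             "scored_db", "clinical_trial")
  }
  rows <- lapply(genes, function(g) {
    sub <- records[records$gene == g, , drop = FALSE]
    scored <- sub[sub$source == "scored_db", , drop = FALSE]
    ids <- sub$trial_ids[!is.na(sub$trial_ids) & sub$trial_ids != ""]
    ids <- unique(trimws(unlist(strsplit(ids, ","))))
    data.frame(gene = g,
               n_scored = nrow(scored),
               max_score = if (nrow(scored)) max(scored$interaction_score)
                           else NA_real_,
               has_trials = length(ids) > 0L,
               trial_ids = paste(ids, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
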