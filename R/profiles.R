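# Tissue / cell-type expression classification (the fourfold
# enriched/enhanced rule used by protein-atlas-style resources) and
# gene-level colocalization summaries (median posterior H4 against 0.8).

#' Flag enriched expression classes in a profile
#'
#' A class is enriched/enhanced when its expression is at least `fold` times
#' the expression of every other class (inclusive at the boundary, per the
#' "at least four times" rule). For `fold > 1` at most one class can qualify;
#' a class with zero expression never does.
#'
#' @param profile named numeric vector of non-negative expression values
#'   (NX for tissues, pTPM for cell types), one per class; at least 2
#'   classes.
#' @param fold enrichment factor (default 4).
#' @return character vector of enriched class labels (possibly empty).
#' @examples
#' enrichment_flag(c(A = 10, B = 2, C = 1)) # "A"
#' enrichment_flag(c(A = 7, B = 2, C = 1))  # none: 7 < 4 * 2
#' @export
enrichment_flag <- function(profile, fold = 4) {
  stopifnot(is.numeric(profile), fold > 0)
  if (length(profile) < 2L || is.null(names(profile))) {
    gt_stop("profile needs >= 2 named classes for the comparison",
            "undefined_comparison")
  }
  if (any(is.na(profile)) || any(profile < 0)) {
    gt_stop("expression values must be non-negative", "validation_error")
  }
  enriched <- vapply(seq_along(profile), function(i) {
    profile[i] > 0 && profile[i] >= fold * max(profile[-i])
  }, logical(1L))
  names(profile)[enriched]
}

#' Log-transform a pTPM matrix for heat-map display
#'
#' Elementwise `log10(value + pseudocount)`. The default pseudocount of 1
#' maps zero expression to zero and preserves ordering within every row and
#' column.
#'
#' @param values non-negative numeric matrix (gene x class).
#' @param pseudocount non-negative real added before the log (default 1).
#' @return transformed matrix of the same shape.
#' @examples
#' log_matrix(matrix(c(0, 9, 99, 999), 2)) # 0, 1, 2, 3
#' @export
log_matrix <- function(values, pseudocount = 1) {
  stopifnot(is.numeric(values), pseudocount >= 0)
  if (any(values < 0, na.rm = TRUE)) {
    gt_stop("expression values must be non-negative", "validation_error")
  }
  log10(values + pseudocount)
}

#' Summarize colocalization evidence per gene and tissue class
#'
#' Takes per-study posterior probabilities that the trait signal and the
#' gene's expression signal share a causal variant (H4) and reduces them to
#' the median per (gene, tissue class). A gene-class is "linked" when its
#' median H4 strictly exceeds 0.8 (the even-count median is the midpoint of
#' the two central values).
#'
#' @param records data.frame with columns `gene`, `tissue_class`, `h4`
#'   (each in `[0, 1]`).
#' @param cutoff linkage cutoff on the median H4 (strict `>`; default 0.8).
#' @return data.frame: `gene`, `tissue_class`, `n_records`, `median_h4`,
#'   `linked`.
#' @export
coloc_summarize <- function(records, cutoff = 0.8) {
  stopifnot(is.data.frame(records))
  needed <- c("gene", "tissue_class", "h4")
  if (!all(needed %in% names(records))) {
    gt_stop("records need columns gene, tissue_class, h4", "schema_error")
  }
  if (nrow(records) == 0L) {
    return(data.frame(gene = character(), tissue_class = character(),
                      n_records = integer(), median_h4 = numeric(),
                      linked = logical(), stringsAsFactors = FALSE))
  }
  if (any(records$h4 < 0 | records$h4 > 1)) {
    gt_stop("h4 must lie in [0, 1]", "validation_error")
  }
  key <- paste(records$gene, records$tissue_class, sep = "\r")
  pieces <- split(records, factor(key, levels = unique(key)))
  out <- do.call(rbind, lapply(pieces, function(d) {
    data.frame(gene = d$gene[1L], tissue_class = d$tissue_class[1L],
               n_records = nrow(d), median_h4 = stats::median(d$h4),
               stringsAsFactors = FALSE)
  }))
  out$linked <- out$median_h4 > cutoff
  rownames(out) <- NULL
  out
}

#' Classify a gene's colocalization pattern across tissue classes
#'
#' @param summaries rows of [coloc_summarize()] output for one gene,
#'   covering at most the two tissue classes `"lung"` and `"blood_immune"`.
#' @return one of `"lung_only"`, `"blood_only"`, `"both"`, `"neither"`,
#'   `"no_data"`.
#' @export
classify_coloc_pattern <- function(summaries) {
  stopifnot(is.data.frame(summaries))
  if (nrow(summaries) == 0L) return("no_data")
  if (length(unique(summaries$gene)) != 1L) {
    gt_stop("summaries must cover a single gene", "validation_error")
  }
  if (nrow(summaries) > 2L ||
      anyDuplicated(summaries$tissue_class)) {
    gt_stop("at most one summary per tissue class (max 2 classes)",
            "validation_error")
  }
  lung <- summaries$linked[summaries$tissue_class == "lung"]
  blood <- summaries$linked[summaries$tissue_class == "blood_immune"]
  lung <- isTRUE(any(lung))
  blood <- isTRUE(any(blood))
  if (lung && blood) "both"
  else if (lung) "lung_only"
  else if (blood) "blood_only"
  else "neither"
}
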