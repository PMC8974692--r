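# Phenome-wide trait screening: Bonferroni-corrected significance over a
# summary table of variant x trait associations, with trait grouping and
# effect orientation relative to the asthma risk allele.

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error level in `(0, 1)`.
#' @param n_traits number of traits tested.
#' @return `alpha / n_traits` at full precision. Use
#'   [display_threshold()] for the truncated 3-significant-digit display
#'   form (the convention used in the source trait database: 0.05/778 prints
#'   as 6.42e-05 although it rounds to 6.43e-05).
#' @examples
#' bonferroni_threshold(0.05, 778)
#' display_threshold(bonferroni_threshold(0.05, 778))
#' @export
bonferroni_threshold <- function(alpha, n_traits) {
  if (!is_fraction(alpha, open_left = TRUE, open_right = TRUE)) {
    gt_stop("alpha must be in (0, 1)", "validation_error")
  }
  if (!is_count(n_traits)) {
    gt_stop("n_traits must be a positive integer", "validation_error")
  }
  alpha / n_traits
}

#' Display form of a significance threshold
#'
#' Truncates (does not round) to `digits` significant digits, matching how
#' corrected thresholds are conventionally printed.
#'
#' @param threshold numeric threshold.
#' @param digits significant digits to keep (default 3).
#' @return numeric truncated value (e.g. `6.42e-05` for `0.05/778`).
#' @export
display_threshold <- function(threshold, digits = 3L) {
  trunc_signif(threshold, digits)
}

#' Read a trait-group map from YAML
#'
#' The YAML maps group names to lists of trait strings. Groups must be
#' disjoint over traits. Trait matching downstream is case-insensitive.
#'
#' @param path YAML file (see the bundled `trait_groups.yaml` for the
#'   format).
#' @return named list of character vectors.
#' @export
read_trait_groups <- function(path) {
  groups <- yaml::read_yaml(path)
  groups <- lapply(groups, as.character)
  all_traits <- tolower(unlist(groups, use.names = FALSE))
  if (anyDuplicated(all_traits)) {
    gt_stop("trait groups must be disjoint over traits", "validation_error")
  }
  groups
}

#' Screen PheWAS records against a significance threshold
#'
#' Retains records with `p_value` strictly below the threshold (so the
#' threshold itself is non-significant), annotates each retained record with
#' its trait group (`"ungrouped"` when unmatched), and flags protective
#' associations: a disease record with an odds ratio strictly below 1 is
#' protective with respect to the risk allele. Records without an odds ratio
#' (quantitative traits) are never flagged protective.
#'
#' @param records PheWAS data.frame (columns `rsid`, `trait`, `effect`,
#'   `p_value`, optional `odds_ratio`).
#' @param threshold significance threshold in `(0, 1)`; typically
#'   [bonferroni_threshold()].
#' @param groups optional trait-group map (see [read_trait_groups()]).
#' @return data.frame of retained records with added columns `group`,
#'   `protective` (logical) and `neg_log10_p`. Zero rows is a valid result.
#' @export
screen_traits <- function(records, threshold, groups = NULL) {
  stopifnot(is.data.frame(records))
  if (!is_fraction(threshold, open_left = TRUE, open_right = TRUE)) {
    gt_stop("threshold must be in (0, 1)", "validation_error")
  }
  out <- records[records$p_value < threshold, , drop = FALSE]
  if (is.null(out$odds_ratio)) out$odds_ratio <- NA_real_
  out$group <- "ungrouped"
  if (!is.null(groups) && nrow(out)) {
    for (g in names(groups)) {
      out$group[tolower(out$trait) %in% tolower(groups[[g]])] <- g
    }
  }
  out$protective <- !is.na(out$odds_ratio) & out$odds_ratio < 1
  out$neg_log10_p <- -log10(out$p_value)
  rownames(out) <- NULL
  out
}

#' Significance matrix of screened PheWAS results
#'
#' @param screened output of [screen_traits()].
#' @return numeric matrix, rsid x trait, of `-log10(p)` for retained
#'   associations and 0 elsewhere.
#' @export
significance_matrix <- function(screened) {
  stopifnot(is.data.frame(screened))
  rsids <- unique(screened$rsid)
  traits <- unique(screened$trait)
  m <- matrix(0, length(rsids), length(traits),
              dimnames = list(rsids, traits))
  if (nrow(screened)) {
    m[cbind(match(screened$rsid, rsids), match(screened$trait, traits))] <-
      screened$neg_log10_p
  }
  m
}
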