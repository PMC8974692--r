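#' Evidence categories recognised by the scoring scheme
#'
#' The closed set of fourteen signal-to-gene evidence categories: ten
#' singleton-weight database categories (GTEx respiratory and blood eQTL and
#' sQTL, Open Target Genetics respiratory and blood eQTL, variant-to-gene
#' assignment, colocalization study, HaploReg eQTL, tagged functional
#' variant), three U-BIOPRED airway eQTL compartments (bronchial brush,
#' bronchial biopsy, nasal brush) and a literature association category.
#'
#' @return character vector of category codes, in scheme order.
#' @export
evidence_categories <- function() {
  c(
    "gtex_resp_eqtl", "gtex_blood_eqtl", "gtex_resp_sqtl", "gtex_blood_sqtl",
    "otg_eqtl_resp", "otg_eqtl_blood", "otg_v2g", "otg_coloc",
    "haploreg_eqtl", "functional_variant_ld",
    "ub_brush_eqtl", "ub_biopsy_eqtl", "ub_nasal_eqtl",
    "literature"
  )
}

#' U-BIOPRED eQTL compartment categories
#'
#' The three airway compartments (bronchial brush, bronchial biopsy, nasal
#' brush) whose eQTL evidence carries double weight because of its
#' specificity to respiratory tissue.
#'
#' @return character vector of the three U-BIOPRED category codes.
#' @export
ub_categories <- function() {
  c("ub_brush_eqtl", "ub_biopsy_eqtl", "ub_nasal_eqtl")
}

#' Construct an evidence weighting scheme
#'
#' Builds the per-category point map used to score signal-to-gene evidence.
#' The default assigns 1 point to every category and 2 points to each of the
#' three U-BIOPRED eQTL compartments, with a candidate-selection threshold of
#' 3 points.
#'
#' @param weights named non-negative integer vector over
#'   [evidence_categories()]; `NULL` for the default scheme.
#' @param threshold integer selection threshold on the weighted total
#'   (inclusive, i.e. genes with total `>= threshold` are selected).
#' @return an object of class `weight_scheme`: a list with elements
#'   `weights` (named integer vector) and `threshold`.
#' @seealso [max_possible_score()], [score_pair()], [select_candidates()]
#' @examples
#' sc <- weight_scheme()
#' sc$weights[ub_categories()]
#' max_possible_score(sc)
#' @export
weight_scheme <- function(weights = NULL, threshold = 3L) {
  cats <- evidence_categories()
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1L, length(cats)), cats)
    weights[ub_categories()] <- 2L
  }
  if (is.null(names(weights)) || !setequal(names(weights), cats)) {
    gt_stop("weights must be named over the full category enumeration",
            "validation_error")
  }
  weights <- weights[cats]
  if (any(is.na(weights)) || any(weights < 0) || any(weights != floor(weights))) {
    gt_stop("all category weights must be non-negative integers",
            "validation_error")
  }
  if (!is_count(threshold)) {
    gt_stop("threshold must be a positive integer", "validation_error")
  }
  structure(
    list(weights = stats::setNames(as.integer(weights), cats),
         threshold = as.integer(threshold)),
    class = "weight_scheme"
  )
}

#' Maximum attainable total score under a weighting scheme
#'
#' The sum of all category weights: the score a gene would reach if every
#' evidence category were present. Note that the curated weight table
#' bundled with the package prints a grand total of 16 although its row
#' weights sum to 17; `max_possible_score()` always returns the arithmetic
#' sum of the weights, and [load_fixture()] surfaces the discrepancy as an
#' annotation on the weight fixture.
#'
#' @param scheme a [weight_scheme()].
#' @return integer, the sum of all category weights.
#' @export
max_possible_score <- function(scheme = weight_scheme()) {
  stopifnot(inherits(scheme, "weight_scheme"))
  sum(scheme$weights)
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("Evidence weighting scheme\n")
  cat(sprintf("  categories: %d (max possible score %d)\n",
              length(x$weights), max_possible_score(x)))
  cat(sprintf("  selection threshold: total >= %d\n", x$threshold))
  w <- x$weights
  for (i in seq_along(w)) cat(sprintf("  %-22s %d\n", names(w)[i], w[i]))
  invisible(x)
}
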