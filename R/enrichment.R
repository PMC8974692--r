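# Term enrichment over a gene-set collection: overlap counts, fold
# enrichment, hypergeometric upper-tail p-values (with the conservative
# EASE variant that discounts one overlapping gene), and step-up FDR.

#' Term enrichment of a query gene set
#'
#' For each term with `K` genes in a background of `N`, a query of `n` genes
#' overlapping in `k`: fold enrichment `FE = (k/n) / (K/N)` and the upper
#' hypergeometric tail `P[X >= k]`. In `"ease"` mode (the default, matching
#' the conservative variant used by annotation-clustering servers) the tail
#' is computed at `k - 1` (floored at 0), so EASE p-values are never smaller
#' than the plain hypergeometric ones. FDR across terms is the linear
#' step-up (Benjamini-Hochberg) adjustment.
#'
#' @param query character vector of gene symbols; genes outside the
#'   collection's background are dropped with a warning.
#' @param collection a [gene_set_collection()].
#' @param mode `"ease"` or `"hypergeometric"`.
#' @return data.frame of class `enrichment_results`, sorted by ascending
#'   p-value: `term`, `k`, `n`, `K`, `N`, `percent` (100 k/n, 2 decimals),
#'   `fold_enrichment`, `p_value`, `fdr_q`.
#' @examples
#' coll <- gene_set_collection(list(t1 = letters[1:5]),
#'                             background = letters[1:20])
#' term_enrichment(letters[1:5][c(1, 2, 3, 4)], coll,
#'                 mode = "hypergeometric")
#' @export
term_enrichment <- function(query, collection, mode = c("ease", "hypergeometric")) {
  mode <- match.arg(mode)
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(collection$background) == 0L) {
    gt_stop("empty background", "validation_error")
  }
  query <- unique(as.character(query))
  outside <- setdiff(query, collection$background)
  if (length(outside)) {
    warning(sprintf("dropping %d query gene(s) outside the background: %s",
                    length(outside),
                    paste(utils::head(outside, 5L), collapse = ", ")),
            call. = FALSE)
    query <- setdiff(query, outside)
  }
  n <- length(query)
  if (n == 0L) gt_stop("empty query after background filtering",
                       "validation_error")
  n_bg <- length(collection$background)
  rows <- lapply(names(collection$terms), function(term) {
    genes <- collection$terms[[term]]
    big_k <- length(genes)
    k <- length(intersect(query, genes))
    fe <- (k / n) / (big_k / n_bg)
    k_eff <- if (mode == "ease") max(k - 1L, 0L) else k
    p <- if (k == 0L) 1 else
      stats::phyper(k_eff - 1L, big_k, n_bg - big_k, n, lower.tail = FALSE)
    data.frame(term = term, k = k, n = n, K = big_k, N = n_bg,
               percent = percent_of_query(k, n),
               fold_enrichment = fe, p_value = min(p, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_q <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_results", "data.frame")
  out
}

#' Percent of the query set covered by a term overlap
#'
#' @param k overlap count, `0 <= k <= n`.
#' @param n query-set size, `> 0`.
#' @return `100 * k / n` rounded to 2 decimals (the "Count (%)" convention).
#' @examples
#' percent_of_query(17, 37) # 45.95
#' @export
percent_of_query <- function(k, n) {
  stopifnot(is.numeric(k), is.numeric(n), n > 0, k >= 0, k <= n)
  round(100 * k / n, 2L)
}
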