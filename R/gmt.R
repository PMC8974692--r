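# Gene-set collections and the GMT dialect (term <TAB> description <TAB>
# gene1 <TAB> gene2 ...).

#' Construct a gene-set collection
#'
#' @param terms named list of character vectors (term name -> member genes).
#'   Duplicate genes within a term are collapsed; empty terms are an error.
#' @param background character vector of background gene symbols; defaults to
#'   the union of all term genes. Every term gene must belong to the
#'   background.
#' @param descriptions optional named character vector of term descriptions.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(terms, background = NULL, descriptions = NULL) {
  stopifnot(is.list(terms), !is.null(names(terms)))
  terms <- lapply(terms, function(g) unique(as.character(g)))
  if (any(lengths(terms) == 0L)) {
    gt_stop("empty terms are not allowed", "validation_error")
  }
  if (is.null(background)) background <- unique(unlist(terms, use.names = FALSE))
  background <- unique(as.character(background))
  stray <- setdiff(unlist(terms, use.names = FALSE), background)
  if (length(stray)) {
    gt_stop(sprintf("term gene(s) outside background: %s",
                    paste(utils::head(stray, 5L), collapse = ", ")),
            "validation_error")
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(terms)), names(terms))
  }
  structure(list(terms = terms, background = background,
                 descriptions = descriptions[names(terms)]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene-set collection: %d terms over %d background genes\n",
              length(x$terms), length(x$background)))
  sizes <- lengths(x$terms)
  cat(sprintf("  term sizes: %d-%d (median %.0f)\n",
              min(sizes), max(sizes), stats::median(sizes)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one term per line, tab-separated
#' `term, description, gene, gene, ...`. Duplicate genes within a term are
#' deduplicated; term order is preserved.
#'
#' @param path GMT file path.
#' @param background optional background gene universe (defaults to the union
#'   of all term genes).
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, background = NULL) {
  if (!file.exists(path)) gt_stop(paste0("file not found: ", path), "io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    gt_stop(sprintf("%s: fewer than 3 fields at line %s", path,
                    paste(short, collapse = ", ")), "format_error")
  }
  terms <- lapply(fields, function(f) f[-(1:2)])
  names(terms) <- vapply(fields, `[[`, "", 1L)
  descriptions <- stats::setNames(vapply(fields, `[[`, "", 2L), names(terms))
  gene_set_collection(terms, background, descriptions)
}

#' Write a gene-set collection in GMT format
#'
#' A [read_gmt()] of the output reproduces the collection (the background is
#' not part of the format and falls back to the term union on re-read).
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$terms), function(term) {
    paste(c(term, collection$descriptions[[term]], collection$terms[[term]]),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
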