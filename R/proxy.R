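# Proxy SNP selection: when a sentinel variant is absent from a target
# database, substitute the variant in strongest linkage disequilibrium with
# it, subject to a minimum r-squared.

#' Select a proxy SNP for a sentinel variant
#'
#' If the sentinel itself is present in the interrogated dataset it is its
#' own proxy (r-squared 1). Otherwise the available neighbour with the
#' highest r-squared is chosen, provided it reaches `r2_min` (inclusive).
#' Ties at equal r-squared break to the lexicographically smallest rsid, a
#' stated convention chosen for determinism. If no neighbour qualifies, a
#' classed error of class `"no_proxy"` is raised carrying the best
#' sub-threshold r-squared found (`best_r2`), signalling that the signal
#' cannot be interrogated in that dataset.
#'
#' @param sentinel sentinel rsid.
#' @param neighbors data.frame of LD pairs with columns `rsid_a`, `rsid_b`,
#'   `r2`; every pair must reference the sentinel on one side.
#' @param available character vector of rsids present in the target dataset.
#' @param r2_min minimum acceptable r-squared, in `(0, 1]`; default 0.2.
#' @return an object of class `proxy_choice`: list with `sentinel`, `chosen`,
#'   `r2`, `is_self`.
#' @examples
#' nb <- data.frame(rsid_a = "rs61816761",
#'                  rsid_b = c("rs61816766", "rs61816764"),
#'                  r2 = c(0.50, 0.21))
#' select_proxy("rs61816761", nb, available = "rs61816766")
#' @export
select_proxy <- function(sentinel, neighbors, available, r2_min = 0.2) {
  stopifnot(is_string(sentinel))
  if (!is_fraction(r2_min, open_left = TRUE)) {
    gt_stop("r2_min must be in (0, 1]", "validation_error")
  }
  if (sentinel %in% available) {
    return(proxy_choice(sentinel, sentinel, 1, TRUE))
  }
  if (nrow(neighbors) > 0) {
    refs_sentinel <- neighbors$rsid_a == sentinel | neighbors$rsid_b == sentinel
    if (!all(refs_sentinel)) {
      gt_stop("all neighbor pairs must reference the sentinel",
              "validation_error")
    }
  }
  other <- ifelse(neighbors$rsid_a == sentinel, neighbors$rsid_b,
                  neighbors$rsid_a)
  keep <- other %in% available & other != sentinel
  other <- other[keep]
  r2 <- neighbors$r2[keep]
  qualifying <- r2 >= r2_min
  if (!any(qualifying)) {
    best <- if (length(r2)) max(r2) else NA_real_
    gt_stop(sprintf(
      "no proxy for %s at r2 >= %g (best available r2: %s)",
      sentinel, r2_min, if (is.na(best)) "none" else format(best)),
      "no_proxy", sentinel = sentinel, best_r2 = best)
  }
  other <- other[qualifying]
  r2 <- r2[qualifying]
  top <- which(r2 == max(r2))
  pick <- top[order(other[top])][1L]
  proxy_choice(sentinel, other[pick], r2[pick], FALSE)
}

proxy_choice <- function(sentinel, chosen, r2, is_self) {
  structure(list(sentinel = sentinel, chosen = chosen, r2 = r2,
                 is_self = is_self),
            class = "proxy_choice")
}

#' @export
print.proxy_choice <- function(x, ...) {
  if (x$is_self) {
    cat(sprintf("%s: present in dataset (self-proxy)\n", x$sentinel))
  } else {
    cat(sprintf("%s: proxied by %s (r2 = %.2f)\n", x$sentinel, x$chosen, x$r2))
  }
  invisible(x)
}

#' Read an availability set (one rsid per line)
#' @param path newline-delimited rsid file.
#' @return character vector of rsids.
#' @export
read_availability <- function(path) {
  if (!file.exists(path)) gt_stop(paste0("file not found: ", path), "io_error")
  ids <- trimws(readLines(path, warn = FALSE))
  unique(ids[nzchar(ids)])
}
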