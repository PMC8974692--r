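# internal helpers shared across modules

gt_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "gwastrans_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

is_fraction <- function(x, open_left = FALSE, open_right = FALSE) {
  is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open_left) x > 0 else x >= 0) &&
    (if (open_right) x < 1 else x <= 1)
}

#' Expand a slash-clustered gene label into atomic symbols
#'
#' Study tables abbreviate gene families as e.g. `"HLA-DQA1/A2"` or
#' `"SLC22A4/5"`. Downstream set operations need atomic symbols, so each
#' trailing fragment is re-prefixed with the matching head of the first
#' symbol: `"HLA-DQA1/A2/B1/B2"` expands to `HLA-DQA1, HLA-DQA2, HLA-DQB1,
#' HLA-DQB2`.
#'
#' @param label character vector of gene labels, possibly slash-clustered.
#' @return character vector of atomic gene symbols (may be longer than the
#'   input).
#' @examples
#' split_gene_cluster("HLA-DQA1/A2")
#' split_gene_cluster("SLC22A4/5")
#' @export
split_gene_cluster <- function(label) {
  stopifnot(is.character(label))
  out <- lapply(label, function(lab) {
    if (is.na(lab) || !grepl("/", lab, fixed = TRUE)) return(lab)
    parts <- strsplit(lab, "/", fixed = TRUE)[[1L]]
    head_sym <- parts[1L]
    vapply(parts, function(fragment) {
      if (fragment == head_sym) return(head_sym)
      keep <- nchar(head_sym) - nchar(fragment)
      if (keep <= 0) return(fragment)
      paste0(substr(head_sym, 1L, keep), fragment)
    }, character(1L), USE.NAMES = FALSE)
  })
  unlist(out, use.names = FALSE)
}

# deterministic sub-seed derivation: a counter-based fan-out so adding a new
# stream never perturbs existing ones. Result stays below 2^31 - 1.
derive_seed <- function(seed, stream) {
  stopifnot(is_count(seed + 1), is_string(stream))
  code <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((seed + 48271 * (code %% 44449)) %% 2147483629 + 1)
}

# truncate (not round) to a number of significant digits; used for the
# display form of corrected significance thresholds.
trunc_signif <- function(x, digits = 3L) {
  stopifnot(is.numeric(x), digits >= 1)
  out <- x
  nz <- !is.na(x) & x != 0
  e <- floor(log10(abs(x[nz])))
  f <- 10^(digits - 1 - e)
  out[nz] <- trunc(x[nz] * f) / f
  out
}

# stable polynomial rolling hash of a character serialization; used for
# config/report hashes (change detection only, no cryptographic intent).
stable_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
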