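# Validated TSV input/output.
#
# All tabular interchange is tab-separated with a header row and '.' decimal
# separator. Missing numeric cells are encoded as the empty string, which is
# distinct from 0: "no evidence" is not "zero effect". Scientific notation is
# accepted on input; p-values are stored as plain decimals.

#' Declare a column specification for [read_table()]
#'
#' @param type one of `"character"`, `"numeric"`, `"integer"`,
#'   `"fraction"` (closed unit interval), `"p_value"` (half-open `(0, 1]`).
#' @param required must the column be present in the file header?
#' @param nonempty for character columns, forbid empty cells.
#' @param allow_na allow missing values (empty cells) after coercion.
#' @return a `col_spec` list used inside a schema.
#' @export
col_spec <- function(type = c("character", "numeric", "integer",
                              "fraction", "p_value"),
                     required = TRUE, nonempty = FALSE, allow_na = TRUE) {
  type <- match.arg(type)
  structure(list(type = type, required = required, nonempty = nonempty,
                 allow_na = allow_na),
            class = "col_spec")
}

coerce_column <- function(values, spec, col, path) {
  values[values %in% c("", "NA")] <- NA_character_
  bad_row <- function(rows, why) {
    gt_stop(sprintf("%s: column '%s' %s at row %s", path, col, why,
                    paste(rows, collapse = ", ")),
            "parse_error")
  }
  out <- switch(spec$type,
    character = values,
    numeric = ,
    integer = ,
    fraction = ,
    p_value = suppressWarnings(as.numeric(values))
  )
  if (spec$type != "character") {
    uncoercible <- which(is.na(out) & !is.na(values))
    if (length(uncoercible)) bad_row(uncoercible, "is not numeric")
  }
  if (spec$type == "integer") {
    frac <- which(!is.na(out) & out != floor(out))
    if (length(frac)) bad_row(frac, "is not an integer")
    out <- as.integer(out)
  }
  if (spec$type == "fraction") {
    oob <- which(!is.na(out) & (out < 0 | out > 1))
    if (length(oob)) bad_row(oob, "is outside [0, 1]")
  }
  if (spec$type == "p_value") {
    oob <- which(!is.na(out) & (out <= 0 | out > 1))
    if (length(oob)) bad_row(oob, "is outside (0, 1]")
  }
  if (spec$type == "character" && spec$nonempty) {
    empty <- which(is.na(out))
    if (length(empty)) bad_row(empty, "is empty")
  }
  if (!spec$allow_na) {
    missing_cells <- which(is.na(out))
    if (length(missing_cells)) bad_row(missing_cells, "is missing")
  }
  out
}

#' Read a validated tab-separated table
#'
#' Reads a TSV file with a header row, checks the header against a declared
#' schema (order-insensitive), coerces every column to its semantic type and
#' reports uncoercible or out-of-range cells with their row number. Columns
#' not named in the schema are dropped with a warning.
#'
#' @param path path to a tab-separated file with a header row.
#' @param schema named list of [col_spec()] objects.
#' @return a `data.frame` with exactly the schema's columns, in schema order.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) gt_stop(paste0("file not found: ", path), "io_error")
  stopifnot(is.list(schema), !is.null(names(schema)))
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                           na.strings = NULL, strip.white = FALSE)
  required <- names(schema)[vapply(schema, `[[`, TRUE, "required")]
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    gt_stop(sprintf("%s: missing mandatory column(s): %s", path,
                    paste(missing_cols, collapse = ", ")),
            "schema_error")
  }
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown)) {
    warning(sprintf("%s: ignoring unknown column(s): %s", path,
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  keep <- intersect(names(schema), names(raw))
  out <- raw[, keep, drop = FALSE]
  for (col in keep) {
    out[[col]] <- coerce_column(out[[col]], schema[[col]], col, path)
  }
  # optional columns absent from the file come back as all-NA
  for (col in setdiff(names(schema), keep)) {
    out[[col]] <- rep(if (schema[[col]]$type == "character") NA_character_
                      else NA_real_, nrow(out))
  }
  out[, names(schema), drop = FALSE]
}

#' Write a table in the package's TSV dialect
#'
#' Tab-separated, header row, no quoting, missing values as empty strings.
#' A [read_table()] of the result with the same schema round-trips.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# ---- record schemas ---------------------------------------------------------

schema_signals <- function() {
  list(
    rsid = col_spec("character", nonempty = TRUE, allow_na = FALSE),
    closest_gene = col_spec("character"),
    risk_allele = col_spec("character", nonempty = TRUE, allow_na = FALSE),
    non_risk_allele = col_spec("character", nonempty = TRUE, allow_na = FALSE),
    raf_eur = col_spec("fraction", allow_na = FALSE)
  )
}

schema_evidence <- function() {
  list(
    signal_rsid = col_spec("character", nonempty = TRUE, allow_na = FALSE),
    gene = col_spec("character", nonempty = TRUE, allow_na = FALSE),
    category = col_spec("character", nonempty = TRUE, allow_na = FALSE),
    tissue = col_spec("character", required = FALSE),
    p_value = col_spec("p_value", required = FALSE),
    effect_b = col_spec("numeric", required = FALSE),
    h4 = col_spec("fraction", required = FALSE)
  )
}

schema_ld_pairs <- function() {
  list(
    rsid_a = col_spec("character", nonempty = TRUE, allow_na = FALSE),
    rsid_b = col_spec("character", nonempty = TRUE, allow_na = FALSE),
    r2 = col_spec("fraction", allow_na = FALSE)
  )
}

schema_phewas <- function() {
  list(
    rsid = col_spec("character", nonempty = TRUE, allow_na = FALSE),
    trait = col_spec("character", nonempty = TRUE, allow_na = FALSE),
    effect = col_spec("numeric", allow_na = FALSE),
    p_value = col_spec("p_value", allow_na = FALSE),
    odds_ratio = col_spec("numeric", required = FALSE)
  )
}

schema_profiles <- function() {
  list(
    gene = col_spec("character", nonempty = TRUE, allow_na = FALSE),
    class = col_spec("character", nonempty = TRUE, allow_na = FALSE),
    value = col_spec("numeric", allow_na = FALSE),
    class_kind = col_spec("character", required = FALSE)
  )
}

schema_coloc <- function() {
  list(
    gene = col_spec("character", nonempty = TRUE, allow_na = FALSE),
    tissue_class = col_spec("character", nonempty = TRUE, allow_na = FALSE),
    study = col_spec("character", required = FALSE),
    h4 = col_spec("fraction", allow_na = FALSE)
  )
}

schema_drugs <- function() {
  list(
    gene = col_spec("character", nonempty = TRUE, allow_na = FALSE),
    drug = col_spec("character"),
    interaction_type = col_spec("character", required = FALSE),
    pmids = col_spec("character", required = FALSE),
    interaction_score = col_spec("numeric", required = FALSE),
    trial_ids = col_spec("character", required = FALSE)
  )
}

schema_scorecards <- function() {
  list(
    signal_rsid = col_spec("character", nonempty = TRUE, allow_na = FALSE),
    gene = col_spec("character", nonempty = TRUE, allow_na = FALSE),
    base_score = col_spec("integer", allow_na = FALSE),
    ub_count = col_spec("integer", allow_na = FALSE),
    total = col_spec("integer", allow_na = FALSE)
  )
}

#' Read GWAS signal records
#'
#' @param path TSV with columns `rsid`, `closest_gene`, `risk_allele`,
#'   `non_risk_allele`, `raf_eur` (risk-allele frequency as a fraction).
#' @return validated data.frame of signals. Fails if a risk allele equals its
#'   non-risk allele or a frequency leaves the unit interval.
#' @export
read_signals <- function(path) {
  df <- read_table(path, schema_signals())
  same <- which(df$risk_allele == df$non_risk_allele)
  if (length(same)) {
    gt_stop(sprintf("%s: risk_allele equals non_risk_allele at row %s", path,
                    paste(same, collapse = ", ")), "parse_error")
  }
  df
}

#' Read signal-to-gene evidence records
#'
#' @param path TSV with columns `signal_rsid`, `gene`, `category` and
#'   optional `tissue`, `p_value`, `effect_b`, `h4`.
#' @return validated data.frame; unknown evidence categories are an error.
#' @export
read_evidence <- function(path) {
  df <- read_table(path, schema_evidence())
  bad <- which(!df$category %in% evidence_categories())
  if (length(bad)) {
    gt_stop(sprintf("%s: unknown evidence category '%s' at row %s", path,
                    df$category[bad[1L]], paste(bad, collapse = ", ")),
            "validation_error")
  }
  df
}

#' Read a long-format linkage-disequilibrium table
#'
#' Symmetric duplicates (`a,b` and `b,a`) are collapsed to one row keeping
#' the first occurrence; conflicting r-squared values for the same pair are
#' an error.
#'
#' @param path TSV with columns `rsid_a`, `rsid_b`, `r2`.
#' @return deduplicated data.frame of LD pairs.
#' @export
read_ld_pairs <- function(path) {
  df <- read_table(path, schema_ld_pairs())
  key <- ifelse(df$rsid_a <= df$rsid_b,
                paste(df$rsid_a, df$rsid_b), paste(df$rsid_b, df$rsid_a))
  dup <- duplicated(key)
  if (any(dup)) {
    first <- match(key[dup], key)
    if (any(abs(df$r2[dup] - df$r2[first]) > 1e-12)) {
      gt_stop(sprintf("%s: conflicting r2 for duplicated pair(s)", path),
              "validation_error")
    }
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read PheWAS summary records
#' @param path TSV with columns `rsid`, `trait`, `effect`, `p_value` and
#'   optional `odds_ratio` (disease traits only).
#' @return validated data.frame.
#' @export
read_phewas <- function(path) {
  df <- read_table(path, schema_phewas())
  bad <- which(!is.na(df$odds_ratio) & df$odds_ratio <= 0)
  if (length(bad)) {
    gt_stop(sprintf("%s: odds_ratio must be positive at row %s", path,
                    paste(bad, collapse = ", ")), "parse_error")
  }
  df
}

#' Read per-class expression profiles (tissue NX / single-cell pTPM)
#' @param path TSV with columns `gene`, `class`, `value` and optional
#'   `class_kind`.
#' @return validated data.frame; negative expression values are an error.
#' @export
read_profiles <- function(path) {
  df <- read_table(path, schema_profiles())
  bad <- which(df$value < 0)
  if (length(bad)) {
    gt_stop(sprintf("%s: negative expression value at row %s", path,
                    paste(bad, collapse = ", ")), "validation_error")
  }
  df
}

#' Read gene-level colocalization (H4) records
#' @param path TSV with columns `gene`, `tissue_class`, optional `study`,
#'   `h4`.
#' @return validated data.frame.
#' @export
read_coloc <- function(path) {
  read_table(path, schema_coloc())
}

#' Read drug-gene interaction records
#'
#' Rows with an `interaction_score` are scored-database records; rows with
#' only registry trial identifiers are clinical-trial records. `trial_ids`
#' is a comma-separated list of NCT-prefixed identifiers.
#'
#' @param path TSV mirroring the bundled drug-interaction table.
#' @return validated data.frame with a derived `source` column
#'   (`"scored_db"` or `"clinical_trial"`).
#' @export
read_drug_interactions <- function(path) {
  df <- read_table(path, schema_drugs())
  df <- df[!is.na(df$drug) & df$drug != "", , drop = FALSE]
  df$source <- ifelse(!is.na(df$interaction_score), "scored_db", "clinical_trial")
  ids <- unlist(strsplit(df$trial_ids[!is.na(df$trial_ids)], ","))
  ids <- trimws(ids)
  bad <- ids[!grepl("^NCT[0-9]+$", ids) & ids != ""]
  if (length(bad)) {
    gt_stop(sprintf("%s: malformed trial id(s): %s", path,
                    paste(unique(bad), collapse = ", ")), "validation_error")
  }
  rownames(df) <- NULL
  df
}

#' Read an expression matrix with its sample sheet
#'
#' @param matrix_path TSV, first column `gene`, remaining columns one per
#'   sample (expression values on the platform scale).
#' @param samples_path TSV with columns `sample`, `group`.
#' @return an [expression_dataset()].
#' @export
read_expression <- function(matrix_path, samples_path) {
  mat_df <- utils::read.delim(matrix_path, check.names = FALSE)
  if (names(mat_df)[1L] != "gene") {
    gt_stop(sprintf("%s: first column must be 'gene'", matrix_path),
            "schema_error")
  }
  genes <- as.character(mat_df$gene)
  values <- as.matrix(mat_df[, -1L, drop = FALSE])
  rownames(values) <- genes
  sheet <- read_table(samples_path, list(
    sample = col_spec("character", nonempty = TRUE, allow_na = FALSE),
    group = col_spec("character", nonempty = TRUE, allow_na = FALSE)
  ))
  if (!setequal(sheet$sample, colnames(values))) {
    gt_stop("sample sheet and expression matrix disagree on sample ids",
            "validation_error")
  }
  groups <- stats::setNames(sheet$group, sheet$sample)[colnames(values)]
  expression_dataset(values, groups)
}
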