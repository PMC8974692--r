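# Differential expression across control / mild-moderate / severe groups:
# a per-gene Shapiro-Wilk normality gate dispatches each gene to either the
# Kruskal-Wallis rank test (any group non-normal) or Welch's heteroscedastic
# ANOVA (all groups normal); omnibus p-values across genes are adjusted with
# the two-stage linear step-up procedure of Benjamini, Krieger and Yekutieli
# (BKY), and discoveries get post-hoc pairwise comparisons in the same
# distributional family.

#' Construct an expression dataset
#'
#' @param values numeric gene x sample matrix (rownames = gene symbols,
#'   colnames = sample ids), expression on the platform scale.
#' @param group named character vector or factor, sample -> group label;
#'   names must match the matrix columns. Each group must be non-empty.
#' @return object of class `expression_dataset`: list with `values` and
#'   `group` (factor aligned to columns).
#' @export
expression_dataset <- function(values, group) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    gt_stop("expression matrix needs gene rownames and sample colnames",
            "validation_error")
  }
  if (!is.null(names(group))) {
    missing_samples <- setdiff(colnames(values), names(group))
    if (length(missing_samples)) {
      gt_stop(sprintf("no group for sample(s): %s",
                      paste(utils::head(missing_samples, 5L), collapse = ", ")),
              "validation_error")
    }
    group <- group[colnames(values)]
  } else if (length(group) != ncol(values)) {
    gt_stop("group length must match the number of samples",
            "validation_error")
  }
  group <- droplevels(as.factor(as.character(group)))
  if (nlevels(group) < 2L || any(table(group) == 0L)) {
    gt_stop("need at least two non-empty groups", "validation_error")
  }
  structure(list(values = values, group = group),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("Expression dataset: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  print(table(x$group))
  invisible(x)
}

#' Normality gate: choose the omnibus test for one gene
#'
#' Applies the Shapiro-Wilk test within every group; the gene takes the
#' Welch ANOVA path only if every group is compatible with normality
#' (p >= `alpha_gate` in all groups), otherwise the Kruskal-Wallis path.
#' A group of constant values is degenerate for the normality test and
#' routes to Kruskal-Wallis.
#'
#' @param values_by_group list of numeric vectors, one per group (each with
#'   at least 3 observations).
#' @param alpha_gate gate level (default 0.05).
#' @return list with `test` (`"welch_anova"` or `"kruskal_wallis"`) and
#'   `shapiro_p` (per-group p-values, `NA` for degenerate groups).
#' @export
normality_gate <- function(values_by_group, alpha_gate = 0.05) {
  stopifnot(is.list(values_by_group), length(values_by_group) >= 2L)
  n <- lengths(values_by_group)
  if (any(n < 3L)) {
    gt_stop("every group needs at least 3 observations for the gate",
            "insufficient_data")
  }
  ps <- vapply(values_by_group, function(v) {
    if (length(unique(v)) < 3L) return(NA_real_) # degenerate: no normal fit
    stats::shapiro.test(v)$p.value
  }, numeric(1L))
  all_normal <- all(!is.na(ps)) && all(ps >= alpha_gate)
  list(test = if (all_normal) "welch_anova" else "kruskal_wallis",
       shapiro_p = ps)
}

#' Kruskal-Wallis rank test
#'
#' The H statistic on mid-ranks with the standard tie correction,
#' `H = [12 / (N(N+1)) * sum R_i^2 / n_i - 3(N+1)] / C` where
#' `C = 1 - sum(t^3 - t) / (N^3 - N)` over tie blocks, referred to the
#' chi-square distribution with k-1 degrees of freedom. All values identical
#' across all groups returns `H = 0, p = 1` (not an error).
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty).
#' @return list with `statistic` (H), `df`, `p_value`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))$statistic # 27/7
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) == 0L)) {
    gt_stop("every group must be non-empty", "validation_error")
  }
  x <- unlist(groups, use.names = FALSE)
  if (anyNA(x)) gt_stop("missing values in expression data", "validation_error")
  g <- rep(seq_along(groups), lengths(groups))
  n_total <- length(x)
  k <- length(groups)
  r <- rank(x) # mid-ranks
  rank_sums <- tapply(r, g, sum)
  h <- 12 / (n_total * (n_total + 1)) *
    sum(rank_sums^2 / lengths(groups)) - 3 * (n_total + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n_total^3 - n_total)
  if (correction == 0) { # all values identical
    return(list(statistic = 0, df = k - 1L, p_value = 1))
  }
  h <- h / correction
  h <- max(h, 0)
  list(statistic = h, df = k - 1L,
       p_value = stats::pchisq(h, df = k - 1L, lower.tail = FALSE))
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' The F* statistic with weights `w_i = n_i / s_i^2` and the
#' Welch-Satterthwaite denominator degrees of freedom; with two groups F*
#' equals the square of the Welch two-sample t statistic.
#'
#' @param groups list of numeric vectors, each with >= 2 observations and
#'   positive variance.
#' @return list with `statistic` (F*), `df1`, `df2`, `p_value`.
#' @export
welch_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  n <- lengths(groups)
  if (any(n < 2L)) {
    gt_stop("every group needs at least 2 observations", "validation_error")
  }
  v <- vapply(groups, stats::var, numeric(1L))
  if (any(v <= 0)) {
    gt_stop("zero within-group variance: Welch ANOVA undefined",
            "degenerate_variance")
  }
  m <- vapply(groups, mean, numeric(1L))
  k <- length(groups)
  w <- n / v
  w_total <- sum(w)
  grand <- sum(w * m) / w_total
  a <- sum(w * (m - grand)^2) / (k - 1)
  lambda <- sum((1 - w / w_total)^2 / (n - 1))
  b <- 1 + 2 * (k - 2) / (k^2 - 1) * lambda
  f_star <- a / b
  df2 <- (k^2 - 1) / (3 * lambda)
  list(statistic = f_star, df1 = k - 1, df2 = df2,
       p_value = stats::pf(f_star, k - 1, df2, lower.tail = FALSE))
}

# linear step-up (Benjamini-Hochberg form) rejection count at level q
bh_reject_count <- function(p_sorted, q) {
  m <- length(p_sorted)
  below <- which(p_sorted <= q * seq_len(m) / m)
  if (length(below)) max(below) else 0L
}

# number of rejections of the two-stage procedure at level q, given sorted p
bky_reject_count <- function(p_sorted, q) {
  m <- length(p_sorted)
  q1 <- q / (1 + q)
  r1 <- bh_reject_count(p_sorted, q1)
  if (r1 == 0L) return(0L)
  if (r1 == m) return(m)
  bh_reject_count(p_sorted, q1 * m / (m - r1))
}

#' Two-stage Benjamini-Krieger-Yekutieli step-up FDR procedure
#'
#' Stage 1 runs the linear step-up procedure at the deflated level
#' `q' = q / (1 + q)`; with `r1` stage-1 rejections (0 < r1 < m), stage 2
#' re-runs the step-up at `q' * m / (m - r1)`, using `m - r1` as the
#' estimate of the number of true nulls. `r1 = 0` rejects nothing and
#' `r1 = m` rejects everything. Adjusted q-values are the smallest nominal
#' level at which each hypothesis is rejected, found by bisection (the
#' rejection set is monotone non-decreasing in q); they are monotone in p
#' and bounded by 1.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q nominal FDR level in `(0, 1)` (default 0.05).
#' @param compute_q_values set `FALSE` to skip the (more expensive) adjusted
#'   q-values, e.g. inside large simulations that only need rejection flags.
#' @return list with `reject` (logical, input order), `q_value` (numeric or
#'   `NULL`), `r1` (stage-1 rejection count), `stage2_level`.
#' @examples
#' bky_two_stage(c(0.001, 0.2, 0.9), q = 0.05)$reject
#' @export
bky_two_stage <- function(p_values, q = 0.05, compute_q_values = TRUE) {
  if (!is.numeric(p_values) || length(p_values) == 0L) {
    gt_stop("p_values must be a non-empty numeric vector", "validation_error")
  }
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    gt_stop("p-values must lie in [0, 1]", "validation_error")
  }
  if (!is_fraction(q, open_left = TRUE, open_right = TRUE)) {
    gt_stop("q must be in (0, 1)", "validation_error")
  }
  m <- length(p_values)
  ord <- order(p_values)
  p_sorted <- p_values[ord]
  q1 <- q / (1 + q)
  r1 <- bh_reject_count(p_sorted, q1)
  n_reject <- bky_reject_count(p_sorted, q)
  reject_sorted <- seq_len(m) <= n_reject
  stage2_level <- if (r1 > 0L && r1 < m) q1 * m / (m - r1) else q1
  q_values <- NULL
  if (compute_q_values) {
    q_sorted <- numeric(m)
    r_max <- bky_reject_count(p_sorted, 1 - 1e-12)
    prev <- 0
    for (i in seq_len(m)) {
      if (r_max < i) {
        q_sorted[i:m] <- 1
        break
      }
      lo <- prev
      hi <- 1
      for (iter in 1:50) {
        mid <- (lo + hi) / 2
        if (bky_reject_count(p_sorted, mid) >= i) hi <- mid else lo <- mid
      }
      q_sorted[i] <- hi
      prev <- hi # adjusted values are monotone in the sorted order
    }
    q_sorted <- pmin(q_sorted, 1)
    q_values <- numeric(m)
    q_values[ord] <- q_sorted
  }
  reject <- logical(m)
  reject[ord] <- reject_sorted
  list(reject = reject, q_value = q_values, r1 = r1,
       stage2_level = stage2_level)
}

pairwise_tests <- function(groups, family) {
  gl <- names(groups)
  combos <- utils::combn(seq_along(groups), 2L)
  ps <- apply(combos, 2L, function(ij) {
    a <- groups[[ij[1L]]]
    b <- groups[[ij[2L]]]
    if (family == "kruskal_wallis") {
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    } else {
      stats::t.test(a, b, var.equal = FALSE)$p.value
    }
  })
  data.frame(group_i = gl[combos[1L, ]], group_j = gl[combos[2L, ]],
             p_value = as.numeric(ps), stringsAsFactors = FALSE)
}

#' Run the differential-expression stage over a dataset
#'
#' Per gene: the normality gate picks Kruskal-Wallis or Welch ANOVA; the
#' omnibus p-values across all genes are adjusted with [bky_two_stage()] at
#' level `q`; genes declared significant receive post-hoc pairwise
#' comparisons in the matching family (rank-sum for the Kruskal-Wallis path,
#' Welch t for the ANOVA path), corrected with the same two-stage procedure
#' either within each gene (`posthoc_scope = "per_gene"`) or across all
#' pairwise tests (`"global"`).
#'
#' @param dataset an [expression_dataset()].
#' @param q FDR level (default 0.05).
#' @param alpha_gate Shapiro-Wilk gate level (default 0.05).
#' @param force_test `NULL` for gated dispatch, or `"kruskal_wallis"` to
#'   force the rank test for every gene (mirrors analyses that skip the
#'   gate).
#' @param posthoc_scope `"per_gene"` or `"global"` correction family for
#'   pairwise p-values.
#' @return data.frame of class `de_results`: per gene `test_used`,
#'   `statistic`, `p_value`, `q_value`, `significant`; pairwise results for
#'   significant genes in `attr(, "pairwise")`.
#' @export
run_de <- function(dataset, q = 0.05, alpha_gate = 0.05, force_test = NULL,
                   posthoc_scope = c("per_gene", "global")) {
  stopifnot(inherits(dataset, "expression_dataset"))
  posthoc_scope <- match.arg(posthoc_scope)
  if (!is.null(force_test) && force_test != "kruskal_wallis") {
    gt_stop("force_test must be NULL or 'kruskal_wallis'", "validation_error")
  }
  genes <- rownames(dataset$values)
  res <- lapply(genes, function(g) {
    by_group <- split(dataset$values[g, ], dataset$group)
    test <- if (is.null(force_test)) {
      normality_gate(by_group, alpha_gate)$test
    } else force_test
    fit <- if (test == "welch_anova") {
      out <- tryCatch(welch_anova(by_group), gwastrans_error = function(e) NULL)
      if (is.null(out)) { # degenerate variance: fall back to the rank test
        test <- "kruskal_wallis"
        kruskal_wallis(by_group)
      } else out
    } else {
      kruskal_wallis(by_group)
    }
    data.frame(gene = g, test_used = test, statistic = fit$statistic,
               p_value = fit$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  adj <- bky_two_stage(out$p_value, q = q)
  out$q_value <- adj$q_value
  out$significant <- adj$reject
  pairwise <- list()
  for (g in out$gene[out$significant]) {
    by_group <- split(dataset$values[g, ], dataset$group)
    fam <- out$test_used[out$gene == g]
    pw <- pairwise_tests(by_group, fam)
    if (posthoc_scope == "per_gene") {
      pw$q_value <- bky_two_stage(pw$p_value, q = q)$q_value
    }
    pairwise[[g]] <- pw
  }
  if (posthoc_scope == "global" && length(pairwise)) {
    all_p <- unlist(lapply(pairwise, `[[`, "p_value"), use.names = FALSE)
    all_q <- bky_two_stage(all_p, q = q)$q_value
    i <- 0L
    for (g in names(pairwise)) {
      n_g <- nrow(pairwise[[g]])
      pairwise[[g]]$q_value <- all_q[i + seq_len(n_g)]
      i <- i + n_g
    }
  }
  rownames(out) <- NULL
  attr(out, "pairwise") <- pairwise
  attr(out, "q") <- q
  class(out) <- c("de_results", "data.frame")
  out
}

#' @export
print.de_results <- function(x, ...) {
  cat(sprintf(
    "Differential expression: %d genes, %d significant at BKY q = %g\n",
    nrow(x), sum(x$significant), attr(x, "q")))
  print.data.frame(utils::head(x[order(x$p_value),
                                 c("gene", "test_used", "statistic",
                                   "p_value", "q_value", "significant")],
                               10L), row.names = FALSE, digits = 4)
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}
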