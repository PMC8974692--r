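# Independent oracles and small fixture builders used across the suite.

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# brute-force upper hypergeometric tail P[X >= k] by direct summation of
# binomial-coefficient terms (no distribution function involved)
hyper_tail_bruteforce <- function(k, K, N, n) {
  if (k <= 0) return(1)
  i <- seq(k, min(K, n))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# brute-force proxy scan: best available neighbor at or above the cutoff
proxy_bruteforce <- function(sentinel, neighbors, available, r2_min) {
  if (sentinel %in% available) {
    return(list(chosen = sentinel, r2 = 1))
  }
  other <- ifelse(neighbors$rsid_a == sentinel, neighbors$rsid_b,
                  neighbors$rsid_a)
  best <- NULL
  for (i in seq_along(other)) {
    if (!other[i] %in% available || other[i] == sentinel) next
    if (neighbors$r2[i] < r2_min) next
    if (is.null(best) || neighbors$r2[i] > best$r2 ||
        (neighbors$r2[i] == best$r2 && other[i] < best$chosen)) {
      best <- list(chosen = other[i], r2 = neighbors$r2[i])
    }
  }
  best
}

# vectorized Monte-Carlo permutation p-value for the Kruskal-Wallis H:
# pooled mid-ranks are fixed under permutation, so only group sums move
kw_permutation_p <- function(groups, n_perm = 1e5, seed = 101) {
  set.seed(seed)
  x <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  n <- length(x)
  r <- rank(x)
  h_of_sums <- function(rank_sums) {
    12 / (n * (n + 1)) * sum(rank_sums^2 / sizes) - 3 * (n + 1)
  }
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  grp <- rep(seq_along(sizes), sizes)
  h_obs <- h_of_sums(vapply(seq_along(sizes), function(g)
    sum(r[grp == g]), numeric(1))) / correction
  perms <- replicate(n_perm, sample(r)) # n x n_perm matrix of permuted ranks
  indicator <- outer(seq_along(sizes), grp, `==`) + 0 # k x n
  rank_sums <- indicator %*% perms # k x n_perm
  h_perm <- (12 / (n * (n + 1)) * colSums(rank_sums^2 / sizes) -
               3 * (n + 1)) / correction
  mean(h_perm >= h_obs - 1e-12)
}

# tiny deterministic evidence bundle for one pair
make_evidence <- function(signal, gene, categories) {
  data.frame(signal_rsid = signal, gene = gene, category = categories,
             stringsAsFactors = FALSE)
}
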