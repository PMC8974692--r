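test_that("the Shapiro-Wilk gate dispatches to the matching omnibus test", {
  set.seed(31)
  normal <- list(rnorm(50), rnorm(50), rnorm(50))
  expect_equal(normality_gate(normal)$test, "welch_anova")
  skewed <- normal
  skewed[[2]] <- rexp(50)
  expect_equal(normality_gate(skewed)$test, "kruskal_wallis")
  degenerate <- normal
  degenerate[[1]] <- rep(5, 50)
  expect_equal(normality_gate(degenerate)$test, "kruskal_wallis")
  expect_error(normality_gate(list(rnorm(2), rnorm(10))),
               class = "insufficient_data")
})

test_that("Kruskal-Wallis H matches the hand rank-sum formula and base R", {
  # 12/(n(n+1)) * sum R_i^2/n_i - 3(n+1) on ranks 1..6 gives 27/7
  k <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(k$statistic, 27 / 7)
  expect_equal(k$df, 1L)

  # all values identical: H = 0, p = 1, not an error
  flat <- kruskal_wallis(list(c(5, 5, 5), c(5, 5, 5)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  # agreement with the independent base implementation, including ties
  set.seed(77)
  for (rep in 1:20) {
    groups <- lapply(1:sample(2:4, 1), function(i)
      sample(1:6, sample(4:12, 1), replace = TRUE))
    ours <- kruskal_wallis(groups)
    base <- stats::kruskal.test(groups)
    expect_equal(ours$statistic, unname(base$statistic))
    expect_equal(ours$p_value, unname(base$p.value))
  }
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(8)
  groups <- list(rnorm(10), rnorm(12, 1), rnorm(9, 2))
  h0 <- kruskal_wallis(groups)$statistic
  expect_equal(kruskal_wallis(lapply(groups, exp))$statistic, h0)
  expect_equal(kruskal_wallis(lapply(groups, function(v) 3 * v - 7))$statistic,
               h0)
})

test_that("chi-square p agrees with a permutation oracle on small groups", {
  # the chi-square reference is an approximation at these sizes; agreement
  # is asserted within the approximation + Monte-Carlo error budget
  g5 <- list(c(1.2, 3.4, 2.2, 5.1, 4.0), c(2.8, 6.1, 5.5, 7.2, 3.3),
             c(4.4, 8.0, 6.6, 9.1, 7.7))
  expect_lt(abs(kruskal_wallis(g5)$p_value - kw_permutation_p(g5)), 0.025)
  set.seed(5)
  g8 <- list(rnorm(8), rnorm(8, 0.8), rnorm(8, 1.2))
  expect_lt(abs(kruskal_wallis(g8)$p_value - kw_permutation_p(g8)), 0.025)
})

test_that("Welch ANOVA matches base R and the two-group t identity", {
  set.seed(42)
  for (rep in 1:10) {
    groups <- lapply(1:3, function(i) rnorm(sample(5:40, 1), i / 2, i))
    ours <- welch_anova(groups)
    base <- stats::oneway.test(
      y ~ g, data.frame(y = unlist(groups),
                        g = factor(rep(seq_along(groups), lengths(groups)))),
      var.equal = FALSE)
    expect_equal(ours$statistic, unname(base$statistic))
    expect_equal(ours$df2, unname(base$parameter[2]))
    expect_equal(ours$p_value, unname(base$p.value))
  }
  # k = 2: F* is the squared Welch t statistic
  for (rep in 1:10) {
    a <- rnorm(sample(5:30, 1))
    b <- rnorm(sample(5:30, 1), 0.5, 2)
    f2 <- welch_anova(list(a, b))
    tt <- stats::t.test(a, b, var.equal = FALSE)
    expect_equal(f2$statistic, unname(tt$statistic)^2)
    expect_equal(f2$p_value, tt$p.value)
  }
})

test_that("Welch ANOVA degenerates and limits behave as documented", {
  expect_error(welch_anova(list(c(1, 1, 1), rnorm(5))),
               class = "degenerate_variance")
  expect_error(welch_anova(list(1, rnorm(5))), class = "validation_error")
  # identical groups up to permutation: p near 1, F* near 0
  set.seed(3)
  v <- rnorm(30)
  same <- welch_anova(list(v, sample(v), rev(v)))
  expect_lt(same$statistic, 1e-20)
  expect_gt(same$p_value, 0.999)
  # balanced equal-variance normal data: within 2% of the classic F
  set.seed(7)
  g <- lapply(1:3, function(i) rnorm(100, mean = 0.2 * i))
  classic <- summary(stats::aov(y ~ f, data.frame(
    y = unlist(g), f = factor(rep(1:3, each = 100)))))[[1]][["F value"]][1]
  expect_equal(welch_anova(g)$statistic, classic, tolerance = 0.02)
})

test_that("Welch p-values are uniform under the global null", {
  set.seed(12)
  ps <- replicate(5000, welch_anova(list(rnorm(15), rnorm(15, 0, 2),
                                         rnorm(15, 0, 0.5)))$p_value)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the two-stage step-up handles the documented edge cases", {
  expect_equal(sum(bky_two_stage(rep(1, 20))$reject), 0L)
  # m = 1: stage-1 level 0.05/1.05 ~ 0.0476 > 0.001, so reject everything
  one <- bky_two_stage(0.001, q = 0.05)
  expect_true(one$reject)
  expect_equal(one$r1, 1L)
  # smallest q at which p = 0.001 is rejected solves q/(1+q) = 0.001
  expect_equal(one$q_value, 0.001 / 0.999, tolerance = 1e-6)
  expect_error(bky_two_stage(c(0.5, 1.2)), class = "validation_error")
  expect_error(bky_two_stage(c(0.5, 0.1), q = 0), class = "validation_error")
})

test_that("two-stage rejections contain stage 1 and grow with q", {
  set.seed(50)
  for (rep in 1:10) {
    p <- c(runif(80), rbeta(20, 0.1, 1))
    res <- bky_two_stage(p, q = 0.05)
    # stage 1 is the plain step-up at the deflated level
    stage1 <- stats::p.adjust(p, "BH") <= 0.05 / 1.05
    expect_true(all(res$reject[stage1]))
    # monotone non-decreasing rejection count in q
    counts <- vapply(c(0.01, 0.05, 0.1, 0.2),
                     function(q) sum(bky_two_stage(p, q)$reject), integer(1))
    expect_true(all(diff(counts) >= 0))
    # adjusted q-values are consistent with the rejection flags
    expect_equal(res$q_value <= 0.05, res$reject, tolerance = 0)
    # and monotone in p
    ord <- order(p)
    expect_true(all(diff(res$q_value[ord]) >= -1e-9))
    expect_true(all(res$q_value >= 0 & res$q_value <= 1))
  }
})

test_that("run_de recovers planted effects and respects the gate", {
  cfg <- sim_config(seed = 7, effect_sd_units = 3)
  sim <- gen_expression(cfg, n_genes = 60, n_de = 6)
  de <- run_de(sim$dataset)
  expect_s3_class(de, "de_results")
  expect_true(all(de$significant[sim$truth$planted]))
  expect_lte(sum(de$significant & !sim$truth$planted), 2L)
  # log-normal noise routes genes through the rank test
  expect_true(all(de$test_used == "kruskal_wallis"))
  # significant genes carry pairwise comparisons in the same family
  pw <- attr(de, "pairwise")
  expect_setequal(names(pw), de$gene[de$significant])
  expect_equal(nrow(pw[[1]]), 3L)
  # planted genes separate severe from control in the post-hoc tests
  planted_sig <- intersect(names(pw), sim$truth$gene[sim$truth$planted])
  for (g in planted_sig) {
    row <- pw[[g]][pw[[g]]$group_i == "control" &
                     pw[[g]]$group_j == "severe", ]
    expect_lt(row$p_value, 0.01)
  }
})

test_that("run_de on a null dataset keeps discoveries near the nominal level", {
  cfg <- sim_config(seed = 23, effect_sd_units = 0)
  sim <- gen_expression(cfg, n_genes = 150, n_de = 0)
  de <- run_de(sim$dataset)
  # with no signal the expected number of false discoveries is ~ q * m in
  # the worst case; a handful is tolerable, a flood is a bug
  expect_lte(sum(de$significant), ceiling(0.05 * nrow(de)) + 2L)
})

test_that("a single strongly shifted gene is declared significant", {
  cfg <- sim_config(seed = 11, effect_sd_units = 4)
  sim <- gen_expression(cfg, n_genes = 1, n_de = 1)
  de <- run_de(sim$dataset)
  expect_true(de$significant)
})

test_that("forcing the rank test and normal noise both work end to end", {
  cfg <- sim_config(seed = 19, effect_sd_units = 3)
  sim <- gen_expression(cfg, n_genes = 20, n_de = 2, dist = "normal")
  gated <- run_de(sim$dataset)
  forced <- run_de(sim$dataset, force_test = "kruskal_wallis")
  expect_true(any(gated$test_used == "welch_anova"))
  expect_true(all(forced$test_used == "kruskal_wallis"))
  expect_true(all(forced$significant[sim$truth$planted]))
})

test_that("expression datasets validate their construction", {
  m <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_error(expression_dataset(m, c(a = "x")), class = "validation_error")
  expect_error(expression_dataset(m, rep("one", 4)),
               class = "validation_error")
  ds <- expression_dataset(m, stats::setNames(c("a", "a", "b", "b"),
                                              colnames(m)))
  expect_equal(nlevels(ds$group), 2L)
  expect_error(expression_dataset(unname(m), rep(c("a", "b"), 2)),
               class = "validation_error")
})
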