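scheme <- weight_scheme()

test_that("score_pair sums category weights with presence/absence semantics", {
  # all eleven weight-1 categories plus one U-BIOPRED compartment: the
  # highest total observed in the study tables
  cats13 <- c(setdiff(evidence_categories(), ub_categories()),
              "ub_biopsy_eqtl")
  card <- score_pair(make_evidence("rs12479210", "IL1RL1", cats13), scheme)
  expect_equal(card$base_score, 11L)
  expect_equal(card$ub_count, 1L)
  expect_equal(card$total, 13L)

  # single weight-1 hit
  one <- score_pair(make_evidence("rs1", "G", "haploreg_eqtl"), scheme)
  expect_equal(one$total, 1L)

  # every category present attains the scheme maximum (sum of all weights)
  full <- score_pair(make_evidence("rs1", "G", evidence_categories()), scheme)
  expect_equal(full$total, max_possible_score(scheme))

  # duplicates within a category never add points
  dup <- score_pair(make_evidence("rs1", "G", rep("gtex_resp_eqtl", 5)), scheme)
  expect_equal(dup$total, 1L)

  empty <- make_evidence("rs1", "G", "otg_v2g")[0, , drop = FALSE]
  expect_error(score_pair(empty, scheme), class = "validation_error")
  expect_error(score_pair(make_evidence("rs1", "G", "astrology"), scheme),
               class = "validation_error")
  mixed <- rbind(make_evidence("rs1", "G", "otg_v2g"),
                 make_evidence("rs1", "H", "otg_v2g"))
  expect_error(score_pair(mixed, scheme), class = "validation_error")
})

test_that("score_pair is order-invariant and monotone in added categories", {
  set.seed(11)
  for (rep in 1:25) {
    cats <- sample(evidence_categories(), sample(1:14, 1))
    ev <- make_evidence("rs1", "G", cats)
    base_total <- score_pair(ev, scheme)$total
    shuffled <- ev[sample(nrow(ev)), , drop = FALSE]
    expect_equal(score_pair(shuffled, scheme)$total, base_total)
    # idempotent under duplication
    expect_equal(score_pair(rbind(ev, ev), scheme)$total, base_total)
    # adding a category never decreases the total
    remaining <- setdiff(evidence_categories(), cats)
    if (length(remaining)) {
      grown <- rbind(ev, make_evidence("rs1", "G", sample(remaining, 1)))
      expect_gte(score_pair(grown, scheme)$total, base_total)
    }
    expect_true(base_total >= 0 && base_total <= max_possible_score(scheme))
  }
})

test_that("max_possible_score is the sum of the scheme's weights", {
  expect_equal(max_possible_score(weight_scheme()), 17L)
  all_ones <- stats::setNames(rep(1L, 14L), evidence_categories())
  expect_equal(max_possible_score(weight_scheme(all_ones)), 14L)
  # U-BIOPRED weights reduced to 1: 11 x 1 + 3 x 1
  flat <- weight_scheme()$weights
  flat[ub_categories()] <- 1L
  expect_equal(max_possible_score(weight_scheme(flat)), 14L)
})

test_that("the packaged score table reproduces published totals", {
  es <- load_fixture("evidence_scores")
  consistent <- es[es$weight2_consistent, ]
  expect_equal(consistent$base_score + 2L * consistent$ub_column,
               consistent$published_total)
  cards <- as_scorecards(es)
  expect_equal(max(cards$total), 13L)
  expect_equal(cards$total, es$published_total)
})

test_that("candidate selection applies threshold, fallback and override rules", {
  cards <- as_scorecards(data.frame(
    signal_rsid = c(rep("rs7523907", 3), rep("rs1837253", 2), "rs61816761",
                    "rs61816761"),
    gene = c("CD247", "BRP44", "CREG1", "TSLP", "WDR36", "FLG", "TUFT1"),
    base_score = c(7L, 0L, 0L, 2L, 1L, 2L, 0L),
    ub_count = c(0L, 1L, 1L, 0L, 0L, 0L, 1L)))
  sel <- select_candidates(cards, scheme,
                           overrides = c(rs61816761 = "FLG"))
  per <- sel$per_signal
  expect_equal(per$gene[per$signal_rsid == "rs7523907"], "CD247")
  expect_equal(per$rule[per$signal_rsid == "rs7523907"], "threshold")
  expect_equal(per$gene[per$signal_rsid == "rs1837253"], "TSLP")
  expect_equal(per$rule[per$signal_rsid == "rs1837253"], "fallback_highest")
  expect_equal(per$gene[per$signal_rsid == "rs61816761"], "FLG")
  expect_equal(per$rule[per$signal_rsid == "rs61816761"],
               "literature_override")
})

test_that("a fallback tie without an override is an ambiguity error", {
  cards <- as_scorecards(data.frame(
    signal_rsid = "rsT", gene = c("A", "B"),
    base_score = c(2L, 2L), ub_count = c(0L, 0L)))
  err <- tryCatch(select_candidates(cards, scheme), ambiguity_error = identity)
  expect_s3_class(err, "ambiguity_error")
  expect_setequal(err$tied_genes, c("A", "B"))
  # the same tie resolved by an override passes
  sel <- select_candidates(cards, scheme, overrides = c(rsT = "B"))
  expect_equal(sel$per_signal$gene, "B")
})

test_that("full-fixture selection gives 21 threshold signals, 4 fallback, 38 genes", {
  cards <- as_scorecards(load_fixture("evidence_scores"))
  sel <- select_candidates(cards, scheme,
                           overrides = c(rs61816761 = "FLG"),
                           reference_genes = load_fixture("candidate_genes")$gene)
  by_signal <- split(sel$per_signal$rule, sel$per_signal$signal_rsid)
  n_threshold <- sum(vapply(by_signal, function(r) any(r == "threshold"),
                            logical(1)))
  expect_equal(n_threshold, 21L)
  expect_equal(length(by_signal) - n_threshold, 4L)
  # every signal selects at least one gene
  expect_equal(length(by_signal), 25L)
  # the stated rule admits HLA-DOB on top of the published 37-gene set
  expect_equal(length(sel$unique_genes), 38L)
  expect_true("HLA-DOB" %in% sel$unique_genes)
  expect_match(sel$annotations, "HLA-DOB", all = FALSE)
  # unique_genes keeps first-appearance (signal-table) order
  expect_equal(sel$unique_genes[1:3], c("FLG", "CD247", "IL1RL1"))
  # candidate JSON round-trips
  path <- withr::local_tempfile(fileext = ".json")
  write_candidates_json(sel, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$unique_genes, sel$unique_genes)
  expect_equal(back$per_signal$rule, sel$per_signal$rule)
})

test_that("score_evidence groups an evidence table into one card per pair", {
  ev <- rbind(
    make_evidence("rs1", "A", c("gtex_resp_eqtl", "ub_brush_eqtl")),
    make_evidence("rs1", "B", "literature"),
    make_evidence("rs2", "A", c("otg_v2g", "otg_v2g")))
  cards <- score_evidence(ev)
  expect_equal(nrow(cards), 3L)
  expect_equal(cards$total, c(3L, 1L, 1L))
  expect_equal(score_evidence(ev[0, ])$total, integer(0))
})
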