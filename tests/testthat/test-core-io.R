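test_that("the packaged signal table loads as 25 validated records", {
  sig <- load_fixture("signals")
  expect_equal(nrow(sig), 25L)
  expect_true(all(nzchar(sig$rsid)))
  expect_true(all(sig$risk_allele != sig$non_risk_allele))
  expect_true(all(sig$raf_eur >= 0 & sig$raf_eur <= 1))
  # multi-base indel alleles survive as strings
  expect_equal(sig$risk_allele[sig$rsid == "rs560026225"], "GATT")
})

test_that("read_table validates headers, coerces types and flags bad cells", {
  header <- "rsid\tclosest_gene\trisk_allele\tnon_risk_allele\traf_eur"
  ok <- write_tsv_lines(c(header, "rs1\tG1\tA\tG\t0.25"))
  df <- read_signals(ok)
  expect_equal(df$raf_eur, 0.25)

  empty <- write_tsv_lines(header)
  expect_equal(nrow(read_signals(empty)), 0L)

  oob <- write_tsv_lines(c(header, "rs1\tG1\tA\tG\t0.25", "rs2\tG2\tC\tT\t1.2"))
  expect_error(read_signals(oob), class = "parse_error")
  expect_error(read_signals(oob), "row 2")

  junk <- write_tsv_lines(c(header, "rs1\tG1\tA\tG\tabc"))
  expect_error(read_signals(junk), class = "parse_error")

  nohdr <- write_tsv_lines(c("rsid\tclosest_gene", "rs1\tG1"))
  expect_error(read_signals(nohdr), class = "schema_error")
  expect_error(read_signals(nohdr), "risk_allele")

  extra <- write_tsv_lines(c(paste0(header, "\tmystery"),
                             "rs1\tG1\tA\tG\t0.25\tx"))
  expect_warning(df2 <- read_signals(extra), "mystery")
  expect_false("mystery" %in% names(df2))

  same_allele <- write_tsv_lines(c(header, "rs1\tG1\tA\tA\t0.25"))
  expect_error(read_signals(same_allele), class = "parse_error")
})

test_that("scientific notation is accepted and empty cells stay missing", {
  path <- write_tsv_lines(c(
    "rsid\ttrait\teffect\tp_value\todds_ratio",
    "rs1\tasthma\t0.12\t1.5e-12\t1.3",
    "rs1\teosinophil count\t0.05\t2e-8\t"))
  df <- read_phewas(path)
  expect_equal(df$p_value[1], 1.5e-12)
  expect_true(is.na(df$odds_ratio[2]))
})

test_that("record tables round-trip losslessly through write and read", {
  ev <- data.frame(
    signal_rsid = c("rs1", "rs1", "rs2"),
    gene = c("A", "A", "B"),
    category = c("gtex_resp_eqtl", "otg_coloc", "ub_brush_eqtl"),
    tissue = c("lung", "lung", "nasal"),
    p_value = c(0.01, NA, 0.002),
    effect_b = c(-0.37, NA, 0.1),
    h4 = c(NA, 0.92, NA),
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table(ev, path)
  expect_equal(read_evidence(path), ev)

  ld <- data.frame(rsid_a = c("rs1", "rs1"), rsid_b = c("rs2", "rs3"),
                   r2 = c(0.5, 0.81), stringsAsFactors = FALSE)
  write_table(ld, path)
  expect_equal(read_ld_pairs(path), ld)
})

test_that("symmetric LD duplicates collapse; conflicting r2 is an error", {
  dup <- write_tsv_lines(c("rsid_a\trsid_b\tr2",
                           "rs1\trs2\t0.5", "rs2\trs1\t0.5"))
  expect_equal(nrow(read_ld_pairs(dup)), 1L)
  conflict <- write_tsv_lines(c("rsid_a\trsid_b\tr2",
                                "rs1\trs2\t0.5", "rs2\trs1\t0.6"))
  expect_error(read_ld_pairs(conflict), class = "validation_error")
})

test_that("GMT files parse, deduplicate within terms and round-trip", {
  gmt <- write_tsv_lines(c(
    "term1\tdesc one\tA\tB\tC",
    "term2\t\tD\tE\tF\tG\tH"))
  coll <- read_gmt(gmt)
  expect_equal(names(coll$terms), c("term1", "term2"))
  expect_equal(lengths(coll$terms), c(term1 = 3L, term2 = 5L))

  dup <- write_tsv_lines("term1\td\tA\tB\tA")
  expect_equal(lengths(read_gmt(dup)$terms), c(term1 = 2L))

  short <- write_tsv_lines(c("term1\td\tA", "broken\tdesc"))
  expect_error(read_gmt(short), class = "format_error")
  expect_error(read_gmt(short), "line 2")

  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, out)
  expect_equal(read_gmt(out), coll)
})

test_that("GMT parsing agrees with an independent reader", {
  skip_if_not_installed("fgsea")
  gmt <- write_tsv_lines(c(
    "pathway_a\tsource\tTP53\tEGFR\tKRAS",
    "pathway_b\tsource\tIL6\tIL33\tTSLP\tKRAS"))
  ours <- read_gmt(gmt)$terms
  theirs <- fgsea::gmtPathways(gmt)
  expect_equal(ours[order(names(ours))], theirs[order(names(theirs))])
})

test_that("gene_set_collection enforces background and non-empty terms", {
  expect_error(gene_set_collection(list(t1 = character())),
               class = "validation_error")
  expect_error(gene_set_collection(list(t1 = c("A", "B")), background = "A"),
               class = "validation_error")
  coll <- gene_set_collection(list(t1 = c("A", "B")),
                              background = c("A", "B", "C"))
  expect_equal(coll$background, c("A", "B", "C"))
})

test_that("load_fixture returns verbatim study tables and rejects unknowns", {
  expect_error(load_fixture("nonsense"), class = "lookup_error")

  es <- load_fixture("evidence_scores")
  il1rl1 <- es[es$signal_rsid == "rs12479210" & es$gene == "IL1RL1", ]
  expect_equal(il1rl1$base_score, 11L)
  expect_equal(il1rl1$ub_column, 1L)
  expect_equal(il1rl1$published_total, 13L)
  # normalization reproduces every published total from base + 2 * ub_count
  expect_true(all(es$base_score + 2L * es$ub_count == es$published_total))
  expect_true(all(es$ub_count <= 3L))
  # the rs776111176 rows are the weight-2-inconsistent ones
  expect_true(all(!es$weight2_consistent[
    es$signal_rsid == "rs776111176" & es$ub_column > 0]))

  dr <- load_fixture("drug_table")
  carnitine <- dr[dr$gene == "SLC22A5" & dr$drug == "CARNITINE", ]
  expect_equal(carnitine$interaction_score, 63.79)

  w <- load_fixture("weights")
  expect_equal(nrow(w), 14L)
  expect_true(attr(w, "total_mismatch")) # printed total 16, row sum 17
  expect_equal(sum(w$weight), 17L)
  expect_equal(attr(w, "declared_total"), 16L)
  # fixture weights match the in-code default scheme
  expect_equal(stats::setNames(w$weight, w$category),
               weight_scheme()$weights[w$category])

  expect_equal(nrow(load_fixture("candidate_genes")), 37L)
  expect_equal(length(unique(load_fixture("proxies")$sentinel)), 25L)
  expect_equal(nrow(load_fixture("enrichment_table")), 10L)
})

test_that("slash-clustered gene labels expand to atomic symbols", {
  expect_equal(split_gene_cluster("HLA-DQA1/A2"), c("HLA-DQA1", "HLA-DQA2"))
  expect_equal(split_gene_cluster("HLA-DQA1/A2/B1/B2"),
               c("HLA-DQA1", "HLA-DQA2", "HLA-DQB1", "HLA-DQB2"))
  expect_equal(split_gene_cluster("SLC22A4/5"), c("SLC22A4", "SLC22A5"))
  expect_equal(split_gene_cluster("STAT6"), "STAT6")
  expect_equal(split_gene_cluster(c("GSDMB", "IL18R1/IL1RL1")),
               c("GSDMB", "IL18R1", "IL1RL1"))
})
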