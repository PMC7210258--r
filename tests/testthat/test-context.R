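toy_annotation <- function() {
  genome_annotation(
    chrom_sizes = c(chr1 = 100000),
    genes = data.frame(
      gene_id = c("gA", "gB"), chrom = "chr1",
      start = c(10000L, 40000L), end = c(20000L, 50000L),
      strand = c("+", "-"),
      tss = c(10000L, 49999L),
      gene_set = c("up", "down"), stringsAsFactors = FALSE),
    exons = data.frame(gene_id = c("gA", "gA", "gB"), chrom = "chr1",
                       start = c(10000L, 15000L, 40000L),
                       end = c(12000L, 16000L, 43000L)),
    cgis = data.frame(chrom = "chr1", start = 9500L, end = 10500L),
    states = data.frame(chrom = "chr1", start = c(0L, 30000L),
                        end = c(30000L, 100000L),
                        state = c("Weak Txn", "Quiescent")))
}

test_that("positions are annotated with the documented precedence and distance rules", {
  ann <- toy_annotation()
  probes <- data.frame(
    probe_id = sprintf("p%d", 1:8), chrom = "chr1",
    # 0-based points: 9500 (500bp upstream of gA TSS), 13000 (intron),
    # 15500 (exon), 10200 (promoter AND exon -> promoter), 12001 (CGI+1501bp),
    # 13500 (CGI+3000), 60000 (open sea / intergenic), 49700 (gB promoter,
    # minus strand, 299bp downstream of its TSS)
    pos = c(9500, 13000, 15500, 10200, 12001, 13500, 60000, 49700) + 1L)
  ctx <- annotate_positions(probes, ann)
  expect_identical(ctx$feature,
                   c("promoter", "intron", "exon", "promoter", "intron",
                     "intron", "intergenic", "promoter"))
  expect_identical(ctx$cgi_context[c(1, 5, 6, 7)],
                   c("island", "shore", "shelf", "open_sea"))
  expect_identical(ctx$chrom_state, c(rep("Weak Txn", 6), "Quiescent",
                                      "Quiescent"))
  # nearest gene by TSS with signed orientation-aware distance
  expect_identical(ctx$nearest_gene_id[1], "gA")
  expect_equal(ctx$tss_distance[1], -500)
  expect_identical(ctx$nearest_gene_id[8], "gB")
  expect_equal(ctx$tss_distance[8], 49999 - 49700)

  # feature labels partition the probe set
  expect_equal(sum(table(ctx$feature)), nrow(probes))
  expect_error(annotate_positions(transform(probes, chrom = "chrX"), ann),
               class = "oxbspipe_annotation_error")
})

test_that("category enrichment matches hand arithmetic and enumeration", {
  # fg 30/100 intronic vs bg-only 10/100
  labels <- setNames(rep(c("intron", "other"), c(40, 160)),
                     sprintf("p%03d", 1:200))
  fg <- c(sprintf("p%03d", 1:30), sprintf("p%03d", 41:110))
  bg <- names(labels)
  out <- enrichment_vs_background(fg, bg, labels)
  expect_equal(out$odds_ratio[out$category == "intron"],
               (30 * 90) / (70 * 10), tolerance = 1e-12)

  # identical fg and bg composition gives no enrichment signal
  labels2 <- setNames(rep(c("a", "b"), 50), sprintf("q%03d", 1:100))
  fg2 <- sprintf("q%03d", 1:50)   # 25 a's and 25 b's, as in the background
  out2 <- enrichment_vs_background(fg2, names(labels2), labels2)
  expect_true(all(out2$odds_ratio == 1))
  expect_equal(out2$p, rep(1, nrow(out2)), tolerance = 1e-12)

  # background against itself degenerates to the no-information answer
  out3 <- enrichment_vs_background(names(labels2), names(labels2), labels2)
  expect_true(all(out3$odds_ratio == 1))
  expect_true(all(out3$p == 1))

  # small-table p equals the exact enumeration of tables with fixed margins
  labels3 <- setNames(rep(c("x", "y"), c(4, 6)), letters[1:10])
  fg3 <- c("a", "b", "c", "e", "f")   # 3 of 5 in x; bg-only has 1 of 5
  out4 <- enrichment_vs_background(fg3, letters[1:10], labels3)
  expect_equal(out4$p[out4$category == "x"], fisher_enum_oracle(3, 2, 1, 4),
               tolerance = 1e-12)
  expect_error(enrichment_vs_background(character(0), bg, labels),
               class = "oxbspipe_validation_error")
})

test_that("metagene profiles are flat for constant signal and mirror across strands", {
  ann <- toy_annotation()
  set.seed(3)
  pos <- sort(sample(5000:55000, 600))
  probes <- data.frame(probe_id = sprintf("mp%03d", seq_along(pos)),
                       chrom = "chr1", pos = pos + 1L)
  const <- setNames(rep(0.5, nrow(probes)), probes$probe_id)
  prof <- metagene_profile(const, probes, ann, gene_sets = c("up", "down"))
  expect_true(all(abs(prof$mean[prof$count > 0] - 0.5) < 1e-12))
  # mass conservation: every (gene, probe-in-window) pair is binned once
  flank <- prof$scheme$flank
  expected_pairs <- sum(sapply(seq_len(nrow(ann$genes)), function(i)
    sum(pos >= ann$genes$start[i] - flank & pos < ann$genes$end[i] + flank)))
  expect_equal(sum(prof$count), expected_pairs)

  # strand symmetry: a minus-strand mirror of a plus-strand gene sees the
  # reversed body profile under a coordinate-linear signal
  ann2 <- toy_annotation()
  ann2$genes <- data.frame(
    gene_id = c("gP", "gM"), chrom = "chr1",
    start = c(10000L, 40000L), end = c(20000L, 50000L),
    strand = c("+", "-"), tss = c(10000L, 49999L),
    gene_set = c("up", "down"), stringsAsFactors = FALSE)
  ann2$exons <- data.frame(gene_id = c("gP", "gM"), chrom = "chr1",
                           start = c(10000L, 40000L), end = c(20000L, 50000L))
  p1 <- seq(10000L, 19999L, by = 100L)
  p2 <- seq(40000L, 49999L, by = 100L)
  probes2 <- data.frame(probe_id = sprintf("s%03d", seq_along(c(p1, p2))),
                        chrom = "chr1", pos = c(p1, p2) + 1L)
  # identical increasing signal along each gene in + orientation
  sig <- setNames(c((p1 - 10000) / 10000, (p2 - 40000) / 10000),
                  probes2$probe_id)
  prof2 <- metagene_profile(sig, probes2, ann2, gene_sets = c("up", "down"),
                            flank = 0, flank_bins = 0, body_bins = 10)
  expect_equal(unname(prof2$mean["up", ]), rev(unname(prof2$mean["down", ])),
               tolerance = 1e-12)
})

test_that("gene-body summaries report percent means and detect condition shifts", {
  run <- default_small_run()
  est <- run$estimate

  # truth-equal flat estimate: every defined 5hmC cell at 0.04 reads 4.0%
  flat <- est
  flat$h[] <- 0.04; flat$m[] <- 0.5; flat$na_mask[] <- FALSE
  gs <- suppressWarnings(gene_body_summary(flat, run$annotation))
  expect_true(all(abs(gs$summary$mean_h_pct - 4.0) < 1e-9))
  expect_true(all(abs(gs$summary$mean_m_pct - 50) < 1e-9))

  # on the default simulation the differentiation gain is recovered with a
  # convincing rank-sum p, mirroring the direction of the design
  gs2 <- run$body_summary
  s <- gs2$summary
  expect_lt(s$mean_h_pct[s$condition == "proliferative"],
            s$mean_h_pct[s$condition == "differentiating"])
  p <- gs2$tests
  expect_lt(p$p[p$condition_a == "proliferative" &
                  p$condition_b == "differentiating" & p$mark == "5hmC"], 0.01)

  # restricting to an absent gene set is an explicit error
  expect_error(gene_body_summary(est, run$annotation, gene_sets = "nope"),
               class = "oxbspipe_validation_error")
})

test_that("hypergeometric overlap agrees with exact summation and simulation", {
  U <- sprintf("g%03d", 1:100)
  A <- U[1:10]; B <- U[c(1:5, 51:55)]
  ov <- overlap_hypergeometric(A, B, U)
  expect_equal(ov$k, 5)
  expect_equal(ov$expected, 1.0)
  expect_equal(ov$fold, 5.0)
  expect_equal(ov$p, hyper_tail_oracle(5, 10, 10, 100), tolerance = 1e-12)

  # self-overlap saturates
  full <- overlap_hypergeometric(U, U, U)
  expect_equal(full$fold, 1.0)
  expect_equal(full$p, 1.0)

  # disjoint small sets show no enrichment
  dis <- overlap_hypergeometric(U[1:3], U[50:52], U)
  expect_gt(dis$p, 0.7)

  # permutation cross-check on a small universe
  set.seed(14)
  U2 <- letters[1:20]; A2 <- letters[1:6]; B2 <- letters[c(1:4, 10:12)]
  ov2 <- overlap_hypergeometric(A2, B2, U2)
  draws <- replicate(20000, length(intersect(sample(U2, length(B2)), A2)))
  expect_lt(abs(mean(draws >= ov2$k) - ov2$p), 0.02)

  expect_error(overlap_hypergeometric(A, B, character(0)),
               class = "oxbspipe_validation_error")
})
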