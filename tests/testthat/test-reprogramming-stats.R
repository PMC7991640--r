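test_that("peak decomposition classifies common and unique peaks correctly", {
  a <- gr0(c("chr1", "chr1"), c(0, 5000), c(1000, 6000))
  b <- gr0(c("chr1", "chr2"), c(500, 0), c(1500, 1000))
  d <- decompose_peaks(a, b)
  expect_equal(d$venn,
               list(a_only = 1, b_only = 1, common_a_perspective = 1,
                    common_b_perspective = 1))
  disjoint <- decompose_peaks(gr0("chr1", 0, 100), gr0("chr1", 200, 300))
  expect_equal(disjoint$venn$a_only, 1)
  expect_equal(disjoint$venn$common_a_perspective, 0)
  same <- decompose_peaks(a, a)
  expect_equal(same$venn$a_only, 0)
  expect_equal(same$venn$common_b_perspective, 2)
})

test_that("decomposition matches brute force and is symmetric in classification", {
  genome <- toy_genome()
  set.seed(5)
  for (i in 1:10) {
    a <- rand_intervals(300, genome, max_len = 4000)
    b <- rand_intervals(300, genome, max_len = 4000)
    d <- decompose_peaks(a, b)
    expect_equal(as_triple(d$common_a),
                 as_triple(a[naive_overlaps_any(a, b)]), ignore_attr = TRUE)
    expect_equal(as_triple(d$unique_b),
                 as_triple(b[!naive_overlaps_any(b, a)]), ignore_attr = TRUE)
    # symmetry: a has common peaks iff b does
    expect_equal(d$venn$common_a_perspective > 0,
                 d$venn$common_b_perspective > 0)
  }
})

test_that("element annotation assigns midpoints by precedence and partitions", {
  genome <- toy_genome()
  gm <- toy_genes()
  # geneA: body 100000-120000, exons 100000-105000 and 110000-115000,
  # promoter 98000-100500
  peaks <- gr0(rep("chr1", 4),
               c(98200, 102000, 106000, 300000),
               c(98800, 103000, 107000, 301000))
  ann <- annotate_elements(peaks, gm)
  expect_equal(attr(ann, "element"),
               c("promoter", "exon", "intron", "intergenic"))
  expect_equal(sum(ann$fraction), 1)
  # a promoter-overlapping exon midpoint counts as promoter
  pk <- gr0("chr1", 100000, 100400)  # midpoint 100200, in exon AND promoter
  expect_equal(attr(annotate_elements(pk, gm), "element"), "promoter")
  # gene-free chromosome is intergenic
  pk2 <- gr0("chr2", 900000, 901000)
  expect_equal(attr(annotate_elements(pk2, gm), "element"), "intergenic")
})

test_that("expression stratification splits ranked tertiles deterministically", {
  fpkm <- setNames(as.numeric(1:9), paste0("g", 1:9))
  st <- stratify_expression(fpkm)
  expect_equal(unname(st[c("g1", "g2", "g3")]), rep("low", 3))
  expect_equal(unname(st[c("g4", "g5", "g6")]), rep("medium", 3))
  expect_equal(unname(st[c("g7", "g8", "g9")]), rep("high", 3))
  ties <- setNames(rep(5, 6), paste0("g", 1:6))
  st2 <- stratify_expression(ties)
  expect_equal(unname(st2), rep(c("low", "medium", "high"), each = 2))
  expect_identical(st2, stratify_expression(ties))  # deterministic
  zero <- setNames(c(0, 0, 0, 1, 2, 3, 4, 5, 6), paste0("g", 1:9))
  expect_true(all(stratify_expression(zero)[1:3] == "low"))
  expect_error(stratify_expression(setNames(1:2, c("a", "b"))), "fewer genes")
})

test_that("delta correlation is exact on lines and fails on degenerate input", {
  x <- seq(-3, 5, length.out = 25)
  rec <- data.frame(u = x, v = 2 * x + 1, w = -x, z = rep(2, 25))
  expect_equal(delta_correlation(rec, "u", "v")$r, 1.0)
  expect_equal(delta_correlation(rec, "u", "w")$r, -1.0)
  expect_equal(delta_correlation(rec, "u", "v")$n, 25)
  expect_error(delta_correlation(rec, "u", "z"), "zero variance")
  expect_error(delta_correlation(rec[1:2, ], "u", "v"), "at least 3")
  expect_error(delta_correlation(rec, "u", "missing"), "not found")
})

test_that("delta correlation equals the closed-form Pearson formula", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(5:400, 1)
    rec <- data.frame(x = rnorm(n, sd = runif(1, 0.5, 20)),
                      y = rnorm(n, sd = runif(1, 0.5, 20)))
    got <- delta_correlation(rec, "x", "y")$r
    expect_equal(got, pearson_formula(rec$x, rec$y), tolerance = 1e-12)
  }
})

test_that("inactivation association handles edge cases exactly", {
  genome <- toy_genome()
  gm <- toy_genes()
  enh <- assign_enhancers(gr0(c("chr1", "chr1"), c(130000, 150000),
                              c(131000, 151000)), gm)
  wt <- classify_enhancers(enh, enh, GRanges())          # both active
  mut_none <- classify_enhancers(enh, enh, GRanges())    # both stay active
  tr0 <- enhancer_transitions(wt, mut_none)
  de <- setNames(c("down", "up", "unchanged"), c("geneA", "geneB", "geneC"))
  res0 <- inactivation_gene_association(tr0, wt, de)
  expect_equal(res0$de_fractions$fraction, c(0, 0, 0))
  # both enhancers inactivated; both assigned to geneA
  mut_all <- classify_enhancers(enh, GRanges(), GRanges())  # primed now
  tr2 <- enhancer_transitions(wt, mut_all)
  fpkm_wt <- setNames(c(8, 2, 1), c("geneA", "geneB", "geneC"))
  fpkm_mut <- setNames(c(2, 2, 1), c("geneA", "geneB", "geneC"))
  res2 <- inactivation_gene_association(tr2, wt, de, fpkm_wt, fpkm_mut)
  expect_equal(res2$de_fractions$fraction[res2$de_fractions$status == "down"],
               1.0)
  expect_equal(res2$fc_bins$bin, c("0", "1", "2", ">=3"))
  expect_equal(res2$fc_bins$n_genes, c(2L, 0L, 1L, 0L))
  expect_equal(res2$fc_bins$median_lfc[3], log2(3 / 9))
})

test_that("per-state expression summaries order states and handle identical sets", {
  genome <- toy_genome()
  gm <- toy_genes()
  fpkm <- setNames(c(10, 5, 1), c("geneA", "geneB", "geneC"))
  # one enhancer near geneA and one near geneB per state
  enh <- gr0(rep("chr1", 6),
             rep(c(130000, 370000), 3) + rep(c(0, 2000, 4000), each = 2),
             rep(c(130500, 370500), 3) + rep(c(0, 2000, 4000), each = 2))
  enh <- assign_enhancers(enh, gm)
  mcols(enh)$state <- rep(c("active", "primed", "poised"), each = 2)
  res <- class_expression_summary(enh, fpkm)
  expect_equal(res$summary$state, c("active", "primed", "poised"))
  # all states share the same assigned gene set here -> p ~ 1
  expect_true(all(res$contrasts$p > 0.9))
  solo <- enh[mcols(enh)$state == "active"]
  res1 <- class_expression_summary(solo, fpkm)
  expect_null(res1$contrasts)
  expect_equal(res1$summary$n_genes[res1$summary$state == "primed"], 0L)
})
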