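test_that("promoters are strand-aware 2 kb upstream / 500 bp downstream windows", {
  genome <- toy_genome()
  genes <- data.frame(gene_id = c("p", "m", "edge"),
                      chrom = "chr1", strand = c("+", "-", "+"),
                      tss = c(10000, 10000, 1000),
                      tes = c(20000, 5000, 9000), fpkm = 1)
  gm <- gene_models(genes, data.frame(gene_id = c("p", "m", "edge"),
                                      chrom = "chr1",
                                      start = c(10000, 5000, 1000),
                                      end = c(10500, 5500, 1500)), genome)
  pr <- define_promoters(gm)
  tri <- as_triple(pr)
  expect_equal(tri[tri$chrom == "chr1", ][1, c("start", "end")],
               data.frame(start = 8000, end = 10500), ignore_attr = TRUE)
  expect_equal(tri[2, c("start", "end")],
               data.frame(start = 9500, end = 12000), ignore_attr = TRUE)
  expect_equal(tri[3, c("start", "end")],
               data.frame(start = 0, end = 1500), ignore_attr = TRUE)
})

test_that("enhancer calling excludes any K4me3/promoter overlap, even 1 bp", {
  genome <- toy_genome()
  gm <- toy_genes()
  promoters <- define_promoters(gm)
  # promoter of geneA (+ strand, TSS 100000) spans 98000-100500
  k4me1 <- gr0(rep("chr1", 3), c(90000, 97000, 200000),
               c(95000, 98001, 201000))
  k4me3 <- gr0("chr1", 90500, 91000)
  enh <- call_enhancers(k4me1, k4me3, promoters)
  # first peak hits K4me3, second touches the promoter by exactly 1 bp
  expect_equal(as_triple(enh),
               data.frame(chrom = "chr1", start = 200000, end = 201000))
  expect_true(all(is.na(mcols(enh)$state)))
})

test_that("enhancer calling matches a brute-force set filter on random peaks", {
  genome <- toy_genome()
  gm <- toy_genes()
  promoters <- define_promoters(gm)
  set.seed(17)
  k4me1 <- rand_intervals(200, genome, max_len = 3000)
  k4me3 <- rand_intervals(50, genome, max_len = 2000)
  enh <- call_enhancers(k4me1, k4me3, promoters)
  drop <- naive_overlaps_any(k4me1, k4me3) |
    naive_overlaps_any(k4me1, promoters)
  expect_equal(as_triple(enh), as_triple(k4me1[!drop]), ignore_attr = TRUE)
})

test_that("classification is a partition with active > poised precedence", {
  enh <- call_enhancers(gr0(rep("chr1", 4), c(0, 1000, 2000, 3000) * 10,
                            c(500, 10500, 20500, 30500)),
                        GRanges(), GRanges())
  ac <- gr0("chr1", 0, 400)            # overlaps enhancer 1
  me3 <- gr0(c("chr1", "chr1"), c(0, 20000), c(400, 20100))  # 1 and 3
  cl <- classify_enhancers(enh, ac, me3)
  expect_equal(mcols(cl)$state, c("active", "primed", "poised", "primed"))
  expect_equal(attr(cl, "ambiguous_fraction"), 0.25)
  sf <- state_fractions(cl)
  expect_equal(sum(sf$fraction), 1)
  expect_equal(sum(sf$n), length(cl))
  # adding an H3K27ac peak only ever moves states toward active
  cl2 <- classify_enhancers(enh, c(ac, gr0("chr1", 20000, 20050)), me3)
  moved <- mcols(cl2)$state != mcols(cl)$state
  expect_true(all(mcols(cl2)$state[moved] == "active"))
})

test_that("transitions flag WT-active enhancers that lose the active state", {
  wt <- classify_enhancers(
    call_enhancers(gr0(rep("chr1", 3), c(1e4, 5e4, 9e4), c(2e4, 6e4, 1e5)),
                   GRanges(), GRanges()),
    gr0(rep("chr1", 3), c(1e4, 5e4, 9e4), c(2e4, 6e4, 1e5)), GRanges())
  expect_equal(sum(summary(enhancer_transitions(wt, wt))$n_inactivated), 0)
  # mutant: first enhancer poised, second absent, third still active
  mut <- classify_enhancers(
    call_enhancers(gr0(c("chr1", "chr1"), c(1e4, 9e4), c(2e4, 1e5)),
                   GRanges(), GRanges()),
    gr0("chr1", 9e4, 1e5), gr0("chr1", 1e4, 2e4))
  tr <- enhancer_transitions(wt, mut)
  expect_equal(tr$mutant_state, c("poised", "lost", "active"))
  expect_equal(tr$inactivated, c(TRUE, TRUE, FALSE))
  s <- summary(tr)
  expect_equal(s$inactivated_percent, 100 * 2 / 3)
})

test_that("gene assignment respects the distance window and matches brute force", {
  genome <- toy_genome()
  gm <- toy_genes()
  near <- assign_enhancers(gr0("chr1", 150000, 151000), gm)
  expect_equal(mcols(near)$assigned_gene, "geneA")
  far <- assign_enhancers(gr0("chr1", 150000, 151000), gm, max_dist = 10000)
  expect_true(is.na(mcols(far)$assigned_gene))
  set.seed(25)
  q <- rand_intervals(1000, genome, max_len = 2000)
  got <- assign_enhancers(q, gm)
  want <- naive_nearest_tss(q, gm, max_dist = 500000)
  expect_equal(mcols(got)$assigned_gene, want$gene_id)
  expect_equal(mcols(got)$tss_distance, want$distance)
})

test_that("enhancer summary statistics aggregate per condition and class", {
  e1 <- gr0("chr1", 1000, 1400)
  mcols(e1)$tss_distance <- 5000
  s <- enhancer_stats(list(wt = e1))
  expect_equal(s$length_mean, 400)
  expect_equal(s$dist_mean, 5000)
  two <- gr0(c("chr1", "chr1"), c(0, 5000), c(1000, 5500))
  mcols(two)$tss_distance <- c(1000, 3000)
  s2 <- enhancer_stats(list(a = two, b = two))
  expect_equal(s2[s2$condition == "a", -1], s2[s2$condition == "b", -1],
               ignore_attr = TRUE)
  expect_error(enhancer_stats(list(a = GRanges())), "at least one")
})
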