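test_that("BED round-trips preserve coordinates, names, scores and strand", {
  genome <- toy_genome()
  gr <- gr0(c("chr1", "chr1", "chr2"), c(0, 500, 1000),
            c(100, 900, 5000),
            name = c("a", "b", "c"), score = c(1, 2.5, 0))
  strand(gr) <- c("+", "-", "*")
  p <- withr::local_tempfile(fileext = ".bed")
  write_bed(gr, p)
  back <- read_bed(p, genome)
  expect_equal(start(back), start(gr))
  expect_equal(end(back), end(gr))
  expect_equal(mcols(back)$name, mcols(gr)$name)
  expect_equal(mcols(back)$score, mcols(gr)$score)
  expect_equal(as.character(strand(back)), as.character(strand(gr)))
  # minimal 3-column line maps fields directly
  p2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100", p2)
  b <- read_bed(p2)
  expect_equal(start(b), 1L)
  expect_equal(end(b), 100L)
})

test_that("malformed or invalid BED lines fail with the line number", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t50\t50"), p)
  expect_error(read_bed(p), "line 2")
  writeLines(c("chr1\t0\t100", "chr1\tx\t200"), p)
  expect_error(read_bed(p), "line 2")
  writeLines(c("chr1\t0\t100", "chr9\t0\t100"), p)
  expect_error(read_bed(p, toy_genome()), "line 2.*chr9")
  writeLines("chr1\t0", p)
  expect_error(read_bed(p), "line 1")
})

test_that("overlap predicate honors half-open coordinates and min_bp", {
  a <- gr0("chr1", 0, 100)
  expect_true(interval_overlaps(a, gr0("chr1", 50, 150)))
  expect_false(interval_overlaps(a, gr0("chr1", 100, 200)))  # book-ended
  expect_false(interval_overlaps(a, gr0("chr2", 0, 100)))
  expect_true(interval_overlaps(a, gr0("chr1", 50, 150), min_bp = 50))
  expect_false(interval_overlaps(a, gr0("chr1", 50, 150), min_bp = 51))
  expect_equal(overlaps_any(a, gr0("chr1", 99, 200)), TRUE)
})

test_that("subtract drops whole peaks or trims bases as requested", {
  a <- gr0("chr1", 0, 100)
  b <- gr0("chr1", 90, 200)
  expect_length(subtract_intervals(a, b, mode = "whole"), 0)
  base <- subtract_intervals(a, b, mode = "base")
  expect_equal(as_triple(base),
               data.frame(chrom = "chr1", start = 0, end = 90))
  expect_equal(as_triple(subtract_intervals(a, GRanges())), as_triple(a))
  # splitting: removing the middle leaves both flanks
  split2 <- subtract_intervals(gr0("chr1", 0, 100), gr0("chr1", 40, 60),
                               mode = "base")
  expect_equal(as_triple(split2)$start, c(0, 60))
  expect_equal(as_triple(split2)$end, c(40, 100))
})

test_that("merge unites overlapping and book-ended intervals and is idempotent", {
  m <- merge_intervals(gr0(c("chr1", "chr1"), c(0, 50), c(100, 150)))
  expect_equal(as_triple(m), data.frame(chrom = "chr1", start = 0, end = 150))
  u <- merge_intervals(gr0(c("chr1", "chr1"), c(0, 200), c(100, 300)))
  expect_length(u, 2)
  bk <- merge_intervals(gr0(c("chr1", "chr1"), c(0, 100), c(100, 150)))
  expect_equal(as_triple(bk), naive_merge(gr0(c("chr1", "chr1"), c(0, 100),
                                              c(100, 150))))
  set.seed(42)
  for (i in 1:10) {
    x <- rand_intervals(100, toy_genome(), max_len = 20000)
    m1 <- merge_intervals(x)
    expect_equal(as_triple(merge_intervals(m1)), as_triple(m1))
  }
})

test_that("interval algebra agrees with naive O(n^2) references on random sets", {
  genome <- toy_genome()
  set.seed(11)
  for (i in 1:15) {
    a <- rand_intervals(sample(20:200, 1), genome, max_len = 30000)
    b <- rand_intervals(sample(20:200, 1), genome, max_len = 30000)
    expect_equal(overlaps_any(a, b), naive_overlaps_any(a, b))
    keep <- !naive_overlaps_any(a, b)
    expect_equal(as_triple(subtract_intervals(a, b, mode = "whole")),
                 as_triple(a[keep]), ignore_attr = TRUE)
    expect_equal(canon(merge_intervals(a)), canon(naive_merge(a)))
    sb <- subtract_intervals(a, b, mode = "base")
    nb <- naive_subtract_base(a, b)
    expect_equal(canon(merge_intervals(sb)),
                 canon(naive_merge(gr0(nb$chrom, nb$start, nb$end))))
  }
})

test_that("nearest_tss picks the closest TSS with deterministic tie-breaks", {
  gm <- toy_genes()
  q <- gr0("chr1", 1000, 1200)  # midpoint 1100
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      strand = "+", tss = c(1150, 5000),
                      tes = c(3000, 9000), fpkm = 1)
  gm2 <- gene_models(genes, data.frame(gene_id = "g1", chrom = "chr1",
                                       start = 1150, end = 1300),
                     toy_genome())
  nn <- nearest_tss(q, gm2, max_dist = 1e6)
  expect_equal(nn$gene_id, "g1")
  expect_equal(nn$distance, 50)
  expect_true(is.na(nearest_tss(q, gm2, max_dist = 10)$gene_id))
  # equidistant TSSs resolve to the lexicographically smaller gene_id
  genes$tss <- c(1000, 1200)
  gm3 <- gene_models(genes, data.frame(gene_id = "g1", chrom = "chr1",
                                       start = 1000, end = 1100),
                     toy_genome())
  expect_equal(nearest_tss(q, gm3, max_dist = 1e6)$gene_id, "g1")
})

test_that("nearest_tss matches an exhaustive scan on random queries", {
  genome <- toy_genome()
  set.seed(3)
  ng <- 100
  ch <- sample(names(genome), ng, replace = TRUE)
  tss <- floor(runif(ng, 1000, 990000))
  genes <- data.frame(gene_id = sprintf("g%03d", 1:ng), chrom = ch,
                      strand = "+", tss = tss, tes = tss + 500, fpkm = 1)
  gm <- gene_models(genes, data.frame(gene_id = genes$gene_id, chrom = ch,
                                      start = tss, end = tss + 500), genome)
  q <- rand_intervals(1000, genome, max_len = 2000)
  got <- nearest_tss(q, gm, max_dist = 50000)
  want <- naive_nearest_tss(q, gm, max_dist = 50000)
  expect_equal(got$gene_id, want$gene_id)
  expect_equal(got$distance, want$distance)
})

test_that("shuffle preserves chromosome and length, avoids exclusions, and is seeded", {
  genome <- toy_genome()
  a <- rand_intervals(200, genome, max_len = 10000)
  s1 <- shuffle_intervals(a, genome, seed = 99)
  s2 <- shuffle_intervals(a, genome, seed = 99)
  expect_identical(as_triple(s1), as_triple(s2))
  expect_identical(as.character(seqnames(s1)), as.character(seqnames(a)))
  expect_identical(width(s1), width(a))
  excl <- gr0("chr1", 0, 900000)
  s3 <- shuffle_intervals(a, genome, seed = 7, exclude = excl)
  expect_false(any(overlaps_any(s3, excl)))
  expect_error(
    shuffle_intervals(gr0("chr1", 0, 999999), genome, seed = 1,
                      exclude = gr0("chr1", 0, 999000), max_tries = 5),
    "could not place")
})

test_that("shuffled start positions are uniform along the chromosome", {
  genome <- genome_table(c(chr1 = 1e6))
  one <- gr0("chr1", 0, 100)
  many <- rep(one, 10000)
  s <- shuffle_intervals(many, genome, seed = 2024)
  starts <- start(s) - 1
  cnt <- table(cut(starts, breaks = seq(0, 1e6 - 100, length.out = 21),
                   include.lowest = TRUE))
  p <- suppressWarnings(chisq.test(as.vector(cnt))$p.value)
  expect_gt(p, 0.01)
})
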