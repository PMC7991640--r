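test_that("interval density equals the length-weighted bin mean", {
  genome <- toy_genome(1, 1000)
  tr <- flat_track(genome, 100, value = 3.7)
  d <- interval_density(tr, gr0("chr1", 123, 777))
  expect_equal(d$density, 3.7)
  # two bins of values 1 and 3 with equal overlap -> 2.0
  tr2 <- coverage_track(list(chr1 = c(1, 3, rep(0, 8))), 100, genome)
  expect_equal(interval_density(tr2, gr0("chr1", 50, 150))$density, 2.0)
  expect_error(interval_density(tr, gr0("chr1", 900, 1100)),
               "outside the declared genome")
})

test_that("interval density matches base-resolution means on bin-aligned intervals", {
  genome <- genome_table(c(chr1 = 10000))
  set.seed(21)
  v <- runif(1000, 0, 20)          # bin size 10
  tr <- coverage_track(list(chr1 = v), 10, genome)
  per_bp <- rep(v, each = 10)      # brute-force base expansion
  starts <- sample(seq(0, 9000, by = 10), 500, replace = TRUE)
  ends <- starts + sample(seq(10, 1000, by = 10), 500, replace = TRUE)
  ends <- pmin(ends, 10000)
  d <- interval_density(tr, gr0(rep("chr1", 500), starts, ends))$density
  want <- vapply(seq_len(500), function(i) {
    mean(per_bp[(starts[i] + 1):ends[i]])
  }, 0)
  expect_equal(d, want, tolerance = 1e-9)
})

test_that("interval density is invariant to bin refinement on aligned intervals", {
  genome <- genome_table(c(chr1 = 10000))
  set.seed(4)
  v100 <- runif(100, 0, 10)
  coarse <- coverage_track(list(chr1 = v100), 100, genome)
  fine <- coverage_track(list(chr1 = rep(v100, each = 2)), 50, genome)
  iv <- gr0(rep("chr1", 50), seq(0, 4900, by = 100), seq(400, 5300, by = 100))
  expect_equal(interval_density(coarse, iv)$density,
               interval_density(fine, iv)$density)
})

test_that("metagene profiles are flat on uniform tracks and body-restricted signal stays in the body", {
  genome <- toy_genome()
  gm <- toy_genes()
  tr <- flat_track(genome, 50, value = 2.5)
  pm <- metagene_profile(tr, gm, flank = 5000, flank_bin = 100,
                         body_bins = 100)
  expect_equal(ncol(pm$values), 200)
  expect_equal(unname(pm$mean), rep(2.5, 200))
  # signal confined to the body of geneA
  v <- lapply(names(genome), function(ch) numeric(1e6 / 50))
  names(v) <- names(genome)
  v$chr1[(100000 / 50 + 1):(120000 / 50)] <- 4
  tr2 <- coverage_track(v, 50, genome)
  one <- gm
  one$genes <- one$genes[1, ]
  pm2 <- metagene_profile(tr2, one)
  expect_equal(unname(pm2$mean[1:50]), rep(0, 50))    # upstream flank
  expect_equal(unname(pm2$mean[51:150]), rep(4, 100)) # body
  expect_equal(unname(pm2$mean[151:200]), rep(0, 50)) # downstream flank
})

test_that("a linear gradient across the body yields analytic bin means", {
  genome <- genome_table(c(chr1 = 40000))
  L <- 10000
  genes <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                      tss = 10000, tes = 10000 + L, fpkm = 1)
  gm <- gene_models(genes, data.frame(gene_id = "g", chrom = "chr1",
                                      start = 10000, end = 20000), genome)
  v <- numeric(40000 / 50)
  body_bins <- (10000 / 50 + 1):(20000 / 50)
  v[body_bins] <- (seq_along(body_bins) - 0.5) / length(body_bins)
  tr <- coverage_track(list(chr1 = v), 50, genome)
  pm <- metagene_profile(tr, gm, body_bins = 10)
  got <- unname(pm$mean[51:60])
  # each profile column spans 20 consecutive 50 bp track bins
  want <- vapply(0:9, function(j) mean(v[body_bins][(20 * j + 1):(20 * j + 20)]), 0)
  expect_equal(got, want, tolerance = 1e-6)
  expect_true(all(diff(got) > 0))
})

test_that("minus-strand genes are orientation-flipped", {
  genome <- toy_genome()
  gm <- toy_genes()
  set.seed(13)
  v <- lapply(names(genome), function(ch) runif(1e6 / 50, 0, 5))
  names(v) <- names(genome)
  tr <- coverage_track(v, 50, genome)
  pm <- metagene_profile(tr, gm)
  # flipping every strand and reversing the track mirrors the matrix
  gm_f <- gm
  gm_f$genes$strand <- ifelse(gm$genes$strand == "+", "-", "+")
  L <- 1e6
  gm_f$genes$tss <- L - gm$genes$tss
  gm_f$genes$tes <- L - gm$genes$tes
  gm_f$exons <- data.frame(gene_id = gm$exons$gene_id,
                           chrom = gm$exons$chrom,
                           start = L - gm$exons$end, end = L - gm$exons$start)
  gm_f <- gene_models(gm_f$genes, gm_f$exons, genome)
  tr_f <- coverage_track(lapply(v, rev), 50, genome)
  pm_f <- metagene_profile(tr_f, gm_f)
  expect_equal(pm_f$values[rownames(pm$values), ], pm$values,
               ignore_attr = TRUE)
})

test_that("aggregate of identical genes equals the single-gene profile and short genes drop", {
  genome <- toy_genome()
  gm <- toy_genes()
  tr <- flat_track(genome, 50, value = 1)
  one <- gm
  one$genes <- one$genes[1, ]
  pm1 <- metagene_profile(tr, one)
  pmN <- metagene_profile(tr, gm)
  expect_equal(unname(pm1$mean), unname(pmN$values["geneA", ]))
  short <- data.frame(gene_id = "tiny", chrom = "chr1", strand = "+",
                      tss = 500000, tes = 500050, fpkm = 1)
  gm2 <- gene_models(rbind(gm$genes, short),
                     rbind(gm$exons, data.frame(gene_id = "tiny",
                                                chrom = "chr1",
                                                start = 500000,
                                                end = 500050)), genome)
  pm2 <- metagene_profile(tr, gm2, body_bins = 100)
  expect_equal(pm2$dropped, "tiny")
})

test_that("group density summaries test locations and reject tiny groups", {
  genome <- toy_genome(1, 100000)
  set.seed(9)
  v <- rpois(1000, 5)
  tr <- coverage_track(list(chr1 = v), 100, genome)
  iv <- rand_intervals(60, genome, max_len = 3000, min_len = 500)
  res <- group_mean_density(tr, c(iv, iv),
                            groups = rep(c("a", "b"), each = 60))
  expect_equal(res$summary$mean[1], res$summary$mean[2])
  expect_gt(res$contrasts$p, 0.9)
  expect_error(group_mean_density(tr, iv, groups = c("solo",
                                                     rep("g", 59))),
               "at least 2")
})

test_that("group contrast holds its type-I error rate under label permutation", {
  genome <- toy_genome(1, 6000)
  set.seed(31)
  v <- rpois(60, 20) + runif(60)   # one interval per bin, null signal
  tr <- coverage_track(list(chr1 = v), 100, genome)
  iv <- gr0(rep("chr1", 60), seq(0, 5900, by = 100), seq(100, 6000, by = 100))
  reject <- logical(1000)
  for (i in 1:1000) {
    lab <- sample(rep(c("a", "b"), each = 30))
    res <- group_mean_density(tr, iv, groups = lab)
    reject[i] <- res$contrasts$p < 0.05
  }
  expect_lt(abs(mean(reject) - 0.05), 0.02)
})
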