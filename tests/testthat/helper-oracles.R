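# Shared fixtures and naive O(n^2) reference implementations the fast
# interval algebra is checked against. The oracles work on plain 0-based
# half-open triples (chrom, start, end) and never touch GenomicRanges.

library(GenomicRanges)

toy_genome <- function(n = 2, len = 1e6) {
  genome_table(stats::setNames(rep(len, n), paste0("chr", seq_len(n))))
}

gr0 <- function(chrom, start0, end, ...) {
  gr <- GRanges(chrom, IRanges(start0 + 1, end))
  m <- list(...)
  for (nm in names(m)) mcols(gr)[[nm]] <- m[[nm]]
  gr
}

as_triple <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1,
             end = end(gr), stringsAsFactors = FALSE)
}

# order-insensitive canonical form for set comparisons
canon <- function(x) {
  d <- if (is.data.frame(x)) x else as_triple(x)
  d <- d[order(d$chrom, d$start, d$end), , drop = FALSE]
  rownames(d) <- NULL
  d
}

rand_intervals <- function(n, genome, max_len = 5000, min_len = 50) {
  ch <- sample(names(genome), n, replace = TRUE)
  w <- sample(min_len:max_len, n, replace = TRUE)
  s <- floor(runif(n, 0, unclass(genome)[ch] - w))
  gr0(ch, s, s + w)
}

# pairwise overlap length in bp between two 0-based half-open intervals
.ov_bp <- function(c1, s1, e1, c2, s2, e2) {
  ifelse(c1 == c2, pmax(0, pmin(e1, e2) - pmax(s1, s2)), 0)
}

naive_overlaps_any <- function(a, b, min_bp = 1) {
  A <- as_triple(a); B <- as_triple(b)
  vapply(seq_len(nrow(A)), function(i) {
    any(.ov_bp(A$chrom[i], A$start[i], A$end[i],
               B$chrom, B$start, B$end) >= min_bp)
  }, logical(1))
}

naive_merge <- function(a, gap = 0) {
  d <- as_triple(a)
  repeat {
    changed <- FALSE
    i <- 1
    while (i < nrow(d) || (i == 1 && nrow(d) > 1)) {
      if (i >= nrow(d)) break
      hit <- FALSE
      for (j in (i + 1):nrow(d)) {
        if (d$chrom[i] == d$chrom[j] &&
            d$start[j] <= d$end[i] + gap && d$end[j] >= d$start[i] - gap) {
          d$start[i] <- min(d$start[i], d$start[j])
          d$end[i] <- max(d$end[i], d$end[j])
          d <- d[-j, , drop = FALSE]
          hit <- TRUE
          changed <- TRUE
          break
        }
      }
      if (!hit) i <- i + 1
    }
    if (!changed) break
  }
  d <- d[order(d$chrom, d$start), , drop = FALSE]
  rownames(d) <- NULL
  d
}

naive_subtract_base <- function(a, b) {
  A <- as_triple(a); B <- as_triple(b)
  out <- list()
  for (i in seq_len(nrow(A))) {
    keep <- rep(TRUE, A$end[i] - A$start[i])  # one flag per bp
    pos <- A$start[i]:(A$end[i] - 1)
    for (j in seq_len(nrow(B))) {
      if (B$chrom[j] == A$chrom[i]) {
        keep[pos >= B$start[j] & pos < B$end[j]] <- FALSE
      }
    }
    if (any(keep)) {
      r <- rle(keep)
      ends <- cumsum(r$lengths)
      starts <- c(0, ends[-length(ends)])
      for (k in which(r$values)) {
        out[[length(out) + 1]] <- data.frame(
          chrom = A$chrom[i], start = A$start[i] + starts[k],
          end = A$start[i] + ends[k])
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  }
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  d
}

naive_nearest_tss <- function(query, gm, max_dist) {
  Q <- as_triple(query)
  g <- gm$genes
  out <- data.frame(gene_id = rep(NA_character_, nrow(Q)),
                    distance = rep(NA_real_, nrow(Q)))
  for (i in seq_len(nrow(Q))) {
    mid <- floor((Q$start[i] + Q$end[i]) / 2)
    best_d <- Inf
    best_id <- NA_character_
    for (j in seq_len(nrow(g))) {
      if (g$chrom[j] != Q$chrom[i]) next
      d <- abs(g$tss[j] - mid)
      if (d < best_d || (d == best_d && g$gene_id[j] < best_id)) {
        best_d <- d
        best_id <- g$gene_id[j]
      }
    }
    if (best_d <= max_dist) {
      out$gene_id[i] <- best_id
      out$distance[i] <- best_d
    }
  }
  out
}

# Pearson r from the textbook sum formula, no cor() involved
pearson_formula <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# small gene set on a toy genome for promoter/assignment tests
toy_genes <- function(genome = toy_genome()) {
  genes <- data.frame(
    gene_id = c("geneA", "geneB", "geneC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tss = c(100000, 400000, 50000),
    tes = c(120000, 380000, 80000),
    fpkm = c(10, 0, 3))
  exons <- data.frame(
    gene_id = c("geneA", "geneA", "geneB", "geneB", "geneC"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(100000, 110000, 380000, 390000, 50000),
    end = c(105000, 115000, 385000, 395000, 60000))
  gene_models(genes, exons, genome)
}

flat_track <- function(genome, bin_size = 100, value = 0, units = "raw") {
  v <- lapply(names(genome), function(ch) {
    rep(value, ceiling(unclass(genome)[[ch]] / bin_size))
  })
  names(v) <- names(genome)
  coverage_track(v, bin_size, genome, units = units)
}

# a quick small simulated experiment shared by simdata/pipeline tests
small_config <- function(seed = 5, ...) {
  args <- list(seed = seed, chrom_length = 1e6, n_genes = 40,
               n_enhancers = 150)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}
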