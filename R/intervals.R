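#' Read a BED3/BED6 file into GRanges
#'
#' Tab-separated, no header, 3-6 columns (chrom, start, end, name, score,
#' strand), 0-based half-open. Input order is preserved. Malformed lines
#' raise an error naming the line number; if a genome table is supplied,
#' intervals on undeclared chromosomes or beyond chromosome ends are
#' rejected.
#'
#' @param path BED file path.
#' @param genome optional \code{genome_table} to validate against (also sets
#'   seqinfo on the result).
#' @return a \link[GenomicRanges]{GRanges}; name/score columns become mcols.
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) stop_chiprx("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges()
    if (!is.null(genome)) seqinfo(gr) <- genome_seqinfo(check_genome(genome))
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L | nf > 6L)
  if (length(bad)) {
    stop_chiprx(sprintf("BED parse error at line %d: expected 3-6 fields, got %d",
                        bad[1], nf[bad[1]]))
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
               end != floor(end))
  if (length(bad)) {
    stop_chiprx(sprintf("BED parse error at line %d: non-integer coordinates",
                        bad[1]))
  }
  bad <- which(start < 0 | start >= end)
  if (length(bad)) {
    stop_chiprx(sprintf(
      "BED validation error at line %d: need 0 <= start < end", bad[1]))
  }
  name <- vapply(fields, function(f) if (length(f) >= 4L) f[4L] else NA_character_, "")
  score <- suppressWarnings(as.numeric(
    vapply(fields, function(f) if (length(f) >= 5L) f[5L] else NA_character_, "")))
  strand <- vapply(fields, function(f) if (length(f) >= 6L) f[6L] else "*", "")
  strand[strand == "."] <- "*"
  bad <- which(!strand %in% c("+", "-", "*"))
  if (length(bad)) {
    stop_chiprx(sprintf("BED parse error at line %d: bad strand", bad[1]))
  }
  if (!is.null(genome)) {
    genome <- check_genome(genome)
    bad <- which(!chrom %in% names(genome))
    if (length(bad)) {
      stop_chiprx(sprintf(
        "BED validation error at line %d: unknown chromosome '%s'",
        bad[1], chrom[bad[1]]))
    }
    bad <- which(end > genome[chrom])
    if (length(bad)) {
      stop_chiprx(sprintf(
        "BED validation error at line %d: interval beyond end of %s",
        bad[1], chrom[bad[1]]))
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand,
    seqinfo = if (is.null(genome)) NULL else genome_seqinfo(genome))
  if (any(!is.na(name))) mcols(gr)$name <- name
  if (any(!is.na(score))) mcols(gr)$score <- score
  gr
}

#' @rdname read_bed
#' @param gr a GRanges to write (mcols name/score used when present).
#' @export
write_bed <- function(gr, path) {
  n <- length(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  name <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else rep(".", n)
  score <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else rep(0, n)
  has_extra <- !is.null(mcols(gr)$name) || !is.null(mcols(gr)$score) ||
    any(strand != ".")
  d <- data.frame(chrom = as.character(seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1L,
                  end = GenomicRanges::end(gr))
  if (has_extra) {
    d$name <- ifelse(is.na(name), ".", name)
    d$score <- ifelse(is.na(score), 0, score)
    d$strand <- strand
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# GRanges constructor from 0-based half-open coordinates.
granges0 <- function(chrom, start0, end, strand = "*", genome = NULL) {
  if (length(chrom) == 0L) {
    gr <- GenomicRanges::GRanges()
    if (!is.null(genome)) seqinfo(gr) <- genome_seqinfo(check_genome(genome))
    return(gr)
  }
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end),
    strand = strand,
    seqinfo = if (is.null(genome)) NULL else genome_seqinfo(check_genome(genome)))
}

#' Pairwise and set-level overlap predicates
#'
#' Intervals on different chromosomes never overlap; on the same chromosome
#' the intersection must span at least \code{min_bp} bases (half-open
#' convention: book-ended intervals share zero bases).
#'
#' @param a,b GRanges. For \code{interval_overlaps}, \code{a} and \code{b}
#'   are compared element-wise after recycling length-1 arguments; for
#'   \code{overlaps_any}, each element of \code{a} is tested against the
#'   whole of \code{b}.
#' @param min_bp minimum shared bases (default 1).
#' @return logical vector.
#' @export
overlaps_any <- function(a, b, min_bp = 1L) {
  min_bp <- check_count(min_bp, "min_bp")
  IRanges::overlapsAny(a, b, minoverlap = min_bp, ignore.strand = TRUE)
}

#' @rdname overlaps_any
#' @export
interval_overlaps <- function(a, b, min_bp = 1L) {
  min_bp <- check_count(min_bp, "min_bp")
  if (length(a) == 1L && length(b) > 1L) a <- rep(a, length(b))
  if (length(b) == 1L && length(a) > 1L) b <- rep(b, length(a))
  stopifnot(length(a) == length(b))
  same <- as.character(seqnames(a)) == as.character(seqnames(b))
  ov <- pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1
  same & ov >= min_bp
}

#' Subtract one interval set from another
#'
#' In \code{"whole"} mode (peak-level exclusion), members of \code{a} with at
#' least \code{min_bp} overlapping bases with any member of \code{b} are
#' dropped entirely. In \code{"base"} mode the overlapping bases are trimmed
#' out, possibly splitting intervals.
#'
#' @param a,b GRanges.
#' @param mode "whole" or "base".
#' @param min_bp minimum overlap to trigger exclusion (whole mode only).
#' @return GRanges.
#' @export
subtract_intervals <- function(a, b, mode = c("whole", "base"), min_bp = 1L) {
  mode <- match.arg(mode)
  if (length(b) == 0L) return(a)
  if (mode == "whole") {
    a[!overlaps_any(a, b, min_bp = min_bp)]
  } else {
    res <- GenomicRanges::subtract(a, b, ignore.strand = TRUE)
    unlist(res, use.names = FALSE)
  }
}

#' Merge intervals separated by at most a gap
#'
#' Overlapping or book-ended intervals (and intervals separated by
#' \code{<= gap} bases) are united; output is sorted and non-overlapping.
#' Used e.g. to pool peak calls from independent clones (union-merge).
#'
#' @param a GRanges.
#' @param gap maximum separation in bp to bridge (default 0: merge
#'   overlapping and book-ended intervals only).
#' @return GRanges, sorted, strand-ignored.
#' @export
merge_intervals <- function(a, gap = 0L) {
  gap <- check_count(gap, "gap", positive = FALSE)
  GenomicRanges::reduce(a, min.gapwidth = gap + 1, ignore.strand = TRUE)
}

#' Nearest TSS assignment
#'
#' For each query interval, finds the gene whose TSS is closest to the query
#' midpoint (same chromosome), up to \code{max_dist} bp away. Distance is
#' \code{|TSS - midpoint|}; ties are broken by lexicographically smaller
#' gene_id. Queries with no TSS within range get NA.
#'
#' @param query GRanges.
#' @param gm a \code{gene_models} object.
#' @param max_dist maximum distance in bp (default 500 kb, the standard
#'   enhancer-to-promoter assignment window).
#' @return data.frame with columns gene_id, distance (bp), one row per query.
#' @export
nearest_tss <- function(query, gm, max_dist = 500000) {
  if (nrow(gm$genes) == 0L) stop_chiprx("no genes to assign to")
  mid <- floor((start(query) - 1 + end(query)) / 2)  # 0-based midpoint
  qchrom <- as.character(seqnames(query))
  out <- data.frame(gene_id = rep(NA_character_, length(query)),
                    distance = rep(NA_real_, length(query)),
                    stringsAsFactors = FALSE)
  g <- gm$genes
  for (ch in unique(qchrom)) {
    gi <- which(g$chrom == ch)
    qi <- which(qchrom == ch)
    if (!length(gi) || !length(qi)) next
    o <- order(g$tss[gi], g$gene_id[gi])
    tss <- g$tss[gi][o]; ids <- g$gene_id[gi][o]
    for (j in qi) {
      d <- abs(tss - mid[j])
      dm <- min(d)
      if (dm <= max_dist) {
        cand <- which(d == dm)
        best <- cand[order(ids[cand])][1]
        out$gene_id[j] <- ids[best]
        out$distance[j] <- dm
      }
    }
  }
  out
}

#' Shuffle intervals to build a matched null
#'
#' Produces one shuffled interval per input with the same chromosome and the
#' same length, uniformly placed along that chromosome, optionally avoiding a
#' set of excluded intervals. Deterministic given \code{seed}; the caller's
#' RNG state is untouched.
#'
#' @param a GRanges to shuffle.
#' @param genome a \code{genome_table}.
#' @param seed integer seed (NULL: use current RNG state).
#' @param exclude optional GRanges the shuffled intervals must not overlap.
#' @param max_tries placement attempts per interval before failing.
#' @return GRanges of the same length, chromosome- and width-matched.
#' @export
shuffle_intervals <- function(a, genome, seed = NULL, exclude = NULL,
                              max_tries = 1000L) {
  genome <- check_genome(genome)
  if (length(a) == 0L) return(granges0(character(), numeric(), numeric(),
                                       genome = genome))
  chrom <- as.character(seqnames(a))
  if (!all(chrom %in% names(genome))) {
    stop_chiprx("interval chromosome not in genome table")
  }
  w <- width(a)
  if (any(w > genome[chrom])) {
    stop_chiprx("interval longer than its chromosome")
  }
  # per-chromosome exclusion lists in 0-based half-open coordinates
  excl <- NULL
  if (!is.null(exclude) && length(exclude) > 0L) {
    ec <- as.character(seqnames(exclude))
    excl <- split(data.frame(s = start(exclude) - 1, e = end(exclude)), ec)
  }
  with_seed(seed, {
    new_start0 <- numeric(length(a))
    for (i in seq_along(a)) {
      L <- genome[chrom[i]]
      bl <- excl[[chrom[i]]]
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        s0 <- floor(stats::runif(1, min = 0, max = L - w[i] + 1))
        if (s0 > L - w[i]) s0 <- L - w[i]  # guard the open upper edge
        placed <- is.null(bl) || !any(s0 < bl$e & s0 + w[i] > bl$s)
        if (placed) { new_start0[i] <- s0; break }
      }
      if (!placed) {
        stop_chiprx(sprintf(
          "could not place shuffled interval %d (%s:%d-%d) after %d tries",
          i, chrom[i], start(a)[i] - 1L, end(a)[i], max_tries))
      }
    }
    granges0(chrom, new_start0, new_start0 + w, genome = genome)
  })
}
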