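# Length-weighted mean of track bins over [s0, e) (0-based, possibly
# fractional bp) on one chromosome, via cumulative sums.
.density_1 <- function(csum, v, b, s0, e) {
  if (e <= s0) return(NA_real_)
  i0 <- floor(s0 / b)
  i1 <- ceiling(e / b) - 1
  tot <- b * (csum[i1 + 2] - csum[i0 + 1]) -
    v[i0 + 1] * (s0 - i0 * b) -
    v[i1 + 1] * ((i1 + 1) * b - e)
  tot / (e - s0)
}

#' Mean normalized read density over intervals
#'
#' The length-weighted mean of the coverage bins intersecting each interval
#' (partial bins weighted by their overlap in bp), i.e. the per-bp mean
#' signal of the interval in the track's units.
#'
#' @param track a \code{coverage_track}.
#' @param intervals GRanges within the track's genome.
#' @return data.frame with columns chrom, start, end (0-based half-open) and
#'   density, one row per interval, in input order.
#' @export
interval_density <- function(track, intervals) {
  stopifnot(inherits(track, "coverage_track"))
  chrom <- as.character(seqnames(intervals))
  if (!all(chrom %in% names(track$genome))) {
    stop_chiprx("interval chromosome not in the track's genome")
  }
  s0 <- start(intervals) - 1
  e <- end(intervals)
  if (any(s0 < 0) || any(e > track$genome[chrom])) {
    stop_chiprx("interval outside the declared genome")
  }
  b <- track$bin_size
  dens <- numeric(length(intervals))
  for (ch in unique(chrom)) {
    v <- track$values[[ch]]
    csum <- c(0, cumsum(v))
    idx <- which(chrom == ch)
    for (j in idx) dens[j] <- .density_1(csum, v, b, s0[j], e[j])
  }
  data.frame(chrom = chrom, start = s0, end = e, density = dens,
             stringsAsFactors = FALSE)
}

#' Scaled metagene profile
#'
#' Averages track signal over genes rescaled to a common body length:
#' \code{flank} bp upstream of the TSS in fixed \code{flank_bin}-bp bins, the
#' gene body in \code{body_bins} equal fractions, and \code{flank} bp
#' downstream of the TES. Minus-strand genes are orientation-flipped so
#' column 1 is always biological upstream. Genes with body shorter than
#' \code{body_bins} bp are dropped and reported in \code{$dropped}; flank
#' bins beyond chromosome ends are NA and excluded from the aggregate.
#'
#' @param track a \code{coverage_track}.
#' @param gm a \code{gene_models} object (or subset).
#' @param flank flank length in bp (default 5000).
#' @param flank_bin flank bin width in bp (default 100).
#' @param body_bins number of scaled body bins (default 100).
#' @return object of class \code{profile_matrix}: list with \code{values}
#'   (gene x bin matrix), bin bookkeeping, \code{dropped} gene ids, and
#'   \code{mean} (aggregate profile over genes).
#' @export
metagene_profile <- function(track, gm, flank = 5000, flank_bin = 100,
                             body_bins = 100) {
  stopifnot(inherits(track, "coverage_track"))
  g <- gm$genes
  if (nrow(g) == 0L) stop_chiprx("empty gene list")
  lo <- pmin(g$tss, g$tes); hi <- pmax(g$tss, g$tes)
  keep <- (hi - lo) >= body_bins
  dropped <- g$gene_id[!keep]
  g <- g[keep, , drop = FALSE]; lo <- lo[keep]; hi <- hi[keep]
  if (nrow(g) == 0L) stop_chiprx("all genes shorter than body_bins bp")
  nf <- flank %/% flank_bin
  ncol_total <- 2L * nf + body_bins
  mat <- matrix(NA_real_, nrow(g), ncol_total)
  b <- track$bin_size
  csums <- lapply(track$values, function(v) c(0, cumsum(v)))
  for (i in seq_len(nrow(g))) {
    ch <- g$chrom[i]
    v <- track$values[[ch]]
    csum <- csums[[ch]]
    L <- track$genome[[ch]]
    # genomic-order column boundaries: left flank, body fractions, right flank
    left <- lo[i] - flank + flank_bin * (0:nf)
    body <- lo[i] + (hi[i] - lo[i]) * (0:body_bins) / body_bins
    right <- hi[i] + flank_bin * (0:nf)
    bounds <- c(left[-length(left)], body, right[-1])
    row <- numeric(ncol_total)
    for (k in seq_len(ncol_total)) {
      s0 <- max(0, bounds[k]); e <- min(L, bounds[k + 1])
      row[k] <- if (e <= s0) NA_real_ else .density_1(csum, v, b, s0, e)
    }
    if (g$strand[i] == "-") row <- rev(row)
    mat[i, ] <- row
  }
  rownames(mat) <- g$gene_id
  structure(list(values = mat, upstream_bins = nf, body_bins = body_bins,
                 downstream_bins = nf, flank = flank, flank_bin = flank_bin,
                 units = track$units, dropped = dropped,
                 mean = colMeans(mat, na.rm = TRUE)),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf(
    "profile_matrix: %d genes x %d bins (%d flank + %d body + %d flank), units %s\n",
    nrow(x$values), ncol(x$values), x$upstream_bins, x$body_bins,
    x$downstream_bins, x$units))
  if (length(x$dropped)) {
    cat(sprintf("  %d gene(s) dropped (body < body_bins bp)\n",
                length(x$dropped)))
  }
  invisible(x)
}

#' @export
#' @method plot profile_matrix
#' @rdname metagene_profile
#' @param x a \code{profile_matrix}.
#' @param ... further arguments passed to \code{\link[graphics]{plot}}.
plot.profile_matrix <- function(x, ...) {
  nf <- x$upstream_bins
  nb <- x$body_bins
  graphics::plot(seq_along(x$mean), x$mean, type = "l",
                 xlab = "", ylab = paste("mean signal (", x$units, ")"),
                 xaxt = "n", ...)
  graphics::axis(1, at = c(1, nf + 0.5, nf + nb + 0.5, 2 * nf + nb),
                 labels = c(sprintf("-%d kb", x$flank / 1000), "TSS", "TES",
                            sprintf("+%d kb", x$flank / 1000)))
  graphics::abline(v = c(nf + 0.5, nf + nb + 0.5), lty = 3, col = "grey40")
  invisible(x)
}

#' Write a profile matrix as headered TSV
#' @param pm a \code{profile_matrix}.
#' @param path file path.
#' @export
write_profile_matrix <- function(pm, path) {
  d <- as.data.frame(pm$values)
  names(d) <- paste0("bin", seq_len(ncol(d)))
  d <- cbind(gene_id = rownames(pm$values), d)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-group density summaries with rank-based location tests
#'
#' Computes interval densities per group of intervals, then per-group
#' mean/median and a two-sided Mann-Whitney (Wilcoxon rank-sum) test for
#' every pairwise contrast, Benjamini-Hochberg corrected across contrasts.
#'
#' @param track a \code{coverage_track} (or a list of tracks, one per group,
#'   to compare e.g. the same loci across samples).
#' @param intervals GRanges (or a list of GRanges, one per group).
#' @param groups group label per interval (ignored when lists are given:
#'   list names label the groups).
#' @return list with \code{summary} (group, n, mean, median) and
#'   \code{contrasts} (group1, group2, p, p_adj).
#' @export
group_mean_density <- function(track, intervals, groups = NULL) {
  if (is.list(intervals) && !is(intervals, "GRanges")) {
    if (is.null(names(intervals))) {
      names(intervals) <- paste0("group", seq_along(intervals))
    }
    tracks <- if (inherits(track, "coverage_track")) {
      rep(list(track), length(intervals))
    } else track
    dens <- mapply(function(tr, iv) interval_density(tr, iv)$density,
                   tracks, intervals, SIMPLIFY = FALSE)
    groups <- rep(names(intervals), lengths(dens))
    dens <- unlist(dens, use.names = FALSE)
  } else {
    if (is.null(groups) || length(groups) != length(intervals)) {
      stop_chiprx("groups must label every interval")
    }
    dens <- interval_density(track, intervals)$density
    groups <- as.character(groups)
  }
  tab <- table(groups)
  if (any(tab < 2)) {
    stop_chiprx("each group needs at least 2 intervals: ",
                paste(names(tab)[tab < 2], collapse = ", "))
  }
  lv <- names(tab)
  summary <- data.frame(
    group = lv,
    n = as.integer(tab[lv]),
    mean = vapply(lv, function(g) mean(dens[groups == g]), 0),
    median = vapply(lv, function(g) stats::median(dens[groups == g]), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  contrasts <- NULL
  if (length(lv) >= 2) {
    pairs <- utils::combn(lv, 2)
    p <- apply(pairs, 2, function(pr) {
      stats::wilcox.test(dens[groups == pr[1]], dens[groups == pr[2]],
                         exact = FALSE)$p.value
    })
    contrasts <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                            p = p, p_adj = stats::p.adjust(p, "BH"),
                            stringsAsFactors = FALSE)
  }
  list(summary = summary, contrasts = contrasts)
}
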