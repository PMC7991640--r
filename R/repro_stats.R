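#' Decompose two peak sets into common and unique classes
#'
#' A peak is \emph{common} if it overlaps (>= 1 bp) any peak of the other
#' set, else \emph{unique}; counts are reported from each set's perspective
#' (Venn semantics: with many-to-one overlaps the two common counts can
#' differ, so both are kept).
#'
#' @param peaks_a,peaks_b GRanges (merged/validated peak sets).
#' @return list of class \code{peak_decomposition}: GRanges
#'   \code{common_a}, \code{unique_a}, \code{common_b}, \code{unique_b} and
#'   a \code{venn} list (a_only, b_only, common_a_perspective,
#'   common_b_perspective).
#' @export
decompose_peaks <- function(peaks_a, peaks_b) {
  in_b <- overlaps_any(peaks_a, peaks_b)
  in_a <- overlaps_any(peaks_b, peaks_a)
  out <- list(common_a = peaks_a[in_b], unique_a = peaks_a[!in_b],
              common_b = peaks_b[in_a], unique_b = peaks_b[!in_a],
              venn = list(a_only = sum(!in_b), b_only = sum(!in_a),
                          common_a_perspective = sum(in_b),
                          common_b_perspective = sum(in_a)))
  class(out) <- "peak_decomposition"
  out
}

#' @export
print.peak_decomposition <- function(x, ...) {
  v <- x$venn
  cat(sprintf(
    "peak_decomposition: %d a-only, %d b-only; common %d (a) / %d (b)\n",
    v$a_only, v$b_only, v$common_a_perspective, v$common_b_perspective))
  invisible(x)
}

#' Annotate peaks to genomic elements
#'
#' Assigns each peak to exactly one of promoter, exon, intron or intergenic
#' by its midpoint, with precedence promoter > exon > intron > intergenic,
#' and reports the fraction of peaks per element (fractions sum to 1).
#'
#' @param peaks GRanges.
#' @param gm a \code{gene_models} object.
#' @param promoters GRanges (default: \code{define_promoters(gm)}).
#' @return data.frame with element, n, fraction; peak-level assignment in
#'   \code{attr(, "element")}.
#' @export
annotate_elements <- function(peaks, gm, promoters = define_promoters(gm)) {
  mid0 <- floor((start(peaks) - 1 + end(peaks)) / 2)
  midgr <- granges0(as.character(seqnames(peaks)), mid0, mid0 + 1)
  in_prom <- overlaps_any(midgr, promoters)
  exons <- granges0(gm$exons$chrom, gm$exons$start, gm$exons$end)
  in_exon <- overlaps_any(midgr, exons)
  gb <- gene_bodies(gm)
  bodies <- granges0(gb$chrom, gb$start, gb$end)
  in_gene <- overlaps_any(midgr, bodies)
  element <- ifelse(in_prom, "promoter",
             ifelse(in_exon, "exon",
             ifelse(in_gene, "intron", "intergenic")))
  lv <- c("promoter", "exon", "intron", "intergenic")
  n <- as.integer(table(factor(element, levels = lv)))
  out <- data.frame(element = lv, n = n,
                    fraction = if (length(peaks)) n / length(peaks) else
                      rep(NA_real_, 4),
                    stringsAsFactors = FALSE)
  attr(out, "element") <- element
  out
}

#' Stratify genes into expression tiers
#'
#' Splits expressed genes into \code{n_strata} rank-based tiers of FPKM
#' ("low" < ... < "high" for the default 3), sizes differing by at most 1.
#' Ties are broken by gene_id so the split is deterministic; zero-FPKM genes
#' are assigned to the lowest stratum.
#'
#' @param fpkm named numeric vector gene_id -> FPKM.
#' @param n_strata number of tiers (default 3).
#' @return named character vector gene_id -> stratum
#'   ("low"/"medium"/"high" for 3 strata, "s1".."sk" otherwise).
#' @export
stratify_expression <- function(fpkm, n_strata = 3L) {
  n_strata <- check_count(n_strata, "n_strata")
  if (length(fpkm) < n_strata) {
    stop_chiprx("fewer genes than strata")
  }
  labels <- if (n_strata == 3L) c("low", "medium", "high") else
    paste0("s", seq_len(n_strata))
  o <- order(fpkm, names(fpkm))  # ascending FPKM, gene_id tie-break
  k <- length(fpkm)
  sizes <- rep(k %/% n_strata, n_strata)
  extra <- k %% n_strata
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stratum <- rep(labels, times = sizes)
  res <- stats::setNames(stratum[order(o)], names(fpkm))
  res[fpkm == 0] <- labels[1]
  res
}

#' Pearson correlation of mark changes
#'
#' Standard Pearson product-moment correlation between two fields of a
#' per-interval change table (e.g. delta H3K27ac vs mutant-histone
#' occupancy). Fails on fewer than 3 records or zero variance (undefined r).
#'
#' @param records data.frame of per-interval records.
#' @param x_field,y_field column names to correlate.
#' @return list with \code{r} and \code{n}.
#' @export
delta_correlation <- function(records, x_field, y_field) {
  x <- records[[x_field]]; y <- records[[y_field]]
  if (is.null(x) || is.null(y)) stop_chiprx("field not found in records")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop_chiprx("need at least 3 finite records")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_chiprx("zero variance: correlation undefined")
  }
  list(r = stats::cor(x, y, method = "pearson"), n = length(x))
}

#' Build a per-enhancer change table
#'
#' For a set of intervals, computes density in two tracks of one mark (delta
#' = B - A) and the mutant-histone occupancy density at the same intervals.
#'
#' @param intervals GRanges.
#' @param track_a,track_b the mark's tracks in condition A (e.g. wild type)
#'   and B (mutant), same units.
#' @param occupancy_track mutant-histone (e.g. H3K36M) coverage track.
#' @return data.frame with chrom/start/end, density_a, density_b, delta,
#'   occupancy.
#' @export
delta_records <- function(intervals, track_a, track_b, occupancy_track) {
  if (track_a$units != track_b$units) {
    stop_chiprx("delta requires both tracks in the same units")
  }
  da <- interval_density(track_a, intervals)
  db <- interval_density(track_b, intervals)$density
  occ <- interval_density(occupancy_track, intervals)$density
  data.frame(chrom = da$chrom, start = da$start, end = da$end,
             density_a = da$density, density_b = db, delta = db - da$density,
             occupancy = occ, stringsAsFactors = FALSE)
}

#' Associate enhancer inactivation with differential expression
#'
#' Links enhancer transitions to their assigned genes and a
#' differential-expression status table: (i) per DE class, the fraction of
#' genes with at least one assigned inactivated enhancer; (ii) genes binned
#' by their count of assigned inactivated enhancers (0/1/2/>=3 by default)
#' with log2 fold-change summaries per bin,
#' \code{log2((fpkm_mut + 1)/(fpkm_wt + 1))}.
#'
#' @param transitions an \code{enhancer_transitions} table.
#' @param assigned_enhancers the wild-type enhancer GRanges after
#'   \code{\link{assign_enhancers}} (coordinates must cover the transition
#'   rows' wild-type active enhancers).
#' @param de named character vector gene_id -> up/down/unchanged.
#' @param fpkm_wt,fpkm_mut named FPKM vectors (optional: fold-change bins
#'   reported only when both given).
#' @param bins upper edges of the inactivated-enhancer count bins.
#' @return list with \code{de_fractions} (status, n_genes, n_with_inactivated,
#'   fraction) and \code{fc_bins} (bin, n_genes, median_lfc, mean_lfc) or
#'   NULL.
#' @export
inactivation_gene_association <- function(transitions, assigned_enhancers,
                                          de, fpkm_wt = NULL, fpkm_mut = NULL,
                                          bins = c(0, 1, 2, Inf)) {
  key <- function(ch, s, e) paste(ch, s, e, sep = ":")
  tk <- key(transitions$chrom, transitions$start, transitions$end)
  ek <- key(as.character(seqnames(assigned_enhancers)),
            start(assigned_enhancers) - 1L, end(assigned_enhancers))
  idx <- match(tk, ek)
  if (anyNA(idx)) {
    stop_chiprx("transitions contain enhancers absent from the assigned set")
  }
  gene <- mcols(assigned_enhancers)$assigned_gene[idx]
  inact_genes <- gene[transitions$inactivated & !is.na(gene)]
  n_inact <- table(inact_genes)
  count_for <- function(gid) {
    m <- n_inact[gid]
    ifelse(is.na(m), 0L, as.integer(m))
  }
  de_fractions <- do.call(rbind, lapply(c("up", "down", "unchanged"),
    function(st) {
      gids <- names(de)[de == st]
      nwith <- sum(count_for(gids) >= 1)
      data.frame(status = st, n_genes = length(gids),
                 n_with_inactivated = nwith,
                 fraction = if (length(gids)) nwith / length(gids) else
                   NA_real_,
                 stringsAsFactors = FALSE)
    }))
  fc_bins <- NULL
  if (!is.null(fpkm_wt) && !is.null(fpkm_mut)) {
    gids <- intersect(names(fpkm_wt), names(fpkm_mut))
    m <- count_for(gids)
    lfc <- log2((fpkm_mut[gids] + 1) / (fpkm_wt[gids] + 1))
    lab <- vapply(seq_along(bins), function(i) {
      lo <- if (i == 1) 0 else bins[i - 1] + 1
      hi <- bins[i]
      if (is.infinite(hi)) paste0(">=", lo) else
        if (lo == hi) as.character(lo) else paste0(lo, "-", hi)
    }, "")
    bin_id <- cut(m, breaks = c(-1, bins), labels = lab)
    fc_bins <- do.call(rbind, lapply(levels(bin_id), function(b) {
      v <- lfc[bin_id == b]
      data.frame(bin = b, n_genes = length(v),
                 median_lfc = if (length(v)) stats::median(v) else NA_real_,
                 mean_lfc = if (length(v)) mean(v) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  list(de_fractions = de_fractions, fc_bins = fc_bins)
}

#' Expression of genes by enhancer state class
#'
#' For each enhancer state, the FPKM distribution of the genes assigned to
#' enhancers of that state, with pairwise two-sided Mann-Whitney tests
#' between states, Benjamini-Hochberg corrected. States with no assigned
#' genes are reported with n = 0 and skipped in the contrasts.
#'
#' @param enhancers classified and assigned GRanges.
#' @param fpkm named numeric vector gene_id -> FPKM.
#' @return list with \code{summary} (state, n_genes, mean_fpkm, median_fpkm),
#'   \code{contrasts} (state1, state2, p, p_adj) and \code{fpkm_by_state}
#'   (named list of FPKM vectors).
#' @export
class_expression_summary <- function(enhancers, fpkm) {
  m <- mcols(enhancers)
  if (is.null(m$state) || is.null(m$assigned_gene)) {
    stop_chiprx("enhancers must be classified and assigned")
  }
  states <- c("active", "primed", "poised")
  by_state <- lapply(states, function(st) {
    g <- unique(m$assigned_gene[m$state == st & !is.na(m$assigned_gene)])
    fpkm[g[g %in% names(fpkm)]]
  })
  names(by_state) <- states
  summary <- data.frame(
    state = states,
    n_genes = lengths(by_state),
    mean_fpkm = vapply(by_state, function(v) if (length(v)) mean(v) else
      NA_real_, 0),
    median_fpkm = vapply(by_state, function(v) if (length(v))
      stats::median(v) else NA_real_, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  nonempty <- states[lengths(by_state) >= 2]
  contrasts <- NULL
  if (length(nonempty) >= 2) {
    pairs <- utils::combn(nonempty, 2)
    p <- apply(pairs, 2, function(pr) {
      stats::wilcox.test(by_state[[pr[1]]], by_state[[pr[2]]],
                         exact = FALSE)$p.value
    })
    contrasts <- data.frame(state1 = pairs[1, ], state2 = pairs[2, ],
                            p = p, p_adj = stats::p.adjust(p, "BH"),
                            stringsAsFactors = FALSE)
  }
  list(summary = summary, contrasts = contrasts, fpkm_by_state = by_state)
}
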