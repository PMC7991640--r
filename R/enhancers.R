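#' Define promoters from gene TSSs
#'
#' A promoter is the strand-aware window from 2 kb upstream to 500 bp
#' downstream of the TSS (the standard RefSeq-based definition): on the plus
#' strand \code{[TSS-2000, TSS+500)}, mirrored on the minus strand, clipped
#' at chromosome ends.
#'
#' @param gm a \code{gene_models} object.
#' @param genome a \code{genome_table} (defaults to the one in \code{gm}).
#' @param upstream,downstream window sizes in bp.
#' @return GRanges with one promoter per gene (mcols \code{name} = gene_id).
#' @export
define_promoters <- function(gm, genome = gm$genome, upstream = 2000,
                             downstream = 500) {
  genome <- check_genome(genome)
  g <- gm$genes
  plus <- g$strand == "+"
  s0 <- ifelse(plus, g$tss - upstream, g$tss - downstream)
  e <- ifelse(plus, g$tss + downstream, g$tss + upstream)
  s0 <- pmax(0, s0)
  e <- pmin(as.numeric(genome[g$chrom]), e)
  gr <- granges0(g$chrom, s0, e, strand = g$strand, genome = genome)
  mcols(gr)$name <- g$gene_id
  gr
}

#' Call enhancers from H3K4me1 peaks
#'
#' Enhancers are genomic loci carrying an H3K4me1 peak that does not overlap
#' (by >= 1 bp, whole-peak exclusion) any H3K4me3 peak or any annotated
#' promoter. Surviving H3K4me1 peaks become enhancers with state unset.
#'
#' @param h3k4me1_peaks,h3k4me3_peaks GRanges peak sets.
#' @param promoters GRanges from \code{\link{define_promoters}}.
#' @return GRanges of enhancers with mcols \code{state} = NA.
#' @export
call_enhancers <- function(h3k4me1_peaks, h3k4me3_peaks, promoters) {
  enh <- subtract_intervals(h3k4me1_peaks, h3k4me3_peaks, mode = "whole")
  enh <- subtract_intervals(enh, promoters, mode = "whole")
  mcols(enh)$state <- NA_character_
  enh
}

#' Classify enhancers as active, primed or poised
#'
#' An enhancer overlapping an H3K27ac peak is \strong{active}; otherwise one
#' overlapping an H3K27me3 peak is \strong{poised}; an enhancer lacking both
#' marks is \strong{primed}. Enhancers carrying both marks are classed
#' active (precedence active > poised) and their fraction is reported in
#' \code{attr(, "ambiguous_fraction")} so the precedence rule's impact is
#' visible.
#'
#' @param enhancers GRanges from \code{\link{call_enhancers}}.
#' @param h3k27ac_peaks,h3k27me3_peaks GRanges peak sets.
#' @return the enhancers with mcols \code{state} set; attributes
#'   \code{ambiguous_fraction} and \code{convention} ("poised=H3K27me3+").
#' @export
classify_enhancers <- function(enhancers, h3k27ac_peaks, h3k27me3_peaks) {
  ac <- overlaps_any(enhancers, h3k27ac_peaks)
  me3 <- overlaps_any(enhancers, h3k27me3_peaks)
  state <- ifelse(ac, "active", ifelse(me3, "poised", "primed"))
  mcols(enhancers)$state <- state
  attr(enhancers, "ambiguous_fraction") <-
    if (length(enhancers)) mean(ac & me3) else 0
  attr(enhancers, "convention") <- "active=H3K27ac+; poised=H3K27me3+; primed=neither"
  enhancers
}

#' Per-state enhancer counts and fractions
#' @param enhancers classified GRanges.
#' @return data.frame with state, n, fraction (fractions sum to 1).
#' @export
state_fractions <- function(enhancers) {
  st <- factor(mcols(enhancers)$state,
               levels = c("active", "primed", "poised"))
  if (anyNA(st)) stop_chiprx("enhancers must be classified first")
  n <- as.integer(table(st))
  data.frame(state = levels(st), n = n, fraction = n / length(enhancers),
             stringsAsFactors = FALSE)
}

#' Map wild-type active enhancers onto their mutant state
#'
#' Each wild-type \emph{active} enhancer is matched (>= 1 bp overlap) to the
#' mutant enhancer set; its mutant state is the overlapped enhancer's state,
#' or \code{"lost"} if no mutant enhancer overlaps. An enhancer is
#' \emph{inactivated} when its mutant state is anything but active (lost
#' counts as inactivated). When several mutant enhancers overlap, active
#' wins, then poised, then primed (an enhancer that retains any active
#' overlap is not inactivated).
#'
#' @param wt,mut classified enhancer GRanges.
#' @return object of class \code{enhancer_transitions}: data.frame with the
#'   wild-type active enhancers' coordinates, mutant_state and inactivated.
#' @export
enhancer_transitions <- function(wt, mut) {
  if (anyNA(mcols(wt)$state) || anyNA(mcols(mut)$state)) {
    stop_chiprx("both enhancer sets must be classified")
  }
  act <- wt[mcols(wt)$state == "active"]
  hits <- GenomicRanges::findOverlaps(act, mut, ignore.strand = TRUE)
  mstate <- rep("lost", length(act))
  if (length(hits)) {
    pr <- c(active = 1L, poised = 2L, primed = 3L)
    hs <- mcols(mut)$state[subjectHits(hits)]
    for (q in unique(queryHits(hits))) {
      st <- hs[queryHits(hits) == q]
      mstate[q] <- names(pr)[min(pr[st])]
    }
  }
  out <- data.frame(chrom = as.character(seqnames(act)),
                    start = start(act) - 1L, end = end(act),
                    mutant_state = mstate,
                    inactivated = mstate != "active",
                    stringsAsFactors = FALSE)
  class(out) <- c("enhancer_transitions", "data.frame")
  out
}

#' Inactivation arithmetic on transition counts
#'
#' The reporting arithmetic behind transition summaries: the percentage of
#' wild-type active enhancers that are no longer active in the mutant,
#' \code{100 * n_inactivated / n_active}, printed to one decimal.
#'
#' @param n_inactivated count of inactivated enhancers.
#' @param n_active count of wild-type active enhancers.
#' @return percentage (numeric).
#' @export
inactivated_percent <- function(n_inactivated, n_active) {
  n_inactivated <- check_count(n_inactivated, "n_inactivated", positive = FALSE)
  n_active <- check_count(n_active, "n_active")
  100 * n_inactivated / n_active
}

#' @export
#' @method summary enhancer_transitions
#' @rdname enhancer_transitions
#' @param object an \code{enhancer_transitions} table.
#' @param ... unused.
summary.enhancer_transitions <- function(object, ...) {
  n_active <- nrow(object)
  n_inact <- sum(object$inactivated)
  list(n_active = n_active, n_inactivated = n_inact,
       inactivated_percent = inactivated_percent(n_inact, n_active),
       by_state = table(object$mutant_state))
}

#' @export
print.enhancer_transitions <- function(x, ...) {
  s <- summary(x)
  cat(sprintf(
    "enhancer_transitions: %d of %d WT-active enhancers inactivated (%.1f%%)\n",
    s$n_inactivated, s$n_active, s$inactivated_percent))
  invisible(x)
}

#' Assign enhancers to the closest promoter
#'
#' Delegates to \code{\link{nearest_tss}}: each enhancer is assigned to the
#' gene whose TSS is nearest to the enhancer midpoint, within
#' \code{max_dist} (default 500 kb); unassigned enhancers carry NA.
#'
#' @param enhancers GRanges.
#' @param gm a \code{gene_models} object.
#' @param max_dist assignment window in bp.
#' @return the enhancers with mcols \code{assigned_gene} and
#'   \code{tss_distance}.
#' @export
assign_enhancers <- function(enhancers, gm, max_dist = 500000) {
  nn <- nearest_tss(enhancers, gm, max_dist = max_dist)
  mcols(enhancers)$assigned_gene <- nn$gene_id
  mcols(enhancers)$tss_distance <- nn$distance
  enhancers
}

#' Enhancer summary statistics by condition and class
#'
#' Per condition (and optionally per common/unique class within condition):
#' count, length mean/median, and distance-to-TSS mean/median for assigned
#' enhancers.
#'
#' @param enhancer_sets named list of GRanges (assigned; mcols may carry
#'   \code{class} with values like "common"/"unique").
#' @return data.frame, one row per condition (x class).
#' @export
enhancer_stats <- function(enhancer_sets) {
  if (!length(enhancer_sets) || any(lengths(enhancer_sets) == 0)) {
    stop_chiprx("each condition needs at least one enhancer")
  }
  rows <- list()
  for (cond in names(enhancer_sets)) {
    e <- enhancer_sets[[cond]]
    cls <- if (!is.null(mcols(e)$class)) mcols(e)$class else rep("all", length(e))
    for (cl in unique(cls)) {
      ei <- e[cls == cl]
      w <- width(ei)
      d <- mcols(ei)$tss_distance
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, class = cl, n = length(ei),
        length_mean = mean(w), length_median = stats::median(w),
        dist_mean = if (is.null(d)) NA_real_ else mean(d, na.rm = TRUE),
        dist_median = if (is.null(d)) NA_real_ else
          stats::median(d, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write enhancers as BED6+ with state, gene and distance columns
#' @param enhancers classified/assigned GRanges.
#' @param path file path.
#' @export
write_enhancers <- function(enhancers, path) {
  m <- mcols(enhancers)
  d <- data.frame(chrom = as.character(seqnames(enhancers)),
                  start = start(enhancers) - 1L, end = end(enhancers),
                  name = if (!is.null(m$name)) m$name else
                    paste0("enh", seq_along(enhancers)),
                  score = 0, strand = ".",
                  state = if (!is.null(m$state)) m$state else NA,
                  assigned_gene = if (!is.null(m$assigned_gene))
                    m$assigned_gene else NA,
                  tss_distance = if (!is.null(m$tss_distance))
                    m$tss_distance else NA)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, na = ".")
  invisible(path)
}
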