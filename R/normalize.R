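#' Spike-in (ChIP-Rx) normalization factors
#'
#' Each ChIP sample carries a fixed proportion of foreign-genome (e.g.
#' drosophila) spike-in chromatin; reads mapping to the spike-in genome
#' calibrate the sample so that genuine global changes in the target signal
#' survive normalization. The factor is the standard ChIP-Rx convention
#' \code{1e6 / spike_reads} (reads per million spike-in reads), a
#' deterministic function of the spike-in count only; target reads are
#' recorded for reporting.
#'
#' @param sample_id sample label.
#' @param target_reads reads mapped to the target genome.
#' @param spike_reads reads mapped to the spike-in genome (> 0).
#' @return one-row data.frame of class \code{norm_factor} with columns
#'   sample_id, target_reads, spike_reads, factor.
#' @examples
#' norm_factor("wt_k36me2", 2.1e7, 1e6)   # factor 1
#' @export
norm_factor <- function(sample_id, target_reads, spike_reads) {
  target_reads <- check_count(target_reads, "target_reads", positive = FALSE)
  if (!is.numeric(spike_reads) || length(spike_reads) != 1L ||
      is.na(spike_reads) || spike_reads <= 0) {
    stop_chiprx("spike-in absent: spike_reads must be > 0")
  }
  structure(data.frame(sample_id = as.character(sample_id),
                       target_reads = target_reads,
                       spike_reads = as.numeric(spike_reads),
                       factor = 1e6 / as.numeric(spike_reads),
                       stringsAsFactors = FALSE),
            class = c("norm_factor", "data.frame"))
}

#' Read / write norm-factor tables (headered TSV)
#' @param path file path.
#' @return data.frame with sample_id, target_reads, spike_reads, factor.
#' @export
read_norm_factors <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
    norm_factor(d$sample_id[i], d$target_reads[i], d$spike_reads[i])
  }))
}

#' @rdname read_norm_factors
#' @param nf data.frame of norm factors.
#' @export
write_norm_factors <- function(nf, path) {
  utils::write.table(as.data.frame(nf), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Fixed-bin coverage tracks
#'
#' A coverage track holds one non-negative numeric vector per chromosome at a
#' fixed bin size; bin i of a chromosome covers
#' \code{[(i-1)*bin_size, i*bin_size)} (the last bin may be truncated by the
#' chromosome end). Units are \code{"raw"} (counts), \code{"RRPM"}
#' (reference-adjusted reads per million, i.e. spike-in normalized) or
#' \code{"RPM"} (per-million-target scaled, for samples sequenced without
#' spike-in).
#'
#' @param values named list of numeric vectors, one per chromosome.
#' @param bin_size bin width in bp.
#' @param genome a \code{genome_table}.
#' @param units "raw", "RRPM" or "RPM".
#' @return object of class \code{coverage_track}.
#' @export
coverage_track <- function(values, bin_size, genome, units = "raw") {
  genome <- check_genome(genome)
  bin_size <- check_count(bin_size, "bin_size")
  if (!units %in% c("raw", "RRPM", "RPM")) {
    stop_chiprx("units must be raw, RRPM or RPM")
  }
  if (!setequal(names(values), names(genome))) {
    stop_chiprx("track chromosomes must match the genome table")
  }
  values <- values[names(genome)]
  for (ch in names(genome)) {
    nb <- ceiling(genome[[ch]] / bin_size)
    v <- values[[ch]]
    if (length(v) != nb) {
      stop_chiprx(sprintf("track %s: expected %d bins, got %d", ch, nb,
                          length(v)))
    }
    if (any(!is.finite(v)) || any(v < 0)) {
      stop_chiprx("track values must be finite and >= 0")
    }
  }
  structure(list(values = values, bin_size = bin_size, genome = genome,
                 units = units), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track (%s): %d chromosome(s), bin %d bp, %d bins\n",
              x$units, length(x$values), x$bin_size,
              sum(lengths(x$values))))
  invisible(x)
}

#' Apply a spike-in normalization factor to a raw track
#'
#' Multiplies every bin by \code{nf$factor}, turning raw counts into RRPM.
#' Re-normalizing an already normalized track is an error.
#'
#' @param track a \code{coverage_track} in raw units.
#' @param nf a \code{norm_factor} row.
#' @return the track in RRPM units.
#' @export
normalize_track <- function(track, nf) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$units != "raw") {
    stop_chiprx("track is already normalized (units ", track$units, ")")
  }
  f <- nf$factor[1]
  track$values <- lapply(track$values, function(v) v * f)
  track$units <- "RRPM"
  track
}

#' Depth-normalize a raw track to reads per million target reads
#'
#' The per-million-target scaling that spike-in normalization replaces; kept
#' for samples sequenced without spike-in (e.g. mutant-histone ChIP) and as
#' the contrast in spike-in rescue analyses. \code{total_reads} defaults to
#' the track's own total.
#'
#' @param track a \code{coverage_track} in raw units.
#' @param total_reads total mapped target reads (default: track sum).
#' @return the track in RPM units.
#' @export
rpm_track <- function(track, total_reads = NULL) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$units != "raw") {
    stop_chiprx("track is already normalized (units ", track$units, ")")
  }
  if (is.null(total_reads)) total_reads <- sum(vapply(track$values, sum, 0))
  if (total_reads <= 0) stop_chiprx("total_reads must be > 0")
  f <- 1e6 / total_reads
  track$values <- lapply(track$values, function(v) v * f)
  track$units <- "RPM"
  track
}

#' Read / write coverage tracks as bedGraph
#'
#' bedGraph lines are chrom, start, end, value (0-based half-open, tab
#' separated, no header). Writing emits one line per run of equal-valued
#' bins; reading requires bin-aligned records and fills unlisted bins
#' with 0.
#'
#' @param path file path.
#' @param bin_size bin width of the track being read.
#' @param genome a \code{genome_table}.
#' @param units units to stamp on the returned track.
#' @return \code{read_bedgraph}: a \code{coverage_track}.
#' @export
read_bedgraph <- function(path, bin_size, genome, units = "raw") {
  genome <- check_genome(genome)
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "value"),
                         colClasses = c("character", "numeric", "numeric",
                                        "numeric"))
  if (!all(d$chrom %in% names(genome))) {
    stop_chiprx("bedGraph chromosome not in genome table")
  }
  if (any(d$start %% bin_size != 0)) {
    stop_chiprx("bedGraph records must be aligned to the bin grid")
  }
  values <- lapply(names(genome), function(ch) {
    numeric(ceiling(genome[[ch]] / bin_size))
  })
  names(values) <- names(genome)
  for (ch in unique(d$chrom)) {
    di <- d[d$chrom == ch, ]
    i0 <- di$start / bin_size
    i1 <- ceiling(di$end / bin_size)
    for (k in seq_len(nrow(di))) {
      values[[ch]][(i0[k] + 1):i1[k]] <- di$value[k]
    }
  }
  coverage_track(values, bin_size, genome, units = units)
}

#' @rdname read_bedgraph
#' @param track a \code{coverage_track} to write.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  b <- track$bin_size
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    if (!length(v)) next
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- c(0, ends_bin[-length(ends_bin)])
    keep <- r$values != 0
    if (!any(keep)) next
    L <- track$genome[[ch]]
    out <- data.frame(ch, starts_bin[keep] * b,
                      pmin(ends_bin[keep] * b, L),
                      format(r$values[keep], trim = TRUE, scientific = FALSE,
                             digits = 10))
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
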