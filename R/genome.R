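#' Declare a genome as an ordered table of chromosome lengths
#'
#' All interval containers in the package are validated against a genome
#' table: a named numeric vector mapping chromosome name to length in bp.
#' Coordinates are 0-based half-open (BED convention) at every file boundary;
#' in-memory intervals are \link[GenomicRanges]{GRanges} (1-based closed) and
#' converted at the parser/writer boundary only.
#'
#' @param lengths named numeric vector, chromosome name -> length in bp.
#' @return a validated named numeric vector of class \code{genome_table}.
#' @examples
#' genome_table(c(chr1 = 5e6, chr2 = 5e6))
#' @export
genome_table <- function(lengths) {
  if (is.null(names(lengths)) || any(names(lengths) == "") ||
      anyDuplicated(names(lengths))) {
    stop_chiprx("genome table needs unique, non-empty chromosome names")
  }
  if (!is.numeric(lengths) || any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop_chiprx("chromosome lengths must be positive finite numbers")
  }
  structure(as.numeric(stats::setNames(lengths, names(lengths))),
            names = names(lengths), class = "genome_table")
}

genome_seqinfo <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = names(genome), seqlengths = as.integer(genome))
}

check_genome <- function(genome) {
  if (!inherits(genome, "genome_table")) genome <- genome_table(genome)
  genome
}

#' Read / write a genome table as two-column TSV (chrom, length)
#' @param path file path.
#' @return \code{read_genome_table}: a \code{genome_table}.
#' @export
read_genome_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "length"),
                         colClasses = c("character", "numeric"))
  genome_table(stats::setNames(d$length, d$chrom))
}

#' @rdname read_genome_table
#' @param genome a \code{genome_table}.
#' @export
write_genome_table <- function(genome, path) {
  genome <- check_genome(genome)
  utils::write.table(data.frame(names(genome), as.numeric(genome)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Gene models: TSS/TES, exons, strand and expression
#'
#' A \code{gene_models} object bundles one row per gene (id, chromosome,
#' strand, TSS, TES, FPKM) with an exon table. Coordinates are 0-based
#' half-open. \code{tss} is the coordinate of the transcription start: on the
#' plus strand \code{tss < tes}, on the minus strand \code{tss > tes}, so the
#' gene body is always \code{[min(tss, tes), max(tss, tes))}.
#'
#' @param genes data.frame with columns gene_id, chrom, strand (+/-), tss,
#'   tes and optionally fpkm (>= 0 or NA).
#' @param exons data.frame with columns gene_id, chrom, start, end
#'   (0-based half-open), all exons within their gene body and
#'   non-overlapping within a gene.
#' @param genome a \code{genome_table} the coordinates must respect.
#' @return an object of class \code{gene_models}.
#' @export
gene_models <- function(genes, exons, genome) {
  genome <- check_genome(genome)
  need <- c("gene_id", "chrom", "strand", "tss", "tes")
  if (!all(need %in% names(genes))) {
    stop_chiprx("genes must have columns ", paste(need, collapse = ", "))
  }
  if (is.null(genes$fpkm)) genes$fpkm <- NA_real_
  genes <- genes[, c(need, "fpkm")]
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  if (anyDuplicated(genes$gene_id)) stop_chiprx("duplicate gene_id")
  if (!all(genes$strand %in% c("+", "-"))) {
    stop_chiprx("gene strand must be '+' or '-'")
  }
  bad <- genes$strand == "+" & genes$tss >= genes$tes |
         genes$strand == "-" & genes$tss <= genes$tes
  if (any(bad)) {
    stop_chiprx("tss/tes inconsistent with strand for gene(s): ",
                paste(utils::head(genes$gene_id[bad], 5), collapse = ", "))
  }
  if (!all(genes$chrom %in% names(genome))) {
    stop_chiprx("gene chromosome not in genome table")
  }
  lo <- pmin(genes$tss, genes$tes); hi <- pmax(genes$tss, genes$tes)
  if (any(lo < 0) || any(hi > genome[genes$chrom])) {
    stop_chiprx("gene coordinates outside the genome")
  }
  if (any(!is.na(genes$fpkm) & genes$fpkm < 0)) stop_chiprx("fpkm must be >= 0")

  exons <- exons[, c("gene_id", "chrom", "start", "end")]
  exons$gene_id <- as.character(exons$gene_id)
  exons$chrom <- as.character(exons$chrom)
  if (!all(exons$gene_id %in% genes$gene_id)) {
    stop_chiprx("exon with unknown gene_id")
  }
  idx <- match(exons$gene_id, genes$gene_id)
  if (any(exons$chrom != genes$chrom[idx]) ||
      any(exons$start < lo[idx]) || any(exons$end > hi[idx]) ||
      any(exons$start >= exons$end)) {
    stop_chiprx("exon outside its gene body or empty")
  }
  o <- order(exons$gene_id, exons$start)
  exons <- exons[o, , drop = FALSE]
  same <- exons$gene_id[-1] == exons$gene_id[-nrow(exons)]
  if (nrow(exons) > 1 && any(same & exons$start[-1] < exons$end[-nrow(exons)])) {
    stop_chiprx("overlapping exons within a gene")
  }
  rownames(genes) <- rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons, genome = genome),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons), length(x$genome)))
  invisible(x)
}

gene_bodies <- function(gm) {
  g <- gm$genes
  data.frame(gene_id = g$gene_id, chrom = g$chrom,
             start = pmin(g$tss, g$tes), end = pmax(g$tss, g$tes),
             strand = g$strand, stringsAsFactors = FALSE)
}

#' Read / write simplified gene annotation
#'
#' Tab-separated, headered columns: gene_id, chrom, strand, txStart, txEnd,
#' exonStarts, exonEnds (comma lists), optionally fpkm. txStart/txEnd are
#' 0-based half-open; TSS is txStart on '+' and txEnd on '-'.
#'
#' @param path file path.
#' @param genome a \code{genome_table}.
#' @return \code{read_gene_table}: a \code{gene_models} object.
#' @export
read_gene_table <- function(path, genome) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  tss <- ifelse(d$strand == "+", d$txStart, d$txEnd)
  tes <- ifelse(d$strand == "+", d$txEnd, d$txStart)
  genes <- data.frame(gene_id = d$gene_id, chrom = d$chrom, strand = d$strand,
                      tss = tss, tes = tes,
                      fpkm = if (is.null(d$fpkm)) NA_real_ else d$fpkm,
                      stringsAsFactors = FALSE)
  es <- strsplit(d$exonStarts, ",", fixed = TRUE)
  ee <- strsplit(d$exonEnds, ",", fixed = TRUE)
  n <- lengths(es)
  exons <- data.frame(gene_id = rep(d$gene_id, n), chrom = rep(d$chrom, n),
                      start = as.numeric(unlist(es)),
                      end = as.numeric(unlist(ee)), stringsAsFactors = FALSE)
  gene_models(genes, exons, genome)
}

#' @rdname read_gene_table
#' @param gm a \code{gene_models} object.
#' @export
write_gene_table <- function(gm, path) {
  g <- gm$genes
  ex <- split(gm$exons, gm$exons$gene_id)
  starts <- ends <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    e <- ex[[g$gene_id[i]]]
    starts[i] <- paste(e$start, collapse = ",")
    ends[i] <- paste(e$end, collapse = ",")
  }
  out <- data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
                    txStart = pmin(g$tss, g$tes), txEnd = pmax(g$tss, g$tes),
                    exonStarts = starts, exonEnds = ends, fpkm = g$fpkm)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write expression (FPKM) and differential-expression status tables
#'
#' FPKM tables are headered TSV with columns gene_id, fpkm. DE tables are
#' headered TSV with columns gene_id, status where status is one of
#' "up", "down", "unchanged".
#' @param path file path.
#' @return named numeric vector (FPKM) or named character vector (status).
#' @export
read_fpkm_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  stats::setNames(as.numeric(d$fpkm), d$gene_id)
}

#' @rdname read_fpkm_table
#' @param fpkm named numeric vector gene_id -> FPKM.
#' @export
write_fpkm_table <- function(fpkm, path) {
  utils::write.table(data.frame(gene_id = names(fpkm), fpkm = as.numeric(fpkm)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_fpkm_table
#' @export
read_de_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if (!all(d$status %in% c("up", "down", "unchanged"))) {
    stop_chiprx("DE status must be up/down/unchanged")
  }
  stats::setNames(d$status, d$gene_id)
}

#' @rdname read_fpkm_table
#' @param status named character vector gene_id -> up/down/unchanged.
#' @export
write_de_table <- function(status, path) {
  utils::write.table(data.frame(gene_id = names(status),
                                status = as.character(status)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
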