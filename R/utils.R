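#' @importFrom methods is
#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<-
#' @importFrom GenomeInfoDb seqnames seqlevels seqlengths Seqinfo seqinfo
NULL

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's RNG afterwards. seed = NULL runs under the current RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

stop_chiprx <- function(...) stop(..., call. = FALSE)

check_flag <- function(x, nm) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_chiprx(sprintf("'%s' must be TRUE or FALSE", nm))
  }
  x
}

check_count <- function(x, nm, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) ||
      (positive && x <= 0) || (!positive && x < 0)) {
    stop_chiprx(sprintf("'%s' must be a %s integer", nm,
                        if (positive) "positive" else "non-negative"))
  }
  as.numeric(x)
}
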