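#' Configuration for the synthetic ChIP-Rx experiment generator
#'
#' The generator emits a toy genome, gene annotation, per-mark/per-condition
#' coverage tracks and peak sets, spike-in read counts, expression and
#' differential-expression tables, together with the ground truth needed to
#' score recovery. Conditions are \code{"wt"} plus two mutant-histone
#' conditions: \code{"h33"} (replication-independent variant: mutant histone
#' incorporated at enhancers/intergenic loci and introns of actively
#' transcribed genes) and \code{"h31"} (replication-coupled variant:
#' incorporated at exons of repressed genes).
#'
#' @param seed integer seed; identical configs give identical output.
#' @param n_chroms,chrom_length,bin_size toy genome shape (default 2 x 5 Mb
#'   at 50 bp bins).
#' @param n_genes number of genes (placed without overlap).
#' @param gene_length min/max gene length in bp.
#' @param exons_per_gene min/max exon count per gene.
#' @param fraction_expressed fraction of genes with nonzero FPKM.
#' @param fpkm_meanlog,fpkm_sdlog log-normal FPKM parameters.
#' @param n_enhancers number of base (wild-type) enhancers.
#' @param enhancer_length mean/sd of common-enhancer length (bp).
#' @param unique_enhancer_length mean/sd of mutant-unique enhancer length;
#'   shorter, mirroring the shortened enhancers seen in mutant cells.
#' @param dist_common_mean,dist_unique_mean mean drawn distance (bp) from an
#'   enhancer to its seeding gene's TSS for common and mutant-unique
#'   enhancers (~40 kb and ~68 kb).
#' @param state_fractions_wt named fractions of active/primed/poised states
#'   among wild-type enhancers.
#' @param inactivated_fraction named (h33, h31) fraction of wild-type active
#'   enhancers inactivated in each mutant.
#' @param unique_enhancer_fraction mutant-unique enhancers per mutant, as a
#'   fraction of \code{n_enhancers}.
#' @param spike_fraction spike-in chromatin proportion per sample (equal
#'   across samples; 0 < f < 0.5).
#' @param global_depletion named (h33, h31) genome-wide multiplier in (0, 1]
#'   applied to H3K36me2/me3 in the mutant conditions.
#' @param locus_effect coupling constant k in [0, 1) linking normalized
#'   local mutant-histone occupancy to additional local H3K36me2/me3 loss:
#'   mutant rate = wt rate x depletion x (1 - k x occupancy).
#' @param k27me3_intergenic_gain named (h33, h31) multiplier on the
#'   intergenic (enhancer) H3K27me3 component in the mutants.
#' @param effect_size expected log2 fold-change decrease per assigned
#'   inactivated enhancer.
#' @param de_lfc_cut |log2 FC| threshold for up/down status on true fold
#'   changes.
#' @param random_de_frac,random_de_shift fraction of expressed genes given
#'   an enhancer-independent expression shift of +/- shift.
#' @param expr_noise_sd gaussian sd of log2 fold-change noise.
#' @param depth named per-condition sequencing-depth multipliers.
#' @param dispersion NULL for Poisson bin counts, or a negative-binomial
#'   dispersion (counts ~ NB(mu, size = 1/dispersion)).
#' @param peak_mode "noiseless" (peaks are the true enriched compartments)
#'   or "noisy" (endpoint jitter + dropout).
#' @param peak_jitter_sd,peak_dropout noisy-mode jitter sd (bp) and peak
#'   dropout fraction.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_length = 5e6, bin_size = 50L,
                       n_genes = 300L,
                       gene_length = c(5000, 20000),
                       exons_per_gene = c(2L, 8L),
                       fraction_expressed = 0.7,
                       fpkm_meanlog = 1.5, fpkm_sdlog = 1,
                       n_enhancers = 1500L,
                       enhancer_length = c(mean = 1200, sd = 300),
                       unique_enhancer_length = c(mean = 700, sd = 150),
                       dist_common_mean = 40000,
                       dist_unique_mean = 68000,
                       state_fractions_wt = c(active = 0.68, primed = 0.20,
                                              poised = 0.12),
                       inactivated_fraction = c(h33 = 0.61, h31 = 0.55),
                       unique_enhancer_fraction = 0.4,
                       spike_fraction = 0.05,
                       global_depletion = c(h33 = 0.5, h31 = 0.5),
                       locus_effect = 0.5,
                       k27me3_intergenic_gain = c(h33 = 1.4, h31 = 1.0),
                       effect_size = 1.0,
                       de_lfc_cut = 1.0,
                       random_de_frac = 0.2,
                       random_de_shift = 3.0,
                       expr_noise_sd = 0.4,
                       depth = c(wt = 1, h33 = 1, h31 = 1),
                       dispersion = NULL,
                       peak_mode = c("noiseless", "noisy"),
                       peak_jitter_sd = 100,
                       peak_dropout = 0.02) {
  peak_mode <- match.arg(peak_mode)
  cfg <- as.list(environment())
  if (cfg$spike_fraction <= 0 || cfg$spike_fraction >= 0.5) {
    stop_chiprx("spike_fraction must be in (0, 0.5)")
  }
  if (any(cfg$global_depletion <= 0) || any(cfg$global_depletion > 1)) {
    stop_chiprx("global_depletion multipliers must be in (0, 1]")
  }
  if (cfg$locus_effect < 0 || cfg$locus_effect >= 1) {
    stop_chiprx("locus_effect must be in [0, 1): k x occupancy may not exceed 1")
  }
  if (abs(sum(cfg$state_fractions_wt) - 1) > 1e-8) {
    stop_chiprx("state_fractions_wt must sum to 1")
  }
  structure(cfg, class = "sim_config")
}

# Base per-bin signal rates (counts per 50 bp bin before depth scaling).
.sim_rates <- function() {
  list(background = 0.2,
       k36me2_gene = 6, k36me2_enh_domain = 14, k36me2_redist = 5,
       enh_domain_pad = 2000,
       k36me3_gene = 8,
       k4me1_enh = 8, k4me3_prom = 10,
       k27ac_enh = 8, k27ac_prom = 6,
       k27me3_enh = 6, k27me3_gene = 3,
       k36m_enh = 12, k36m_gene = 6,
       k36m_peak_min_occ = 0.3)
}

#' Simulate the toy genome and gene annotation
#'
#' Genes are placed uniformly without overlap (3 kb buffer, leaving promoter
#' room), given a random strand, 2-8 non-overlapping exons, and an FPKM
#' drawn from a log-normal with a point mass at zero for the unexpressed
#' fraction.
#'
#' @param cfg a \code{sim_config}.
#' @return list with \code{genome} (a \code{genome_table}) and \code{genes}
#'   (a \code{gene_models}).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genome <- genome_table(stats::setNames(
    rep(cfg$chrom_length, cfg$n_chroms),
    paste0("chr", seq_len(cfg$n_chroms))))
  if (cfg$n_genes == 0L) {
    empty <- data.frame(gene_id = character(), chrom = character(),
                        strand = character(), tss = numeric(),
                        tes = numeric(), fpkm = numeric())
    exon0 <- data.frame(gene_id = character(), chrom = character(),
                        start = numeric(), end = numeric())
    return(list(genome = genome, genes = gene_models(empty, exon0, genome)))
  }
  with_seed(cfg$seed, {
    placed <- list()  # per chrom: matrix of (start, end) with buffer
    rows <- vector("list", cfg$n_genes)
    exon_rows <- list()
    buffer <- 3000
    for (i in seq_len(cfg$n_genes)) {
      ok <- FALSE
      for (try in seq_len(300L)) {
        ch <- sample(names(genome), 1L)
        len <- round(stats::runif(1, cfg$gene_length[1], cfg$gene_length[2]))
        L <- genome[[ch]]
        if (L < len + 2 * buffer) next
        s <- round(stats::runif(1, buffer, L - len - buffer))
        prev <- placed[[ch]]
        if (!is.null(prev) &&
            any(s - buffer < prev[, 2] & s + len + buffer > prev[, 1])) next
        ok <- TRUE
        break
      }
      if (!ok) {
        stop_chiprx("could not place gene ", i,
                    " without overlap; use a larger genome or fewer genes")
      }
      placed[[ch]] <- rbind(placed[[ch]], c(s, s + len))
      strand <- sample(c("+", "-"), 1L)
      gid <- sprintf("gene%04d", i)
      rows[[i]] <- data.frame(
        gene_id = gid, chrom = ch, strand = strand,
        tss = if (strand == "+") s else s + len,
        tes = if (strand == "+") s + len else s,
        stringsAsFactors = FALSE)
      n_ex <- sample(cfg$exons_per_gene[1]:cfg$exons_per_gene[2], 1L)
      bs <- len / n_ex
      off <- stats::runif(n_ex, 0.05, 0.3) * bs
      wid <- stats::runif(n_ex, 0.2, 0.5) * bs
      es <- floor(s + (seq_len(n_ex) - 1) * bs + off)
      ee <- pmin(floor(es + pmax(wid, 50)), s + len)
      exon_rows[[i]] <- data.frame(gene_id = gid, chrom = ch,
                                   start = es, end = ee,
                                   stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, rows)
    expressed <- stats::runif(cfg$n_genes) < cfg$fraction_expressed
    fpkm <- ifelse(expressed,
                   stats::rlnorm(cfg$n_genes, cfg$fpkm_meanlog, cfg$fpkm_sdlog),
                   0)
    genes$fpkm <- fpkm
    list(genome = genome,
         genes = gene_models(genes, do.call(rbind, exon_rows), genome))
  })
}

# Place one enhancer near a gene TSS at a drawn distance, avoiding
# promoters, gene bodies and already-placed enhancers. Returns c(chrom,
# start0, end, gene_idx) or NULL.
.place_enhancer <- function(genome, genes_df, blocked, placed_by_chrom,
                            dist_mean, len, max_tries = 300L) {
  ng <- nrow(genes_df)
  for (try in seq_len(max_tries)) {
    gi <- sample.int(ng, 1L)
    ch <- genes_df$chrom[gi]
    d <- stats::rnorm(1, dist_mean, 0.25 * dist_mean)
    if (d < 3000) next
    sgn <- sample(c(-1, 1), 1L)
    mid <- genes_df$tss[gi] + sgn * d
    s0 <- round(mid - len / 2); e <- s0 + len
    if (s0 < 0 || e > genome[[ch]]) next
    bl <- blocked[[ch]]
    if (!is.null(bl) && any(s0 < bl[, 2] & e > bl[, 1])) next
    pl <- placed_by_chrom[[ch]]
    if (!is.null(pl) && any(s0 < pl[, 2] & e > pl[, 1])) next
    return(list(chrom = ch, start0 = s0, end = e, gene_idx = gi))
  }
  NULL
}

# Add `rate` (per fully covered bin) to the bins of values[[chrom]]
# overlapped by [s0, e), fractional at the edges.
.add_rate <- function(values, bin_size, chrom, s0, e, rate) {
  if (length(rate) == 1L) rate <- rep(rate, length(chrom))
  b <- bin_size
  for (i in seq_along(chrom)) {
    v <- values[[chrom[i]]]
    i0 <- floor(s0[i] / b); i1 <- ceiling(e[i] / b) - 1
    idx <- (i0 + 1):(i1 + 1)
    w <- rep(1, length(idx))
    w[1] <- w[1] - (s0[i] - i0 * b) / b
    w[length(w)] <- w[length(w)] - ((i1 + 1) * b - e[i]) / b
    v[idx] <- v[idx] + rate[i] * w
    values[[chrom[i]]] <- v
  }
  values
}

.zero_values <- function(genome, bin_size) {
  v <- lapply(names(genome), function(ch) {
    numeric(ceiling(genome[[ch]] / bin_size))
  })
  names(v) <- names(genome)
  v
}

.intron_table <- function(gm) {
  gb <- gene_bodies(gm)
  rows <- list()
  for (i in seq_len(nrow(gb))) {
    ex <- gm$exons[gm$exons$gene_id == gb$gene_id[i], , drop = FALSE]
    bounds <- c(gb$start[i], as.vector(t(ex[, c("start", "end")])), gb$end[i])
    s <- bounds[seq(1, length(bounds), 2)]
    e <- bounds[seq(2, length(bounds), 2)]
    keep <- e > s
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gb$gene_id[i], chrom = gb$chrom[i],
        start = s[keep], end = e[keep], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.jitter_peaks <- function(gr, genome, sd, dropout) {
  keep <- stats::runif(length(gr)) >= dropout
  gr <- gr[keep]
  if (!length(gr)) return(gr)
  ch <- as.character(seqnames(gr))
  s0 <- pmax(0, round(start(gr) - 1 + stats::rnorm(length(gr), 0, sd)))
  e <- pmin(as.numeric(genome[ch]), round(end(gr) + stats::rnorm(length(gr), 0, sd)))
  ok <- e > s0
  granges0(ch[ok], s0[ok], e[ok], genome = genome)
}

#' Simulate mark coverage, peaks, spike-in counts and the truth ledger
#'
#' Wild-type tracks are built from compartment base rates (H3K36me2 over
#' gene bodies of expressed genes and broad enhancer-surrounding intergenic
#' domains; H3K36me3 over expressed gene bodies scaled by expression;
#' H3K4me1 at enhancers; H3K4me3/H3K27ac at expressed promoters; H3K27ac at
#' active enhancers; H3K27me3 at poised enhancers and repressed gene
#' bodies). Mutant H3K36me2/me3 tracks are the wild-type rates times the
#' global depletion times \code{(1 - k x normalized local mutant-histone
#' occupancy)}; mutant H3K27ac at wild-type-active enhancers falls in
#' proportion to local occupancy, and the most-occupied enhancers are the
#' inactivated truth set. Bin counts are Poisson (or negative-binomial)
#' sampled; spike-in read counts are scaled to the configured spike
#' chromatin fraction so that genuine global losses are only recoverable
#' after spike-in normalization.
#'
#' @param cfg a \code{sim_config}.
#' @param genome a \code{genome_table} from \code{\link{simulate_genome}}.
#' @param gm the matching \code{gene_models}.
#' @return list with \code{tracks[[mark]][[condition]]} (raw
#'   \code{coverage_track}s), \code{peaks[[mark]][[condition]]} (GRanges),
#'   \code{spike} (norm-factor table, one row per mark x condition with
#'   spike-in) and \code{truth} (ground-truth ledger; see Details).
#' @details The truth ledger contains the common-enhancer GRanges with
#'   per-condition states, occupancy draws and seeding gene, the
#'   mutant-unique enhancer sets, the per-condition inactivated flags, the
#'   injected depletion factors and the expected (noise-free) per-bin rates'
#'   totals used for spike scaling.
#' @export
simulate_marks <- function(cfg, genome, gm) {
  stopifnot(inherits(cfg, "sim_config"))
  R <- .sim_rates()
  conds <- c("wt", "h33", "h31")
  muts <- c("h33", "h31")
  g <- gm$genes
  expressed <- g$fpkm > 0
  exprw <- log1p(g$fpkm); exprw <- if (max(exprw) > 0) exprw / max(exprw) else exprw
  promoters <- define_promoters(gm)
  gb <- gene_bodies(gm)
  exons <- gm$exons
  introns <- .intron_table(gm)

  with_seed(cfg$seed + 1L, {
    # --- enhancer placement -------------------------------------------------
    blocked <- list()  # promoters + gene bodies per chrom
    for (ch in names(genome)) {
      pr <- promoters[as.character(seqnames(promoters)) == ch]
      bd <- gb[gb$chrom == ch, , drop = FALSE]
      blocked[[ch]] <- rbind(cbind(start(pr) - 1, end(pr)),
                             cbind(bd$start, bd$end))
    }
    placed <- stats::setNames(vector("list", length(genome)), names(genome))
    place_set <- function(n, dist_mean, len_par) {
      out <- vector("list", n)
      for (i in seq_len(n)) {
        len <- max(300, round(stats::rnorm(1, len_par[["mean"]],
                                           len_par[["sd"]])))
        p <- .place_enhancer(genome, g, blocked, placed, dist_mean, len)
        if (is.null(p)) {
          stop_chiprx("could not place enhancer ", i,
                      "; lower n_enhancers or enlarge the genome")
        }
        placed[[p$chrom]] <<- rbind(placed[[p$chrom]], c(p$start0, p$end))
        out[[i]] <- data.frame(chrom = p$chrom, start = p$start0, end = p$end,
                               gene_id = g$gene_id[p$gene_idx],
                               stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    }
    enh <- place_set(cfg$n_enhancers, cfg$dist_common_mean,
                     cfg$enhancer_length)
    n_u <- round(cfg$unique_enhancer_fraction * cfg$n_enhancers)
    uniq <- lapply(stats::setNames(muts, muts), function(m) {
      place_set(n_u, cfg$dist_unique_mean, cfg$unique_enhancer_length)
    })

    # --- truth: states, occupancy, inactivation -----------------------------
    st_lv <- c("active", "primed", "poised")
    state_wt <- sample(st_lv, cfg$n_enhancers, replace = TRUE,
                       prob = cfg$state_fractions_wt[st_lv])
    occ <- lapply(stats::setNames(muts, muts), function(m) {
      stats::runif(cfg$n_enhancers)
    })
    state_mut <- list(); inact <- list()
    for (m in muts) {
      sm <- state_wt
      act <- which(state_wt == "active")
      n_in <- round(cfg$inactivated_fraction[[m]] * length(act))
      ina <- act[order(occ[[m]][act], decreasing = TRUE)][seq_len(n_in)]
      sm[ina] <- sample(c("primed", "poised"), n_in, replace = TRUE,
                        prob = c(0.7, 0.3))
      state_mut[[m]] <- sm
      flag <- rep(FALSE, cfg$n_enhancers)
      flag[ina] <- TRUE
      inact[[m]] <- flag
    }
    uniq_state <- lapply(stats::setNames(muts, muts), function(m) {
      sample(st_lv, n_u, replace = TRUE, prob = c(0.1, 0.6, 0.3))
    })

    # --- redistribution compartments (mutant-unique K36me2 domains) ---------
    # K36me2 moves where the mutant histone is NOT: to exons in the h33
    # condition, to introns in h31; repressed genes keep these disjoint
    # from the wild-type domains.
    rep_ids <- g$gene_id[!expressed]
    redist <- list(
      h33 = {
        cand <- exons[exons$gene_id %in% rep_ids, , drop = FALSE]
        cand[sample.int(nrow(cand), min(200L, nrow(cand))), , drop = FALSE]
      },
      h31 = {
        cand <- introns[introns$gene_id %in% rep_ids, , drop = FALSE]
        cand[sample.int(nrow(cand), min(200L, nrow(cand))), , drop = FALSE]
      })

    # --- expected per-bin rates ---------------------------------------------
    b <- cfg$bin_size
    base <- function() {
      v <- .zero_values(genome, b)
      lapply(v, function(x) x + R$background)
    }
    rates <- list()
    exp_gb <- gb[expressed, , drop = FALSE]
    exp_w <- exprw[expressed]
    rep_gb <- gb[!expressed, , drop = FALSE]
    exp_prom <- promoters[expressed]
    pr0 <- function(gr) list(chrom = as.character(seqnames(gr)),
                             s0 = start(gr) - 1, e = end(gr))

    # H3K36me2 (wt rate; mutants derived below). Enhancer-surrounding
    # domains are merged before the rate is laid down so that nearby
    # enhancers do not stack signal.
    v <- base()
    v <- .add_rate(v, b, exp_gb$chrom, exp_gb$start, exp_gb$end, R$k36me2_gene)
    pad <- R$enh_domain_pad
    dom_s <- pmax(0, enh$start - pad)
    dom_e <- pmin(as.numeric(genome[enh$chrom]), enh$end + pad)
    dom_merged <- merge_intervals(granges0(enh$chrom, dom_s, dom_e,
                                           genome = genome))
    v <- .add_rate(v, b, as.character(seqnames(dom_merged)),
                   start(dom_merged) - 1, end(dom_merged),
                   R$k36me2_enh_domain)
    rates$H3K36me2 <- list(wt = v)

    # H3K36me3
    v <- base()
    v <- .add_rate(v, b, exp_gb$chrom, exp_gb$start, exp_gb$end,
                   R$k36me3_gene * (0.3 + 0.7 * exp_w))
    rates$H3K36me3 <- list(wt = v)

    # H3K36M occupancy per mutant
    occ_rates <- list()
    for (m in muts) {
      v <- base()
      v <- .add_rate(v, b, enh$chrom, enh$start, enh$end,
                     R$k36m_enh * occ[[m]])
      if (m == "h33") {
        gw <- exprw[match(introns$gene_id, g$gene_id)]
        keep <- gw > 0
        v <- .add_rate(v, b, introns$chrom[keep], introns$start[keep],
                       introns$end[keep], R$k36m_gene * gw[keep])
      } else {
        gw <- 1 - exprw[match(exons$gene_id, g$gene_id)]
        keep <- gw > 0.5  # repressed genes
        v <- .add_rate(v, b, exons$chrom[keep], exons$start[keep],
                       exons$end[keep], R$k36m_gene * gw[keep])
      }
      occ_rates[[m]] <- v
    }
    rates$H3K36M <- c(list(wt = base()), occ_rates)

    # normalized occupancy in [0, 1] for the locus effect
    occ_norm <- lapply(occ_rates, function(v) {
      mx <- max(vapply(v, max, 0))
      lapply(v, function(x) x / mx)
    })

    # mutant H3K36me2/me3: global depletion x (1 - k x occupancy)
    k <- cfg$locus_effect
    for (mark in c("H3K36me2", "H3K36me3")) {
      for (m in muts) {
        gd <- cfg$global_depletion[[m]]
        wtv <- rates[[mark]]$wt
        v <- lapply(names(wtv), function(ch) {
          wtv[[ch]] * gd * (1 - k * occ_norm[[m]][[ch]])
        })
        names(v) <- names(wtv)
        if (mark == "H3K36me2") {
          rd <- redist[[m]]
          v <- .add_rate(v, b, rd$chrom, rd$start, rd$end, R$k36me2_redist)
        }
        rates[[mark]][[m]] <- v
      }
    }

    # H3K4me1: enhancers (per condition), unchanged globally
    all_enh <- function(cond) {
      if (cond == "wt") enh[, 1:3] else
        rbind(enh[, 1:3], uniq[[cond]][, 1:3])
    }
    rates$H3K4me1 <- lapply(stats::setNames(conds, conds), function(cond) {
      e <- all_enh(cond)
      .add_rate(base(), b, e$chrom, e$start, e$end, R$k4me1_enh)
    })

    # H3K4me3: expressed promoters, all conditions alike
    v <- base()
    p <- pr0(exp_prom)
    v <- .add_rate(v, b, p$chrom, p$s0, p$e, R$k4me3_prom)
    rates$H3K4me3 <- stats::setNames(rep(list(v), 3), conds)

    # H3K27ac: active enhancers + expressed promoters; in mutants the
    # wild-type-active enhancers lose H3K27ac in proportion to occupancy
    a_base <- R$k27ac_enh * stats::runif(cfg$n_enhancers, 0.6, 1.4)
    rates$H3K27ac <- lapply(stats::setNames(conds, conds), function(cond) {
      v <- base()
      v <- .add_rate(v, b, p$chrom, p$s0, p$e, R$k27ac_prom)
      if (cond == "wt") {
        act <- state_wt == "active"
        v <- .add_rate(v, b, enh$chrom[act], enh$start[act], enh$end[act],
                       a_base[act])
      } else {
        act <- state_wt == "active"
        rate <- a_base * (1 - 0.9 * occ[[cond]])
        v <- .add_rate(v, b, enh$chrom[act], enh$start[act], enh$end[act],
                       rate[act])
        ua <- uniq_state[[cond]] == "active"
        u <- uniq[[cond]]
        v <- .add_rate(v, b, u$chrom[ua], u$start[ua], u$end[ua], R$k27ac_enh)
      }
      v
    })

    # H3K27me3: poised enhancers + repressed gene bodies; intergenic gain
    rates$H3K27me3 <- lapply(stats::setNames(conds, conds), function(cond) {
      v <- base()
      v <- .add_rate(v, b, rep_gb$chrom, rep_gb$start, rep_gb$end,
                     R$k27me3_gene)
      gain <- if (cond == "wt") 1 else cfg$k27me3_intergenic_gain[[cond]]
      st <- if (cond == "wt") state_wt else state_mut[[cond]]
      po <- st == "poised"
      v <- .add_rate(v, b, enh$chrom[po], enh$start[po], enh$end[po],
                     R$k27me3_enh * gain)
      if (cond != "wt") {
        up <- uniq_state[[cond]] == "poised"
        u <- uniq[[cond]]
        v <- .add_rate(v, b, u$chrom[up], u$start[up], u$end[up],
                       R$k27me3_enh * gain)
      }
      v
    })

    # --- sample counts, spike reads, assemble tracks ------------------------
    marks <- names(rates)
    tracks <- list(); spike_rows <- list()
    f <- cfg$spike_fraction
    for (mark in marks) {
      tracks[[mark]] <- list()
      expected_wt <- sum(vapply(rates[[mark]]$wt, sum, 0))
      for (cond in conds) {
        rv <- rates[[mark]][[cond]]
        if (is.null(rv)) next
        depth <- cfg$depth[[cond]]
        counts <- lapply(rv, function(lam) {
          mu <- lam * depth
          if (is.null(cfg$dispersion)) stats::rpois(length(mu), mu)
          else stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
        })
        tracks[[mark]][[cond]] <- coverage_track(counts, b, genome, "raw")
        if (mark != "H3K36M") {  # mutant-histone ChIP carries no spike-in
          spike_reads <- max(1, round(expected_wt * depth * f / (1 - f)))
          spike_rows[[paste(mark, cond, sep = "_")]] <- norm_factor(
            paste(mark, cond, sep = "_"),
            target_reads = sum(vapply(counts, sum, 0)),
            spike_reads = spike_reads)
        }
      }
    }
    spike <- do.call(rbind, spike_rows)
    rownames(spike) <- NULL

    # --- peak emission ------------------------------------------------------
    enh_gr <- function(d, ...) {
      gr <- granges0(d$chrom, d$start, d$end, genome = genome)
      m <- list(...)
      for (nm in names(m)) mcols(gr)[[nm]] <- m[[nm]]
      gr
    }
    peaks <- list()
    peaks$H3K4me1 <- lapply(stats::setNames(conds, conds), function(cond) {
      enh_gr(all_enh(cond))
    })
    prom_peaks <- granges0(as.character(seqnames(exp_prom)),
                           start(exp_prom) - 1, end(exp_prom),
                           genome = genome)
    peaks$H3K4me3 <- stats::setNames(rep(list(prom_peaks), 3), conds)
    peaks$H3K27ac <- lapply(stats::setNames(conds, conds), function(cond) {
      st <- if (cond == "wt") state_wt else state_mut[[cond]]
      prt <- enh[st == "active", 1:3]
      if (cond != "wt") {
        prt <- rbind(prt, uniq[[cond]][uniq_state[[cond]] == "active", 1:3])
      }
      merge_intervals(c(enh_gr(prt), prom_peaks))
    })
    peaks$H3K27me3 <- lapply(stats::setNames(conds, conds), function(cond) {
      st <- if (cond == "wt") state_wt else state_mut[[cond]]
      prt <- enh[st == "poised", 1:3]
      if (cond != "wt") {
        prt <- rbind(prt, uniq[[cond]][uniq_state[[cond]] == "poised", 1:3])
      }
      merge_intervals(c(enh_gr(prt),
                        granges0(rep_gb$chrom, rep_gb$start, rep_gb$end,
                                 genome = genome)))
    })
    gene_dom <- granges0(exp_gb$chrom, exp_gb$start, exp_gb$end,
                         genome = genome)
    enh_dom <- granges0(enh$chrom, dom_s, dom_e, genome = genome)
    k36me2_wt_dom <- merge_intervals(c(gene_dom, enh_dom))
    peaks$H3K36me2 <- list(wt = k36me2_wt_dom)
    for (m in muts) {
      # enhancer domains with the strongest in-cis depletion (top-occupancy
      # quintile) drop out of the mutant peak set; redistribution domains
      # come in
      keep <- occ[[m]] <= stats::quantile(occ[[m]], 0.8)
      rd <- redist[[m]]
      peaks$H3K36me2[[m]] <- merge_intervals(c(
        gene_dom, enh_dom[keep],
        granges0(rd$chrom, rd$start, rd$end, genome = genome)))
    }
    k36me3_dom <- merge_intervals(
      granges0(exp_gb$chrom, exp_gb$start, exp_gb$end, genome = genome))
    peaks$H3K36me3 <- stats::setNames(rep(list(k36me3_dom), 3), conds)
    peaks$H3K36M <- lapply(stats::setNames(muts, muts), function(m) {
      hi <- occ[[m]] >= R$k36m_peak_min_occ
      e <- enh[hi, 1:3]
      extra <- if (m == "h33") {
        gw <- exprw[match(introns$gene_id, g$gene_id)]
        introns[gw > 0.3, c("chrom", "start", "end")]
      } else {
        gw <- 1 - exprw[match(exons$gene_id, g$gene_id)]
        exons[gw > 0.5, c("chrom", "start", "end")]
      }
      merge_intervals(enh_gr(rbind(e, extra)))
    })
    if (cfg$peak_mode == "noisy") {
      peaks <- lapply(peaks, function(bycond) {
        lapply(bycond, .jitter_peaks, genome = genome,
               sd = cfg$peak_jitter_sd, dropout = cfg$peak_dropout)
      })
    }

    truth <- list(
      enhancers = enh_gr(enh, gene_id = enh$gene_id, state_wt = state_wt,
                         state_h33 = state_mut$h33, state_h31 = state_mut$h31,
                         occ_h33 = occ$h33, occ_h31 = occ$h31,
                         inactivated_h33 = inact$h33,
                         inactivated_h31 = inact$h31),
      unique_enhancers = lapply(stats::setNames(muts, muts), function(m) {
        enh_gr(uniq[[m]], gene_id = uniq[[m]]$gene_id,
               state = uniq_state[[m]])
      }),
      k36me2_domains = k36me2_wt_dom,
      global_depletion = cfg$global_depletion,
      locus_effect = cfg$locus_effect,
      spike_fraction = cfg$spike_fraction,
      k36m_mode = "RPM (no spike-in for mutant-histone ChIP)")

    list(tracks = tracks, peaks = peaks, spike = spike, truth = truth)
  })
}

#' Simulate mutant expression tables coupled to enhancer inactivation
#'
#' Genes seeded with m inactivated assigned enhancers get an expected log2
#' fold change of \code{-m x effect_size}; an enhancer-independent fraction
#' of expressed genes is shifted by +/- \code{random_de_shift}; gaussian
#' noise is added; and up/down/unchanged statuses are thresholded on the
#' true fold changes at \code{de_lfc_cut}. Unexpressed genes stay at zero.
#'
#' @param cfg a \code{sim_config}.
#' @param gm the simulated \code{gene_models}.
#' @param truth the truth ledger from \code{\link{simulate_marks}}.
#' @return list with \code{fpkm} (named list: wt, h33, h31), \code{de}
#'   (named list of status vectors for h33, h31) and \code{lfc_true}
#'   (named list of true log2 fold changes).
#' @export
simulate_expression_effects <- function(cfg, gm, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  g <- gm$genes
  fpkm_wt <- stats::setNames(g$fpkm, g$gene_id)
  te <- truth$enhancers
  # an enhancer regulates the gene whose TSS is nearest (within 500 kb),
  # which is what downstream assignment recovers
  reg_gene <- nearest_tss(te, gm)$gene_id
  with_seed(cfg$seed + 2L, {
    fpkm <- list(wt = fpkm_wt)
    de <- list(); lfc_all <- list()
    for (m in c("h33", "h31")) {
      ina <- mcols(te)[[paste0("inactivated_", m)]]
      m_count <- table(reg_gene[ina & !is.na(reg_gene)])
      mg <- stats::setNames(rep(0, nrow(g)), g$gene_id)
      mg[names(m_count)] <- as.integer(m_count)
      lfc <- -cfg$effect_size * mg
      expressed <- fpkm_wt > 0
      rnd <- expressed & stats::runif(nrow(g)) < cfg$random_de_frac
      lfc[rnd] <- lfc[rnd] +
        sample(c(-1, 1), sum(rnd), replace = TRUE) * cfg$random_de_shift
      lfc <- lfc + stats::rnorm(nrow(g), 0, cfg$expr_noise_sd)
      lfc[!expressed] <- 0
      fpkm[[m]] <- fpkm_wt * 2^lfc
      status <- ifelse(!expressed, "unchanged",
                ifelse(lfc <= -cfg$de_lfc_cut, "down",
                ifelse(lfc >= cfg$de_lfc_cut, "up", "unchanged")))
      de[[m]] <- stats::setNames(status, g$gene_id)
      lfc_all[[m]] <- stats::setNames(lfc, g$gene_id)
    }
    list(fpkm = fpkm, de = de, lfc_true = lfc_all)
  })
}

#' Run the full synthetic experiment
#'
#' Convenience wrapper chaining \code{\link{simulate_genome}},
#' \code{\link{simulate_marks}} and
#' \code{\link{simulate_expression_effects}}. Fully deterministic under
#' \code{cfg$seed}; the caller's RNG state is untouched.
#'
#' @param cfg a \code{sim_config}.
#' @return list of class \code{chiprx_sim} with genome, genes, tracks,
#'   peaks, spike, fpkm, de, lfc_true and truth.
#' @export
simulate_chiprx <- function(cfg = sim_config()) {
  geno <- simulate_genome(cfg)
  mk <- simulate_marks(cfg, geno$genome, geno$genes)
  ex <- simulate_expression_effects(cfg, geno$genes, mk$truth)
  structure(c(list(config = cfg, genome = geno$genome, genes = geno$genes),
              mk, ex),
            class = "chiprx_sim")
}

#' @export
print.chiprx_sim <- function(x, ...) {
  cat(sprintf(
    "chiprx_sim: %d chromosomes, %d genes, %d enhancers; %d marks, seed %d\n",
    length(x$genome), nrow(x$genes$genes), length(x$truth$enhancers),
    length(x$tracks), x$config$seed))
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Emits: genome table and annotation TSVs, BED peak files and bedGraph raw
#' tracks per mark and condition, the norm-factor TSV, FPKM and DE TSVs,
#' and a truth JSON. Every file parses back through the package's own
#' readers.
#'
#' @param sim a \code{chiprx_sim}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, paste0(...))
  write_genome_table(sim$genome, fp("genome.tsv"))
  write_gene_table(sim$genes, fp("genes.tsv"))
  write_norm_factors(sim$spike, fp("norm_factors.tsv"))
  for (mark in names(sim$peaks)) {
    for (cond in names(sim$peaks[[mark]])) {
      write_bed(sim$peaks[[mark]][[cond]], fp(mark, "_", cond, "_peaks.bed"))
    }
  }
  for (mark in names(sim$tracks)) {
    for (cond in names(sim$tracks[[mark]])) {
      write_bedgraph(sim$tracks[[mark]][[cond]],
                     fp(mark, "_", cond, ".bedGraph"))
    }
  }
  for (cond in names(sim$fpkm)) {
    write_fpkm_table(sim$fpkm[[cond]], fp("fpkm_", cond, ".tsv"))
  }
  for (cond in names(sim$de)) {
    write_de_table(sim$de[[cond]], fp("de_", cond, ".tsv"))
  }
  te <- sim$truth$enhancers
  truth_json <- list(
    global_depletion = as.list(sim$truth$global_depletion),
    locus_effect = sim$truth$locus_effect,
    spike_fraction = sim$truth$spike_fraction,
    k36m_mode = sim$truth$k36m_mode,
    enhancers = data.frame(
      chrom = as.character(seqnames(te)), start = start(te) - 1L,
      end = end(te), as.data.frame(mcols(te))),
    lfc_true = lapply(sim$lfc_true, as.list))
  jsonlite::write_json(truth_json, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
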