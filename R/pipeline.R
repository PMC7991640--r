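# 32-bit FNV-1a hash of the deparsed resolved config; embedded in every
# output table header so each file traces to the exact parameters used.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

write_tsv_prov <- function(d, path, hash) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Resolve and validate a pipeline configuration
#'
#' Parameters of the end-to-end analysis, with the package defaults
#' matching the conventions used throughout: promoter window 2000/500 bp,
#' enhancer-to-gene window 500 kb, profile flanks 5 kb at 100 bp bins with
#' 100 scaled body bins, whole-peak enhancer exclusion, classification
#' precedence active > poised, and per-million-target (RPM) scaling for the
#' mutant-histone ChIP which carries no spike-in.
#'
#' @param seed seed for the shuffled-null backgrounds.
#' @param max_dist enhancer-to-gene assignment window (bp).
#' @param promoter_upstream,promoter_downstream promoter window (bp).
#' @param flank,flank_bin,body_bins metagene profile geometry.
#' @param fc_bins upper edges of the inactivated-enhancer count bins.
#' @param k36m_mode "RPM" or "RRPM" scaling for mutant-histone tracks.
#' @return list of class \code{chiprx_config}.
#' @export
chiprx_config <- function(seed = 1L, max_dist = 500000,
                          promoter_upstream = 2000, promoter_downstream = 500,
                          flank = 5000, flank_bin = 100, body_bins = 100,
                          fc_bins = c(0, 1, 2, Inf),
                          k36m_mode = c("RPM", "RRPM")) {
  k36m_mode <- match.arg(k36m_mode)
  structure(as.list(environment()), class = "chiprx_config")
}

#' Run the full analysis pipeline on a simulated (or loaded) experiment
#'
#' Chains the stages: spike-in normalization to RRPM -> peak-set
#' decomposition (wild type vs each mutant, with a shuffled null) ->
#' enhancer calling, classification and assignment -> wild-type-to-mutant
#' enhancer transitions -> density, correlation and expression statistics.
#' When \code{out_dir} is given, all tables are written as headered TSV
#' (with the resolved config hash in a header comment), the Venn counts and
#' summary as JSON, and the resolved config as JSON.
#'
#' @param sim a \code{chiprx_sim} (from \code{\link{simulate_chiprx}}) or a
#'   list with the same components built from files.
#' @param config a \code{chiprx_config}.
#' @param out_dir optional output directory.
#' @return object of class \code{chiprx_run}: all stage results plus a
#'   \code{summary} list mirroring the summary JSON.
#' @export
run_chiprx <- function(sim, config = chiprx_config(), out_dir = NULL) {
  stopifnot(inherits(config, "chiprx_config"))
  genome <- sim$genome
  gm <- sim$genes
  hash <- config_hash(config)
  stage <- "normalize"
  res <- tryCatch({
    # --- 1. normalization -------------------------------------------------
    rrpm <- list()
    for (mark in names(sim$tracks)) {
      rrpm[[mark]] <- list()
      for (cond in names(sim$tracks[[mark]])) {
        tr <- sim$tracks[[mark]][[cond]]
        sid <- paste(mark, cond, sep = "_")
        row <- sim$spike[sim$spike$sample_id == sid, ]
        if (mark == "H3K36M" && config$k36m_mode == "RPM" || nrow(row) == 0) {
          rrpm[[mark]][[cond]] <- rpm_track(tr)
        } else {
          rrpm[[mark]][[cond]] <- normalize_track(tr, row)
        }
      }
    }

    # --- 2. peak decomposition with shuffled nulls ------------------------
    stage <- "decompose"
    decomp <- list(); shuffled <- list()
    for (m in c("h33", "h31")) {
      decomp[[m]] <- decompose_peaks(sim$peaks$H3K36me2$wt,
                                     sim$peaks$H3K36me2[[m]])
      shuffled[[m]] <- shuffle_intervals(decomp[[m]]$unique_b, genome,
                                         seed = config$seed,
                                         exclude = sim$peaks$H3K36me2[[m]])
    }

    # --- 3. enhancers -----------------------------------------------------
    stage <- "enhancers"
    promoters <- define_promoters(gm, genome,
                                  upstream = config$promoter_upstream,
                                  downstream = config$promoter_downstream)
    conds <- names(sim$peaks$H3K4me1)
    enhancers <- list()
    for (cond in conds) {
      e <- call_enhancers(sim$peaks$H3K4me1[[cond]],
                          sim$peaks$H3K4me3[[cond]], promoters)
      e <- classify_enhancers(e, sim$peaks$H3K27ac[[cond]],
                              sim$peaks$H3K27me3[[cond]])
      enhancers[[cond]] <- assign_enhancers(e, gm,
                                            max_dist = config$max_dist)
    }

    # --- 4. transitions ---------------------------------------------------
    stage <- "transitions"
    transitions <- list()
    for (m in c("h33", "h31")) {
      transitions[[m]] <- enhancer_transitions(enhancers$wt, enhancers[[m]])
    }

    # --- 5. statistics ----------------------------------------------------
    stage <- "statistics"
    # spike-in rescue over wild-type H3K36me2 domains
    doms <- sim$peaks$H3K36me2$wt
    d_wt <- interval_density(rrpm$H3K36me2$wt, doms)$density
    rescue <- list()
    for (m in c("h33", "h31")) {
      d_m <- interval_density(rrpm$H3K36me2[[m]], doms)$density
      raw_wt <- interval_density(rpm_track(sim$tracks$H3K36me2$wt),
                                 doms)$density
      raw_m <- interval_density(rpm_track(sim$tracks$H3K36me2[[m]]),
                                doms)$density
      rescue[[m]] <- list(rrpm_ratio = mean(d_m) / mean(d_wt),
                          rpm_ratio = mean(raw_m) / mean(raw_wt),
                          n_domains = length(doms))
    }

    # mark changes vs mutant-histone occupancy at WT-active enhancers
    # lying within wild-type H3K36me2 peaks
    wt_act <- enhancers$wt[mcols(enhancers$wt)$state == "active"]
    wt_act <- wt_act[overlaps_any(wt_act, sim$peaks$H3K36me2$wt)]
    correlations <- list(); deltas <- list()
    for (m in c("h33", "h31")) {
      occ_tr <- rrpm$H3K36M[[m]]
      d36 <- delta_records(wt_act, rrpm$H3K36me2$wt, rrpm$H3K36me2[[m]],
                           occ_tr)
      d27 <- delta_records(wt_act, rrpm$H3K27ac$wt, rrpm$H3K27ac[[m]],
                           occ_tr)
      correlations[[m]] <- list(
        k36me2_vs_occ = delta_correlation(d36, "delta", "occupancy"),
        k27ac_vs_occ = delta_correlation(d27, "delta", "occupancy"))
      deltas[[m]] <- list(k36me2 = d36, k27ac = d27)
    }

    # common/unique/shuffled density contrast (H3K36me2, mutant perspective)
    cus <- list()
    for (m in c("h33", "h31")) {
      cus[[m]] <- group_mean_density(
        rrpm$H3K36me2[[m]],
        list(common = decomp[[m]]$common_b,
             unique = decomp[[m]]$unique_b,
             shuffled = shuffled[[m]]))
    }

    # genomic-element annotation of peaks
    elements <- list(
      H3K36me2_wt = annotate_elements(sim$peaks$H3K36me2$wt, gm, promoters),
      H3K36M_h33 = annotate_elements(sim$peaks$H3K36M$h33, gm, promoters),
      H3K36M_h31 = annotate_elements(sim$peaks$H3K36M$h31, gm, promoters))

    # expression strata and per-state expression
    expressed <- sim$fpkm$wt[sim$fpkm$wt > 0]
    strata <- stratify_expression(expressed)
    class_expr <- class_expression_summary(enhancers$wt, sim$fpkm$wt)

    # enhancer inactivation vs differential expression
    assoc <- list()
    expr_ids <- names(sim$fpkm$wt)[sim$fpkm$wt > 0]
    for (m in c("h33", "h31")) {
      assoc[[m]] <- inactivation_gene_association(
        transitions[[m]], enhancers$wt, sim$de[[m]],
        fpkm_wt = sim$fpkm$wt[expr_ids], fpkm_mut = sim$fpkm[[m]][expr_ids],
        bins = config$fc_bins)
    }

    # enhancer summary stats (common/unique classes per condition)
    sets <- list(wt = enhancers$wt)
    for (m in c("h33", "h31")) {
      e <- enhancers[[m]]
      dc <- decompose_peaks(e, enhancers$wt)
      cls <- ifelse(overlaps_any(e, enhancers$wt), "common", "unique")
      mcols(e)$class <- cls
      sets[[m]] <- e
    }
    stats_tab <- enhancer_stats(sets)

    summary <- list(
      config_hash = hash,
      package_version = as.character(utils::packageVersion("chiprx")),
      seed = config$seed,
      k36m_mode = config$k36m_mode,
      classification_convention = attr(enhancers$wt, "convention"),
      enhancer_counts = lapply(enhancers, function(e) {
        s <- state_fractions(e)
        stats::setNames(as.list(s$n), s$state)
      }),
      ambiguous_fraction = lapply(enhancers, attr, "ambiguous_fraction"),
      inactivation = lapply(transitions, function(tr) {
        s <- summary(tr)
        s[c("n_active", "n_inactivated", "inactivated_percent")]
      }),
      venn = lapply(decomp, `[[`, "venn"),
      rescue = rescue,
      correlations = lapply(correlations, function(cc) {
        lapply(cc, function(x) list(r = x$r, n = x$n))
      }))

    list(config = config, enhancers = enhancers, transitions = transitions,
         decomp = decomp, shuffled = shuffled, rrpm = rrpm,
         rescue = rescue, correlations = correlations, deltas = deltas,
         common_unique_shuffled = cus, elements = elements,
         strata = strata, class_expr = class_expr, assoc = assoc,
         enhancer_stats = stats_tab, promoters = promoters,
         summary = summary)
  }, error = function(e) {
    stop_chiprx(sprintf("pipeline failed at stage '%s': %s", stage,
                        conditionMessage(e)))
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(...) file.path(out_dir, paste0(...))
    jsonlite::write_json(res$summary, fp("summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(
      lapply(config, function(x) if (is.numeric(x)) unname(x) else x),
      fp("config.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (cond in names(res$enhancers)) {
      write_enhancers(res$enhancers[[cond]], fp("enhancers_", cond, ".bed"))
    }
    for (m in names(res$transitions)) {
      write_tsv_prov(as.data.frame(res$transitions[[m]]),
                     fp("transitions_", m, ".tsv"), hash)
      write_tsv_prov(res$assoc[[m]]$de_fractions,
                     fp("de_fractions_", m, ".tsv"), hash)
      if (!is.null(res$assoc[[m]]$fc_bins)) {
        write_tsv_prov(res$assoc[[m]]$fc_bins, fp("fc_bins_", m, ".tsv"),
                       hash)
      }
      write_tsv_prov(res$deltas[[m]]$k36me2, fp("delta_k36me2_", m, ".tsv"),
                     hash)
      write_tsv_prov(res$deltas[[m]]$k27ac, fp("delta_k27ac_", m, ".tsv"),
                     hash)
    }
    for (nm in names(res$elements)) {
      write_tsv_prov(res$elements[[nm]], fp("elements_", nm, ".tsv"), hash)
    }
    write_tsv_prov(res$enhancer_stats, fp("enhancer_stats.tsv"), hash)
    write_tsv_prov(res$class_expr$summary, fp("class_expression.tsv"), hash)
  }
  res$out_dir <- out_dir
  class(res) <- "chiprx_run"
  res
}

#' @export
print.chiprx_run <- function(x, ...) {
  s <- x$summary
  cat("chiprx_run (config", s$config_hash, ")\n")
  for (cond in names(s$enhancer_counts)) {
    n <- s$enhancer_counts[[cond]]
    cat(sprintf("  %-4s enhancers: %d active / %d primed / %d poised\n",
                cond, n$active, n$primed, n$poised))
  }
  for (m in names(s$inactivation)) {
    i <- s$inactivation[[m]]
    cat(sprintf("  %s: %d/%d WT-active inactivated (%.1f%%)\n",
                m, i$n_inactivated, i$n_active, i$inactivated_percent))
  }
  for (m in names(s$correlations)) {
    cc <- s$correlations[[m]]
    cat(sprintf("  %s: r(dK36me2, occ) = %.2f (n=%d); r(dK27ac, occ) = %.2f (n=%d)\n",
                m, cc$k36me2_vs_occ$r, cc$k36me2_vs_occ$n,
                cc$k27ac_vs_occ$r, cc$k27ac_vs_occ$n))
  }
  invisible(x)
}

#' @export
#' @method summary chiprx_run
summary.chiprx_run <- function(object, ...) object$summary

#' Render figure panels for a pipeline run
#'
#' Writes SVG panels from a \code{chiprx_run}: per-condition enhancer state
#' fractions, the common/unique/shuffled density contrast, change-vs-
#' occupancy scatter plots annotated with Pearson r, and FPKM boxplots per
#' enhancer state. Panels whose upstream table is missing are skipped with
#' a notice. Requires cairo SVG support; otherwise returns with a notice.
#'
#' @param run a \code{chiprx_run}.
#' @param dir output directory (default: the run's \code{out_dir}).
#' @return invisibly, the paths written.
#' @export
make_report <- function(run, dir = run$out_dir) {
  stopifnot(inherits(run, "chiprx_run"))
  if (is.null(dir)) stop_chiprx("no output directory for the report")
  if (!isTRUE(unname(capabilities("cairo")))) {
    message("cairo SVG device unavailable; report skipped")
    return(invisible(character()))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  emit <- function(name, w, h, expr) {
    p <- file.path(dir, name)
    grDevices::svg(p, width = w, height = h)
    on.exit(grDevices::dev.off(), add = TRUE)
    force(expr)
    paths <<- c(paths, p)
  }
  emit("state_fractions.svg", 6, 4, {
    fr <- sapply(run$enhancers, function(e) state_fractions(e)$fraction)
    rownames(fr) <- c("active", "primed", "poised")
    graphics::barplot(fr, beside = TRUE, col = c("#d95f02", "#7570b3",
                                                "#1b9e77"),
                      ylab = "fraction of enhancers",
                      legend.text = rownames(fr))
    graphics::mtext(sprintf("config %s", run$summary$config_hash), cex = 0.6)
  })
  for (m in names(run$common_unique_shuffled)) {
    emit(paste0("common_unique_shuffled_", m, ".svg"), 5, 4, {
      s <- run$common_unique_shuffled[[m]]$summary
      graphics::barplot(stats::setNames(s$mean, s$group),
                        ylab = "mean H3K36me2 RRPM density",
                        main = paste("condition", m))
    })
  }
  for (m in names(run$deltas)) {
    emit(paste0("delta_k36me2_vs_occ_", m, ".svg"), 5, 5, {
      d <- run$deltas[[m]]$k36me2
      r <- run$correlations[[m]]$k36me2_vs_occ
      graphics::plot(d$occupancy, d$delta, pch = 16, cex = 0.4,
                     col = "#00000066",
                     xlab = "mutant-histone occupancy (RPM)",
                     ylab = "delta H3K36me2 (RRPM)",
                     main = sprintf("%s: r = %.2f, n = %d", m, r$r, r$n))
    })
  }
  if (!is.null(run$class_expr)) {
    emit("fpkm_by_state.svg", 5, 4, {
      bs <- run$class_expr$fpkm_by_state
      bs <- bs[lengths(bs) > 0]
      graphics::boxplot(lapply(bs, function(v) log2(v + 1)),
                        ylab = "log2(FPKM + 1)",
                        main = "expression by wild-type enhancer state")
    })
  } else message("class expression table missing; panel skipped")
  invisible(paths)
}
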