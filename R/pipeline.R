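#' Pipeline configuration
#'
#' Bundles the simulation (or input) definition with the analysis
#' thresholds used by [run_pipeline()].
#'
#' @param sim A [simulation_config()] describing the synthetic experiment.
#' @param reference_sample Sample id used as the scaling reference
#'   (default: the first sample in the manifest).
#' @param percentile Percentile for scaling factors (default 99).
#' @param alpha Adjusted-p threshold for differential classes
#'   (default 0.05).
#' @param fc_threshold Fold-change threshold (default 1.5).
#' @param n_bins Body bins for length-scaled abundance (default 100).
#' @param blacklist_recurrence,blacklist_quantile Blacklist-builder knobs
#'   (defaults 1 and 0.999).
#' @return A list of class `cr_pipeconfig`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            reference_sample = NULL,
                            percentile = 99, alpha = 0.05, fc_threshold = 1.5,
                            n_bins = 100,
                            blacklist_recurrence = 1.0,
                            blacklist_quantile = 0.999) {
  structure(as.list(environment()), class = "cr_pipeconfig")
}

#' Run the full analysis pipeline on a synthetic experiment
#'
#' Stage order mirrors the analysis workflow: simulate (or load) tracks,
#' detect local maxima, build the artifact blacklist, scale every sample to
#' the reference by the percentile factor, classify loci (consensus,
#' co-occupied vs PRC1-only, bivalent vs H3K4me3-only), quantify
#' length-scaled abundance, run the moderated-t differential comparison of
#' the two timepoints, the K-S comparison within H3K27me3 regions, and the
#' blacklist-filtered correlation matrix. Deterministic for a fixed config.
#'
#' @param cfg A [pipeline_config()].
#' @return A `cr_report` list: scaling factors, blacklist size, region
#'   counts per class, differential counts and percentages, K-S results,
#'   correlation matrix, and provenance (seed, thresholds).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "cr_pipeconfig"))
  sim <- simulate_experiment(cfg$sim)
  manifest <- cfg$sim$samples
  timepoints <- unique(manifest$timepoint)
  if (length(timepoints) != 2) {
    stop("comparison stages need exactly two timepoints; manifest has ",
         length(timepoints), " (", paste(timepoints, collapse = ", "), ")")
  }

  # normalization
  maxima <- lapply(sim$tracks, find_local_maxima)
  blacklist <- build_blacklist(maxima, sim$genes,
                               recurrence = cfg$blacklist_recurrence,
                               height_quantile = cfg$blacklist_quantile)
  # samples are normalized within a mark: each scales to the mark's first
  # listed sample (or to `reference_sample` for its own mark)
  mark_ref <- vapply(unique(manifest$mark), function(mk) {
    ids <- manifest$sample_id[manifest$mark == mk]
    if (!is.null(cfg$reference_sample) && cfg$reference_sample %in% ids) {
      cfg$reference_sample
    } else {
      ids[1]
    }
  }, "")
  factors <- lapply(seq_len(nrow(manifest)), function(i) {
    ref <- sim$tracks[[mark_ref[[manifest$mark[i]]]]]
    compute_scaling_factor(ref, sim$tracks[[manifest$sample_id[i]]], blacklist,
                           percentile = cfg$percentile)
  })
  names(factors) <- manifest$sample_id
  normalized <- purrr::map2(sim$tracks, factors, apply_scaling)

  # locus classification
  h2aub_peaks <- sim$peaks$h2aub
  k27_peaks <- sim$peaks$k27me3
  k4_peaks <- sim$peaks$k4me3
  h2aub_classes <- classify_h2aub_loci(h2aub_peaks, k27_peaks)
  prom_classes <- classify_promoters(k4_peaks, k27_peaks)

  # differential H2AK119ub over consensus peaks (log2 length-scaled abundance)
  h2_samples <- manifest[manifest$mark == "h2aub", , drop = FALSE]
  diff_table <- NULL
  if (nrow(h2aub_peaks) && nrow(h2_samples) >= 4) {
    abund <- lapply(h2_samples$sample_id, function(sid) {
      length_scaled_abundance(normalized[[sid]], h2aub_peaks, n_bins = cfg$n_bins)
    })
    mat <- log2(do.call(cbind, lapply(abund, `[[`, "abundance")) + 1)
    rownames(mat) <- abund[[1]]$id
    colnames(mat) <- h2_samples$sample_id
    mt <- moderated_t(mat, factor(h2_samples$timepoint, levels = timepoints))
    diff_table <- classify_differential(mt, alpha = cfg$alpha,
                                        fc_threshold = cfg$fc_threshold)
  }

  # K-S: H2AK119ub length-scaled abundance within H3K27me3 peak regions
  ks <- NULL
  if (nrow(k27_peaks)) {
    first_rep <- function(tp) {
      h2_samples$sample_id[h2_samples$timepoint == tp][1]
    }
    a_early <- length_scaled_abundance(normalized[[first_rep(timepoints[1])]],
                                       k27_peaks, n_bins = cfg$n_bins)
    a_late <- length_scaled_abundance(normalized[[first_rep(timepoints[2])]],
                                      k27_peaks, n_bins = cfg$n_bins)
    ks <- ks_two_sample(a_early$abundance, a_late$abundance)
  }

  cormat <- correlation_matrix(normalized, blacklist = blacklist)

  diff_summary <- if (!is.null(diff_table)) glance(diff_table) else NULL
  report <- list(
    scaling_factors = purrr::map_dbl(factors, "value"),
    blacklist_size = nrow(blacklist),
    region_counts = list(
      h2aub = nrow(h2aub_peaks), k27me3 = nrow(k27_peaks), k4me3 = nrow(k4_peaks),
      co_occupied = nrow(h2aub_classes$co_occupied),
      prc1_only = nrow(h2aub_classes$prc1_only),
      bivalent = nrow(prom_classes$bivalent),
      k4_only = nrow(prom_classes$k4_only)
    ),
    differential = diff_summary,
    ks = if (!is.null(ks)) tidy(ks) else NULL,
    correlation = tidy(cormat),
    provenance = list(seed = cfg$sim$seed, reference = as.list(mark_ref),
                      percentile = cfg$percentile, alpha = cfg$alpha,
                      fc_threshold = cfg$fc_threshold)
  )
  structure(
    list(report = report, blacklist = blacklist, factors = factors,
         normalized = normalized, classes = c(h2aub_classes, prom_classes),
         diff = diff_table, sim = sim),
    class = "cr_report"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cr_report <- function(x, ...) {
  r <- x$report
  cat("<cr_report> seed ", r$provenance$seed, "\n", sep = "")
  cat("  blacklist: ", r$blacklist_size, " region(s)\n", sep = "")
  cat("  scaling factors: ",
      paste(sprintf("%s=%.3f", names(r$scaling_factors), r$scaling_factors),
            collapse = ", "), "\n", sep = "")
  if (!is.null(r$differential)) {
    cat("  differential: ", r$differential$increased, " up (",
        r$differential$pct_increased, "%), ", r$differential$decreased,
        " down (", r$differential$pct_decreased, "%) of ",
        r$differential$n, " regions\n", sep = "")
  }
  if (!is.null(r$ks)) {
    cat("  K-S within H3K27me3 regions: D = ", format(r$ks$D, digits = 3),
        ", p = ", format(r$ks$p_value, digits = 3), "\n", sep = "")
  }
  invisible(x)
}

#' Write a run report as JSON and text
#'
#' @param result A `cr_report` from [run_pipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- result$report
  jsonlite::write_json(
    lapply(r, function(x) if (inherits(x, "tbl_df")) as.data.frame(x) else x),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  txt <- utils::capture.output(print(result))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}

#' Generate and analyse a self-contained worked example
#'
#' Runs the default simulation end to end, writes the tracks, peak sets,
#' blacklist, differential table and report under `outdir`, and returns
#' the pipeline result.
#'
#' @param outdir Output directory.
#' @param seed Simulation seed (default 1).
#' @return The `cr_report`, invisibly.
#' @export
make_demo <- function(outdir, seed = 1) {
  cfg <- pipeline_config(sim = simulation_config(seed = seed))
  res <- run_pipeline(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_report(res, outdir)
  write_bed(res$blacklist, file.path(outdir, "blacklist.bed"))
  write_bed(res$sim$peaks$h2aub, file.path(outdir, "h2aub_peaks.bed"))
  write_bed(res$sim$peaks$k27me3, file.path(outdir, "k27me3_peaks.bed"))
  write_genes(res$sim$genes, file.path(outdir, "genes.tsv"))
  for (sid in names(res$normalized)) {
    write_bedgraph(res$normalized[[sid]],
                   file.path(outdir, paste0(sid, ".norm.bedGraph")))
  }
  if (!is.null(res$diff)) {
    utils::write.table(as.data.frame(res$diff),
                       file.path(outdir, "differential.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_ground_truth(res$sim$truth, file.path(outdir, "truth"))
  invisible(res)
}
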