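#' Configuration for a synthetic CUT&RUN experiment
#'
#' Defines a desk-scale experiment emulating the statistical structure of
#' binned CUT&RUN coverage: Poisson background, flat-top peak enrichments
#' with log-normal heights, per-sample global scale factors, shared
#' intergenic artifact spikes, condition-specific differential regions with
#' known log2 fold changes, a gene-body-restricted H3K27me1-like mark, and
#' negative-binomial expression counts.
#'
#' @param seed Integer seed; a fixed seed makes every output byte-identical.
#' @param chrom_lengths Named chromosome lengths (default 2 x 2 Mb).
#' @param bin_width Bin width in bp (default 50).
#' @param background Mean background reads per bin (default 2; CUT&RUN
#'   backgrounds are low relative to enrichment).
#' @param noise If `FALSE`, tracks carry the expected coverage with no
#'   Poisson noise (useful for exact constructions).
#' @param n_peaks Named integer vector of peak counts per mark.
#' @param peak_width_bins Range of peak footprint widths in bins.
#' @param peak_height_meanlog,peak_height_sdlog Log-normal parameters of
#'   peak enrichment heights (reads per bin above background).
#' @param samples Sample manifest: tibble with columns `sample_id`, `mark`,
#'   `timepoint`, `replicate`, `scale` (true global scale factor).
#' @param n_artifacts Number of shared intergenic artifact spikes.
#' @param artifact_multiplier Spike height as a multiple of the 99th
#'   percentile local-maxima height (0 disables artifacts).
#' @param frac_up,frac_down Fractions of H2AK119ub peaks whose enrichment
#'   increases / decreases between timepoints.
#' @param lfc_mean,lfc_sd Magnitude distribution (normal, truncated at
#'   0.5) of true log2 fold changes for differential peaks.
#' @param n_genes Number of gene models.
#' @param gene_length_bp Range of gene body lengths.
#' @param exons_per_gene Range of exon counts per gene.
#' @param expr_meanlog,expr_sdlog,expr_size Log-normal mean parameters and
#'   NB size (inverse dispersion) for expression counts.
#' @param me1_gain_frac Fraction of genes whose H3K27me1 is enriched at the
#'   late timepoint (the rest are depleted), emulating gene-body
#'   redistribution of this mark.
#' @return A list of class `cr_simconfig`.
#' @export
simulation_config <- function(seed = 1,
                              chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                              bin_width = 50,
                              background = 2,
                              noise = TRUE,
                              n_peaks = c(h2aub = 300, k27me3 = 150, k4me3 = 150),
                              peak_width_bins = c(5, 40),
                              peak_height_meanlog = log(25),
                              peak_height_sdlog = 1,
                              samples = default_samples(),
                              n_artifacts = 10,
                              artifact_multiplier = 30,
                              frac_up = 0.15,
                              frac_down = 0.20,
                              lfc_mean = 1.5,
                              lfc_sd = 0.25,
                              n_genes = 250,
                              gene_length_bp = c(1000, 12000),
                              exons_per_gene = c(1, 8),
                              expr_meanlog = log(100),
                              expr_sdlog = 1,
                              expr_size = 10,
                              me1_gain_frac = 0.2) {
  cfg <- as.list(environment())
  if (cfg$background < 0 || any(cfg$n_peaks < 0)) stop("rates must be >= 0")
  if (!all(c("sample_id", "mark", "timepoint", "replicate", "scale") %in% names(cfg$samples))) {
    stop("sample manifest needs sample_id, mark, timepoint, replicate, scale")
  }
  if (any(cfg$samples$scale <= 0)) stop("scale factors must be > 0")
  structure(cfg, class = "cr_simconfig")
}

default_samples <- function() {
  tibble::tibble(
    sample_id = c("h2aub_early_r1", "h2aub_early_r2", "h2aub_late_r1", "h2aub_late_r2",
                  "k27me3_early_r1", "k27me3_late_r1", "k4me3_early_r1",
                  "k27me1_early_r1", "k27me1_late_r1"),
    mark = c("h2aub", "h2aub", "h2aub", "h2aub",
             "k27me3", "k27me3", "k4me3", "k27me1", "k27me1"),
    timepoint = c("early", "early", "late", "late",
                  "early", "late", "early", "early", "late"),
    replicate = c(1L, 2L, 1L, 2L, 1L, 1L, 1L, 1L, 1L),
    scale = c(1.0, 1.15, 0.9, 1.25, 1.05, 0.95, 1.1, 1.0, 1.2)
  )
}

# Greedy non-overlapping placement of n footprints; returns a region tibble.
place_footprints <- function(genome, n, width_bins, mask_env, label_prefix) {
  nb <- n_bins(genome)
  if (n == 0) return(empty_regions(genome))
  chrom_prob <- genome$chroms / sum(genome$chroms)
  out <- vector("list", n)
  placed <- 0
  tries <- 0
  while (placed < n && tries < n * 200) {
    tries <- tries + 1
    ch <- sample(names(nb), 1, prob = chrom_prob)
    w <- sample(seq(width_bins[1], width_bins[2]), 1)
    if (nb[[ch]] <= w + 2) next
    b0 <- sample.int(nb[[ch]] - w - 2, 1)  # keep off chromosome boundaries
    idx <- b0:(b0 + w - 1)
    if (any(mask_env$mask[[ch]][idx])) next
    mask_env$mask[[ch]][idx] <- TRUE
    placed <- placed + 1
    out[[placed]] <- tibble::tibble(chrom = ch, start = b0 * genome$bin_width,
                                    end = (b0 + w) * genome$bin_width)
  }
  if (placed < n) stop("could not place ", n, " footprints; genome too small for the configuration")
  df <- dplyr::bind_rows(out[seq_len(placed)])
  df$name <- sprintf("%s_%04d", label_prefix, seq_len(placed))
  as_regions(df, genome)
}

add_footprints <- function(lambda, regions, heights, genome) {
  bw <- genome$bin_width
  for (i in seq_len(nrow(regions))) {
    ch <- regions$chrom[i]
    idx <- (regions$start[i] / bw + 1):(regions$end[i] / bw)
    lambda[[ch]][idx] <- lambda[[ch]][idx] + heights[i]
  }
  lambda
}

#' Simulate a full synthetic experiment
#'
#' Generates the genome, gene models, per-sample binned tracks, per-mark
#' peak footprints, nuclear RNA coverage, and a ground-truth record.
#' Each sample's track is `scale * Poisson(background + enrichment)`, with
#' shared intergenic artifact spikes of equal absolute height injected
#' into every CUT&RUN sample afterwards (alignment artifacts do not follow
#' a sample's scale, which is exactly why they corrupt percentile scaling).
#'
#' @param cfg A [simulation_config()].
#' @return List with elements `genome`, `genes`, `tracks` (named list of
#'   track tibbles), `peaks` (named list of region tibbles; the H2AK119ub
#'   set carries `class` and `lfc` columns), `rna` (tracks `early`/`late`),
#'   `expression` (per-gene counts), and `truth`.
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "cr_simconfig"))
  set.seed(cfg$seed)
  genome <- genome_spec(cfg$chrom_lengths, cfg$bin_width)
  nb <- n_bins(genome)

  # gene models on a placement mask of their own
  gene_mask <- new.env()
  gene_mask$mask <- lapply(nb, function(k) logical(k))
  wb <- pmax(1, round(cfg$gene_length_bp / cfg$bin_width))
  gene_rs <- place_footprints(genome, cfg$n_genes, wb, gene_mask, "gene")
  genes <- tibble::tibble(
    gene_id = sprintf("gene_%04d", seq_len(nrow(gene_rs))),
    chrom = gene_rs$chrom,
    strand = sample(c("+", "-"), nrow(gene_rs), replace = TRUE),
    start = gene_rs$start,
    end = gene_rs$end
  )
  genes$exons <- lapply(seq_len(nrow(genes)), function(i) {
    k <- sample(seq(cfg$exons_per_gene[1], cfg$exons_per_gene[2]), 1)
    brk <- sort(round(stats::runif(2 * k, genes$start[i], genes$end[i])))
    ex <- tibble::tibble(start = brk[seq(1, 2 * k, 2)], end = brk[seq(2, 2 * k, 2)])
    ex <- ex[ex$end > ex$start, , drop = FALSE]
    if (!nrow(ex)) ex <- tibble::tibble(start = genes$start[i], end = genes$end[i])
    ex
  })
  genes <- as_genes(genes, genome)

  # peak footprints per mark: H2AK119ub partially co-occupies H3K27me3;
  # H3K4me3 sits at promoters (so a subset intersects H3K27me3 -> bivalent)
  peak_mask <- new.env()
  peak_mask$mask <- lapply(nb, function(k) logical(k))
  peaks <- list()
  n_k27 <- cfg$n_peaks[["k27me3"]]
  peaks$k27me3 <- place_footprints(genome, n_k27, cfg$peak_width_bins, peak_mask, "k27me3")
  n_h2 <- cfg$n_peaks[["h2aub"]]
  n_co <- min(round(n_h2 / 3), n_k27)
  co_idx <- sort(sample.int(n_k27, n_co))
  h2_own <- place_footprints(genome, n_h2 - n_co, cfg$peak_width_bins, peak_mask, "h2aub")
  h2 <- dplyr::bind_rows(
    tibble::as_tibble(peaks$k27me3[co_idx, c("chrom", "start", "end")]),
    tibble::as_tibble(h2_own[c("chrom", "start", "end")])
  )
  h2$name <- sprintf("h2aub_%04d", seq_len(nrow(h2)))
  peaks$h2aub <- as_regions(h2, genome)
  n_k4 <- min(cfg$n_peaks[["k4me3"]], nrow(genes))
  k4_genes <- sort(sample.int(nrow(genes), n_k4))
  k4w <- sample(4:10, n_k4, replace = TRUE) * cfg$bin_width
  k4_start <- ifelse(genes$strand[k4_genes] == "+",
                     pmax(genes$tss[k4_genes] - k4w / 2, 0),
                     pmax(genes$tss[k4_genes] - k4w / 2, 0))
  k4_start <- floor(k4_start / cfg$bin_width) * cfg$bin_width
  k4_end <- pmin(k4_start + k4w, genome$chroms[genes$chrom[k4_genes]])
  peaks$k4me3 <- as_regions(
    tibble::tibble(chrom = genes$chrom[k4_genes], start = k4_start, end = k4_end,
                   name = sprintf("k4me3_%04d", seq_len(n_k4))),
    genome
  )
  # a fifth of H3K4me3-marked promoters also carry H3K27me3 -> bivalent
  if (n_k4 > 0) {
    n_biv <- max(1, round(n_k4 / 5))
    biv_idx <- sort(sample.int(n_k4, n_biv))
    biv <- tibble::as_tibble(peaks$k4me3[biv_idx, c("chrom", "start", "end")])
    biv$start <- pmax(biv$start - 2 * cfg$bin_width, 0)
    biv$end <- pmin(biv$end + 2 * cfg$bin_width, genome$chroms[biv$chrom])
    k27_all <- dplyr::bind_rows(
      tibble::as_tibble(peaks$k27me3[c("chrom", "start", "end")]), biv
    )
    k27_all$name <- sprintf("k27me3_%04d", seq_len(nrow(k27_all)))
    peaks$k27me3 <- as_regions(k27_all, genome)
  }

  # true differential H2AK119ub classes
  n_up <- round(cfg$frac_up * nrow(peaks$h2aub))
  n_down <- round(cfg$frac_down * nrow(peaks$h2aub))
  cls <- rep("stable", nrow(peaks$h2aub))
  pick <- sample.int(nrow(peaks$h2aub), n_up + n_down)
  cls[pick[seq_len(n_up)]] <- "up"
  cls[pick[n_up + seq_len(n_down)]] <- "down"
  lfc_mag <- pmax(0.5, stats::rnorm(nrow(peaks$h2aub), cfg$lfc_mean, cfg$lfc_sd))
  lfc <- ifelse(cls == "up", lfc_mag, ifelse(cls == "down", -lfc_mag, 0))
  peaks$h2aub$class <- cls
  peaks$h2aub$lfc <- lfc

  heights <- list(
    h2aub = stats::rlnorm(nrow(peaks$h2aub), cfg$peak_height_meanlog, cfg$peak_height_sdlog),
    k27me3 = stats::rlnorm(nrow(peaks$k27me3), cfg$peak_height_meanlog, cfg$peak_height_sdlog),
    k4me3 = stats::rlnorm(nrow(peaks$k4me3), cfg$peak_height_meanlog, cfg$peak_height_sdlog)
  )

  # mark- and timepoint-specific expected enrichment (reads/bin over background)
  zero_lambda <- lapply(nb, function(k) numeric(k))
  enrich <- list()
  for (tp in c("early", "late")) {
    h <- heights$h2aub * ifelse(rep(tp == "late", nrow(peaks$h2aub)), 2^peaks$h2aub$lfc, 1)
    enrich[[paste0("h2aub_", tp)]] <- add_footprints(zero_lambda, peaks$h2aub, h, genome)
  }
  enrich$k27me3_early <- add_footprints(zero_lambda, peaks$k27me3, heights$k27me3, genome)
  enrich$k27me3_late <- enrich$k27me3_early
  enrich$k4me3_early <- add_footprints(zero_lambda, peaks$k4me3, heights$k4me3, genome)
  enrich$k4me3_late <- enrich$k4me3_early

  # H3K27me1: gene-body-restricted; late redistribution concentrates it in
  # a gain class and depletes the rest
  me1_base <- stats::rlnorm(nrow(genes), log(6), 0.4)
  me1_gain <- stats::runif(nrow(genes)) < cfg$me1_gain_frac
  me1_late <- ifelse(me1_gain, me1_base * 4, me1_base * 0.3)
  body_rs <- gene_bodies(genes)
  enrich$k27me1_early <- add_footprints(zero_lambda, body_rs, me1_base, genome)
  enrich$k27me1_late <- add_footprints(zero_lambda, body_rs, me1_late, genome)

  # expression: NB counts; genes with H2AK119ub-up promoters lose mRNA late
  expr_mu <- stats::rlnorm(nrow(genes), cfg$expr_meanlog, cfg$expr_sdlog)
  k4_peak_gene <- genes$gene_id[k4_genes]
  up_regions <- peaks$h2aub[peaks$h2aub$class == "up", , drop = FALSE]
  prom <- promoters_of(genes, 1000)
  prom_up <- if (nrow(up_regions)) {
    hits <- GenomicRanges::countOverlaps(regions_to_gr(prom), regions_to_gr(up_regions))
    prom$name[hits > 0]
  } else character()
  rna_lfc <- ifelse(genes$gene_id %in% prom_up, -1, 0)
  expr_early <- stats::rnbinom(nrow(genes), mu = expr_mu, size = cfg$expr_size)
  expr_late <- stats::rnbinom(nrow(genes), mu = expr_mu * 2^rna_lfc, size = cfg$expr_size)
  expression <- tibble::tibble(
    gene_id = genes$gene_id, count_early = expr_early, count_late = expr_late,
    true_mu = expr_mu, true_rna_lfc = rna_lfc
  )

  # RNA coverage tracks: reads spread uniformly over exonic bins
  rna <- list()
  for (tp in c("early", "late")) {
    lam <- lapply(nb, function(k) numeric(k))
    cnt <- if (tp == "early") expr_early else expr_late
    for (i in seq_len(nrow(genes))) {
      ex <- genes$exons[[i]]
      bins <- unlist(lapply(seq_len(nrow(ex)), function(j) {
        (floor(ex$start[j] / cfg$bin_width)):(ceiling(ex$end[j] / cfg$bin_width) - 1)
      }))
      bins <- unique(pmin(bins, nb[[genes$chrom[i]]] - 1)) + 1
      lam[[genes$chrom[i]]][bins] <- lam[[genes$chrom[i]]][bins] + cnt[i] / length(bins)
    }
    vals <- lapply(lam, function(l) if (cfg$noise) stats::rpois(length(l), l) else l)
    rna[[tp]] <- as_track(genome, vals)
  }

  # CUT&RUN tracks
  tracks <- vector("list", nrow(cfg$samples))
  names(tracks) <- cfg$samples$sample_id
  for (i in seq_len(nrow(cfg$samples))) {
    s <- cfg$samples[i, ]
    key <- paste0(s$mark, "_", s$timepoint)
    lam <- enrich[[key]]
    if (is.null(lam)) lam <- zero_lambda
    vals <- lapply(names(nb), function(ch) {
      base <- lam[[ch]] + cfg$background
      v <- if (cfg$noise) stats::rpois(nb[[ch]], base) else base
      v * s$scale
    })
    names(vals) <- names(nb)
    tracks[[i]] <- as_track(genome, vals)
  }

  # shared intergenic artifact spikes, equal absolute height in all samples
  artifact_bins <- tibble::tibble(chrom = character(), bin = integer())
  artifact_height <- 0
  if (cfg$n_artifacts > 0 && cfg$artifact_multiplier > 0) {
    artifact_bins <- pick_artifact_bins(genome, genes, cfg$n_artifacts)
    mx <- find_local_maxima(tracks[[1]])
    artifact_height <- cfg$artifact_multiplier *
      stats::quantile(mx$height, 0.99, names = FALSE, type = 7)
    for (i in seq_along(tracks)) {
      tracks[[i]] <- inject_artifacts(tracks[[i]], artifact_bins,
                                      height = artifact_height, genes = genes)
    }
  }

  truth <- list(
    seed = cfg$seed,
    scale_factors = stats::setNames(cfg$samples$scale, cfg$samples$sample_id),
    artifact_bins = artifact_bins,
    artifact_height = artifact_height,
    differential = tibble::tibble(name = peaks$h2aub$name,
                                  class = peaks$h2aub$class,
                                  lfc = peaks$h2aub$lfc),
    me1 = tibble::tibble(gene_id = genes$gene_id, gain = me1_gain,
                         early = me1_base, late = me1_late),
    k4me3_gene = k4_peak_gene,
    expression = expression
  )

  list(genome = genome, genes = genes, tracks = tracks, peaks = peaks,
       rna = rna, expression = expression, truth = truth)
}

pick_artifact_bins <- function(genome, genes, n) {
  nb <- n_bins(genome)
  bw <- genome$bin_width
  cand <- dplyr::bind_rows(lapply(names(nb), function(ch) {
    free <- rep(TRUE, nb[[ch]])
    gb <- genes[genes$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(gb))) {
      idx <- (floor(gb$start[i] / bw)):(ceiling(gb$end[i] / bw) - 1)
      free[idx + 1] <- FALSE
    }
    free[c(1, nb[[ch]])] <- FALSE  # keep off boundaries
    tibble::tibble(chrom = ch, bin = which(free) - 1L)
  }))
  if (nrow(cand) < n * 3) stop("not enough intergenic bins for artifact placement")
  picked <- cand[sort(sample.int(nrow(cand), n * 3)), , drop = FALSE]
  # enforce >= 3-bin spacing so spikes stay distinct local maxima
  keep <- logical(nrow(picked))
  last_chrom <- ""
  last_bin <- -10L
  for (i in seq_len(nrow(picked))) {
    if (picked$chrom[i] != last_chrom || picked$bin[i] - last_bin >= 3) {
      keep[i] <- TRUE
      last_chrom <- picked$chrom[i]
      last_bin <- picked$bin[i]
    }
  }
  picked <- picked[keep, , drop = FALSE]
  if (nrow(picked) < n) stop("not enough spaced intergenic bins for artifacts")
  picked[sort(sample.int(nrow(picked), n)), , drop = FALSE]
}

#' Inject artifact spikes into a track
#'
#' Adds narrow spikes at the given intergenic bins. Unless an absolute
#' `height` is supplied, the spike height is `multiplier` times the track's
#' 99th-percentile local-maxima height.
#'
#' @param track A track tibble.
#' @param positions Tibble with columns `chrom` and `bin` (0-based), or a
#'   region tibble whose bins are used.
#' @param multiplier Spike height multiplier (0 leaves the track unchanged).
#' @param genes Optional gene models; positions inside a gene body raise an
#'   error (artifacts are intergenic by construction).
#' @param height Optional absolute spike height overriding `multiplier`.
#' @return The track with spikes added.
#' @export
inject_artifacts <- function(track, positions, multiplier = 10, genes = NULL,
                             height = NULL) {
  g <- genome_of(track)
  if ("start" %in% names(positions) && !"bin" %in% names(positions)) {
    positions <- tibble::tibble(chrom = positions$chrom,
                                bin = as.integer(positions$start %/% g$bin_width))
  }
  if (is.null(height)) {
    if (multiplier == 0) return(track)
    mx <- find_local_maxima(track)
    height <- multiplier * stats::quantile(mx$height, 0.99, names = FALSE, type = 7)
  }
  if (height == 0) return(track)
  if (!is.null(genes) && nrow(genes) && nrow(positions)) {
    mid <- positions$bin * g$bin_width + floor(g$bin_width / 2)
    gr_p <- gr_make(positions$chrom, mid + 1, mid + 1, g)
    gr_g <- gr_make(genes$chrom, genes$start + 1, genes$end, g)
    if (any(GenomicRanges::countOverlaps(gr_p, gr_g) > 0)) {
      stop("artifact position inside a gene body")
    }
  }
  key <- paste(track$chrom, track$start %/% g$bin_width)
  hit <- key %in% paste(positions$chrom, positions$bin)
  track$value[hit] <- track$value[hit] + height
  track
}

#' Simulate a log2-scale count matrix for differential testing
#'
#' Emulates the hierarchical model under which the moderated t-statistic is
#' calibrated: per-region variances drawn from a scaled inverse-chi-square
#' prior (`d0`, `s0`), Gaussian replicate noise on the log2 scale, and a
#' subset of regions shifted by a known log2 fold change in condition 2.
#'
#' @param n_regions Number of regions (rows).
#' @param n_per_group Replicates per condition.
#' @param prop_differential Fraction of regions that are truly differential.
#' @param lfc Absolute log2 fold change of differential regions (sign
#'   randomized per region).
#' @param d0,s0 Prior degrees of freedom and prior standard deviation of
#'   the variance distribution.
#' @param base_meanlog,base_sdlog Distribution of region baseline log2
#'   abundance.
#' @param sd_noise If `0`, replicate noise is suppressed entirely.
#' @return List with `matrix` (regions x samples), `condition` (factor,
#'   levels condition1/condition2) and `truth` tibble (`region`,
#'   `differential`, `lfc`).
#' @export
simulate_counts_matrix <- function(n_regions = 2000, n_per_group = 4,
                                   prop_differential = 0, lfc = 2,
                                   d0 = 4, s0 = 0.25,
                                   base_meanlog = 8, base_sdlog = 1.5,
                                   sd_noise = 1) {
  if (n_per_group < 2) stop("need >= 2 replicates per condition")
  mu <- stats::rnorm(n_regions, base_meanlog, base_sdlog)
  n_diff <- round(prop_differential * n_regions)
  diff_idx <- if (n_diff) sort(sample.int(n_regions, n_diff)) else integer()
  true_lfc <- numeric(n_regions)
  if (n_diff) true_lfc[diff_idx] <- lfc * sample(c(-1, 1), n_diff, replace = TRUE)
  sigma <- if (sd_noise == 0) {
    numeric(n_regions)
  } else {
    sd_noise * s0 * sqrt(d0 / stats::rchisq(n_regions, df = d0))
  }
  m <- matrix(0, n_regions, 2 * n_per_group)
  for (j in seq_len(n_per_group)) {
    m[, j] <- stats::rnorm(n_regions, mu, sigma)
    m[, n_per_group + j] <- stats::rnorm(n_regions, mu + true_lfc, sigma)
  }
  rownames(m) <- sprintf("region_%05d", seq_len(n_regions))
  colnames(m) <- c(paste0("cond1_r", seq_len(n_per_group)),
                   paste0("cond2_r", seq_len(n_per_group)))
  list(
    matrix = m,
    condition = factor(rep(c("condition1", "condition2"), each = n_per_group)),
    truth = tibble::tibble(region = rownames(m),
                           differential = seq_len(n_regions) %in% diff_idx,
                           lfc = true_lfc)
  )
}

#' Write / read the ground-truth record of a simulation
#'
#' Serializes the truth list of [simulate_experiment()] as JSON (full
#' precision) plus TSV sidecars for the differential-region and expression
#' tables; `read_ground_truth()` restores it exactly.
#'
#' @param truth The `truth` element of a [simulate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly / the restored truth list.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ser <- lapply(truth, function(x) {
    if (inherits(x, "tbl_df")) return(as.data.frame(x))
    if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
    x
  })
  jsonlite::write_json(ser, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  utils::write.table(truth$differential, file.path(dir, "differential.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$expression, file.path(dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(dir) {
  raw <- jsonlite::fromJSON(file.path(dir, "ground_truth.json"))
  raw$scale_factors <- vapply(raw$scale_factors, as.double, 0)
  raw$artifact_height <- as.double(raw$artifact_height)
  for (nm in c("artifact_bins", "differential", "me1", "expression")) {
    cols <- lapply(raw[[nm]], function(x) {
      x <- unlist(x)
      if (is.numeric(x)) as.double(x) else x
    })
    raw[[nm]] <- tibble::as_tibble(cols)
  }
  raw$artifact_bins$bin <- as.integer(raw$artifact_bins$bin)
  raw$k4me3_gene <- unlist(raw$k4me3_gene)
  raw
}
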