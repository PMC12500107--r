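#' Signal matrix over anchors (reference-point or scale-regions)
#'
#' Builds the regions x bins matrix behind aggregate heatmaps and
#' metagenes. In `reference_point` mode each row holds the raw bin values
#' in a window of `flank` bp on either side of the anchor midpoint. In
#' `scale_regions` mode each region body is resampled to `n_bins` bins by
#' coverage-weighted averaging (so regions of different lengths become
#' comparable) with optional unscaled flanks. Rows for regions on the `-`
#' strand are reversed so that all rows read 5' to 3'.
#'
#' @param track A track tibble.
#' @param anchors A region tibble (optionally with `strand`) or a
#'   gene-model tibble (bodies are used; strand-aware).
#' @param mode `"reference_point"` or `"scale_regions"`.
#' @param n_bins Number of body bins in `scale_regions` mode (default 100).
#' @param flank Flank in bp on each side; must be a multiple of the track
#'   bin width (default 0).
#' @return A `cr_matrix`: list with `values` (matrix), `row_id`, `mode`,
#'   `n_bins`, `flank`, `bin_width` and `clipped` (rows that hit a
#'   chromosome edge and were zero-padded).
#' @export
signal_matrix <- function(track, anchors,
                          mode = c("reference_point", "scale_regions"),
                          n_bins = 100, flank = 0) {
  mode <- match.arg(mode)
  g <- check_same_genome(track, anchors, "track and anchors")
  if (inherits(anchors, "cr_genes")) anchors <- gene_bodies(anchors)
  if (!nrow(anchors)) stop("`anchors` is empty")
  bw <- g$bin_width
  if (flank %% bw != 0) stop("`flank` must be a multiple of the bin width (", bw, ")")
  fl_bins <- as.integer(flank / bw)
  vals <- track_values(track)
  strand <- if ("strand" %in% names(anchors)) anchors$strand else rep("*", nrow(anchors))
  ids <- region_id(anchors)

  n_col <- if (mode == "reference_point") 2L * fl_bins else as.integer(n_bins) + 2L * fl_bins
  if (n_col < 1) stop("matrix would have zero columns; increase `flank` or `n_bins`")
  m <- matrix(0, nrow(anchors), n_col)
  clipped <- logical(nrow(anchors))

  for (ch in unique(anchors$chrom)) {
    rows <- which(anchors$chrom == ch)
    v <- vals[[ch]]
    k <- length(v)
    if (mode == "reference_point") {
      mid_bin <- as.integer(((anchors$start[rows] + anchors$end[rows]) %/% 2) %/% bw)
      for (jj in seq_along(rows)) {
        bins <- (mid_bin[jj] - fl_bins):(mid_bin[jj] + fl_bins - 1L)
        ok <- bins >= 0 & bins < k
        row <- numeric(n_col)
        row[ok] <- v[bins[ok] + 1L]
        clipped[rows[jj]] <- any(!ok)
        m[rows[jj], ] <- row
      }
    } else {
      Fx <- track_integral_fun(v, g$chroms[[ch]], bw)
      for (jj in seq_along(rows)) {
        i <- rows[jj]
        s <- anchors$start[i]; e <- anchors$end[i]
        if (e <= s) stop("zero-length region at row ", i)
        edges <- seq(s, e, length.out = n_bins + 1)
        body <- diff(Fx(edges)) / diff(edges)
        row <- body
        if (fl_bins > 0) {
          sb <- as.integer(s %/% bw); eb <- as.integer(ceiling(e / bw))
          lbins <- (sb - fl_bins):(sb - 1L)
          rbins <- eb:(eb + fl_bins - 1L)
          lok <- lbins >= 0 & lbins < k
          rok <- rbins >= 0 & rbins < k
          lrow <- numeric(fl_bins); lrow[lok] <- v[lbins[lok] + 1L]
          rrow <- numeric(fl_bins); rrow[rok] <- v[rbins[rok] + 1L]
          clipped[i] <- any(!lok) || any(!rok)
          row <- c(lrow, body, rrow)
        }
        m[i, ] <- row
      }
    }
  }
  flip <- strand == "-"
  if (any(flip)) m[flip, ] <- m[flip, n_col:1, drop = FALSE]
  structure(
    list(values = m, row_id = ids, mode = mode,
         n_bins = if (mode == "scale_regions") as.integer(n_bins) else n_col,
         flank = flank, bin_width = bw, clipped = clipped),
    class = "cr_matrix"
  )
}

#' @export
print.cr_matrix <- function(x, ...) {
  cat("<cr_matrix> ", nrow(x$values), " regions x ", ncol(x$values), " bins (",
      x$mode, ", flank ", x$flank, " bp)\n", sep = "")
  invisible(x)
}

#' @describeIn signal_matrix Long tibble (`row_id`, `bin`, `value`) of a
#'   signal matrix.
#' @param x A `cr_matrix`.
#' @param ... Unused.
#' @export
#' @method tidy cr_matrix
tidy.cr_matrix <- function(x, ...) {
  tibble::tibble(
    row_id = rep(x$row_id, each = ncol(x$values)),
    bin = rep(seq_len(ncol(x$values)), nrow(x$values)),
    value = as.vector(t(x$values))
  )
}

#' Export a signal matrix as TSV with a JSON metadata sidecar
#'
#' @param x A `cr_matrix`.
#' @param path Output TSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(x, path) {
  df <- as.data.frame(x$values)
  names(df) <- paste0("bin_", seq_len(ncol(df)))
  df <- cbind(row_id = x$row_id, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(mode = x$mode, n_bins = x$n_bins, flank = x$flank,
         bin_width = x$bin_width),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' Length-scaled signal abundance per region
#'
#' The row sum of the `scale_regions` matrix with no flanks: each region is
#' resampled to `n_bins` bins and the bin values summed, which equals
#' `n_bins` times the region's per-base mean signal. The result is
#' comparable across regions of different lengths.
#'
#' @param track A track tibble.
#' @param regions A region tibble or gene-model tibble.
#' @param n_bins Number of bins each region is scaled to (default 100).
#' @return Tibble with `id`, `length` (bp) and `abundance`.
#' @export
length_scaled_abundance <- function(track, regions, n_bins = 100) {
  if (inherits(regions, "cr_genes")) regions <- gene_bodies(regions)
  if (!nrow(regions)) stop("`regions` is empty")
  sm <- signal_matrix(track, regions, mode = "scale_regions",
                      n_bins = n_bins, flank = 0)
  tibble::tibble(
    id = sm$row_id,
    length = regions$end - regions$start,
    abundance = rowSums(sm$values)
  )
}

#' Partition genes into deciles by abundance
#'
#' Ranks regions ascending by abundance (ties broken by id) and assigns
#' decile labels 1-10 with sizes differing by at most one.
#'
#' @param table An abundance tibble from [length_scaled_abundance()] (or any
#'   tibble with `id` and `abundance`).
#' @return The table with a `decile` integer column (1 = lowest abundance).
#' @export
decile_partition <- function(table) {
  n <- nrow(table)
  if (n < 10) stop("need at least 10 entries to form deciles")
  ord <- order(table$abundance, table$id)
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  out <- table
  out$decile <- as.integer(ceiling(rank * 10 / n))
  out
}

#' Log2 ratio (M) and average (A) table between two timepoints
#'
#' `M = log2((late + pc) / (early + pc))` and
#' `A = 0.5 * log2((late + pc) * (early + pc))` per matched region.
#'
#' @param early,late Abundance tibbles with matching `id` sets.
#' @param pseudocount Added to both abundances before taking logs
#'   (default 1).
#' @return Tibble with `id`, `early`, `late`, `M`, `A`.
#' @export
log2_ratio_table <- function(early, late, pseudocount = 1) {
  if (!setequal(early$id, late$id) || nrow(early) != nrow(late)) {
    stop("`early` and `late` must cover the same region ids")
  }
  late <- late[match(early$id, late$id), , drop = FALSE]
  e <- early$abundance + pseudocount
  l <- late$abundance + pseudocount
  tibble::tibble(
    id = early$id, early = early$abundance, late = late$abundance,
    M = log2(l / e), A = 0.5 * log2(l * e)
  )
}

#' Quadrant fractions of two joint log2 ratios
#'
#' For claims of the form "61% of peak regions gained one mark while losing
#' the other": the fraction of matched regions in each sign quadrant of two
#' M (log2 ratio) vectors.
#'
#' @param x,y Ratio tibbles from [log2_ratio_table()] with matching ids.
#' @return Tibble with columns `quadrant` (`x_up_y_up`, `x_up_y_down`,
#'   `x_down_y_up`, `x_down_y_down`), `n` and `fraction`; regions with a
#'   zero ratio on either axis are excluded from the denominator.
#' @export
quadrant_fractions <- function(x, y) {
  if (!setequal(x$id, y$id)) stop("`x` and `y` must cover the same region ids")
  y <- y[match(x$id, y$id), , drop = FALSE]
  keep <- x$M != 0 & y$M != 0
  qx <- x$M[keep] > 0; qy <- y$M[keep] > 0
  lab <- paste0(ifelse(qx, "x_up", "x_down"), "_", ifelse(qy, "y_up", "y_down"))
  lev <- c("x_up_y_up", "x_up_y_down", "x_down_y_up", "x_down_y_down")
  counts <- table(factor(lab, levels = lev))
  tibble::tibble(quadrant = lev, n = as.integer(counts),
                 fraction = as.numeric(counts) / max(sum(counts), 1))
}

#' Exonic transcripts-per-million
#'
#' `TPM = 1e6 * rate / sum(rates)` with `rate = count / exonic length in
#' kb`; only exons contribute to the length. TPMs sum to 1e6.
#'
#' @param counts Tibble with `gene_id` and `count` (or a named numeric
#'   vector).
#' @param genes A gene-model tibble covering all counted genes.
#' @return Tibble with `gene_id`, `count`, `exonic_kb`, `tpm`.
#' @export
tpm_exonic <- function(counts, genes) {
  if (is.numeric(counts)) {
    counts <- tibble::tibble(gene_id = names(counts), count = as.double(counts))
  }
  counts <- tibble::as_tibble(counts)
  exlen <- exonic_length(genes)
  missing <- setdiff(counts$gene_id, names(exlen))
  if (length(missing)) stop("no gene model for: ", paste(utils::head(missing, 5), collapse = ", "))
  kb <- exlen[counts$gene_id] / 1000
  if (any(kb <= 0)) stop("exonic length must be > 0")
  if (all(counts$count == 0)) stop("all counts are zero; TPM undefined")
  rate <- counts$count / kb
  tibble::tibble(
    gene_id = counts$gene_id, count = counts$count,
    exonic_kb = unname(kb), tpm = unname(1e6 * rate / sum(rate))
  )
}

#' H3K27me1 vs expression table with repressed-promoter exclusion
#'
#' Pairs each gene's length-scaled gene-body H3K27me1 abundance with its
#' expression (TPM), after excluding genes with an H3K27me3 peak within
#' `exclusion` bp upstream of (or overlapping) the promoter, since such
#' genes are likely repressed through the trimethyl mark rather than
#' fine-tuned by the monomethyl one.
#'
#' @param me1 Abundance tibble of gene-body H3K27me1
#'   ([length_scaled_abundance()] over gene models; ids = gene ids).
#' @param tpm TPM tibble from [tpm_exonic()].
#' @param genes A gene-model tibble.
#' @param k27me3_peaks Region tibble of H3K27me3 peaks.
#' @param promoter_len Promoter length upstream of the TSS in bp
#'   (default 1000).
#' @param exclusion Extra upstream exclusion window in bp (default 5000).
#' @return Tibble (`gene_id`, `me1`, `tpm`) of retained genes; the Pearson
#'   correlation of the pairing is attached as attribute `"pearson_r"` and
#'   reported by [glance()].
#' @export
me1_expression_table <- function(me1, tpm, genes, k27me3_peaks,
                                 promoter_len = 1000, exclusion = 5000) {
  g <- genome_of(genes)
  window <- promoters_of(genes, promoter_len + exclusion)
  excluded <- character()
  if (nrow(k27me3_peaks) && nrow(window)) {
    hits <- GenomicRanges::countOverlaps(regions_to_gr(window),
                                         regions_to_gr(k27me3_peaks))
    excluded <- window$name[hits > 0]
  }
  keep <- setdiff(intersect(me1$id, tpm$gene_id), excluded)
  out <- tibble::tibble(
    gene_id = keep,
    me1 = me1$abundance[match(keep, me1$id)],
    tpm = tpm$tpm[match(keep, tpm$gene_id)]
  )
  r <- if (nrow(out) >= 3 && stats::sd(out$me1) > 0 && stats::sd(out$tpm) > 0) {
    stats::cor(out$me1, out$tpm)
  } else {
    NA_real_
  }
  attr(out, "pearson_r") <- r
  attr(out, "n_excluded") <- length(excluded)
  class(out) <- unique(c("cr_me1_expr", class(out)))
  out
}

#' @export
#' @method glance cr_me1_expr
glance.cr_me1_expr <- function(x, ...) {
  tibble::tibble(n = nrow(x), n_excluded = attr(x, "n_excluded"),
                 pearson_r = attr(x, "pearson_r"))
}

#' Expression metagenes for promoter classes stratified by H2AK119ub dynamics
#'
#' Assigns genes to promoter regions (nearest gene within `max_dist`),
#' crosses the promoter class (H3K4me3-only vs bivalent) with the
#' H2AK119ub dynamics of the promoter region (`all`, `increased`,
#' `unchanged`), and builds an RNA metagene matrix (gene bodies scaled,
#' `flank` bp unscaled on each side) per group and timepoint.
#'
#' @param k4_only,bivalent Region tibbles from [classify_promoters()].
#' @param diff A differential table ([classify_differential()]) whose `id`
#'   column covers the promoter regions.
#' @param genes A gene-model tibble.
#' @param rna_tracks Named list of RNA coverage tracks (e.g. `early`,
#'   `late`).
#' @param flank Unscaled flank in bp (default 2000).
#' @param n_bins Body bins (default 100).
#' @param max_dist Maximum promoter-to-gene distance (default 10000).
#' @return List with `groups` (tibble `gene_id`, `promoter_class`,
#'   `dynamics`) and `matrices` (`matrices[[group]][[track]]`, each a
#'   `cr_matrix`), where group names are e.g. `"bivalent_increased"`.
#' @export
promoter_class_expression <- function(k4_only, bivalent, diff, genes, rna_tracks,
                                      flank = 2000, n_bins = 100,
                                      max_dist = 10000) {
  assign_genes <- function(rs, cls) {
    if (!nrow(rs)) {
      return(tibble::tibble(gene_id = character(), promoter_class = character(),
                            dynamics_class = character()))
    }
    cf <- closest_feature(rs, genes, max_dist = max_dist)
    dyn <- diff$class[match(region_id(rs), diff$id)]
    tibble::tibble(gene_id = cf$gene_id, promoter_class = cls,
                   dynamics_class = dyn)[!is.na(cf$gene_id), , drop = FALSE]
  }
  members <- dplyr::bind_rows(
    assign_genes(k4_only, "k4_only"),
    assign_genes(bivalent, "bivalent")
  )
  members <- dplyr::distinct(members)
  group_def <- tidyr::expand_grid(
    promoter_class = c("k4_only", "bivalent"),
    dynamics = c("all", "increased", "unchanged")
  )
  matrices <- list()
  groups <- list()
  for (i in seq_len(nrow(group_def))) {
    pc <- group_def$promoter_class[i]; dy <- group_def$dynamics[i]
    sel <- members$promoter_class == pc
    if (dy == "increased") sel <- sel & members$dynamics_class %in% "increased"
    if (dy == "unchanged") sel <- sel & members$dynamics_class %in% "unchanged"
    ids <- unique(members$gene_id[sel])
    key <- paste0(pc, "_", dy)
    groups[[key]] <- tibble::tibble(gene_id = ids, promoter_class = pc, dynamics = dy)
    if (length(ids)) {
      sub <- genes[genes$gene_id %in% ids, , drop = FALSE]
      matrices[[key]] <- lapply(rna_tracks, function(tr) {
        signal_matrix(tr, sub, mode = "scale_regions",
                      n_bins = n_bins, flank = flank)
      })
    } else {
      matrices[[key]] <- NULL
    }
  }
  list(groups = dplyr::bind_rows(groups), matrices = matrices)
}
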