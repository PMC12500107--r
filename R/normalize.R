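#' Local maxima of a binned track
#'
#' Bin i is a local maximum iff `value[i] > value[i-1]` and
#' `value[i] >= value[i+1]`, so plateau runs count once at their leftmost
#' bin. Chromosome-boundary bins are never maxima. Maxima with height
#' `<= min_height` are dropped (default 0, so all positive maxima count).
#'
#' @param track A track tibble.
#' @param min_height Drop maxima with height at or below this value.
#' @return Tibble with columns `chrom`, `bin` (0-based bin index), `start`
#'   (bp of bin start) and `height`.
#' @export
find_local_maxima <- function(track, min_height = 0) {
  g <- genome_of(track)
  vals <- track_values(track)
  out <- lapply(names(vals), function(ch) {
    v <- vals[[ch]]
    n <- length(v)
    if (n < 3) {
      return(tibble::tibble(chrom = character(), bin = integer(),
                            start = double(), height = double()))
    }
    i <- 2:(n - 1)
    is_max <- v[i] > v[i - 1] & v[i] >= v[i + 1] & v[i] > min_height
    bins <- i[is_max] - 1L  # to 0-based
    tibble::tibble(chrom = ch, bin = bins,
                   start = bins * g$bin_width, height = v[bins + 1])
  })
  out <- dplyr::bind_rows(out)
  structure(out, genome = g, class = c("cr_maxima", class(out)))
}

#' Build a blacklist of recurrent intergenic artifact maxima
#'
#' Spurious alignment artifacts show up as extreme, intergenic local maxima
#' at the same position in unrelated samples (different antibodies, IgG).
#' A bin is blacklisted when, in at least `recurrence` of the samples, it
#' carries (within +/- 1 bin) an intergenic maximum whose height exceeds
#' that sample's `height_quantile` of all maxima heights. Adjacent
#' blacklisted bins are merged into one region.
#'
#' @param maxima_by_sample Named list (>= 2) of [find_local_maxima()]
#'   outputs, ideally spanning unrelated antibodies and controls.
#' @param genes Gene-model tibble used for the intergenic filter (a
#'   maximum whose bin midpoint lies in a gene body is never blacklisted).
#' @param recurrence Fraction of samples a position must recur in
#'   (default 1, i.e. all samples).
#' @param height_quantile Per-sample height quantile an artifact must
#'   exceed (default 0.999).
#' @return A region tibble of blacklisted bins.
#' @export
build_blacklist <- function(maxima_by_sample, genes, recurrence = 1.0,
                            height_quantile = 0.999) {
  if (!is.list(maxima_by_sample) || length(maxima_by_sample) < 2) {
    stop("need local maxima from at least 2 samples")
  }
  g <- genome_of(maxima_by_sample[[1]])
  gr_genes <- gr_make(genes$chrom, genes$start + 1, genes$end, g)
  candidates <- lapply(maxima_by_sample, function(mx) {
    if (!nrow(mx)) return(mx)
    thr <- stats::quantile(mx$height, height_quantile, names = FALSE, type = 7)
    mx <- mx[mx$height > thr, , drop = FALSE]
    if (!nrow(mx)) return(mx)
    mid <- mx$start + floor(g$bin_width / 2)
    gr <- gr_make(mx$chrom, mid + 1, mid + 1, g)
    mx[GenomicRanges::countOverlaps(gr, gr_genes) == 0, , drop = FALSE]
  })
  n_samp <- length(maxima_by_sample)
  all_pos <- dplyr::distinct(
    dplyr::bind_rows(lapply(candidates, function(d) d[c("chrom", "bin")]))
  )
  if (!nrow(all_pos)) return(empty_regions(g))
  support <- rowSums(vapply(candidates, function(d) {
    if (!nrow(d)) return(rep(FALSE, nrow(all_pos)))
    key <- paste(d$chrom, d$bin)
    keys <- c(key,
              paste(d$chrom, d$bin - 1L),
              paste(d$chrom, d$bin + 1L))
    paste(all_pos$chrom, all_pos$bin) %in% keys
  }, logical(nrow(all_pos))))
  keep <- all_pos[support / n_samp >= recurrence, , drop = FALSE]
  if (!nrow(keep)) return(empty_regions(g))
  rs <- as_regions(
    tibble::tibble(chrom = keep$chrom,
                   start = keep$bin * g$bin_width,
                   end = pmin((keep$bin + 1) * g$bin_width, g$chroms[keep$chrom])),
    g
  )
  gr_to_regions(GenomicRanges::reduce(regions_to_gr(rs)), g)
}

maxima_outside <- function(maxima, blacklist) {
  if (is.null(blacklist) || !nrow(blacklist) || !nrow(maxima)) return(maxima)
  g <- genome_of(maxima)
  gr_m <- gr_make(maxima$chrom, maxima$start + 1,
                  pmin(maxima$start + g$bin_width, g$chroms[maxima$chrom]), g)
  hits <- GenomicRanges::countOverlaps(gr_m, regions_to_gr(blacklist))
  maxima[hits == 0, , drop = FALSE]
}

#' Percentile scaling factor between two tracks
#'
#' The factor that equalizes a target track to a reference track: the
#' ratio of the reference to the target `percentile` (default 99th)
#' local-maxima height, after excluding blacklisted maxima. Multiplying
#' every bin of the target by this factor normalizes it to the reference.
#' Percentiles are computed by linear interpolation on the sorted heights.
#'
#' @param reference,target Track tibbles on the same genome.
#' @param blacklist Optional region tibble of artifact positions to
#'   exclude from the maxima.
#' @param percentile Percentile of maxima heights to match (default 99).
#' @param min_maxima Minimum number of usable maxima required per track
#'   (default 100).
#' @return A `cr_scale` object; see [tidy.cr_scale()].
#' @export
compute_scaling_factor <- function(reference, target, blacklist = NULL,
                                   percentile = 99, min_maxima = 100) {
  check_same_genome(reference, target, "tracks")
  if (percentile <= 0 || percentile >= 100) stop("`percentile` must be in (0, 100)")
  mx_ref <- maxima_outside(find_local_maxima(reference), blacklist)
  mx_tgt <- maxima_outside(find_local_maxima(target), blacklist)
  if (nrow(mx_ref) < min_maxima || nrow(mx_tgt) < min_maxima) {
    stop("too few non-blacklisted local maxima (", nrow(mx_ref), " reference, ",
         nrow(mx_tgt), " target; need >= ", min_maxima, ")")
  }
  q_ref <- stats::quantile(mx_ref$height, percentile / 100, names = FALSE, type = 7)
  q_tgt <- stats::quantile(mx_tgt$height, percentile / 100, names = FALSE, type = 7)
  if (q_tgt <= 0) stop("target percentile height is zero; cannot scale")
  structure(
    list(value = q_ref / q_tgt, percentile = percentile,
         q_reference = q_ref, q_target = q_tgt,
         n_maxima_reference = nrow(mx_ref), n_maxima_target = nrow(mx_tgt)),
    class = "cr_scale"
  )
}

#' @export
print.cr_scale <- function(x, ...) {
  cat("<cr_scale> factor ", format(x$value, digits = 6),
      " (P", x$percentile, " maxima height ", format(x$q_reference, digits = 6),
      " / ", format(x$q_target, digits = 6), ")\n", sep = "")
  invisible(x)
}

#' @describeIn compute_scaling_factor One-row tibble of the factor and the
#'   quantities behind it.
#' @param x A `cr_scale` object.
#' @param ... Unused.
#' @export
#' @method tidy cr_scale
tidy.cr_scale <- function(x, ...) {
  tibble::tibble(
    factor = x$value, percentile = x$percentile,
    q_reference = x$q_reference, q_target = x$q_target,
    n_maxima_reference = x$n_maxima_reference,
    n_maxima_target = x$n_maxima_target
  )
}

#' Apply a scaling factor to a track
#'
#' Multiplies every bin by the factor. Re-deriving the factor against the
#' same reference afterwards yields 1 (the percentile is linear in a
#' global rescaling).
#'
#' @param track A track tibble.
#' @param f A `cr_scale` object or a single positive number.
#' @return The scaled track.
#' @export
apply_scaling <- function(track, f) {
  v <- if (inherits(f, "cr_scale")) f$value else f
  if (!is.numeric(v) || length(v) != 1 || v <= 0) stop("scaling factor must be a single value > 0")
  track$value <- track$value * v
  track
}

#' Spike-in antibody specificity table
#'
#' Converts read counts from a spiked-in modified-nucleosome panel into
#' per-antibody fractions: each antibody's counts are normalized to the
#' total reads derived from all spiked-in modifications for that antibody.
#'
#' @param counts Data frame of non-negative integer counts with one column
#'   `antibody` and one numeric column per spiked-in modification, or a
#'   matrix with antibodies as rownames.
#' @return Long tibble with columns `antibody`, `modification`, `reads`,
#'   `fraction`; fractions sum to 1 within each antibody.
#' @export
spikein_specificity <- function(counts) {
  if (is.matrix(counts)) {
    counts <- tibble::as_tibble(counts, rownames = "antibody")
  }
  counts <- tibble::as_tibble(counts)
  if (!"antibody" %in% names(counts)) stop("`counts` needs an `antibody` column or rownames")
  mods <- setdiff(names(counts), "antibody")
  m <- as.matrix(counts[mods])
  if (any(m < 0)) stop("read counts must be non-negative")
  totals <- rowSums(m)
  if (any(totals == 0)) {
    stop("antibody with all-zero spike-in counts: ",
         paste(counts$antibody[totals == 0], collapse = ", "))
  }
  long <- tidyr::pivot_longer(counts, cols = dplyr::all_of(mods),
                              names_to = "modification", values_to = "reads")
  long$fraction <- long$reads / totals[match(long$antibody, counts$antibody)]
  long
}
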