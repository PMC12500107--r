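#' Base-level intersection of two region sets
#'
#' Returns the maximal intervals covered by at least one region of `a` AND
#' at least one region of `b` (BEDTools `intersect` semantics after merging
#' each set; minimum overlap 1 bp).
#'
#' @param a,b Region tibbles on the same genome.
#' @return A merged, sorted region tibble.
#' @export
intersect_regions <- function(a, b) {
  g <- check_same_genome(a, b, "region sets")
  gr <- GenomicRanges::intersect(
    GenomicRanges::reduce(regions_to_gr(a)),
    GenomicRanges::reduce(regions_to_gr(b))
  )
  gr_to_regions(gr, g)
}

#' Region-level subtraction
#'
#' Keeps whole regions of `a` that have zero overlap with every region of
#' `b`. This matches "peak regions that did not overlap" classification:
#' regions are kept or dropped as units, never clipped.
#'
#' @inheritParams intersect_regions
#' @return The non-overlapping subset of `a`, whole regions intact.
#' @export
subtract_regions <- function(a, b) {
  check_same_genome(a, b, "region sets")
  if (!nrow(a)) return(a)
  if (!nrow(b)) return(a)
  hits <- GenomicRanges::countOverlaps(regions_to_gr(a), regions_to_gr(b))
  a[hits == 0, , drop = FALSE]
}

#' Consensus regions across replicate peak sets
#'
#' Intervals present (>= 1 bp overlap) in every replicate, reported as the
#' iterated base-level intersection.
#'
#' @param replicates List of >= 2 region tibbles on the same genome.
#' @return A merged region tibble.
#' @export
consensus_regions <- function(replicates) {
  if (!is.list(replicates) || length(replicates) < 2) {
    stop("need at least 2 replicate region sets")
  }
  Reduce(intersect_regions, replicates)
}

#' Fraction of regions in each set overlapped by the other
#'
#' @inheritParams intersect_regions
#' @return One-row tibble with columns `frac_a` (fraction of `a` regions
#'   overlapping some region of `b`), `frac_b`, `n_a`, `n_b`.
#' @export
overlap_fraction <- function(a, b) {
  check_same_genome(a, b, "region sets")
  if (!nrow(a) || !nrow(b)) stop("overlap fraction undefined for an empty region set")
  ga <- regions_to_gr(a); gb <- regions_to_gr(b)
  tibble::tibble(
    frac_a = mean(GenomicRanges::countOverlaps(ga, gb) > 0),
    frac_b = mean(GenomicRanges::countOverlaps(gb, ga) > 0),
    n_a = nrow(a),
    n_b = nrow(b)
  )
}

#' Classify promoters as bivalent or H3K4me3-only
#'
#' Bivalent promoters are the base-level intersection of H3K4me3 and
#' H3K27me3 peak regions; H3K4me3-only promoters are the H3K4me3 regions
#' with no H3K27me3 overlap at all (region-level subtraction). The two
#' outputs never overlap each other.
#'
#' @param k4me3,k27me3 Peak region tibbles on the same genome.
#' @return Named list with region tibbles `bivalent` and `k4_only`.
#' @export
classify_promoters <- function(k4me3, k27me3) {
  check_same_genome(k4me3, k27me3, "peak sets")
  list(
    bivalent = intersect_regions(k4me3, k27me3),
    k4_only = subtract_regions(k4me3, k27me3)
  )
}

#' Classify H2AK119ub loci by H3K27me3 co-occupancy
#'
#' Co-occupied (PRC1-PRC2) loci are the base-level intersection of the two
#' peak sets; PRC1-only loci are the H2AK119ub regions with no H3K27me3
#' overlap, kept whole. Every H2AK119ub region is either PRC1-only or
#' contributes to the co-occupied set, never both.
#'
#' @param h2aub,k27me3 Peak region tibbles on the same genome.
#' @return Named list with region tibbles `co_occupied` and `prc1_only`.
#' @export
classify_h2aub_loci <- function(h2aub, k27me3) {
  check_same_genome(h2aub, k27me3, "peak sets")
  list(
    co_occupied = intersect_regions(h2aub, k27me3),
    prc1_only = subtract_regions(h2aub, k27me3)
  )
}

#' Nearest gene within a maximum distance
#'
#' For each region, the nearest gene body by genomic distance (0 when
#' overlapping); regions farther than `max_dist` from every gene get `NA`.
#' Ties are broken deterministically by smaller gene start.
#'
#' @param regions A region tibble.
#' @param genes A gene-model tibble (see [as_genes()]).
#' @param max_dist Maximum distance in bp (default 10000).
#' @return `regions` with columns `gene_id` and `gene_distance` appended.
#' @export
closest_feature <- function(regions, genes, max_dist = 10000) {
  check_same_genome(regions, genes, "regions and genes")
  gene_id <- rep(NA_character_, nrow(regions))
  gene_distance <- rep(NA_real_, nrow(regions))
  if (nrow(regions) && nrow(genes)) {
    gr_r <- regions_to_gr(regions)
    gr_g <- gr_make(genes$chrom, genes$start + 1, genes$end, genome_of(genes))
    hits <- GenomicRanges::distanceToNearest(gr_r, gr_g, select = "all")
    h <- tibble::tibble(
      q = S4Vectors::queryHits(hits),
      s = S4Vectors::subjectHits(hits),
      d = as.double(S4Vectors::mcols(hits)$distance)
    )
    h <- h[h$d <= max_dist, , drop = FALSE]
    if (nrow(h)) {
      h$gstart <- genes$start[h$s]
      h <- h[order(h$q, h$d, h$gstart), , drop = FALSE]
      h <- h[!duplicated(h$q), , drop = FALSE]
      gene_id[h$q] <- genes$gene_id[h$s]
      gene_distance[h$q] <- h$d
    }
  }
  out <- regions
  out$gene_id <- gene_id
  out$gene_distance <- gene_distance
  out
}

#' Label summits as intragenic or intergenic
#'
#' A summit is intragenic iff its midpoint falls within any gene body.
#'
#' @param summits A region tibble of peak summits (1 bp or short regions).
#' @param genes A gene-model tibble.
#' @return `summits` with a `location` column (`"intragenic"` /
#'   `"intergenic"`); the label fractions are attached as attribute
#'   `"fractions"` and available via [glance()].
#' @export
annotate_location <- function(summits, genes) {
  check_same_genome(summits, genes, "summits and genes")
  mid <- floor((summits$start + summits$end) / 2)
  intra <- rep(FALSE, nrow(summits))
  if (nrow(summits) && nrow(genes)) {
    g <- genome_of(genes)
    gr_m <- gr_make(summits$chrom, mid + 1, mid + 1, g)
    gr_g <- gr_make(genes$chrom, genes$start + 1, genes$end, g)
    intra <- GenomicRanges::countOverlaps(gr_m, gr_g) > 0
  }
  out <- summits
  out$location <- ifelse(intra, "intragenic", "intergenic")
  attr(out, "fractions") <- c(
    intragenic = if (nrow(out)) mean(intra) else NA_real_,
    intergenic = if (nrow(out)) mean(!intra) else NA_real_
  )
  class(out) <- unique(c("cr_location", class(out)))
  out
}

#' @export
#' @method glance cr_location
glance.cr_location <- function(x, ...) {
  f <- attr(x, "fractions")
  tibble::tibble(
    n = nrow(x),
    frac_intragenic = f[["intragenic"]],
    frac_intergenic = f[["intergenic"]]
  )
}
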