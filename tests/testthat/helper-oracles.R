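# Brute-force oracles and tiny fixtures shared across the suite.
# The oracles deliberately avoid the package's interval/statistics code
# paths: membership is decided per base, suprema by full enumeration.

tiny_genome <- function(len = c(chr1 = 1e5, chr2 = 5e4), bw = 50) {
  genome_spec(len, bin_width = bw)
}

rand_regions <- function(genome, n, max_len = 2000) {
  chrom <- sample(names(genome$chroms), n, replace = TRUE)
  len <- genome$chroms[chrom]
  start <- floor(runif(n, 0, len - max_len))
  width <- ceiling(runif(n, 1, max_len))
  as_regions(
    tibble::tibble(chrom = chrom, start = start,
                   end = pmin(start + width, len)),
    genome
  )
}

# per-base coverage bitmap of a region set
bitmap <- function(rs, genome) {
  out <- lapply(genome$chroms, function(l) logical(l))
  for (i in seq_len(nrow(rs))) {
    idx <- (rs$start[i] + 1):rs$end[i]
    out[[rs$chrom[i]]][idx] <- TRUE
  }
  out
}

# maximal runs of TRUE -> region tibble
bitmap_to_regions <- function(bm, genome) {
  rows <- list()
  for (ch in names(bm)) {
    r <- rle(bm[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep)) {
      rows[[ch]] <- tibble::tibble(chrom = ch, start = starts[keep],
                                   end = ends[keep])
    }
  }
  if (!length(rows)) return(empty_regions_for_tests(genome))
  as_regions(dplyr::bind_rows(rows), genome)
}

empty_regions_for_tests <- function(genome) {
  as_regions(tibble::tibble(chrom = character(), start = double(),
                            end = double()), genome)
}

oracle_intersect <- function(a, b, genome) {
  ba <- bitmap(a, genome); bb <- bitmap(b, genome)
  bitmap_to_regions(purrr::map2(ba, bb, `&`), genome)
}

# region-level: regions of a with zero per-base overlap against b
oracle_subtract <- function(a, b, genome) {
  bb <- bitmap(b, genome)
  keep <- vapply(seq_len(nrow(a)), function(i) {
    !any(bb[[a$chrom[i]]][(a$start[i] + 1):a$end[i]])
  }, logical(1))
  a[keep, , drop = FALSE]
}

oracle_overlap_fraction <- function(a, b, genome) {
  bb <- bitmap(b, genome); ba <- bitmap(a, genome)
  fa <- mean(vapply(seq_len(nrow(a)), function(i) {
    any(bb[[a$chrom[i]]][(a$start[i] + 1):a$end[i]])
  }, logical(1)))
  fb <- mean(vapply(seq_len(nrow(b)), function(i) {
    any(ba[[b$chrom[i]]][(b$start[i] + 1):b$end[i]])
  }, logical(1)))
  c(fa, fb)
}

regions_equal <- function(x, y) {
  isTRUE(all.equal(
    as.data.frame(x[c("chrom", "start", "end")]),
    as.data.frame(y[c("chrom", "start", "end")]),
    check.attributes = FALSE
  ))
}

# K-S D by enumerating the ECDF difference at every pooled point
brute_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), 0)))
}

# local maxima by an explicit neighborhood scan over one value vector
brute_local_maxima <- function(v, min_height = 0) {
  out <- integer()
  for (i in seq_along(v)) {
    if (i == 1 || i == length(v)) next
    if (v[i] > v[i - 1] && v[i] >= v[i + 1] && v[i] > min_height) out <- c(out, i - 1L)
  }
  out
}

# a track with guaranteed plentiful distinct local maxima
noisy_track <- function(genome, lambda = 5) {
  vals <- lapply(n_bins(genome), function(k) rpois(k, lambda))
  as_track(genome, vals)
}

# per-bin membership of a track's bins in a region set
usable_bins_for_tests <- function(track, regions) {
  g <- attr(track, "genome")
  key <- paste(track$chrom, track$start)
  hit <- rep(FALSE, nrow(track))
  for (i in seq_len(nrow(regions))) {
    bins <- seq(floor(regions$start[i] / g$bin_width),
                ceiling(regions$end[i] / g$bin_width) - 1)
    hit[key %in% paste(regions$chrom[i], bins * g$bin_width)] <- TRUE
  }
  hit
}
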