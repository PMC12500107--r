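#' Build a binned coverage track
#'
#' A track stores one non-negative value per fixed-width genomic bin,
#' complete over every chromosome of its genome (uncovered bins are 0).
#' The user-facing representation is a tibble with one row per bin:
#' `chrom`, `start` (bp of bin start) and `value`.
#'
#' @param genome A `cr_genome`.
#' @param values Named list of numeric vectors, one per chromosome, each of
#'   length `n_bins(genome, chrom)`. Missing chromosomes are filled with 0.
#' @return A track tibble of class `cr_track`.
#' @export
as_track <- function(genome, values = list()) {
  stopifnot(is_genome(genome))
  nb <- n_bins(genome)
  unknown <- setdiff(names(values), names(nb))
  if (length(unknown)) stop("unknown chromosome: ", paste(unknown, collapse = ", "))
  vals <- lapply(names(nb), function(ch) {
    v <- values[[ch]]
    if (is.null(v)) return(numeric(nb[[ch]]))
    v <- as.double(v)
    if (length(v) != nb[[ch]]) {
      stop("chromosome ", ch, " needs ", nb[[ch]], " bins, got ", length(v))
    }
    if (anyNA(v) || any(!is.finite(v))) stop("track values must be finite")
    if (any(v < 0)) stop("track values must be >= 0")
    v
  })
  df <- tibble::tibble(
    chrom = rep(names(nb), nb),
    start = unlist(lapply(nb, function(k) (seq_len(k) - 1) * genome$bin_width),
                   use.names = FALSE),
    value = unlist(vals, use.names = FALSE)
  )
  structure(df, genome = genome, class = c("cr_track", class(df)))
}

#' Per-chromosome value vectors of a track
#'
#' @param track A track tibble.
#' @return Named list of numeric vectors in genome chromosome order.
#' @export
track_values <- function(track) {
  g <- genome_of(track)
  split(track$value, factor(track$chrom, levels = names(g$chroms)))
}

#' Read a bedGraph file into a binned track
#'
#' Intervals need not align to bin boundaries: values are resampled by
#' coverage-weighted mean (an interval covering half a bin contributes half
#' its value to that bin's mean). Uncovered bins are 0. Overlapping
#' bedGraph intervals are rejected as ambiguous.
#'
#' @param path Path to a bedGraph file (chrom, start, end, value).
#' @param genome A `cr_genome`.
#' @return A track tibble.
#' @export
read_bedgraph <- function(path, genome) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(as_track(genome))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4)) {
    stop("malformed bedGraph line ", which(nf < 4)[1], " in ", path,
         ": need 4 tab-separated fields")
  }
  df <- tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1),
    start = suppressWarnings(as.double(vapply(fields, `[[`, "", 2))),
    end = suppressWarnings(as.double(vapply(fields, `[[`, "", 3))),
    value = suppressWarnings(as.double(vapply(fields, `[[`, "", 4)))
  )
  bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$value))
  if (length(bad)) stop("malformed bedGraph line ", bad[1], " in ", path)
  unknown <- setdiff(unique(df$chrom), names(genome$chroms))
  if (length(unknown)) stop("unknown chromosome: ", paste(unknown, collapse = ", "))
  if (any(df$start < 0 | df$start >= df$end | df$end > genome$chroms[df$chrom])) {
    stop("bedGraph interval outside chromosome bounds in ", path)
  }
  vals <- lapply(names(genome$chroms), function(ch) {
    d <- df[df$chrom == ch, , drop = FALSE]
    bin_means_from_intervals(d$start, d$end, d$value,
                             genome$chroms[[ch]], genome$bin_width)
  })
  names(vals) <- names(genome$chroms)
  as_track(genome, vals)
}

# Coverage-weighted mean per bin from sorted disjoint step intervals.
# F(x) = integral of the step function on [0, x); bin mean = dF / bin width,
# where the final bin's width is clipped to the chromosome end so that
# write/read round trips are exact.
bin_means_from_intervals <- function(start, end, value, chrom_len, bw) {
  k <- as.integer(ceiling(chrom_len / bw))
  if (!length(start)) return(numeric(k))
  ord <- order(start)
  start <- start[ord]; end <- end[ord]; value <- value[ord]
  if (any(start[-1] < end[-length(end)])) {
    stop("overlapping bedGraph intervals (ambiguous value)")
  }
  # bin-aligned intervals carry one constant value per covered bin: assign
  # directly so write/read round trips are bitwise exact
  if (all(start %% bw == 0) && all(end %% bw == 0 | end == chrom_len)) {
    v <- numeric(k)
    first <- start %/% bw
    last <- ceiling(end / bw) - 1
    for (i in seq_along(start)) v[(first[i]:last[i]) + 1] <- value[i]
    return(v)
  }
  cum <- c(0, cumsum(value * (end - start)))
  Fx <- function(x) {
    j <- findInterval(x, start)
    out <- numeric(length(x))
    pos <- j > 0
    jj <- j[pos]
    out[pos] <- cum[jj] + value[jj] * pmin(pmax(x[pos] - start[jj], 0), end[jj] - start[jj])
    out
  }
  edges <- pmin((0:k) * bw, chrom_len)
  diff(Fx(edges)) / diff(edges)
}

#' Write a binned track as bedGraph text
#'
#' Runs of equal-valued bins are merged into single intervals and zero bins
#' are left implicit, so `read_bedgraph(write_bedgraph(t, path), genome)`
#' reproduces `t` bitwise.
#'
#' @param track A track tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  g <- genome_of(track)
  vals <- track_values(track)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in names(vals)) {
    v <- vals[[ch]]
    if (!length(v)) next
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    lines <- paste(ch,
                   format_coord(starts_bin[keep] * g$bin_width),
                   format_coord(pmin(ends_bin[keep] * g$bin_width, g$chroms[[ch]])),
                   sprintf("%.17g", r$values[keep]),
                   sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' @export
print.cr_track <- function(x, ...) {
  g <- attr(x, "genome")
  cat("<cr_track> ", nrow(x), " bins of ", g$bin_width, " bp across ",
      length(g$chroms), " chromosome(s)\n", sep = "")
  NextMethod()
}

# Integral of a track's step function over [from, to) in bp, vectorized over
# region endpoints within one chromosome.
track_integral_fun <- function(values, chrom_len, bw) {
  k <- length(values)
  edges <- pmin((0:k) * bw, chrom_len)
  widths <- diff(edges)
  cum <- c(0, cumsum(values * widths))
  function(x) {
    x <- pmin(pmax(x, 0), chrom_len)
    j <- pmin(pmax(findInterval(x, edges), 1), k)
    cum[j] + values[j] * (x - edges[j])
  }
}
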