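#' Define a genome for binned-track analyses
#'
#' Every track, region set and gene model in an analysis refers to one
#' genome: a set of named chromosomes with lengths and a fixed bin width.
#' Coordinates are 0-based half-open (BED convention) throughout the
#' package. Coverage tracks are stored as one value per `bin_width` bp bin;
#' the last bin of a chromosome may be shorter than `bin_width`.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param bin_width Bin width in bp (default 50, the resolution at which
#'   CUT&RUN coverage is typically binned).
#' @return An object of class `cr_genome`.
#' @examples
#' genome_spec(c(chr1 = 1e5, chr2 = 5e4))
#' @export
genome_spec <- function(chrom_lengths, bin_width = 50) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("`chrom_lengths` must be a named vector of chromosome lengths")
  }
  if (anyDuplicated(names(chrom_lengths))) {
    stop("duplicated chromosome names in `chrom_lengths`")
  }
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  if (length(bin_width) != 1 || bin_width <= 0) stop("`bin_width` must be a single value > 0")
  structure(
    list(
      chroms = stats::setNames(as.double(chrom_lengths), names(chrom_lengths)),
      bin_width = as.double(bin_width)
    ),
    class = "cr_genome"
  )
}

#' @export
print.cr_genome <- function(x, ...) {
  cat("<cr_genome> ", length(x$chroms), " chromosome(s), ",
      format(sum(x$chroms), big.mark = ","), " bp, ",
      x$bin_width, " bp bins\n", sep = "")
  invisible(x)
}

is_genome <- function(x) inherits(x, "cr_genome")

#' Number of bins per chromosome
#'
#' @param genome A `cr_genome`.
#' @param chrom Optional chromosome name(s); default all.
#' @return Named integer vector, `ceiling(length / bin_width)` per chromosome.
#' @export
n_bins <- function(genome, chrom = NULL) {
  stopifnot(is_genome(genome))
  len <- if (is.null(chrom)) genome$chroms else genome$chroms[chrom]
  if (anyNA(len)) stop("unknown chromosome: ", paste(chrom[is.na(len)], collapse = ", "))
  stats::setNames(as.integer(ceiling(len / genome$bin_width)), names(len))
}

same_genome <- function(a, b) {
  isTRUE(all.equal(a$chroms, b$chroms)) && isTRUE(a$bin_width == b$bin_width)
}

check_same_genome <- function(a, b, what = "inputs") {
  ga <- attr(a, "genome"); gb <- attr(b, "genome")
  if (is.null(ga) || is.null(gb) || !same_genome(ga, gb)) {
    stop(what, " refer to different genomes")
  }
  invisible(ga)
}

genome_of <- function(x) {
  g <- attr(x, "genome")
  if (is.null(g)) stop("object carries no genome attribute")
  g
}
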