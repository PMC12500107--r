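#' Build a region set from a data frame
#'
#' Region sets hold genomic intervals (peaks, blacklists, CpG islands,
#' promoters) in 0-based half-open coordinates, sorted by (chrom, start).
#'
#' @param df Data frame with columns `chrom`, `start`, `end`, optionally
#'   `name`, `score` and `strand`.
#' @param genome A `cr_genome` the regions must fall inside.
#' @return A sorted tibble of regions with the genome attached.
#' @export
as_regions <- function(df, genome) {
  stopifnot(is_genome(genome))
  df <- tibble::as_tibble(df)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df))) {
    stop("regions need columns chrom, start, end")
  }
  df$chrom <- as.character(df$chrom)
  df$start <- as.double(df$start)
  df$end <- as.double(df$end)
  unknown <- setdiff(unique(df$chrom), names(genome$chroms))
  if (length(unknown)) stop("unknown chromosome: ", paste(unknown, collapse = ", "))
  if (nrow(df)) {
    bad <- df$start < 0 | df$start >= df$end | df$end > genome$chroms[df$chrom]
    if (any(bad)) {
      stop("invalid region(s) at row(s) ", paste(utils::head(which(bad), 5), collapse = ", "),
           ": need 0 <= start < end <= chromosome length")
    }
  }
  ord <- order(match(df$chrom, names(genome$chroms)), df$start, df$end)
  df <- df[ord, , drop = FALSE]
  structure(df, genome = genome, class = c("cr_regions", class(df)))
}

empty_regions <- function(genome) {
  as_regions(tibble::tibble(chrom = character(), start = double(), end = double()),
             genome)
}

#' Read a BED file into a region set
#'
#' Accepts 3+ column BED (chrom, start, end, then optionally name, score,
#' strand). Coordinates are 0-based half-open. Regions exceeding chromosome
#' bounds and unknown chromosomes are rejected.
#'
#' @param path Path to a BED file.
#' @inheritParams as_regions
#' @return A sorted region tibble (see [as_regions()]).
#' @export
read_bed <- function(path, genome) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_regions(genome))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line ", which(nf < 3)[1], " in ", path,
         ": fewer than 3 tab-separated fields")
  }
  starts <- suppressWarnings(as.double(vapply(fields, `[[`, "", 2)))
  ends <- suppressWarnings(as.double(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(starts) | is.na(ends))
  if (length(bad)) {
    stop("malformed BED line ", bad[1], " in ", path, ": non-numeric coordinates")
  }
  df <- tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1),
    start = starts,
    end = ends
  )
  field_k <- function(k) {
    vapply(fields, function(f) if (length(f) >= k) f[[k]] else NA_character_, "")
  }
  if (any(nf >= 4)) df$name <- field_k(4)
  if (any(nf >= 5)) df$score <- suppressWarnings(as.double(field_k(5)))
  if (any(nf >= 6)) {
    s <- field_k(6)
    df$strand <- ifelse(is.na(s), "*", s)
  }
  as_regions(df, genome)
}

#' Write a region set as BED text
#'
#' Inverse of [read_bed()]: `read_bed(write_bed(rs, path), genome)`
#' reproduces `rs` exactly.
#'
#' @param rs A region tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(rs, path) {
  cols <- list(rs$chrom, format_coord(rs$start), format_coord(rs$end))
  has_name <- "name" %in% names(rs)
  if (has_name) cols <- c(cols, list(rs$name))
  if ("score" %in% names(rs)) {
    if (!has_name) cols <- c(cols, list(rep(".", nrow(rs))))
    cols <- c(cols, list(as.character(rs$score)))
  }
  if ("strand" %in% names(rs)) {
    while (length(cols) < 5) cols <- c(cols, list(rep(".", nrow(rs))))
    cols <- c(cols, list(rs$strand))
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Region identifiers
#'
#' The `name` column where present and non-missing, otherwise
#' `"chrom:start-end"`.
#'
#' @param rs A region tibble.
#' @return Character vector of ids, one per region.
#' @export
region_id <- function(rs) {
  auto <- paste0(rs$chrom, ":", format_coord(rs$start), "-", format_coord(rs$end))
  if (!"name" %in% names(rs)) return(auto)
  ifelse(is.na(rs$name) | rs$name == ".", auto, rs$name)
}

regions_to_gr <- function(rs, genome = attr(rs, "genome")) {
  gr_make(rs$chrom, rs$start + 1, rs$end, genome)
}

# all GRanges share the genome's seqlevels so cross-set ops are well-defined
gr_make <- function(chrom, start1, end1, genome) {
  lev <- if (!is.null(genome)) names(genome$chroms) else unique(chrom)
  GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = lev),
    ranges = IRanges::IRanges(start = start1, end = end1)
  )
}

gr_to_regions <- function(gr, genome) {
  as_regions(
    tibble::tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,
      end = as.double(GenomicRanges::end(gr))
    ),
    genome
  )
}
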