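#' Build gene models from a data frame
#'
#' A gene model carries an id, chromosome, strand, gene body span and exon
#' spans (0-based half-open). The transcription start site (TSS) is the
#' body start on the + strand and the body end on the - strand.
#'
#' @param df Data frame with columns `gene_id`, `chrom`, `strand` (`+`/`-`),
#'   `start`, `end`, and `exons`: either a list-column of two-column
#'   data frames (`start`, `end`) or a character column of comma-separated
#'   `start-end` pairs. Missing exons default to the whole gene body.
#' @param genome A `cr_genome`.
#' @return A gene-model tibble sorted by (chrom, start), with a `tss`
#'   column derived from the strand, class `cr_genes`.
#' @export
as_genes <- function(df, genome) {
  stopifnot(is_genome(genome))
  df <- tibble::as_tibble(df)
  need <- c("gene_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(df))) {
    stop("gene models need columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) stop("duplicated gene_id")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df$start <- as.double(df$start)
  df$end <- as.double(df$end)
  unknown <- setdiff(unique(df$chrom), names(genome$chroms))
  if (length(unknown)) stop("unknown chromosome: ", paste(unknown, collapse = ", "))
  if (nrow(df) && any(df$start < 0 | df$start >= df$end | df$end > genome$chroms[df$chrom])) {
    stop("gene body outside chromosome bounds")
  }
  if (!"exons" %in% names(df)) {
    df$exons <- lapply(seq_len(nrow(df)), function(i) {
      tibble::tibble(start = df$start[i], end = df$end[i])
    })
  } else if (is.character(df$exons)) {
    df$exons <- lapply(strsplit(df$exons, ",", fixed = TRUE), function(p) {
      m <- do.call(rbind, strsplit(p, "-", fixed = TRUE))
      tibble::tibble(start = as.double(m[, 1]), end = as.double(m[, 2]))
    })
  }
  for (i in seq_len(nrow(df))) {
    ex <- df$exons[[i]]
    if (!nrow(ex) || any(ex$start < df$start[i] | ex$end > df$end[i] | ex$start >= ex$end)) {
      stop("exons of gene ", df$gene_id[i], " must be non-empty and lie within the gene body")
    }
  }
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  ord <- order(match(df$chrom, names(genome$chroms)), df$start, df$end)
  df <- df[ord, , drop = FALSE]
  structure(df, genome = genome, class = c("cr_genes", class(df)))
}

#' Read gene models from a 6-column table
#'
#' Tab-separated columns: gene_id, chrom, strand, start, end, exons
#' (comma-separated `start-end` pairs, or `.` for a single whole-body exon).
#'
#' @param path Path to the gene table.
#' @param genome A `cr_genome`.
#' @return A gene-model tibble (see [as_genes()]).
#' @export
read_genes <- function(path, genome) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("gene_id", "chrom", "strand", "start", "end", "exons"),
                          colClasses = c("character", "character", "character",
                                         "numeric", "numeric", "character"))
  df <- tibble::as_tibble(df)
  df$exons[df$exons == "."] <- paste0(df$start[df$exons == "."], "-", df$end[df$exons == "."])
  as_genes(df, genome)
}

#' Write gene models as a 6-column table
#'
#' @param genes A gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  exons <- vapply(genes$exons, function(ex) {
    paste(paste0(format_coord(ex$start), "-", format_coord(ex$end)), collapse = ",")
  }, "")
  lines <- paste(genes$gene_id, genes$chrom, genes$strand,
                 format_coord(genes$start), format_coord(genes$end), exons,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Gene body spans as a region set
#'
#' @param genes A gene-model tibble.
#' @return A region tibble with `name` = gene id and `strand`.
#' @export
gene_bodies <- function(genes) {
  rs <- as_regions(
    tibble::tibble(chrom = genes$chrom, start = genes$start, end = genes$end,
                   name = genes$gene_id, strand = genes$strand),
    genome_of(genes)
  )
  rs
}

#' Promoter regions upstream of the TSS
#'
#' The promoter is the `width` bp immediately upstream of the TSS,
#' strand-adjusted: `[tss - width, tss)` on the + strand, `[tss, tss + width)`
#' on the - strand, clipped to the chromosome.
#'
#' @param genes A gene-model tibble.
#' @param width Promoter width in bp (default 1000).
#' @return A region tibble named by gene id.
#' @export
promoters_of <- function(genes, width = 1000) {
  g <- genome_of(genes)
  start <- ifelse(genes$strand == "+", genes$tss - width, genes$tss)
  end <- ifelse(genes$strand == "+", genes$tss, genes$tss + width)
  start <- pmax(start, 0)
  end <- pmin(end, g$chroms[genes$chrom])
  keep <- start < end
  as_regions(
    tibble::tibble(chrom = genes$chrom[keep], start = start[keep], end = end[keep],
                   name = genes$gene_id[keep], strand = genes$strand[keep]),
    g
  )
}

#' Summed exon length per gene
#'
#' @param genes A gene-model tibble.
#' @return Named numeric vector of exonic lengths in bp.
#' @export
exonic_length <- function(genes) {
  stats::setNames(
    vapply(genes$exons, function(ex) sum(ex$end - ex$start), 0),
    genes$gene_id
  )
}
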