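# per-base mean of a track over [start, end), brute force
per_base_mean <- function(track, chrom, start, end) {
  g <- attr(track, "genome")
  v <- track$value[track$chrom == chrom]
  bases <- (start + 1):end
  widths <- pmin(g$bin_width, g$chroms[[chrom]] - (seq_along(v) - 1) * g$bin_width)
  per_base <- rep(v, times = widths)
  mean(per_base[bases])
}

test_that("signal matrices reproduce raw bins and per-base means", {
  g <- tiny_genome()
  set.seed(30)
  tr <- noisy_track(g)

  # uniform track: every cell is the constant
  u <- as_track(g, lapply(n_bins(g), function(k) rep(3.5, k)))
  rs <- rand_regions(g, 10, max_len = 1000)
  sm <- signal_matrix(u, rs, mode = "scale_regions", n_bins = 20, flank = 100)
  expect_true(all(abs(sm$values[!sm$clipped, ] - 3.5) < 1e-8))
  sm <- signal_matrix(u, rs, mode = "reference_point", flank = 200)
  expect_true(all(sm$values[!sm$clipped, ] == 3.5))

  # a bin-aligned region with n_bins = its bin count returns the raw bins
  r1 <- as_regions(tibble::tibble(chrom = "chr1", start = 500, end = 1000), g)
  sm <- signal_matrix(tr, r1, mode = "scale_regions", n_bins = 10, flank = 0)
  expect_equal(as.vector(sm$values),
               tr$value[tr$chrom == "chr1"][11:20])

  # scale_regions bin means equal brute-force per-base means
  set.seed(31)
  rs <- rand_regions(g, 15, max_len = 3000)
  sm <- signal_matrix(tr, rs, mode = "scale_regions", n_bins = 7, flank = 0)
  for (i in seq_len(nrow(rs))) {
    edges <- seq(rs$start[i], rs$end[i], length.out = 8)
    for (b in 1:7) {
      lo <- floor(edges[b]); hi <- floor(edges[b + 1])
      # brute force only at integer-aligned sub-bins
      if (lo == edges[b] && hi == edges[b + 1]) {
        expect_lt(abs(sm$values[i, b] -
                        per_base_mean(tr, rs$chrom[i], lo, hi)), 1e-9)
      }
    }
    expect_lt(abs(mean(sm$values[i, ]) -
                    per_base_mean(tr, rs$chrom[i], rs$start[i], rs$end[i])),
              1e-9)
  }

  # anchors at the chromosome edge are zero-padded and flagged
  r_edge <- as_regions(tibble::tibble(chrom = "chr1", start = 0, end = 100), g)
  sm <- signal_matrix(tr, r_edge, mode = "reference_point", flank = 500)
  expect_true(sm$clipped[1])
  expect_error(signal_matrix(tr, r_edge, flank = 77), "multiple")
})

test_that("strand reversal flips metagene rows exactly", {
  g <- tiny_genome()
  set.seed(32)
  tr <- noisy_track(g)
  gp <- as_genes(tibble::tibble(gene_id = "g", chrom = "chr1", strand = "+",
                                start = 10000, end = 20000), g)
  gm <- as_genes(tibble::tibble(gene_id = "g", chrom = "chr1", strand = "-",
                                start = 10000, end = 20000), g)
  mp <- signal_matrix(tr, gp, mode = "scale_regions", n_bins = 50, flank = 500)
  mm <- signal_matrix(tr, gm, mode = "scale_regions", n_bins = 50, flank = 500)
  expect_identical(mm$values[1, ], rev(mp$values[1, ]))
})

test_that("length-scaled abundance equals n_bins times the per-base mean", {
  g <- tiny_genome()
  set.seed(33)
  tr <- noisy_track(g)

  # uniform signal: abundance = v * n_bins regardless of region length
  u <- as_track(g, lapply(n_bins(g), function(k) rep(2.5, k)))
  rs <- as_regions(tibble::tibble(chrom = "chr1",
                                  start = c(0, 5000, 40000),
                                  end = c(400, 17000, 41000)), g)
  ab <- length_scaled_abundance(u, rs, n_bins = 100)
  expect_equal(ab$abundance, rep(250, 3))

  z <- as_track(g)
  expect_equal(length_scaled_abundance(z, rs)$abundance, rep(0, 3))

  rs <- rand_regions(g, 20, max_len = 2500)
  ab <- length_scaled_abundance(tr, rs, n_bins = 100)
  for (i in seq_len(nrow(rs))) {
    expect_lt(abs(ab$abundance[i] -
                    100 * per_base_mean(tr, rs$chrom[i], rs$start[i], rs$end[i])),
              1e-9)
  }
})

test_that("decile partition is balanced, exhaustive and monotone", {
  ab <- tibble::tibble(id = sprintf("r%03d", 1:100), abundance = rnorm(100))
  dp <- decile_partition(ab)
  expect_equal(as.vector(table(dp$decile)), rep(10, 10))
  for (k in 2:10) {
    expect_gte(min(dp$abundance[dp$decile == k]),
               max(dp$abundance[dp$decile == k - 1]))
  }

  # all-equal values: deterministic id-ordered partition
  ab <- tibble::tibble(id = sprintf("r%03d", 1:50), abundance = 1)
  dp <- decile_partition(ab)
  expect_equal(as.vector(table(dp$decile)), rep(5, 10))
  expect_equal(dp$decile[order(dp$id)], rep(1:10, each = 5))

  # sizes differ by at most one when n is not a multiple of 10
  ab <- tibble::tibble(id = sprintf("r%03d", 1:53), abundance = runif(53))
  dp <- decile_partition(ab)
  expect_lte(diff(range(table(dp$decile))), 1)
  expect_error(decile_partition(ab[1:9, ]), "at least 10")
})

test_that("log2 ratio tables and quadrant fractions count signs correctly", {
  early <- tibble::tibble(id = c("a", "b", "c"), abundance = c(3, 7, 0))
  same <- log2_ratio_table(early, early)
  expect_equal(same$M, rep(0, 3))

  late <- tibble::tibble(id = c("a", "b", "c"), abundance = 4 * c(3, 7, 0))
  rt <- log2_ratio_table(early, late, pseudocount = 1e-9)
  expect_equal(rt$M[rt$id %in% c("a", "b")], c(2, 2), tolerance = 1e-6)

  expect_error(log2_ratio_table(early, late[1:2, ]), "same region ids")

  set.seed(34)
  n <- 200
  x <- tibble::tibble(id = sprintf("r%03d", 1:n),
                      early = runif(n, 0, 50), late = runif(n, 0, 50))
  rx <- log2_ratio_table(x[c("id", "early")] |> dplyr::rename(abundance = early),
                         x[c("id", "late")] |> dplyr::rename(abundance = late))
  y <- tibble::tibble(id = x$id, early = runif(n, 0, 50), late = runif(n, 0, 50))
  ry <- log2_ratio_table(y[c("id", "early")] |> dplyr::rename(abundance = early),
                         y[c("id", "late")] |> dplyr::rename(abundance = late))
  qf <- quadrant_fractions(rx, ry)
  both_up <- sum(rx$M > 0 & ry$M > 0)
  expect_equal(qf$n[qf$quadrant == "x_up_y_up"], both_up)
  expect_equal(sum(qf$fraction), 1)
})

test_that("TPM normalizes by exonic length and sums to 1e6", {
  g <- tiny_genome()
  genes <- as_genes(tibble::tibble(
    gene_id = c("g1", "g2", "g3"), chrom = "chr1", strand = "+",
    start = c(0, 30000, 60000), end = c(10000, 40000, 70000),
    exons = c("0-2000", "30000-32000", "60000-64000")
  ), g)

  one <- tpm_exonic(tibble::tibble(gene_id = "g1", count = 55), genes[1, ])
  expect_equal(one$tpm, 1e6)

  two <- tpm_exonic(tibble::tibble(gene_id = c("g1", "g2"), count = c(10, 10)),
                    genes)
  expect_equal(two$tpm, c(5e5, 5e5))

  set.seed(35)
  counts <- tibble::tibble(gene_id = genes$gene_id, count = rpois(3, 200))
  tp <- tpm_exonic(counts, genes)
  expect_lt(abs(sum(tp$tpm) - 1e6), 1e-6)
  rate <- counts$count / (exonic_length(genes)[counts$gene_id] / 1000)
  expect_equal(tp$tpm, unname(1e6 * rate / sum(rate)))

  expect_error(tpm_exonic(tibble::tibble(gene_id = "g1", count = 0), genes),
               "all counts are zero")
})

test_that("H3K27me3-proximal genes are excluded from the me1/expression pairing", {
  g <- tiny_genome()
  genes <- as_genes(tibble::tibble(
    gene_id = c("g_clear", "g_prom", "g_far5k"), chrom = "chr1",
    strand = "+", start = c(10000, 40000, 70000),
    end = c(20000, 50000, 80000)
  ), g)
  set.seed(36)
  tr <- noisy_track(g)
  me1 <- length_scaled_abundance(tr, genes)
  tpm <- tpm_exonic(tibble::tibble(gene_id = genes$gene_id, count = c(5, 50, 500)),
                    genes)

  none <- me1_expression_table(me1, tpm, genes, empty_regions_for_tests(g))
  expect_setequal(none$gene_id, genes$gene_id)

  # peak overlapping g_prom's promoter, and one 4 kb upstream of g_far5k's
  # promoter (inside the 5 kb exclusion window); g_clear stays
  peaks <- as_regions(tibble::tibble(
    chrom = "chr1", start = c(39200, 64500), end = c(39700, 64900)
  ), g)
  tab <- me1_expression_table(me1, tpm, genes, peaks)
  expect_setequal(tab$gene_id, "g_clear")
  expect_equal(glance(tab)$n_excluded, 2)

  # a peak > 5 kb + promoter upstream is not excluded
  far_peak <- as_regions(tibble::tibble(chrom = "chr1", start = 63000,
                                        end = 63900), g)
  tab <- me1_expression_table(me1, tpm, genes, far_peak)
  expect_true("g_far5k" %in% tab$gene_id)

  # randomized agreement with a brute-force distance check
  set.seed(37)
  for (rep in 1:5) {
    rgenes <- as_genes(tibble::tibble(
      gene_id = sprintf("g%02d", 1:20), chrom = "chr1", strand = sample(c("+", "-"), 20, TRUE),
      start = seq(0, 95000, by = 5000), end = seq(0, 95000, by = 5000) + 3000
    ), g)
    rpeaks <- rand_regions(g, 10, max_len = 800)
    rme1 <- length_scaled_abundance(tr, rgenes)
    rtpm <- tpm_exonic(tibble::tibble(gene_id = rgenes$gene_id,
                                      count = rpois(20, 100) + 1), rgenes)
    tab <- me1_expression_table(rme1, rtpm, rgenes, rpeaks)
    excluded_truth <- vapply(seq_len(nrow(rgenes)), function(i) {
      tss <- rgenes$tss[i]
      win <- if (rgenes$strand[i] == "+") c(tss - 6000, tss) else c(tss, tss + 6000)
      win <- pmax(win, 0)
      any(rpeaks$chrom == rgenes$chrom[i] &
            rpeaks$start < win[2] & rpeaks$end > win[1])
    }, logical(1))
    expect_setequal(tab$gene_id, rgenes$gene_id[!excluded_truth])
  }
})

test_that("promoter-class H2AK119ub gain maps onto reduced late expression", {
  g <- genome_spec(c(chr1 = 2e5), bin_width = 50)
  tss <- seq(10000, 190000, by = 20000)
  genes <- as_genes(tibble::tibble(
    gene_id = sprintf("g%02d", 1:10), chrom = "chr1", strand = "+",
    start = tss, end = tss + 3000
  ), g)
  k4 <- as_regions(tibble::tibble(chrom = "chr1", start = tss - 200,
                                  end = tss + 200,
                                  name = sprintf("k4_%02d", 1:10)), g)
  k27 <- as_regions(tibble::tibble(chrom = "chr1", start = tss[6:10] - 300,
                                   end = tss[6:10] + 100), g)
  pc <- classify_promoters(k4, k27)
  expect_equal(nrow(pc$k4_only), 5)
  expect_equal(nrow(pc$bivalent), 5)

  # genes 1,2 (H3K4me3-only) and 6,7 (bivalent) gain promoter H2AK119ub;
  # their late transcription is halved
  increased_genes <- c("g01", "g02", "g06", "g07")
  rna_track <- function(level) {
    vals <- numeric(n_bins(g, "chr1"))
    for (i in seq_len(nrow(genes))) {
      bins <- (genes$start[i] / 50 + 1):(genes$end[i] / 50)
      vals[bins] <- level[i]
    }
    as_track(g, list(chr1 = vals))
  }
  early_level <- rep(10, 10)
  late_level <- ifelse(genes$gene_id %in% increased_genes, 5, 10)
  rna <- list(early = rna_track(early_level), late = rna_track(late_level))

  class_of_region <- function(rs) {
    inc_tss <- tss[match(increased_genes, genes$gene_id)]
    cls <- vapply(seq_len(nrow(rs)), function(i) {
      hit <- any(rs$start[i] < inc_tss & rs$end[i] > inc_tss - 1000)
      if (hit) "increased" else "unchanged"
    }, "")
    tibble::tibble(id = region_id(rs), class = cls)
  }
  diff <- dplyr::bind_rows(class_of_region(pc$k4_only),
                           class_of_region(pc$bivalent))

  res <- promoter_class_expression(pc$k4_only, pc$bivalent, diff, genes, rna,
                                   flank = 2000)
  grp <- res$groups
  expect_setequal(grp$gene_id[grp$promoter_class == "k4_only" &
                                grp$dynamics == "increased"], c("g01", "g02"))
  expect_setequal(grp$gene_id[grp$promoter_class == "bivalent" &
                                grp$dynamics == "increased"], c("g06", "g07"))
  for (pcls in c("k4_only", "bivalent")) {
    inc <- res$matrices[[paste0(pcls, "_increased")]]
    unc <- res$matrices[[paste0(pcls, "_unchanged")]]
    expect_lt(mean(inc$late$values) / mean(inc$early$values), 1)
    expect_equal(mean(unc$late$values), mean(unc$early$values))
  }

  diff_none <- diff
  diff_none$class <- "unchanged"
  res2 <- promoter_class_expression(pc$k4_only, pc$bivalent, diff_none, genes, rna)
  expect_equal(nrow(res2$groups[res2$groups$dynamics == "increased", ]), 0)
})
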