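test_that("BED reading parses, sorts, validates and round-trips", {
  g <- tiny_genome()
  f <- withr::local_tempfile()

  writeLines("chr1\t0\t100", f)
  rs <- read_bed(f, g)
  expect_equal(nrow(rs), 1)
  expect_equal(c(rs$start, rs$end), c(0, 100))

  writeLines(character(), f)
  expect_equal(nrow(read_bed(f, g)), 0)

  # unsorted input comes back sorted (brute-force sort oracle)
  writeLines(c("chr2\t10\t20", "chr1\t500\t600", "chr1\t0\t100"), f)
  rs <- read_bed(f, g)
  df <- tibble::tibble(chrom = c("chr2", "chr1", "chr1"),
                       start = c(10, 500, 0), end = c(20, 600, 100))
  df <- df[order(match(df$chrom, c("chr1", "chr2")), df$start), ]
  expect_equal(rs$start, df$start)
  expect_equal(rs$chrom, df$chrom)

  writeLines("chr1\t50", f)
  expect_error(read_bed(f, g), "line 1")
  writeLines(c("chr1\t0\t100", "chrX\t0\t100"), f)
  expect_error(read_bed(f, g), "chrX")
  writeLines("chr1\t0\t200000", f)
  expect_error(read_bed(f, g), "chromosome length")

  # round trip, including an empty set and 100 random regions
  set.seed(11)
  for (rs in list(empty_regions_for_tests(g), rand_regions(g, 100))) {
    write_bed(rs, f)
    back <- read_bed(f, g)
    expect_true(regions_equal(rs, back))
  }
})

test_that("bedGraph loading bins by coverage-weighted mean and round-trips", {
  g <- tiny_genome()
  f <- withr::local_tempfile()

  writeLines("chr1\t0\t100\t2.0", f)
  tr <- read_bedgraph(f, g)
  expect_equal(tr$value[1:3], c(2, 2, 0))

  # partial bin coverage: 25 of 50 bp at height 4 -> 2
  writeLines("chr1\t0\t75\t4.0", f)
  tr <- read_bedgraph(f, g)
  expect_equal(tr$value[1:2], c(4, 2))

  # chromosomes absent from the file are all zero
  expect_true(all(tr$value[tr$chrom == "chr2"] == 0))

  writeLines(c("chr1\t0\t100\t1", "chr1\t50\t150\t2"), f)
  expect_error(read_bedgraph(f, g), "overlapping")

  # merged-run writing: [1,1,2] -> two lines; all-zero -> no lines
  t1 <- as_track(g, list(chr1 = c(1, 1, 2, rep(0, n_bins(g, "chr1") - 3))))
  write_bedgraph(t1, f)
  expect_equal(length(readLines(f)), 2)
  expect_equal(readLines(f)[1], "chr1\t0\t100\t1")
  write_bedgraph(as_track(g), f)
  expect_equal(length(readLines(f)), 0)

  # random track round trip is bitwise exact
  set.seed(5)
  tr <- noisy_track(g)
  tr$value <- tr$value * exp(rnorm(nrow(tr)) / 10)  # non-integer values too
  write_bedgraph(tr, f)
  back <- read_bedgraph(f, g)
  expect_identical(back$value, tr$value)
})

test_that("intersect/subtract/consensus/overlap match the per-base bitmap oracle", {
  set.seed(42)
  g <- tiny_genome()
  for (rep in 1:25) {
    a <- rand_regions(g, sample(10:50, 1))
    b <- rand_regions(g, sample(10:50, 1))
    expect_true(regions_equal(intersect_regions(a, b), oracle_intersect(a, b, g)))
    expect_true(regions_equal(subtract_regions(a, b), oracle_subtract(a, b, g)))
    of <- overlap_fraction(a, b)
    expect_equal(c(of$frac_a, of$frac_b), oracle_overlap_fraction(a, b, g))
    c3 <- rand_regions(g, 30)
    cons <- consensus_regions(list(a, b, c3))
    o <- oracle_intersect(a, b, g)
    o <- oracle_intersect(o, c3, g)
    expect_true(regions_equal(cons, o))
  }
})

test_that("interval algebra obeys its algebraic identities", {
  set.seed(7)
  g <- tiny_genome()
  a <- rand_regions(g, 40)
  b <- rand_regions(g, 40)
  empty <- empty_regions_for_tests(g)

  expect_true(regions_equal(intersect_regions(a, b), intersect_regions(b, a)))
  expect_true(regions_equal(subtract_regions(a, empty), a))
  # intersect(a, a) == merge(a)
  merged <- bitmap_to_regions(bitmap(a, g), g)
  expect_true(regions_equal(intersect_regions(a, a), merged))
  expect_equal(nrow(intersect_regions(a, empty)), 0)

  # simple hand cases
  one <- as_regions(tibble::tibble(chrom = "chr1", start = 0, end = 100), g)
  two <- as_regions(tibble::tibble(chrom = "chr1", start = 50, end = 150), g)
  expect_equal(intersect_regions(one, two)$start, 50)
  expect_equal(intersect_regions(one, two)$end, 100)
  expect_equal(nrow(subtract_regions(one, two)), 0)
  far <- as_regions(tibble::tibble(chrom = "chr1", start = 200, end = 300), g)
  expect_true(regions_equal(subtract_regions(one, far), one))

  g2 <- genome_spec(c(chrA = 1000))
  other <- as_regions(tibble::tibble(chrom = "chrA", start = 0, end = 10), g2)
  expect_error(intersect_regions(one, other), "different genomes")
  expect_error(consensus_regions(list(a)), "at least 2")
  expect_error(overlap_fraction(a, empty), "empty")
})

test_that("promoter and H2AK119ub locus classification partition correctly", {
  g <- tiny_genome()
  k4 <- as_regions(tibble::tibble(chrom = "chr1", start = 0, end = 100), g)
  k27 <- as_regions(tibble::tibble(chrom = "chr1", start = 50, end = 150), g)
  pc <- classify_promoters(k4, k27)
  expect_equal(pc$bivalent$start, 50)
  expect_equal(pc$bivalent$end, 100)
  expect_equal(nrow(pc$k4_only), 0)

  empty <- empty_regions_for_tests(g)
  pc <- classify_promoters(k4, empty)
  expect_equal(nrow(pc$bivalent), 0)
  expect_true(regions_equal(pc$k4_only, k4))

  hc <- classify_h2aub_loci(k4, empty)
  expect_true(regions_equal(hc$prc1_only, k4))
  hc <- classify_h2aub_loci(k27, k27)
  expect_equal(nrow(hc$prc1_only), 0)

  # randomized partition property: every input region is either prc1_only
  # or overlaps k27me3; the two outputs never share a base with each other
  set.seed(99)
  for (rep in 1:10) {
    h2 <- rand_regions(g, 30)
    k27 <- rand_regions(g, 30)
    hc <- classify_h2aub_loci(h2, k27)
    overl <- vapply(seq_len(nrow(h2)), function(i) {
      any(bitmap(k27, g)[[h2$chrom[i]]][(h2$start[i] + 1):h2$end[i]])
    }, logical(1))
    expect_equal(nrow(hc$prc1_only), sum(!overl))
    expect_true(regions_equal(hc$prc1_only, oracle_subtract(h2, k27, g)))
    pc <- classify_promoters(h2, k27)
    if (nrow(pc$bivalent) && nrow(pc$k4_only)) {
      both <- purrr::map2(bitmap(pc$bivalent, g), bitmap(pc$k4_only, g), `&`)
      expect_false(any(unlist(both)))
    }
  }
})

test_that("closest_feature matches the all-pairs distance scan", {
  g <- tiny_genome()
  genes <- as_genes(tibble::tibble(
    gene_id = c("gA", "gB", "gC"), chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    start = c(10000, 40000, 1000), end = c(20000, 45000, 9000)
  ), g)

  inside <- as_regions(tibble::tibble(chrom = "chr1", start = 15000, end = 15100), g)
  cf <- closest_feature(inside, genes)
  expect_equal(cf$gene_id, "gA")
  expect_equal(cf$gene_distance, 0)

  far <- as_regions(tibble::tibble(chrom = "chr2", start = 19001, end = 19002), g)
  expect_true(is.na(closest_feature(far, genes)$gene_id))
  near <- as_regions(tibble::tibble(chrom = "chr2", start = 19000, end = 19001), g)
  expect_equal(closest_feature(near, genes)$gene_id, "gC")
  expect_equal(closest_feature(near, genes)$gene_distance, 10000)

  set.seed(21)
  for (rep in 1:10) {
    rs <- rand_regions(g, 25, max_len = 500)
    cf <- closest_feature(rs, genes, max_dist = 10000)
    for (i in seq_len(nrow(rs))) {
      same <- genes[genes$chrom == rs$chrom[i], , drop = FALSE]
      if (!nrow(same)) { expect_true(is.na(cf$gene_id[i])); next }
      d <- pmax(0, pmax(same$start - rs$end[i], rs$start[i] - same$end))
      if (min(d) > 10000) {
        expect_true(is.na(cf$gene_id[i]))
      } else {
        best <- same[d == min(d), , drop = FALSE]
        best <- best[order(best$start), , drop = FALSE]
        expect_equal(cf$gene_id[i], best$gene_id[1])
        expect_equal(cf$gene_distance[i], min(d))
      }
    }
  }
})

test_that("summit location labels match brute-force membership", {
  g <- tiny_genome()
  genes <- as_genes(tibble::tibble(
    gene_id = "gA", chrom = "chr1", strand = "+", start = 1000, end = 5000
  ), g)
  s_in <- as_regions(tibble::tibble(chrom = "chr1", start = 2000, end = 2001), g)
  expect_equal(annotate_location(s_in, genes)$location, "intragenic")
  s_out <- as_regions(tibble::tibble(chrom = "chr2", start = 100, end = 101), g)
  expect_equal(annotate_location(s_out, genes)$location, "intergenic")

  set.seed(3)
  summits <- rand_regions(g, 200, max_len = 2)
  ann <- annotate_location(summits, genes)
  mid <- floor((summits$start + summits$end) / 2)
  truth <- summits$chrom == "chr1" & mid >= 1000 & mid < 5000
  expect_equal(ann$location == "intragenic", truth)
  gl <- glance(ann)
  expect_equal(gl$frac_intragenic, mean(truth))
  expect_equal(gl$frac_intragenic + gl$frac_intergenic, 1)
})

test_that("gene models validate, derive TSS/promoters, and round-trip", {
  g <- tiny_genome()
  genes <- as_genes(tibble::tibble(
    gene_id = c("gP", "gM"), chrom = "chr1", strand = c("+", "-"),
    start = c(10000, 40000), end = c(20000, 45000),
    exons = c("10000-12000,15000-20000", "40000-45000")
  ), g)
  expect_equal(genes$tss, c(10000, 45000))
  expect_equal(unname(exonic_length(genes)), c(7000, 5000))

  pr <- promoters_of(genes, 1000)
  expect_equal(pr$start[pr$name == "gP"], 9000)
  expect_equal(pr$end[pr$name == "gP"], 10000)
  expect_equal(pr$start[pr$name == "gM"], 45000)
  expect_equal(pr$end[pr$name == "gM"], 46000)

  f <- withr::local_tempfile()
  write_genes(genes, f)
  back <- read_genes(f, g)
  expect_equal(back$gene_id, genes$gene_id)
  expect_equal(back$tss, genes$tss)
  expect_equal(exonic_length(back), exonic_length(genes))

  expect_error(as_genes(tibble::tibble(
    gene_id = "bad", chrom = "chr1", strand = "+", start = 100, end = 50
  ), g), "bounds")
  expect_error(as_genes(tibble::tibble(
    gene_id = "bad", chrom = "chr1", strand = "x", start = 100, end = 500
  ), g), "strand")
})
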