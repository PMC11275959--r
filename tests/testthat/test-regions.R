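# Region calling, interval algebra, segregation arithmetic, gene overlap.

make_fitted <- function(chrom, pos, fitted, depth = 80) {
  structure(data.frame(chrom = chrom, pos = pos, fitted = fitted,
                       depth = depth, stringsAsFactors = FALSE),
            class = c("fitted_track", "data.frame"))
}

test_that("tracks below threshold yield no regions", {
  fit <- make_fitted("chr1", 1:100 * 1000L, runif(100, 0, 0.4))
  expect_equal(nrow(call_regions(fit, 0.5, min_len = 1)), 0)
})

test_that("runs shorter than min_len are discarded", {
  fit <- make_fitted("chr1", seq(100L, 9000L, by = 100L), 1)
  expect_equal(nrow(call_regions(fit, 0.5, min_len = 10000)), 0)
  expect_equal(nrow(call_regions(fit, 0.5, min_len = 8000)), 1)
})

test_that("called regions are disjoint, sorted, above threshold, and exact", {
  pos <- seq(1e6, 30e6, by = 1e5)
  val <- rep(0.01, length(pos))
  val[pos >= 10e6 & pos <= 12e6] <- 0.9
  val[pos >= 20e6 & pos <= 20.5e6] <- 0.8
  fit <- make_fitted("chr8", as.integer(pos), val)
  iv <- call_regions(fit, 0.5, min_len = 10000)
  expect_equal(nrow(iv), 2)
  expect_equal(iv$start, c(10e6, 20e6))
  expect_equal(iv$end, c(12e6, 20.5e6))
  expect_true(all(iv$score > 0.5))
  expect_true(all(diff(iv$start) > 0))
  # every run boundary is an evaluation-point position
  expect_true(all(iv$start %in% fit$pos & iv$end %in% fit$pos))
})

test_that("band thresholds call two-sided exceedances by depth", {
  bands <- simulate_delta_ci(50, depth_grid = c(40, 80, 160),
                             replicates = 2000, seed = 5)
  pos <- seq(1e6, 5e6, by = 1e4)
  val <- rep(0, length(pos))
  val[100:150] <- 0.6    # strong positive excursion
  val[300:340] <- -0.6   # and a negative one
  fit <- make_fitted("chr2", as.integer(pos), val)
  iv <- call_regions(fit, bands, level = 0.95, min_len = 10000)
  expect_equal(nrow(iv), 2)
  iv_pos <- call_regions(fit, bands, level = 0.95, side = "positive",
                         min_len = 10000)
  expect_equal(nrow(iv_pos), 1)
})

test_that("interval intersection reproduces the published worked example", {
  a <- data.frame(chrom = "chr8", start = 20961544, end = 25920942)
  b <- data.frame(chrom = "chr8", start = 24280402, end = 26669931)
  iv <- intersect_interval_sets(a, b)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start, 24280402)
  expect_equal(iv$end, 25920942)
  expect_equal(total_length_mb(iv)$mb, 1.64)
})

test_that("interval intersection is commutative, idempotent, and bounded", {
  a <- data.frame(chrom = c("chr1", "chr2"), start = c(100, 5000),
                  end = c(1000, 9000))
  b <- data.frame(chrom = c("chr1", "chr3"), start = c(500, 1),
                  end = c(2000, 10))
  ab <- intersect_interval_sets(a, b)
  ba <- intersect_interval_sets(b, a)
  expect_equal(ab[c("chrom", "start", "end")], ba[c("chrom", "start", "end")])
  aa <- intersect_interval_sets(a, a)
  expect_equal(aa[c("chrom", "start", "end")],
               a[c("chrom", "start", "end")])
  expect_lte(total_length_mb(ab)$mb_exact,
             min(total_length_mb(a)$mb_exact, total_length_mb(b)$mb_exact))
  # disjoint sets
  expect_equal(nrow(intersect_interval_sets(
    data.frame(chrom = "chr1", start = 1, end = 10),
    data.frame(chrom = "chr1", start = 20, end = 30))), 0)
})

test_that("total interval length reproduces the published megabase sums", {
  ed <- data.frame(chrom = "chr8", start = c(15885239, 16941335),
                   end = c(16757732, 25920942))
  expect_equal(total_length_mb(ed)$mb, 9.85)
  expect_equal(total_length_mb(ed[0, ])$mb, 0)
})

test_that("segregation ratios and chi-square match the published counts", {
  a <- segregation_test(386, 64)
  expect_equal(a$ratio, 6.03)
  expect_lt(a$p_value, 0.05)
  b <- segregation_test(628, 62)
  expect_equal(b$ratio, 10.1)
  expect_lt(b$p_value, 0.05)
  perfect <- segregation_test(300, 100)
  expect_equal(perfect$chi2, 0)
  expect_equal(perfect$p_value, 1)
  expect_error(segregation_test(10, 0), "undefined")
})

test_that("gene overlap uses inclusive 1 bp overlap, strand-agnostic", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t200\t.\t+\t.\tID=gA",
    "chr1\tsrc\tgene\t100\t149\t.\t-\t.\tID=gB",
    "chr1\tsrc\tgene\t300\t300\t.\t-\t.\tID=gC"), gff)
  hits <- genes_in_interval(gff, "chr1:150-300")
  expect_setequal(hits, c("gA", "gC"))
})

test_that("gene overlap matches a brute-force scan on a toy annotation", {
  set.seed(51)
  starts <- sort(sample.int(1e6, 10))
  ends <- starts + sample.int(5e4, 10)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               sprintf("chr5\tsrc\tgene\t%d\t%d\t.\t+\t.\tID=g%02d",
                       starts, ends, 1:10)), gff)
  iv <- data.frame(chrom = "chr5", start = 2e5, end = 6e5)
  got <- genes_in_interval(gff, iv)
  want <- sprintf("g%02d", oracle_genes(starts, ends, 2e5, 6e5))
  expect_setequal(got, want)
})

test_that("malformed GFF lines are skipped with a warning", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t100\t200\t.\t+\t.\tID=gA",
               "chr1\tbroken line without tabs",
               "chr1\tsrc\tgene\t400\t500\t.\t+\t.\tID=gB"), gff)
  expect_warning(hits <- genes_in_interval(gff, "chr1:1-1000"),
                 "malformed")
  expect_setequal(hits, c("gA", "gB"))
})

test_that("gene-list intersection keeps first-list order, drops duplicates", {
  expect_equal(intersect_gene_lists(c("A", "B", "C"), c("B", "C", "D")),
               c("B", "C"))
  expect_equal(intersect_gene_lists(c("C", "B", "B"), c("B", "C")),
               c("C", "B"))
  expect_length(intersect_gene_lists(c("A"), c("B")), 0)
})

test_that("the bundled candidate-interval DEG lists share 18 genes", {
  f <- function(x) system.file("extdata", x, package = "bulkmapr")
  a <- read_gene_list(f("deg_c6xc13_synthetic.txt"))
  b <- read_gene_list(f("deg_c13xc6_synthetic.txt"))
  common <- intersect_gene_lists(a, b)
  expect_length(common, 18)
  expect_length(intersect_gene_lists(common, common), 18)
  expect_true(all(startsWith(common, "LOC_Os08g")))
})

test_that("BED output converts coordinates and reads back unchanged", {
  iv <- data.frame(chrom = "chr8", start = 24280402, end = 25920942,
                   score = 0.9, method = "SNP-index", population = "A")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, bed)
  raw <- read.table(bed, sep = "\t")
  expect_equal(raw$V2, 24280401)  # 0-based start on disk
  expect_equal(raw$V3, 25920942)
  back <- read_bed(bed)
  expect_equal(back$start, iv$start)
  expect_equal(back$end, iv$end)
})
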