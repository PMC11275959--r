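# The F2 simulator: Mendelian segregation, recombination, phenotype
# architectures, bulk selection, and depth sampling.

test_that("unlinked markers segregate 1:2:1 and conserve allele frequency", {
  cfg <- sim_config(chromosomes = c(chr1 = 1e4), snp_density = 1e-4,
                    pop_size = 10000, bulk_size = 10,
                    architecture = "none", seed = 3)
  exp <- simulate_f2_population(cfg)
  g <- exp$genotypes[, 1]
  freq <- tabulate(g + 1L, 3L) / length(g)
  sds <- sqrt(c(.25 * .75, .5 * .5, .25 * .75) / length(g))
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 3 * sds))
  # per-marker parent-2 allele frequency ~ 0.5
  expect_lt(abs(mean(g) / 2 - 0.5), 3 * sqrt(0.125 / length(g)))
})

test_that("markers 1 bp apart are completely linked", {
  cfg <- sim_config(chromosomes = c(chr1 = 10), snp_density = 0.2,
                    pop_size = 5000, bulk_size = 10,
                    architecture = "none", seed = 4)
  exp <- simulate_f2_population(cfg)
  stopifnot(nrow(exp$marker_map) >= 2)
  d_bp <- diff(exp$marker_map$pos[1:2])
  expect_lte(d_bp, 10)
  expect_equal(exp$genotypes[, 1], exp$genotypes[, 2])
})

test_that("gamete recombination matches the Haldane map (r = 0.2)", {
  # Haldane distance giving r = 0.2 is d = -log(1 - 0.4)/2 Morgans
  d <- -log(1 - 2 * 0.2) / 2
  set.seed(5)
  gam <- bulkmapr:::.sim_gametes(20000, gpos = c(0.1, 0.1 + d),
                                 glen = 0.1 + d + 0.1)
  r_hat <- mean(gam[, 1] != gam[, 2])  # brute-force recombinant count
  expect_lt(abs(r_hat - 0.2), 3 * sqrt(0.2 * 0.8 / 20000))
})

test_that("Kosambi rescaling reproduces Kosambi recombination fractions", {
  d <- 0.2                      # Morgans
  r_kosambi <- 0.5 * tanh(2 * d)
  gp <- bulkmapr:::.genetic_positions(c(1, 1 + d / (1 / 25e6)),
                                      chrom_len_bp = 2e7 + d / (1 / 25e6),
                                      morgans_per_bp = 1 / 25e6,
                                      map_function = "kosambi")
  set.seed(6)
  gam <- bulkmapr:::.sim_gametes(20000, gp$marker, gp$total)
  r_hat <- mean(gam[, 1] != gam[, 2])
  expect_lt(abs(r_hat - r_kosambi),
            3 * sqrt(r_kosambi * (1 - r_kosambi) / 20000))
})

test_that("recombinant fraction is monotone in map distance", {
  dists <- c(0.02, 0.1, 0.25, 0.5, 1.0)
  set.seed(7)
  r_hat <- vapply(dists, function(d) {
    gam <- bulkmapr:::.sim_gametes(20000, c(0, d), d)
    mean(gam[, 1] != gam[, 2])
  }, 0)
  expect_true(all(diff(r_hat) > 0))
})

test_that("phenotype architectures give the expected segregation ratios", {
  base <- function(arch, causal, pen = 1, seed)
    sim_config(chromosomes = c(chr1 = 1e6, chr2 = 1e6), snp_density = 2e-6,
               pop_size = 20000, bulk_size = 10, causal = causal,
               architecture = arch, penetrance = pen, seed = seed)
  frac <- function(cfg) {
    exp <- assign_phenotypes(simulate_f2_population(cfg))
    mean(exp$phenotypes == "albino")
  }
  tol <- function(p) 3 * sqrt(p * (1 - p) / 20000)

  one <- data.frame(chrom = "chr1", pos = 5e5)
  two <- data.frame(chrom = c("chr1", "chr2"), pos = c(5e5, 5e5))
  expect_lt(abs(frac(base("single_recessive", one, seed = 8)) - 0.25),
            tol(0.25))
  expect_lt(abs(frac(base("duplicate_recessive_two_locus", two,
                          seed = 9)) - 1 / 16), tol(1 / 16))
  expect_lt(abs(frac(base("single_recessive_penetrance", one, pen = 0.5,
                          seed = 10)) - 0.125), tol(0.125))
})

test_that("two-locus architecture demands two causal loci", {
  expect_error(
    sim_config(chromosomes = c(chr1 = 1e6),
               causal = data.frame(chrom = "chr1", pos = 5e5),
               architecture = "duplicate_recessive_two_locus",
               pop_size = 100, bulk_size = 10),
    "requires 2")
})

test_that("config validation rejects off-chromosome causal loci", {
  expect_error(sim_config(chromosomes = c(chr1 = 1e6),
                          causal = data.frame(chrom = "chr9", pos = 10),
                          pop_size = 100, bulk_size = 10),
               "not declared")
  expect_error(sim_config(chromosomes = c(chr1 = 1e6),
                          causal = data.frame(chrom = "chr1", pos = 2e6),
                          pop_size = 100, bulk_size = 10),
               "outside")
  expect_error(sim_config(chromosomes = c(chr1 = 1e6), snp_density = 0,
                          architecture = "none",
                          pop_size = 100, bulk_size = 10),
               "snp_density")
})

test_that("bulk selection takes exact, disjoint, class-pure subsets", {
  cfg <- sim_config(chromosomes = c(chr1 = 1e5), snp_density = 1e-4,
                    pop_size = 110, bulk_size = 50,
                    architecture = "none", seed = 11)
  exp <- simulate_f2_population(cfg)
  exp$phenotypes <- rep(c("albino", "normal"), c(60, 50))
  b <- form_bulks(exp, 50)$bulks
  expect_length(b$albino, 50)
  expect_length(b$normal, 50)
  expect_length(intersect(b$albino, b$normal), 0)
  expect_true(all(exp$phenotypes[b$albino] == "albino"))

  exp$phenotypes <- rep(c("albino", "normal"), c(40, 70))
  expect_error(form_bulks(exp, 50), "albino")
})

test_that("bulk membership is reproducible under a fixed seed", {
  cfg <- sim_config(chromosomes = c(chr1 = 1e5), pop_size = 400,
                    bulk_size = 50, architecture = "none", seed = 12)
  run <- function() {
    set.seed(33)
    form_bulks(assign_phenotypes(simulate_f2_population(cfg)))$bulks
  }
  expect_identical(run(), run())
})

test_that("pooled depths follow the binomial allele model", {
  cfg <- sim_config(chromosomes = c(chr1 = 1e8), snp_density = 1e-4,
                    pop_size = 100, bulk_size = 50, mean_depth = 78,
                    architecture = "none", unlinked = TRUE, seed = 13)
  exp <- assign_phenotypes(simulate_f2_population(cfg))
  # fixed bulk genotypes: all 2 -> alt fraction 1; all 0 -> 0
  exp$bulks <- list(albino = 1:50, normal = 51:100)
  exp$genotypes[1:50, ] <- 2L
  # normal bulk: dosage mean 0.5 (half genotype 0, half genotype 1)
  exp$genotypes[51:75, ] <- 0L
  exp$genotypes[76:100, ] <- 1L
  rec <- sample_read_depths(exp)
  m <- nrow(rec)
  expect_gte(m, 9000)
  expect_true(all(rec$alb_ref == 0))            # f = 1: alt = total depth
  af <- sum(rec$nor_alt) / sum(rec$nor_ref + rec$nor_alt)
  expect_lt(abs(af - 0.25), 3 * sqrt(0.25 * 0.75 / (78 * m)))
  # mean depth within 2% of the configured 78
  expect_lt(abs(mean(rec$alb_ref + rec$alb_alt) - 78), 0.02 * 78)
})

test_that("the full simulated experiment is byte-identical under one seed", {
  cfg <- sim_config(chromosomes = c(chr1 = 1e6), pop_size = 120,
                    bulk_size = 30,
                    causal = data.frame(chrom = "chr1", pos = 5e5),
                    seed = 14)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$exp$genotypes, b$exp$genotypes)
  expect_identical(a$exp$bulks, b$exp$bulks)
  expect_identical(a$records, b$records)
})

test_that("albino bulk is fixed for the albino-parent allele at the causal locus", {
  cfg <- sim_config(chromosomes = c(chr1 = 1e6), snp_density = 1e-5,
                    pop_size = 400, bulk_size = 50,
                    causal = data.frame(chrom = "chr1", pos = 5e5),
                    architecture = "single_recessive", seed = 15)
  exp <- form_bulks(assign_phenotypes(simulate_f2_population(cfg)))
  ci <- which(exp$marker_map$causal)
  # albino iff genotype 0 = homozygous parent-1 (REF) allele
  expect_true(all(exp$genotypes[exp$bulks$albino, ci] == 0L))
})
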