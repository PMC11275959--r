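#' Configuration for a simulated bulked-segregant experiment
#'
#' Bundles every parameter of the synthetic F2 cross: the physical map,
#' marker density, population and bulk sizes, the pooled sequencing depth
#' model, the causal architecture of the recessive phenotype, and the
#' recombination map function.
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp.
#' @param snp_density SNPs per bp (default 1e-4, i.e. one SNP per 10 kb).
#' @param bulk_size individuals sequenced per bulk (default 50).
#' @param pop_size F2 individuals simulated (default 500).
#' @param mean_depth mean pooled reads per SNP per bulk (default 78).
#' @param depth_dispersion negative-binomial size parameter of the depth
#'   distribution; `Inf` gives the Poisson limit. Default 10 (overdispersed,
#'   as short-read depth is in practice).
#' @param causal data.frame with columns `chrom`, `pos` giving causal loci;
#'   may be empty (`NULL`) only with `architecture = "none"`.
#' @param architecture one of `"single_recessive"`,
#'   `"single_recessive_penetrance"`, `"duplicate_recessive_two_locus"`,
#'   or `"none"` (phenotypes independent of genotype; null control).
#' @param penetrance probability of the albino phenotype given the
#'   susceptible genotype (used by `"single_recessive_penetrance"`).
#' @param map_function `"haldane"` (no interference; default) or
#'   `"kosambi"` (applied as a monotone rescaling of genetic distances).
#' @param unlinked if `TRUE`, genotypes are drawn i.i.d. from the 1:2:1
#'   F2 distribution at every marker (all markers mutually unlinked).
#'   Used for null-calibration checks of the confidence bands, which
#'   model independent sites; the default `FALSE` simulates meiosis with
#'   linkage.
#' @param morgans_per_bp physical-to-genetic scaling; default 1 Morgan per
#'   25 Mb.
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(chromosomes = c(chr1 = 5e6), pop_size = 100,
#'                   causal = data.frame(chrom = "chr1", pos = 2.5e6),
#'                   seed = 1)
sim_config <- function(chromosomes,
                       snp_density = 1e-4,
                       bulk_size = 50,
                       pop_size = 500,
                       mean_depth = 78,
                       depth_dispersion = 10,
                       causal = NULL,
                       architecture = c("single_recessive",
                                        "single_recessive_penetrance",
                                        "duplicate_recessive_two_locus",
                                        "none"),
                       penetrance = 1,
                       map_function = c("haldane", "kosambi"),
                       morgans_per_bp = 1 / 25e6,
                       unlinked = FALSE,
                       seed = NULL) {
  architecture <- match.arg(architecture)
  map_function <- match.arg(map_function)
  if (length(chromosomes) == 0L || is.null(names(chromosomes)) ||
      any(!nzchar(names(chromosomes))))
    stop("'chromosomes' must be a non-empty named vector of lengths in bp")
  if (any(chromosomes < 1)) stop("chromosome lengths must be >= 1 bp")
  if (snp_density <= 0) stop("'snp_density' must be > 0")
  if (mean_depth <= 0) stop("'mean_depth' must be > 0")
  if (bulk_size < 1) stop("'bulk_size' must be >= 1")
  if (pop_size < 2 * bulk_size)
    stop("'pop_size' must be at least twice 'bulk_size'")
  if (penetrance < 0 || penetrance > 1) stop("'penetrance' must be in [0,1]")

  if (is.null(causal)) {
    causal <- data.frame(chrom = character(), pos = numeric())
  }
  causal <- as.data.frame(causal)
  if (nrow(causal)) {
    if (!all(c("chrom", "pos") %in% names(causal)))
      stop("'causal' needs columns 'chrom' and 'pos'")
    bad <- !(causal$chrom %in% names(chromosomes))
    if (any(bad))
      stop("causal chromosome not declared: ", causal$chrom[bad][1])
    len <- chromosomes[causal$chrom]
    if (any(causal$pos < 1 | causal$pos > len))
      stop("causal position outside [1, chromosome length]")
  }
  n_needed <- switch(architecture,
                     duplicate_recessive_two_locus = 2L,
                     none = 0L,
                     1L)
  if (nrow(causal) < n_needed)
    stop(sprintf("architecture '%s' requires %d causal locus/loci, got %d",
                 architecture, n_needed, nrow(causal)))

  structure(list(chromosomes = chromosomes, snp_density = snp_density,
                 bulk_size = bulk_size, pop_size = pop_size,
                 mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion,
                 causal = causal, architecture = architecture,
                 penetrance = penetrance, map_function = map_function,
                 morgans_per_bp = morgans_per_bp, unlinked = unlinked,
                 seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", length(x$chromosomes), "chromosome(s),",
      "pop", x$pop_size, "| bulks", x$bulk_size,
      "| depth", x$mean_depth, "| architecture", x$architecture, "\n")
  invisible(x)
}

## Map genetic positions (Morgans) of sorted marker positions. Under the
## Kosambi option each inter-marker gap d is replaced by the Haldane
## distance giving the same recombination fraction as Kosambi's map,
## d' = -log(1 - 2 * (tanh(2 d) / 2)) / 2, so that the interference-free
## crossover process reproduces Kosambi recombination fractions between
## adjacent markers.
.genetic_positions <- function(pos_bp, chrom_len_bp, morgans_per_bp,
                               map_function) {
  g <- pos_bp * morgans_per_bp
  g_len <- chrom_len_bp * morgans_per_bp
  if (map_function == "kosambi") {
    resc <- function(d) {
      r <- 0.5 * tanh(2 * d)          # Kosambi map
      -log(1 - 2 * pmin(r, 0.499999)) / 2  # inverse Haldane
    }
    gaps <- diff(c(0, g, g_len))
    cs <- cumsum(resc(gaps))
    g <- cs[seq_along(g)]
    g_len <- cs[length(cs)]
  }
  list(marker = g, total = g_len)
}

## One chromosome's worth of gametes: n_gametes haplotype vectors (0 =
## parent-1 allele, 1 = parent-2 allele) at the marker genetic positions.
.sim_gametes <- function(n_gametes, gpos, glen) {
  n_mark <- length(gpos)
  out <- matrix(0L, nrow = n_gametes, ncol = n_mark)
  n_xo <- rpois(n_gametes, glen)
  start <- rbinom(n_gametes, 1L, 0.5)
  for (i in seq_len(n_gametes)) {
    if (n_xo[i] == 0L) {
      out[i, ] <- start[i]
    } else {
      xo <- sort(runif(n_xo[i], 0, glen))
      out[i, ] <- (start[i] + findInterval(gpos, xo)) %% 2L
    }
  }
  out
}

#' Simulate an F2 population from a cross of two inbred parents
#'
#' Markers are placed along each chromosome at the configured density (causal
#' positions are always included as markers). Each F2 individual is the union
#' of two independent gametes; each gamete is a mosaic of the two parental
#' haplotypes with a Poisson number of crossovers per chromosome placed
#' uniformly in genetic distance (Haldane model; Kosambi available as a
#' distance rescaling). Genotypes are coded 0/1/2 as the count of parent-2
#' alleles, so unlinked markers segregate 1:2:1.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_experiment`: list with `config`,
#'   `marker_map` (data.frame `chrom`, `pos`, `causal`), `genotypes`
#'   (integer matrix, individuals x markers), and empty slots for
#'   `phenotypes` and `bulks` filled by [assign_phenotypes()] and
#'   [form_bulks()].
#' @export
simulate_f2_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  maps <- lapply(names(config$chromosomes), function(cn) {
    len <- config$chromosomes[[cn]]
    n <- max(1L, round(len * config$snp_density))
    pos <- sort(sample.int(len, min(n, len)))
    cpos <- config$causal$pos[config$causal$chrom == cn]
    pos <- sort(unique(c(pos, as.integer(cpos))))
    data.frame(chrom = cn, pos = pos,
               causal = pos %in% as.integer(cpos))
  })
  marker_map <- do.call(rbind, maps)
  if (nrow(marker_map) == 0L) stop("no markers simulated")

  geno <- matrix(0L, nrow = config$pop_size, ncol = nrow(marker_map))
  if (isTRUE(config$unlinked)) {
    geno[] <- rbinom(length(geno), 2L, 0.5)
    return(structure(list(config = config, marker_map = marker_map,
                          genotypes = geno, phenotypes = NULL,
                          bulks = NULL, truth = config$causal),
                     class = "sim_experiment"))
  }
  for (cn in names(config$chromosomes)) {
    idx <- which(marker_map$chrom == cn)
    gp <- .genetic_positions(marker_map$pos[idx], config$chromosomes[[cn]],
                             config$morgans_per_bp, config$map_function)
    g1 <- .sim_gametes(config$pop_size, gp$marker, gp$total)
    g2 <- .sim_gametes(config$pop_size, gp$marker, gp$total)
    geno[, idx] <- g1 + g2
  }

  structure(list(config = config, marker_map = marker_map,
                 genotypes = geno, phenotypes = NULL, bulks = NULL,
                 truth = config$causal),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("sim_experiment:", nrow(x$genotypes), "F2 individuals,",
      nrow(x$marker_map), "markers on",
      length(unique(x$marker_map$chrom)), "chromosome(s)\n")
  if (!is.null(x$phenotypes))
    cat("  phenotypes:", sum(x$phenotypes == "normal"), "normal :",
        sum(x$phenotypes == "albino"), "albino\n")
  invisible(x)
}

#' Assign albino/normal phenotypes under the configured genetic architecture
#'
#' `single_recessive`: albino iff genotype 0 (homozygous for the
#' albino-parent allele, here parent 1) at the causal locus.
#' `single_recessive_penetrance`: as above, but albino with probability
#' `penetrance` given the susceptible genotype (expected normal:albino of
#' 7:1 at penetrance 0.5).
#' `duplicate_recessive_two_locus`: albino only when homozygous at both
#' causal loci (expected 15:1).
#' `none`: albino with probability 1/4 independent of genotype (null
#' control).
#'
#' @param exp a `sim_experiment` from [simulate_f2_population()].
#' @return the experiment with `phenotypes` filled
#'   (`"normal"`/`"albino"` per individual).
#' @export
assign_phenotypes <- function(exp) {
  stopifnot(inherits(exp, "sim_experiment"))
  cfg <- exp$config
  n <- nrow(exp$genotypes)
  causal_idx <- which(exp$marker_map$causal)
  susceptible <- switch(cfg$architecture,
    none = rep(TRUE, n),
    single_recessive = ,
    single_recessive_penetrance = {
      exp$genotypes[, causal_idx[1]] == 0L
    },
    duplicate_recessive_two_locus = {
      exp$genotypes[, causal_idx[1]] == 0L &
        exp$genotypes[, causal_idx[2]] == 0L
    })
  p <- switch(cfg$architecture,
              none = 0.25,
              single_recessive = 1,
              single_recessive_penetrance = cfg$penetrance,
              duplicate_recessive_two_locus = 1)
  albino <- susceptible & (runif(n) < p)
  exp$phenotypes <- ifelse(albino, "albino", "normal")
  exp
}

#' Select the two extreme bulks
#'
#' Draws a uniformly random subset of exactly `bulk_size` individuals from
#' each phenotype class.
#'
#' @param exp a phenotyped `sim_experiment`.
#' @param bulk_size individuals per bulk; defaults to the configured value.
#' @return the experiment with `bulks`, a list of index vectors
#'   `albino` and `normal` (disjoint by construction).
#' @export
form_bulks <- function(exp, bulk_size = exp$config$bulk_size) {
  stopifnot(inherits(exp, "sim_experiment"))
  if (is.null(exp$phenotypes)) stop("assign phenotypes before forming bulks")
  idx <- split(seq_along(exp$phenotypes), exp$phenotypes)
  for (cls in c("albino", "normal")) {
    have <- length(idx[[cls]])
    if (have < bulk_size)
      stop(sprintf("cannot form %s bulk: need %d individuals, have %d",
                   cls, bulk_size, have))
  }
  exp$bulks <- list(albino = sort(sample(idx$albino, bulk_size)),
                    normal = sort(sample(idx$normal, bulk_size)))
  exp
}

#' Sample pooled read depths and build the SNP record table
#'
#' For every marker and bulk, the total read depth is drawn from a
#' negative-binomial distribution with mean `mean_depth` and size
#' `depth_dispersion` (Poisson when the dispersion is infinite). The
#' parent-2 (ALT) read count is Binomial(total, f), where f is the mean
#' allele dosage / 2 of the bulk's members at that marker. Parents are
#' sequenced as fixed homozygotes (parent 1 REF, parent 2 ALT). Site
#' annotations default to passing values (QUAL 60, QD 25, MQ 60, FS 1);
#' `fail_fraction` > 0 randomly degrades that fraction of sites to failing
#' annotations, for exercising the hard filters.
#'
#' @param exp a `sim_experiment` with bulks formed.
#' @param fail_fraction fraction of sites given failing annotations.
#' @return a `snp_records` data.frame (one row per marker) with columns
#'   `chrom, pos, ref, alt, qual, qd, mq, fs, near_indel, p1_gt, p2_gt,
#'   p1_ref, p1_alt, p2_ref, p2_alt, alb_ref, alb_alt, nor_ref, nor_alt`.
#' @export
sample_read_depths <- function(exp, fail_fraction = 0) {
  stopifnot(inherits(exp, "sim_experiment"))
  if (is.null(exp$bulks)) stop("form bulks before sampling read depths")
  cfg <- exp$config
  m <- nrow(exp$marker_map)

  rdepth <- function(n) {
    if (is.infinite(cfg$depth_dispersion)) rpois(n, cfg$mean_depth)
    else rnbinom(n, size = cfg$depth_dispersion, mu = cfg$mean_depth)
  }

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")

  f_alb <- colMeans(exp$genotypes[exp$bulks$albino, , drop = FALSE]) / 2
  f_nor <- colMeans(exp$genotypes[exp$bulks$normal, , drop = FALSE]) / 2

  d_alb <- rdepth(m); d_nor <- rdepth(m)
  alb_alt <- rbinom(m, d_alb, f_alb); nor_alt <- rbinom(m, d_nor, f_nor)
  d_p1 <- rdepth(m); d_p2 <- rdepth(m)

  rec <- data.frame(
    chrom = exp$marker_map$chrom, pos = exp$marker_map$pos,
    ref = unname(ref), alt = unname(alt),
    qual = 60, qd = 25, mq = 60, fs = 1, near_indel = FALSE,
    p1_gt = "hom_ref", p2_gt = "hom_alt",
    p1_ref = d_p1, p1_alt = 0L, p2_ref = 0L, p2_alt = d_p2,
    alb_ref = d_alb - alb_alt, alb_alt = alb_alt,
    nor_ref = d_nor - nor_alt, nor_alt = nor_alt,
    stringsAsFactors = FALSE)

  if (fail_fraction > 0) {
    k <- which(runif(m) < fail_fraction)
    if (length(k)) {
      rule <- sample(c("qual", "qd", "mq", "fs", "near_indel"),
                     length(k), replace = TRUE)
      rec$qual[k[rule == "qual"]] <- 10
      rec$qd[k[rule == "qd"]] <- 1
      rec$mq[k[rule == "mq"]] <- 20
      rec$fs[k[rule == "fs"]] <- 90
      rec$near_indel[k[rule == "near_indel"]] <- TRUE
    }
  }
  class(rec) <- c("snp_records", "data.frame")
  rec
}

#' Run the whole simulator in one call
#'
#' Convenience wrapper: [simulate_f2_population()], [assign_phenotypes()],
#' [form_bulks()], [sample_read_depths()].
#'
#' @inheritParams simulate_f2_population
#' @param fail_fraction passed to [sample_read_depths()].
#' @return list with `exp` (the `sim_experiment`) and `records`
#'   (the `snp_records` table).
#' @export
simulate_experiment <- function(config, fail_fraction = 0) {
  exp <- simulate_f2_population(config)
  exp <- assign_phenotypes(exp)
  exp <- form_bulks(exp)
  records <- sample_read_depths(exp, fail_fraction = fail_fraction)
  list(exp = exp, records = records)
}
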