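## End-to-end orchestration: simulate (or load) -> filter -> associate ->
## call regions, for one population and for a reciprocal pair.

#' Run the full mapping analysis for one population
#'
#' Executes the whole per-population workflow: obtain SNP records (from a
#' simulation config or a VCF path), apply the site-quality hard filters
#' and the pool-informativeness filters, compute the ED^power and delta
#' SNP-index tracks, fit both with fixed SNP-count windows, derive the ED
#' threshold (median + 3 SD of all fitted values) and the simulated delta
#' confidence bands, and call candidate regions with both methods.
#'
#' @param input a `sim_config` (simulated population) or a VCF file path.
#' @param recessive_parent `"P1"` or `"P2"`.
#' @param window_snps,step_snps window specification for [fit_snpnum()].
#' @param power ED exponent (default 5).
#' @param ci_levels,ci_replicates,ci_depth_grid confidence-band
#'   simulation; see [simulate_delta_ci()].
#' @param ci_level band level used for delta region calls (default 0.99).
#' @param min_len minimum region length in bp.
#' @param ci_seed seed for the band simulation (defaults to the sim
#'   config's seed + 1 when available).
#' @param bands precomputed `confidence_bands` to reuse (skips the band
#'   simulation).
#' @param population tag carried into interval output.
#' @param out_dir optional directory; when given, the filtered VCF,
#'   per-SNP statistics, fitted tracks, intervals (BED) and a JSON
#'   manifest are written there.
#' @return list (class `population_run`) with `records`, `report`,
#'   `stats`, `ed_fit`, `ed_thr`, `ed_regions`, `bands`, `delta_fit`,
#'   `delta_regions`, `manifest`, and `exp` (the simulation, when
#'   simulated).
#' @export
run_population <- function(input,
                           recessive_parent = "P1",
                           window_snps = 101, step_snps = 1,
                           power = 5,
                           ci_levels = c(0.90, 0.95, 0.99),
                           ci_replicates = 10000,
                           ci_depth_grid = 1:200,
                           ci_level = 0.99,
                           min_len = 10000,
                           ci_seed = NULL,
                           bands = NULL,
                           population = "pop",
                           out_dir = NULL) {
  exp <- NULL
  bulk_size <- 50
  if (inherits(input, "sim_config")) {
    sim <- simulate_experiment(input)
    exp <- sim$exp
    records <- sim$records
    bulk_size <- input$bulk_size
    if (is.null(ci_seed) && !is.null(input$seed))
      ci_seed <- input$seed + 1L
  } else if (is.character(input)) {
    records <- read_snp_vcf(input)
  } else {
    records <- input  # pre-built snp_records
  }
  n_in <- nrow(records)

  hard <- apply_hard_filters(records)
  hq <- filter_high_quality(hard$records,
                            recessive_parent = recessive_parent)
  report <- combine_reports(hard$report, hq$report)
  filtered <- hq$records

  stats <- snp_stats(filtered, recessive_parent = recessive_parent)

  ed_tr <- association_track(stats, "ed", power = power)
  ed_fit <- fit_snpnum(ed_tr, window_snps, step_snps)
  ed_thr <- ed_threshold(ed_fit)
  ed_regions <- call_regions(ed_fit, ed_thr, min_len = min_len,
                             method = "ED", population = population)

  if (is.null(bands))
    bands <- simulate_delta_ci(bulk_size, depth_grid = ci_depth_grid,
                               levels = ci_levels,
                               replicates = ci_replicates,
                               seed = ci_seed)
  d_tr <- association_track(stats, "delta")
  delta_fit <- fit_snpnum(d_tr, window_snps, step_snps)
  delta_regions <- call_regions(delta_fit, bands, level = ci_level,
                                side = "two", min_len = min_len,
                                method = "SNP-index",
                                population = population)

  manifest <- list(
    population = population,
    n_input = n_in,
    filter_counts = setNames(as.list(report$rules$removed),
                             report$rules$rule),
    n_filtered = nrow(filtered),
    n_stats = nrow(stats),
    window = c(window_snps = window_snps, step_snps = step_snps),
    power = power,
    ed_threshold = ed_thr$value,
    ci_level = ci_level,
    n_ed_regions = nrow(ed_regions),
    n_delta_regions = nrow(delta_regions))

  res <- structure(list(records = filtered, report = report,
                        stats = stats, ed_fit = ed_fit, ed_thr = ed_thr,
                        ed_regions = ed_regions, bands = bands,
                        delta_fit = delta_fit,
                        delta_regions = delta_regions,
                        manifest = manifest, exp = exp),
                   class = "population_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_vcf(filtered, file.path(out_dir, "filtered.vcf"))
    write.table(stats, file.path(out_dir, "snp_stats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(ed_fit, file.path(out_dir, "ed_fitted.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(delta_fit, file.path(out_dir, "delta_fitted.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_bed(ed_regions, file.path(out_dir, "ed_regions.bed"))
    write_bed(delta_regions, file.path(out_dir, "delta_regions.bed"))
    write.table(as.data.frame(bands), file.path(out_dir, "bands.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.population_run <- function(x, ...) {
  cat("population_run:", x$manifest$population, "-",
      x$manifest$n_input, "SNPs in,", x$manifest$n_filtered,
      "after filtering;", x$manifest$n_ed_regions, "ED region(s),",
      x$manifest$n_delta_regions, "delta region(s)\n")
  invisible(x)
}

#' Combine two reciprocal populations into a final candidate interval
#'
#' Selects each population's candidate intervals according to `policy`
#' (delta regions, the union of ED and delta regions, or their
#' intersection) and intersects the two populations' selections.
#'
#' @param run_a,run_b `population_run` objects.
#' @param policy `"delta"` (default), `"union"` or `"intersect"`.
#' @return list (class `reciprocal_run`) with `intervals` (the final
#'   candidate set), `total_mb`, `policy`, and the two per-population
#'   selections. An empty intersection is a valid result.
#' @export
run_reciprocal <- function(run_a, run_b,
                           policy = c("delta", "union", "intersect")) {
  policy <- match.arg(policy)
  pick <- function(r) {
    switch(policy,
           delta = r$delta_regions,
           union = {
             both <- rbind(r$ed_regions, r$delta_regions)
             if (nrow(both) == 0) both
             else {
               g <- GenomicRanges::reduce(.as_granges(both))
               data.frame(chrom = as.character(
                            GenomicRanges::seqnames(g)),
                          start = GenomicRanges::start(g),
                          end = GenomicRanges::end(g),
                          score = NA_real_, method = "ED+SNP-index",
                          population = r$manifest$population,
                          stringsAsFactors = FALSE)
             }
           },
           intersect = intersect_interval_sets(r$ed_regions,
                                               r$delta_regions))
  }
  sel_a <- pick(run_a); sel_b <- pick(run_b)
  final <- intersect_interval_sets(sel_a, sel_b)
  if (nrow(final) == 0)
    message("reciprocal intersection is empty")
  structure(list(intervals = final,
                 total_mb = total_length_mb(final),
                 policy = policy,
                 selection_a = sel_a, selection_b = sel_b),
            class = "reciprocal_run")
}

#' @export
print.reciprocal_run <- function(x, ...) {
  cat("reciprocal_run (policy:", x$policy, "):", nrow(x$intervals),
      "final interval(s),", x$total_mb$mb, "Mb\n")
  if (nrow(x$intervals))
    print(x$intervals[, c("chrom", "start", "end", "score")])
  invisible(x)
}

#' Generate the small bundled test dataset
#'
#' Writes a two-chromosome simulated experiment of about 1,200 SNPs
#' (200 F2 individuals, bulks of 30, mean depth 78) with a known causal
#' locus, as VCF + ground-truth TSV, plus a ten-gene toy GFF3 around the
#' causal position.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed (default 42).
#' @return named list of written paths, invisibly.
#' @export
make_fixtures <- function(dir, seed = 42) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sim_config(chromosomes = c(chrA = 6e6, chrB = 6e6),
                    snp_density = 1e-4, bulk_size = 30, pop_size = 200,
                    mean_depth = 78,
                    causal = data.frame(chrom = "chrA", pos = 3e6),
                    architecture = "single_recessive", seed = seed)
  sim <- simulate_experiment(cfg)
  vcf <- file.path(dir, "fixture.vcf")
  truth <- file.path(dir, "fixture_truth.tsv")
  gff <- file.path(dir, "fixture_genes.gff3")
  write_vcf(sim$records, vcf, contigs = cfg$chromosomes)
  write_truth(sim$exp, truth)
  starts <- seq(2.5e6, 3.4e6, by = 1e5)
  lines <- c("##gff-version 3",
             sprintf(paste0("chrA\tbulkmapr\tgene\t%d\t%d\t.\t+\t.\t",
                            "ID=toy_gene_%02d;Name=toy_gene_%02d"),
                     as.integer(starts), as.integer(starts + 5e4),
                     seq_along(starts), seq_along(starts)))
  writeLines(lines, gff)
  invisible(list(vcf = vcf, truth = truth, gff = gff, config = cfg))
}
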