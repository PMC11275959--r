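## Per-SNP association statistics for bulked-segregant mapping: the
## Euclidean distance between the two bulks' allele-frequency vectors
## (raised to the fifth power to suppress background noise) and the delta
## SNP-index, plus fixed SNP-count window fitting and simulated null
## confidence bands for the delta statistic.

#' Euclidean distance between two pools' allele-frequency vectors
#'
#' For a biallelic site with pool allele-fraction pairs (f, 1-f) and
#' (g, 1-g), ED = sqrt((f-g)^2 + ((1-f)-(1-g))^2) = sqrt(2) * |f - g|;
#' identical pools score 0 and fully divergent pools sqrt(2).
#'
#' @param pool1,pool2 numeric length-2 allele-fraction vectors, or n x 2
#'   matrices of such rows for vectorised use.
#' @param tol tolerance on each pool's fractions summing to 1.
#' @return ED value(s).
#' @export
#' @examples
#' compute_ed(c(0.9, 0.1), c(0.4, 0.6))  # sqrt(0.5)
compute_ed <- function(pool1, pool2, tol = 1e-9) {
  p1 <- if (is.matrix(pool1)) pool1 else matrix(pool1, ncol = 2)
  p2 <- if (is.matrix(pool2)) pool2 else matrix(pool2, ncol = 2)
  if (ncol(p1) != 2L || ncol(p2) != 2L || nrow(p1) != nrow(p2))
    stop("each pool must supply 2 allele fractions per site")
  if (any(p1 < -tol | p1 > 1 + tol) || any(p2 < -tol | p2 > 1 + tol))
    stop("allele fractions must lie in [0, 1]")
  if (any(abs(rowSums(p1) - 1) > tol) || any(abs(rowSums(p2) - 1) > tol))
    stop("each pool's allele fractions must sum to 1")
  ed <- sqrt(rowSums((p1 - p2)^2))
  if (!is.matrix(pool1)) ed[1] else ed
}

#' Raise a raw association statistic to a power
#'
#' The fifth power of the ED statistic is used as the association value;
#' the transform leaves 0 and 1 fixed and shrinks background values toward
#' zero while preserving strong signals.
#'
#' @param x numeric vector, or an association track (data.frame with a
#'   `raw` column).
#' @param k exponent (default 5).
#' @return same shape as `x` with values raised to `k`.
#' @export
power_transform <- function(x, k = 5) {
  if (is.data.frame(x)) {
    x$raw <- x$raw^k
    x
  } else {
    x^k
  }
}

#' SNP-index of one bulk at one site
#'
#' Fraction of reads carrying the oriented allele. The package orients to
#' the albino-parent allele so the albino bulk's index rises toward 1 at a
#' linked locus.
#'
#' @param ad numeric length-2 `(ref_depth, alt_depth)`, or an n x 2 matrix.
#' @param oriented_allele `"ref"` or `"alt"`: which allele the index
#'   counts.
#' @return index value(s) in \[0, 1\]; `NA` with a warning at zero total
#'   depth (callers exclude such records).
#' @export
compute_snp_index <- function(ad, oriented_allele = c("ref", "alt")) {
  oriented_allele <- match.arg(oriented_allele)
  m <- if (is.matrix(ad)) ad else matrix(ad, ncol = 2)
  if (any(m < 0)) stop("allele depths must be >= 0")
  tot <- rowSums(m)
  num <- if (oriented_allele == "ref") m[, 1] else m[, 2]
  idx <- ifelse(tot >= 1, num / tot, NA_real_)
  if (anyNA(idx)) warning("zero total depth: SNP-index undefined, flagged NA")
  if (!is.matrix(ad)) idx[1] else idx
}

#' Delta SNP-index
#'
#' Difference of the albino bulk's and the normal bulk's SNP-indices.
#' With indices oriented to the albino-parent allele, delta approaches
#' +2/3 at a fully linked recessive locus (albino bulk fixed at 1, normal
#' bulk at 1/3) and 0 at unlinked sites.
#'
#' @param index_albino,index_normal SNP-index values.
#' @return delta in \[-1, 1\].
#' @export
compute_delta <- function(index_albino, index_normal) {
  index_albino - index_normal
}

#' Per-SNP statistics table from filtered records
#'
#' Computes for every record: each bulk's depth, the SNP-index of each bulk
#' oriented to the albino-parent allele, delta, and ED. Records where
#' either bulk has zero depth are excluded (counted in the `n_dropped`
#' attribute).
#'
#' @param records filtered `snp_records`.
#' @param recessive_parent `"P1"` or `"P2"`: parent carrying the albino
#'   allele; fixes the index orientation.
#' @return data.frame `chrom, pos, depth_alb, depth_nor, idx_alb, idx_nor,
#'   delta, ed` with attribute `n_dropped`.
#' @export
snp_stats <- function(records, recessive_parent = c("P1", "P2")) {
  recessive_parent <- match.arg(recessive_parent)
  rec <- as.data.frame(records)
  oriented <- if (recessive_parent == "P1") "ref" else "alt"
  d_alb <- rec$alb_ref + rec$alb_alt
  d_nor <- rec$nor_ref + rec$nor_alt
  ok <- d_alb >= 1 & d_nor >= 1
  rec <- rec[ok, , drop = FALSE]
  d_alb <- d_alb[ok]; d_nor <- d_nor[ok]
  idx_alb <- suppressWarnings(compute_snp_index(
    cbind(rec$alb_ref, rec$alb_alt), oriented))
  idx_nor <- suppressWarnings(compute_snp_index(
    cbind(rec$nor_ref, rec$nor_alt), oriented))
  fa <- rec$alb_alt / d_alb
  fn <- rec$nor_alt / d_nor
  ed <- compute_ed(cbind(fa, 1 - fa), cbind(fn, 1 - fn))
  out <- data.frame(chrom = rec$chrom, pos = rec$pos,
                    depth_alb = d_alb, depth_nor = d_nor,
                    idx_alb = idx_alb, idx_nor = idx_nor,
                    delta = compute_delta(idx_alb, idx_nor), ed = ed,
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Build an association track
#'
#' @param stats output of [snp_stats()].
#' @param statistic `"ed"` (raw ED, to be power-transformed) or
#'   `"delta"`.
#' @param power exponent applied to ED (default 5); ignored for delta.
#' @return data.frame `chrom, pos, raw, depth` (class `assoc_track`);
#'   `depth` is the harmonic mean of the two bulk depths, the effective
#'   depth used for confidence-band lookup.
#' @export
association_track <- function(stats, statistic = c("ed", "delta"),
                              power = 5) {
  statistic <- match.arg(statistic)
  raw <- switch(statistic, ed = stats$ed^power, delta = stats$delta)
  out <- data.frame(chrom = stats$chrom, pos = stats$pos, raw = raw,
                    depth = 2 / (1 / stats$depth_alb + 1 / stats$depth_nor),
                    stringsAsFactors = FALSE)
  o <- order(out$chrom, out$pos)
  out <- out[o, , drop = FALSE]
  if (any(tapply(out$pos, out$chrom, function(p) any(diff(p) <= 0))))
    stop("positions must be strictly increasing within a chromosome")
  rownames(out) <- NULL
  class(out) <- c("assoc_track", "data.frame")
  attr(out, "statistic") <- statistic
  out
}

#' Fixed SNP-count window fitting (SNPNUM smoothing)
#'
#' Fits the raw statistic with windows holding exactly `window_snps`
#' consecutive SNPs (by count, not bp), advancing by `step_snps`. Each
#' window's fitted value is the mean of its raw values, assigned to the
#' window's median SNP position. Chromosomes with fewer SNPs than the
#' window yield no fitted values there (with a message).
#'
#' @param track an `assoc_track`.
#' @param window_snps SNPs per window (odd values give a well-defined
#'   median position; default 101).
#' @param step_snps step between window starts (default 1).
#' @return data.frame `chrom, pos, fitted, depth, start_pos, end_pos`
#'   (class `fitted_track`); `depth` is the mean effective depth over the
#'   window, `start_pos`/`end_pos` the window's outer SNP positions.
#' @export
fit_snpnum <- function(track, window_snps = 101, step_snps = 1) {
  stopifnot(window_snps >= 1, step_snps >= 1)
  pieces <- lapply(split(seq_len(nrow(track)), track$chrom), function(i) {
    n <- length(i)
    if (n < window_snps) {
      message("chromosome ", track$chrom[i[1]], ": ", n,
              " SNPs < window of ", window_snps, "; no fitted values")
      return(NULL)
    }
    starts <- seq.int(1L, n - window_snps + 1L, by = step_snps)
    fullmean <- data.table::frollmean(track$raw[i], n = window_snps,
                                      align = "left")
    fulldepth <- data.table::frollmean(track$depth[i], n = window_snps,
                                       align = "left")
    med <- starts + (window_snps - 1L) %/% 2L
    data.frame(chrom = track$chrom[i[1]],
               pos = track$pos[i][med],
               fitted = fullmean[starts],
               depth = fulldepth[starts],
               start_pos = track$pos[i][starts],
               end_pos = track$pos[i][starts + window_snps - 1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(chrom = character(), pos = integer(),
                      fitted = numeric(), depth = numeric(),
                      start_pos = integer(), end_pos = integer())
  rownames(out) <- NULL
  class(out) <- c("fitted_track", "data.frame")
  attr(out, "window_spec") <- c(window = window_snps, step = step_snps)
  attr(out, "statistic") <- attr(track, "statistic")
  out
}

#' Genome-wide ED association threshold
#'
#' Threshold = median of all fitted values (all chromosomes pooled) plus
#' three standard deviations (n - 1 denominator).
#'
#' @param fitted a `fitted_track` or a numeric vector of fitted values.
#' @return list (class `ed_threshold`) with `value`, `median`, `sd`.
#' @export
ed_threshold <- function(fitted) {
  x <- if (is.data.frame(fitted)) fitted$fitted else fitted
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("need at least 2 fitted values")
  m <- median(x); s <- sd(x)
  structure(list(value = m + 3 * s, median = m, sd = s),
            class = "ed_threshold")
}

#' @export
print.ed_threshold <- function(x, ...) {
  cat(sprintf("ED threshold = median + 3*SD = %.6g (median %.6g, SD %.6g)\n",
              x$value, x$median, x$sd))
  invisible(x)
}

#' Simulate null confidence bands for the delta SNP-index
#'
#' Under the null of no linkage, each bulk's true allele frequency at a
#' site is the mean dosage/2 of `bulk_size` F2 individuals drawn from the
#' 1:2:1 genotype distribution — equivalently Binomial(2*bulk_size, 1/2) /
#' (2*bulk_size) — and its observed index is Binomial(depth, freq)/depth.
#' For every depth on the grid, `replicates` null deltas are drawn and
#' their two-sided empirical quantiles at each confidence level form the
#' bands.
#'
#' @param bulk_size individuals per bulk.
#' @param depth_grid integer depths to tabulate (default 1:200).
#' @param levels confidence levels (default 0.90, 0.95, 0.99).
#' @param replicates null draws per depth (>= 1000; default 10000).
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @return object of class `confidence_bands`: data.frame
#'   `depth, level, lower, upper` plus simulation metadata attributes.
#' @export
simulate_delta_ci <- function(bulk_size, depth_grid = 1:200,
                              levels = c(0.90, 0.95, 0.99),
                              replicates = 10000, seed = NULL) {
  stopifnot(bulk_size >= 1, replicates >= 1000, all(depth_grid >= 1))
  if (!is.null(seed)) set.seed(seed)
  depth_grid <- sort(unique(as.integer(depth_grid)))
  rows <- vector("list", length(depth_grid))
  for (j in seq_along(depth_grid)) {
    d <- depth_grid[j]
    f1 <- rbinom(replicates, 2L * bulk_size, 0.5) / (2 * bulk_size)
    f2 <- rbinom(replicates, 2L * bulk_size, 0.5) / (2 * bulk_size)
    delta <- rbinom(replicates, d, f1) / d - rbinom(replicates, d, f2) / d
    qs <- lapply(levels, function(lv)
      quantile(delta, c((1 - lv) / 2, (1 + lv) / 2), names = FALSE))
    rows[[j]] <- data.frame(depth = d, level = levels,
                            lower = vapply(qs, `[`, 0, 1),
                            upper = vapply(qs, `[`, 0, 2))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            class = c("confidence_bands", "data.frame"),
            bulk_size = bulk_size, population = "F2",
            replicates = replicates, seed = seed)
}

#' Look up a confidence band at arbitrary depths
#'
#' Linear interpolation on the simulated depth grid; depths outside the
#' grid are clamped to its ends.
#'
#' @param bands a `confidence_bands` object.
#' @param depth numeric vector of effective depths.
#' @param level one of the simulated confidence levels.
#' @return data.frame `lower, upper`, one row per depth.
#' @export
band_at <- function(bands, depth, level = 0.95) {
  b <- bands[abs(bands$level - level) < 1e-9, , drop = FALSE]
  if (nrow(b) == 0)
    stop("level ", level, " was not simulated")
  d <- pmin(pmax(depth, min(b$depth)), max(b$depth))
  data.frame(
    lower = approx(b$depth, b$lower, xout = d, rule = 2)$y,
    upper = approx(b$depth, b$upper, xout = d, rule = 2)$y)
}
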