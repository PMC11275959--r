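## Candidate-region calling and interval/genetics arithmetic. Coordinates
## are 1-based inclusive throughout (VCF/GFF convention); BED output is
## converted at the file boundary.

.empty_intervals <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             score = numeric(), method = character(),
             population = character(), stringsAsFactors = FALSE)
}

#' Call candidate regions from a fitted track
#'
#' Maximal runs of consecutive evaluation points whose fitted value exceeds
#' the threshold become intervals spanning the first to the last exceeding
#' SNP position. The threshold is either a scalar (ED-style; exceedance is
#' `fitted > value`) or simulated confidence bands (delta-style; matched to
#' each point's effective depth, two-sided by default). Runs separated by
#' fewer than `gap_snps` non-exceeding points are merged; intervals shorter
#' than `min_len` bp are discarded.
#'
#' @param fitted a `fitted_track`.
#' @param threshold scalar threshold, an `ed_threshold`, or a
#'   `confidence_bands` object.
#' @param level confidence level used when `threshold` is bands.
#' @param side `"two"` (default), `"positive"` or `"negative"` exceedance
#'   for band thresholds.
#' @param min_len minimum interval length in bp (default 10000).
#' @param gap_snps merge runs separated by fewer than this many
#'   non-exceeding points (default 1: no merging).
#' @param method,population tags carried into the output.
#' @return data.frame of intervals `chrom, start, end, score, method,
#'   population`, disjoint and sorted; `score` is the peak fitted value
#'   (largest magnitude) in the run.
#' @export
call_regions <- function(fitted, threshold, level = 0.95,
                         side = c("two", "positive", "negative"),
                         min_len = 10000, gap_snps = 1,
                         method = "", population = "") {
  side <- match.arg(side)
  if (nrow(fitted) == 0) return(.empty_intervals())
  if (inherits(threshold, "ed_threshold")) threshold <- threshold$value
  if (inherits(threshold, "confidence_bands")) {
    bb <- band_at(threshold, fitted$depth, level = level)
    exceed <- switch(side,
                     two = fitted$fitted > bb$upper |
                       fitted$fitted < bb$lower,
                     positive = fitted$fitted > bb$upper,
                     negative = fitted$fitted < bb$lower)
  } else {
    exceed <- fitted$fitted > threshold
  }
  exceed[is.na(exceed)] <- FALSE

  pieces <- lapply(split(seq_len(nrow(fitted)), fitted$chrom), function(i) {
    e <- exceed[i]
    if (!any(e)) return(NULL)
    r <- rle(e)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    if (gap_snps > 1 && nrow(runs) > 1) {
      merged <- runs[1, , drop = FALSE]
      for (k in 2:nrow(runs)) {
        gap <- runs$start[k] - merged$end[nrow(merged)] - 1L
        if (gap < gap_snps) merged$end[nrow(merged)] <- runs$end[k]
        else merged <- rbind(merged, runs[k, ])
      }
      runs <- merged
    }
    data.frame(chrom = fitted$chrom[i[1]],
               start = fitted$pos[i][runs$start],
               end = fitted$pos[i][runs$end],
               score = vapply(seq_len(nrow(runs)), function(k) {
                 v <- fitted$fitted[i][runs$start[k]:runs$end[k]]
                 v[which.max(abs(v))]
               }, 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) return(.empty_intervals())
  out <- out[out$end - out$start + 1 >= min_len, , drop = FALSE]
  if (nrow(out) == 0) return(.empty_intervals())
  out$method <- method
  out$population <- population
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.as_granges <- function(iv, seqlevels = unique(iv$chrom)) {
  GenomicRanges::GRanges(factor(iv$chrom, levels = seqlevels),
                         IRanges::IRanges(start = iv$start, end = iv$end))
}

#' Intersect two interval sets
#'
#' Pairwise overlaps of intervals on matching chromosomes, each clipped to
#' `[max(starts), min(ends)]`; empty overlaps are dropped. The score of a
#' clipped interval is the larger of its two parents' scores.
#'
#' @param a,b interval data.frames (as from [call_regions()]).
#' @return interval data.frame.
#' @export
intersect_interval_sets <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(.empty_intervals())
  lev <- unique(c(a$chrom, b$chrom))
  ga <- .as_granges(a, lev); gb <- .as_granges(b, lev)
  h <- GenomicRanges::findOverlaps(ga, gb)
  if (length(h) == 0) return(.empty_intervals())
  qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
  p <- GenomicRanges::pintersect(ga[qi], gb[si])
  sa <- if ("score" %in% names(a)) a$score[qi] else NA_real_
  sb <- if ("score" %in% names(b)) b$score[si] else NA_real_
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(p)),
                    start = GenomicRanges::start(p),
                    end = GenomicRanges::end(p),
                    score = pmax(sa, sb, na.rm = TRUE),
                    method = paste0(unique(c(a$method, b$method)),
                                    collapse = "+")[1],
                    population = "intersection",
                    stringsAsFactors = FALSE)
  out <- unique(out[order(out$chrom, out$start), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Total interval length in megabases
#'
#' Length of an interval is `end - start + 1` (1-based inclusive).
#'
#' @param intervals interval data.frame.
#' @return list with `mb` (rounded half-up to 2 decimals, for reporting)
#'   and `mb_exact`.
#' @export
total_length_mb <- function(intervals) {
  x <- if (nrow(intervals)) sum(intervals$end - intervals$start + 1) / 1e6
       else 0
  list(mb = floor(x * 100 + 0.5) / 100, mb_exact = x)
}

#' Test a segregation ratio against an expected Mendelian ratio
#'
#' Pearson chi-square (1 df) of observed normal:albino counts against the
#' expected ratio (default 3:1). The reported ratio is normal/albino to 3
#' significant figures.
#'
#' @param n_normal,n_albino observed counts.
#' @param expected expected ratio as a length-2 vector (normal, albino).
#' @return list (class `segregation_result`) with `n_normal`, `n_albino`,
#'   `ratio` (3 sig. figs), `ratio_exact`, `chi2`, `df`, `p_value`.
#' @export
#' @examples
#' segregation_test(386, 64)  # 6.03:1, rejects 3:1
segregation_test <- function(n_normal, n_albino, expected = c(3, 1)) {
  if (n_normal < 0 || n_albino < 0) stop("counts must be >= 0")
  if (n_albino == 0)
    stop("zero albino count: segregation ratio undefined")
  ht <- suppressWarnings(
    chisq.test(c(n_normal, n_albino), p = expected / sum(expected)))
  structure(list(n_normal = n_normal, n_albino = n_albino,
                 ratio = signif(n_normal / n_albino, 3),
                 ratio_exact = n_normal / n_albino,
                 chi2 = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = unname(ht$p.value)),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("%d normal : %d albino = %s:1 (chi2 = %.2f, df = %d, p = %.3g)\n",
              x$n_normal, x$n_albino, format(x$ratio), x$chi2, x$df,
              x$p_value))
  invisible(x)
}

#' Parse an interval string like "chr8:24280402-25920942"
#'
#' @param x interval string (1-based inclusive), or a 1-row interval
#'   data.frame (returned unchanged).
#' @return 1-row interval data.frame.
#' @export
parse_interval <- function(x) {
  if (is.data.frame(x)) return(x)
  m <- regmatches(x, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", x))[[1]]
  if (length(m) != 4) stop("cannot parse interval: ", x)
  num <- function(s) as.numeric(gsub(",", "", s, fixed = TRUE))
  data.frame(chrom = m[2], start = num(m[3]), end = num(m[4]),
             stringsAsFactors = FALSE)
}

#' Genes overlapping an interval
#'
#' Reads gene features from a GFF3 file and returns the identifiers of
#' genes whose span overlaps the interval by at least 1 bp, strand
#' ignored. Lines with fewer than 9 tab-separated fields are skipped with
#' a warning.
#'
#' @param gff path to a GFF3 file, or a `GRanges` of gene features.
#' @param interval interval string or 1-row data.frame (1-based
#'   inclusive).
#' @param feature_type GFF3 `type` to keep (default `"gene"`).
#' @return character vector of gene IDs (the `ID` attribute, falling back
#'   to `Name`).
#' @export
genes_in_interval <- function(gff, interval, feature_type = "gene") {
  iv <- parse_interval(interval)
  if (is.character(gff)) {
    lines <- readLines(gff)
    nfields <- vapply(strsplit(lines, "\t", fixed = TRUE), length, 0L)
    blank <- !nzchar(trimws(lines))
    keep <- grepl("^#", lines) | blank | nfields >= 9L
    if (any(!keep)) {
      warning(sum(!keep), " malformed GFF line(s) skipped")
      tmp <- tempfile(fileext = ".gff3")
      writeLines(lines[keep], tmp)
      gff <- tmp
    }
    gr <- rtracklayer::import(gff, format = "gff3")
  } else {
    gr <- gff
  }
  if ("type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[gr$type == feature_type]
  target <- GenomicRanges::GRanges(
    iv$chrom, IRanges::IRanges(iv$start, iv$end))
  hits <- GenomicRanges::findOverlaps(gr, target, ignore.strand = TRUE)
  g <- gr[unique(S4Vectors::queryHits(hits))]
  ids <- if ("ID" %in% names(S4Vectors::mcols(g))) g$ID else NULL
  if (is.null(ids) && "Name" %in% names(S4Vectors::mcols(g)))
    ids <- g$Name
  as.character(ids)
}

#' Intersect two gene lists
#'
#' Set intersection preserving the order of the first list, duplicates
#' collapsed.
#'
#' @param list_a,list_b character vectors of gene identifiers.
#' @return character vector of common identifiers.
#' @export
intersect_gene_lists <- function(list_a, list_b) {
  unique(list_a[list_a %in% list_b])
}

#' Read a one-ID-per-line gene list
#' @param path text file, one identifier per line; blank lines and `#`
#'   comments ignored.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write intervals as BED
#'
#' Converts the package's 1-based inclusive intervals to BED's 0-based
#' half-open convention.
#'
#' @param intervals interval data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  bed <- data.frame(chrom = intervals$chrom,
                    start = as.integer(intervals$start) - 1L,
                    end = as.integer(intervals$end),
                    name = if (nrow(intervals))
                      paste0(intervals$method, "_",
                             seq_len(nrow(intervals))) else character(),
                    score = if ("score" %in% names(intervals))
                      intervals$score else 0)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file as 1-based inclusive intervals
#' @param path BED file.
#' @return interval data.frame.
#' @export
read_bed <- function(path) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  out <- data.frame(chrom = bed[[1]], start = bed[[2]] + 1L,
                    end = bed[[3]],
                    score = if (ncol(bed) >= 5) bed[[5]] else NA_real_,
                    stringsAsFactors = FALSE)
  out
}
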