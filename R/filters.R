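## Two-stage SNP filtering: site-quality hard filters, then
## pool-informativeness filters. Every rule is a pure predicate on a record
## (the cluster rule on the record set), so the stage-two rules compose in
## any order. Comparators are strict as conventionally printed for GATK-style
## hard filters: remove QUAL < 30, QD < 2.0, MQ < 40, FS > 60; boundary
## values are retained.

.new_report <- function(rules, removed, n_in) {
  rep <- data.frame(rule = rules, removed = as.integer(removed))
  structure(list(rules = rep, input = as.integer(n_in),
                 survivors = as.integer(n_in - sum(removed))),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", x$input, "in ->", x$survivors, "out\n")
  for (i in seq_len(nrow(x$rules)))
    cat(sprintf("  %-14s -%d\n", x$rules$rule[i], x$rules$removed[i]))
  invisible(x)
}

#' Combine filter reports from successive stages
#' @param ... `filter_report` objects in application order.
#' @return a single `filter_report`.
#' @export
combine_reports <- function(...) {
  reps <- list(...)
  rules <- do.call(rbind, lapply(reps, function(r) r$rules))
  .new_report(rules$rule, rules$removed, reps[[1]]$input)
}

## SNPs lying in any 5 bp window holding more than `max_in_window` SNPs.
## A window with > k SNPs necessarily contains a run of k+1 consecutive
## (sorted) SNPs spanning <= window - 1 bp, so marking every member of such
## runs is exact.
.cluster_mask <- function(chrom, pos, window = 5L, max_in_window = 2L) {
  bad <- logical(length(pos))
  k <- max_in_window          # run length k+1 triggers
  for (cn in unique(chrom)) {
    i <- which(chrom == cn)
    p <- pos[i]
    if (length(p) <= k) next
    span_ok <- p[(k + 1):length(p)] - p[1:(length(p) - k)] <= window - 1L
    for (j in which(span_ok)) bad[i[j:(j + k)]] <- TRUE
  }
  bad
}

#' Site-quality hard filters
#'
#' Removes records failing, in order: QUAL below 30, QD (quality by depth)
#' below 2.0, MQ (RMS mapping quality) below 40, FS (Fisher strand bias,
#' phred) above 60, proximity to an InDel (within 5 bp), and membership in
#' an SNP cluster (more than 2 SNPs in any 5 bp window). Each removed
#' record is attributed to the first rule it fails. In strict mode a
#' missing annotation fails its rule; in lenient mode the rule is skipped
#' for that record.
#'
#' @param records `snp_records`, sorted by chromosome and position.
#' @param thresholds named list overriding `qual`, `qd`, `mq`, `fs`,
#'   `cluster_window`, `cluster_max`.
#' @param strict treat missing annotations as failing (default TRUE).
#' @return list with `records` (survivors) and `report`
#'   (a `filter_report`).
#' @export
apply_hard_filters <- function(records,
                               thresholds = list(),
                               strict = TRUE) {
  thr <- modifyList(list(qual = 30, qd = 2.0, mq = 40, fs = 60,
                         cluster_window = 5L, cluster_max = 2L),
                    thresholds)
  rec <- as.data.frame(records)
  if (nrow(rec) > 1 &&
      !identical(order(rec$chrom, rec$pos), seq_len(nrow(rec))))
    stop("records must be sorted by chromosome and position")

  fail_low <- function(x, cut) {
    f <- x < cut
    f[is.na(f)] <- strict
    f
  }
  fail_high <- function(x, cut) {
    f <- x > cut
    f[is.na(f)] <- strict
    f
  }

  alive <- rep(TRUE, nrow(rec))
  removed <- integer(6)
  rules <- c("QUAL", "QD", "MQ", "FS", "near_indel", "cluster")
  preds <- list(fail_low(rec$qual, thr$qual),
                fail_low(rec$qd, thr$qd),
                fail_low(rec$mq, thr$mq),
                fail_high(rec$fs, thr$fs),
                rec$near_indel %in% TRUE)
  for (i in seq_along(preds)) {
    kill <- alive & preds[[i]]
    removed[i] <- sum(kill)
    alive <- alive & !kill
  }
  idx <- which(alive)
  cl <- .cluster_mask(rec$chrom[idx], rec$pos[idx],
                      window = thr$cluster_window,
                      max_in_window = thr$cluster_max)
  removed[6] <- sum(cl)
  alive[idx[cl]] <- FALSE

  out <- rec[alive, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("snp_records", "data.frame")
  list(records = out, report = .new_report(rules, removed, nrow(rec)))
}

.keep_filter <- function(records, keep, rule) {
  rec <- as.data.frame(records)
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("snp_records", "data.frame")
  list(records = out,
       report = .new_report(rule, sum(!keep), nrow(rec)))
}

#' Keep only biallelic records
#'
#' Records whose ALT field lists more than one allele are removed.
#'
#' @param records `snp_records`.
#' @return list with `records` and `report`.
#' @export
filter_biallelic <- function(records) {
  rec <- as.data.frame(records)
  keep <- !grepl(",", rec$alt, fixed = TRUE) & nzchar(rec$alt) &
    rec$alt != "."
  if (nrow(rec) == 0L) keep <- logical(0)
  .keep_filter(records, keep, "multiallelic")
}

#' Remove records with insufficient pooled read support
#'
#' A record is removed when either bulk's total depth (ref + alt) is below
#' `min_depth`; records with depth exactly `min_depth` are retained.
#'
#' @param records `snp_records`.
#' @param min_depth minimum per-bulk depth (default 4).
#' @return list with `records` and `report`.
#' @export
filter_pool_depth <- function(records, min_depth = 4) {
  rec <- as.data.frame(records)
  keep <- (rec$alb_ref + rec$alb_alt) >= min_depth &
    (rec$nor_ref + rec$nor_alt) >= min_depth
  .keep_filter(records, keep, "pool_depth")
}

.pool_alt_frac <- function(ref, alt) {
  tot <- ref + alt
  ifelse(tot > 0, alt / tot, NA_real_)
}

#' Remove uninformative records
#'
#' Removes records where (a) both bulks are effectively homozygous for the
#' same allele — alt-allele fraction at or below `eps` in both, or at or
#' above `1 - eps` in both — or (b) the two parents carry the same
#' homozygous genotype. In strict mode a missing parent genotype also
#' removes the record.
#'
#' @param records `snp_records`.
#' @param eps pool-homozygosity tolerance on the allele fraction
#'   (default 0.01).
#' @param strict remove records with missing parent genotypes
#'   (default TRUE).
#' @return list with `records` and `report`.
#' @export
filter_uninformative <- function(records, eps = 0.01, strict = TRUE) {
  rec <- as.data.frame(records)
  fa <- .pool_alt_frac(rec$alb_ref, rec$alb_alt)
  fn <- .pool_alt_frac(rec$nor_ref, rec$nor_alt)
  pools_hom_same <- (fa <= eps & fn <= eps) |
    (fa >= 1 - eps & fn >= 1 - eps)
  pools_hom_same[is.na(pools_hom_same)] <- FALSE
  parents_same_hom <-
    (rec$p1_gt == "hom_ref" & rec$p2_gt == "hom_ref") |
    (rec$p1_gt == "hom_alt" & rec$p2_gt == "hom_alt")
  parent_missing <- rec$p1_gt == "missing" | rec$p2_gt == "missing"
  drop <- pools_hom_same | parents_same_hom |
    (strict & parent_missing)
  .keep_filter(records, !drop, "uninformative")
}

#' Remove records whose pooled alleles do not trace to the expected parent
#'
#' At a true segregating site the recessive (albino) bulk is enriched for
#' the recessive parent's allele and the dominant (normal) bulk for the
#' dominant parent's. Records are removed when the albino bulk's majority
#' allele differs from the recessive parent's homozygous allele, or the
#' normal bulk's majority allele differs from the dominant parent's. Exact
#' 50/50 pools carry no evidence of wrong origin and are retained.
#'
#' @param records `snp_records` with both parents homozygous and different.
#' @param recessive_parent `"P1"` or `"P2"`: which parent donated the
#'   albino allele.
#' @return list with `records` and `report`.
#' @export
filter_allele_origin <- function(records, recessive_parent = c("P1", "P2")) {
  recessive_parent <- match.arg(recessive_parent)
  rec <- as.data.frame(records)
  rgt <- if (recessive_parent == "P1") rec$p1_gt else rec$p2_gt
  dgt <- if (recessive_parent == "P1") rec$p2_gt else rec$p1_gt
  fa <- .pool_alt_frac(rec$alb_ref, rec$alb_alt)   # albino bulk alt frac
  fn <- .pool_alt_frac(rec$nor_ref, rec$nor_alt)   # normal bulk alt frac
  ## wrong when the majority allele is not the expected parent's allele;
  ## ties (fraction exactly 0.5) and zero-depth pools are retained
  maj_is_alt <- function(f) !is.na(f) & f > 0.5
  maj_is_ref <- function(f) !is.na(f) & f < 0.5
  alb_wrong <- ifelse(rgt == "hom_alt", maj_is_ref(fa),
                      ifelse(rgt == "hom_ref", maj_is_alt(fa), FALSE))
  nor_wrong <- ifelse(dgt == "hom_alt", maj_is_ref(fn),
                      ifelse(dgt == "hom_ref", maj_is_alt(fn), FALSE))
  .keep_filter(records, !(alb_wrong | nor_wrong), "allele_origin")
}

#' Run the full pool-informativeness filter chain
#'
#' Applies [filter_biallelic()], [filter_pool_depth()],
#' [filter_uninformative()] and (optionally) [filter_allele_origin()] in
#' sequence. Each rule is a pure predicate, so the surviving set does not
#' depend on the order.
#'
#' @param records `snp_records`.
#' @param recessive_parent passed to [filter_allele_origin()]; `NULL`
#'   skips the origin filter.
#' @param min_depth passed to [filter_pool_depth()].
#' @param eps,strict passed to [filter_uninformative()].
#' @return list with `records` and a combined `report`.
#' @export
filter_high_quality <- function(records, recessive_parent = "P1",
                                min_depth = 4, eps = 0.01, strict = TRUE) {
  s1 <- filter_biallelic(records)
  s2 <- filter_pool_depth(s1$records, min_depth = min_depth)
  s3 <- filter_uninformative(s2$records, eps = eps, strict = strict)
  if (!is.null(recessive_parent)) {
    s4 <- filter_allele_origin(s3$records,
                               recessive_parent = recessive_parent)
    list(records = s4$records,
         report = combine_reports(s1$report, s2$report, s3$report,
                                  s4$report))
  } else {
    list(records = s3$records,
         report = combine_reports(s1$report, s2$report, s3$report))
  }
}
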