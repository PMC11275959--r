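# Shared builders and independent brute-force oracles.

# A snp_records row with passing annotations; override any field.
make_record <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                        qual = 60, qd = 25, mq = 60, fs = 1,
                        near_indel = FALSE,
                        p1_gt = "hom_ref", p2_gt = "hom_alt",
                        p1 = c(30L, 0L), p2 = c(0L, 30L),
                        alb = c(20L, 20L), nor = c(20L, 20L)) {
  rec <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    qual = qual, qd = qd, mq = mq, fs = fs,
                    near_indel = near_indel,
                    p1_gt = p1_gt, p2_gt = p2_gt,
                    p1_ref = p1[1], p1_alt = p1[2],
                    p2_ref = p2[1], p2_alt = p2[2],
                    alb_ref = alb[1], alb_alt = alb[2],
                    nor_ref = nor[1], nor_alt = nor[2],
                    stringsAsFactors = FALSE)
  class(rec) <- c("snp_records", "data.frame")
  rec
}

bind_records <- function(...) {
  rec <- do.call(rbind, lapply(list(...), as.data.frame))
  rec <- rec[order(rec$chrom, rec$pos), , drop = FALSE]
  rownames(rec) <- NULL
  class(rec) <- c("snp_records", "data.frame")
  rec
}

# Random informative record table for property tests.
random_records <- function(n, seed) {
  set.seed(seed)
  recs <- lapply(seq_len(n), function(i) {
    make_record(chrom = sample(c("chr1", "chr2"), 1),
                pos = i * 1000L,
                alt = if (runif(1) < 0.1) "G,T" else "G",
                alb = as.integer(rbinom(2, 40, 0.5)),
                nor = as.integer(rbinom(2, 40, 0.5)),
                p1_gt = sample(c("hom_ref", "hom_alt", "het"), 1,
                               prob = c(.6, .3, .1)),
                p2_gt = sample(c("hom_ref", "hom_alt"), 1))
  })
  do.call(bind_records, recs)
}

# Brute-force cluster scan: SNP i is clustered iff some window of
# `window` bp containing it holds more than `max_in` SNPs.
oracle_cluster_mask <- function(chrom, pos, window = 5L, max_in = 2L) {
  n <- length(pos)
  bad <- logical(n)
  for (i in seq_len(n)) {
    for (s in (pos[i] - window + 1L):pos[i]) {
      inside <- chrom == chrom[i] & pos >= s & pos <= s + window - 1L
      if (sum(inside) > max_in) { bad[i] <- TRUE; break }
    }
  }
  bad
}

# Brute-force SNPNUM window fit for one chromosome.
oracle_fit <- function(pos, raw, window, step) {
  n <- length(raw)
  if (n < window) return(data.frame(pos = numeric(), fitted = numeric()))
  starts <- seq.int(1L, n - window + 1L, by = step)
  data.frame(pos = pos[starts + (window - 1L) %/% 2L],
             fitted = vapply(starts,
                             function(s) mean(raw[s:(s + window - 1L)]), 0))
}

# Brute-force 1-bp-overlap gene scan against an inclusive interval.
oracle_genes <- function(gene_start, gene_end, iv_start, iv_end) {
  which(gene_start <= iv_end & gene_end >= iv_start)
}

interval_contains <- function(iv, chrom, pos) {
  nrow(iv) > 0 && any(iv$chrom == chrom & iv$start <= pos & iv$end >= pos)
}
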