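## VCF 4.2 input/output for the four-sample (two parents, two bulks) design.
## Writing is direct text emission; reading goes through vcfR.

.gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
              missing = "./.")

#' Write SNP records as a VCF 4.2 file
#'
#' Emits one record per row with QUAL, INFO fields `QD`, `MQ`, `FS` (and the
#' flag `NIDL` marking sites within 5 bp of an InDel), and per-sample
#' `GT:AD` for samples `P1`, `P2`, `BULK_ALBINO`, `BULK_NORMAL`.
#'
#' @param records a `snp_records` data.frame sorted by chromosome then
#'   position (unsorted input is an error).
#' @param path output file path.
#' @param contigs optional named vector of chromosome lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, contigs = NULL) {
  rec <- as.data.frame(records)
  if (nrow(rec) > 0) {
    o <- order(rec$chrom, rec$pos)
    if (!identical(o, seq_len(nrow(rec))))
      stop("records must be sorted by chromosome and position")
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=bulkmapr",
    if (!is.null(contigs))
      sprintf("##contig=<ID=%s,length=%d>", names(contigs),
              as.integer(contigs)),
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled Fisher strand bias\">",
    "##INFO=<ID=NIDL,Number=0,Type=Flag,Description=\"Within 5 bp of an InDel\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "P1", "P2", "BULK_ALBINO", "BULK_NORMAL"),
          collapse = "\t"))
  body <- character(0)
  if (nrow(rec) > 0) {
    info <- sprintf("QD=%g;MQ=%g;FS=%g", rec$qd, rec$mq, rec$fs)
    info <- ifelse(rec$near_indel, paste0(info, ";NIDL"), info)
    samp <- function(gt, ad_ref, ad_alt)
      sprintf("%s:%d,%d", .gt_code[gt], as.integer(ad_ref),
              as.integer(ad_alt))
    body <- paste(rec$chrom, as.integer(rec$pos), ".", rec$ref, rec$alt,
                  format(rec$qual, trim = TRUE), "PASS", info, "GT:AD",
                  samp(rec$p1_gt, rec$p1_ref, rec$p1_alt),
                  samp(rec$p2_gt, rec$p2_ref, rec$p2_alt),
                  samp("missing", rec$alb_ref, rec$alb_alt),
                  samp("missing", rec$nor_ref, rec$nor_alt),
                  sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

.gt_decode <- function(gt) {
  gt <- sub("\\|", "/", gt)
  out <- rep("missing", length(gt))
  out[gt %in% "0/0"] <- "hom_ref"
  out[gt %in% c("0/1", "1/0")] <- "het"
  out[gt %in% "1/1"] <- "hom_alt"
  out
}

.ad_split <- function(ad) {
  parts <- strsplit(ifelse(is.na(ad), "0,0", ad), ",", fixed = TRUE)
  list(ref = vapply(parts, function(p) as.integer(p[1]), 0L),
       alt = vapply(parts, function(p)
         if (length(p) >= 2) as.integer(p[2]) else 0L, 0L))
}

#' Read a VCF into the package's SNP record table
#'
#' Parses with `vcfR` and maps the four expected samples (two parents,
#' albino bulk, normal bulk) onto the `snp_records` layout. Multiallelic
#' ALT strings are preserved verbatim (and later removed by
#' [filter_biallelic()]); for such records the AD of the first ALT allele
#' is used.
#'
#' @param path VCF file.
#' @param samples character(4): names of the parent-1, parent-2,
#'   albino-bulk and normal-bulk samples in the file.
#' @return a `snp_records` data.frame.
#' @export
read_snp_vcf <- function(path,
                         samples = c("P1", "P2", "BULK_ALBINO",
                                     "BULK_NORMAL")) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm)))  # single-record VCFs collapse to a vector
    fixm <- matrix(fixm, nrow = length(fixm) > 0,
                   dimnames = list(NULL, names(fixm)))
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  n <- nrow(fix)
  if (n == 0L) {
    rec <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      qual = numeric(), qd = numeric(), mq = numeric(),
                      fs = numeric(), near_indel = logical(),
                      p1_gt = character(), p2_gt = character(),
                      p1_ref = integer(), p1_alt = integer(),
                      p2_ref = integer(), p2_alt = integer(),
                      alb_ref = integer(), alb_alt = integer(),
                      nor_ref = integer(), nor_alt = integer())
    class(rec) <- c("snp_records", "data.frame")
    return(rec)
  }
  if (!all(samples %in% colnames(v@gt)[-1]))
    stop("VCF is missing expected samples: ",
         paste(setdiff(samples, colnames(v@gt)[-1]), collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  num_info <- function(key) {
    x <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
    x
  }
  info_raw <- v@fix[, "INFO"]
  rec <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    qd = num_info("QD"), mq = num_info("MQ"), fs = num_info("FS"),
    near_indel = grepl("(^|;)NIDL(;|$)", info_raw),
    p1_gt = .gt_decode(gt[, samples[1]]),
    p2_gt = .gt_decode(gt[, samples[2]]),
    stringsAsFactors = FALSE)
  for (nm in c("p1", "p2", "alb", "nor")) {
    i <- match(nm, c("p1", "p2", "alb", "nor"))
    d <- .ad_split(ad[, samples[i]])
    rec[[paste0(nm, "_ref")]] <- d$ref
    rec[[paste0(nm, "_alt")]] <- d$alt
  }
  rownames(rec) <- NULL
  class(rec) <- c("snp_records", "data.frame")
  rec
}

#' Write the simulation ground truth as a TSV sidecar
#'
#' @param exp a `sim_experiment`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(exp, path) {
  tr <- exp$config$causal
  tr$architecture <- rep(exp$config$architecture,
                         length.out = max(1, nrow(tr)))[seq_len(nrow(tr))]
  if (nrow(tr) == 0)
    tr <- data.frame(chrom = NA, pos = NA,
                     architecture = exp$config$architecture)
  write.table(tr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
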