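# In-memory container for a multi-sample genotype cohort, plus VCF 4.2 I/O.

#' Cohort genotype container
#'
#' Holds a participants-by-variants dosage matrix (0/1/2 alternate-allele
#' copies, `NA` missing) with parallel per-call quality matrices and a
#' per-variant site table.
#'
#' @param gt integer matrix, participants x variants (rownames = sample ids).
#' @param gq,dp,ad matrices of genotype quality, read depth and alternate
#'   allele depth, same shape as `gt` (or `NULL`).
#' @param variants data.frame with one row per variant; must contain `chrom`,
#'   `pos`, `id`, `ref`, `alt` and may carry site statistics (`qual`, `qd`,
#'   `mq`, `rprs`, `mqrs`, `filter`).
#' @return an object of class `cohort_genotypes`.
#' @export
cohort_genotypes <- function(gt, gq = NULL, dp = NULL, ad = NULL, variants) {
  stopifnot(is.matrix(gt), nrow(variants) == ncol(gt),
            !is.null(rownames(gt)))
  for (m in list(gq, dp, ad))
    if (!is.null(m)) stopifnot(identical(dim(m), dim(gt)))
  structure(list(gt = gt, gq = gq, dp = dp, ad = ad,
                 samples = rownames(gt), variants = variants),
            class = "cohort_genotypes")
}

#' @export
print.cohort_genotypes <- function(x, ...) {
  cat(sprintf("cohort_genotypes: %d participants x %d variants (%.2f%% missing)\n",
              length(x$samples), nrow(x$variants),
              100 * mean(is.na(x$gt))))
  invisible(x)
}

#' @export
dim.cohort_genotypes <- function(x) dim(x$gt)

#' Subset a cohort by samples and/or variants
#'
#' @param geno a `cohort_genotypes` object.
#' @param samples,variants logical, integer or character index into samples /
#'   variants (default: keep all).
#' @return the subset `cohort_genotypes`.
#' @export
subset_cohort <- function(geno, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_along(geno$samples) else samples
  vi <- if (is.null(variants)) seq_len(nrow(geno$variants)) else variants
  if (is.character(si)) si <- match(si, geno$samples)
  sub <- function(m) if (is.null(m)) NULL else m[si, vi, drop = FALSE]
  cohort_genotypes(gt = geno$gt[si, vi, drop = FALSE],
                   gq = sub(geno$gq), dp = sub(geno$dp), ad = sub(geno$ad),
                   variants = geno$variants[vi, , drop = FALSE])
}

#' Write a cohort as a multi-sample VCF 4.2 file
#'
#' Emits plain-text VCF with FORMAT `GT:GQ:DP:AD`, INFO fields `QD`, `MQ`,
#' `ReadPosRankSum`, `MQRankSum`, and FILTER `PASS` or a VQSR tranche label.
#' Output is byte-deterministic for a given cohort.
#'
#' @param geno a `cohort_genotypes` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(geno, path) {
  v <- geno$variants
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=rdvload",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$samples), collapse = "\t")
  )
  info <- sprintf("QD=%s;MQ=%s%s%s",
                  fmt_num(v$qd), fmt_num(v$mq),
                  ifelse(is.na(v$rprs), "",
                         sprintf(";ReadPosRankSum=%s", fmt_num(v$rprs))),
                  ifelse(is.na(v$mqrs), "",
                         sprintf(";MQRankSum=%s", fmt_num(v$mqrs))))
  gt_str <- matrix("./.:.:.:.,.", nrow = nrow(geno$gt), ncol = ncol(geno$gt))
  ok <- !is.na(geno$gt)
  gtx <- c("0/0", "0/1", "1/1")[geno$gt[ok] + 1L]
  dp <- geno$dp[ok]; ad <- geno$ad[ok]; gq <- geno$gq[ok]
  gt_str[ok] <- sprintf("%s:%d:%d:%d,%d", gtx, gq, dp, dp - ad, ad)
  sample_block <- do.call(paste,
                          c(lapply(seq_len(nrow(gt_str)),
                                   function(i) gt_str[i, ]), sep = "\t"))
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t%s\t%s\t%s\tGT:GQ:DP:AD\t%s",
                  v$chrom, as.integer(v$pos), v$id, v$ref, v$alt,
                  fmt_num(v$qual), v$filter, info, sample_block)
  writeLines(c(hdr, body), path)
  invisible(path)
}

fmt_num <- function(x) ifelse(is.na(x), ".", formatC(x, format = "g", digits = 6))

#' Read a multi-sample VCF into a cohort container
#'
#' Parses a VCF 4.2 file (via `vcfR`) with FORMAT `GT:GQ:DP:AD`, decomposing
#' genotypes to alternate-allele dosages. Multi-allelic records are not
#' expected (the upstream convention is biallelic, decomposed records).
#'
#' @param path VCF file path.
#' @return a `cohort_genotypes` object.
#' @export
read_cohort_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(vcf)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  dosage <- matrix(NA_integer_, nrow(gt_raw), ncol(gt_raw))
  dosage[gt_raw %in% c("0/0", "0|0")] <- 0L
  dosage[gt_raw %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dosage[gt_raw %in% c("1/1", "1|1")] <- 2L
  gq <- suppressWarnings(vcfR::extract.gt(vcf, "GQ", as.numeric = TRUE))
  dp <- suppressWarnings(vcfR::extract.gt(vcf, "DP", as.numeric = TRUE))
  ad_raw <- vcfR::extract.gt(vcf, "AD")
  ad_alt <- suppressWarnings(as.numeric(sub("^[^,]*,", "", ad_raw)))
  ad <- matrix(ad_alt, nrow(ad_raw), ncol(ad_raw))
  getinfo <- function(key) suppressWarnings(
    as.numeric(vcfR::extract.info(vcf, element = key)))
  variants <- data.frame(
    chrom = fx[, "CHROM"], pos = as.integer(fx[, "POS"]), id = fx[, "ID"],
    ref = fx[, "REF"], alt = fx[, "ALT"],
    qual = suppressWarnings(as.numeric(fx[, "QUAL"])),
    filter = fx[, "FILTER"],
    qd = getinfo("QD"), mq = getinfo("MQ"),
    rprs = getinfo("ReadPosRankSum"), mqrs = getinfo("MQRankSum"),
    stringsAsFactors = FALSE
  )
  samples <- colnames(gt_raw)
  tr <- function(m) {
    m <- t(m); rownames(m) <- samples; m
  }
  cohort_genotypes(gt = tr(dosage), gq = tr(gq), dp = tr(dp), ad = tr(ad),
                   variants = variants)
}
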