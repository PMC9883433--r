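# Genotype-level and case/control-aware site-level QC cascade.

#' QC thresholds
#'
#' Container of the genotype- and site-level QC thresholds. Defaults: genotype
#' quality >= 20, depth >= 10, alternate allele depth >= 4, heterozygous
#' allele balance within \[0.30, 0.70\] (inclusive), site QUAL >= 50, quality
#' by depth >= 2, mapping quality >= 40, ReadPosRankSum > -3,
#' MQRankSum > -10, VQSR tranche < 99, differential case/control missingness
#' <= 0.05, per-arm completeness >= 0.88, sample missingness < 0.15.
#'
#' @param ... named overrides of any default.
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(...) {
  t <- list(gq_min = 20, dp_min = 10, ad_alt_min = 4,
            ab_low = 0.30, ab_high = 0.70,
            qual_min = 50, qd_min = 2, mq_min = 40,
            rprs_min = -3, mqrs_min = -10, tranche_max = 99,
            diff_miss_max = 0.05, completeness_min = 0.88,
            sample_miss_max = 0.15)
  ov <- list(...)
  bad <- setdiff(names(ov), names(t))
  if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
  t[names(ov)] <- ov
  structure(t, class = "qc_thresholds")
}

#' Remove samples with excessive missing genotype data
#'
#' Drops participants with 15% or more missing genotypes (threshold
#' configurable). Applied before genotype masking and site screens so
#' missingness fractions downstream refer to the retained samples.
#'
#' @param geno a `cohort_genotypes` object.
#' @param thresholds a [qc_thresholds()] object.
#' @return `geno` restricted to retained samples, with a `removed_samples`
#'   attribute.
#' @export
filter_sample_missingness <- function(geno, thresholds = qc_thresholds()) {
  miss <- rowMeans(is.na(geno$gt))
  drop <- miss >= thresholds$sample_miss_max
  out <- subset_cohort(geno, samples = !drop)
  attr(out, "removed_samples") <- geno$samples[drop]
  out
}

#' Mask genotype calls failing per-call quality filters
#'
#' Sets to missing any call with genotype quality < `gq_min`, depth <
#' `dp_min`, an alternate-carrying call with alternate allele depth <
#' `ad_alt_min`, or a heterozygous call whose alternate allele fraction lies
#' outside \[`ab_low`, `ab_high`\] (homozygous calls are exempt from the
#' allele-balance rule). Calls with missing FORMAT fields are masked and
#' counted in the report rather than raising an error.
#'
#' @inheritParams filter_sample_missingness
#' @return `geno` with failing calls set to `NA` and a `qc_report` attribute
#'   tabulating masked calls per rule.
#' @export
apply_genotype_filters <- function(geno, thresholds = qc_thresholds()) {
  gt <- geno$gt
  called <- !is.na(gt)
  no_format <- called & (is.na(geno$gq) | is.na(geno$dp))
  fail_gq <- called & !is.na(geno$gq) & geno$gq < thresholds$gq_min
  fail_dp <- called & !is.na(geno$dp) & geno$dp < thresholds$dp_min
  has_alt <- called & gt >= 1
  fail_ad <- has_alt & (is.na(geno$ad) | geno$ad < thresholds$ad_alt_min)
  het <- called & gt == 1
  ab <- geno$ad / geno$dp
  fail_ab <- het & !is.na(ab) &
    (ab < thresholds$ab_low | ab > thresholds$ab_high)
  mask <- no_format | fail_gq | fail_dp | fail_ad | fail_ab
  gt[mask] <- NA_integer_
  geno$gt <- gt
  attr(geno, "qc_report") <- c(
    missing_format = sum(no_format), gq = sum(fail_gq), dp = sum(fail_dp),
    ad_alt = sum(fail_ad & !no_format), allele_balance = sum(fail_ab),
    total_masked = sum(mask)
  )
  geno
}

# lower sensitivity bound of a GATK VQSR tranche FILTER string, NA otherwise
tranche_lower_bound <- function(filter) {
  m <- regmatches(filter, regexpr("Tranche[A-Z]*([0-9]+\\.?[0-9]*)to", filter))
  out <- rep(NA_real_, length(filter))
  hit <- lengths(regmatches(filter, gregexpr("Tranche", filter))) > 0
  out[hit] <- as.numeric(sub("to$", "", sub("^Tranche[A-Z]*", "", m)))
  out
}

#' Site-level QC filters
#'
#' Evaluates the site statistics against their thresholds: QUAL >= 50,
#' QD >= 2, MQ >= 40, ReadPosRankSum > -3, MQRankSum > -10, and VQSR tranche
#' lower bound < 99 (PASS always passes). Absent rank-sum statistics do not
#' fail a site. Boundary semantics are inclusive for >=-style rules and
#' strict for >-style rules.
#'
#' @param sites data.frame with columns `qual`, `qd`, `mq`, `rprs`, `mqrs`,
#'   `filter` (any may be `NA` except as noted).
#' @param thresholds a [qc_thresholds()] object.
#' @return data.frame with logical `pass` and a `reasons` string column
#'   enumerating every violated rule (comma-separated, empty when passing).
#' @export
apply_site_filters <- function(sites, thresholds = qc_thresholds()) {
  n <- nrow(sites)
  fail <- list(
    qual = !is.na(sites$qual) & sites$qual < thresholds$qual_min,
    qd = !is.na(sites$qd) & sites$qd < thresholds$qd_min,
    mq = !is.na(sites$mq) & sites$mq < thresholds$mq_min,
    rprs = !is.na(sites$rprs) & sites$rprs <= thresholds$rprs_min,
    mqrs = !is.na(sites$mqrs) & sites$mqrs <= thresholds$mqrs_min,
    tranche = {
      tb <- tranche_lower_bound(sites$filter)
      !is.na(tb) & tb >= thresholds$tranche_max
    }
  )
  reasons <- vapply(seq_len(n), function(i) {
    paste(names(fail)[vapply(fail, `[`, logical(1), i)], collapse = ",")
  }, character(1))
  data.frame(pass = !Reduce(`|`, fail), reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Case/control-aware site screen
#'
#' Keeps a site iff the absolute difference in missing-call fraction between
#' cases and controls is <= `diff_miss_max` and completeness (1 - missing
#' fraction) is >= `completeness_min` in both arms. Evaluated on the
#' genotype-masked matrix, i.e. after per-call filters.
#'
#' @inheritParams filter_sample_missingness
#' @param labels case indicator per participant.
#' @return list with logical `keep` per site and a `report` of removal counts
#'   per rule (differential missingness vs completeness).
#' @export
case_control_site_screen <- function(geno, labels,
                                     thresholds = qc_thresholds()) {
  y <- align_labels(labels, geno$samples)
  if (!any(y == 1) || !any(y == 0))
    stop("screen undefined without both cases and controls")
  miss_case <- colMeans(is.na(geno$gt[y == 1, , drop = FALSE]))
  miss_ctrl <- colMeans(is.na(geno$gt[y == 0, , drop = FALSE]))
  fail_diff <- abs(miss_case - miss_ctrl) > thresholds$diff_miss_max
  fail_comp <- (1 - miss_case) < thresholds$completeness_min |
    (1 - miss_ctrl) < thresholds$completeness_min
  list(keep = !(fail_diff | fail_comp),
       miss_case = miss_case, miss_control = miss_ctrl,
       report = c(differential = sum(fail_diff & !fail_comp),
                  completeness = sum(fail_comp),
                  removed = sum(fail_diff | fail_comp)))
}

#' Full variant QC cascade
#'
#' Applies, in order: sample-missingness filter, per-call genotype masks,
#' site-statistic filters, and the case/control missingness screen, returning
#' the surviving cohort and a per-stage report.
#'
#' @inheritParams case_control_site_screen
#' @return list with `geno` (filtered `cohort_genotypes`), `labels` (aligned
#'   to retained samples) and `report`.
#' @export
qc_cohort <- function(geno, labels, thresholds = qc_thresholds()) {
  y0 <- align_labels(labels, geno$samples)
  names(y0) <- geno$samples
  g1 <- filter_sample_missingness(geno, thresholds)
  g2 <- apply_genotype_filters(g1, thresholds)
  site <- apply_site_filters(g2$variants, thresholds)
  g3 <- subset_cohort(g2, variants = site$pass)
  scr <- case_control_site_screen(g3, y0[g3$samples], thresholds)
  g4 <- subset_cohort(g3, variants = scr$keep)
  list(geno = g4, labels = y0[g4$samples],
       report = list(
         samples_removed = length(attr(g1, "removed_samples")),
         genotype_masks = attr(g2, "qc_report"),
         site_filters = table(factor(site$pass, levels = c(FALSE, TRUE))),
         cc_screen = scr$report,
         n_samples = length(g4$samples), n_variants = nrow(g4$variants)))
}
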