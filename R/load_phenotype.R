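# Per-individual RDV load groups and their phenotype associations:
# dose-response risk, age of onset, TMB, tumor immune fractions, survival.

#' Assign RDV load groups for a gene-set
#'
#' Counts, per participant, the distinct genes of the set carrying at least
#' one RDV and maps the count to the load groups zero (0 genes), one
#' (exactly 1) and multi (2 or more).
#'
#' @param rdv an `rdv_matrix`.
#' @param gene_set character vector of gene ids.
#' @param set_id optional label recorded in the output.
#' @return data.frame: `participant`, `gene_set`, `n_rdv_genes`, `group`
#'   (factor zero/one/multi).
#' @export
assign_load_groups <- function(rdv, gene_set, set_id = "set") {
  genes <- intersect(gene_set, rdv$genes)
  n_genes <- if (length(genes) == 0) {
    rep(0L, length(rdv$participants))
  } else {
    as.integer(rowSums(rdv$counts[, genes, drop = FALSE] > 0))
  }
  grp <- cut(n_genes, c(-Inf, 0, 1, Inf), labels = c("zero", "one", "multi"))
  data.frame(participant = rdv$participants, gene_set = set_id,
             n_rdv_genes = n_genes, group = grp, stringsAsFactors = FALSE)
}

#' Dose-response association of RDV load with case status
#'
#' Firth-penalized contrasts of the one-gene and multi-gene load groups
#' against the zero group (same covariates as the burden tests). An empty
#' multi group drops that contrast with a message; monotonicity of the two
#' odds ratios is reported, not enforced.
#'
#' @param load data.frame from [assign_load_groups()].
#' @param labels case indicator per participant.
#' @param covariates optional covariate data.frame aligned with participants.
#' @param method,level see [burden_test()].
#' @return data.frame with one row per contrast (`one_vs_zero`,
#'   `multi_vs_zero`): OR, CI, p, group sizes.
#' @export
load_dose_association <- function(load, labels, covariates = NULL,
                                  method = c("pl", "wald"), level = 0.95) {
  method <- match.arg(method)
  y_all <- align_labels(labels, load$participant)
  one_row <- function(contrast) {
    sel <- load$group %in% c("zero", contrast)
    if (sum(load$group == contrast) == 0) {
      message("empty '", contrast, "' load group; contrast skipped")
      return(NULL)
    }
    expo <- load$group[sel] == contrast
    cv <- if (is.null(covariates)) NULL else covariates[sel, , drop = FALSE]
    f <- burden_fit(y_all[sel], expo, cv, method = method, level = level)
    data.frame(contrast = paste0(contrast, "_vs_zero"),
               odds_ratio = exp(f$logor), ci_low = exp(f$ci[1]),
               ci_high = exp(f$ci[2]), p_value = f$p,
               n_exposed = sum(expo), n_zero = sum(!expo),
               converged = f$converged, stringsAsFactors = FALSE)
  }
  out <- rbind(one_row("one"), one_row("multi"))
  if (is.null(out)) stop("no non-zero load groups to contrast")
  out
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test with midrank ties. When both samples have at most
#' 8 observations the p-value is computed by exhaustive enumeration of all
#' group assignments of the pooled values (two-sided: assignments whose U is
#' at least as far from the null mean n1*n2/2 as observed); otherwise a
#' normal approximation with tie-corrected variance is used, with a
#' continuity correction by default. With `correct = FALSE` the two-group
#' case agrees exactly with the Kruskal-Wallis chi-square p-value. All
#' values tied across both samples gives p = 1.
#'
#' @param x,y numeric samples.
#' @param exact force (`TRUE`) or suppress (`FALSE`) enumeration; default
#'   enumerates when both sizes are <= 8.
#' @param correct apply the continuity correction in the normal
#'   approximation (default TRUE).
#' @return list of class `rank_test`: `statistic` (U for `x`), `p_value`,
#'   `n` (group sizes), `method`.
#' @export
mann_whitney <- function(x, y, exact = NULL, correct = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 > 0, n2 > 0)
  if (is.null(exact)) exact <- n1 <= 8 && n2 <= 8
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (exact) {
    dev <- abs(U - mu)
    combs <- utils::combn(n1 + n2, n1)
    us <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(us - mu) >= dev - 1e-9)
    method <- "exact enumeration"
  } else {
    N <- n1 + n2
    ties <- table(pooled)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      dev <- abs(U - mu)
      if (correct) dev <- max(0, dev - 0.5)
      p <- min(1, 2 * stats::pnorm(-dev / sqrt(sig2)))
    }
    method <- "normal approximation, tie-corrected"
  }
  structure(list(statistic = c(U = U), p_value = p, n = c(n1 = n1, n2 = n2),
                 method = method), class = "rank_test")
}

#' Kruskal-Wallis test across load groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square (k-1 df) p-value,
#' delegated to [stats::kruskal.test()].
#'
#' @param groups list of at least two non-empty numeric vectors.
#' @return list of class `rank_test`: `statistic` (H), `p_value`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop("need at least two non-empty groups")
  kt <- stats::kruskal.test(groups)
  p <- kt$p.value
  if (is.nan(p)) p <- 1  # zero variance in ranks
  structure(list(statistic = c(H = unname(kt$statistic)), p_value = p,
                 n = lengths(groups), method = "Kruskal-Wallis, tie-corrected"),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g, p = %.4g (n = %s)\n", x$method,
              names(x$statistic), x$statistic, x$p_value,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Tumor mutational burden
#'
#' TMB = (missense + nonsense + frameshift + inframe somatic mutation count)
#' per megabase of exome, with 38 Mb as the exome-size estimate. Synonymous
#' and other consequences are excluded by the consequence list.
#'
#' @param counts data.frame with columns `missense`, `nonsense`, `frameshift`,
#'   `inframe` (extra columns ignored).
#' @param exome_mb exome size in Mb (default 38).
#' @return numeric TMB per row (mutations/Mb).
#' @export
compute_tmb <- function(counts, exome_mb = 38) {
  need <- c("missense", "nonsense", "frameshift", "inframe")
  stopifnot(all(need %in% names(counts)))
  m <- as.matrix(counts[, need, drop = FALSE])
  if (any(m < 0, na.rm = TRUE)) stop("negative mutation count")
  rowSums(m) / exome_mb
}

#' Absolute immune-cell fractions
#'
#' Scales the 22 relative immune-cell fractions (deconvolution output, rows
#' summing to 1) by the per-tumor leukocyte fraction, giving absolute
#' fractions of tissue; rows then sum to the leukocyte fraction.
#'
#' @param relative matrix/data.frame of relative fractions (rows = tumors).
#' @param leukocyte numeric vector of leukocyte fractions in \[0, 1\].
#' @return matrix of absolute fractions.
#' @export
absolute_immune_fraction <- function(relative, leukocyte) {
  rel <- as.matrix(relative)
  stopifnot(nrow(rel) == length(leukocyte))
  if (any(leukocyte < 0 | leukocyte > 1, na.rm = TRUE))
    stop("leukocyte fraction outside [0, 1]")
  rs <- rowSums(rel)
  if (any(abs(rs - 1) > 1e-6, na.rm = TRUE))
    stop("relative fractions must sum to 1 per tumor")
  rel * leukocyte
}

#' Cox proportional-hazards association with survival
#'
#' Fits a stratified Cox model (Breslow tie handling) of survival on a single
#' covariate — typically the absolute M1 macrophage fraction — and reports
#' the hazard ratio per unit covariate with a Wald p-value. Strata without
#' events are dropped with a message; a covariate without variation yields a
#' flagged, undefined fit.
#'
#' @param time,event survival time (> 0) and event indicator.
#' @param covariate numeric covariate.
#' @param strata optional stratification factor (e.g. cancer type).
#' @return list: `hr`, `log_hr`, `p_value`, `n`, `n_events`, `flagged`.
#' @export
cox_survival <- function(time, event, covariate, strata = NULL) {
  stopifnot(all(time > 0, na.rm = TRUE))
  d <- data.frame(time = time, event = event, x = covariate)
  if (!is.null(strata)) d$s <- factor(strata)
  if (sum(d$event, na.rm = TRUE) < 1) stop("no events")
  if (!is.null(strata)) {
    ev <- tapply(d$event, d$s, sum)
    dead_strata <- names(ev)[is.na(ev) | ev == 0]
    if (length(dead_strata)) {
      message("stratum with no events skipped: ",
              paste(dead_strata, collapse = ", "))
      d <- d[!(d$s %in% dead_strata), , drop = FALSE]
      d$s <- droplevels(d$s)
    }
  }
  if (stats::var(d$x, na.rm = TRUE) == 0) {
    return(list(hr = NA_real_, log_hr = 0, p_value = NA_real_,
                n = nrow(d), n_events = sum(d$event), flagged = TRUE))
  }
  fml <- if (is.null(strata)) survival::Surv(time, event) ~ x
         else survival::Surv(time, event) ~ x + survival::strata(s)
  fit <- survival::coxph(fml, data = d, ties = "breslow")
  sm <- summary(fit)
  list(hr = unname(exp(stats::coef(fit)["x"])),
       log_hr = unname(stats::coef(fit)["x"]),
       p_value = unname(sm$coefficients["x", "Pr(>|z|)"]),
       n = fit$n, n_events = fit$nevent, flagged = FALSE)
}

#' Load-group phenotype comparisons
#'
#' Convenience wrapper producing the standard contrasts for one continuous
#' phenotype across load groups: pairwise Mann-Whitney tests (any-RDV vs
#' zero, one vs zero, multi vs zero) and the 3-group Kruskal-Wallis test.
#'
#' @param values numeric phenotype per participant.
#' @param group load-group factor (zero/one/multi) per participant.
#' @return data.frame of contrasts with statistics and p-values.
#' @export
load_phenotype_tests <- function(values, group) {
  group <- factor(group, levels = c("zero", "one", "multi"))
  stopifnot(length(values) == length(group))
  v <- split(values, group)
  rows <- list()
  pair <- function(label, a, b) {
    if (length(a) == 0 || length(b) == 0) return(NULL)
    mt <- mann_whitney(a, b)
    data.frame(contrast = label, statistic = unname(mt$statistic),
               p_value = mt$p_value, n1 = length(a), n2 = length(b))
  }
  rows$any <- pair("any_vs_zero", c(v$one, v$multi), v$zero)
  rows$one <- pair("one_vs_zero", v$one, v$zero)
  rows$multi <- pair("multi_vs_zero", v$multi, v$zero)
  nz <- sum(lengths(v) > 0)
  if (nz >= 2) {
    kw <- kruskal_wallis(v[lengths(v) > 0])
    rows$kw <- data.frame(contrast = "kruskal_wallis",
                          statistic = unname(kw$statistic),
                          p_value = kw$p_value,
                          n1 = sum(lengths(v)), n2 = NA_integer_)
  }
  do.call(rbind, rows)
}
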