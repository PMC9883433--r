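# Carrier-collapsing burden tests at gene and gene-set level.

# Fast internal fit: intercept + carrier + covariate columns, inference on the
# carrier coefficient only.
burden_fit <- function(y, carrier, covariates = NULL, method = "pl",
                       level = 0.95, penalty = 0.5, tol = 1e-6, maxit = 50,
                       ci = TRUE) {
  X <- cbind(`(Intercept)` = 1, carrier = as.numeric(carrier))
  if (!is.null(covariates) && ncol(covariates) > 0)
    X <- cbind(X, as.matrix(covariates))
  keep <- qr(X)$rank == ncol(X)
  if (!keep) stop("rank-deficient burden design; check covariates")
  fit <- firth_engine(X, y, penalty = penalty, tol = tol, maxit = maxit)
  est <- fit$beta["carrier"]
  if (method == "pl") {
    if (ci) {
      pci <- profile_ci_one(X, y, fit, "carrier", penalty = penalty,
                            level = level, tol = tol, maxit = maxit)
      lo <- pci$lower; hi <- pci$upper
    } else {
      lo <- NA_real_; hi <- NA_real_
    }
    p <- plr_pvalue(X, y, fit, "carrier", penalty = penalty, tol = tol,
                    maxit = maxit)
  } else {
    V <- chol2inv(chol(fit$info))
    se <- sqrt(V[2, 2])
    zc <- stats::qnorm(1 - (1 - level) / 2)
    lo <- est - zc * se; hi <- est + zc * se
    p <- 2 * stats::pnorm(-abs(est / se))
  }
  list(logor = unname(est), ci = c(unname(lo), unname(hi)), p = unname(p),
       converged = fit$converged)
}

#' Carrier-collapsing RDV burden test for a gene or gene-set
#'
#' Collapses a unit (one gene or a set of genes) to a single binary exposure —
#' whether a participant carries at least one qualifying rare deleterious
#' variant (RDV) in the unit — and tests case-control association with a
#' Firth-penalized logistic regression, adjusting for the supplied covariates
#' (typically the synonymous background gene count and the first two ancestry
#' principal components).
#'
#' @param rdv an `rdv_matrix` from [build_rdv_matrix()].
#' @param unit character vector of gene ids forming the unit.
#' @param labels logical or 0/1 vector of case status, aligned with
#'   `rdv$participants` (or a named vector).
#' @param covariates optional data.frame/matrix of numeric covariates aligned
#'   with participants.
#' @param unit_id label for the output row.
#' @param method `"pl"` (profile-penalized-likelihood, default) or `"wald"`.
#' @param level confidence level.
#' @param ci compute confidence limits (profile limits dominate the cost of
#'   large scans; set `FALSE` when only p-values are needed).
#' @param tol convergence tolerance on the modified score.
#' @return one-row data.frame: unit id, odds ratio with CI and p-value, carrier
#'   counts and percentages per arm, distinct variant and gene counts
#'   (the layout of a gene-set burden report row).
#' @export
burden_test <- function(rdv, unit, labels, covariates = NULL,
                        unit_id = NULL, method = c("pl", "wald"),
                        level = 0.95, ci = TRUE, tol = 1e-6) {
  method <- match.arg(method)
  stopifnot(inherits(rdv, "rdv_matrix"))
  y <- align_labels(labels, rdv$participants)
  genes <- intersect(unit, rdv$genes)
  if (is.null(unit_id)) unit_id <- paste(unit, collapse = "+")
  carrier <- unit_carrier(rdv, genes)
  cs <- carrier_summary(rdv, genes, y)
  if (sum(carrier) == 0) {
    return(cbind(data.frame(unit = unit_id, odds_ratio = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            p_value = NA_real_, converged = NA), cs,
                 data.frame(tested = FALSE)))
  }
  f <- burden_fit(y, carrier, covariates, method = method, level = level,
                  ci = ci, tol = tol)
  cbind(data.frame(unit = unit_id, odds_ratio = exp(f$logor),
                   ci_low = exp(f$ci[1]), ci_high = exp(f$ci[2]),
                   p_value = f$p, converged = f$converged), cs,
        data.frame(tested = TRUE))
}

# carrier indicator for a unit (any RDV in any of its genes)
unit_carrier <- function(rdv, genes) {
  genes <- intersect(genes, rdv$genes)
  if (length(genes) == 0) return(rep(FALSE, length(rdv$participants)))
  rowSums(rdv$counts[, genes, drop = FALSE]) > 0
}

#' Carrier/variant/gene counts per arm for a unit
#'
#' Tabulates, for a gene or gene-set, the number of distinct RDV sites and
#' genes observed in each arm and the number (and percentage) of unique
#' carrier individuals — the descriptive columns of a burden report.
#'
#' @inheritParams burden_test
#' @param genes gene ids of the unit.
#' @param labels case indicator aligned with participants.
#' @return one-row data.frame of counts and percentages.
#' @export
carrier_summary <- function(rdv, genes, labels) {
  y <- align_labels(labels, rdv$participants)
  genes <- intersect(genes, rdv$genes)
  carrier <- unit_carrier(rdv, genes)
  case_idx <- which(y == 1)
  ctrl_idx <- which(y == 0)
  vt <- rdv$variants[rdv$variants$gene %in% genes, , drop = FALSE]
  in_arm <- function(idx) {
    if (nrow(vt) == 0) return(c(0L, 0L))
    hit <- vapply(vt$carriers, function(ix) any(ix %in% idx), logical(1))
    c(sum(hit), length(unique(vt$gene[hit])))
  }
  vc_case <- in_arm(case_idx)
  vc_ctrl <- in_arm(ctrl_idx)
  data.frame(
    n_variants_case = vc_case[1], n_variants_control = vc_ctrl[1],
    n_genes_case = vc_case[2], n_genes_control = vc_ctrl[2],
    n_case_carriers = sum(carrier[case_idx]),
    n_control_carriers = sum(carrier[ctrl_idx]),
    pct_case_carriers = carrier_pct(sum(carrier[case_idx]), length(case_idx)),
    pct_control_carriers = carrier_pct(sum(carrier[ctrl_idx]), length(ctrl_idx))
  )
}

#' Carrier percentage as reported (two decimals)
#'
#' @param n_carriers carrier count.
#' @param n_total arm size.
#' @return percentage rounded to two decimal places.
#' @export
carrier_pct <- function(n_carriers, n_total) round(100 * n_carriers / n_total, 2)

#' Burden scan over a catalog of units
#'
#' Runs [burden_test()] for every unit in a catalog (all single genes, or a
#' named gene-set catalog such as one read from GMT), appends
#' Benjamini-Hochberg q-values over the testable units, and orders rows by
#' p-value then unit id.
#'
#' @inheritParams burden_test
#' @param catalog named list of gene-id vectors; a character vector is treated
#'   as a catalog of single-gene units.
#' @return data.frame of burden results with a `q_value` column.
#' @export
scan_units <- function(rdv, catalog, labels, covariates = NULL,
                       method = c("pl", "wald"), level = 0.95, ci = TRUE) {
  method <- match.arg(method)
  if (is.character(catalog)) catalog <- stats::setNames(as.list(catalog), catalog)
  if (length(catalog) == 0) stop("empty unit catalog")
  if (is.null(names(catalog)) || any(names(catalog) == ""))
    stop("catalog units must be named")
  rows <- lapply(names(catalog), function(nm) {
    genes <- intersect(catalog[[nm]], rdv$genes)
    if (length(genes) == 0 || !any(unit_carrier(rdv, genes))) {
      message("unit '", nm, "' has no observed RDV carriers; skipped")
      return(NULL)
    }
    burden_test(rdv, catalog[[nm]], labels, covariates, unit_id = nm,
                method = method, level = level, ci = ci)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("no testable units in catalog")
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value, out$unit), , drop = FALSE]
}

# normalize a case/control label vector against the participant id order
align_labels <- function(labels, participants) {
  if (!is.null(names(labels))) labels <- labels[participants]
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  if (is.character(labels)) labels <- labels %in% c("case", "1", "TRUE")
  y <- as.integer(labels)
  if (length(y) != length(participants) || anyNA(y))
    stop("labels must cover every participant")
  if (!any(y == 1) || !any(y == 0))
    stop("need at least one case and one control")
  y
}

#' Read a GMT gene-set catalog
#'
#' @param path GMT file (unit name, description, then gene ids, tab-separated).
#' @return named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    stats::setNames(list(f[-(1:2)]), f[1])
  })
  do.call(c, out)
}
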