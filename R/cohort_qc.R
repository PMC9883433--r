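# Sample-level QC: KING-robust kinship, relative pruning, PCA ancestry gating.

#' KING-robust kinship coefficient for one pair
#'
#' Allele-frequency-free kinship estimator from heterozygote concordance and
#' opposite-homozygote counts over co-called SNPs:
#' \deqn{\hat\phi = \frac{N_{Aa,Aa} - 2 N_{AA,aa}}{N_{Aa}(i) + N_{Aa}(j)}}
#' Duplicates give 0.5, parent-offspring ~0.25, second degree ~0.125;
#' pairs with \eqn{\hat\phi > 0.0884} are conventionally flagged as related up
#' to second degree.
#'
#' @param g_i,g_j dosage vectors (0/1/2, `NA` missing) over a common-SNP panel.
#' @return list with `phi`, `n_snps` (co-called count) and `evaluable`.
#' @export
estimate_kinship <- function(g_i, g_j) {
  ok <- !is.na(g_i) & !is.na(g_j)
  gi <- g_i[ok]; gj <- g_j[ok]
  n_het_het <- sum(gi == 1 & gj == 1)
  n_opp_hom <- sum(abs(gi - gj) == 2)
  denom <- sum(gi == 1) + sum(gj == 1)
  if (denom == 0)
    return(list(phi = NA_real_, n_snps = sum(ok), evaluable = FALSE))
  list(phi = (n_het_het - 2 * n_opp_hom) / denom, n_snps = sum(ok),
       evaluable = TRUE)
}

#' Pairwise KING-robust kinship over a cohort
#'
#' Computes \eqn{\hat\phi} for every participant pair on a common-variant
#' panel, via indicator-matrix cross-products (missing calls excluded
#' pairwise).
#'
#' @param gt dosage matrix, participants x panel SNPs.
#' @param threshold relatedness flag threshold (default 0.0884, the
#'   second-degree bound).
#' @return data.frame of pairs: `i`, `j` (sample ids), `phi`, `n_snps`,
#'   `flagged`.
#' @export
kinship_matrix <- function(gt, threshold = 0.0884) {
  ids <- rownames(gt)
  M <- !is.na(gt)
  H <- (gt == 1) & M
  A <- (gt == 2) & M
  R <- (gt == 0) & M
  storage.mode(H) <- storage.mode(A) <- storage.mode(R) <- "double"
  storage.mode(M) <- "double"
  n_hh <- tcrossprod(H)
  n_opp <- tcrossprod(A, R) + tcrossprod(R, A)
  het_i <- tcrossprod(H, M)   # hets of i over sites co-called with j
  denom <- het_i + t(het_i)
  n_co <- tcrossprod(M)
  phi <- (n_hh - 2 * n_opp) / denom
  ut <- which(upper.tri(phi), arr.ind = TRUE)
  data.frame(i = ids[ut[, 1]], j = ids[ut[, 2]],
             phi = phi[ut], n_snps = n_co[ut],
             flagged = !is.na(phi[ut]) & phi[ut] > threshold,
             stringsAsFactors = FALSE)
}

#' Prune related participants
#'
#' Greedy pruning over flagged pairs (processed in deterministic id order):
#' from each pair with both members still retained, the member with the
#' higher missing-genotype fraction is removed; ties break lexicographically
#' (the later id is removed). The result leaves no retained pair above the
#' kinship threshold, which is asserted.
#'
#' @param kin data.frame from [kinship_matrix()] (needs `i`, `j`, `flagged`).
#' @param missingness named numeric vector of per-participant missing
#'   fractions.
#' @return character vector of participant ids to remove.
#' @export
prune_relatives <- function(kin, missingness) {
  fl <- kin[kin$flagged %in% TRUE, , drop = FALSE]
  if (nrow(fl) == 0) return(character(0))
  stopifnot(all(c(fl$i, fl$j) %in% names(missingness)))
  fl <- fl[order(fl$i, fl$j), , drop = FALSE]
  removed <- character(0)
  for (k in seq_len(nrow(fl))) {
    a <- fl$i[k]; b <- fl$j[k]
    if (a %in% removed || b %in% removed) next
    drop <- if (missingness[a] > missingness[b]) a
            else if (missingness[b] > missingness[a]) b
            else max(a, b)
    removed <- c(removed, drop)
  }
  left <- fl[!(fl$i %in% removed) & !(fl$j %in% removed), , drop = FALSE]
  stopifnot(nrow(left) == 0)
  removed
}

#' Ancestry PCA on a common-variant panel
#'
#' Standardizes each panel SNP by \eqn{(g - 2\hat p)/\sqrt{2\hat p(1-\hat p)}}
#' (allele frequency estimated over all rows, residual missingness
#' mean-imputed), then decomposes by SVD. Study and reference samples share
#' one score space. Component signs are fixed so the largest-magnitude
#' loading of each component is positive.
#'
#' @param gt study dosage matrix (participants x panel SNPs); the panel should
#'   be biallelic, common (MAF >= 0.05) and near-complete.
#' @param ref_gt optional reference-panel dosage matrix over the same SNPs.
#' @param ref_labels optional population labels for reference rows.
#' @param k number of components.
#' @return object of class `pca_model`: `scores` (all samples x k),
#'   `loadings`, `ids`, `is_ref`, `ref_labels`, `dropped` (monomorphic SNPs).
#' @export
compute_ancestry_pcs <- function(gt, ref_gt = NULL, ref_labels = NULL, k = 2) {
  X <- if (is.null(ref_gt)) gt else rbind(gt, ref_gt)
  is_ref <- c(rep(FALSE, nrow(gt)),
              rep(TRUE, if (is.null(ref_gt)) 0 else nrow(ref_gt)))
  p_hat <- colMeans(X, na.rm = TRUE) / 2
  mono <- is.na(p_hat) | p_hat <= 0 | p_hat >= 1
  if (any(mono)) {
    message(sum(mono), " monomorphic panel SNP(s) dropped")
    X <- X[, !mono, drop = FALSE]
    p_hat <- p_hat[!mono]
  }
  if (k > min(dim(X))) stop("k exceeds the rank of the panel matrix")
  Z <- sweep(X, 2, 2 * p_hat)
  Z <- sweep(Z, 2, sqrt(2 * p_hat * (1 - p_hat)), "/")
  Z[is.na(Z)] <- 0  # mean imputation of residual missingness
  sv <- svd(Z, nu = k, nv = k)
  if (sv$d[k] < 1e-12) stop("k exceeds the rank of the panel matrix")
  flip <- apply(sv$v, 2, function(v) sign(v[which.max(abs(v))]))
  scores <- sweep(sv$u %*% diag(sv$d[1:k], k), 2, flip, "*")
  loadings <- sweep(sv$v, 2, flip, "*")
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(X)
  structure(list(scores = scores, loadings = loadings, ids = rownames(X),
                 is_ref = is_ref, ref_labels = ref_labels,
                 dropped = sum(mono), k = k),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d samples (%d reference), k = %d\n",
              length(x$ids), sum(x$is_ref), x$k))
  invisible(x)
}

#' Rectangular ancestry gate on (PC1, PC2)
#'
#' Retains study participants whose first two principal-component scores fall
#' inside a rectangle (bounds inclusive) — the "gating" step that restricts
#' the cohort to its largest ancestry cluster.
#'
#' @param model a `pca_model`.
#' @param region numeric vector `c(pc1_min, pc1_max, pc2_min, pc2_max)`.
#' @param labels optional case indicator per study participant; when given,
#'   gates that exclude every case (or every control) raise an error.
#' @return character vector of retained study participant ids.
#' @export
gate_ancestry <- function(model, region, labels = NULL) {
  stopifnot(length(region) == 4, region[1] < region[2], region[3] < region[4])
  sc <- model$scores[!model$is_ref, , drop = FALSE]
  inside <- sc[, 1] >= region[1] & sc[, 1] <= region[2] &
            sc[, 2] >= region[3] & sc[, 2] <= region[4]
  if (!any(inside)) stop("empty ancestry gate; inspect PC scores")
  kept <- rownames(sc)[inside]
  if (!is.null(labels)) {
    y <- align_labels(labels, rownames(sc))
    if (!any(y[inside] == 1) || !any(y[inside] == 0))
      stop("ancestry gate excludes an entire arm")
  }
  kept
}

#' Derive a gate rectangle from reference-population scores
#'
#' Convenience mode: centroid of a labeled reference population plus/minus
#' `c_sd` standard deviations on PC1 and PC2.
#'
#' @param model a `pca_model` fitted with reference samples and labels.
#' @param ref_group reference population label to center on.
#' @param c_sd half-width in reference SDs (default 3).
#' @return region vector usable by [gate_ancestry()].
#' @export
gate_from_reference <- function(model, ref_group, c_sd = 3) {
  stopifnot(any(model$is_ref), !is.null(model$ref_labels))
  sc <- model$scores[model$is_ref, , drop = FALSE]
  sc <- sc[model$ref_labels == ref_group, , drop = FALSE]
  if (nrow(sc) < 2) stop("reference group too small: ", ref_group)
  c(mean(sc[, 1]) + c(-1, 1) * c_sd * stats::sd(sc[, 1]),
    mean(sc[, 2]) + c(-1, 1) * c_sd * stats::sd(sc[, 2]))
}

#' Greedy LD pruning of a SNP panel
#'
#' Windowed pairwise-r2 pruning (default r2 > 0.2 within 50-SNP windows,
#' step 5), the standard pre-PCA thinning when the panel has local
#' correlation.
#'
#' @param gt dosage matrix (participants x SNPs, assumed ordered by position).
#' @param r2_max maximum squared correlation retained.
#' @param window,step window size and slide step in SNPs.
#' @return integer indices of retained SNPs.
#' @export
ld_prune <- function(gt, r2_max = 0.2, window = 50, step = 5) {
  m <- ncol(gt)
  keep <- rep(TRUE, m)
  start <- 1
  while (start <= m) {
    idx <- start:min(start + window - 1, m)
    idx <- idx[keep[idx]]
    if (length(idx) > 1) {
      r2 <- suppressWarnings(stats::cor(gt[, idx, drop = FALSE],
                                        use = "na.or.complete"))^2
      for (a in seq_along(idx)) {
        if (!keep[idx[a]]) next
        hits <- which(r2[a, ] > r2_max & seq_along(idx) > a & keep[idx])
        keep[idx[hits]] <- FALSE
      }
    }
    start <- start + step
    if (start > m - 1) break
  }
  which(keep)
}

#' Select a common-variant panel for kinship/PCA
#'
#' Restricts to biallelic SNPs with MAF >= `maf_min` and call rate >=
#' `call_rate_min`, then LD-prunes.
#'
#' @param geno a `cohort_genotypes` object.
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param call_rate_min minimum call rate (default 0.99).
#' @param r2_max LD pruning threshold.
#' @return dosage matrix restricted to the panel.
#' @export
common_panel <- function(geno, maf_min = 0.05, call_rate_min = 0.99,
                         r2_max = 0.2) {
  snp <- nchar(geno$variants$ref) == 1 & nchar(geno$variants$alt) == 1
  af <- colMeans(geno$gt, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  cr <- colMeans(!is.na(geno$gt))
  sel <- which(snp & !is.na(maf) & maf >= maf_min & cr >= call_rate_min)
  gt <- geno$gt[, sel, drop = FALSE]
  # residual missingness is mean-imputed before correlation pruning
  gtc <- gt
  if (anyNA(gtc)) {
    mu <- colMeans(gtc, na.rm = TRUE)
    na_idx <- which(is.na(gtc), arr.ind = TRUE)
    gtc[na_idx] <- mu[na_idx[, 2]]
  }
  gt[, ld_prune(gtc, r2_max = r2_max), drop = FALSE]
}
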