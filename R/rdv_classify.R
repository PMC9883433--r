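# Classification of QC-passed variants as rare + deleterious (RDVs),
# the per-participant per-gene RDV matrix, and the synonymous background
# covariate.

#' Cohort minor allele frequencies
#'
#' Computes per-variant minor allele frequency from non-missing genotypes,
#' overall and per arm.
#'
#' @param geno a `cohort_genotypes` object.
#' @param labels optional case indicator; when given, per-arm MAFs are added.
#' @return data.frame with `maf` (overall) and, with labels, `maf_case`,
#'   `maf_control`.
#' @export
cohort_maf <- function(geno, labels = NULL) {
  fold <- function(af) pmin(af, 1 - af)
  af_of <- function(gt) colSums(gt, na.rm = TRUE) / (2 * colSums(!is.na(gt)))
  out <- data.frame(maf = fold(af_of(geno$gt)))
  if (!is.null(labels)) {
    y <- align_labels(labels, geno$samples)
    out$maf_case <- fold(af_of(geno$gt[y == 1, , drop = FALSE]))
    out$maf_control <- fold(af_of(geno$gt[y == 0, , drop = FALSE]))
  }
  out
}

#' Rarity classification
#'
#' A variant is rare unless it is common (MAF above `cohort_max`) in *both*
#' the case and control arms, or exceeds `ref_max` in either reference
#' population (ExAC non-TCGA NFE; gnomAD ASJ). Reference frequencies absent
#' from the annotation are treated as 0 by default (the variant was not
#' observed there), configurable to exclusion.
#'
#' @param maf_case,maf_control cohort arm MAFs per variant.
#' @param ann annotation data.frame with `maf_exac_nfe_nontcga`,
#'   `maf_gnomad_asj` columns.
#' @param cohort_max cohort-arm MAF cutoff (default 0.02; the 0.01
#'   sensitivity mode is selected by passing 0.01).
#' @param ref_max reference-population MAF cutoff (default 0.01).
#' @param absent_ref `"zero"` (default) treats `NA` reference MAF as 0;
#'   `"exclude"` marks such variants not rare.
#' @return logical vector.
#' @export
is_rare <- function(maf_case, maf_control, ann, cohort_max = 0.02,
                    ref_max = 0.01, absent_ref = c("zero", "exclude")) {
  absent_ref <- match.arg(absent_ref)
  nfe <- ann$maf_exac_nfe_nontcga
  asj <- ann$maf_gnomad_asj
  if (absent_ref == "zero") {
    nfe[is.na(nfe)] <- 0
    asj[is.na(asj)] <- 0
  }
  common_both <- !is.na(maf_case) & !is.na(maf_control) &
    maf_case > cohort_max & maf_control > cohort_max
  !common_both & !is.na(nfe) & nfe <= ref_max & !is.na(asj) & asj <= ref_max
}

#' Deleteriousness classification
#'
#' A variant is deleterious if (i) its ClinVar significance is pathogenic or
#' likely pathogenic; or (ii) it is a frameshift or stopgain (nonsense)
#' variant lying 5' — in coding-sequence coordinates — of a ClinVar
#' pathogenic loss-of-function (nonsense/frameshift) record in the same gene.
#' Rule (ii) uses the most 3' anchor per gene as the boundary; a variant
#' qualifies when its CDS position is strictly smaller than that boundary.
#' Because CDS coordinates are already in coding direction, transcript strand
#' is absorbed by the coordinate frame. Coding variants lacking a CDS
#' position are skipped for rule (ii) with a message.
#'
#' @param ann annotation data.frame with `gene`, `consequence`, `cds_pos`,
#'   `clinvar` columns for the cohort's variants.
#' @param anchors optional data.frame of ClinVar LOF records (`gene`,
#'   `cds_pos`, `consequence`, `clinvar`); defaults to the qualifying records
#'   within `ann` itself.
#' @param include_lp_anchors should likely-pathogenic LOF records anchor rule
#'   (ii) (default TRUE)?
#' @return logical vector.
#' @export
is_deleterious <- function(ann, anchors = NULL, include_lp_anchors = TRUE) {
  plp <- c("pathogenic", if (include_lp_anchors) "likely_pathogenic")
  if (is.null(anchors)) anchors <- ann
  anch <- anchors[anchors$clinvar %in% plp &
                  anchors$consequence %in% c("stopgain", "frameshift") &
                  !is.na(anchors$cds_pos), , drop = FALSE]
  boundary <- tapply(anch$cds_pos, anch$gene, max)
  direct <- ann$clinvar %in% c("pathogenic", "likely_pathogenic")
  lof <- ann$consequence %in% c("stopgain", "frameshift")
  no_cds <- lof & is.na(ann$cds_pos)
  if (any(no_cds))
    message(sum(no_cds), " truncating variant(s) without CDS position ",
            "skipped for the 5' propagation rule")
  bd <- boundary[ann$gene]
  five_prime <- lof & !is.na(ann$cds_pos) & !is.na(bd) & ann$cds_pos < bd
  direct | five_prime
}

#' Classify cohort variants as RDVs
#'
#' Combines [is_rare()] and [is_deleterious()] on QC-passed variants.
#'
#' @param geno a `cohort_genotypes` object (QC-passed, gated, pruned).
#' @param ann annotation data.frame aligned with `geno$variants` rows (matched
#'   on variant `id`).
#' @param labels case indicator per participant.
#' @param cohort_max,ref_max,absent_ref,include_lp_anchors see [is_rare()] and
#'   [is_deleterious()].
#' @return `ann` with appended logical columns `rare`, `deleterious`, `rdv`
#'   and the cohort arm MAFs.
#' @export
classify_rdv <- function(geno, ann, labels, cohort_max = 0.02, ref_max = 0.01,
                         absent_ref = "zero", include_lp_anchors = TRUE) {
  stopifnot(all(geno$variants$id %in% ann$id))
  ann <- ann[match(geno$variants$id, ann$id), , drop = FALSE]
  maf <- cohort_maf(geno, labels)
  ann$maf_case <- maf$maf_case
  ann$maf_control <- maf$maf_control
  ann$maf_cohort <- maf$maf
  ann$rare <- is_rare(maf$maf_case, maf$maf_control, ann,
                      cohort_max = cohort_max, ref_max = ref_max,
                      absent_ref = absent_ref)
  ann$deleterious <- is_deleterious(ann,
                                    include_lp_anchors = include_lp_anchors)
  ann$rdv <- ann$rare & ann$deleterious
  ann
}

#' Per-participant per-gene RDV matrix
#'
#' Counts, for each participant and gene, the qualifying RDV sites at which
#' the participant carries at least one alternate allele (dominant carrier
#' coding: a homozygous alternate genotype counts once).
#'
#' @param geno a `cohort_genotypes` object.
#' @param ann classified annotation from [classify_rdv()] (needs `rdv`,
#'   `gene`, `id`).
#' @return object of class `rdv_matrix`: `counts` (participants x genes
#'   integer matrix), `participants`, `genes`, and `variants` (per-RDV-site
#'   gene and carrier index list).
#' @export
build_rdv_matrix <- function(geno, ann) {
  stopifnot(all(c("rdv", "gene", "id") %in% names(ann)))
  ann <- ann[match(geno$variants$id, ann$id), , drop = FALSE]
  sel <- which(ann$rdv %in% TRUE)
  genes <- sort(unique(ann$gene[sel]))
  n <- length(geno$samples)
  counts <- matrix(0L, n, length(genes),
                   dimnames = list(geno$samples, genes))
  carriers <- vector("list", length(sel))
  for (k in seq_along(sel)) {
    j <- sel[k]
    idx <- which(geno$gt[, j] >= 1L)  # NA drops out of which()
    carriers[[k]] <- idx
    if (length(idx))
      counts[idx, ann$gene[j]] <- counts[idx, ann$gene[j]] + 1L
  }
  variants <- data.frame(id = ann$id[sel], gene = ann$gene[sel],
                         stringsAsFactors = FALSE)
  variants$carriers <- carriers
  structure(list(counts = counts, participants = geno$samples,
                 genes = genes, variants = variants),
            class = "rdv_matrix")
}

#' @export
print.rdv_matrix <- function(x, ...) {
  cat(sprintf("rdv_matrix: %d participants x %d genes, %d RDV sites, %d carriers\n",
              length(x$participants), length(x$genes), nrow(x$variants),
              sum(rowSums(x$counts) > 0)))
  invisible(x)
}

#' Long-format RDV assignment table
#'
#' @param x an `rdv_matrix`.
#' @param row.names,optional,... passed for S3 compatibility (unused).
#' @return data.frame with `participant`, `gene`, `n_rdv_variants`, `carrier`
#'   rows for every participant-gene pair with at least one RDV.
#' @export
as.data.frame.rdv_matrix <- function(x, row.names = NULL, optional = FALSE, ...) {
  idx <- which(x$counts > 0, arr.ind = TRUE)
  data.frame(participant = x$participants[idx[, 1]],
             gene = x$genes[idx[, 2]],
             n_rdv_variants = x$counts[idx],
             carrier = TRUE, stringsAsFactors = FALSE)
}

#' Synonymous background load
#'
#' Per participant, the number of distinct autosomal genes harboring at least
#' one carried rare synonymous variant (ExAC global MAF <= 0.005% and
#' full-cohort MAF <= 0.05%) — the background-variation covariate that
#' absorbs platform and coverage differences between arms.
#'
#' @param geno a `cohort_genotypes` object.
#' @param ann annotation with `consequence`, `gene`, `chrom`,
#'   `maf_exac_global` (matched to `geno` on `id`).
#' @param exac_max,cohort_max rarity cutoffs (defaults 5e-5 and 5e-4).
#' @return data.frame with `participant`, `n_syn_genes`.
#' @export
synonymous_background <- function(geno, ann, exac_max = 5e-5,
                                  cohort_max = 5e-4) {
  ann <- ann[match(geno$variants$id, ann$id), , drop = FALSE]
  maf <- cohort_maf(geno)$maf
  exac <- ann$maf_exac_global
  exac[is.na(exac)] <- 0
  autosome <- !(sub("^chr", "", ann$chrom) %in% c("X", "Y"))
  sel <- which(ann$consequence == "synonymous" & autosome &
               exac <= exac_max & !is.na(maf) & maf <= cohort_max)
  n <- length(geno$samples)
  if (length(sel) == 0)
    return(data.frame(participant = geno$samples, n_syn_genes = 0L))
  # distinct genes with >=1 carried qualifying synonymous variant
  tallies <- matrix(FALSE, n, length(unique(ann$gene[sel])),
                    dimnames = list(NULL, unique(ann$gene[sel])))
  for (j in sel) {
    idx <- which(geno$gt[, j] >= 1L)
    if (length(idx)) tallies[idx, ann$gene[j]] <- TRUE
  }
  data.frame(participant = geno$samples, n_syn_genes = rowSums(tallies))
}
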