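# End-to-end orchestration: QC -> sample QC -> RDV classification -> burden
# -> load -> phenotype associations, with a reproducibility manifest.

#' Pipeline configuration
#'
#' Assembles the configuration of [run_pipeline()]: input paths, QC
#' thresholds, kinship/gating settings, rarity cutoffs, covariate selection
#' and subset filters. All thresholds default to the analysis defaults; see
#' [qc_thresholds()], [is_rare()] and [kinship_matrix()].
#'
#' @param vcf,annotations,covariates,gene_sets,tumor input file paths (VCF,
#'   annotation TSV, covariate TSV, GMT catalog, optional tumor TSV).
#' @param out_dir output directory for stage tables.
#' @param thresholds a [qc_thresholds()] object.
#' @param kinship_threshold relatedness flag threshold.
#' @param gate rectangle `c(pc1_min, pc1_max, pc2_min, pc2_max)` or `NULL`
#'   to span all scores (gate disabled).
#' @param n_pcs number of ancestry PCs used as covariates.
#' @param cohort_maf_max,ref_maf_max rarity cutoffs (sensitivity mode: set
#'   `cohort_maf_max = 0.01`).
#' @param covariate_set covariates for the burden fits: any of `"syn_load"`,
#'   `"pcs"`, `"gender"`.
#' @param case_subset optional case filter: keep only cases whose
#'   covariate-table `cancer_type` (if present) is in this set; controls are
#'   always all retained.
#' @param seed integer seed recorded in the manifest.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, annotations, covariates, gene_sets,
                            tumor = NULL, out_dir = tempfile("rdvload_"),
                            thresholds = qc_thresholds(),
                            kinship_threshold = 0.0884, gate = NULL,
                            n_pcs = 2, cohort_maf_max = 0.02,
                            ref_maf_max = 0.01,
                            covariate_set = c("syn_load", "pcs"),
                            case_subset = NULL, seed = 1) {
  for (p in c(vcf, annotations, covariates, gene_sets, tumor))
    if (!file.exists(p)) stop("input file does not exist: ", p)
  structure(list(vcf = vcf, annotations = annotations,
                 covariates = covariates, gene_sets = gene_sets,
                 tumor = tumor, out_dir = out_dir, thresholds = thresholds,
                 kinship_threshold = kinship_threshold, gate = gate,
                 n_pcs = n_pcs, cohort_maf_max = cohort_maf_max,
                 ref_maf_max = ref_maf_max, covariate_set = covariate_set,
                 case_subset = case_subset, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()] arguments
#'   (threshold overrides under a `thresholds:` mapping).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  thr <- do.call(qc_thresholds, as.list(y$thresholds))
  y$thresholds <- NULL
  y$gate <- if (is.null(y$gate)) NULL else as.numeric(y$gate)
  do.call(pipeline_config, c(y, list(thresholds = thr)))
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}

require_columns <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("schema mismatch in ", file, ": missing column(s) ",
         paste(miss, collapse = ", "))
  df
}

#' Run the full RDV analysis pipeline
#'
#' Executes, in fixed order: sample-missingness filter, genotype-level QC
#' masks, site-level QC, case/control missingness screen, kinship-based
#' relative pruning, PCA ancestry gating, RDV classification, synonymous
#' background computation, burden tests for the gene-set catalog plus a
#' per-gene scan, load-group assignment and (when tumor data are supplied)
#' load-phenotype associations. Each stage's record counts are logged in the
#' returned manifest, and stage tables are written under the output
#' directory.
#'
#' @param config a [pipeline_config()].
#' @return list with `burden` (gene-set results), `gene_scan`, `load`
#'   (per-set dose-response), `phenotype` (rank-test tables, if tumor data),
#'   `rdv` (the RDV matrix), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, started = format(Sys.time()),
                   version = as.character(utils::packageVersion("rdvload")),
                   stages = list())
  log_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
    message(sprintf("[%s] %s", name,
                    paste(names(list(...)), unlist(list(...)),
                          sep = "=", collapse = " ")))
  }

  geno <- read_cohort_vcf(config$vcf)
  ann <- require_columns(read_tsv(config$annotations),
                         c("id", "chrom", "pos", "gene", "cds_pos",
                           "consequence", "clinvar", "maf_exac_nfe_nontcga",
                           "maf_gnomad_asj", "maf_exac_global"),
                         config$annotations)
  cov <- require_columns(read_tsv(config$covariates),
                         c("participant", "status"), config$covariates)
  sets <- read_gmt(config$gene_sets)
  labels0 <- stats::setNames(cov$status == "case", cov$participant)
  log_stage("input", n_samples = length(geno$samples),
            n_variants = nrow(geno$variants), n_sets = length(sets))

  if (!is.null(config$case_subset) && "cancer_type" %in% names(cov)) {
    keep_ids <- cov$participant[cov$status == "control" |
                                cov$cancer_type %in% config$case_subset]
    geno <- subset_cohort(geno, samples = geno$samples %in% keep_ids)
    log_stage("case_subset", n_samples = length(geno$samples))
  }

  qc <- qc_cohort(geno, labels0[geno$samples], config$thresholds)
  geno <- qc$geno
  log_stage("variant_qc", n_samples = length(geno$samples),
            n_variants = nrow(geno$variants))

  panel <- common_panel(geno)
  if (ncol(panel) >= 10) {
    kin <- kinship_matrix(panel, config$kinship_threshold)
    missv <- rowMeans(is.na(geno$gt))
    names(missv) <- geno$samples
    removed <- prune_relatives(kin, missv)
    geno <- subset_cohort(geno, samples = !(geno$samples %in% removed))
    log_stage("kinship", n_flagged_pairs = sum(kin$flagged),
              n_removed = length(removed), n_samples = length(geno$samples))

    panel <- common_panel(geno)
    pca <- compute_ancestry_pcs(panel, k = config$n_pcs)
    region <- config$gate
    if (is.null(region)) {
      sc <- pca$scores
      region <- c(min(sc[, 1]) - 1, max(sc[, 1]) + 1,
                  min(sc[, 2]) - 1, max(sc[, 2]) + 1)
    }
    kept <- gate_ancestry(pca, region, labels0[geno$samples])
    geno <- subset_cohort(geno, samples = geno$samples %in% kept)
    # covariate PCs are recomputed on the gated participants
    pca <- compute_ancestry_pcs(common_panel(geno), k = config$n_pcs)
    pcs <- pca$scores[geno$samples, , drop = FALSE]
    log_stage("pca_gate", n_samples = length(geno$samples))
  } else {
    pcs <- NULL
    log_stage("pca_gate", skipped = "common panel too small")
  }
  labels <- labels0[geno$samples]

  ann_cl <- classify_rdv(geno, ann, labels,
                         cohort_max = config$cohort_maf_max,
                         ref_max = config$ref_maf_max)
  rdv <- build_rdv_matrix(geno, ann_cl)
  syn <- synonymous_background(geno, ann)
  log_stage("rdv_classify", n_rdv_sites = sum(ann_cl$rdv),
            n_rdv_genes = length(rdv$genes),
            mean_syn_load = round(mean(syn$n_syn_genes), 3))

  covmat <- NULL
  cm <- list()
  if ("syn_load" %in% config$covariate_set) cm$syn_load <- syn$n_syn_genes
  if ("pcs" %in% config$covariate_set && !is.null(pcs))
    for (j in seq_len(ncol(pcs))) cm[[colnames(pcs)[j]]] <- pcs[, j]
  drop_missing_gender <- "gender" %in% config$covariate_set
  if (drop_missing_gender) {
    g <- cov$gender[match(geno$samples, cov$participant)]
    ok <- !is.na(g)
    geno_g <- subset_cohort(geno, samples = ok)
    rdv_g <- build_rdv_matrix(geno_g, ann_cl)
    cm <- lapply(cm, `[`, ok)
    cm$gender <- as.numeric(factor(g[ok]))
    labels <- labels[ok]
    rdv <- rdv_g
    log_stage("gender_filter", n_samples = length(labels))
  }
  if (length(cm)) {
    cm <- as.data.frame(cm)
    degenerate <- vapply(cm, function(v) stats::var(v) == 0, logical(1))
    if (any(degenerate)) {
      message("constant covariate(s) dropped: ",
              paste(names(cm)[degenerate], collapse = ", "))
      cm <- cm[, !degenerate, drop = FALSE]
    }
    if (ncol(cm) > 0) covmat <- cm
  }

  burden <- scan_units(rdv, sets, labels, covmat)
  gene_scan <- scan_units(rdv, rdv$genes, labels, covmat)
  log_stage("burden", n_sets_tested = nrow(burden),
            n_genes_tested = nrow(gene_scan))

  load_tabs <- lapply(names(sets), function(nm)
    assign_load_groups(rdv, sets[[nm]], nm))
  names(load_tabs) <- names(sets)
  dose <- lapply(load_tabs, function(lt)
    tryCatch(load_dose_association(lt, labels, covmat),
             error = function(e) NULL))
  log_stage("load", n_sets = length(load_tabs))

  phenotype <- NULL
  if (!is.null(config$tumor)) {
    tum <- read_tsv(config$tumor)
    tum <- tum[tum$participant %in% rdv$participants, , drop = FALSE]
    tum <- tum[!(tum$is_hematological %in% TRUE), , drop = FALSE]
    tum$tmb <- compute_tmb(tum)
    relc <- grep("^frac_", names(tum), value = TRUE)
    absf <- absolute_immune_fraction(tum[, relc], tum$leukocyte_fraction)
    m1 <- absf[, "frac_Macrophage_M1"]
    phenotype <- lapply(load_tabs, function(lt) {
      grp <- lt$group[match(tum$participant, lt$participant)]
      list(onset = load_phenotype_tests(tum$age_at_diagnosis, grp),
           tmb = load_phenotype_tests(tum$tmb, grp),
           m1 = load_phenotype_tests(m1, grp),
           survival = cox_survival(tum$surv_time, tum$surv_event, m1,
                                   strata = tum$cancer_type))
    })
    log_stage("phenotype", n_tumors = nrow(tum))
  }

  wt <- function(d, f) utils::write.table(
    d, file.path(config$out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wt(burden, "burden_gene_sets.tsv")
  wt(gene_scan, "burden_genes.tsv")
  wt(as.data.frame(rdv), "rdv_assignments.tsv")
  wt(syn, "synonymous_background.tsv")
  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(burden = burden, gene_scan = gene_scan, load = load_tabs,
       dose = dose, phenotype = phenotype, rdv = rdv, syn = syn,
       manifest = manifest)
}
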