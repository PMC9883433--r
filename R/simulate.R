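# Seeded synthetic case-control cohort generator. Emulates the statistical
# structure the downstream analysis assumes: a rare-variant MAF spectrum with
# planted per-gene-set carrier log-odds effects on case status, ClinVar
# annotation (direct P/LP labels plus 5'-rule anchor records), ultra-rare
# synonymous background variation independent of status, ancestry strata on a
# common-SNP panel, planted duplicate/1st/2nd-degree pairs, and load-linked
# tumor phenotypes.

IMMUNE_CELLS <- c(
  "B_naive", "B_memory", "Plasma", "T_CD8", "T_CD4_naive", "T_CD4_mem_rest",
  "T_CD4_mem_act", "T_FH", "T_reg", "T_gd", "NK_rest", "NK_act", "Monocyte",
  "Macrophage_M0", "Macrophage_M1", "Macrophage_M2", "DC_rest", "DC_act",
  "Mast_rest", "Mast_act", "Eosinophil", "Neutrophil")

#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic cohort generator.
#' Defaults emulate the discovery-cohort structure: 6371 cases and 6647
#' controls, four cancer gene-sets with planted carrier log-odds effects equal
#' to the log of the reported gene-set odds ratios (CPD 1.51, DDR 1.50, SCD
#' 1.46, FA 2.05), a rare-variant MAF spectrum of point masses between 0.01%
#' and 0.5%, and a common-SNP panel (MAF >= 5%) for kinship/PCA.
#'
#' @param n_cases,n_controls cohort arm sizes.
#' @param genes data.frame with `gene`, `strand`, `cds_length`; default panel
#'   of 36 gene-set genes plus `n_null_genes` null genes.
#' @param gene_sets named list of gene-id vectors.
#' @param n_null_genes null genes added to the default panel.
#' @param variants_per_gene planted deleterious variants per gene.
#' @param maf_spectrum point masses of rare-variant population frequencies
#'   (support in (0, 0.5]).
#' @param n_common_snps,common_maf_range common panel size and MAF range.
#' @param planted_logor named vector: carrier log-odds effect per gene-set.
#' @param clinvar_fraction proportion of planted deleterious variants labeled
#'   P/LP directly (the rest are unlabeled truncating variants lying 5' of a
#'   ClinVar pathogenic LOF anchor record).
#' @param synonymous_rate mean rare-synonymous genes per participant.
#' @param ancestry list: `weights` (named mixture weights) and `offsets`
#'   (per-stratum logit-scale allele-frequency dispersion on the common
#'   panel).
#' @param related_pairs named counts of planted `duplicate`, `first_degree`,
#'   `second_degree` pairs (planted among controls).
#' @param phenotype_effects list: `set` (gene-set driving tumor phenotypes),
#'   `onset_shift` (years subtracted for the one/multi load groups),
#'   `tmb_multiplier` (somatic count multiplier per load group), `m1_shift`
#'   (additive shift of the expected relative M1 macrophage fraction),
#'   `survival_loghr` (log hazard ratio per unit absolute M1 fraction),
#'   `age_floor` (minimum onset age after shifting).
#' @param distractors also plant benign and reference-common variants so every
#'   classification filter branch is exercised (default TRUE).
#' @param quality generate per-call GQ/DP/AD matrices (default TRUE).
#' @param seed integer seed; identical configs with identical seeds reproduce
#'   all outputs exactly.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 6371, n_controls = 6647,
                       genes = NULL, gene_sets = NULL, n_null_genes = 24,
                       variants_per_gene = 3,
                       maf_spectrum = c(1e-4, 5e-4, 1e-3, 2e-3, 5e-3),
                       n_common_snps = 2000, common_maf_range = c(0.05, 0.5),
                       planted_logor = c(CPD = log(1.51), DDR = log(1.50),
                                         SCD = log(1.46), FA = log(2.05)),
                       clinvar_fraction = 0.7,
                       synonymous_rate = 1.5,
                       ancestry = list(weights = c(EUR = 0.9, OTH = 0.1),
                                       offsets = c(EUR = 0, OTH = 1.5)),
                       related_pairs = c(duplicate = 2, first_degree = 3,
                                         second_degree = 3),
                       phenotype_effects = list(
                         set = NULL,
                         onset_shift = c(one = 4, multi = 8),
                         tmb_multiplier = c(one = 1.5, multi = 2.0),
                         m1_shift = c(one = 0.015, multi = 0.03),
                         survival_loghr = 5,
                         age_floor = 18),
                       distractors = TRUE, quality = TRUE, seed = 1) {
  if (is.null(genes)) {
    nm <- c(sprintf("CPD%02d", 1:10), sprintf("DDR%02d", 1:10),
            sprintf("SCD%02d", 1:10), sprintf("FA%02d", 1:6),
            if (n_null_genes > 0) sprintf("NUL%02d", seq_len(n_null_genes)))
    genes <- data.frame(gene = nm,
                        strand = rep_len(c("+", "-"), length(nm)),
                        cds_length = 900 + 300 * (seq_along(nm) %% 5),
                        stringsAsFactors = FALSE)
  }
  if (is.null(gene_sets)) {
    gene_sets <- list(CPD = grep("^CPD", genes$gene, value = TRUE),
                      DDR = grep("^DDR", genes$gene, value = TRUE),
                      SCD = grep("^SCD", genes$gene, value = TRUE),
                      FA = grep("^FA", genes$gene, value = TRUE))
    gene_sets <- gene_sets[lengths(gene_sets) > 0]
  }
  stopifnot(n_cases >= 1, n_controls >= 1, variants_per_gene >= 1,
            all(maf_spectrum > 0), all(maf_spectrum <= 0.5),
            clinvar_fraction >= 0, clinvar_fraction <= 1,
            synonymous_rate >= 0, all(related_pairs >= 0),
            abs(sum(ancestry$weights) - 1) < 1e-9)
  undeclared <- setdiff(unlist(gene_sets), genes$gene)
  if (length(undeclared))
    stop("gene_sets reference undeclared gene(s): ",
         paste(undeclared, collapse = ", "))
  unknown <- setdiff(names(planted_logor), names(gene_sets))
  if (length(unknown))
    stop("planted_logor for unknown gene-set(s): ",
         paste(unknown, collapse = ", "))
  if (is.null(phenotype_effects$set))
    phenotype_effects$set <- names(gene_sets)[1]
  structure(list(n_cases = n_cases, n_controls = n_controls, genes = genes,
                 gene_sets = gene_sets, variants_per_gene = variants_per_gene,
                 maf_spectrum = maf_spectrum, n_common_snps = n_common_snps,
                 common_maf_range = common_maf_range,
                 planted_logor = planted_logor,
                 clinvar_fraction = clinvar_fraction,
                 synonymous_rate = synonymous_rate, ancestry = ancestry,
                 related_pairs = related_pairs,
                 phenotype_effects = phenotype_effects,
                 distractors = distractors, quality = quality,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# HWE genotype matrix, chunked to bound temporaries
draw_geno <- function(n, p, chunk = 500L) {
  m <- length(p)
  out <- matrix(0L, n, m)
  j <- 1L
  while (j <= m) {
    jj <- j:min(j + chunk - 1L, m)
    out[, jj] <- matrix(as.integer(
      stats::rbinom(n * length(jj), 2L, rep(p[jj], each = n))), n)
    j <- j + chunk
  }
  out
}

# variant annotation/spec table for one config (uses the active RNG stream)
build_variant_table <- function(config) {
  g <- config$genes
  set_genes <- unique(unlist(config$gene_sets))
  rows <- list()
  for (i in seq_len(nrow(g))) {
    gene <- g$gene[i]; L <- g$cds_length[i]
    K <- config$variants_per_gene
    direct <- stats::runif(K) < config$clinvar_fraction
    cons <- ifelse(direct,
                   sample(c("missense", "stopgain", "frameshift"), K, TRUE),
                   sample(c("stopgain", "frameshift"), K, TRUE))
    cds <- ifelse(direct,
                  sample.int(L, K, replace = TRUE),
                  sample.int(max(1L, floor(0.6 * L)), K, replace = TRUE))
    clin <- ifelse(direct,
                   sample(c("pathogenic", "likely_pathogenic"), K, TRUE),
                   "absent")
    rows[[length(rows) + 1L]] <- data.frame(
      gene = gene, role = "rdv", consequence = cons, cds_pos = cds,
      clinvar = clin, maf = sample(config$maf_spectrum, K, TRUE),
      stringsAsFactors = FALSE)
    if (any(!direct)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, role = "anchor", consequence = "stopgain",
        cds_pos = as.integer(floor(0.9 * L)), clinvar = "pathogenic",
        maf = min(config$maf_spectrum), stringsAsFactors = FALSE)
    }
    if (config$distractors) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, role = c("benign", "refcommon"),
        consequence = c("missense", "missense"),
        cds_pos = sample.int(L, 2, replace = TRUE),
        clinvar = c("benign", "pathogenic"),
        maf = c(0.01, max(config$maf_spectrum)), stringsAsFactors = FALSE)
    }
  }
  # synonymous background: ultra-rare, independent of status
  if (config$synonymous_rate > 0) {
    syn_maf_pool <- c(1e-4, 2e-4, 3e-4)
    n_syn <- ceiling(config$synonymous_rate / (2 * mean(syn_maf_pool)))
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g$gene[rep_len(seq_len(nrow(g)), n_syn)], role = "synonymous",
      consequence = "synonymous",
      cds_pos = sample.int(min(g$cds_length), n_syn, replace = TRUE),
      clinvar = "absent", maf = sample(syn_maf_pool, n_syn, TRUE),
      stringsAsFactors = FALSE)
  }
  if (config$n_common_snps > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      gene = NA_character_, role = "common", consequence = "other",
      cds_pos = NA_integer_, clinvar = "absent",
      maf = stats::runif(config$n_common_snps, config$common_maf_range[1],
                         config$common_maf_range[2]),
      stringsAsFactors = FALSE)
  }
  vt <- do.call(rbind, rows)
  m <- nrow(vt)
  gene_chrom <- stats::setNames(as.character(rep_len(1:22, nrow(g))), g$gene)
  vt$chrom <- ifelse(is.na(vt$gene), as.character(rep_len(1:22, m)),
                     gene_chrom[vt$gene])
  vt$pos <- as.integer(1e6 + 100L * seq_len(m))
  vt$id <- sprintf("v%05d", seq_len(m))
  bases <- c("A", "C", "G", "T")
  vt$ref <- sample(bases, m, TRUE)
  vt$alt <- vapply(vt$ref, function(r) sample(setdiff(bases, r), 1),
                   character(1))
  vt$strand <- ifelse(is.na(vt$gene), NA_character_,
                      stats::setNames(g$strand, g$gene)[vt$gene])
  # reference-population frequencies: unobserved for rare variants (half NA,
  # half 0); distractor "refcommon" variants exceed the 1% reference gate
  vt$maf_exac_nfe_nontcga <- ifelse(vt$role == "refcommon", 0.015,
                                    ifelse(stats::runif(m) < 0.5, 0, NA))
  vt$maf_gnomad_asj <- ifelse(vt$role == "refcommon", 0.012,
                              ifelse(stats::runif(m) < 0.5, 0, NA))
  vt$maf_exac_global <- ifelse(vt$role == "synonymous",
                               ifelse(stats::runif(m) < 0.05, 1e-4, 0), 0)
  vt[, c("id", "chrom", "pos", "ref", "alt", "gene", "strand", "cds_pos",
         "consequence", "clinvar", "role", "maf", "maf_exac_nfe_nontcga",
         "maf_gnomad_asj", "maf_exac_global")]
}

#' Simulate a case-control cohort
#'
#' Draws a seeded synthetic cohort under the generative model: genotypes are
#' Hardy-Weinberg within ancestry stratum; carrying at least one planted
#' deleterious variant in a gene-set multiplies the case odds by
#' `exp(planted_logor)` for that set; synonymous background variants are
#' drawn independently of status; duplicate and 1st/2nd-degree relative pairs
#' are planted by genotype copying / Mendelian gamete sharing.
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_cohort`: `genotypes`
#'   (`cohort_genotypes`), `annotations`, `covariates`, `truth` (planted
#'   per-set carrier status, gene counts and load groups, strata, related
#'   pairs), `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  vt <- build_variant_table(config)
  m <- nrow(vt)
  n_total <- config$n_cases + config$n_controls
  eff_sets <- names(config$planted_logor)[
    abs(config$planted_logor) >= 0 & names(config$planted_logor) %in%
      names(config$gene_sets)]
  empty <- names(config$gene_sets)[lengths(config$gene_sets) == 0]
  if (length(empty)) {
    warning("gene-set(s) with zero variants skipped: ",
            paste(empty, collapse = ", "))
    eff_sets <- setdiff(eff_sets, empty)
  }
  planted_idx <- which(vt$role %in% c("rdv", "anchor"))
  set_cols <- lapply(config$gene_sets[eff_sets], function(gs)
    which(vt$role %in% c("rdv", "anchor") & vt$gene %in% gs))

  strat_names <- names(config$ancestry$weights)
  alpha <- stats::qlogis(config$n_cases / n_total)
  lam <- config$planted_logor[eff_sets]

  # rejection-free retrospective sampling: draw candidates, assign status by
  # the logistic model, fill both arm quotas
  got_case <- 0L; got_ctrl <- 0L
  acc_g <- list(); acc_status <- list(); acc_strat <- list()
  guard <- 0L
  while (got_case < config$n_cases || got_ctrl < config$n_controls) {
    guard <- guard + 1L
    if (guard > 60L) stop("sampler failed to fill arm quotas")
    nc <- n_total
    strat <- sample(strat_names, nc, TRUE, prob = config$ancestry$weights)
    gp <- draw_geno(nc, vt$maf[planted_idx])
    colnames(gp) <- vt$id[planted_idx]
    score <- rep(0, nc)
    for (s in eff_sets) {
      cols <- match(vt$id[set_cols[[s]]], colnames(gp))
      if (length(cols))
        score <- score + lam[[s]] *
          (rowSums(gp[, cols, drop = FALSE] > 0) > 0)
    }
    status <- stats::rbinom(nc, 1L, stats::plogis(alpha + score))
    need_case <- config$n_cases - got_case
    need_ctrl <- config$n_controls - got_ctrl
    take <- (status == 1L & cumsum(status == 1L) <= need_case) |
            (status == 0L & cumsum(status == 0L) <= need_ctrl)
    acc_g[[guard]] <- gp[take, , drop = FALSE]
    acc_status[[guard]] <- status[take]
    acc_strat[[guard]] <- strat[take]
    got_case <- got_case + sum(status[take] == 1L)
    got_ctrl <- got_ctrl + sum(status[take] == 0L)
  }
  g_planted <- do.call(rbind, acc_g)
  status <- unlist(acc_status)
  stratum <- unlist(acc_strat)
  ids <- sprintf("P%06d", seq_len(n_total))

  # remaining variants (independent of status)
  gt <- matrix(0L, n_total, m)
  gt[, planted_idx] <- g_planted
  other_idx <- setdiff(seq_len(m), planted_idx)
  common <- vt$role == "common"
  rare_other <- other_idx[!common[other_idx]]
  if (length(rare_other))
    gt[, rare_other] <- draw_geno(n_total, vt$maf[rare_other])
  if (any(common)) {
    z <- stats::rnorm(sum(common))
    for (s in strat_names) {
      rows_s <- which(stratum == s)
      if (!length(rows_s)) next
      ps <- stats::plogis(stats::qlogis(vt$maf[common]) +
                          config$ancestry$offsets[[s]] * z)
      gt[rows_s, which(common)] <- draw_geno(length(rows_s), ps)
    }
  }

  # planted relative pairs (among controls; the pair shares a stratum)
  ctrl_rows <- which(status == 0L)
  rel <- data.frame(i = character(0), j = character(0),
                    relation = character(0), stringsAsFactors = FALSE)
  n_rel <- sum(config$related_pairs)
  if (n_rel > 0 && length(ctrl_rows) >= 2 * n_rel) {
    picked <- ctrl_rows[seq_len(2 * n_rel)]
    k <- 1L
    pop_p <- vt$maf  # population frequency for the non-shared gamete
    for (rtype in names(config$related_pairs)) {
      cnt <- config$related_pairs[[rtype]]
      if (cnt == 0) next
      for (u in seq_len(cnt)) {
        a <- picked[k]; b <- picked[k + 1L]; k <- k + 2L
        stratum[b] <- stratum[a]
        if (rtype == "duplicate") {
          gt[b, ] <- gt[a, ]
        } else {
          shared <- stats::rbinom(m, 1L, gt[a, ] / 2)
          other <- stats::rbinom(m, 1L, pop_p)
          if (rtype == "first_degree") {
            gt[b, ] <- shared + other
          } else {
            keep <- stats::rbinom(m, 1L, 0.5)
            gam <- ifelse(keep == 1L, shared, stats::rbinom(m, 1L, pop_p))
            gt[b, ] <- gam + other
          }
        }
        rel <- rbind(rel, data.frame(i = ids[a], j = ids[b],
                                     relation = rtype,
                                     stringsAsFactors = FALSE))
      }
    }
  } else if (n_rel > 0) {
    warning("too few controls to plant the requested related pairs; skipped")
  }

  # sporadic missingness + per-call quality fields
  miss <- matrix(stats::runif(n_total * m) < 0.004, n_total, m)
  gt[miss] <- NA_integer_
  gq <- dp <- ad <- NULL
  if (config$quality) {
    dp <- matrix(as.integer(pmax(10L, stats::rpois(n_total * m, 60))),
                 n_total, m)
    lowdp <- stats::runif(n_total * m) < 0.002
    dp[lowdp] <- sample(0:9, sum(lowdp), TRUE)
    gq <- matrix(as.integer(pmin(99, pmax(0, round(
      stats::rnorm(n_total * m, 75, 12))))), n_total, m)
    lowgq <- stats::runif(n_total * m) < 0.002
    gq[lowgq] <- sample(0:19, sum(lowgq), TRUE)
    ad <- matrix(0L, n_total, m)
    het <- !is.na(gt) & gt == 1L
    ad[het] <- as.integer(stats::rbinom(sum(het), dp[het], 0.5))
    hom <- !is.na(gt) & gt == 2L
    ad[hom] <- as.integer(dp[hom] - stats::rbinom(sum(hom), dp[hom], 0.02))
    rr <- !is.na(gt) & gt == 0L
    ad[rr] <- as.integer(stats::rbinom(sum(rr), dp[rr], 0.01))
    gq[is.na(gt)] <- NA_integer_
    dp[is.na(gt)] <- NA_integer_
    ad[is.na(gt)] <- NA_integer_
  }
  rownames(gt) <- ids
  if (config$quality) { rownames(gq) <- rownames(dp) <- rownames(ad) <- ids }

  # site-level statistics (a small fraction fail each rule)
  vt$qual <- round(100 + stats::rexp(m, 1 / 300), 2)
  vt$qd <- round(pmax(2.1, stats::rnorm(m, 15, 4)), 2)
  vt$mq <- round(stats::rnorm(m, 59.5, 0.7), 2)
  vt$rprs <- round(stats::rnorm(m, 0, 1), 3)
  vt$mqrs <- round(stats::rnorm(m, 0, 1), 3)
  vt$rprs[stats::runif(m) < 0.03] <- NA
  vt$mqrs[stats::runif(m) < 0.03] <- NA
  vt$filter <- ifelse(stats::runif(m) < 0.01,
                      "VQSRTrancheSNP99.00to99.90", "PASS")
  badsite <- stats::runif(m) < 0.005
  vt$qd[badsite] <- round(stats::runif(sum(badsite), 0, 1.9), 2)

  geno <- cohort_genotypes(gt = gt, gq = gq, dp = dp, ad = ad, variants = vt)

  gender <- sample(c("M", "F"), n_total, TRUE)
  gender[stats::runif(n_total) < 0.003] <- NA
  age <- round(pmin(90, pmax(20, stats::rnorm(
    n_total, ifelse(status == 1L, 60.2, 57.5), 12))), 1)
  covariates <- data.frame(participant = ids,
                           status = ifelse(status == 1L, "case", "control"),
                           gender = gender, age = age, stratum = stratum,
                           stringsAsFactors = FALSE)

  truth <- data.frame(participant = ids, status = status, stratum = stratum,
                      stringsAsFactors = FALSE)
  for (s in names(config$gene_sets)) {
    gs <- config$gene_sets[[s]]
    cols <- which(vt$role %in% c("rdv", "anchor") & vt$gene %in% gs)
    if (length(cols)) {
      sub <- gt[, cols, drop = FALSE] > 0
      sub[is.na(sub)] <- FALSE
      gene_of <- vt$gene[cols]
      ngene <- vapply(seq_len(n_total), function(i)
        length(unique(gene_of[sub[i, ]])), integer(1))
    } else ngene <- rep(0L, n_total)
    truth[[paste0("carrier_", s)]] <- ngene > 0
    truth[[paste0("n_genes_", s)]] <- ngene
    truth[[paste0("load_", s)]] <-
      as.character(cut(ngene, c(-Inf, 0, 1, Inf),
                       labels = c("zero", "one", "multi")))
  }
  structure(list(genotypes = geno, annotations = vt, covariates = covariates,
                 truth = truth, related = rel, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d cases + %d controls, %d variants (seed %d)\n",
              sum(x$covariates$status == "case"),
              sum(x$covariates$status == "control"),
              nrow(x$annotations), x$config$seed))
  invisible(x)
}

#' Simulate tumor phenotypes linked to RDV load
#'
#' For the case arm, draws per-tumor phenotypes whose distributions shift
#' with the participant's true load group in the configured gene-set:
#' age at diagnosis shifted down by the configured years (clipped at the age
#' floor, with a message when clipping occurs); somatic mutation counts by
#' consequence (Poisson, multiplied by the load-group TMB multiplier); 22
#' relative immune-cell fractions (Dirichlet, rows summing to 1) with an
#' additive shift of the expected M1 macrophage fraction; leukocyte fraction
#' in \[0, 1\]; and exponential survival with hazard tied to the absolute M1
#' fraction, with uniform censoring.
#'
#' @param cohort a `synthetic_cohort`.
#' @param config a [sim_config()] (default: the cohort's own).
#' @return data.frame keyed by case participant: cancer type (with an
#'   `is_hematological` flag), `age_at_diagnosis`, somatic counts
#'   (`missense`, `nonsense`, `frameshift`, `inframe`, `synonymous`),
#'   relative immune fractions (`frac_*`), `leukocyte_fraction`,
#'   `surv_time`, `surv_event`, and the driving `load_group`.
#' @export
simulate_tumor_phenotypes <- function(cohort, config = cohort$config) {
  pe <- config$phenotype_effects
  set.seed(config$seed + 1000003L)
  cases <- cohort$truth[cohort$truth$status == 1L, , drop = FALSE]
  stopifnot(nrow(cases) > 0)
  load_col <- paste0("load_", pe$set)
  if (!load_col %in% names(cases)) stop("unknown phenotype gene-set: ", pe$set)
  grp <- cases[[load_col]]
  n <- nrow(cases)
  shift <- c(zero = 0, one = unname(pe$onset_shift["one"]),
             multi = unname(pe$onset_shift["multi"]))[grp]
  base_age <- cohort$covariates$age[match(cases$participant,
                                          cohort$covariates$participant)]
  onset <- base_age - shift
  n_clip <- sum(onset < pe$age_floor)
  if (n_clip > 0)
    message(n_clip, " onset age(s) clipped at the floor of ", pe$age_floor)
  onset <- pmax(pe$age_floor, onset)
  mult <- c(zero = 1, one = unname(pe$tmb_multiplier["one"]),
            multi = unname(pe$tmb_multiplier["multi"]))[grp]
  somatic <- data.frame(
    missense = stats::rpois(n, 75 * mult),
    nonsense = stats::rpois(n, 8 * mult),
    frameshift = stats::rpois(n, 10 * mult),
    inframe = stats::rpois(n, 4 * mult),
    synonymous = stats::rpois(n, 30))
  # immune fractions: Dirichlet with M1 concentration shifted by load group
  conc <- 30
  base_frac <- rep(1 / 22, 22)
  names(base_frac) <- IMMUNE_CELLS
  m1s <- c(zero = 0, one = unname(pe$m1_shift["one"]),
           multi = unname(pe$m1_shift["multi"]))[grp]
  rel <- matrix(0, n, 22, dimnames = list(NULL, paste0("frac_", IMMUNE_CELLS)))
  for (i in seq_len(n)) {
    a <- base_frac * conc
    a["Macrophage_M1"] <- (base_frac["Macrophage_M1"] + m1s[i]) * conc
    g <- stats::rgamma(22, shape = a)
    rel[i, ] <- g / sum(g)
  }
  leuk <- stats::rbeta(n, 2, 3)
  m1_abs <- rel[, "frac_Macrophage_M1"] * leuk
  types <- c("breast", "lung_sq", "colon", "stomach", "ovary", "kidney_cc",
             "glioma", "heme")
  ctype <- sample(types, n, TRUE,
                  prob = c(0.22, 0.14, 0.13, 0.1, 0.12, 0.12, 0.12, 0.05))
  rate <- 0.08 * exp(pe$survival_loghr * m1_abs)
  t_ev <- stats::rexp(n, rate)
  t_cn <- stats::runif(n, 1, 12)
  out <- data.frame(participant = cases$participant, cancer_type = ctype,
                    is_hematological = ctype == "heme",
                    age_at_diagnosis = onset, stringsAsFactors = FALSE)
  out <- cbind(out, somatic, as.data.frame(rel))
  out$leukocyte_fraction <- leuk
  out$surv_time <- pmin(t_ev, t_cn)
  out$surv_event <- as.integer(t_ev <= t_cn)
  out$load_group <- grp
  out
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits the cohort VCF, tab-separated annotation / covariate / tumor tables,
#' a GMT gene-set catalog, and a JSON truth file into a directory — the input
#' layout [run_pipeline()] consumes.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @param tumor optional tumor table from [simulate_tumor_phenotypes()].
#' @return named vector of file paths, invisibly.
#' @export
write_synthetic_cohort <- function(cohort, dir, tumor = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             annotations = file.path(dir, "annotations.tsv"),
             covariates = file.path(dir, "covariates.tsv"),
             gene_sets = file.path(dir, "gene_sets.gmt"),
             truth = file.path(dir, "truth.json"))
  write_cohort_vcf(cohort$genotypes, paths["vcf"])
  wt <- function(d, p) utils::write.table(d, p, sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  ann <- cohort$annotations
  ann$carriers <- NULL
  wt(ann, paths["annotations"])
  wt(cohort$covariates, paths["covariates"])
  gmt <- vapply(names(cohort$config$gene_sets), function(nm)
    paste(c(nm, nm, cohort$config$gene_sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(gmt, paths["gene_sets"])
  jsonlite::write_json(list(truth = cohort$truth, related = cohort$related,
                            planted_logor =
                              as.list(cohort$config$planted_logor)),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  if (!is.null(tumor)) {
    paths["tumor"] <- file.path(dir, "tumor.tsv")
    wt(tumor, paths["tumor"])
  }
  invisible(paths)
}
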