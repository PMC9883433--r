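# Fixtures built in code: a 20-site QC cohort, a 12-variant classification
# fixture, and independent oracles (grid-maximized penalized likelihood,
# exhaustive rank-test enumeration, count-based kinship).

# minimal cohort constructor with clean quality fields unless overridden
tiny_cohort <- function(gt, variants = NULL, gq = 90, dp = 60, ad = NULL) {
  n <- nrow(gt); m <- ncol(gt)
  if (is.null(rownames(gt))) rownames(gt) <- sprintf("S%03d", seq_len(n))
  if (is.null(variants)) {
    variants <- data.frame(
      chrom = rep("1", m), pos = seq_len(m) * 100L,
      id = sprintf("v%03d", seq_len(m)), ref = "A", alt = "G",
      qual = 200, qd = 15, mq = 60, rprs = 0, mqrs = 0, filter = "PASS",
      stringsAsFactors = FALSE)
  }
  gqm <- matrix(as.integer(gq), n, m)
  dpm <- matrix(as.integer(dp), n, m)
  if (is.null(ad)) {
    adm <- matrix(0L, n, m)
    adm[gt == 1L & !is.na(gt)] <- as.integer(dp / 2)
    adm[gt == 2L & !is.na(gt)] <- as.integer(dp)
  } else adm <- ad
  gqm[is.na(gt)] <- NA_integer_
  dpm[is.na(gt)] <- NA_integer_
  adm[is.na(gt)] <- NA_integer_
  cohort_genotypes(gt = gt, gq = gqm, dp = dpm, ad = adm, variants = variants)
}

# 20-site QC fixture with hand-enumerated keep/drop expectations.
# 20 cases + 20 controls; sites 1-13 exercise site-statistic rules, 14-17
# genotype-call rules, 18-19 the case/control screen, 20 is clean.
qc_fixture <- function() {
  n <- 40L
  labels <- rep(c(TRUE, FALSE), each = 20)
  m <- 20L
  gt <- matrix(1L, n, m)  # all het so allele-balance rules bite
  rownames(gt) <- sprintf("S%03d", 1:n)
  variants <- data.frame(
    chrom = "1", pos = 1:20 * 1000L, id = sprintf("site%02d", 1:20),
    ref = "A", alt = "G", qual = 200, qd = 15, mq = 60, rprs = 0, mqrs = 0,
    filter = "PASS", stringsAsFactors = FALSE)
  variants$qual[2] <- 49.9          # fail qual
  variants$qd[3] <- 1.9             # fail qd
  variants$mq[4] <- 39              # fail mq
  variants$rprs[5] <- -3            # fail (strict >)
  variants$rprs[6] <- -2.999        # pass
  variants$mqrs[7] <- -10           # fail (strict >)
  variants$mqrs[8] <- -9.99         # pass
  variants$filter[9] <- "VQSRTrancheSNP99.00to99.90"  # fail tranche
  variants$filter[10] <- "VQSRTrancheSNP90.00to99.00" # pass (bound < 99)
  variants$rprs[11] <- NA           # absent rank sums do not fail
  variants$mqrs[11] <- NA
  variants$qual[12] <- 50; variants$qd[12] <- 2; variants$mq[12] <- 40 # boundary pass
  variants$qual[13] <- 10; variants$qd[13] <- 1  # fail two rules
  co <- tiny_cohort(gt, variants)
  # genotype-call rules (mask single calls; sites survive the screens)
  co$gq[1, 14] <- 19L                      # gq < 20 -> masked
  co$dp[2, 15] <- 9L                       # dp < 10 -> masked
  co$ad[3, 16] <- 3L                       # alt depth < 4 -> masked
  co$ad[4, 17] <- 29L; co$dp[4, 17] <- 100L  # ab 0.29 -> masked
  co$ad[5, 17] <- 30L; co$dp[5, 17] <- 100L  # ab 0.30 boundary -> retained
  # case/control screen: site 18 differential 0.10; site 19 case
  # completeness 0.85
  co$gt[1:2, 18] <- NA
  co$gt[1:3, 19] <- NA
  co$gt[21:22, 19] <- NA
  fixup_quality(co)
}

fixup_quality <- function(co) {
  co$gq[is.na(co$gt)] <- NA_integer_
  co$dp[is.na(co$gt)] <- NA_integer_
  co$ad[is.na(co$gt)] <- NA_integer_
  co
}

qc_fixture_expected_sites <- function() {
  # hand enumeration: site filters drop 2,3,4,5,7,9,13; screen drops 18,19
  sprintf("site%02d", setdiff(1:20, c(2, 3, 4, 5, 7, 9, 13, 18, 19)))
}

# 12-variant classification fixture: genes G1 (+ strand, external ClinVar
# anchor at CDS 900) and G2 (- strand, in-table anchor v12 at CDS 800).
# 50 cases + 50 controls; carrier counts chosen to pin the cohort MAF gates.
rdv_fixture <- function() {
  ann <- data.frame(
    id = sprintf("v%03d", 1:12),
    chrom = c(rep("1", 7), rep("2", 5)),
    pos = 1:12 * 100L, ref = "A", alt = "G",
    gene = c("G1", "G1", "G1", "G1", "G2", "G2", "G1", "G1", "G2", "G2",
             "G1", "G2"),
    strand = c(rep("+", 4), "-", "-", "+", "+", "-", "-", "+", "-"),
    cds_pos = c(50L, 60L, 120L, 1200L, 100L, 70L, 80L, 90L, 150L, 160L,
                110L, 800L),
    consequence = c("missense", "missense", "stopgain", "stopgain",
                    "frameshift", "missense", "missense", "missense",
                    "missense", "missense", "missense", "stopgain"),
    clinvar = c("pathogenic", "likely_pathogenic", "absent", "absent",
                "absent", "absent", "pathogenic", "pathogenic",
                "pathogenic", "pathogenic", "benign", "pathogenic"),
    maf_exac_nfe_nontcga = c(0, 0, NA, 0, NA, 0, 0.015, 0, 0, 0, 0, 0),
    maf_gnomad_asj = c(0, NA, 0, 0, 0, NA, 0, 0.012, 0, 0, 0, 0),
    maf_exac_global = 0,
    stringsAsFactors = FALSE)
  n <- 100L
  gt <- matrix(0L, n, 12)
  rownames(gt) <- sprintf("S%03d", 1:n)
  labels <- setNames(rep(c(TRUE, FALSE), each = 50), rownames(gt))
  gt[1, ] <- 1L                      # one case carries every variant
  gt[2:3, 9] <- 1L; gt[51:53, 9] <- 1L  # v009: case MAF 3%, control MAF 3%
  gt[2:3, 10] <- 1L; gt[51, 10] <- 1L   # v010: case MAF 3%, control MAF 1%
  list(geno = tiny_cohort(gt, ann_to_variants(ann)), ann = ann,
       labels = labels,
       expected_rdv = c("v001", "v002", "v003", "v005", "v010", "v012"),
       anchors_external = data.frame(
         gene = "G1", cds_pos = 900L, consequence = "stopgain",
         clinvar = "pathogenic", stringsAsFactors = FALSE))
}

ann_to_variants <- function(ann) {
  data.frame(chrom = ann$chrom, pos = ann$pos, id = ann$id,
             ref = if (is.null(ann$ref)) "A" else ann$ref,
             alt = if (is.null(ann$alt)) "G" else ann$alt,
             qual = 200, qd = 15, mq = 60, rprs = 0, mqrs = 0,
             filter = "PASS", stringsAsFactors = FALSE)
}

# independent penalized-likelihood oracle: direct objective + general-purpose
# optimizer, no shared code with the package internals
oracle_penalized_loglik <- function(beta, X, y, penalty = 0.5) {
  eta <- as.vector(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  ll <- sum(stats::dbinom(y, 1, p, log = TRUE))
  if (penalty > 0) {
    W <- diag(p * (1 - p))
    ll <- ll + penalty * log(det(t(X) %*% W %*% X))
  }
  ll
}

oracle_firth_beta <- function(X, y, penalty = 0.5, start = NULL) {
  if (is.null(start)) start <- rep(0, ncol(X))
  op <- stats::optim(start, oracle_penalized_loglik, X = X, y = y,
                     penalty = penalty, method = "BFGS",
                     control = list(fnscale = -1, maxit = 500, reltol = 1e-14))
  op$par
}

# exhaustive Mann-Whitney: all assignments of pooled values to group 1
oracle_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# tie-corrected Kruskal-Wallis H from the textbook formula (explicit sums)
oracle_kw_H <- function(groups) {
  pooled <- unlist(groups)
  N <- length(pooled)
  r <- rank(pooled)
  sizes <- lengths(groups)
  grp <- rep(seq_along(groups), sizes)
  Rj <- tapply(r, grp, sum)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / sizes) - 3 * (N + 1)
  ties <- table(pooled)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# count-based kinship oracle (explicit loops)
oracle_kinship <- function(g1, g2) {
  num <- 0; het1 <- 0; het2 <- 0
  for (k in seq_along(g1)) {
    if (is.na(g1[k]) || is.na(g2[k])) next
    if (g1[k] == 1 && g2[k] == 1) num <- num + 1
    if (abs(g1[k] - g2[k]) == 2) num <- num - 2
    if (g1[k] == 1) het1 <- het1 + 1
    if (g2[k] == 1) het2 <- het2 + 1
  }
  num / (het1 + het2)
}

# fast lean config for simulation-driven tests
lean_config <- function(n_cases, n_controls, n_genes = 10, seed = 1,
                        logor = 0, vpg = 2,
                        maf = c(3e-3, 6e-3, 1e-2), ...) {
  genes <- data.frame(gene = sprintf("GEN%04d", seq_len(n_genes)),
                      strand = "+", cds_length = 1500L,
                      stringsAsFactors = FALSE)
  sim_config(n_cases = n_cases, n_controls = n_controls, genes = genes,
             gene_sets = list(SET1 = genes$gene[1:min(5, n_genes)]),
             planted_logor = c(SET1 = logor), variants_per_gene = vpg,
             maf_spectrum = maf, n_common_snps = 0, synonymous_rate = 0,
             related_pairs = c(duplicate = 0, first_degree = 0,
                               second_degree = 0),
             distractors = FALSE, quality = FALSE, seed = seed, ...)
}
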