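test_that("configuration is validated", {
  expect_error(sim_config(planted_logor = c(NOPE = 0.5)), "unknown gene-set")
  g <- data.frame(gene = "A", strand = "+", cds_length = 900L)
  expect_error(sim_config(genes = g, gene_sets = list(S = "B"),
                          planted_logor = c(S = 0)), "undeclared")
  expect_error(sim_config(maf_spectrum = c(0.1, 0.6)), "maf_spectrum")
  cfg <- sim_config(n_cases = 10, n_controls = 10)
  expect_s3_class(cfg, "sim_config")
  expect_true(all(names(cfg$planted_logor) %in% names(cfg$gene_sets)))
})

test_that("identical config and seed reproduce byte-identical VCF output", {
  cfg <- sim_config(n_cases = 40, n_controls = 40, n_null_genes = 2,
                    n_common_snps = 50, synonymous_rate = 0.2, seed = 77)
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_cohort_vcf(simulate_cohort(cfg)$genotypes, f1)
  write_cohort_vcf(simulate_cohort(cfg)$genotypes, f2)
  expect_identical(readLines(f1), readLines(f2))
  cfg2 <- sim_config(n_cases = 40, n_controls = 40, n_null_genes = 2,
                     n_common_snps = 50, synonymous_rate = 0.2, seed = 78)
  expect_false(identical(simulate_cohort(cfg2)$genotypes$gt,
                         simulate_cohort(cfg)$genotypes$gt))
})

test_that("VCF output round-trips through the reader", {
  cfg <- sim_config(n_cases = 25, n_controls = 25, n_null_genes = 2,
                    n_common_snps = 30, synonymous_rate = 0.2, seed = 5)
  co <- simulate_cohort(cfg)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_cohort_vcf(co$genotypes, f)
  back <- read_cohort_vcf(f)
  expect_identical(back$samples, co$genotypes$samples)
  expect_equal(unname(back$gt), unname(co$genotypes$gt))
  expect_equal(unname(back$ad), unname(co$genotypes$ad))
  expect_equal(back$variants$pos, co$genotypes$variants$pos)
  expect_equal(back$variants$filter, co$genotypes$variants$filter)
  expect_equal(back$variants$qd, co$genotypes$variants$qd, tolerance = 1e-6)
})

test_that("null effects leave carrier frequencies balanced between arms", {
  cfg <- lean_config(2000, 2000, seed = 301, logor = 0)
  co <- simulate_cohort(cfg)
  carrier <- co$truth$carrier_SET1
  f_case <- mean(carrier[co$truth$status == 1])
  f_ctrl <- mean(carrier[co$truth$status == 0])
  se <- sqrt(f_ctrl * (1 - f_ctrl) * (1 / 2000 + 1 / 2000))
  expect_lt(abs(f_case - f_ctrl), 3 * se + 1e-9)
})

test_that("planted log-odds reproduce the target carrier odds ratio at large n", {
  cfg <- lean_config(10000, 10000, seed = 303, logor = log(1.5),
                     maf = c(2e-3, 4e-3))
  co <- simulate_cohort(cfg)
  carrier <- co$truth$carrier_SET1
  y <- co$truth$status
  tab <- table(carrier, y)
  or <- (tab["TRUE", "1"] * tab["FALSE", "0"]) /
        (tab["FALSE", "1"] * tab["TRUE", "0"])
  # MC standard error of the log-OR from the 2x2 counts
  se <- sqrt(sum(1 / tab))
  expect_lt(abs(log(or) - log(1.5)), 3 * se)
})

test_that("planted relatives carry the intended genotype-sharing structure", {
  cfg <- lean_config(100, 200, seed = 307)
  cfg$related_pairs <- c(duplicate = 1, first_degree = 1, second_degree = 1)
  cfg$n_common_snps <- 4000
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$related), 3)
  gt <- co$genotypes$gt
  for (r in seq_len(nrow(co$related))) {
    phi <- estimate_kinship(gt[co$related$i[r], ], gt[co$related$j[r], ])$phi
    target <- c(duplicate = 0.5, first_degree = 0.25,
                second_degree = 0.125)[co$related$relation[r]]
    expect_lt(abs(phi - unname(target)), 0.05)
  }
})

test_that("synonymous background emerges at the configured rate", {
  cfg <- sim_config(n_cases = 1500, n_controls = 1500, n_null_genes = 2,
                    n_common_snps = 0, synonymous_rate = 1.5,
                    related_pairs = c(duplicate = 0, first_degree = 0,
                                      second_degree = 0),
                    distractors = FALSE, quality = FALSE, seed = 311)
  co <- simulate_cohort(cfg)
  bg <- synonymous_background(co$genotypes, co$annotations)
  # carried genes per participant: generative mean 1.5, attenuated by the
  # cohort-MAF gate clipping variants whose observed MAF drifts above 0.05%
  expect_gt(mean(bg$n_syn_genes), 0.5)
  expect_lt(mean(bg$n_syn_genes), 2.5)
  # independent of status
  y <- co$truth$status
  expect_gt(mann_whitney(bg$n_syn_genes[y == 1],
                         bg$n_syn_genes[y == 0])$p_value, 1e-3)
})

test_that("tumor phenotypes respect the generative contracts", {
  cfg <- lean_config(2500, 500, seed = 313, logor = log(1.8),
                     maf = c(5e-3, 1e-2))
  co <- simulate_cohort(cfg)
  tum <- simulate_tumor_phenotypes(co)
  expect_equal(nrow(tum), 2500)
  rel <- as.matrix(tum[, grep("^frac_", names(tum))])
  expect_equal(ncol(rel), 22)
  expect_equal(unname(rowSums(rel)), rep(1, nrow(tum)), tolerance = 1e-9)
  expect_true(all(tum$leukocyte_fraction >= 0 & tum$leukocyte_fraction <= 1))
  expect_true(all(tum$surv_time > 0))
  expect_true(all(tum$surv_event %in% 0:1))
  expect_true(all(tum$age_at_diagnosis >= cfg$phenotype_effects$age_floor))
  # TMB multiplier: multi-vs-zero ratio approaches the configured 2.0
  tmb <- compute_tmb(tum)
  g <- tum$load_group
  if (sum(g == "multi") > 30) {
    ratio <- mean(tmb[g == "multi"]) / mean(tmb[g == "zero"])
    expect_equal(ratio, 2.0, tolerance = 0.15)
  }
  # onset shift direction
  expect_lt(mean(tum$age_at_diagnosis[g != "zero"]),
            mean(tum$age_at_diagnosis[g == "zero"]))
})

test_that("zero phenotype effects leave load groups exchangeable", {
  cfg <- lean_config(1200, 300, seed = 317, logor = log(2),
                     maf = c(5e-3, 1e-2))
  cfg$phenotype_effects <- list(set = "SET1",
                                onset_shift = c(one = 0, multi = 0),
                                tmb_multiplier = c(one = 1, multi = 1),
                                m1_shift = c(one = 0, multi = 0),
                                survival_loghr = 0, age_floor = 18)
  co <- simulate_cohort(cfg)
  tum <- simulate_tumor_phenotypes(co)
  g <- tum$load_group
  expect_gt(mann_whitney(tum$age_at_diagnosis[g == "zero"],
                         tum$age_at_diagnosis[g != "zero"],
                         exact = FALSE)$p_value, 0.001)
  expect_gt(mann_whitney(compute_tmb(tum)[g == "zero"],
                         compute_tmb(tum)[g != "zero"],
                         exact = FALSE)$p_value, 0.001)
})
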