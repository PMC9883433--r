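test_that("rarity gates follow the both-arms / reference-frequency rules", {
  ann1 <- data.frame(maf_exac_nfe_nontcga = 0, maf_gnomad_asj = 0)
  expect_true(is_rare(0.03, 0.01, ann1))      # common in one arm only
  expect_false(is_rare(0.03, 0.03, ann1))     # common in both arms
  expect_true(is_rare(0.02, 0.03, ann1))      # boundary: 2% is not > 2%
  ann2 <- data.frame(maf_exac_nfe_nontcga = 0.015, maf_gnomad_asj = 0)
  expect_false(is_rare(0, 0, ann2))
  ann3 <- data.frame(maf_exac_nfe_nontcga = 0, maf_gnomad_asj = 0.011)
  expect_false(is_rare(0, 0, ann3))
  ann4 <- data.frame(maf_exac_nfe_nontcga = NA, maf_gnomad_asj = NA)
  expect_true(is_rare(0, 0, ann4))                       # absent -> 0
  expect_false(is_rare(0, 0, ann4, absent_ref = "exclude"))
  expect_true(is_rare(0, 0, data.frame(maf_exac_nfe_nontcga = 0,
                                       maf_gnomad_asj = 0)))
})

test_that("deleteriousness: direct P/LP and the 5' LOF propagation rule", {
  base <- data.frame(gene = "G", consequence = "missense",
                     cds_pos = 10L, clinvar = "likely_pathogenic")
  expect_true(is_deleterious(base))
  anchors <- data.frame(gene = "G", cds_pos = 900L, consequence = "frameshift",
                        clinvar = "pathogenic")
  v5p <- data.frame(gene = "G", consequence = "stopgain", cds_pos = 120L,
                    clinvar = "absent")
  expect_true(is_deleterious(v5p, anchors))
  v3p <- data.frame(gene = "G", consequence = "stopgain", cds_pos = 1200L,
                    clinvar = "absent")
  expect_false(is_deleterious(v3p, anchors))
  # missense never propagates; boundary: at the anchor is not 5' of it
  vmis <- data.frame(gene = "G", consequence = "missense", cds_pos = 120L,
                     clinvar = "absent")
  expect_false(is_deleterious(vmis, anchors))
  vat <- data.frame(gene = "G", consequence = "stopgain", cds_pos = 900L,
                    clinvar = "absent")
  expect_false(is_deleterious(vat, anchors))
  # most 3' anchor defines the boundary
  two_anchors <- rbind(anchors, data.frame(gene = "G", cds_pos = 300L,
                                           consequence = "stopgain",
                                           clinvar = "pathogenic"))
  v_mid <- data.frame(gene = "G", consequence = "frameshift", cds_pos = 600L,
                      clinvar = "absent")
  expect_true(is_deleterious(v_mid, two_anchors))
  # likely-pathogenic anchors can be excluded
  lp_anchor <- data.frame(gene = "G", cds_pos = 900L,
                          consequence = "stopgain",
                          clinvar = "likely_pathogenic")
  expect_true(is_deleterious(v5p, lp_anchor))
  expect_false(is_deleterious(v5p, lp_anchor, include_lp_anchors = FALSE))
  # truncating variant without CDS position: skipped for rule (ii)
  v_nocds <- data.frame(gene = "G", consequence = "frameshift",
                        cds_pos = NA_integer_, clinvar = "absent")
  expect_message(expect_false(is_deleterious(v_nocds, anchors)), "CDS")
})

test_that("the 12-variant fixture reproduces the hand-enumerated RDV set", {
  fx <- rdv_fixture()
  ann_all <- rbind(
    cbind(fx$ann[, c("gene", "cds_pos", "consequence", "clinvar")]),
    fx$anchors_external)
  cl <- classify_rdv(fx$geno, fx$ann, fx$labels)
  # re-run deleteriousness with the external G1 anchor record included
  cl$deleterious <- is_deleterious(cl, anchors = ann_all)
  cl$rdv <- cl$rare & cl$deleterious
  expect_identical(cl$id[cl$rdv], fx$expected_rdv)
})

test_that("classification is order-invariant and the 1% mode is a subset", {
  fx <- rdv_fixture()
  perm <- sample(nrow(fx$ann))
  geno_p <- subset_cohort(fx$geno, variants = perm)
  cl1 <- classify_rdv(fx$geno, fx$ann, fx$labels)
  cl2 <- classify_rdv(geno_p, fx$ann[perm, ], fx$labels)
  expect_setequal(cl1$id[cl1$rdv], cl2$id[cl2$rdv])
  sens <- classify_rdv(fx$geno, fx$ann, fx$labels, cohort_max = 0.01)
  expect_true(all(sens$id[sens$rdv] %in% cl1$id[cl1$rdv]))
  # and on a simulated cohort
  cfg <- lean_config(300, 300, seed = 17, maf = c(2e-3, 8e-3, 1.2e-2))
  co <- simulate_cohort(cfg)
  labels <- setNames(co$covariates$status == "case",
                     co$covariates$participant)
  c2 <- classify_rdv(co$genotypes, co$annotations, labels)
  c1 <- classify_rdv(co$genotypes, co$annotations, labels, cohort_max = 0.01)
  expect_true(all(c1$id[c1$rdv] %in% c2$id[c2$rdv]))
})

test_that("RDV matrix uses dominant carrier coding", {
  ann <- data.frame(id = c("va", "vb", "vc"), chrom = "1", pos = 1:3,
                    gene = c("G1", "G1", "G2"), cds_pos = 1:3,
                    consequence = "missense", clinvar = "pathogenic",
                    maf_exac_nfe_nontcga = 0, maf_gnomad_asj = 0,
                    maf_exac_global = 0, rdv = TRUE)
  gt <- rbind(A = c(1L, 0L, 0L), B = c(2L, 0L, 0L), C = c(1L, 1L, 1L),
              D = c(0L, 0L, 0L))
  geno <- tiny_cohort(gt, ann_to_variants(ann))
  rdv <- build_rdv_matrix(geno, ann)
  expect_identical(rdv$counts["A", "G1"], 1L)
  expect_identical(rdv$counts["B", "G1"], 1L)  # hom-alt counted once
  expect_identical(rdv$counts["C", "G1"], 2L)  # two distinct sites
  expect_identical(unname(rowSums(rdv$counts)["D"]), 0)
  long <- as.data.frame(rdv)
  expect_false("D" %in% long$participant)
  expect_true(all(long$carrier))
})

test_that("synonymous background counts genes, not variants, under both gates", {
  # 10 participants; gene S1 has two qualifying synonymous variants, S2 has
  # one too-frequent (cohort MAF 6e-4 > 5e-4 with 10 carriers of 1000)
  n <- 1000
  ann <- data.frame(id = c("s1", "s2", "s3", "s4"), chrom = c("1", "1", "2", "X"),
                    pos = 1:4, gene = c("S1", "S1", "S2", "S3"),
                    cds_pos = 1:4, consequence = "synonymous",
                    clinvar = "absent", maf_exac_nfe_nontcga = 0,
                    maf_gnomad_asj = 0,
                    maf_exac_global = c(0, 0, 0, 0))
  gt <- matrix(0L, n, 4, dimnames = list(sprintf("P%04d", 1:n), NULL))
  gt[1, 1:2] <- 1L          # two variants, same gene -> contributes 1
  gt[1:12, 3] <- 1L         # cohort MAF 12/2000 = 6e-4 -> excluded
  gt[1, 4] <- 1L            # X chromosome -> excluded
  geno <- tiny_cohort(gt, ann_to_variants(ann))
  bg <- synonymous_background(geno, ann)
  expect_equal(bg$n_syn_genes[1], 1)
  expect_equal(sum(bg$n_syn_genes), 1)
  # ExAC global gate
  ann2 <- ann; ann2$maf_exac_global <- c(1e-4, 1e-4, 0, 0)
  bg2 <- synonymous_background(geno, ann2)
  expect_equal(sum(bg2$n_syn_genes), 0)
})
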