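manual_rdv2 <- function(counts) {
  structure(list(counts = counts, participants = rownames(counts),
                 genes = colnames(counts),
                 variants = data.frame(id = colnames(counts),
                                       gene = colnames(counts))),
            class = "rdv_matrix")
}

test_that("load groups count distinct genes, not variants, and partition the cohort", {
  counts <- rbind(A = c(2L, 0L, 0L),  # 2 RDVs in one set gene -> one
                  B = c(1L, 1L, 0L),  # 2 set genes -> multi
                  C = c(0L, 0L, 1L),  # only outside the set -> zero
                  D = c(0L, 0L, 0L))
  colnames(counts) <- c("G1", "G2", "G3")
  rdv <- manual_rdv2(counts)
  lg <- assign_load_groups(rdv, c("G1", "G2"), "S")
  expect_equal(as.character(lg$group), c("one", "multi", "zero", "zero"))
  expect_equal(lg$n_rdv_genes, c(1L, 2L, 0L, 0L))
  expect_equal(sum(table(lg$group)), 4)
  expect_error(assign_load_groups(rdv, character(0)), NA)  # empty set -> all zero
})

test_that("Mann-Whitney: exact enumeration examples and tie handling", {
  mt <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(mt$statistic), 0)
  expect_equal(mt$p_value, 0.1)  # 2 of C(6,3)=20 assignments as extreme
  x <- c(2, 4, 7)
  same <- mann_whitney(x, x)
  expect_equal(unname(same$statistic), length(x)^2 / 2)
  expect_equal(same$p_value, 1)
  allties <- mann_whitney(rep(5, 12), rep(5, 9))
  expect_equal(allties$p_value, 1)
})

test_that("Mann-Whitney matches exhaustive enumeration on all small instances", {
  set.seed(211)
  sizes <- list(c(3, 3), c(2, 5), c(4, 4), c(5, 5), c(2, 8), c(9, 1))
  for (sz in sizes) {
    for (rep in 1:3) {
      x <- sample(1:5, sz[1], replace = TRUE)  # ties likely
      y <- sample(1:5, sz[2], replace = TRUE)
      mt <- mann_whitney(x, y, exact = TRUE)
      expect_equal(mt$p_value, oracle_mw_p(x, y), tolerance = 1e-12)
    }
  }
})

test_that("normal approximation tracks the exact p at n = 8 per group", {
  set.seed(223)
  for (rep in 1:5) {
    x <- rnorm(8); y <- rnorm(8, 0.5)
    pe <- mann_whitney(x, y, exact = TRUE)$p_value
    pn <- mann_whitney(x, y, exact = FALSE)$p_value
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("untied exact p agrees with the reference distribution", {
  set.seed(227)
  x <- sample(100, 6); y <- sample(200:300, 7)
  pe <- mann_whitney(x, y, exact = TRUE)$p_value
  pw <- wilcox.test(x, y, exact = TRUE)$p.value
  expect_equal(pe, pw, tolerance = 1e-12)
})

test_that("Kruskal-Wallis: tie-corrected H, degenerate input, 2-group equivalence", {
  g <- list(c(1, 2, 2, 5), c(3, 3, 7), c(2, 8, 9, 9))
  kw <- kruskal_wallis(g)
  expect_equal(unname(kw$statistic), oracle_kw_H(g), tolerance = 1e-10)
  expect_error(kruskal_wallis(list(1:5)), "two")
  expect_equal(kruskal_wallis(list(c(3, 3), c(3, 3, 3)))$p_value, 1)
  set.seed(229)
  x <- rnorm(30); y <- rnorm(25, 0.4)
  p_kw <- kruskal_wallis(list(x, y))$p_value
  p_mw <- mann_whitney(x, y, exact = FALSE, correct = FALSE)$p_value
  expect_equal(p_kw, p_mw, tolerance = 1e-9)
})

test_that("TMB follows the stated consequence list over 38 Mb", {
  counts <- data.frame(missense = c(50, 0, 0), nonsense = c(10, 0, 0),
                       frameshift = c(10, 0, 0), inframe = c(6, 0, 0),
                       synonymous = c(100, 0, 55))
  expect_equal(compute_tmb(counts), c(2, 0, 0))
  # linearity and category-order invariance
  a <- data.frame(missense = 3, nonsense = 1, frameshift = 2, inframe = 0)
  b <- data.frame(inframe = 0, frameshift = 2, nonsense = 1, missense = 3)
  expect_equal(compute_tmb(a), compute_tmb(b))
  expect_equal(compute_tmb(a * 3), 3 * compute_tmb(a))
  expect_error(compute_tmb(data.frame(missense = -1, nonsense = 0,
                                      frameshift = 0, inframe = 0)),
               "negative")
})

test_that("absolute immune fractions scale by leukocyte fraction", {
  rel <- matrix(c(0.25, 0.75, 0.5, 0.5), 2, byrow = TRUE)
  out <- absolute_immune_fraction(rel, c(0.4, 0))
  expect_equal(out[1, 1], 0.10)
  expect_equal(out[2, ], c(0, 0))
  set.seed(233)
  for (rep in 1:10) {
    k <- sample(3:22, 1)
    r <- matrix(rgamma(5 * k, 1), 5)
    r <- r / rowSums(r)
    lf <- runif(5)
    expect_equal(rowSums(absolute_immune_fraction(r, lf)), lf,
                 tolerance = 1e-12)
  }
  expect_error(absolute_immune_fraction(rel, c(1.2, 0.5)), "leukocyte")
  expect_error(absolute_immune_fraction(rel * 2, c(0.5, 0.5)), "sum")
})

test_that("Cox association: recovery, no-variation flag, stratified fit", {
  set.seed(239)
  n <- 2000
  x <- runif(n)
  t_ev <- rexp(n, 0.2 * exp(0.5 * x))
  t_cn <- runif(n, 1, 30)
  time <- pmin(t_ev, t_cn); event <- as.integer(t_ev <= t_cn)
  fit <- cox_survival(time, event, x)
  expect_false(fit$flagged)
  expect_equal(fit$log_hr, 0.5, tolerance = 0.2)
  flat <- cox_survival(time, event, rep(0.3, n))
  expect_true(flat$flagged)
  strata <- sample(c("a", "b", "c"), n, replace = TRUE)
  event2 <- event; event2[strata == "c"] <- 0L
  expect_message(f2 <- cox_survival(time, event2, x, strata), "skipped")
  expect_false(f2$flagged)
  expect_equal(f2$log_hr, 0.5, tolerance = 0.3)
})

test_that("permuted covariate yields well-behaved Cox p-values", {
  set.seed(241)
  n <- 300
  x <- runif(n)
  time <- rexp(n, 0.3); event <- rep(1L, n)
  ps <- replicate(40, cox_survival(time, event, sample(x))$p_value)
  expect_gt(mean(ps > 0.05), 0.7)
  expect_gt(min(ps), 0)
})

test_that("dose-response contrasts: null ORs near 1, empty multi handled", {
  set.seed(251)
  n <- 3000
  ng <- sample(0:2, n, replace = TRUE, prob = c(0.9, 0.08, 0.02))
  load <- data.frame(participant = sprintf("P%04d", 1:n), gene_set = "S",
                     n_rdv_genes = ng,
                     group = cut(ng, c(-Inf, 0, 1, Inf),
                                 labels = c("zero", "one", "multi")))
  y <- rbinom(n, 1, 0.5)
  res <- load_dose_association(load, y)
  expect_equal(nrow(res), 2)
  expect_lt(max(abs(log(res$odds_ratio))), 0.6)
  load2 <- load; load2$group[load2$group == "multi"] <- "one"
  expect_message(res2 <- load_dose_association(load2, y), "skipped")
  expect_equal(res2$contrast, "one_vs_zero")
})

test_that("planted additive effects produce a dose-response in expectation", {
  set.seed(257)
  n <- 6000
  ng <- sample(0:2, n, replace = TRUE, prob = c(0.85, 0.1, 0.05))
  y <- rbinom(n, 1, plogis(-0.2 + 0.45 * ng))
  load <- data.frame(participant = sprintf("P%04d", 1:n), gene_set = "S",
                     n_rdv_genes = ng,
                     group = cut(ng, c(-Inf, 0, 1, Inf),
                                 labels = c("zero", "one", "multi")))
  res <- load_dose_association(load, y)
  or1 <- res$odds_ratio[res$contrast == "one_vs_zero"]
  or2 <- res$odds_ratio[res$contrast == "multi_vs_zero"]
  expect_gt(or2, or1)
  expect_equal(log(or1), 0.45, tolerance = 0.35)
  expect_equal(log(or2), 0.9, tolerance = 0.4)
})

test_that("pairwise and omnibus phenotype contrasts are assembled per group", {
  set.seed(263)
  grp <- factor(rep(c("zero", "one", "multi"), c(50, 20, 10)),
                levels = c("zero", "one", "multi"))
  vals <- rnorm(80) - 2 * (grp != "zero")
  out <- load_phenotype_tests(vals, grp)
  expect_setequal(out$contrast, c("any_vs_zero", "one_vs_zero",
                                  "multi_vs_zero", "kruskal_wallis"))
  expect_lt(out$p_value[out$contrast == "any_vs_zero"], 0.01)
})
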