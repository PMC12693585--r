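test_that("TPM normalises by length in kb and sums to one million", {
  one <- matrix(5L, 1, 2, dimnames = list("g1", c("s1", "s2")))
  expect_equal(unname(tpm(one, 1000)[1, ]), c(1e6, 1e6))
  two <- matrix(c(10L, 10L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(tpm(two, c(1000, 1000))[, 1]), c(5e5, 5e5))
  m <- matrix(c(30L, 10L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(tpm(m, c(1000, 1000))[, 1]), c(7.5e5, 2.5e5))
  # length normalisation: same counts, half the length, double the rate
  m2 <- matrix(c(10L, 10L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(tpm(m2, c(500, 1000))[, 1]),
               c(2e6 / 3, 1e6 / 3))
  set.seed(2)
  big <- matrix(rnbinom(600, mu = 100, size = 10), 200, 3,
                dimnames = list(sprintf("g%d", 1:200), NULL))
  out <- tpm(big, sample(500:2000, 200, replace = TRUE))
  expect_equal(unname(colSums(out)), rep(1e6, 3), tolerance = 1e-9)
  expect_error(tpm(matrix(0L, 2, 1), c(1, 1)), "all-zero")
  expect_error(tpm(matrix(1L, 1, 1), 0), "positive")
})

test_that("log2fc compares group means with a pseudocount and is antisymmetric", {
  expect_equal(log2fc(c(4, 4), c(4, 4)), 0)
  expect_equal(log2fc(8, 4, pseudocount = 0), 1)
  expect_equal(log2fc(c(3, 9), c(1, 2), pseudocount = 0.5),
               -log2fc(c(1, 2), c(3, 9), pseudocount = 0.5))
  m <- matrix(1:4, 2); n <- matrix(c(2, 2, 2, 2), 2)
  expect_length(log2fc(m, n), 2L)
  expect_error(log2fc(-1, 2), "non-negative")
})

test_that("significance rule has inclusive boundaries and flags missing p", {
  expect_true(classify_de(0.5, 0.05))
  expect_true(classify_de(-0.5, 0.05))
  expect_false(classify_de(0.49, 0.001))
  expect_false(classify_de(-3, 0.2))
  expect_false(classify_de(3, NA))
  got <- classify_de(c(1, 2, 0.1), c(0.01, NA, 0.01))
  expect_equal(as.logical(got), c(TRUE, FALSE, FALSE))
  expect_equal(attr(got, "n_missing_p"), 1L)
})

test_that("hybrid allele filter drops X-linked and sparsely expressed genes", {
  tab <- rbind(
    data.frame(gene = "gx", chrom = "X", allele = "A",
               s1 = 10, s2 = 10, s3 = 10),
    data.frame(gene = "gx", chrom = "X", allele = "B",
               s1 = 10, s2 = 10, s3 = 10),
    data.frame(gene = "g3", chrom = "2L", allele = "A",
               s1 = 5, s2 = 0, s3 = 0),
    data.frame(gene = "g3", chrom = "2L", allele = "B",
               s1 = 4, s2 = 3, s3 = 0),
    data.frame(gene = "g4", chrom = "3R", allele = "A",
               s1 = 5, s2 = 2, s3 = 0),
    data.frame(gene = "g4", chrom = "3R", allele = "B",
               s1 = 4, s2 = 3, s3 = 0))
  out <- hybrid_allele_filter(tab)
  expect_false("gx" %in% out$gene)   # X chromosome excluded
  expect_false("g3" %in% out$gene)   # expressed in 3 < 4 pooled columns
  expect_true("g4" %in% out$gene)    # expressed in exactly 4: kept
  expect_equal(nrow(out), 2L)
})

test_that("divergence fractions and group chi-squared tests are consistent", {
  de <- data.frame(gene = sprintf("g%03d", 1:300),
                   significant = rep(c(TRUE, FALSE), c(60, 240)))
  groups <- list(acp = de$gene[1:100],          # 60/100 significant
                 rand = de$gene[101:200],       # 0/100
                 ctrl = de$gene[41:140])        # 20/100
  out <- divergence_fraction(groups, de, control = "ctrl")
  expect_equal(out$pct_significant, c(60, 0, 20))
  expect_true(is.na(out$p_raw[out$group == "ctrl"]))
  hand <- compare_groups_chi2(60, 100, 20, 100)
  expect_equal(out$chi2[1], hand$chi2)
  expect_equal(out$p_adj[1:2], p.adjust(out$p_raw[1:2], "BH"))
  all_sig <- divergence_fraction(list(a = de$gene[1:60], b = de$gene[1:60]), de,
                                 control = "b")
  expect_equal(all_sig$pct_significant, c(100, 100))
  expect_error(divergence_fraction(list(a = character(0)), de), "empty")
})

test_that("identical groups give chi2 = 0 and p = 1; 30 vs 10 gives 12.5", {
  de <- data.frame(gene = sprintf("g%03d", 1:200),
                   significant = rep(c(TRUE, FALSE, TRUE, FALSE),
                                     c(30, 70, 10, 90)))
  out <- divergence_fraction(list(a = de$gene[1:100], b = de$gene[101:200]),
                             de, control = "b")
  expect_equal(out$chi2[1], 12.5)
  same <- divergence_fraction(list(a = de$gene[1:100], b = de$gene[1:100]),
                              de, control = "b")
  expect_equal(same$chi2[1], 0)
  expect_equal(same$p_raw[1], 1)
})

test_that("tertile binning uses (0,33], (33,66], (66,100] with d=0 in bin 1", {
  d <- setNames(c(0, 33, 33.5, 66, 67, 100), sprintf("g%d", 1:6))
  de <- data.frame(gene = names(d), log2fc = c(0, 2, 1, -2, 0, 1.5))
  out <- tertile_enrichment(d, de)
  expect_equal(out$n, c(2L, 2L, 2L))
  # strict |lfc| > 1: g2 (2) yes, g3 (1) no; g4 (-2) yes; g6 (1.5) yes
  expect_equal(out$n_changed, c(1L, 1L, 1L))
  expect_equal(out$pct_changed, c(50, 50, 50))
  expect_error(tertile_enrichment(setNames(101, "g"), de), "\\[0, 100\\]")
})

test_that("enrichment planted in the top tertile is detected against a control", {
  set.seed(55)
  n <- 120
  d <- setNames(runif(n, 0, 100), sprintf("a%03d", 1:n))
  hot <- d > 66
  lfc <- ifelse(hot, rnorm(n, 0, 2.5), rnorm(n, 0, 0.3))
  de <- data.frame(gene = names(d), log2fc = lfc)
  ctrl_d <- setNames(runif(n, 0, 100), sprintf("c%03d", 1:n))
  ctrl_de <- data.frame(gene = names(ctrl_d), log2fc = rnorm(n, 0, 0.3))
  out <- tertile_enrichment(d, de, control_d = ctrl_d, control_de = ctrl_de)
  expect_equal(which.max(out$pct_changed), 3L)
  expect_lt(out$p_raw[3], 0.05)
})

test_that("Mann-Whitney shift test is exact for small samples", {
  r <- distribution_shift_test(c(1, 2, 3), c(10, 20, 30))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_equal(distribution_shift_test(c(10, 20, 30), c(1, 2, 3))$p, 0.1)
  same <- distribution_shift_test(c(1.5, 2.5), c(1.5, 2.5))
  expect_equal(same$p, 1)
  expect_error(distribution_shift_test(numeric(0), 1), "empty")
})

test_that("densitometry normalises band intensity by fragment length", {
  bands <- data.frame(allele = c("mel", "mel", "sim"),
                      intensity = c(300, 100, 400),
                      fragment_length = c(300, 100, 400))
  expect_equal(densitometry_log2fc(bands, "mel"), 1)  # 2 vs 1 per-nt signal
  expect_equal(densitometry_log2fc(bands, "sim"), -1)
  eq <- data.frame(allele = c("a", "b"), intensity = c(50, 100),
                   fragment_length = c(100, 200))
  expect_equal(densitometry_log2fc(eq, "a"), 0)
  zero <- data.frame(allele = c("a", "b"), intensity = c(0, 10),
                     fragment_length = c(100, 100))
  expect_error(densitometry_log2fc(zero, "a"), "zero")
})

test_that("hybrid/non-hybrid normalisation is a guarded ratio", {
  expect_equal(hybrid_vs_nonhybrid_ratio(0.7, 0.7), 1)
  expect_equal(hybrid_vs_nonhybrid_ratio(-2, 1), -0.5)
  expect_error(hybrid_vs_nonhybrid_ratio(0, 1), "undefined")
})

test_that("true log2 fold changes are recovered from simulated counts", {
  set.seed(123)
  cfg <- sim_config(n_expr_genes = 200L)
  sim <- simulate_expression(cfg)
  est <- log2fc(tpm(sim$counts_a, sim$lengths),
                tpm(sim$counts_b, sim$lengths))
  expect_gte(cor(est, sim$truth_lfc, method = "spearman"), 0.9)
})

test_that("hybrid scenarios drive allele ratios as configured", {
  set.seed(321)
  cfg <- sim_config(n_expr_genes = 200L, hybrid_scenario = "cis_maintained")
  sim <- simulate_expression(cfg)
  filt <- hybrid_allele_filter(sim$hybrid)
  expect_false(any(filt$chrom == "X"))
  cnt <- c("rep1", "rep2", "rep3")
  wide <- merge(filt[filt$allele == "A", c("gene", cnt)],
                filt[filt$allele == "B", c("gene", cnt)], by = "gene")
  allele_lfc <- log2fc(as.matrix(wide[, 2:4]), as.matrix(wide[, 5:7]))
  truth <- sim$truth_lfc[wide$gene]
  big <- abs(truth) >= 1
  expect_gte(mean(sign(allele_lfc[big]) == sign(truth[big])), 0.95)

  set.seed(321)
  simA <- simulate_expression(sim_config(n_expr_genes = 200L,
                                         hybrid_scenario = "dominant_A"))
  fA <- hybrid_allele_filter(simA$hybrid)
  wA <- merge(fA[fA$allele == "A", c("gene", cnt)],
              fA[fA$allele == "B", c("gene", cnt)], by = "gene")
  lfcA <- log2fc(as.matrix(wA[, 2:4]), as.matrix(wA[, 5:7]))
  expect_gte(mean(lfcA > 0), 0.95)  # allele A dominant irrespective of truth

  set.seed(321)
  simB <- simulate_expression(sim_config(n_expr_genes = 200L,
                                         hybrid_scenario = "dominant_B"))
  fB <- hybrid_allele_filter(simB$hybrid)
  wB <- merge(fB[fB$allele == "A", c("gene", cnt)],
              fB[fB$allele == "B", c("gene", cnt)], by = "gene")
  lfcB <- log2fc(as.matrix(wB[, 2:4]), as.matrix(wB[, 5:7]))
  expect_gte(mean(lfcB < 0), 0.95)
})

test_that("ortholog mapping renames and drops unmapped genes", {
  m <- matrix(1:4, 2, dimnames = list(c("a", "b"), NULL))
  map <- data.frame(from = "a", to = "A1")
  expect_message(out <- map_orthologs(m, map), "dropping 1")
  expect_equal(rownames(out), "A1")
  expect_equal(unname(out[1, ]), c(1L, 3L))
})
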