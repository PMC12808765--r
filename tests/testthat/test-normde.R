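test_that("TMM factors: identity and pure-depth cases", {
  m <- cbind(a = c(5, 10, 20, 7), b = c(5, 10, 20, 7))
  expect_equal(unname(tmmFactors(m)), c(1, 1))
  ## doubling depth without composition change leaves factors at 1
  m2 <- cbind(a = c(5, 10, 20, 7), b = 2 * c(5, 10, 20, 7))
  expect_equal(unname(tmmFactors(m2)), c(1, 1))
  expect_error(tmmFactors(cbind(a = c(0, 0), b = c(1, 2))), "all-zero")
  expect_error(tmmFactors(matrix(1:4, 4, 1)), "2 samples")
})

test_that("TMM factors match the reference implementation on random matrices", {
  skip_if_not_installed("edgeR")
  set.seed(101)
  for (i in 1:20) {
    m <- matrix(rnbinom(300, mu = exp(runif(300, 2, 7)), size = 5), 50, 6)
    m[sample(300, 20)] <- 0
    colnames(m) <- paste0("s", 1:6)
    ref <- edgeR::calcNormFactors(edgeR::DGEList(m))$samples$norm.factors
    expect_equal(unname(tmmFactors(m)), ref, tolerance = 1e-6)
  }
  ## composition-bias case: one gene takes half of sample B's reads
  m <- matrix(rpois(100, 50), 50, 2, dimnames = list(NULL, c("A", "B")))
  m[1, "B"] <- sum(m[-1, "B"])
  ref <- edgeR::calcNormFactors(edgeR::DGEList(m))$samples$norm.factors
  expect_equal(unname(tmmFactors(m)), ref, tolerance = 1e-6)
})

test_that("TMM factors have geometric mean 1 and are permutation/scale invariant", {
  set.seed(11)
  m <- matrix(rnbinom(600, mu = 60, size = 3), 100, 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  f <- tmmFactors(m)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
  perm <- c(4, 2, 6, 1, 3, 5)
  expect_equal(unname(tmmFactors(m[, perm])), unname(f[perm]),
               tolerance = 1e-12)
  expect_equal(unname(tmmFactors(3 * m)), unname(f), tolerance = 1e-12)
})

test_that("logCPM follows its formula exactly", {
  ## single zero count against a ~1e6 effective library: forced value -1
  m <- matrix(c(0, 999999), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  lc <- logCPM(m, nf = c(s1 = 1), prior = 0.5)
  expect_equal(lc["g1", "s1"], log2(0.5 / 1e6 * 1e6), tolerance = 1e-12)
  ## scale invariance: doubling counts and library leaves logCPM ~unchanged
  set.seed(5)
  m <- matrix(rpois(200, 80), 50, 4, dimnames = list(NULL, paste0("s", 1:4)))
  expect_equal(logCPM(2 * m, nf = setNames(rep(1, 4), colnames(m))),
               logCPM(m, nf = setNames(rep(1, 4), colnames(m))),
               tolerance = 0.01, ignore_attr = TRUE)
  ## random matrix against the hand formula
  nf <- tmmFactors(m)
  lc <- logCPM(m, nf, prior = 0.5)
  eff <- colSums(m) * nf
  manual <- log2(sweep(m + 0.5, 2, eff + 1, "/") * 1e6)
  expect_equal(lc, manual, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(logCPM(m, nf = setNames(c(-1, 1, 1, 1), colnames(m))),
               "nonpositive")
})

test_that("low-expression filter equals the direct CPM rule", {
  set.seed(8)
  m <- matrix(rnbinom(500, mu = 5, size = 1), 100, 5,
              dimnames = list(NULL, paste0("s", 1:5)))
  m[1, ] <- 0                      # all-zero gene must go
  m[2, ] <- 1000                   # strong gene must stay
  mask <- filterLowExpressed(m, min_cpm = 1, min_samples = 3)
  cpm <- sweep(m, 2, colSums(m), "/") * 1e6
  expect_equal(mask, unname(rowSums(cpm >= 1) >= 3))
  expect_false(mask[1])
  expect_true(mask[2])
  ## default min_samples from the smallest design group
  se <- simulateCounts(simCountConfig(n_genes = 100, seed = 2,
    class_sizes = c(early_up = 5, late_up = 5,
                    early_down = 5, late_down = 5)))
  expect_length(filterLowExpressed(se), 100)
})

test_that("BH adjustment equals the step-up definition and is order-invariant", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(21)
  for (i in 1:200) {
    p <- runif(sample(1:500, 1))
    expect_equal(bhAdjust(p), oracleBH(p), tolerance = 1e-12)
  }
  p <- runif(100)
  perm <- sample(100)
  expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]), tolerance = 1e-15)
})

test_that("deTest logFC flips sign with group swap; degenerate genes get p = 1", {
  set.seed(31)
  m <- matrix(rnorm(60, 8), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  a <- paste0("s", 1:3); b <- paste0("s", 4:6)
  d1 <- deTest(m, a, b, method = "welch")
  d2 <- deTest(m, b, a, method = "welch")
  expect_equal(d1$logFC, -d2$logFC)
  expect_equal(d1$p_value, d2$p_value)
  ## identical values in both groups: logFC 0, p 1 by convention
  m[1, ] <- 5
  d <- deTest(m, a, b, method = "welch")
  expect_equal(d$logFC[1], 0)
  expect_equal(d$p_value[1], 1)
  expect_error(deTest(m, a[1], b), "at least 2")
  expect_error(deTest(m, a, c(a[1], b[1:2])), "disjoint")
})

test_that("deTest recovers planted effects on simulated counts", {
  se <- simulateCounts(simCountConfig(seed = 13))
  se <- se[filterLowExpressed(se), ]
  lc <- logCPM(se)
  g <- contrastGroups(se, "A", "24h")
  de <- deTest(lc, g$dex, g$veh)
  truth <- as.data.frame(rowData(se))
  planted <- truth$planted_log2fc_24h != 0
  est <- de$logFC[match(truth$gene_id[planted], de$gene)]
  expect_lt(abs(mean(abs(est)) - 3), 0.3)
})

test_that("thresholdDE applies strict cuts and direction restriction", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   logFC = c(1.0, 1.5, -2, 3),
                   fdr = c(0.001, 0.001, 0.001, 0.5))
  expect_false("a" %in% thresholdDE(de, 1, 0.01))   # |logFC| = 1 exactly
  expect_false("d" %in% thresholdDE(de, 1, 0.01))   # fdr too high
  expect_setequal(thresholdDE(de, 1, 0.01), c("b", "c"))
  expect_setequal(thresholdDE(de, 1, 0.01, direction = "up"), "b")
  expect_setequal(thresholdDE(de, 1, 0.01, direction = "down"), "c")
})
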