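de_tbl <- function(genes, lfc, fdr) {
  data.frame(gene = genes, logFC = lfc, p_value = fdr, fdr = fdr)
}

test_that("shared-effect selection applies both-model thresholds and sign concordance", {
  g <- c("g1", "g2", "g3", "g4")
  a <- de_tbl(g, c(2.5, 2.5, 1.5, -2.5), c(1e-4, 1e-4, 1e-4, 1e-4))
  b <- de_tbl(g, c(2.2, -2.5, 2.6, -2.2), c(1e-3, 1e-3, 1e-3, 1e-3))
  sel <- sharedEffectGenes(a, b)
  expect_true("g1" %in% sel)    # strong concordant up in both
  expect_false("g2" %in% sel)   # sign-discordant despite significance
  expect_false("g3" %in% sel)   # below |logFC| threshold in model A
  expect_true("g4" %in% sel)    # concordant down is retained
  ## without concordance requirement g2 comes back
  sel2 <- sharedEffectGenes(a, b, signatureParams(sign_concordant = FALSE))
  expect_true("g2" %in% sel2)
  expect_error(sharedEffectGenes(a, de_tbl(c("x1"), 1, 1)), "universe")
})

test_that("shared-effect selection matches the direct rule on simulated data", {
  se <- simulateCounts(simCountConfig(seed = 17))
  se <- se[filterLowExpressed(se), ]
  lc <- logCPM(se)
  de <- deContrasts(se, lc)
  sel <- sharedEffectGenes(de$A_24h, de$B_24h)
  b <- de$B_24h[match(de$A_24h$gene, de$B_24h$gene), ]
  direct <- de$A_24h$gene[
    abs(de$A_24h$logFC) > 2 & de$A_24h$fdr < 0.01 &
    abs(b$logFC) > 2 & b$fdr < 0.01 &
    sign(de$A_24h$logFC) == sign(b$logFC)]
  expect_setequal(sel, direct)
})

test_that("mean centering zeroes row means over all samples", {
  m <- matrix(c(1, 2, 3, 7, 7, 7), 2, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:3)))
  cm <- meanCenter(m)
  expect_equal(cm["g1", ], c(s1 = -1, s2 = 0, s3 = 1))
  expect_equal(unname(cm["g2", ]), c(0, 0, 0))
  set.seed(2)
  r <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  expect_true(all(abs(rowMeans(meanCenter(r))) < 1e-12))
  expect_error(meanCenter(m, "nope"), "unknown genes")
})

test_that("k-means recovers well-separated planted profiles", {
  set.seed(4)
  proto <- rbind(c(2, 2, 2, 0), c(0, 0, 2, 0), c(-2, -2, -2, 0),
                 c(0, 0, -2, 0))
  x <- proto[rep(1:4, each = 40), ] + matrix(rnorm(160 * 4, 0, 0.3), 160, 4)
  rownames(x) <- paste0("g", 1:160)
  km <- kmeansCluster(x, k = 4, seed = 1)
  expect_gte(adjustedRand(km$labels, rep(1:4, each = 40)), 0.95)
  ## identical rows: zero inertia
  xx <- matrix(1, 10, 3, dimnames = list(paste0("g", 1:10), NULL))
  km0 <- kmeansCluster(xx, k = 2, seed = 1)
  expect_equal(km0$inertia, 0)
  expect_error(kmeansCluster(x[1:3, ], k = 4), "fewer rows")
  ## determinism under a fixed seed
  expect_identical(kmeansCluster(x, k = 4, seed = 5)$labels,
                   kmeansCluster(x, k = 4, seed = 5)$labels)
})

test_that("onset score is the Dex-8h minus vehicle mean difference", {
  samples <- data.frame(
    sample_id = paste0("s", 1:8),
    treatment = rep(c("dex", "vehicle"), each = 4),
    timepoint = rep(c("8h", "8h", "24h", "24h"), 2))
  m <- matrix(5, 3, 8, dimnames = list(paste0("g", 1:3), paste0("s", 1:8)))
  expect_equal(onsetScore(rownames(m), m, samples), 0)
  m2 <- m
  m2[, samples$treatment == "dex" & samples$timepoint == "8h"] <- 7
  expect_equal(onsetScore(rownames(m2), m2, samples), 2)
  ## formula oracle on random data
  set.seed(9)
  r <- matrix(rnorm(24), 3, 8,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:8)))
  dex8 <- samples$sample_id[samples$treatment == "dex" &
                              samples$timepoint == "8h"]
  veh <- samples$sample_id[samples$treatment == "vehicle"]
  manual <- mean(rowMeans(r[, dex8]) - rowMeans(r[, veh]))
  expect_equal(onsetScore(rownames(r), r, samples), manual,
               tolerance = 1e-12)
  expect_error(onsetScore(character(0), r, samples), "empty")
})

test_that("signature selection takes the argmax positive-onset cluster", {
  samples <- data.frame(
    sample_id = paste0("s", 1:8),
    treatment = rep(c("dex", "vehicle"), each = 4),
    timepoint = rep(c("8h", "8h", "24h", "24h"), 2))
  ## four clusters with onset approximately (-1, 0.5, 2, 0.1)
  onsets <- c(-1, 0.5, 2, 0.1)
  m <- matrix(0, 8, 8, dimnames = list(paste0("g", 1:8), paste0("s", 1:8)))
  labels <- setNames(rep(1:4, each = 2), rownames(m))
  for (k in 1:4)
    m[labels == k, samples$treatment == "dex"] <- onsets[k]
  sig <- selectSignature(labels, m, samples)
  expect_equal(sig@selectedCluster, 3L)
  expect_setequal(signatureGenes(sig), c("g5", "g6"))
  expect_true(all(onsetScores(sig)[sig@selectedCluster] >=
                    onsetScores(sig)))
  ## all-negative onsets abort with guidance
  m_neg <- m; m_neg[, samples$treatment == "dex"] <- -1
  expect_error(selectSignature(labels, m_neg, samples), "positive onset")
})

test_that("response-timing classification follows the early/late rules", {
  g <- c("g1", "g2", "g3", "g4")
  sig_dn <- de_tbl(g, c(-3, 0, -3, 3), c(1e-5, 0.5, 1e-5, 1e-5))
  null_t <- de_tbl(g, c(0, 0, 0, 0), c(1, 1, 1, 1))
  dn24 <- de_tbl(g, c(-3, -3, -3, 3), c(1e-5, 1e-5, 1e-5, 1e-5))
  ## g1: down at 8 h and 24 h in both models -> early_down
  ## g2: down only at 24 h -> late_down; g4: up at both -> early-up rule at 8h
  cls <- classifyResponseTiming(sig_dn, sig_dn, dn24, dn24)
  expect_equal(unname(cls["g1"]), "early_down")
  expect_equal(unname(cls["g2"]), "late_down")
  expect_equal(unname(cls["g4"]), "early_up")
  ## significant nowhere -> unchanged
  cls2 <- classifyResponseTiming(null_t, null_t, null_t, null_t)
  expect_true(all(cls2 == "unchanged"))
})

test_that("timing classes are recovered on planted simulation", {
  se <- simulateCounts(simCountConfig(seed = 23))
  se <- se[filterLowExpressed(se), ]
  lc <- logCPM(se)
  de <- deContrasts(se, lc)
  cls <- classifyResponseTiming(de$A_8h, de$B_8h, de$A_24h, de$B_24h)
  truth <- as.data.frame(rowData(se))
  planted <- truth$planted_class != "null"
  acc <- mean(cls[truth$gene_id[planted]] ==
                truth$planted_class[planted])
  expect_gte(acc, 0.9)
  ## null genes rarely called
  expect_lt(mean(cls[truth$gene_id[!planted]] != "unchanged"), 0.01)
})

test_that("sample scoring sums present signature genes and flags missing ones", {
  m <- matrix(c(3, 4), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(unname(scoreSamples(m, c("g1", "g2"))), 7)
  ## adding a constant shifts scores by |sig| * c
  m2 <- m + 2
  expect_equal(unname(scoreSamples(m2, c("g1", "g2"))), 7 + 2 * 2)
  expect_warning(s <- scoreSamples(m, c("g1", "g2", "g3")), "missing")
  expect_equal(unname(s), 7)
  expect_error(scoreSamples(m, c("g1", "x1", "x2", "x3")), "half")
})

test_that("derived signature recovers the planted early-up cluster end to end", {
  se <- simulateCounts(simCountConfig(seed = 7))
  sig <- deriveSignature(se, signatureParams(seed = 7))
  truth <- as.data.frame(rowData(se))
  early_up <- truth$gene_id[truth$planted_class == "early_up"]
  expect_gte(jaccard(signatureGenes(sig), early_up), 0.9)
  ## containment chain: signature within shared-effect within universe
  expect_true(all(signatureGenes(sig) %in% names(sig@clusterLabels)))
  expect_equal(unname(sig@stageCounts["shared_effect"]),
               length(sig@clusterLabels))
  expect_lte(sig@stageCounts["signature"], sig@stageCounts["shared_effect"])
  ## determinism
  sig2 <- deriveSignature(se, signatureParams(seed = 7))
  expect_identical(signatureGenes(sig), signatureGenes(sig2))
  ## invariance to sample and gene order
  se_perm <- se[sample(nrow(se)), sample(ncol(se))]
  sig3 <- deriveSignature(se_perm, signatureParams(seed = 7))
  expect_setequal(signatureGenes(sig3), signatureGenes(sig))
})

test_that("no-effect data cannot yield a signature", {
  se <- simulateCounts(nullCountConfig(n_genes = 500, seed = 5))
  expect_error(deriveSignature(se, signatureParams(seed = 5)))
})
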