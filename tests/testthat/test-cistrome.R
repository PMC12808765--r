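chrlen <- c(chr1 = 100000, chr2 = 80000, chrM = 20000)

test_that("region exclusion drops flagged chromosomes and blacklist overlaps", {
  gr <- GRanges(c("chr1", "chrM", "chr1"),
                IRanges(c(100, 200, 5000), width = 200),
                seqlengths = chrlen)
  out <- excludeRegions(gr)
  expect_equal(as.character(seqnames(out)), c("chr1", "chr1"))
  ## empty blacklist, no excluded chromosomes: identity
  out2 <- excludeRegions(gr, excluded_chroms = character(0))
  expect_equal(length(out2), 3L)
  bl <- GRanges("chr1", IRanges(5100, 5150))
  out3 <- excludeRegions(gr, blacklist = bl)
  expect_equal(start(out3), 100)
  ## random peaks against the all-pairs oracle
  set.seed(31)
  for (i in 1:30) {
    p <- randomPeaksGR(40, chrlen)
    b <- randomPeaksGR(10, chrlen)
    got <- excludeRegions(p, blacklist = b)
    want <- oracleExclude(grToDf(p), c("chrM", "chrX", "chrY"), grToDf(b))
    want <- want[order(want$chrom, want$start, want$end), ]
    got_df <- grToDf(got)
    expect_equal(got_df$start, want$start)
    expect_equal(got_df$chrom, want$chrom)
  }
})

test_that("enrichment filter is strict, per-sample aware, and idempotent", {
  gr <- GRanges("chr1", IRanges(c(100, 300, 500), width = 100))
  mcols(gr) <- DataFrame(enrich_s1 = c(2.1, 2.0, 1.0),
                         enrich_s2 = c(0.0, 2.0, 2.5))
  out <- filterByEnrichment(gr)
  expect_equal(start(out), c(100, 500))          # 2.1 passes, 2.0 does not
  expect_identical(grToDf(filterByEnrichment(out)), grToDf(out))
  ## matches the direct rule on random enrichment
  set.seed(5)
  gr2 <- randomPeaksGR(50, chrlen)
  e <- matrix(rnorm(100, 2, 1), 50, 2,
              dimnames = list(NULL, c("enrich_s1", "enrich_s2")))
  mcols(gr2) <- DataFrame(e)
  out2 <- filterByEnrichment(gr2, threshold = 2, min_samples = 1)
  expect_equal(length(out2), sum(rowSums(e > 2) >= 1))
  expect_error(filterByEnrichment(granges(gr2)), "enrichment columns")
})

test_that("overlap classification labels merged regions correctly", {
  er <- GRanges("chr1", IRanges(c(100, 1000), width = 100))
  gr <- GRanges("chr1", IRanges(c(150, 5000), width = 100))
  out <- classifyOverlap(er, gr)
  expect_equal(sort(table(out$label)[c("ER_only", "GR_only", "shared")]),
               sort(c(ER_only = 1L, GR_only = 1L, shared = 1L)),
               ignore_attr = TRUE)
  ## identical interval in both factors: shared
  one <- GRanges("chr1", IRanges(10, 20))
  expect_equal(classifyOverlap(one, one)$label, "shared")
  ## disjoint sets: no shared label
  expect_false("shared" %in%
                 classifyOverlap(GRanges("chr1", IRanges(1, 10)),
                                 GRanges("chr1", IRanges(100, 110)))$label)
  ## symmetry under factor swap
  set.seed(7)
  a <- randomPeaksGR(30, chrlen); b <- randomPeaksGR(30, chrlen)
  t1 <- table(classifyOverlap(a, b)$label)
  t2 <- table(classifyOverlap(b, a)$label)
  expect_equal(unname(t1["shared"]), unname(t2["shared"]))
  expect_equal(unname(t1["ER_only"]), unname(t2["GR_only"]))
  ## against the brute-force merged-region oracle
  for (i in 1:20) {
    a <- randomPeaksGR(25, chrlen); b <- randomPeaksGR(25, chrlen)
    got <- classifyOverlap(a, b)
    want <- oracleOverlapLabels(grToDf(a), grToDf(b))
    expect_equal(grToDf(got)$start, want$start)
    expect_equal(got$label, want$label)
  }
})

test_that("regulatory domains follow the basal-plus-extension arithmetic", {
  ## + strand gene, TSS 10000, no distal: 5 kb up / 1 kb down window
  g <- GRanges("chr1", IRanges(10000, width = 1), strand = "+",
               seqlengths = c(chr1 = 100000))
  g$gene_id <- "g1"; g$tss <- 10000
  d0 <- buildRegulatoryDomains(g, regulatoryDomainParams(distal_limit = 0))
  expect_equal(start(d0), 5000)
  expect_equal(width(d0), 6000)              # [5000, 11000) half-open
  ## - strand mirror
  gm <- g; strand(gm) <- "-"
  dm <- buildRegulatoryDomains(gm, regulatoryDomainParams(distal_limit = 0))
  expect_equal(end(dm), 15000)
  expect_equal(width(dm), 6000)              # [9000, 15000) half-open
  ## random gene sets against the per-gene scan oracle
  set.seed(13)
  for (i in 1:30) {
    n <- sample(3:20, 1)
    tss <- sort(sample(seq(8000, 90000, by = 1), n))
    df <- data.frame(gene_id = paste0("g", seq_len(n)), chrom = "chr1",
                     strand = sample(c("+", "-"), n, replace = TRUE),
                     tss = tss)
    gr <- GRanges(df$chrom, IRanges(df$tss, width = 1), strand = df$strand,
                  seqlengths = c(chr1 = 100000))
    gr$gene_id <- df$gene_id; gr$tss <- df$tss
    got <- buildRegulatoryDomains(gr)
    want <- oracleDomains(df, c(chr1 = 100000))
    want <- want[match(got$gene_id, want$gene_id), ]
    expect_equal(start(got), want$start)
    expect_equal(end(got), want$end)
  }
})

test_that("peak assignment uses the midpoint containment convention", {
  g <- GRanges("chr1", IRanges(10000, width = 1), strand = "+",
               seqlengths = c(chr1 = 100000))
  g$gene_id <- "g1"; g$tss <- 10000
  dom <- buildRegulatoryDomains(g, regulatoryDomainParams(distal_limit = 0))
  ## domain is [5000, 11000) in BED terms; midpoint 10999 in, 11000 out
  inside <- GRanges("chr1", IRanges(10990, 11008))   # BED mid 10999
  outside <- GRanges("chr1", IRanges(10992, 11010))  # BED mid 11000
  expect_equal(nrow(assignPeaks(inside, dom)), 1L)
  expect_equal(nrow(assignPeaks(outside, dom)), 0L)
  ## random genomes against the all-pairs oracle
  set.seed(17)
  for (i in 1:30) {
    n <- sample(3:15, 1)
    tss <- sort(sample(seq(8000, 90000), n))
    gr <- GRanges("chr1", IRanges(tss, width = 1),
                  strand = sample(c("+", "-"), n, TRUE),
                  seqlengths = c(chr1 = 100000))
    gr$gene_id <- paste0("g", seq_len(n)); gr$tss <- tss
    dom <- buildRegulatoryDomains(gr)
    p <- randomPeaksGR(50, c(chr1 = 100000))
    got <- assignPeaks(p, dom)
    want <- oracleAssign(grToDf(p), data.frame(
      gene_id = dom$gene_id, chrom = as.character(seqnames(dom)),
      start = start(dom), end = end(dom)))
    got <- got[order(got$peak, got$gene_id), ]
    want <- want[order(want$peak, want$gene_id), ]
    expect_equal(got$gene_id, want$gene_id)
    expect_equal(got$peak, want$peak)
  }
})

test_that("gene-set peak fractions hit the planted target rate", {
  asn <- data.frame(gene_id = c("a", "b"), peak = 1:2)
  expect_equal(geneSetPeakFraction(c("a", "b"), asn), 1.0)
  expect_equal(geneSetPeakFraction(c("x", "y"), asn), 0.0)
  expect_error(geneSetPeakFraction(character(0), asn), "empty")
  fr <- vapply(1:5, function(s) {
    gp <- simulateGenomePeaks(simPeakConfig(seed = s))
    dom <- buildRegulatoryDomains(gp$genes)
    geneSetPeakFraction(gp$genes$gene_id,
                        assignPeaks(gp$peaks$GR_1h, dom))
  }, numeric(1))
  expect_true(all(abs(fr - 0.5) <= 0.1))
  ## planted truth recovered exactly at default domain parameters
  gp <- simulateGenomePeaks(simPeakConfig(seed = 99))
  dom <- buildRegulatoryDomains(gp$genes)
  asn <- assignPeaks(gp$peaks$GR_1h, dom)
  expect_setequal(unique(asn$gene_id), gp$truth$target_genes)
})
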