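## Independent brute-force oracles used to validate the package
## implementations.  These are written from the definitions, not from the
## package code paths they check.

suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(GenomicRanges)
})

## BH step-up from the definition: sort, q_(i) = min_{j>=i} p_(j)*n/j, cap 1
oracleBH <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(n)
  for (i in seq_len(n)) q[i] <- min(ps[i:n] * n / (i:n), 1)
  out <- numeric(n)
  out[ord] <- q
  out
}

## product-limit estimator by explicit event-time loop
oracleKM <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- numeric(length(tt))
  cur <- 1
  for (i in seq_along(tt)) {
    at_risk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event == 1)
    cur <- cur * (1 - d / at_risk)
    s[i] <- cur
  }
  data.frame(time = tt, surv = s)
}

## running-sum enrichment score by explicit walk
oracleES <- function(stats, genes, set, weight = 1) {
  hit <- genes %in% set
  nr <- sum(abs(stats[hit])^weight)
  nmiss <- sum(!hit)
  run <- numeric(length(stats))
  cur <- 0
  for (i in seq_along(stats)) {
    cur <- cur + if (hit[i]) abs(stats[i])^weight / nr else -1 / nmiss
    run[i] <- cur
  }
  run[which.max(abs(run))]
}

## all-pairs interval overlap on plain data frames (1-based closed coords)
.overlaps1 <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 & s1 <= e2 & s2 <= e1
}

oracleExclude <- function(peaks_df, excluded_chroms, bl_df) {
  keep <- !(peaks_df$chrom %in% excluded_chroms)
  if (nrow(bl_df)) {
    for (i in seq_len(nrow(peaks_df))) {
      if (!keep[i]) next
      for (j in seq_len(nrow(bl_df))) {
        if (.overlaps1(peaks_df$chrom[i], peaks_df$start[i], peaks_df$end[i],
                       bl_df$chrom[j], bl_df$start[j], bl_df$end[j])) {
          keep[i] <- FALSE
          break
        }
      }
    }
  }
  peaks_df[keep, , drop = FALSE]
}

## merged-region labels by brute force: union intervals then test each
## against every source interval
oracleOverlapLabels <- function(er_df, gr_df) {
  all_df <- rbind(er_df[, c("chrom", "start", "end")],
                  gr_df[, c("chrom", "start", "end")])
  merged <- do.call(rbind, lapply(split(all_df, all_df$chrom), function(d) {
    d <- d[order(d$start, d$end), ]
    out <- d[1, ]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= out$end[nrow(out)] + 0) {
        out$end[nrow(out)] <- max(out$end[nrow(out)], d$end[i])
      } else out <- rbind(out, d[i, ])
    }
    out
  }))
  lab <- character(nrow(merged))
  for (i in seq_len(nrow(merged))) {
    has_er <- any(.overlaps1(merged$chrom[i], merged$start[i], merged$end[i],
                             er_df$chrom, er_df$start, er_df$end))
    has_gr <- any(.overlaps1(merged$chrom[i], merged$start[i], merged$end[i],
                             gr_df$chrom, gr_df$start, gr_df$end))
    lab[i] <- if (has_er && has_gr) "shared"
              else if (has_er) "ER_only" else "GR_only"
  }
  merged$label <- lab
  merged[order(merged$chrom, merged$start), ]
}

## regulatory domains by per-gene scan over all other genes
oracleDomains <- function(genes_df, chrom_len, basal_up = 5000,
                          basal_down = 1000, distal = 1000) {
  n <- nrow(genes_df)
  bs <- ifelse(genes_df$strand == "+", genes_df$tss - basal_up,
               genes_df$tss - basal_down + 1)
  be <- ifelse(genes_df$strand == "+", genes_df$tss + basal_down - 1,
               genes_df$tss + basal_up)
  bs <- pmax(bs, 1)
  be <- pmin(be, chrom_len[genes_df$chrom])
  ds <- numeric(n); de <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(genes_df$chrom == genes_df$chrom[i])
    left_edges <- be[same][be[same] < bs[i]]
    lo <- bs[i] - distal
    if (length(left_edges)) {
      mid <- floor((max(left_edges) + bs[i]) / 2)
      lo <- max(lo, mid + 1)
    }
    right_edges <- bs[same][bs[same] > be[i]]
    hi <- be[i] + distal
    if (length(right_edges)) {
      mid <- floor((be[i] + min(right_edges)) / 2)
      hi <- min(hi, mid)
    }
    ds[i] <- min(bs[i], max(1, lo))
    de[i] <- max(be[i], min(chrom_len[genes_df$chrom[i]], hi))
  }
  data.frame(gene_id = genes_df$gene_id, chrom = genes_df$chrom,
             start = ds, end = de)
}

## midpoint containment by all pairs (peaks given 1-based closed)
oracleAssign <- function(peaks_df, dom_df) {
  out <- NULL
  for (i in seq_len(nrow(peaks_df))) {
    mid <- (peaks_df$start[i] - 1 + peaks_df$end[i]) %/% 2 + 1
    for (j in seq_len(nrow(dom_df))) {
      if (peaks_df$chrom[i] == dom_df$chrom[j] &&
          mid >= dom_df$start[j] && mid <= dom_df$end[j])
        out <- rbind(out, data.frame(gene_id = dom_df$gene_id[j], peak = i))
    }
  }
  if (is.null(out)) data.frame(gene_id = character(0), peak = integer(0))
  else out
}

## adjusted Rand index between two labelings
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

## GRanges <-> data.frame helpers for the oracles (1-based closed)
grToDf <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
             end = end(gr), stringsAsFactors = FALSE)
}

randomPeaksGR <- function(n, chrom_len, max_width = 500) {
  chrom <- sample(names(chrom_len), n, replace = TRUE)
  start <- vapply(chrom, function(ch)
    sample.int(chrom_len[[ch]] - max_width, 1), integer(1))
  width <- sample.int(max_width, n, replace = TRUE)
  GRanges(chrom, IRanges(start, width = width), seqlengths = chrom_len)
}

nullCountConfig <- function(n_genes = 2000, seed = 1, ...) {
  simCountConfig(n_genes = n_genes,
                 class_sizes = c(early_up = 0, late_up = 0,
                                 early_down = 0, late_down = 0),
                 seed = seed, ...)
}

contrastGroups <- function(se, model, timepoint) {
  cd <- as.data.frame(colData(se))
  list(dex = cd$sample_id[cd$model == model & cd$timepoint == timepoint &
                            cd$treatment == "dex"],
       veh = cd$sample_id[cd$model == model & cd$timepoint == timepoint &
                            cd$treatment == "vehicle"])
}
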