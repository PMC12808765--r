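#' Drop peaks on excluded chromosomes or overlapping a blacklist
#'
#' Removes peaks on mitochondrial/sex chromosomes (configurable) and any
#' peak overlapping a blacklist interval by at least 1 bp.
#'
#' @param peaks `GRanges` of peaks.
#' @param excluded_chroms chromosome names to drop entirely.
#' @param blacklist `GRanges` of blacklist regions (may be empty).
#' @return Filtered, sorted `GRanges`.
#' @export
excludeRegions <- function(peaks,
                           excluded_chroms = c("chrM", "chrX", "chrY"),
                           blacklist = GenomicRanges::GRanges()) {
  keep <- !(as.character(GenomicRanges::seqnames(peaks)) %in% excluded_chroms)
  if (length(blacklist))
    keep <- keep & !IRanges::overlapsAny(peaks, blacklist, ignore.strand = TRUE)
  sort(peaks[keep])
}

.enrichCols <- function(peaks) {
  cols <- grep("^enrich", colnames(S4Vectors::mcols(peaks)), value = TRUE)
  if (length(cols) == 0) stop("no enrichment columns (prefix 'enrich')")
  as.matrix(S4Vectors::mcols(peaks)[, cols, drop = FALSE])
}

#' Keep peaks with high log-enrichment in enough samples
#'
#' A peak is retained iff its log2 enrichment over input exceeds
#' `threshold` (strictly) in at least `min_samples` of its per-sample
#' enrichment columns (metadata columns prefixed `enrich`).
#'
#' @param peaks `GRanges` with enrichment metadata columns.
#' @param threshold log2 enrichment cutoff (strict), default 2.
#' @param min_samples minimum samples above threshold, default 1.
#' @return Filtered `GRanges`.  Idempotent.
#' @export
filterByEnrichment <- function(peaks, threshold = 2, min_samples = 1) {
  e <- .enrichCols(peaks)
  peaks[rowSums(e > threshold) >= min_samples]
}

#' Classify merged regions as ER-only, GR-only or shared
#'
#' Overlapping intervals within each factor are merged first; the union of
#' both merged sets is then partitioned into contiguous regions, each
#' labelled by which factor(s) contributed (>= 1 bp overlap makes a region
#' `shared`).
#'
#' @param er,gr `GRanges` peak sets for the two factors (either may be
#'   empty).
#' @return `GRanges` of merged regions with a `label` metadata column in
#'   \{`ER_only`, `GR_only`, `shared`\}.
#' @export
classifyOverlap <- function(er, gr) {
  ## min.gapwidth = 0: merge on >= 1 bp overlap only, never abutting ranges
  er_m <- GenomicRanges::reduce(GenomicRanges::granges(er),
                                ignore.strand = TRUE, min.gapwidth = 0)
  gr_m <- GenomicRanges::reduce(GenomicRanges::granges(gr),
                                ignore.strand = TRUE, min.gapwidth = 0)
  all_m <- GenomicRanges::reduce(c(er_m, gr_m), ignore.strand = TRUE,
                                 min.gapwidth = 0)
  has_er <- IRanges::overlapsAny(all_m, er_m)
  has_gr <- IRanges::overlapsAny(all_m, gr_m)
  all_m$label <- ifelse(has_er & has_gr, "shared",
                        ifelse(has_er, "ER_only", "GR_only"))
  sort(all_m)
}

#' Basal-plus-extension regulatory-domain parameters
#'
#' GREAT-style settings: a strand-oriented basal window (5 kb upstream,
#' 1 kb downstream of the TSS by default) extended outward up to
#' `distal_limit`, stopping at the neighboring gene's basal domain (with
#' contested gaps split at the midpoint between basal edges).
#'
#' @param basal_up,basal_down basal extent upstream/downstream of the TSS
#'   (bp).
#' @param distal_limit maximum extension beyond the basal window (bp).
#' @return List of class `RegulatoryDomainParams`.
#' @export
regulatoryDomainParams <- function(basal_up = 5000, basal_down = 1000,
                                   distal_limit = 1000) {
  stopifnot(basal_up >= 0, basal_down >= 0, distal_limit >= 0)
  structure(list(basal_up = as.integer(basal_up),
                 basal_down = as.integer(basal_down),
                 distal_limit = as.integer(distal_limit)),
            class = "RegulatoryDomainParams")
}

#' Build per-gene regulatory domains (basal plus extension)
#'
#' The basal domain runs `basal_up` upstream to `basal_down` downstream of
#' the TSS, oriented by strand.  Each basal edge is extended outward up to
#' `distal_limit`, never into a neighboring gene's basal domain; when two
#' extensions contest the same gap the gap is split at the midpoint
#' between the flanking basal edges.  Domains are clipped to chromosome
#' bounds (seqlengths required).
#'
#' @param genes `GRanges` gene annotation with `gene_id` and `tss`
#'   metadata, strand, and seqlengths set.
#' @param params a [regulatoryDomainParams()].
#' @return `GRanges` of domains (unstranded) with `gene_id`, ordered as
#'   sorted genes.
#' @export
buildRegulatoryDomains <- function(genes, params = regulatoryDomainParams()) {
  sl <- GenomeInfoDb::seqlengths(genes)
  if (any(is.na(sl))) stop("gene annotation needs seqlengths")
  tss <- genes$tss
  chrom <- as.character(GenomicRanges::seqnames(genes))
  if (any(tss < 1 | tss > sl[chrom])) stop("TSS outside chromosome")
  plus <- as.character(GenomicRanges::strand(genes)) != "-"
  b_start <- ifelse(plus, tss - params$basal_up, tss - params$basal_down + 1)
  b_end   <- ifelse(plus, tss + params$basal_down - 1, tss + params$basal_up)
  b_start <- pmax(b_start, 1)
  b_end <- pmin(b_end, sl[chrom])
  d_start <- numeric(length(tss)); d_end <- numeric(length(tss))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    i <- i[order(b_start[i], b_end[i])]
    bs <- b_start[i]; be <- b_end[i]; n <- length(i)
    for (k in seq_len(n)) {
      left_edges <- be[-k][be[-k] < bs[k]]
      prev_end <- if (length(left_edges)) max(left_edges) else NA
      nxt <- which(bs > be[k]); nxt <- setdiff(nxt, k)
      next_start <- if (length(nxt)) min(bs[nxt]) else NA
      lo <- bs[k] - params$distal_limit
      if (!is.na(prev_end)) {
        mid <- floor((prev_end + bs[k]) / 2)
        lo <- max(lo, mid + 1)
      }
      hi <- be[k] + params$distal_limit
      if (!is.na(next_start) && next_start > be[k]) {
        mid <- floor((be[k] + next_start) / 2)
        hi <- min(hi, mid)
      }
      d_start[i[k]] <- min(bs[k], max(1, lo))
      d_end[i[k]] <- max(be[k], min(sl[ch], hi))
    }
  }
  out <- GenomicRanges::GRanges(chrom, IRanges::IRanges(d_start, d_end),
                                seqlengths = sl)
  out$gene_id <- genes$gene_id
  out$basal_start <- b_start
  out$basal_end <- b_end
  sort(out, ignore.strand = TRUE)
}

#' Assign peaks to genes whose regulatory domain contains the peak midpoint
#'
#' The midpoint of a peak `[start, end)` (BED convention) is
#' `floor((start + end) / 2)`; a peak is assigned to every gene whose
#' domain contains that position.  `mode = "any_overlap"` assigns on any
#' >= 1 bp overlap instead.
#'
#' @param peaks `GRanges` of peaks.
#' @param domains `GRanges` from [buildRegulatoryDomains()].
#' @param mode `"midpoint"` (default) or `"any_overlap"`.
#' @return data.frame with `gene_id` and `peak` (index into `peaks`).
#' @export
assignPeaks <- function(peaks, domains, mode = c("midpoint", "any_overlap")) {
  mode <- match.arg(mode)
  if (mode == "midpoint") {
    ## BED start0 = start1 - 1, end0 = end1; midpoint0 then back to 1-based
    mid1 <- (GenomicRanges::start(peaks) - 1 +
               GenomicRanges::end(peaks)) %/% 2 + 1
    q <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                IRanges::IRanges(mid1, width = 1))
  } else q <- peaks
  h <- GenomicRanges::findOverlaps(q, domains, ignore.strand = TRUE)
  data.frame(gene_id = domains$gene_id[S4Vectors::subjectHits(h)],
             peak = S4Vectors::queryHits(h), stringsAsFactors = FALSE)
}

#' Fraction of a gene set with at least one assigned peak
#'
#' @param gene_set nonempty character vector of gene ids.
#' @param assignment data.frame from [assignPeaks()].
#' @return Fraction in \[0, 1\].
#' @export
geneSetPeakFraction <- function(gene_set, assignment) {
  if (length(gene_set) == 0) stop("gene set is empty")
  mean(gene_set %in% assignment$gene_id)
}
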