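#' Configuration for the toy genome / peak-set simulator
#'
#' @param chrom_lengths named integer, chromosome lengths (bp).
#' @param n_genes genes placed across chromosomes (proportional to length).
#' @param target_fraction fraction of genes planted with a GR peak inside
#'   their basal regulatory domain.
#' @param n_background_peaks intergenic GR peaks placed away from all gene
#'   domains (so planted gene-peak truth stays exact).
#' @param peak_width width (bp) of simulated peaks.
#' @param enrichment_mean,enrichment_sd per-sample log2-enrichment draw.
#' @param n_enrichment_samples number of per-peak enrichment columns.
#' @param er_shared_fraction fraction of planted GR peaks that also receive
#'   an overlapping ER peak (the shared ER/GR class).
#' @param n_er_extra additional independent ER 1 h peaks.
#' @param er_24h_retention fraction of ER 1 h peaks retained at 24 h
#'   (emulating the loss of ER binding after prolonged Dex).
#' @param min_tss_gap minimum distance (bp) between gene TSSs; the default
#'   keeps basal domains disjoint so the planted gene-peak truth is exact.
#' @param seed integer seed.
#' @return A validated list of class `SimPeakConfig`.
#' @export
simPeakConfig <- function(chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                          n_genes = 100,
                          target_fraction = 0.5,
                          n_background_peaks = 50,
                          peak_width = 400,
                          enrichment_mean = 4,
                          enrichment_sd = 1,
                          n_enrichment_samples = 2,
                          er_shared_fraction = 0.3,
                          n_er_extra = 100,
                          er_24h_retention = 0.4,
                          min_tss_gap = 12000,
                          seed = 1) {
  if (is.null(names(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("chrom_lengths must be a named positive vector")
  for (f in c(target_fraction, er_shared_fraction, er_24h_retention))
    .assertScalarNum(f, "fraction", lower = 0, upper = 1)
  structure(list(chrom_lengths = chrom_lengths,
                 n_genes = as.integer(n_genes),
                 target_fraction = target_fraction,
                 n_background_peaks = as.integer(n_background_peaks),
                 peak_width = as.integer(peak_width),
                 enrichment_mean = enrichment_mean,
                 enrichment_sd = enrichment_sd,
                 n_enrichment_samples = as.integer(n_enrichment_samples),
                 er_shared_fraction = er_shared_fraction,
                 n_er_extra = as.integer(n_er_extra),
                 er_24h_retention = er_24h_retention,
                 min_tss_gap = as.integer(min_tss_gap),
                 seed = as.integer(seed)),
            class = "SimPeakConfig")
}

.drawEnrichment <- function(n, cfg) {
  m <- matrix(rnorm(n * cfg$n_enrichment_samples,
                    cfg$enrichment_mean, cfg$enrichment_sd),
              nrow = n)
  colnames(m) <- paste0("enrich_s", seq_len(cfg$n_enrichment_samples))
  m
}

.peakGRanges <- function(chrom, center, cfg) {
  half <- cfg$peak_width %/% 2L
  start <- pmax(1L, as.integer(center) - half)
  end <- pmin(cfg$chrom_lengths[chrom], as.integer(center) + half)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               seqlengths = cfg$chrom_lengths)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(.drawEnrichment(length(gr), cfg))
  gr
}

#' Simulate a toy genome with gene annotation and factor-specific peaks
#'
#' Places genes (TSS + strand) on toy chromosomes; a configurable fraction
#' of genes is planted with a GR peak inside its basal regulatory domain
#' (5 kb upstream / 1 kb downstream of the TSS, strand-oriented).
#' Background GR peaks are kept clear of all gene domains so the planted
#' gene-to-peak truth is exact.  An ER 1 h peak set shares a fraction of
#' the GR peaks; the ER 24 h set is a retained subset of the ER 1 h set.
#'
#' @param cfg a [simPeakConfig()].
#' @param basal_up,basal_down basal domain extents (bp) used to place
#'   planted peaks; match [regulatoryDomainParams()] defaults.
#' @return List: `genes` (GRanges with `gene_id`, `tss`, `biotype`),
#'   `peaks` (list of GRanges `GR_1h`, `ER_1h`, `ER_24h`, each with
#'   per-sample log2-enrichment metadata columns), `truth` (list with
#'   `target_genes`, `gene2peak`, `er_retained`).
#' @export
simulateGenomePeaks <- function(cfg = simPeakConfig(),
                                basal_up = 5000, basal_down = 1000) {
  stopifnot(inherits(cfg, "SimPeakConfig"))
  withSubstream(cfg$seed, "genome", {
    chroms <- names(cfg$chrom_lengths)
    n_per <- pmax(1L, round(cfg$n_genes * cfg$chrom_lengths /
                              sum(cfg$chrom_lengths)))
    n_per[length(n_per)] <- cfg$n_genes - sum(n_per[-length(n_per)])
    margin <- basal_up + basal_down + 2L * cfg$peak_width
    tss <- integer(0); chrom <- character(0)
    for (i in seq_along(chroms)) {
      len <- cfg$chrom_lengths[i]
      ## jittered grid keeps TSSs >= min_tss_gap apart (basal domains
      ## disjoint); exact collisions re-drawn with bounded retries
      spacing <- (len - 2 * margin) / n_per[i]
      if (spacing < cfg$min_tss_gap)
        stop("chromosome ", chroms[i], " too short for ", n_per[i],
             " genes at min_tss_gap ", cfg$min_tss_gap)
      jit_half <- (spacing - cfg$min_tss_gap) / 2
      pos <- integer(0)
      for (attempt in 1:100) {
        pos <- round(margin + spacing * (seq_len(n_per[i]) - 0.5) +
                       runif(n_per[i], -jit_half, jit_half))
        if (!anyDuplicated(pos)) break
      }
      if (anyDuplicated(pos)) stop("could not place unique gene TSSs")
      tss <- c(tss, pos); chrom <- c(chrom, rep(chroms[i], n_per[i]))
    }
    strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    gene_id <- sprintf("g%03d", seq_len(cfg$n_genes))
    genes <- GenomicRanges::GRanges(chrom, IRanges::IRanges(tss, width = 1),
                                    strand = strand,
                                    seqlengths = cfg$chrom_lengths)
    S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
      gene_id = gene_id, tss = tss, biotype = "protein_coding")

    n_target <- round(cfg$target_fraction * cfg$n_genes)
    target <- sort(sample.int(cfg$n_genes, n_target))
    ## peak centers inside the strand-oriented basal window, clear of edges
    delta <- sample.int(basal_up + basal_down - 2L * cfg$peak_width,
                        n_target, replace = TRUE) -
             (basal_up - cfg$peak_width)
    delta <- ifelse(strand[target] == "+", delta, -delta)
    gr_centers <- tss[target] + delta
    gr_peaks <- .peakGRanges(chrom[target], gr_centers, cfg)
    gr_peaks$planted_gene <- gene_id[target]

    ## background peaks rejection-sampled away from every gene neighborhood
    forbidden <- GenomicRanges::reduce(GenomicRanges::resize(
      GenomicRanges::granges(genes), width = 2L * (basal_up + basal_down),
      fix = "center"))
    bg <- GenomicRanges::GRanges(seqlengths = cfg$chrom_lengths)
    need <- cfg$n_background_peaks
    for (attempt in 1:200) {
      if (need <= 0) break
      ch <- sample(chroms, need, replace = TRUE,
                   prob = cfg$chrom_lengths / sum(cfg$chrom_lengths))
      ctr <- vapply(ch, function(x)
        sample.int(cfg$chrom_lengths[x] - 2L * cfg$peak_width, 1L) +
          cfg$peak_width, numeric(1))
      cand <- .peakGRanges(ch, ctr, cfg)
      keep <- !IRanges::overlapsAny(cand, forbidden)
      cand <- cand[keep]
      if (length(cand)) {
        cand$planted_gene <- NA_character_
        bg <- c(bg, cand)
        need <- cfg$n_background_peaks - length(bg)
      }
    }
    gr_all <- sort(c(gr_peaks, bg))

    ## ER 1h: overlaps a fraction of planted GR peaks + independent peaks
    n_shared <- round(cfg$er_shared_fraction * length(gr_peaks))
    sh <- sort(sample.int(length(gr_peaks), n_shared))
    er_sh <- .peakGRanges(as.character(GenomicRanges::seqnames(gr_peaks))[sh],
                          (GenomicRanges::start(gr_peaks)[sh] +
                           GenomicRanges::end(gr_peaks)[sh]) %/% 2L +
                            sample(-100:100, n_shared, replace = TRUE), cfg)
    ch <- sample(chroms, cfg$n_er_extra, replace = TRUE,
                 prob = cfg$chrom_lengths / sum(cfg$chrom_lengths))
    ctr <- vapply(ch, function(x)
      sample.int(cfg$chrom_lengths[x] - 2L * cfg$peak_width, 1L) +
        cfg$peak_width, numeric(1))
    er1h <- sort(c(er_sh, .peakGRanges(ch, ctr, cfg)))
    er1h$peak_id <- sprintf("er%04d", seq_along(er1h))
    n_ret <- round(cfg$er_24h_retention * length(er1h))
    ret <- sort(sample.int(length(er1h), n_ret))
    er24h <- er1h[ret]

    list(genes = genes,
         peaks = list(GR_1h = gr_all, ER_1h = er1h, ER_24h = er24h),
         truth = list(target_genes = gene_id[target],
                      gene2peak = data.frame(
                        gene_id = gene_id[target],
                        peak_chrom = chrom[target],
                        peak_center = gr_centers),
                      er_retained = er1h$peak_id[ret]))
  })
}
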