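#' Equalize total reporter-ion intensity across TMT channels
#'
#' Each channel is scaled by (mean channel total / its total), so all
#' channel totals become equal while within-channel ratios are preserved
#' exactly.  Idempotent.
#'
#' @param reporter `SummarizedExperiment` with assay `intensity`
#'   (PSMs x channels) or a bare matrix.
#' @return Same container with normalized intensities.
#' @export
normalizeChannels <- function(reporter) {
  m <- if (is(reporter, "SummarizedExperiment"))
    SummarizedExperiment::assay(reporter, "intensity") else as.matrix(reporter)
  tot <- colSums(m)
  if (any(tot <= 0)) stop("zero-total channel(s): ",
                          paste(colnames(m)[tot <= 0], collapse = ", "))
  m2 <- sweep(m, 2, mean(tot) / tot, "*")
  if (is(reporter, "SummarizedExperiment")) {
    SummarizedExperiment::assay(reporter, "intensity") <- m2
    reporter
  } else m2
}

#' Sum PSM reporter intensities per protein and channel
#'
#' PSMs lacking a protein mapping are excluded (their count is reported as
#' an attribute).  Total mapped intensity is conserved.
#'
#' @param reporter `SummarizedExperiment` with assay `intensity` and
#'   rowData column `protein` (optionally `gene`).
#' @return `SummarizedExperiment` proteins x channels, assay `intensity`,
#'   rowData `protein`, `gene`, `n_psm`; attribute `n_unmapped`.
#' @export
rollupProteins <- function(reporter) {
  stopifnot(is(reporter, "SummarizedExperiment"))
  m <- SummarizedExperiment::assay(reporter, "intensity")
  rd <- SummarizedExperiment::rowData(reporter)
  if (!"protein" %in% colnames(rd)) stop("rowData must contain 'protein'")
  prot <- as.character(rd$protein)
  mapped <- !is.na(prot) & prot != ""
  n_unmapped <- sum(!mapped)
  m <- m[mapped, , drop = FALSE]; prot <- prot[mapped]
  agg <- rowsum(m, group = prot)
  n_psm <- as.integer(table(prot)[rownames(agg)])
  gene <- if ("gene" %in% colnames(rd))
    as.character(rd$gene[mapped])[match(rownames(agg), prot)]
    else rownames(agg)
  out <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = agg),
    rowData = S4Vectors::DataFrame(protein = rownames(agg), gene = gene,
                                   n_psm = n_psm),
    colData = SummarizedExperiment::colData(reporter))
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Differential protein abundance between channel groups
#'
#' Tests log2(intensity + 1) between the two channel groups; `logFC` is
#' the group-mean difference, p-values come from a two-sample t
#' (moderated by default, see [deTest()]), FDR from [bhAdjust()].  The
#' significant set uses the strict thresholds |log2FC| > 0.5 and
#' FDR < 0.05.
#'
#' @param proteins `SummarizedExperiment` from [rollupProteins()].
#' @param group_a,group_b channel ids (e.g. Dex vs vehicle); >= 2 each.
#' @param lfc_thresh,fdr_thresh strict significance thresholds.
#' @param method passed to [deTest()].
#' @return List: `table` (protein-level DE data.frame with `gene`) and
#'   `significant` (protein ids).
#' @export
proteinDE <- function(proteins, group_a = NULL, group_b = NULL,
                      lfc_thresh = 0.5, fdr_thresh = 0.05,
                      method = "moderated") {
  stopifnot(is(proteins, "SummarizedExperiment"))
  cd <- SummarizedExperiment::colData(proteins)
  if (is.null(group_a) && "condition" %in% colnames(cd)) {
    group_a <- rownames(cd)[cd$condition == "dex"]
    group_b <- rownames(cd)[cd$condition == "vehicle"]
  }
  lm <- log2(SummarizedExperiment::assay(proteins, "intensity") + 1)
  de <- deTest(lm, group_a, group_b, method = method)
  de$gene <- SummarizedExperiment::rowData(proteins)$gene[
    match(de$gene, rownames(proteins))]
  de$protein <- rownames(proteins)
  sig <- de$protein[de$fdr < fdr_thresh & abs(de$logFC) > lfc_thresh]
  list(table = de[, c("protein", "gene", "logFC", "p_value", "fdr")],
       significant = sig)
}

#' RNA-protein log-fold-change concordance
#'
#' Inner join of a transcript-level and a protein-level DE table on gene
#' symbol, returning the Pearson correlation of the two logFC vectors.
#'
#' @param rna_de [deTest()] table (`gene`, `logFC`).
#' @param prot_de protein DE table with `gene` and `logFC` (see
#'   [proteinDE()]).
#' @return List: `r` (Pearson), `n`, `joined` (data.frame gene,
#'   logFC_rna, logFC_protein).
#' @export
correlateRnaProtein <- function(rna_de, prot_de) {
  shared <- intersect(rna_de$gene, prot_de$gene)
  if (length(shared) < 3) stop("fewer than 3 shared gene symbols")
  j <- data.frame(gene = shared,
                  logFC_rna = rna_de$logFC[match(shared, rna_de$gene)],
                  logFC_protein = prot_de$logFC[match(shared, prot_de$gene)])
  list(r = cor(j$logFC_rna, j$logFC_protein), n = nrow(j), joined = j)
}
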