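#' Read / write the pipeline's plain-text interchange formats
#'
#' Counts are gene-rows x sample-columns TSV with a `gene_id` first
#' column; the sample sheet is TSV with `sample_id`, `model`, `treatment`,
#' `timepoint`, `replicate`; cohorts are TSV with `patient_id`, `time`,
#' `event` and gene columns; peaks are BED3 plus named numeric enrichment
#' columns (0-based half-open converted to/from `GRanges`); gene
#' annotation is TSV with `gene_id`, `chrom`, `strand`, `tss`.
#'
#' @param counts,se,cohort,peaks,genes,sig objects to write.
#' @param path,counts_path,samples_path file paths.
#' @return Readers return the corresponding object; writers return the
#'   path invisibly.
#' @name grsig-io
NULL

#' @rdname grsig-io
#' @export
writeCountsTsv <- function(se, counts_path, samples_path) {
  m <- SummarizedExperiment::assay(se, "counts")
  write.table(data.frame(gene_id = rownames(m), m, check.names = FALSE),
              counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  write.table(cd[, c("sample_id", "model", "treatment", "timepoint",
                     "replicate")],
              samples_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}

#' @rdname grsig-io
#' @export
readCountsTsv <- function(counts_path, samples_path) {
  df <- read.delim(counts_path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  cd <- read.delim(samples_path, colClasses = "character")
  cd$replicate <- as.integer(cd$replicate)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m[, cd$sample_id, drop = FALSE]),
    colData = S4Vectors::DataFrame(cd, row.names = cd$sample_id))
}

#' @rdname grsig-io
#' @export
writeCohortTsv <- function(cohort, path) {
  stopifnot(is(cohort, "PatientCohort"))
  df <- data.frame(patient_id = colnames(cohortExpr(cohort)),
                   time = survivalTime(cohort), event = eventStatus(cohort),
                   t(cohortExpr(cohort)), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname grsig-io
#' @export
readCohortTsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  expr <- t(as.matrix(df[, setdiff(colnames(df),
                                   c("patient_id", "time", "event")),
                         drop = FALSE]))
  colnames(expr) <- df$patient_id
  PatientCohort(expr, time = df$time, event = df$event)
}

#' @rdname grsig-io
#' @export
writePeaksBed <- function(peaks, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                   start = GenomicRanges::start(peaks) - 1L,  # to 0-based
                   end = GenomicRanges::end(peaks))
  mc <- S4Vectors::mcols(peaks)
  if (ncol(mc)) df <- cbind(df, as.data.frame(mc))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname grsig-io
#' @param chrom_lengths optional named vector to set seqlengths.
#' @export
readPeaksBed <- function(path, chrom_lengths = NULL) {
  df <- read.delim(path, check.names = FALSE)
  bad <- which(!(df$start < df$end) | df$start < 0)
  if (length(bad))
    stop("malformed interval at line ", bad[1] + 1L)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  if (!is.null(chrom_lengths))
    GenomeInfoDb::seqlengths(gr) <- chrom_lengths[
      GenomeInfoDb::seqlevels(gr)]
  extra <- setdiff(colnames(df), c("chrom", "start", "end"))
  if (length(extra))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(df[, extra, drop = FALSE])
  gr
}

#' @rdname grsig-io
#' @export
writeGeneAnnotationTsv <- function(genes, path) {
  df <- data.frame(gene_id = genes$gene_id,
                   chrom = as.character(GenomicRanges::seqnames(genes)),
                   strand = as.character(GenomicRanges::strand(genes)),
                   tss = genes$tss)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname grsig-io
#' @export
readGeneAnnotationTsv <- function(path, chrom_lengths) {
  df <- read.delim(path)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$tss, width = 1),
                               strand = df$strand,
                               seqlengths = chrom_lengths)
  gr$gene_id <- df$gene_id
  gr$tss <- df$tss
  gr
}

#' @rdname grsig-io
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(x) x[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  sets
}

#' @rdname grsig-io
#' @export
writeSignatureJson <- function(sig, path) {
  stopifnot(is(sig, "GRSignature"))
  jsonlite::write_json(
    list(genes = sig@geneIds,
         selected_cluster = sig@selectedCluster,
         onset_scores = sig@onsetScores,
         inertia = sig@inertia,
         stage_counts = as.list(sig@stageCounts),
         params = sig@params[!vapply(sig@params, is.function, logical(1))]),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname grsig-io
#' @export
readSignatureJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("GRSignature",
      geneIds = x$genes,
      clusterLabels = integer(0),
      onsetScores = as.numeric(x$onset_scores),
      selectedCluster = as.integer(x$selected_cluster),
      inertia = as.numeric(x$inertia),
      params = as.list(x$params),
      stageCounts = setNames(as.integer(unlist(x$stage_counts)),
                             names(x$stage_counts)))
}
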