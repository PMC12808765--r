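.countsMatrix <- function(counts) {
  if (is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  counts
}

## One pairwise TMM log-factor against the reference column, following the
## published trimmed-mean-of-M-values definition: gene-wise M (log2 ratio of
## proportions) and A (average log2 proportion) over genes nonzero in both,
## double trim by M and A, precision-weighted mean of the surviving M using
## the delta-method binomial variance.
.tmmPairFactor <- function(obs, ref, nO, nR, trim_m, trim_a) {
  logR <- log2((obs / nO) / (ref / nR))
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / (nO * obs) + (nR - ref) / (nR * ref)
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0 || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  keep <- rank(logR) >= loM & rank(logR) <= hiM &
          rank(absE) >= loA & rank(absE) <= hiA
  f <- sum(logR[keep] / v[keep]) / sum(1 / v[keep])
  if (!is.finite(f)) f <- 0
  2^f
}

#' Trimmed-mean-of-M-values (TMM) normalization factors
#'
#' Computes between-sample scaling factors that correct library composition
#' bias.  The reference sample is the one whose 75th-percentile
#' count-per-library-size is closest to the mean across samples; each
#' sample's log2 factor is the precision-weighted, doubly trimmed mean of
#' gene-wise log ratios against the reference; factors are rescaled to
#' geometric mean 1.
#'
#' @param counts a count matrix (genes x samples) or a
#'   `SummarizedExperiment` with a `counts` assay.
#' @param trim_m fraction of gene-wise log-ratios (M) trimmed from each
#'   tail.
#' @param trim_a fraction of average log-intensities (A) trimmed from each
#'   tail.
#' @return Named numeric vector of factors, geometric mean 1.  The
#'   effective library size of sample s is `colSums(counts)[s] * factor[s]`.
#' @export
#' @examples
#' m <- matrix(rpois(600, 50), 100, 6,
#'             dimnames = list(NULL, paste0("s", 1:6)))
#' tmmFactors(m)
tmmFactors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  x <- .countsMatrix(counts)
  if (ncol(x) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(x)
  if (any(lib == 0)) {
    bad <- colnames(x)[lib == 0]
    if (is.null(bad)) bad <- which(lib == 0)
    stop("all-zero sample(s): ", paste(bad, collapse = ", "))
  }
  f75 <- apply(x, 2, function(u) quantile(u, 0.75, names = FALSE)) / lib
  ref <- if (median(f75) < 1e-20) which.max(colSums(sqrt(x)))
         else which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(x)), function(i)
    .tmmPairFactor(x[, i], x[, ref], lib[i], lib[ref], trim_m, trim_a),
    numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(x))
}

#' log2 counts per million against TMM-effective library sizes
#'
#' `logCPM[g, s] = log2((y[g, s] + prior) / (libsize[s] * factor[s] +
#' 2 * prior) * 1e6)`.  The pseudo-count keeps zeros finite.
#'
#' @param counts count matrix or `SummarizedExperiment` with `counts`.
#' @param nf normalization factors from [tmmFactors()]; defaults to
#'   computing them.
#' @param prior pseudo-count (> 0).
#' @return genes x samples numeric matrix with attribute `prior`.
#' @export
logCPM <- function(counts, nf = tmmFactors(counts), prior = 0.5) {
  x <- .countsMatrix(counts)
  .assertScalarNum(prior, "prior", lower = .Machine$double.xmin)
  eff <- colSums(x) * nf
  if (any(eff <= 0)) stop("nonpositive effective library size")
  out <- log2(sweep(x + prior, 2, eff + 2 * prior, "/") * 1e6)
  attr(out, "prior") <- prior
  out
}

#' Filter low-expressed genes by a CPM-in-minimum-samples rule
#'
#' Keeps a gene iff its (raw-library) CPM is at least `min_cpm` in at
#' least `min_samples` samples.  The default `min_samples` is the smallest
#' design-group size derived from the sample sheet
#' (model x treatment x timepoint).
#'
#' @param counts count matrix or `SummarizedExperiment` with `counts`.
#' @param samples sample sheet (data.frame with `model`, `treatment`,
#'   `timepoint`); taken from `colData` when `counts` is a
#'   `SummarizedExperiment`.
#' @param min_cpm CPM threshold.
#' @param min_samples minimum number of samples at or above `min_cpm`.
#' @return Logical mask along the gene rows (TRUE = keep).
#' @export
filterLowExpressed <- function(counts, samples = NULL, min_cpm = 1,
                               min_samples = NULL) {
  if (is(counts, "SummarizedExperiment") && is.null(samples))
    samples <- as.data.frame(SummarizedExperiment::colData(counts))
  x <- .countsMatrix(counts)
  if (is.null(min_samples)) {
    if (is.null(samples))
      stop("min_samples or a sample sheet with model/treatment/timepoint ",
           "is required")
    grp <- interaction(samples$model, samples$treatment, samples$timepoint,
                       drop = TRUE)
    min_samples <- min(table(grp))
  }
  cpm <- sweep(x, 2, colSums(x), "/") * 1e6
  mask <- rowSums(cpm >= min_cpm) >= min_samples
  unname(mask)
}
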