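#' Benjamini-Hochberg step-up false-discovery-rate adjustment
#'
#' Validated wrapper around the standard BH step-up procedure: sort
#' p-values ascending, take `q_(i) = min_{j >= i} p_(j) * n / j` capped at
#' 1, restore input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Vector of adjusted values (FDR), same order as input.
#' @export
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
bhAdjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

.rowVarsBy <- function(x, idx) {
  sub <- x[, idx, drop = FALSE]
  mu <- rowMeans(sub)
  rowSums((sub - mu)^2) / (ncol(sub) - 1)
}

#' Two-group differential expression on logCPM
#'
#' Tests Dex vs vehicle (or any two sample groups) per gene on logCPM
#' values.  `logFC` is the difference of group means.  The default method
#' is an empirical-Bayes moderated t with a mean-variance trend
#' (limma-trend), which stabilizes the per-gene variance at triplicate
#' sample sizes; `method = "welch"` gives the unmoderated Welch two-sample
#' t.  Genes with zero log-fold change and no variance get p = 1.
#'
#' @param logcpm genes x samples logCPM matrix (see [logCPM()]).
#' @param group_a,group_b disjoint character vectors of sample ids
#'   (columns); `logFC > 0` means higher in `group_a`.
#' @param method `"moderated"` (default) or `"welch"`.
#' @return data.frame with `gene`, `logFC`, `p_value`, `fdr`.
#' @export
deTest <- function(logcpm, group_a, group_b,
                   method = c("moderated", "welch")) {
  method <- match.arg(method)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 samples")
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  missing <- setdiff(c(group_a, group_b), colnames(logcpm))
  if (length(missing))
    stop("unknown samples: ", paste(missing, collapse = ", "))
  a <- logcpm[, group_a, drop = FALSE]
  b <- logcpm[, group_b, drop = FALSE]
  lfc <- rowMeans(a) - rowMeans(b)
  if (method == "moderated") {
    m <- cbind(a, b)
    design <- cbind(Intercept = 1,
                    grp = rep(c(1, 0), c(ncol(a), ncol(b))))
    fit <- limma::eBayes(limma::lmFit(m, design), trend = TRUE)
    p <- fit$p.value[, "grp"]
    p[!is.finite(p)] <- 1
  } else {
    na <- ncol(a); nb <- ncol(b)
    va <- .rowVarsBy(logcpm, group_a)
    vb <- .rowVarsBy(logcpm, group_b)
    se2 <- va / na + vb / nb
    tt <- ifelse(se2 > 0, lfc / sqrt(se2), 0)
    df <- ifelse(se2 > 0,
                 se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
                 1)
    p <- ifelse(se2 > 0, 2 * pt(-abs(tt), df), 1)
  }
  data.frame(gene = rownames(logcpm), logFC = unname(lfc),
             p_value = unname(p), fdr = bhAdjust(unname(p)),
             stringsAsFactors = FALSE)
}

#' Threshold a differential-expression table into a gene set
#'
#' Strict inequalities on both criteria: `fdr < fdr_thresh` and
#' `|logFC| > lfc_thresh` (sign-restricted for `direction` `"up"` /
#' `"down"`).
#'
#' @param de data.frame from [deTest()] (`gene`, `logFC`, `fdr`).
#' @param lfc_thresh log2 fold-change threshold (> 0).
#' @param fdr_thresh FDR threshold.
#' @param direction `"both"`, `"up"` or `"down"`.
#' @return Character vector of gene ids.
#' @export
thresholdDE <- function(de, lfc_thresh = 1, fdr_thresh = 0.01,
                        direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  .assertScalarNum(lfc_thresh, "lfc_thresh", lower = .Machine$double.xmin)
  keep <- de$fdr < fdr_thresh & abs(de$logFC) > lfc_thresh
  if (direction == "up")   keep <- keep & de$logFC > 0
  if (direction == "down") keep <- keep & de$logFC < 0
  de$gene[keep]
}

#' Run the four standard Dex-vs-vehicle contrasts of the time-course design
#'
#' One [deTest()] per model x timepoint, comparing Dex with vehicle at the
#' same timepoint within the same model.
#'
#' @param se `SummarizedExperiment` from [simulateCounts()] (or any with
#'   the same colData columns), already filtered.
#' @param logcpm matching logCPM matrix; computed if missing.
#' @param method passed to [deTest()].
#' @return Named list of DE tables `"<model>_<timepoint>"`.
#' @export
deContrasts <- function(se, logcpm = NULL, method = "moderated") {
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  if (is.null(logcpm)) logcpm <- logCPM(se)
  out <- list()
  for (m in unique(cd$model)) for (tp in unique(cd$timepoint)) {
    a <- cd$sample_id[cd$model == m & cd$timepoint == tp &
                        cd$treatment == "dex"]
    b <- cd$sample_id[cd$model == m & cd$timepoint == tp &
                        cd$treatment == "vehicle"]
    out[[paste(m, tp, sep = "_")]] <- deTest(logcpm, a, b, method = method)
  }
  out
}
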