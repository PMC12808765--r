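#' Parameters for GR activity signature derivation
#'
#' @param lfc_thresh |log2FC| threshold of the shared-effect filter at the
#'   late timepoint (default 2, strict).
#' @param fdr_thresh FDR threshold of the shared-effect filter (default
#'   0.01, strict).
#' @param k number of k-means clusters.
#' @param n_restarts k-means++ restarts, lowest inertia kept.
#' @param max_iter Lloyd iterations per restart.
#' @param seed integer seed for the clustering substream.
#' @param sign_concordant require the same logFC sign in both models for a
#'   gene to count as shared-effect.
#' @param control_scope vehicle samples used as the onset baseline:
#'   `"all_vehicle"` (both timepoints) or `"vehicle_8h"`.
#' @param onset_stat `"mean"` (default) or `"median"` across cluster genes.
#' @param de_method passed to [deTest()].
#' @param exclude_genes genes removed before the shared-effect filter
#'   (e.g. keratins in a sensitivity analysis).
#' @return List of class `SignatureParams`.
#' @export
signatureParams <- function(lfc_thresh = 2, fdr_thresh = 0.01, k = 4,
                            n_restarts = 50, max_iter = 300, seed = 1,
                            sign_concordant = TRUE,
                            control_scope = c("all_vehicle", "vehicle_8h"),
                            onset_stat = c("mean", "median"),
                            de_method = "moderated",
                            exclude_genes = character(0)) {
  if (k < 2) stop("k must be >= 2")
  .assertScalarNum(lfc_thresh, "lfc_thresh", lower = .Machine$double.xmin)
  .assertScalarNum(fdr_thresh, "fdr_thresh", lower = .Machine$double.xmin)
  structure(list(lfc_thresh = lfc_thresh, fdr_thresh = fdr_thresh,
                 k = as.integer(k), n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 sign_concordant = isTRUE(sign_concordant),
                 control_scope = match.arg(control_scope),
                 onset_stat = match.arg(onset_stat),
                 de_method = de_method,
                 exclude_genes = as.character(exclude_genes)),
            class = "SignatureParams")
}

#' Genes with a strong shared Dex effect in both models
#'
#' Selects genes passing `|logFC| > lfc_thresh` and `fdr < fdr_thresh`
#' (strict) in BOTH models' late-timepoint contrasts, optionally requiring
#' a concordant logFC sign (a discordant "effect" is not shared).  Both
#' directions are retained.
#'
#' @param de_a,de_b [deTest()] tables of the two models at the late
#'   timepoint, sharing a gene universe.
#' @param params a [signatureParams()].
#' @return Character vector of gene ids (ordered as in `de_a`).
#' @export
sharedEffectGenes <- function(de_a, de_b, params = signatureParams()) {
  if (!setequal(de_a$gene, de_b$gene))
    stop("DE tables must share the same gene universe")
  b <- de_b[match(de_a$gene, de_b$gene), ]
  pass <- abs(de_a$logFC) > params$lfc_thresh &
          de_a$fdr < params$fdr_thresh &
          abs(b$logFC) > params$lfc_thresh &
          b$fdr < params$fdr_thresh
  if (params$sign_concordant)
    pass <- pass & sign(de_a$logFC) == sign(b$logFC)
  setdiff(de_a$gene[pass], params$exclude_genes)
}

#' Row-center a logCPM matrix over all samples
#'
#' @param logcpm genes x samples matrix.
#' @param genes subset of rownames to keep (all by default).
#' @return Matrix with each retained row minus its mean over all samples.
#' @export
meanCenter <- function(logcpm, genes = rownames(logcpm)) {
  missing <- setdiff(genes, rownames(logcpm))
  if (length(missing))
    stop("unknown genes: ", paste(head(missing, 5), collapse = ", "))
  m <- logcpm[genes, , drop = FALSE]
  m - rowMeans(m)
}

.kmppCenters <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx[j] <- sample.int(n, 1, prob = prob)
    d2 <- pmin(d2, rowSums((x - matrix(x[idx[j], ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  x[idx, , drop = FALSE]
}

#' k-means clustering of mean-centered expression profiles
#'
#' Lloyd's algorithm with k-means++ initialization, `n_restarts` restarts
#' keeping the lowest total within-cluster sum of squares (inertia);
#' deterministic given the seed.  If the matrix has fewer than `k`
#' distinct rows, duplicates are collapsed onto identical centers and the
#' inertia is 0.
#'
#' @param centered genes x samples matrix (see [meanCenter()]).
#' @param k,n_restarts,max_iter,seed see [signatureParams()].
#' @return List: `labels` (named integer per gene), `centers`, `inertia`.
#' @export
kmeansCluster <- function(centered, k = 4, n_restarts = 50, max_iter = 300,
                          seed = 1) {
  if (nrow(centered) < k) stop("fewer rows than clusters")
  uniq <- unique(centered)
  if (nrow(uniq) <= k) {
    lab <- match(asplit(centered, 1), asplit(uniq, 1))
    return(list(labels = setNames(as.integer(lab), rownames(centered)),
                centers = uniq, inertia = 0))
  }
  withSubstream(seed, "kmeans", {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      init <- .kmppCenters(centered, k)
      fit <- tryCatch(
        suppressWarnings(kmeans(centered, centers = init,
                                iter.max = max_iter, algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) stop("k-means failed on all restarts")
    list(labels = setNames(best$cluster, rownames(centered)),
         centers = best$centers, inertia = best$tot.withinss)
  })
}

.sampleIdsFor <- function(samples, treatment, timepoint = NULL) {
  keep <- samples$treatment == treatment
  if (!is.null(timepoint)) keep <- keep & samples$timepoint == timepoint
  samples$sample_id[keep]
}

#' Expression-onset score of a gene cluster
#'
#' Mean (or median) over the cluster genes of \[mean logCPM in Dex 8 h
#' samples (both models) minus mean logCPM in the control samples\].
#' Controls are all vehicle samples at both timepoints by default.
#'
#' @param genes gene ids of one cluster.
#' @param logcpm logCPM matrix.
#' @param samples sample sheet with `sample_id`, `treatment`, `timepoint`.
#' @param control_scope `"all_vehicle"` or `"vehicle_8h"`.
#' @param stat `"mean"` or `"median"` across cluster genes.
#' @return Single numeric onset score (log2 units).
#' @export
onsetScore <- function(genes, logcpm, samples,
                       control_scope = c("all_vehicle", "vehicle_8h"),
                       stat = c("mean", "median")) {
  control_scope <- match.arg(control_scope)
  stat <- match.arg(stat)
  if (length(genes) == 0) stop("cluster is empty")
  dex8 <- .sampleIdsFor(samples, "dex", "8h")
  veh <- if (control_scope == "all_vehicle")
    .sampleIdsFor(samples, "vehicle") else .sampleIdsFor(samples, "vehicle", "8h")
  if (length(dex8) == 0 || length(veh) == 0)
    stop("need both Dex-8h and vehicle samples")
  per_gene <- rowMeans(logcpm[genes, dex8, drop = FALSE]) -
              rowMeans(logcpm[genes, veh, drop = FALSE])
  if (stat == "mean") mean(per_gene) else median(per_gene)
}

#' Select the signature cluster by strongest positive onset
#'
#' The signature is the cluster with the largest onset score, which must
#' be positive (the signature is Dex-upregulated).  Ties go to the cluster
#' with the larger Dex 24 h minus vehicle difference, then to the smaller
#' cluster label.
#'
#' @param labels named integer cluster labels (see [kmeansCluster()]).
#' @param logcpm,samples as in [onsetScore()].
#' @param params a [signatureParams()].
#' @param inertia optional k-means inertia to record.
#' @param stage_counts optional named integer provenance counts.
#' @return A [GRSignature-class].
#' @export
selectSignature <- function(labels, logcpm, samples,
                            params = signatureParams(), inertia = NA_real_,
                            stage_counts = integer()) {
  ks <- sort(unique(labels))
  onset <- vapply(ks, function(k)
    onsetScore(names(labels)[labels == k], logcpm, samples,
               control_scope = params$control_scope,
               stat = params$onset_stat), numeric(1))
  if (all(onset <= 0))
    stop("no cluster has a positive onset score; review thresholds/k")
  dex24 <- .sampleIdsFor(samples, "dex", "24h")
  veh <- .sampleIdsFor(samples, "vehicle")
  late_diff <- vapply(ks, function(k) {
    g <- names(labels)[labels == k]
    mean(rowMeans(logcpm[g, dex24, drop = FALSE]) -
         rowMeans(logcpm[g, veh, drop = FALSE]))
  }, numeric(1))
  ord <- order(-onset, -late_diff, ks)
  sel <- ord[1]
  new("GRSignature",
      geneIds = names(labels)[labels == ks[sel]],
      clusterLabels = setNames(as.integer(labels), names(labels)),
      onsetScores = unname(onset),
      selectedCluster = as.integer(sel),
      inertia = as.numeric(inertia),
      params = unclass(params),
      stageCounts = stage_counts)
}

#' Classify response timing of genes from the four contrasts
#'
#' `early_up` passes the up-threshold in both models at 8 h (any 24 h
#' status); `late_up` passes at 24 h in both models but not at 8 h;
#' symmetric for down; everything else is `unchanged`.
#'
#' @param de_8h_a,de_8h_b,de_24h_a,de_24h_b [deTest()] tables over a
#'   shared gene universe.
#' @param lfc_thresh,fdr_thresh strict thresholds (defaults 1, 0.01).
#' @return Named character vector gene -> class.
#' @export
classifyResponseTiming <- function(de_8h_a, de_8h_b, de_24h_a, de_24h_b,
                                   lfc_thresh = 1, fdr_thresh = 0.01) {
  genes <- de_8h_a$gene
  for (d in list(de_8h_b, de_24h_a, de_24h_b))
    if (!setequal(genes, d$gene))
      stop("DE tables must share the same gene universe")
  pass <- function(de, dir) {
    de <- de[match(genes, de$gene), ]
    ok <- de$fdr < fdr_thresh & abs(de$logFC) > lfc_thresh
    if (dir == "up") ok & de$logFC > 0 else ok & de$logFC < 0
  }
  both <- function(d1, d2, dir) pass(d1, dir) & pass(d2, dir)
  e_up <- both(de_8h_a, de_8h_b, "up")
  e_dn <- both(de_8h_a, de_8h_b, "down")
  l_up <- both(de_24h_a, de_24h_b, "up") & !e_up
  l_dn <- both(de_24h_a, de_24h_b, "down") & !e_dn
  cls <- rep("unchanged", length(genes))
  cls[e_up] <- "early_up"; cls[e_dn] <- "early_down"
  cls[l_up] <- "late_up";  cls[l_dn] <- "late_down"
  setNames(cls, genes)
}

#' Score samples by total log-expression of the signature genes
#'
#' Sum of log-expression over the signature genes present in the matrix.
#' Up to half the signature may be missing (cross-platform application);
#' missing genes trigger a warning, more than half an error.
#'
#' @param expr genes x samples matrix (logCPM or cohort log-expression).
#' @param sig a [GRSignature-class] or character vector of genes.
#' @return Named numeric score per sample (column).
#' @export
scoreSamples <- function(expr, sig) {
  genes <- if (is(sig, "GRSignature")) signatureGenes(sig) else sig
  present <- intersect(genes, rownames(expr))
  missing <- setdiff(genes, rownames(expr))
  if (length(present) < length(genes) / 2)
    stop("fewer than half the signature genes present; missing: ",
         paste(head(missing, 10), collapse = ", "))
  if (length(missing))
    warning(length(missing), " signature gene(s) missing; scoring over ",
            length(present), " genes")
  colSums(expr[present, , drop = FALSE])
}

#' Derive a GR activity signature from a time-course count experiment
#'
#' End-to-end pipeline: low-expression filtering, TMM normalization,
#' logCPM, per-model Dex-vs-vehicle tests at both timepoints, shared-effect
#' selection at the late timepoint, mean-centering, k-means clustering,
#' and onset-based cluster selection.  Deterministic given the seed.
#'
#' @param se count `SummarizedExperiment` with the two-model time-course
#'   design (see [simulateCounts()]).
#' @param params a [signatureParams()].
#' @return A [GRSignature-class] with derivation provenance in
#'   `stageCounts`.
#' @export
#' @examples
#' se <- simulateCounts(simCountConfig(n_genes = 600, seed = 3,
#'   class_sizes = c(early_up = 25, late_up = 25,
#'                   early_down = 25, late_down = 25)))
#' sig <- deriveSignature(se, signatureParams(seed = 3))
#' sig
deriveSignature <- function(se, params = signatureParams()) {
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  stopifnot(all(c("model", "treatment", "timepoint") %in% colnames(cd)))
  mask <- filterLowExpressed(se)
  sef <- se[mask, ]
  lc <- logCPM(sef)
  de <- deContrasts(sef, lc, method = params$de_method)
  models <- unique(cd$model)
  if (length(models) != 2) stop("expected exactly 2 models")
  shared <- sharedEffectGenes(de[[paste0(models[1], "_24h")]],
                              de[[paste0(models[2], "_24h")]], params)
  if (length(shared) < params$k)
    stop("fewer shared-effect genes (", length(shared),
         ") than clusters; no signature derivable")
  centered <- meanCenter(lc, shared)
  km <- kmeansCluster(centered, k = params$k, n_restarts = params$n_restarts,
                      max_iter = params$max_iter, seed = params$seed)
  sig <- selectSignature(km$labels, lc, cd, params, inertia = km$inertia,
                         stage_counts = c(genes = nrow(se),
                                          filtered = sum(mask),
                                          shared_effect = length(shared)))
  sig@stageCounts <- c(sig@stageCounts,
                       signature = length(sig@geneIds))
  sig
}
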