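#' Configuration for the time-course count simulator
#'
#' Defines the experimental design emulated by [simulateCounts()]: two
#' cell-line models, vehicle vs dexamethasone (Dex), 8 h and 24 h, three
#' replicates per condition (12 samples per model), with planted gene
#' classes.  Early classes respond at both 8 h and 24 h, late classes only
#' at 24 h; the remainder of the genes are null.
#'
#' @param n_genes total number of genes.
#' @param class_sizes named counts for the planted classes `early_up`,
#'   `late_up`, `early_down`, `late_down`; remaining genes are null.
#' @param effect planted |log2 fold change| for responding classes.
#' @param dispersion negative-binomial dispersion phi (Var = mu + phi mu^2);
#'   0 gives Poisson counts.
#' @param baseline_logmean_mu,baseline_logmean_sd log-normal (natural log)
#'   parameters of per-gene baseline expression.
#' @param libsize_range `[min, max]` of uniform target library sizes.
#' @param n_models number of cell-line models.
#' @param n_reps replicates per model x treatment x timepoint.
#' @param model_jitter_sd sd of the per-model perturbation of planted
#'   log2FC, making the shared-effect intersection nontrivial.
#' @param seed integer seed; all simulator randomness flows from it through
#'   a named substream.
#' @return A validated list of class `SimCountConfig`.
#' @export
simCountConfig <- function(n_genes = 5000,
                           class_sizes = c(early_up = 60, late_up = 60,
                                           early_down = 60, late_down = 60),
                           effect = 3,
                           dispersion = 0.1,
                           baseline_logmean_mu = log(200),
                           baseline_logmean_sd = 1,
                           libsize_range = c(1.5e6, 2.5e6),
                           n_models = 2,
                           n_reps = 3,
                           model_jitter_sd = 0.1,
                           seed = 1) {
  cls <- c("early_up", "late_up", "early_down", "late_down")
  if (!all(cls %in% names(class_sizes)))
    stop("class_sizes must name early_up, late_up, early_down, late_down")
  class_sizes <- class_sizes[cls]
  if (sum(class_sizes) > n_genes)
    stop("sum of class_sizes exceeds n_genes")
  .assertScalarNum(dispersion, "dispersion", lower = 0)
  .assertScalarNum(effect, "effect", lower = 0)
  if (length(libsize_range) != 2L || libsize_range[1] > libsize_range[2] ||
      libsize_range[1] <= 0)
    stop("libsize_range must be [min, max] with 0 < min <= max")
  structure(list(n_genes = as.integer(n_genes),
                 class_sizes = setNames(as.integer(class_sizes), cls),
                 effect = effect, dispersion = dispersion,
                 baseline_logmean_mu = baseline_logmean_mu,
                 baseline_logmean_sd = baseline_logmean_sd,
                 libsize_range = libsize_range,
                 n_models = as.integer(n_models),
                 n_reps = as.integer(n_reps),
                 model_jitter_sd = model_jitter_sd,
                 seed = as.integer(seed)),
            class = "SimCountConfig")
}

.plantedLfc <- function(cfg) {
  cls <- rep("null", cfg$n_genes)
  idx <- 1L
  for (cl in names(cfg$class_sizes)) {
    k <- cfg$class_sizes[[cl]]
    if (k > 0) cls[idx:(idx + k - 1L)] <- cl
    idx <- idx + k
  }
  sgn <- ifelse(grepl("up$", cls), 1, ifelse(cls == "null", 0, -1))
  lfc8  <- ifelse(grepl("^early", cls), sgn * cfg$effect, 0)
  lfc24 <- ifelse(cls == "null", 0, sgn * cfg$effect)
  data.frame(planted_class = cls, planted_log2fc_8h = lfc8,
             planted_log2fc_24h = lfc24, stringsAsFactors = FALSE)
}

#' Simulate a two-model Dex time-course count experiment
#'
#' Draws negative-binomial counts for a `n_models` x \{vehicle, dex\} x
#' \{8h, 24h\} x `n_reps` design (24 samples at defaults).  Planted log2
#' fold changes are applied only in Dex samples at each class's active
#' timepoints, with a small per-model jitter so the two models share an
#' effect without being identical.  Per-sample expected totals equal the
#' drawn target library sizes.
#'
#' @param cfg a [simCountConfig()].
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`, `colData` columns `sample_id`, `model`, `treatment`,
#'   `timepoint`, `replicate`, and `rowData` holding the planted truth
#'   (`planted_class`, `planted_log2fc_8h`, `planted_log2fc_24h`).  The
#'   per-model jittered log2FCs are kept in `metadata()$model_lfc`.
#' @export
#' @examples
#' se <- simulateCounts(simCountConfig(n_genes = 200, seed = 7,
#'   class_sizes = c(early_up = 10, late_up = 10,
#'                   early_down = 10, late_down = 10)))
#' dim(se)
simulateCounts <- function(cfg = simCountConfig()) {
  stopifnot(inherits(cfg, "SimCountConfig"))
  truth <- .plantedLfc(cfg)
  genes <- sprintf("gene%05d", seq_len(cfg$n_genes))
  models <- LETTERS[seq_len(cfg$n_models)]
  design <- expand.grid(replicate = seq_len(cfg$n_reps),
                        timepoint = c("8h", "24h"),
                        treatment = c("vehicle", "dex"),
                        model = models,
                        stringsAsFactors = FALSE)
  design <- design[, c("model", "treatment", "timepoint", "replicate")]
  design$sample_id <- with(design, paste(model, treatment, timepoint,
                                         paste0("r", replicate), sep = "_"))
  withSubstream(cfg$seed, "counts", {
    base <- rlnorm(cfg$n_genes, cfg$baseline_logmean_mu,
                   cfg$baseline_logmean_sd)
    ## per-model jitter on nonzero planted effects, one draw per gene/model
    jit <- matrix(rnorm(cfg$n_genes * cfg$n_models, 0, cfg$model_jitter_sd),
                  cfg$n_genes, cfg$n_models, dimnames = list(genes, models))
    lfc <- list(
      `8h`  = vapply(seq_len(cfg$n_models), function(m)
        ifelse(truth$planted_log2fc_8h != 0,
               truth$planted_log2fc_8h + jit[, m], 0), numeric(cfg$n_genes)),
      `24h` = vapply(seq_len(cfg$n_models), function(m)
        ifelse(truth$planted_log2fc_24h != 0,
               truth$planted_log2fc_24h + jit[, m], 0), numeric(cfg$n_genes))
    )
    libsize <- runif(nrow(design), cfg$libsize_range[1], cfg$libsize_range[2])
    counts <- matrix(0L, cfg$n_genes, nrow(design),
                     dimnames = list(genes, design$sample_id))
    for (s in seq_len(nrow(design))) {
      m <- match(design$model[s], models)
      rel <- base
      if (design$treatment[s] == "dex")
        rel <- base * 2^lfc[[design$timepoint[s]]][, m]
      mu <- rel / sum(rel) * libsize[s]
      counts[, s] <- if (cfg$dispersion == 0) rpois(cfg$n_genes, mu)
                     else rnbinom(cfg$n_genes, mu = mu,
                                  size = 1 / cfg$dispersion)
    }
    dimnames(lfc[["8h"]]) <- dimnames(lfc[["24h"]]) <- list(genes, models)
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts),
      rowData = S4Vectors::DataFrame(gene_id = genes, truth),
      colData = S4Vectors::DataFrame(design, target_libsize = libsize,
                                     row.names = design$sample_id),
      metadata = list(config = cfg, model_lfc = lfc))
  })
}

#' @importFrom stats rpois
NULL
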