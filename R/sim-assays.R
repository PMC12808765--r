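#' Configuration for the TMT reporter-intensity simulator
#'
#' @param n_psms peptide-spectrum matches (rows).
#' @param n_proteins proteins the PSMs map to.
#' @param n_channels TMT channels; the first half are vehicle, the second
#'   half Dex.
#' @param channel_load_factors multiplicative per-channel loading biases
#'   (> 0); length `n_channels` or NULL for log-normal draws (sd 0.15).
#' @param de_fraction fraction of proteins with a planted abundance change.
#' @param effect planted |log2 fold change| for affected proteins.
#' @param noise_sdlog log-normal measurement noise (natural-log sd).
#' @param gene_symbols optional explicit gene symbols, one per protein
#'   (e.g. to pair a proteome run with an RNA-seq simulation).
#' @param planted_lfc optional explicit per-protein planted log2 fold
#'   changes, overriding `de_fraction`/`effect`.
#' @param seed integer seed.
#' @return A validated list of class `SimTmtConfig`.
#' @export
simTmtConfig <- function(n_psms = 2000, n_proteins = 400, n_channels = 8,
                         channel_load_factors = NULL, de_fraction = 0.1,
                         effect = 2, noise_sdlog = 0.1,
                         gene_symbols = NULL, planted_lfc = NULL, seed = 1) {
  if (!is.null(channel_load_factors)) {
    if (length(channel_load_factors) != n_channels)
      stop("channel_load_factors must have length n_channels")
    if (any(channel_load_factors <= 0))
      stop("channel_load_factors must be > 0")
  }
  .assertScalarNum(de_fraction, "de_fraction", 0, 1)
  if (!is.null(gene_symbols) && length(gene_symbols) != n_proteins)
    stop("gene_symbols must have length n_proteins")
  if (!is.null(planted_lfc) && length(planted_lfc) != n_proteins)
    stop("planted_lfc must have length n_proteins")
  structure(list(n_psms = as.integer(n_psms),
                 n_proteins = as.integer(n_proteins),
                 n_channels = as.integer(n_channels),
                 channel_load_factors = channel_load_factors,
                 de_fraction = de_fraction, effect = effect,
                 noise_sdlog = noise_sdlog,
                 gene_symbols = gene_symbols, planted_lfc = planted_lfc,
                 seed = as.integer(seed)),
            class = "SimTmtConfig")
}

#' Simulate a PSM-level TMT reporter-intensity matrix
#'
#' Reporter intensity = protein-level signal x PSM ionization share x
#' channel loading factor x log-normal noise.  A `de_fraction` of proteins
#' carries a planted log2 fold change in the Dex channels (half up, half
#' down).
#'
#' @param cfg a [simTmtConfig()].
#' @return List: `reporter` (a
#'   [SummarizedExperiment::SummarizedExperiment], assay `intensity`,
#'   rowData `psm_id`/`protein`/`gene`, colData `channel`/`condition`) and
#'   `truth` (data.frame protein, planted_log2fc).
#' @export
simulateReporter <- function(cfg = simTmtConfig()) {
  stopifnot(inherits(cfg, "SimTmtConfig"))
  withSubstream(cfg$seed, "tmt", {
    load <- cfg$channel_load_factors
    if (is.null(load)) load <- rlnorm(cfg$n_channels, 0, 0.15)
    prots <- sprintf("P%04d", seq_len(cfg$n_proteins))
    cond <- rep(c("vehicle", "dex"), each = cfg$n_channels %/% 2,
                length.out = cfg$n_channels)
    if (!is.null(cfg$planted_lfc)) {
      lfc <- cfg$planted_lfc
    } else {
      n_de <- round(cfg$de_fraction * cfg$n_proteins)
      lfc <- numeric(cfg$n_proteins)
      if (n_de > 0) {
        de_idx <- sample.int(cfg$n_proteins, n_de)
        lfc[de_idx] <- cfg$effect * rep_len(c(1, -1), n_de)
      }
    }
    genes <- if (is.null(cfg$gene_symbols)) sub("^P", "GENE", prots)
             else cfg$gene_symbols
    prot_base <- rlnorm(cfg$n_proteins, log(1e6), 1)
    ## every protein receives at least one PSM, rest multinomial
    assign <- c(seq_len(cfg$n_proteins),
                sample.int(cfg$n_proteins, cfg$n_psms - cfg$n_proteins,
                           replace = TRUE))
    share <- rlnorm(cfg$n_psms, log(0.2), 0.8)
    signal <- prot_base[assign] * share
    fc <- 2^(outer(lfc[assign], as.numeric(cond == "dex")))
    noise <- matrix(rlnorm(cfg$n_psms * cfg$n_channels, 0, cfg$noise_sdlog),
                    cfg$n_psms, cfg$n_channels)
    intensity <- signal * fc * rep(load, each = cfg$n_psms) * noise
    chans <- sprintf("ch%02d", seq_len(cfg$n_channels))
    dimnames(intensity) <- list(sprintf("psm%05d", seq_len(cfg$n_psms)), chans)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(intensity = intensity),
      rowData = S4Vectors::DataFrame(psm_id = rownames(intensity),
                                     protein = prots[assign],
                                     gene = genes[assign]),
      colData = S4Vectors::DataFrame(channel = chans, condition = cond,
                                     load_factor = load, row.names = chans),
      metadata = list(config = cfg))
    list(reporter = se,
         truth = data.frame(protein = prots, gene = genes,
                            planted_log2fc = lfc))
  })
}

#' Configuration for the viability-plate simulator
#'
#' @param a,b single-drug viability fractions relative to vehicle (in
#'   (0, 1]).
#' @param sigma synergy depth: the combination arm is `a*b*(1 - sigma)`
#'   times vehicle, so `sigma = 0` is Bliss independence.
#' @param baseline vehicle luminescence level (arbitrary units).
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param n_reps replicates per arm.
#' @param seed integer seed.
#' @return A validated list of class `SimViabilityConfig`.
#' @export
simViabilityConfig <- function(a = 0.6, b = 0.7, sigma = 0.3,
                               baseline = 1e5, noise_cv = 0.05,
                               n_reps = 5, seed = 1) {
  .assertScalarNum(a, "a", 1e-9, 1); .assertScalarNum(b, "b", 1e-9, 1)
  .assertScalarNum(sigma, "sigma", 0, 1 - 1e-9)
  structure(list(a = a, b = b, sigma = sigma, baseline = baseline,
                 noise_cv = noise_cv, n_reps = as.integer(n_reps),
                 seed = as.integer(seed)),
            class = "SimViabilityConfig")
}

#' Simulate a drug-combination viability plate
#'
#' Arm means are `C = baseline`, `A = a*C`, `B = b*C`,
#' `AB = a*b*C*(1 - sigma)`; replicates get multiplicative log-normal noise
#' with the configured CV.
#'
#' @param cfg a [simViabilityConfig()].
#' @return List: `plate` (data.frame arm/replicate/value) and `truth`
#'   (list with the true combination index `1 - sigma`).
#' @export
simulateViability <- function(cfg = simViabilityConfig()) {
  stopifnot(inherits(cfg, "SimViabilityConfig"))
  withSubstream(cfg$seed, "viability", {
    means <- c(C = cfg$baseline, A = cfg$a * cfg$baseline,
               B = cfg$b * cfg$baseline,
               AB = cfg$a * cfg$b * cfg$baseline * (1 - cfg$sigma))
    sdlog <- sqrt(log(1 + cfg$noise_cv^2))
    plate <- expand.grid(arm = names(means), replicate = seq_len(cfg$n_reps),
                         stringsAsFactors = FALSE)
    plate$value <- means[plate$arm] *
      rlnorm(nrow(plate), -sdlog^2 / 2, sdlog)
    list(plate = plate[order(plate$arm, plate$replicate), ],
         truth = list(combination_index = 1 - cfg$sigma))
  })
}
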