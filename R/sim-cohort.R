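#' Configuration for the survival-cohort simulator
#'
#' @param n_patients cohort size (>= 8).
#' @param n_genes number of background genes (signature genes and `ESR1`
#'   are added on top of these).
#' @param signature_genes character, the genes whose summed log-expression
#'   defines the planted activity score.
#' @param beta log-hazard per 1 SD of the planted score; negative =
#'   protective (high score, better outcome).
#' @param censor_admin_time administrative censoring time (months).
#' @param target_event_fraction fraction of patients with an observed event
#'   before administrative censoring; the baseline hazard is solved to hit
#'   it.
#' @param gamma_esr1 planted anti-correlation strength between `ESR1`
#'   log-expression and the standardized score.
#' @param noise_sd per-gene log-expression noise sd.
#' @param seed integer seed.
#' @return A validated list of class `SimCohortConfig`.
#' @export
simCohortConfig <- function(n_patients = 800,
                            n_genes = 100,
                            signature_genes = sprintf("sig%02d", 1:52),
                            beta = -0.8,
                            censor_admin_time = 120,
                            target_event_fraction = 0.6,
                            gamma_esr1 = 1,
                            noise_sd = 1,
                            seed = 1) {
  if (n_patients < 8) stop("n_patients must be >= 8")
  if (length(signature_genes) == 0) stop("signature_genes must be nonempty")
  .assertScalarNum(censor_admin_time, "censor_admin_time", lower = 1e-9)
  .assertScalarNum(target_event_fraction, "target_event_fraction",
                   lower = 0.01, upper = 0.99)
  structure(list(n_patients = as.integer(n_patients),
                 n_genes = as.integer(n_genes),
                 signature_genes = as.character(signature_genes),
                 beta = beta, censor_admin_time = censor_admin_time,
                 target_event_fraction = target_event_fraction,
                 gamma_esr1 = gamma_esr1, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "SimCohortConfig")
}

#' Simulate a patient cohort with survival driven by a planted score
#'
#' Per-patient log-expression is drawn around per-gene baselines; the
#' planted activity score is the total log-expression over the signature
#' genes.  Event times are exponential with hazard
#' `h0 * exp(beta * z)` for the standardized score `z`; `h0` is solved so
#' the expected event fraction before administrative censoring matches the
#' configured target.  An `ESR1` row is appended as
#' `alpha - gamma_esr1 * z + noise`, planting the anti-correlation between
#' estrogen-receptor expression and GR activity.
#'
#' @param cfg a [simCohortConfig()].
#' @return A list with elements `cohort` (a [PatientCohort-class]) and
#'   `truth` (list: `score`, `z`, `h0`, `expected_event_fraction`).
#' @export
simulateCohort <- function(cfg = simCohortConfig()) {
  stopifnot(inherits(cfg, "SimCohortConfig"))
  withSubstream(cfg$seed, "cohort", {
    n <- cfg$n_patients
    genes <- unique(c(cfg$signature_genes,
                      sprintf("bg%04d", seq_len(cfg$n_genes))))
    mu <- rnorm(length(genes), 6, 0.5)
    expr <- matrix(rnorm(length(genes) * n, mu, cfg$noise_sd),
                   length(genes), n,
                   dimnames = list(genes, sprintf("pt%04d", seq_len(n))))
    score <- colSums(expr[cfg$signature_genes, , drop = FALSE])
    z <- as.numeric(scale(score))
    risk <- exp(cfg$beta * z)
    cens <- cfg$censor_admin_time
    evfrac <- function(h0) mean(1 - exp(-h0 * risk * cens))
    h0 <- uniroot(function(lh) evfrac(exp(lh)) - cfg$target_event_fraction,
                  lower = -25, upper = 10, tol = 1e-10)$root
    h0 <- exp(h0)
    t_event <- rexp(n, rate = h0 * risk)
    event <- as.integer(t_event <= cens)
    time <- pmin(t_event, cens)
    if (!"ESR1" %in% genes) {
      esr1 <- 8 - cfg$gamma_esr1 * z + rnorm(n, 0, cfg$noise_sd)
      expr <- rbind(expr, ESR1 = esr1)
    }
    list(cohort = PatientCohort(expr, time = time, event = event),
         truth = list(score = score, z = z, h0 = h0,
                      expected_event_fraction = evfrac(h0)))
  })
}
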