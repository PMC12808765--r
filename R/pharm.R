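#' Drug-combination synergy test on viability values
#'
#' Applies the Bliss-style inequality `AB/C < (A/C) * (B/C)`: with
#' vehicle viability `C`, single-drug viabilities `A`, `B`, and
#' combination `AB`, the combination index is `CI = (AB * C) / (A * B)`
#' and the pair is called synergistic iff `CI < 1 - epsilon` (strict).
#' CI is invariant to the measurement unit and to swapping the drugs.
#'
#' @param C,A,B,AB replicate-averaged viability values; `C`, `A`, `B`
#'   must be positive.
#' @param epsilon optional tolerance below the independence boundary
#'   (default 0, the strict inequality).
#' @return List: `combination_index`, `is_synergistic`.
#' @export
#' @examples
#' synergyTest(C = 100, A = 50, B = 50, AB = 20)  # CI 0.8, synergistic
synergyTest <- function(C, A, B, AB, epsilon = 0) {
  for (v in list(C = C, A = A, B = B)) .assertScalarNum(
    v, "viability", lower = .Machine$double.xmin)
  .assertScalarNum(AB, "AB", lower = 0)
  ci <- unname((AB * C) / (A * B))
  list(combination_index = ci, is_synergistic = ci < 1 - epsilon)
}

#' Summarize a viability plate into a synergy call
#'
#' Averages replicates per arm, applies [synergyTest()], and (optionally)
#' bootstraps the combination index over replicates for an uncertainty
#' interval.
#'
#' @param plate data.frame with columns `arm` (`C`, `A`, `B`, `AB`),
#'   `replicate`, `value`.
#' @param epsilon passed to [synergyTest()].
#' @param n_boot bootstrap resamples of replicates (0 = none).
#' @param seed seed for the bootstrap substream.
#' @return List: `means` (per-arm), `combination_index`,
#'   `is_synergistic`, and `ci_interval` (2.5/97.5% bootstrap quantiles)
#'   when `n_boot > 0`.
#' @export
synergyTable <- function(plate, epsilon = 0, n_boot = 0, seed = 1) {
  arms <- c("C", "A", "B", "AB")
  missing <- setdiff(arms, unique(plate$arm))
  if (length(missing))
    stop("missing arm(s): ", paste(missing, collapse = ", "))
  means <- vapply(arms, function(a) mean(plate$value[plate$arm == a]),
                  numeric(1))
  res <- synergyTest(means["C"], means["A"], means["B"], means["AB"],
                     epsilon = epsilon)
  out <- list(means = means, combination_index = res$combination_index,
              is_synergistic = res$is_synergistic)
  if (n_boot > 0) {
    vals <- split(plate$value, plate$arm)
    out$ci_interval <- withSubstream(seed, "synergy-boot", {
      ci <- vapply(seq_len(n_boot), function(i) {
        m <- vapply(arms, function(a) {
          v <- vals[[a]]; mean(v[sample.int(length(v), replace = TRUE)])
        }, numeric(1))
        (m["AB"] * m["C"]) / (m["A"] * m["B"])
      }, numeric(1))
      quantile(ci, c(0.025, 0.975), names = FALSE)
    })
  }
  out
}
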