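#' Quartile stratification of patient scores
#'
#' Patients at or above the top quartile (Q3) are `High`, at or below the
#' bottom quartile (Q1) `Low`, the rest `Intermediate`; quartiles are
#' type-7 (linear interpolation).  `mode = "high_low"` drops the
#' intermediate group.  A degenerate score vector (Q1 == Q3) yields
#' all-Intermediate with a warning.
#'
#' @param scores named numeric per-patient scores (n >= 8).
#' @param mode `"three_way"` or `"high_low"`.
#' @return List: `stratum` (named factor `Low`/`Intermediate`/`High`, NA
#'   for patients dropped in `high_low` mode), `q1`, `q3`.
#' @export
#' @examples
#' stratifyQuartiles(setNames(1:8, paste0("p", 1:8)))
stratifyQuartiles <- function(scores, mode = c("three_way", "high_low")) {
  mode <- match.arg(mode)
  if (length(scores) < 8) stop("need at least 8 patients")
  q <- quantile(scores, c(0.25, 0.75), type = 7, names = FALSE)
  lv <- c("Low", "Intermediate", "High")
  if (q[1] == q[2]) {
    warning("degenerate scores (Q1 == Q3); all patients Intermediate")
    stratum <- factor(rep("Intermediate", length(scores)), levels = lv)
  } else {
    stratum <- factor(ifelse(scores >= q[2], "High",
                             ifelse(scores <= q[1], "Low", "Intermediate")),
                      levels = lv)
  }
  names(stratum) <- names(scores)
  if (mode == "high_low") stratum[stratum == "Intermediate"] <- NA
  list(stratum = stratum, q1 = q[1], q3 = q[2])
}

#' Kaplan-Meier survival curves per stratum
#'
#' Product-limit estimator with right censoring, one curve per stratum.
#'
#' @param time positive survival times.
#' @param event 0/1 event indicator.
#' @param stratum optional factor; a single pooled curve if missing.
#' @return A `survival::survfit` object.
#' @export
kmEstimate <- function(time, event, stratum = NULL) {
  if (any(time <= 0)) stop("survival times must be positive")
  if (is.null(stratum))
    return(survival::survfit(survival::Surv(time, event) ~ 1))
  keep <- !is.na(stratum)
  df <- data.frame(time = time[keep], event = event[keep],
                   stratum = droplevels(factor(stratum[keep])))
  if (any(table(df$stratum) == 0)) stop("empty stratum")
  survival::survfit(survival::Surv(time, event) ~ stratum, data = df)
}

#' Log-rank (Mantel-Cox) test across strata
#'
#' @param time,event,stratum as in [kmEstimate()]; >= 2 nonempty strata.
#' @return List: `chisq`, `df`, `p_value`.
#' @export
logrankTest <- function(time, event, stratum) {
  keep <- !is.na(stratum)
  stratum <- droplevels(factor(stratum[keep]))
  if (nlevels(stratum) < 2) stop("need >= 2 nonempty strata")
  df <- data.frame(time = time[keep], event = event[keep], stratum = stratum)
  sd <- survival::survdiff(survival::Surv(time, event) ~ stratum, data = df)
  dof <- length(sd$n) - 1
  list(chisq = unname(sd$chisq), df = dof,
       p_value = stats::pchisq(sd$chisq, dof, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Breslow tie handling, giving the log-hazard
#' coefficient per unit covariate, its hazard ratio and Wald 95% CI.
#'
#' @param time,event survival data.
#' @param covariate numeric per-patient covariate (e.g. signature score),
#'   non-constant.
#' @return List: `beta`, `se`, `hr`, `ci_lower`, `ci_upper`, `p_value`.
#' @export
coxFit <- function(time, event, covariate) {
  if (length(unique(covariate)) < 2) stop("covariate is constant")
  if (sum(event) < 1) stop("no events")
  fit <- survival::coxph(survival::Surv(time, event) ~ covariate,
                         ties = "breslow")
  beta <- unname(coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  list(beta = beta, se = se, hr = exp(beta),
       ci_lower = exp(beta - 1.96 * se), ci_upper = exp(beta + 1.96 * se),
       p_value = unname(summary(fit)$coefficients[, "Pr(>|z|)"]))
}

#' Compare one gene's expression across score strata
#'
#' Per-stratum mean/median summaries plus a two-sided independent-sample
#' rank-sum (Wilcoxon) test of High vs Low.
#'
#' @param expr numeric named vector, one gene's expression per patient.
#' @param stratum factor `Low`/`Intermediate`/`High` per patient.
#' @return List: `summary` (data.frame stratum/n/mean/median), `p_value`
#'   (High vs Low rank-sum).
#' @export
compareExpressionAcrossStrata <- function(expr, stratum) {
  stratum <- factor(stratum, levels = c("Low", "Intermediate", "High"))
  hi <- expr[which(stratum == "High")]
  lo <- expr[which(stratum == "Low")]
  if (length(hi) == 0 || length(lo) == 0)
    stop("both High and Low strata must be nonempty")
  lvls <- levels(droplevels(stratum[!is.na(stratum)]))
  smry <- do.call(rbind, lapply(lvls, function(l) {
    v <- expr[which(stratum == l)]
    data.frame(stratum = l, n = length(v), mean = mean(v),
               median = median(v))
  }))
  p <- if (length(unique(c(hi, lo))) == 1) 1 else
    suppressWarnings(wilcox.test(hi, lo, exact = FALSE)$p.value)
  list(summary = smry, p_value = p)
}

#' @importFrom stats coef
NULL
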