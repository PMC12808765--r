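#' GRSignature: a derived GR activity gene signature
#'
#' Ordered gene identifiers making up a glucocorticoid-receptor (GR) activity
#' signature, together with the derivation metadata: k-means cluster labels
#' over the shared-effect genes, the per-cluster expression-onset scores, the
#' selected cluster, the k-means within-cluster sum of squares (inertia) and
#' the parameters used.
#'
#' @slot geneIds character, the signature genes (unique, ordered).
#' @slot clusterLabels named integer, k-means cluster label per
#'   shared-effect gene.
#' @slot onsetScores numeric, one expression-onset score per cluster
#'   (Dex 8 h mean minus vehicle mean of logCPM, averaged over cluster genes).
#' @slot selectedCluster integer(1), the cluster chosen for the signature.
#' @slot inertia numeric(1), total within-cluster sum of squares.
#' @slot params list, the derivation parameters (thresholds, k, seed, ...).
#' @slot stageCounts named integer, gene counts surviving each stage
#'   (provenance of the derivation funnel).
#'
#' @aliases GRSignature-class
#' @exportClass GRSignature
setClass("GRSignature",
  representation(
    geneIds         = "character",
    clusterLabels   = "integer",
    onsetScores     = "numeric",
    selectedCluster = "integer",
    inertia         = "numeric",
    params          = "list",
    stageCounts     = "integer"
  )
)

setValidity("GRSignature", function(object) {
  msg <- NULL
  if (length(object@geneIds) == 0L)
    msg <- c(msg, "signature must contain at least one gene")
  if (anyDuplicated(object@geneIds))
    msg <- c(msg, "signature gene ids must be unique")
  if (length(object@selectedCluster) == 1L &&
      length(object@onsetScores) >= object@selectedCluster &&
      object@onsetScores[object@selectedCluster] <= 0)
    msg <- c(msg, "selected cluster must have positive onset score")
  if (is.null(msg)) TRUE else msg
})

#' PatientCohort: expression plus right-censored survival
#'
#' A patient cohort holding per-patient log-expression (genes x patients),
#' survival time, an event indicator, and an optional stratum assignment.
#'
#' @slot expr numeric matrix, genes x patients, log-expression; dimnames
#'   required.
#' @slot time numeric, survival time per patient (months), positive.
#' @slot event integer, 1 = event observed, 0 = right-censored.
#' @slot stratum factor, levels `Low`, `Intermediate`, `High` (may be all
#'   `NA` before stratification).
#'
#' @aliases PatientCohort-class
#' @exportClass PatientCohort
setClass("PatientCohort",
  representation(
    expr    = "matrix",
    time    = "numeric",
    event   = "integer",
    stratum = "factor"
  )
)

setValidity("PatientCohort", function(object) {
  msg <- NULL
  n <- ncol(object@expr)
  if (is.null(rownames(object@expr)) || is.null(colnames(object@expr)))
    msg <- c(msg, "expression matrix must have gene and patient dimnames")
  if (length(object@time) != n || length(object@event) != n)
    msg <- c(msg, "time and event must have one entry per patient")
  if (any(object@time <= 0))
    msg <- c(msg, "survival times must be positive")
  if (!all(object@event %in% c(0L, 1L)))
    msg <- c(msg, "event must be 0 (censored) or 1 (event)")
  if (is.null(msg)) TRUE else msg
})

#' Construct a PatientCohort
#'
#' @param expr genes x patients numeric matrix of log-expression with
#'   dimnames.
#' @param time positive survival times (months), one per patient.
#' @param event 0/1 event indicator, one per patient.
#' @param stratum optional factor of `Low`/`Intermediate`/`High` strata.
#' @return A [PatientCohort-class] object.
#' @export
#' @examples
#' expr <- matrix(rnorm(20), 4, 5,
#'                dimnames = list(paste0("g", 1:4), paste0("p", 1:5)))
#' PatientCohort(expr, time = 1:5, event = c(1, 0, 1, 1, 0))
PatientCohort <- function(expr, time, event,
                          stratum = factor(rep(NA_character_, ncol(expr)),
                                           levels = c("Low", "Intermediate",
                                                      "High"))) {
  new("PatientCohort", expr = expr, time = as.numeric(time),
      event = as.integer(event), stratum = stratum)
}

setMethod("show", "GRSignature", function(object) {
  cat("GRSignature with", length(object@geneIds), "genes\n")
  cat("  selected cluster:", object@selectedCluster,
      sprintf("(onset score %.3f)\n", object@onsetScores[object@selectedCluster]))
  cat("  cluster onset scores:",
      paste(sprintf("%.3f", object@onsetScores), collapse = ", "), "\n")
  if (length(object@stageCounts))
    cat("  derivation funnel:",
        paste(names(object@stageCounts), object@stageCounts,
              sep = "=", collapse = " -> "), "\n")
  cat("  genes:", paste(head(object@geneIds, 8), collapse = ", "),
      if (length(object@geneIds) > 8) "...", "\n")
})

setMethod("show", "PatientCohort", function(object) {
  cat("PatientCohort:", ncol(object@expr), "patients,",
      nrow(object@expr), "genes\n")
  cat(sprintf("  events: %d (%.1f%%), median follow-up %.1f\n",
              sum(object@event), 100 * mean(object@event),
              median(object@time)))
  if (!all(is.na(object@stratum)))
    print(table(stratum = object@stratum))
})

#' @describeIn GRSignature-class the signature gene identifiers.
#' @param x a `GRSignature`.
#' @export
signatureGenes <- function(x) {
  stopifnot(is(x, "GRSignature"))
  x@geneIds
}

#' @describeIn GRSignature-class per-cluster expression-onset scores.
#' @export
onsetScores <- function(x) {
  stopifnot(is(x, "GRSignature"))
  x@onsetScores
}

#' @describeIn PatientCohort the patients' log-expression matrix.
#' @export
cohortExpr <- function(x) {
  stopifnot(is(x, "PatientCohort"))
  x@expr
}

#' @describeIn PatientCohort survival time per patient.
#' @export
survivalTime <- function(x) {
  stopifnot(is(x, "PatientCohort"))
  x@time
}

#' @describeIn PatientCohort 0/1 event indicator per patient.
#' @export
eventStatus <- function(x) {
  stopifnot(is(x, "PatientCohort"))
  x@event
}

#' @describeIn PatientCohort stratum assignment (factor, may be NA).
#' @export
cohortStratum <- function(x) {
  stopifnot(is(x, "PatientCohort"))
  x@stratum
}
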