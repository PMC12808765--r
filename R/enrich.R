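#' Rank genes by log fold change
#'
#' Descending by the ranking statistic (logFC); ties broken by ascending
#' gene id so the order is deterministic.
#'
#' @param de [deTest()]-style data.frame with `gene` and `logFC` (or a
#'   named numeric vector of statistics).
#' @return data.frame `gene`, `stat`, ordered.
#' @export
rankGenes <- function(de) {
  if (is.numeric(de)) de <- data.frame(gene = names(de), logFC = unname(de))
  if (any(!is.finite(de$logFC))) stop("non-finite ranking statistic")
  if (anyDuplicated(de$gene)) stop("duplicate gene ids")
  ord <- order(-de$logFC, de$gene)
  data.frame(gene = de$gene[ord], stat = de$logFC[ord],
             stringsAsFactors = FALSE)
}

#' Weighted Kolmogorov-Smirnov-like running-sum enrichment score
#'
#' Walks the ranked list: at a gene-set hit the running sum increases by
#' `|stat|^weight / N_R` (`N_R` = sum of `|stat|^weight` over hits), at a
#' miss it decreases by `1 / (N - N_hits)`.  The enrichment score is the
#' signed deviation of maximum magnitude; the leading edge contains the
#' hits up to (positive ES) or from (negative ES) the extremum.
#'
#' @param ranked output of [rankGenes()].
#' @param gene_set character vector; intersection with the ranking must be
#'   nonempty.
#' @param weight exponent on |stat| (1 = classic weighted GSEA, 0 =
#'   unweighted KS).
#' @return List: `es`, `running` (curve along the ranking),
#'   `leading_edge` (genes).
#' @export
#' @examples
#' r <- rankGenes(c(a = 2, b = 1, c = -1))
#' enrichmentScore(r, "a")$es  # 1.0
enrichmentScore <- function(ranked, gene_set, weight = 1) {
  hit <- ranked$gene %in% gene_set
  n <- length(hit); nh <- sum(hit)
  if (nh == 0) stop("gene set does not intersect the ranking")
  nr <- sum(abs(ranked$stat[hit])^weight)
  if (nr == 0) stop("all hit statistics are zero")
  incr <- numeric(n)
  incr[hit] <- abs(ranked$stat[hit])^weight / nr
  if (nh < n) incr[!hit] <- -1 / (n - nh)
  running <- cumsum(incr)
  i_star <- which.max(abs(running))
  es <- running[i_star]
  le <- if (es >= 0) ranked$gene[hit & seq_len(n) <= i_star]
        else ranked$gene[hit & seq_len(n) >= i_star]
  list(es = es, running = running, leading_edge = le)
}

## O(k) enrichment score from sorted hit positions (used for the
## permutation null); extremes of the walk occur at hit boundaries.
.esFromPositions <- function(absw, pos, n) {
  k <- length(pos)
  w <- absw[pos]
  nr <- sum(w)
  if (nr == 0) return(0)
  md <- if (k < n) 1 / (n - k) else 0
  cum_hit <- cumsum(w / nr)
  misses_before <- pos - seq_len(k)
  after <- cum_hit - misses_before * md            # just after each hit
  before <- c(0, cum_hit[-k]) - misses_before * md # just before each hit
  hi <- max(after); lo <- min(c(before, 0))
  if (hi >= -lo) hi else lo
}

#' Gene-permutation enrichment test over a gene-set collection
#'
#' For each set, the null is built from random gene-label sets of matched
#' size (shared across sets of equal size); the sign-stratified p-value is
#' `(1 + #{same-sign perm ES at least as extreme}) / (1 + #same-sign
#' perms)`, NES is ES divided by the mean |same-sign perm ES|, and BH
#' adjustment runs across sets.
#'
#' @param ranked output of [rankGenes()].
#' @param collection named list of gene-id vectors.
#' @param n_perm permutations (>= 100).
#' @param seed integer seed.
#' @param weight passed to [enrichmentScore()].
#' @return data.frame: `set`, `size`, `es`, `nes`, `p_value`, `fdr`,
#'   `leading_edge` (comma-separated).
#' @export
permutationTest <- function(ranked, collection, n_perm = 1000, seed = 1,
                            weight = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  n <- nrow(ranked)
  sizes <- vapply(collection, function(s) sum(ranked$gene %in% s), integer(1))
  if (any(sizes == 0)) stop("set(s) with empty ranking intersection: ",
                            paste(names(collection)[sizes == 0], collapse = ", "))
  if (any(lengths(collection) > n)) stop("set larger than the gene universe")
  absw <- abs(ranked$stat)^weight
  null_by_size <- new.env()
  withSubstream(seed, "gsea-perm", {
    for (k in sort(unique(sizes))) {
      assign(as.character(k),
             vapply(seq_len(n_perm), function(i)
               .esFromPositions(absw, sort(sample.int(n, k)), n),
               numeric(1)),
             envir = null_by_size)
    }
  })
  rows <- lapply(names(collection), function(nm) {
    obs <- enrichmentScore(ranked, collection[[nm]], weight = weight)
    null <- get(as.character(sizes[[nm]]), envir = null_by_size)
    pool <- if (obs$es >= 0) null[null >= 0] else null[null < 0]
    if (length(pool) == 0) {
      p <- 1; nes <- NA_real_
    } else if (obs$es >= 0) {
      p <- (1 + sum(pool >= obs$es)) / (1 + length(pool))
      nes <- obs$es / mean(pool)
    } else {
      p <- (1 + sum(pool <= obs$es)) / (1 + length(pool))
      nes <- obs$es / mean(abs(pool))
    }
    data.frame(set = nm, size = sizes[[nm]], es = obs$es, nes = nes,
               p_value = p,
               leading_edge = paste(obs$leading_edge, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bhAdjust(out$p_value)
  out[, c("set", "size", "es", "nes", "p_value", "fdr", "leading_edge")]
}
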