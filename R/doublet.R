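#' Replace per-cell doublet scores by their fine-cluster median
#'
#' Second-stage doublet consolidation: after over-clustering, each cell's
#' Scrublet-style score is replaced by the median score of its fine
#' cluster, so the tested unit becomes the cluster. Idempotent.
#'
#' @param scores Numeric per-cell scores in [0, 1].
#' @param fine_clusters Per-cell cluster labels (same length).
#' @return Numeric vector of consolidated per-cell scores.
#' @export
consolidate_scores <- function(scores, fine_clusters) {
  if (length(scores) == 0L) stop("empty input", call. = FALSE)
  if (length(scores) != length(fine_clusters)) {
    stop("`scores` and `fine_clusters` must have equal length", call. = FALSE)
  }
  med <- tapply(scores, fine_clusters, stats::median)
  as.numeric(med[as.character(fine_clusters)])
}

#' Fit the robust normal null for cluster medians
#'
#' The null is a normal centred on the median of the cluster medians, with
#' a MAD-derived standard deviation estimate (scale constant 1.4826). The
#' MAD is computed from values strictly above the median only, to
#' circumvent zero truncation of doublet scores piled at the low end.
#'
#' @param cluster_medians Numeric vector of per-cluster consolidated scores
#'   (>= 2 distinct values, at least one above the median).
#' @return List with \code{center} and \code{sigma} (class \code{doublet_null}).
#' @examples
#' fit_null(c(0.1, 0.1, 0.1, 0.1, 0.9))  # center 0.1, sigma 1.4826 * 0.8
#' @export
fit_null <- function(cluster_medians) {
  if (length(unique(cluster_medians)) < 2L) {
    stop("degenerate null: cluster medians must take >= 2 distinct values",
         call. = FALSE)
  }
  center <- stats::median(cluster_medians)
  above <- cluster_medians[cluster_medians > center]
  if (length(above) == 0L) {
    stop("degenerate null: no cluster medians above the overall median",
         call. = FALSE)
  }
  sigma <- 1.4826 * stats::median(above - center)
  if (sigma <= 0) stop("degenerate null: sigma is not positive", call. = FALSE)
  structure(list(center = center, sigma = sigma), class = "doublet_null")
}

#' Right-tailed normal p-values for cluster medians
#'
#' @param cluster_medians Numeric vector.
#' @param null A fit from \code{\link{fit_null}}.
#' @return Per-cluster upper-tail p-values \code{1 - pnorm((m - center)/sigma)}.
#' @export
cluster_pvalues <- function(cluster_medians, null) {
  stopifnot(inherits(null, "doublet_null"))
  stats::pnorm(cluster_medians, mean = null$center, sd = null$sigma,
               lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH with monotonicity enforcement; equivalent to
#' \code{p.adjust(method = "BH")} and verified against a brute-force
#' step-up oracle in the test suite.
#'
#' @param p Numeric p-values in [0, 1].
#' @return q-values in [0, 1], in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p))) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(p[o] * m / seq(m, 1)))[ro]
  q
}

#' Run the full cluster-level doublet procedure
#'
#' Consolidates per-cell scores to fine-cluster medians, fits the
#' median/MAD normal null on the cluster medians, computes right-tailed
#' p-values, BH-adjusts them, and flags clusters. A cluster is flagged as
#' doublet when \code{q < q_threshold} and its consolidated median is at
#' least \code{score_floor}; significant clusters whose median falls below
#' the floor are reported as borderline for manual curation instead of
#' being decided automatically.
#'
#' @param scores Per-cell raw doublet scores in [0, 1].
#' @param fine_clusters Per-cell fine-cluster labels.
#' @param q_threshold FDR threshold (default 0.05).
#' @param score_floor Minimum consolidated median for automatic flagging
#'   (default 0.1).
#' @return List with \code{cells} (per-cell table with consolidated score,
#'   p, q, flag) and \code{clusters} (per-cluster summary incl.
#'   \code{borderline}), plus the fitted \code{null}.
#' @export
flag_doublet_clusters <- function(scores, fine_clusters,
                                  q_threshold = 0.05, score_floor = 0.1) {
  if (q_threshold < 0 || q_threshold > 1 || score_floor < 0 || score_floor > 1) {
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  }
  if (any(scores < 0 | scores > 1, na.rm = TRUE)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  consolidated <- consolidate_scores(scores, fine_clusters)
  med <- tapply(scores, fine_clusters, stats::median)
  labels <- names(med)
  null <- fit_null(as.numeric(med))
  p <- cluster_pvalues(as.numeric(med), null)
  q <- bh_adjust(p)
  significant <- q < q_threshold
  flagged <- significant & as.numeric(med) >= score_floor
  clusters <- data.frame(fine_cluster = labels,
                         consolidated_score = as.numeric(med),
                         p_value = p, q_value = q,
                         flagged = flagged,
                         borderline = significant & !flagged,
                         stringsAsFactors = FALSE)
  idx <- match(as.character(fine_clusters), labels)
  cells <- data.frame(cell_id = if (!is.null(names(scores))) names(scores) else
                        seq_along(scores),
                      raw_score = as.numeric(scores),
                      fine_cluster = as.character(fine_clusters),
                      consolidated_score = consolidated,
                      p_value = p[idx], q_value = q[idx],
                      flagged = flagged[idx], stringsAsFactors = FALSE)
  list(cells = cells, clusters = clusters, null = null)
}
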