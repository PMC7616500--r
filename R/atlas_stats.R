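#' Quality-control thresholds for scRNA-seq count matrices
#'
#' Boundary semantics follow the usual wording strictly: cells expressing
#' fewer than \code{min_genes_per_cell} genes are excluded (200 kept),
#' genes expressed by less than \code{min_cells_per_gene} cells are removed
#' (5 kept), and cells with over \code{max_mito_fraction} of UMIs from
#' mitochondrial genes are removed (exactly 0.10 kept).
#'
#' @param min_genes_per_cell,min_cells_per_gene Positive integers.
#' @param max_mito_fraction In (0, 1).
#' @param mito_prefix Gene-name prefix identifying mitochondrial genes.
#' @return List of thresholds (class \code{qc_thresholds}).
#' @export
qc_thresholds <- function(min_genes_per_cell = 200L, min_cells_per_gene = 5L,
                          max_mito_fraction = 0.10, mito_prefix = "MT-") {
  if (min_genes_per_cell < 1 || min_cells_per_gene < 1) {
    stop("gene/cell thresholds must be positive", call. = FALSE)
  }
  if (max_mito_fraction <= 0 || max_mito_fraction >= 1) {
    stop("max_mito_fraction must lie in (0, 1)", call. = FALSE)
  }
  structure(list(min_genes_per_cell = as.integer(min_genes_per_cell),
                 min_cells_per_gene = as.integer(min_cells_per_gene),
                 max_mito_fraction = max_mito_fraction,
                 mito_prefix = mito_prefix), class = "qc_thresholds")
}

#' Filter a genes x cells count matrix
#'
#' Applies, in order: the per-cell expressed-gene filter, the per-gene
#' expressing-cell filter, then the mitochondrial-fraction filter. The
#' order is recorded in the report (it is a convention, not forced by the
#' data). Mitochondrial fractions are computed on each cell's unfiltered
#' profile. If no gene matches the mitochondrial prefix, that filter is
#' skipped with a warning recorded in the report.
#'
#' @param counts Nonnegative genes x cells matrix with gene rownames.
#' @param thresholds A \code{\link{qc_thresholds}}.
#' @return List with \code{counts} (filtered matrix), \code{kept_cells},
#'   \code{kept_genes} and a \code{report} describing each step.
#' @export
qc_filter <- function(counts, thresholds = qc_thresholds()) {
  if (length(counts) == 0L || nrow(counts) == 0L || ncol(counts) == 0L) {
    stop("empty count matrix", call. = FALSE)
  }
  if (is.null(rownames(counts))) {
    stop("`counts` must carry gene identifiers as rownames", call. = FALSE)
  }
  counts <- as_dgc(counts)
  if (any(counts@x < 0)) stop("`counts` must be nonnegative", call. = FALSE)
  report <- list(order = c("cell_gene_count", "gene_cell_count", "mito_fraction"),
                 warnings = character())

  # mito fractions on the unfiltered per-cell profile
  mito_genes <- startsWith(rownames(counts), thresholds$mito_prefix)
  total_umi <- Matrix::colSums(counts)
  mito_frac <- if (any(mito_genes)) {
    Matrix::colSums(counts[mito_genes, , drop = FALSE]) / pmax(total_umi, 1)
  } else NULL

  genes_per_cell <- Matrix::colSums(counts > 0)
  keep_cells <- genes_per_cell >= thresholds$min_genes_per_cell
  report$cells_removed_low_genes <- sum(!keep_cells)
  m <- counts[, keep_cells, drop = FALSE]

  cells_per_gene <- Matrix::rowSums(m > 0)
  keep_genes <- cells_per_gene >= thresholds$min_cells_per_gene
  report$genes_removed_low_cells <- sum(!keep_genes)
  m <- m[keep_genes, , drop = FALSE]

  if (is.null(mito_frac)) {
    report$warnings <- c(report$warnings,
                         paste0("no genes match mito prefix '",
                                thresholds$mito_prefix, "'; mito filter skipped"))
    report$cells_removed_mito <- 0L
  } else {
    keep_mito <- mito_frac[colnames(m)] <= thresholds$max_mito_fraction
    report$cells_removed_mito <- sum(!keep_mito)
    m <- m[, keep_mito, drop = FALSE]
  }

  list(counts = m, kept_cells = colnames(m), kept_genes = rownames(m),
       report = report)
}

#' Estimate embryonic age from crown-rump length
#'
#' Post-conception age in days is a linear function of crown-rump length:
#' \code{days = 0.9022 * crl_mm + 27.372}. The post-conception week (PCW)
#' string writes week and day separated by a decimal point, e.g.
#' \code{"PCW5.6"} is 5 weeks and 6 days; days are rounded to the nearest
#' integer before the divmod by 7.
#'
#' @param crl_mm Crown-rump length in millimetres (> 0).
#' @return List with \code{crl_mm}, \code{days}, \code{pcw_week},
#'   \code{pcw_day} and the rendered \code{pcw} string.
#' @examples
#' estimate_age(15.1)$pcw  # "PCW5.6"
#' @export
estimate_age <- function(crl_mm) {
  assert_scalar_number(crl_mm, "crl_mm")
  if (crl_mm <= 0) stop("crown-rump length must be positive", call. = FALSE)
  days <- 0.9022 * crl_mm + 27.372
  d <- round(days)
  list(crl_mm = crl_mm, days = days,
       pcw_week = d %/% 7L, pcw_day = d %% 7L,
       pcw = sprintf("PCW%d.%d", d %/% 7L, d %% 7L))
}

#' Odds ratio of non-zero cell fractions between two groups
#'
#' For sparsely captured genes, differential expression between groups is
#' summarised by the odds ratio of the fractions of cells with non-zero
#' expression: \code{OR = (p_a/(1-p_a)) / (p_b/(1-p_b))} with
#' \code{p = k/n}. When any cell of the 2x2 table (k or n-k in either
#' group) is zero the Haldane-Anscombe correction adds 0.5 to all four
#' counts; the result then carries attribute \code{corrected = TRUE}.
#'
#' @param k_a,n_a Non-zero and total cell counts in group A.
#' @param k_b,n_b Same for group B.
#' @return Positive odds ratio with a logical \code{corrected} attribute.
#' @export
fraction_odds_ratio <- function(k_a, n_a, k_b, n_b) {
  for (v in list(k_a = k_a, n_a = n_a, k_b = k_b, n_b = n_b)) {
    assert_scalar_number(v, "count")
  }
  if (n_a <= 0 || n_b <= 0) stop("group sizes must be positive", call. = FALSE)
  if (k_a < 0 || k_a > n_a || k_b < 0 || k_b > n_b) {
    stop("need 0 <= k <= n in both groups", call. = FALSE)
  }
  cells <- c(k_a, n_a - k_a, k_b, n_b - k_b)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] / cells[2]) / (cells[3] / cells[4])
  attr(or, "corrected") <- corrected
  or
}

#' Summarise non-zero fractions of genes between two cell groups
#'
#' Convenience builder of per-gene summaries consumed by
#' \code{\link{select_biased_genes}}.
#'
#' @param counts Genes x cells matrix with gene rownames.
#' @param groups Per-cell factor with exactly two levels; the first level
#'   is group A (the numerator).
#' @return data.frame with per-gene counts, fractions and odds ratio.
#' @export
group_expression_summary <- function(counts, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("`groups` must have exactly two levels", call. = FALSE)
  if (length(groups) != ncol(counts)) {
    stop("`groups` length must equal the number of cells", call. = FALSE)
  }
  a <- groups == levels(groups)[1]
  nz <- counts > 0
  k_a <- Matrix::rowSums(nz[, a, drop = FALSE])
  k_b <- Matrix::rowSums(nz[, !a, drop = FALSE])
  n_a <- sum(a); n_b <- sum(!a)
  ors <- mapply(function(ka, kb) {
    or <- fraction_odds_ratio(ka, n_a, kb, n_b)
    c(or = as.numeric(or), corrected = attr(or, "corrected"))
  }, k_a, k_b)
  data.frame(gene = rownames(counts),
             group_a = levels(groups)[1], group_b = levels(groups)[2],
             n_a = n_a, n_b = n_b, k_a = as.numeric(k_a), k_b = as.numeric(k_b),
             fraction_a = as.numeric(k_a) / n_a,
             fraction_b = as.numeric(k_b) / n_b,
             odds_ratio = ors["or", ],
             corrected = ors["corrected", ] == 1,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select axis-biased genes by odds-ratio cut-off
#'
#' Proximal/distal bias uses a 30-fold cut-off, forelimb/hindlimb a 3-fold
#' cut-off; both are applied symmetrically (OR >= cutoff selects genes
#' biased towards group A, OR <= 1/cutoff towards group B) and comparisons
#' are inclusive.
#'
#' @param summaries data.frame from \code{\link{group_expression_summary}}
#'   (needs \code{gene} and \code{odds_ratio}).
#' @param axis \code{"proximal_distal"} or \code{"fore_hind"}.
#' @param cutoff Override the axis default fold cut-off.
#' @return List with \code{up} (biased to group A), \code{down} (to group
#'   B) and the \code{cutoff} used.
#' @export
select_biased_genes <- function(summaries,
                                axis = c("proximal_distal", "fore_hind"),
                                cutoff = NULL) {
  axis <- match.arg(axis)
  if (is.null(cutoff)) {
    cutoff <- switch(axis, proximal_distal = 30, fore_hind = 3)
  }
  if (!all(c("gene", "odds_ratio") %in% names(summaries))) {
    stop("`summaries` needs columns gene and odds_ratio", call. = FALSE)
  }
  or <- summaries$odds_ratio
  list(up = summaries$gene[or >= cutoff],
       down = summaries$gene[or <= 1 / cutoff],
       cutoff = cutoff)
}

#' Non-negative matrix factorization of cell-type abundances
#'
#' Factorises a spots x cell-types abundance matrix into
#' \code{W (spots x k)} and \code{H (k x cell types)} with multiplicative
#' updates under Frobenius loss, from a seeded random initialisation, so
#' identical seeds give identical loadings. The \code{H} rows are the
#' microenvironment loadings over cell types.
#'
#' @param abundance Nonnegative spots x cell-types matrix with column names.
#' @param n_environments Number of factors (< min(dim)).
#' @param seed RNG seed.
#' @param n_iter Multiplicative-update iterations.
#' @return List (class \code{environment_loading}) with \code{loadings}
#'   (environments x cell types), \code{spot_weights},
#'   \code{fractions} (each cell-type column normalised to sum 1) and
#'   \code{reconstruction_error} (Frobenius norm of the residual).
#' @export
run_nmf <- function(abundance, n_environments, seed = 1L, n_iter = 500L) {
  abundance <- as.matrix(abundance)
  if (any(abundance < 0)) stop("`abundance` must be nonnegative", call. = FALSE)
  if (n_environments >= min(dim(abundance))) {
    stop("n_environments must be smaller than both matrix dimensions",
         call. = FALSE)
  }
  if (is.null(colnames(abundance))) {
    colnames(abundance) <- paste0("ct", seq_len(ncol(abundance)))
  }
  n <- nrow(abundance); m <- ncol(abundance); k <- n_environments
  scale0 <- sqrt(mean(abundance) / k)
  init <- with_seed(seed, list(W = matrix(stats::runif(n * k, 0.1, 1), n, k) * scale0,
                               H = matrix(stats::runif(k * m, 0.1, 1), k, m) * scale0))
  W <- init$W; H <- init$H
  eps <- 1e-10
  for (i in seq_len(n_iter)) {
    H <- H * (t(W) %*% abundance) / (t(W) %*% W %*% H + eps)
    W <- W * (abundance %*% t(H)) / (W %*% H %*% t(H) + eps)
  }
  dimnames(H) <- list(paste0("env", seq_len(k)), colnames(abundance))
  err <- norm(abundance - W %*% H, "F")
  fr <- sweep(H, 2, pmax(colSums(H), eps), "/")
  structure(list(loadings = H, spot_weights = W, fractions = fr,
                 reconstruction_error = err),
            class = "environment_loading")
}

#' Microenvironment membership of cell types
#'
#' Loadings are normalised per cell type across environments (so each
#' cell-type column of fractions sums to 1); a cell type is a member of a
#' microenvironment when its fraction there is strictly greater than the
#' threshold. At the default 0.2 a cell type can belong to at most four
#' environments.
#'
#' @param loadings An \code{environment_loading} from \code{\link{run_nmf}}
#'   or a nonnegative environments x cell-types matrix.
#' @param threshold Membership threshold (default 0.2), strict.
#' @return Logical environments x cell-types membership matrix.
#' @export
microenvironment_membership <- function(loadings, threshold = 0.2) {
  H <- if (inherits(loadings, "environment_loading")) loadings$loadings else
    as.matrix(loadings)
  if (any(H < 0)) stop("loadings must be nonnegative", call. = FALSE)
  tot <- colSums(H)
  if (any(tot == 0)) {
    stop("all-zero cell-type column: fraction undefined for ",
         paste(colnames(H)[tot == 0], collapse = ", "), call. = FALSE)
  }
  fr <- sweep(H, 2, tot, "/")
  fr > threshold
}
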