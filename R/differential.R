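# Differential analysis: distribution-level two-sample tests on PSI (plate),
# outlier removal, differential gene expression, droplet feature filters and
# the pseudo-bulk permutation test for droplet splice-junction usage.

#' Two-sample tests for PSI distributions
#'
#' Distribution-level tests compare the full empirical distributions of PSI
#' between two groups of cells: \code{ks} (classical two-sample
#' Kolmogorov-Smirnov), \code{ad} (tie-adjusted two-sample Anderson-Darling
#' statistic), and \code{dts} (ECDF distance integrated over pooled
#' order-statistic gaps, weighted by the reciprocal binomial standard
#' deviation of the pooled ECDF). AD and DTS p-values come from seeded
#' label permutations with the +1 smoothed estimator, so they are bounded
#' below by 1/(B+1). \code{wilcoxon}, \code{ttest} and \code{perm_mean}
#' (permutation test of the absolute mean difference) compare location
#' only.
#'
#' @param x,y Non-missing PSI values of the two groups (each length >= 2
#'   for a defined result).
#' @param method One of \code{"ks"}, \code{"ad"}, \code{"dts"},
#'   \code{"wilcoxon"}, \code{"ttest"}, \code{"perm_mean"}.
#' @param n_perm Number of permutations for the permutation-based methods
#'   (default 1000).
#' @return List with \code{statistic} and \code{p_value}; both NA when a
#'   group has fewer than 2 values.
#' @export
two_sample_test <- function(x, y,
                            method = c("ks", "ad", "dts", "wilcoxon",
                                       "ttest", "perm_mean"),
                            n_perm = 1000) {
  method <- match.arg(method)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    return(list(statistic = NA_real_, p_value = NA_real_))
  }
  if (method == "ks") {
    r <- suppressWarnings(ks.test(x, y))
    return(list(statistic = unname(r$statistic), p_value = r$p.value))
  }
  if (method == "wilcoxon") {
    r <- suppressWarnings(wilcox.test(x, y))
    return(list(statistic = unname(r$statistic), p_value = r$p.value))
  }
  if (method == "ttest") {
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(list(statistic = NA_real_,
                  p_value = if (mean(x) == mean(y)) 1 else NA_real_))
    }
    r <- t.test(x, y)
    return(list(statistic = unname(r$statistic), p_value = r$p.value))
  }
  cpp_method <- c(ad = "ad", dts = "dts", perm_mean = "mean")[method]
  r <- .ecdf_perm_test_cpp(x, y, cpp_method, as.integer(n_perm))
  list(statistic = r$statistic, p_value = r$p_value)
}

#' Remove differential events driven by outlier cells
#'
#' A differentially spliced event is retained only when at least one of the
#' two populations has at least \code{min_cells} cells with PSI strictly
#' inside (0, 1); events whose significance rests on a handful of interior
#' cells (the rest sitting exactly at 0 or 1) are dropped as
#' outlier-driven.
#'
#' @param result Data.frame with an \code{event_id} column (typically the
#'   significant subset of a differential result).
#' @param psi Events x cells PSI matrix.
#' @param groups Character/factor of group labels aligned with columns of
#'   \code{psi}.
#' @param min_cells Interior-cell floor (default 10).
#' @return \code{result} with a logical \code{outlier_removed} column;
#'   retained events have \code{outlier_removed == FALSE}.
#' @export
remove_outlier_events <- function(result, psi, groups, min_cells = 10) {
  gl <- unique(as.character(groups))
  stopifnot(length(gl) == 2)
  removed <- vapply(result$event_id, function(id) {
    x <- psi[id, groups == gl[1]]
    y <- psi[id, groups == gl[2]]
    n1 <- sum(x > 0 & x < 1, na.rm = TRUE)
    n2 <- sum(y > 0 & y < 1, na.rm = TRUE)
    n1 < min_cells && n2 < min_cells
  }, TRUE)
  result$outlier_removed <- unname(removed)
  result
}

#' Differential splicing between two cell populations (plate data)
#'
#' The default method runs the Anderson-Darling and DTS distribution tests
#' on every eligible event, adjusts each test's p-values separately by
#' Benjamini-Hochberg, calls an event significant when either test passes
#' the FDR cut, and then applies the outlier-removal filter (which only
#' ever removes events). Any single method can be selected instead.
#'
#' @param psi Events x cells PSI matrix.
#' @param groups Two-level group labels aligned with columns; the reported
#'   \code{delta_psi} is group2 minus group1 on the percent scale, with
#'   group order taken from \code{group_order} (default: order of first
#'   appearance).
#' @param method \code{"ad+dts"} (default) or a single method accepted by
#'   [two_sample_test()].
#' @param fdr_cut FDR significance threshold (default 0.10).
#' @param min_cells Eligibility floor on informative cells (default 25).
#' @param outlier_min_cells Interior-cell floor for outlier removal
#'   (default 10).
#' @param n_perm Permutations for AD/DTS/perm_mean (default 1000).
#' @param group_order Optional length-2 character giving (group1, group2).
#' @return Data.frame with per-event statistics, p-values, FDRs, group
#'   means, \code{delta_psi} (percent), cell counts, \code{significant}
#'   and \code{outlier_removed} flags; attribute \code{groups} records the
#'   orientation.
#' @export
differential_splicing_plate <- function(psi, groups, method = "ad+dts",
                                        fdr_cut = 0.10, min_cells = 25,
                                        outlier_min_cells = 10,
                                        n_perm = 1000, group_order = NULL) {
  groups <- as.character(groups)
  gl <- if (is.null(group_order)) unique(groups) else group_order
  stopifnot(length(gl) == 2, all(groups %in% gl))
  eligible <- psi_summary_filters(psi, min_cells = min_cells)
  methods <- if (method == "ad+dts") c("ad", "dts") else method
  n <- length(eligible)
  res <- data.frame(event_id = eligible, stringsAsFactors = FALSE)
  res$mean_psi_g1 <- NA_real_; res$mean_psi_g2 <- NA_real_
  res$delta_psi <- NA_real_
  res$n_g1 <- NA_integer_; res$n_g2 <- NA_integer_
  res$skipped <- NA_character_
  stat_cols <- paste0("statistic_", methods)
  p_cols <- paste0("p_", methods)
  for (cn in c(stat_cols, p_cols)) res[[cn]] <- NA_real_
  for (i in seq_len(n)) {
    id <- eligible[i]
    x <- psi[id, groups == gl[1]]; x <- x[!is.na(x)]
    y <- psi[id, groups == gl[2]]; y <- y[!is.na(y)]
    res$n_g1[i] <- length(x); res$n_g2[i] <- length(y)
    if (length(x) < 2 || length(y) < 2) {
      res$skipped[i] <- "insufficient cells in a group"
      next
    }
    res$mean_psi_g1[i] <- mean(x)
    res$mean_psi_g2[i] <- mean(y)
    res$delta_psi[i] <- 100 * (mean(y) - mean(x))
    for (m in methods) {
      r <- two_sample_test(x, y, method = if (m == "perm_mean") m else m,
                           n_perm = n_perm)
      res[[paste0("statistic_", m)]][i] <- r$statistic
      res[[paste0("p_", m)]][i] <- r$p_value
    }
  }
  sig <- rep(FALSE, n)
  for (m in methods) {
    fdr <- bh_adjust(res[[paste0("p_", m)]])
    res[[paste0("fdr_", m)]] <- fdr
    sig <- sig | (!is.na(fdr) & fdr < fdr_cut)
  }
  res$significant <- sig
  res <- remove_outlier_events(res, psi, groups, min_cells = outlier_min_cells)
  # outlier removal only applies to (and only removes) significant calls
  res$outlier_removed <- res$outlier_removed & res$significant
  res$significant <- res$significant & !res$outlier_removed
  attr(res, "groups") <- gl
  res
}

#' Differential gene expression between two cell populations
#'
#' Wilcoxon rank-sum test on log2(x + 1)-transformed normalized expression
#' per gene, BH-adjusted; the log2 fold change is the difference of group
#' means of the transformed values (group2 minus group1). Direction is
#' \code{up}/\code{down} when the FDR and |log2 FC| cuts are both met
#' (default cuts 0.10 and 0.5 as used for plate data; droplet analyses use
#' a fold-change cut of 1).
#'
#' @param expression Genes x cells normalized expression matrix (linear
#'   scale).
#' @param groups Two-level labels aligned with columns.
#' @param log2fc_threshold Fold-change cut on the log2 scale (default 0.5).
#' @param fdr_cut FDR threshold (default 0.10).
#' @param min_cells Feature filter: genes expressed (nonzero) in at least
#'   this many cells (default 3).
#' @param group_order Optional length-2 character giving (group1, group2).
#' @return Data.frame: \code{gene_id}, \code{log2_fc}, \code{p_value},
#'   \code{fdr}, \code{direction}; attribute \code{groups}.
#' @export
differential_genes <- function(expression, groups, log2fc_threshold = 0.5,
                               fdr_cut = 0.10, min_cells = 3,
                               group_order = NULL) {
  groups <- as.character(groups)
  gl <- if (is.null(group_order)) unique(groups) else group_order
  stopifnot(length(gl) == 2, all(groups %in% gl))
  expressed <- rowSums(expression > 0) >= min_cells
  mat <- log2p1(as.matrix(expression[expressed, , drop = FALSE]))
  i1 <- groups == gl[1]; i2 <- groups == gl[2]
  genes <- rownames(mat)
  p <- numeric(length(genes)); fc <- numeric(length(genes))
  for (i in seq_along(genes)) {
    x <- mat[i, i1]; y <- mat[i, i2]
    fc[i] <- mean(y) - mean(x)
    p[i] <- if (stats::sd(c(x, y)) == 0) 1
            else suppressWarnings(wilcox.test(x, y)$p.value)
  }
  fdr <- bh_adjust(p)
  direction <- ifelse(fdr < fdr_cut & fc > log2fc_threshold, "up",
               ifelse(fdr < fdr_cut & fc < -log2fc_threshold, "down", "ns"))
  res <- data.frame(gene_id = genes, log2_fc = fc, p_value = p, fdr = fdr,
                    direction = direction, stringsAsFactors = FALSE)
  attr(res, "groups") <- gl
  res
}

#' Expression-rate feature filters for droplet differential splicing
#'
#' Genes must be expressed (nonzero count) in at least \code{min_pct} of
#' the cells of both populations; junctions must be expressed in at least
#' \code{min_pct} of either population, and their gene must itself be
#' kept.
#'
#' @param gene_counts Genes x cells raw count matrix.
#' @param sj_counts Junctions x cells raw count matrix.
#' @param groups Two-level labels aligned with columns.
#' @param gene_of_junction Named character vector mapping junction keys to
#'   gene ids.
#' @param min_pct Expression-rate threshold (default 0.10).
#' @return List with \code{genes} and \code{junctions} (kept identifiers).
#' @export
droplet_feature_filters <- function(gene_counts, sj_counts, groups,
                                    gene_of_junction, min_pct = 0.10) {
  groups <- as.character(groups)
  gl <- unique(groups)
  stopifnot(length(gl) == 2)
  rate <- function(m, idx) {
    Matrix::rowSums(m[, idx, drop = FALSE] > 0) / sum(idx)
  }
  g1 <- groups == gl[1]; g2 <- groups == gl[2]
  gene_keep <- rate(gene_counts, g1) >= min_pct &
               rate(gene_counts, g2) >= min_pct
  genes <- rownames(gene_counts)[gene_keep]
  sj_rate_keep <- rate(sj_counts, g1) >= min_pct |
                  rate(sj_counts, g2) >= min_pct
  sj_gene <- gene_of_junction[rownames(sj_counts)]
  junctions <- rownames(sj_counts)[sj_rate_keep & sj_gene %in% genes]
  list(genes = genes, junctions = junctions)
}

#' Differential splice-junction usage between two cell types (droplet)
#'
#' For each junction passing [droplet_feature_filters()], the observed
#' usage difference \eqn{\Delta PSI_{obs} = 100 (U_{g2} - U_{g1})} is
#' compared against a null distribution built by shuffling the cell-type
#' labels \code{n_perm} times and recomputing pseudo-bulk usage from the
#' raw counts each time; the p-value is the +1 smoothed fraction of
#' permutations with \eqn{|\Delta PSI_{perm}| \ge |\Delta PSI_{obs}|}. A
#' junction is called significant when the mean log2(x + 1) normalized
#' expression of its gene across all cells of both populations exceeds
#' \code{min_expr}, \eqn{|\Delta PSI_{obs}|} exceeds
#' \code{delta_psi_cut}, and p is below \code{p_cut}. Permutation
#' p-values are not FDR-adjusted by default; set \code{adjust_p} to add a
#' BH column.
#'
#' @param sj_counts,gene_counts Raw count matrices (junctions/genes x
#'   cells).
#' @param expression Genes x cells normalized expression (linear scale).
#' @param groups Two-level labels aligned with columns.
#' @param gene_of_junction Named character mapping junction key to gene.
#' @param n_perm Label shuffles (default 100).
#' @param delta_psi_cut Percent-scale usage-difference cut (default 5).
#' @param min_expr Mean log2 expression cut (default 1.0).
#' @param p_cut Permutation p-value cut (default 0.05).
#' @param min_pct Expression-rate filter (default 0.10).
#' @param adjust_p Add a BH-adjusted column (default FALSE).
#' @param group_order Optional length-2 character giving (group1, group2).
#' @return Data.frame per kept junction: usages, \code{delta_psi}
#'   (percent), \code{p_value}, \code{mean_log2_expr}, \code{significant};
#'   attribute \code{groups}.
#' @export
differential_splicing_droplet <- function(sj_counts, gene_counts, expression,
                                          groups, gene_of_junction,
                                          n_perm = 100, delta_psi_cut = 5,
                                          min_expr = 1.0, p_cut = 0.05,
                                          min_pct = 0.10, adjust_p = FALSE,
                                          group_order = NULL) {
  groups <- as.character(groups)
  gl <- if (is.null(group_order)) unique(groups) else group_order
  stopifnot(length(gl) == 2, all(groups %in% gl))
  keep <- droplet_feature_filters(gene_counts, sj_counts, groups,
                                  gene_of_junction, min_pct = min_pct)
  sj <- as.matrix(sj_counts[keep$junctions, , drop = FALSE])
  genes <- gene_of_junction[keep$junctions]
  gene_mat <- as.matrix(gene_counts[genes, , drop = FALSE])
  n_cells <- ncol(sj)
  g1 <- groups == gl[1]

  usage_delta <- function(sel1) {
    # sel1: logical vector marking group-1 cells; usage recomputed from raw
    # counts for both pseudo-bulks
    num1 <- sj[, sel1, drop = FALSE] %*% rep(1, sum(sel1))
    num2 <- sj[, !sel1, drop = FALSE] %*% rep(1, sum(!sel1))
    den1 <- gene_mat[, sel1, drop = FALSE] %*% rep(1, sum(sel1))
    den2 <- gene_mat[, !sel1, drop = FALSE] %*% rep(1, sum(!sel1))
    u1 <- ifelse(den1 > 0, num1 / den1, NA_real_)
    u2 <- ifelse(den2 > 0, num2 / den2, NA_real_)
    list(u1 = as.numeric(u1), u2 = as.numeric(u2),
         delta = 100 * (as.numeric(u2) - as.numeric(u1)))
  }
  obs <- usage_delta(g1)
  exceed <- rep(0L, length(keep$junctions))
  for (b in seq_len(n_perm)) {
    perm <- sample(g1)
    d <- usage_delta(perm)$delta
    exceed <- exceed + as.integer(!is.na(d) & !is.na(obs$delta) &
                                  abs(d) >= abs(obs$delta))
  }
  p <- (1 + exceed) / (n_perm + 1)
  p[is.na(obs$delta)] <- NA_real_
  expr <- log2p1(as.matrix(expression[genes, , drop = FALSE]))
  mean_expr <- rowMeans(expr)
  res <- data.frame(
    key = keep$junctions, gene_id = unname(genes),
    usage_g1 = obs$u1, usage_g2 = obs$u2, delta_psi = obs$delta,
    p_value = p, mean_log2_expr = unname(mean_expr),
    stringsAsFactors = FALSE)
  if (adjust_p) res$fdr <- bh_adjust(res$p_value)
  res$significant <- !is.na(res$delta_psi) & !is.na(res$p_value) &
    res$mean_log2_expr > min_expr & abs(res$delta_psi) > delta_psi_cut &
    res$p_value < p_cut
  attr(res, "groups") <- gl
  rownames(res) <- NULL
  res
}
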