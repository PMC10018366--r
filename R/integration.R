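# Integration of differential splicing with differential expression, and
# PSI-based linear dimension reduction with random recoding of missing
# values.

#' Classify gene-splicing relationships
#'
#' Joins differential splicing and differential gene-expression results
#' computed on the same, identically oriented group pair. Per
#' differentially spliced event: when the gene is not differentially
#' expressed the event is isoform-switching (the isoform balance shifts
#' without a gene-level change); when the gene is differentially expressed
#' and the signs of the gene log2 fold change and the event's delta PSI
#' agree the pair is coordinated, otherwise opposing. An event with delta
#' PSI exactly zero under a distribution-only significance call is classed
#' isoform-switching. At the gene level, genes whose events span more than
#' one class summarize to complex.
#'
#' @param diff_splice Result of [differential_splicing_plate()] with an
#'   added \code{gene_id} column (or any data.frame with \code{event_id},
#'   \code{gene_id}, \code{delta_psi}, \code{significant}).
#' @param diff_gene Result of [differential_genes()].
#' @return Data.frame: \code{gene_id}, \code{event_id}, \code{relation},
#'   \code{gene_relation_summary}.
#' @export
classify_relation <- function(diff_splice, diff_gene) {
  g1 <- attr(diff_splice, "groups"); g2 <- attr(diff_gene, "groups")
  if (!is.null(g1) && !is.null(g2) && !identical(g1, g2)) {
    stop("group orientation mismatch between splicing and expression results")
  }
  stopifnot("gene_id" %in% names(diff_splice))
  ds <- diff_splice[diff_splice$significant, , drop = FALSE]
  idx <- match(ds$gene_id, diff_gene$gene_id)
  if (anyNA(idx)) {
    stop("differentially spliced gene absent from expression results: ",
         ds$gene_id[is.na(idx)][1])
  }
  gene_de <- diff_gene$direction[idx] != "ns"
  fc <- diff_gene$log2_fc[idx]
  relation <- ifelse(!gene_de, "isoform_switching",
              ifelse(sign(fc) == sign(ds$delta_psi) & ds$delta_psi != 0,
                     "coordinated",
              ifelse(ds$delta_psi == 0, "isoform_switching", "opposing")))
  out <- data.frame(gene_id = ds$gene_id, event_id = ds$event_id,
                    relation = relation, stringsAsFactors = FALSE)
  summary_of <- vapply(split(out$relation, out$gene_id), function(r) {
    if (length(unique(r)) > 1) "complex" else r[1]
  }, "")
  out$gene_relation_summary <- summary_of[out$gene_id]
  rownames(out) <- NULL
  out
}

#' PCA of PSI (or expression) with random recoding of missing values
#'
#' Missing PSI entries (cells below the informative-read floor) are
#' replaced by i.i.d. Uniform(0, 100)/100 draws under the given seed
#' before centered (unscaled) principal component analysis of the cells.
#' With no missing entries the recoding is a no-op and the result is
#' seed-independent.
#'
#' @param mat Features x cells matrix (PSI on [0,1] or expression); NA
#'   marks missing.
#' @param seed Seed for the recoding draws (default 1).
#' @param n_components Number of components returned (default 2).
#' @return List with \code{coordinates} (cells x components) and
#'   \code{explained_variance} (fractions for the returned components).
#' @export
pca_with_na_recoding <- function(mat, seed = 1, n_components = 2) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("fewer than 2 features after filtering")
  miss <- is.na(mat)
  if (any(miss)) {
    set.seed(seed)
    mat[miss] <- runif(sum(miss), 0, 100) / 100
  }
  fit <- prcomp(t(mat), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(fit$x))
  vars <- fit$sdev^2
  list(coordinates = fit$x[, seq_len(k), drop = FALSE],
       explained_variance = (vars / sum(vars))[seq_len(k)])
}
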