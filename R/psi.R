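# PSI quantification: per-cell junction-ratio PSI for plate events,
# coverage-based PSI for retained introns, pseudo-bulk splice-junction usage
# for droplet data, and the eligibility filters applied downstream.

#' Compute per-cell PSI for junction-based events (plate data)
#'
#' For each validated event (SE, MXE, A5SS, A3SS, AFE, ALE) and cell, PSI is
#' the fraction of junction reads supporting the alternative exon(s) over
#' reads supporting or skipping them:
#' \deqn{\psi = \frac{\mathrm{included}}{\mathrm{included} + \mathrm{excluded}}}
#' Cells whose informative total (included + excluded) falls below
#' \code{min_reads} are recorded as missing (NA). For MXE the junctions of
#' the first alternative exon form the numerator and the second exon's
#' junctions the denominator's other half.
#'
#' @param events Validated event table (non-RI rows are used).
#' @param junction_counts Junctions x cells count matrix.
#' @param min_reads Per-cell informative-read floor (default 10).
#' @return List with \code{psi} (events x cells, values in [0,1] or NA) and
#'   \code{support} (events x cells informative-read totals).
#' @export
compute_psi_plate <- function(events, junction_counts, min_reads = 10) {
  ev <- events[events$type != "RI", , drop = FALSE]
  cells <- colnames(junction_counts)
  psi <- matrix(NA_real_, nrow(ev), length(cells),
                dimnames = list(ev$event_id, cells))
  support <- matrix(0, nrow(ev), length(cells),
                    dimnames = list(ev$event_id, cells))
  if (nrow(ev) == 0) return(list(psi = psi, support = support))
  inc_sets <- split_sj_set(ev$included)
  exc_sets <- split_sj_set(ev$excluded)
  jc <- as.matrix(junction_counts)
  for (i in seq_len(nrow(ev))) {
    if (length(inc_sets[[i]]) == 0) {
      stop("event ", ev$event_id[i], " has an empty included junction set")
    }
    inc <- colSums(jc[inc_sets[[i]], , drop = FALSE])
    exc <- colSums(jc[exc_sets[[i]], , drop = FALSE])
    tot <- inc + exc
    support[i, ] <- tot
    ok <- tot >= min_reads
    psi[i, ok] <- inc[ok] / tot[ok]
  }
  list(psi = psi, support = support)
}

#' Compute per-cell PSI for retained introns
#'
#' The retention signal is the intron's total per-base coverage normalized
#' by its length, \eqn{c = \mathrm{coverage} / \mathrm{length}}; PSI is
#' \eqn{c / (c + \mathrm{skip})} where skip is the count of junction reads
#' skipping the intron. A cell is missing when the length-normalized
#' coverage or the skip count falls below their floors (both 10 by
#' default).
#'
#' @param introns Independent-intron table from
#'   [derive_independent_introns()].
#' @param intron_coverage Introns x cells total-coverage matrix; row names
#'   must carry \code{intron_id}s.
#' @param junction_counts Junctions x cells count matrix supplying skip
#'   counts.
#' @param min_coverage Floor on length-normalized coverage (default 10).
#' @param min_skip Floor on skip-junction reads (default 10).
#' @return List with \code{psi} and \code{support} matrices as in
#'   [compute_psi_plate()]; support holds \eqn{c + \mathrm{skip}}.
#' @export
compute_psi_ri <- function(introns, intron_coverage, junction_counts,
                           min_coverage = 10, min_skip = 10) {
  cells <- colnames(junction_counts)
  psi <- matrix(NA_real_, nrow(introns), length(cells),
                dimnames = list(introns$intron_id, cells))
  support <- matrix(0, nrow(introns), length(cells),
                    dimnames = list(introns$intron_id, cells))
  if (nrow(introns) == 0) return(list(psi = psi, support = support))
  if (any(intron_coverage < 0)) stop("negative intron coverage")
  jc <- as.matrix(junction_counts)
  cov <- as.matrix(intron_coverage)
  for (i in seq_len(nrow(introns))) {
    id <- introns$intron_id[i]
    if (!(id %in% rownames(cov))) next
    skip_key <- introns$skip_junction[i]
    if (!(skip_key %in% rownames(jc))) next
    c_norm <- cov[id, cells] / introns$length_bp[i]
    skip <- jc[skip_key, cells]
    support[i, ] <- c_norm + skip
    ok <- c_norm >= min_coverage & skip >= min_skip
    psi[i, ok] <- c_norm[ok] / (c_norm[ok] + skip[ok])
  }
  list(psi = psi, support = support)
}

#' Compute cell-type splice-junction usage (droplet data)
#'
#' Pseudo-bulk usage of a junction in a cell type is the sum of its counts
#' across the type's cells divided by the summed counts of the junction's
#' gene across the same cells:
#' \deqn{U = \frac{\sum_{cell} \mathrm{counts}_{sj}}{\sum_{cell}
#'   \mathrm{counts}_{gene[sj]}}}
#' A zero pseudo-bulk gene count yields a missing usage.
#'
#' @param sj_counts Junctions x cells raw count matrix (pre-filtered by
#'   [annotate_sj_droplet()]).
#' @param gene_counts Genes x cells raw count matrix.
#' @param cell_types Character vector of cell-type labels aligned with
#'   columns.
#' @param gene_of_junction Named character vector mapping junction key to
#'   gene id.
#' @return Long data.frame: \code{key}, \code{cell_type},
#'   \code{numerator}, \code{denominator}, \code{usage}.
#' @export
compute_sj_usage <- function(sj_counts, gene_counts, cell_types,
                             gene_of_junction) {
  stopifnot(length(cell_types) == ncol(sj_counts),
            ncol(sj_counts) == ncol(gene_counts))
  keys <- rownames(sj_counts)
  genes <- gene_of_junction[keys]
  if (anyNA(genes)) {
    stop("junction without assigned gene: ", keys[is.na(genes)][1])
  }
  if (!all(genes %in% rownames(gene_counts))) {
    stop("gene of junction absent from gene_counts")
  }
  types <- sort(unique(cell_types))
  out <- list()
  for (ty in types) {
    idx <- cell_types == ty
    num <- Matrix::rowSums(sj_counts[, idx, drop = FALSE])
    gene_tot <- Matrix::rowSums(gene_counts[, idx, drop = FALSE])
    den <- gene_tot[genes]
    usage <- ifelse(den > 0, num / den, NA_real_)
    out[[ty]] <- data.frame(key = keys, cell_type = ty,
                            numerator = as.numeric(num),
                            denominator = as.numeric(den),
                            usage = as.numeric(usage),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Event eligibility by informative-cell count
#'
#' Events must carry a non-missing PSI (which by construction implies at
#' least \code{min_reads} informative reads) in at least \code{min_cells}
#' cells to enter modality assignment and differential splicing analysis.
#'
#' @param psi Events x cells PSI matrix (NA = missing).
#' @param min_cells Minimum number of informative cells (default 25).
#' @return Character vector of eligible event ids.
#' @export
psi_summary_filters <- function(psi, min_cells = 25) {
  n_inf <- rowSums(!is.na(psi))
  rownames(psi)[n_inf >= min_cells]
}
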