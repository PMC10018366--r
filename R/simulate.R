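# Synthetic-data generation: toy genome + GTF, plate junction/coverage/
# expression matrices with planted modalities and differential events,
# droplet count matrices with planted junction usage, and deterministic
# NMD fixtures. Every generated dataset ships a truth table carrying all
# planted parameters.

# beta parameters producing each modality archetype (see methods vignette)
.archetype_params <- list(
  included_primary   = c(alpha = 50,   beta = 1),
  included_dispersed = c(alpha = 4,    beta = 0.9),
  excluded_primary   = c(alpha = 1,    beta = 50),
  excluded_dispersed = c(alpha = 0.9,  beta = 4),
  bimodal            = c(alpha = 0.35, beta = 0.35),
  middle             = c(alpha = 50,   beta = 50),
  multimodal         = c(alpha = 1.7,  beta = 1.3)
)

#' Event plan with planted modality archetypes
#'
#' One row per event; both groups share the archetype's beta parameters so
#' the plan is non-differential. The archetypes cover the seven modality
#' classes (included/excluded split into primary and dispersed).
#'
#' @param n_per_archetype Events per archetype (default 20).
#' @param archetypes Which archetypes to plant (default all seven).
#' @param type Event type for every row (default \code{"SE"}).
#' @return Plan data.frame for [simulate_plate()], with a
#'   \code{modality_truth} column.
#' @export
modality_plan <- function(n_per_archetype = 20,
                          archetypes = names(.archetype_params),
                          type = "SE") {
  rows <- lapply(archetypes, function(a) {
    p <- .archetype_params[[a]]
    data.frame(type = type,
               alpha_g1 = p[["alpha"]], beta_g1 = p[["beta"]],
               alpha_g2 = p[["alpha"]], beta_g2 = p[["beta"]],
               artifact = FALSE, relation = "null", expr_log2fc = 0,
               modality_truth = sub("_(primary|dispersed)$", "", a),
               sub_modality_truth = ifelse(grepl("primary", a), "primary",
                                    ifelse(grepl("dispersed", a),
                                           "dispersed", "none")),
               stringsAsFactors = FALSE)[rep(1, n_per_archetype), ]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Event plan with planted differential events
#'
#' Null events draw PSI from the same beta distribution in both groups;
#' differential events shift the mean by \code{delta_psi} percentage
#' points (default 40: Beta(6, 14) to Beta(14, 6), mean 0.30 to 0.70).
#'
#' @param n_null Number of null events (default 260).
#' @param n_diff Number of differential events (default 40).
#' @param null_shape Beta shapes of null events (default c(2, 2)).
#' @param diff_g1,diff_g2 Beta shapes of the two groups for differential
#'   events.
#' @param relation Gene-splicing relation planted on differential events:
#'   \code{"coordinated"}, \code{"opposing"} or \code{"isoform_switching"}
#'   (recycled; default coordinated).
#' @param type Event type (default SE).
#' @return Plan data.frame for [simulate_plate()], with a
#'   \code{differential_truth} column.
#' @export
differential_plan <- function(n_null = 260, n_diff = 40,
                              null_shape = c(2, 2),
                              diff_g1 = c(6, 14), diff_g2 = c(14, 6),
                              relation = "coordinated", type = "SE") {
  null_rows <- data.frame(type = type,
                          alpha_g1 = null_shape[1], beta_g1 = null_shape[2],
                          alpha_g2 = null_shape[1], beta_g2 = null_shape[2],
                          artifact = FALSE, relation = "null",
                          expr_log2fc = 0, differential_truth = FALSE,
                          stringsAsFactors = FALSE)
  null_rows <- null_rows[rep(1, n_null), ]
  diff_rows <- NULL
  if (n_diff > 0) {
    rel <- rep(relation, length.out = n_diff)
    diff_rows <- data.frame(type = type,
                            alpha_g1 = diff_g1[1], beta_g1 = diff_g1[2],
                            alpha_g2 = diff_g2[1], beta_g2 = diff_g2[2],
                            artifact = FALSE, relation = rel,
                            expr_log2fc = 0, differential_truth = TRUE,
                            stringsAsFactors = FALSE)
    mu1 <- diff_g1[1] / sum(diff_g1); mu2 <- diff_g2[1] / sum(diff_g2)
    dir <- sign(mu2 - mu1)
    diff_rows$expr_log2fc <- ifelse(diff_rows$relation == "coordinated",
                                    dir * 1,
                             ifelse(diff_rows$relation == "opposing",
                                    -dir * 1, 0))
  }
  out <- rbind(null_rows, diff_rows)
  rownames(out) <- NULL
  out
}

# genomic layout of one gene hosting one event, within a tile starting at
# `offset`; returns exon table (per transcript), event role coordinates and
# the RI intron when applicable
.gene_layout <- function(type, offset, gene_id) {
  ex <- function(tid, s, e) data.frame(transcript_id = tid, start = offset + s,
                                       end = offset + e,
                                       stringsAsFactors = FALSE)
  role <- function(...) {
    v <- c(...)
    out <- rep(NA_integer_, 8)
    out[seq_along(v)] <- offset + v
    names(out) <- c("e1_start", "e1_end", "e2_start", "e2_end",
                    "e3_start", "e3_end", "e4_start", "e4_end")
    out
  }
  t1 <- paste0(gene_id, ".t1"); t2 <- paste0(gene_id, ".t2")
  switch(type,
    SE = list(exons = rbind(ex(t1, 101, 200), ex(t1, 301, 400),
                            ex(t1, 501, 600),
                            ex(t2, 101, 200), ex(t2, 501, 600)),
              role = role(101, 200, 301, 400, 501, 600)),
    MXE = list(exons = rbind(ex(t1, 101, 200), ex(t1, 301, 400),
                             ex(t1, 701, 800),
                             ex(t2, 101, 200), ex(t2, 501, 600),
                             ex(t2, 701, 800)),
               role = role(101, 200, 301, 400, 501, 600, 701, 800)),
    RI = list(exons = rbind(ex(t1, 101, 200), ex(t1, 301, 400)),
              role = role(101, 200, 301, 400)),
    A5SS = list(exons = rbind(ex(t1, 101, 250), ex(t1, 401, 500),
                              ex(t2, 101, 200), ex(t2, 401, 500)),
                role = role(101, 250, 101, 200, 401, 500)),
    A3SS = list(exons = rbind(ex(t1, 301, 450), ex(t1, 101, 200),
                              ex(t2, 351, 450), ex(t2, 101, 200)),
                role = role(301, 450, 351, 450, 101, 200)),
    AFE = list(exons = rbind(ex(t1, 101, 180), ex(t1, 501, 600),
                             ex(t2, 251, 330), ex(t2, 501, 600)),
               role = role(101, 180, 251, 330, 501, 600)),
    ALE = list(exons = rbind(ex(t1, 101, 200), ex(t1, 451, 530),
                             ex(t2, 101, 200), ex(t2, 301, 380)),
               role = role(451, 530, 301, 380, 101, 200)),
    stop("unknown event type: ", type)
  )
}

.random_genome <- function(chrom, length) {
  seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
               collapse = "")
  genome <- Biostrings::DNAStringSet(seq)
  names(genome) <- chrom
  genome
}

#' Simulate a plate-based single-cell splicing dataset
#'
#' Generates, under one seed, every input the plate pipeline consumes: a
#' toy genome, a GTF-compatible annotation (one gene per event, two
#' transcripts where the event type implies them), a junction count
#' matrix, an intron total-coverage matrix (RI events), a normalized
#' expression matrix, cell metadata and a truth table. Per event and cell
#' the latent PSI is drawn from the group's beta distribution, the
#' informative read total from a negative binomial, and included reads
#' binomially — so observed PSI has genuine between-cell (beta) and
#' sampling (binomial) variance. Events flagged \code{artifact} emulate
#' all-or-none amplification capture: each cell reports PSI 0 or 1 with
#' probability equal to the latent mean, the signature that the
#' spurious-bimodality correction targets. Expression is log-normal with
#' the planted group-2 log2 fold change of each event's gene.
#'
#' @param plan Event plan (see [modality_plan()], [differential_plan()]);
#'   default [differential_plan()].
#' @param n_cells_per_group Cells per group (default 60).
#' @param seed RNG seed (default 1).
#' @param depth_mean,depth_size Negative-binomial informative-read depth
#'   (defaults mu = 100, size = 10).
#' @param expr_base Baseline expression level (default 20).
#' @param chrom Chromosome name (default "chrS").
#' @param out_dir Optional directory; when given, all components are also
#'   written in their standard plain-text formats.
#' @return List: \code{genome}, \code{annotation}, \code{events} (mapped),
#'   \code{introns}, \code{junction_counts}, \code{intron_coverage},
#'   \code{expression}, \code{cell_metadata}, \code{truth}.
#' @export
simulate_plate <- function(plan = differential_plan(),
                           n_cells_per_group = 60, seed = 1,
                           depth_mean = 100, depth_size = 10,
                           expr_base = 20, chrom = "chrS", out_dir = NULL) {
  stopifnot(n_cells_per_group > 0, nrow(plan) > 0)
  set.seed(seed)
  n_events <- nrow(plan)
  tile <- 1000L
  gene_ids <- sprintf("G%04d", seq_len(n_events))
  n_cells <- 2L * n_cells_per_group
  cells <- sprintf("cell_%03d", seq_len(n_cells))
  group <- rep(c("G1", "G2"), each = n_cells_per_group)

  # annotation + internal event table
  exon_rows <- vector("list", n_events)
  role_rows <- matrix(NA_integer_, n_events, 8)
  for (i in seq_len(n_events)) {
    lay <- .gene_layout(plan$type[i], (i - 1L) * tile, gene_ids[i])
    lay$exons$gene_id <- gene_ids[i]
    exon_rows[[i]] <- lay$exons
    role_rows[i, ] <- lay$role
  }
  exons <- do.call(rbind, exon_rows)
  exons$chrom <- chrom; exons$strand <- "+"
  ord <- order(exons$transcript_id, exons$start)
  exons <- exons[ord, c("transcript_id", "gene_id", "chrom", "strand",
                        "start", "end")]
  exons$exon_rank <- stats::ave(seq_len(nrow(exons)), exons$transcript_id,
                                FUN = seq_along)
  rownames(exons) <- NULL
  tx_span <- do.call(rbind, lapply(split(exons, exons$transcript_id),
    function(d) data.frame(transcript_id = d$transcript_id[1],
                           gene_id = d$gene_id[1], chrom = chrom,
                           strand = "+", start = min(d$start),
                           end = max(d$end), biotype = "protein_coding",
                           stringsAsFactors = FALSE)))
  rownames(tx_span) <- NULL
  genes <- do.call(rbind, lapply(split(tx_span, tx_span$gene_id),
    function(d) data.frame(gene_id = d$gene_id[1],
                           gene_name = d$gene_id[1], chrom = chrom,
                           strand = "+", start = min(d$start),
                           end = max(d$end), stringsAsFactors = FALSE)))
  rownames(genes) <- NULL
  annotation <- structure(list(genes = genes, transcripts = tx_span,
                               exons = exons,
                               cds = exons[0, c("transcript_id", "gene_id",
                                                "chrom", "strand", "start",
                                                "end")]),
                          class = "splice_annotation")

  events <- data.frame(type = plan$type, gene_id = gene_ids, chrom = chrom,
                       strand = "+", stringsAsFactors = FALSE)
  role_df <- as.data.frame(role_rows)
  names(role_df) <- c("e1_start", "e1_end", "e2_start", "e2_end",
                      "e3_start", "e3_end", "e4_start", "e4_end")
  events <- cbind(events, role_df)
  attr(events, "coordinates") <- "internal"
  events <- map_event_junctions(events)

  # latent PSI per event and cell
  psi_latent <- matrix(NA_real_, n_events, n_cells)
  for (i in seq_len(n_events)) {
    a <- ifelse(group == "G1", plan$alpha_g1[i], plan$alpha_g2[i])
    b <- ifelse(group == "G1", plan$beta_g1[i], plan$beta_g2[i])
    p <- rbeta(n_cells, a, b)
    if (isTRUE(plan$artifact[i])) {
      mu <- ifelse(group == "G1",
                   plan$alpha_g1[i] / (plan$alpha_g1[i] + plan$beta_g1[i]),
                   plan$alpha_g2[i] / (plan$alpha_g2[i] + plan$beta_g2[i]))
      p <- as.numeric(rbinom(n_cells, 1, mu))
    }
    psi_latent[i, ] <- p
  }

  # junction counts / intron coverage
  jkeys <- unique(unlist(c(split_sj_set(events$included),
                           split_sj_set(events$excluded))))
  junction_counts <- matrix(0L, length(jkeys), n_cells,
                            dimnames = list(jkeys, cells))
  intron_ids <- events$event_id[events$type == "RI"]
  intron_coverage <- matrix(0, length(intron_ids), n_cells,
                            dimnames = list(intron_ids, cells))
  for (i in seq_len(n_events)) {
    p <- psi_latent[i, ]
    n_tot <- rnbinom(n_cells, size = depth_size, mu = depth_mean)
    if (plan$type[i] == "RI") {
      p <- pmin(p, 0.98)
      skip <- rbinom(n_cells, n_tot, 1 - p)
      len <- events$intron_end[i] - events$intron_start[i] + 1L
      cov <- round(p / (1 - p) * skip * len)
      key <- split_sj_set(events$excluded[i])[[1]]
      junction_counts[key, ] <- junction_counts[key, ] + skip
      intron_coverage[events$event_id[i], ] <- cov
    } else {
      inc_keys <- split_sj_set(events$included[i])[[1]]
      exc_keys <- split_sj_set(events$excluded[i])[[1]]
      inc <- rbinom(n_cells, n_tot, p)
      exc <- n_tot - inc
      if (length(inc_keys) == 2) {
        j1 <- rbinom(n_cells, inc, 0.5)
        junction_counts[inc_keys[1], ] <- junction_counts[inc_keys[1], ] + j1
        junction_counts[inc_keys[2], ] <-
          junction_counts[inc_keys[2], ] + (inc - j1)
      } else {
        junction_counts[inc_keys[1], ] <- junction_counts[inc_keys[1], ] + inc
      }
      if (length(exc_keys) == 2) {
        j1 <- rbinom(n_cells, exc, 0.5)
        junction_counts[exc_keys[1], ] <- junction_counts[exc_keys[1], ] + j1
        junction_counts[exc_keys[2], ] <-
          junction_counts[exc_keys[2], ] + (exc - j1)
      } else {
        junction_counts[exc_keys[1], ] <- junction_counts[exc_keys[1], ] + exc
      }
    }
  }

  # expression: log-normal baseline, planted group-2 fold change
  expression <- matrix(0, n_events, n_cells,
                       dimnames = list(gene_ids, cells))
  for (i in seq_len(n_events)) {
    fc <- plan$expr_log2fc[i]
    meanlog <- log(expr_base) + ifelse(group == "G2", fc * log(2), 0)
    expression[i, ] <- rlnorm(n_cells, meanlog = meanlog, sdlog = 0.4)
  }

  introns <- derive_independent_introns(events, annotation)
  genome <- .random_genome(chrom, n_events * tile)
  truth <- cbind(data.frame(event_id = events$event_id,
                            gene_id = gene_ids,
                            stringsAsFactors = FALSE), plan)
  mu1 <- plan$alpha_g1 / (plan$alpha_g1 + plan$beta_g1)
  mu2 <- plan$alpha_g2 / (plan$alpha_g2 + plan$beta_g2)
  truth$delta_psi_true <- 100 * (mu2 - mu1)
  cell_metadata <- data.frame(cell_id = cells, group = group,
                              stringsAsFactors = FALSE)

  out <- list(genome = genome, annotation = annotation, events = events,
              introns = introns, junction_counts = junction_counts,
              intron_coverage = intron_coverage, expression = expression,
              cell_metadata = cell_metadata, truth = truth)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    Biostrings::writeXStringSet(genome, file.path(out_dir, "genome.fa"))
    write_gtf(annotation, file.path(out_dir, "annotation.gtf"))
    write_matrix_tsv(junction_counts, file.path(out_dir, "sj_counts.tsv"))
    write_matrix_tsv(intron_coverage,
                     file.path(out_dir, "intron_coverage.tsv"))
    write_matrix_tsv(expression, file.path(out_dir, "expression.tsv"))
    write.table(cell_metadata, file.path(out_dir, "cell_metadata.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(events, file.path(out_dir, "events.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}

#' Junction plan for the droplet simulator
#'
#' @param n_null Junctions with identical usage in both cell types
#'   (default 300).
#' @param n_diff Junctions with a planted usage shift (default 5).
#' @param usage_null Usage of null junctions (default 0.3).
#' @param usage_diff Length-2 usage of differential junctions per group
#'   (default c(0.2, 0.5)).
#' @return Plan data.frame for [simulate_droplet()].
#' @export
droplet_plan <- function(n_null = 300, n_diff = 5, usage_null = 0.3,
                         usage_diff = c(0.2, 0.5)) {
  data.frame(
    usage_g1 = c(rep(usage_null, n_null), rep(usage_diff[1], n_diff)),
    usage_g2 = c(rep(usage_null, n_null), rep(usage_diff[2], n_diff)),
    differential_truth = c(rep(FALSE, n_null), rep(TRUE, n_diff)),
    stringsAsFactors = FALSE)
}

#' Simulate a droplet-based dataset with planted junction usage
#'
#' One gene per junction. Gene counts are zero-inflated negative binomial;
#' junction counts are a binomial thinning of the cell's gene count at the
#' planted usage, which guarantees junction counts never exceed gene
#' counts and that pseudo-bulk usage converges to the planted value.
#' Normalized expression is a CPM-style per-cell scaling of the gene
#' counts (fixture convenience only). Cell types sit at two Gaussian
#' clusters in the returned 2-D embedding.
#'
#' @param plan Junction plan (default [droplet_plan()]).
#' @param n_cells_per_group Cells per cell type (default 200).
#' @param seed RNG seed (default 1).
#' @param gene_mu,gene_size Negative-binomial gene-count parameters
#'   (defaults 5, 2).
#' @param dropout Structural-zero rate of gene counts (default 0.3).
#' @param norm_scale Per-cell library scale of the normalized matrix
#'   (default 1e4).
#' @return List: \code{gene_counts}, \code{sj_counts} (sparse),
#'   \code{expression}, \code{cell_metadata}, \code{embedding},
#'   \code{gene_of_junction}, \code{truth}.
#' @export
simulate_droplet <- function(plan = droplet_plan(), n_cells_per_group = 200,
                             seed = 1, gene_mu = 5, gene_size = 2,
                             dropout = 0.3, norm_scale = 1e4) {
  set.seed(seed)
  n_j <- nrow(plan)
  n_cells <- 2L * n_cells_per_group
  cells <- sprintf("bc_%04d", seq_len(n_cells))
  cell_type <- rep(c("T1", "T2"), each = n_cells_per_group)
  genes <- sprintf("DG%04d", seq_len(n_j))
  keys <- sj_key(rep("chrD", n_j), seq_len(n_j) * 1000L + 1L,
                 seq_len(n_j) * 1000L + 200L)
  gene_counts <- matrix(0L, n_j, n_cells, dimnames = list(genes, cells))
  sj_counts <- matrix(0L, n_j, n_cells, dimnames = list(keys, cells))
  for (i in seq_len(n_j)) {
    g <- rnbinom(n_cells, size = gene_size, mu = gene_mu) *
      rbinom(n_cells, 1, 1 - dropout)
    u <- ifelse(cell_type == "T1", plan$usage_g1[i], plan$usage_g2[i])
    gene_counts[i, ] <- g
    sj_counts[i, ] <- rbinom(n_cells, g, u)
  }
  lib <- colSums(gene_counts)
  lib[lib == 0] <- 1
  expression <- sweep(gene_counts, 2, lib, "/") * norm_scale
  embedding <- cbind(
    x = rnorm(n_cells, ifelse(cell_type == "T1", -3, 3), 0.8),
    y = rnorm(n_cells, 0, 0.8))
  rownames(embedding) <- cells
  truth <- cbind(data.frame(key = keys, gene_id = genes,
                            stringsAsFactors = FALSE), plan)
  list(gene_counts = as(Matrix::Matrix(gene_counts, sparse = TRUE),
                        "CsparseMatrix"),
       sj_counts = as(Matrix::Matrix(sj_counts, sparse = TRUE),
                      "CsparseMatrix"),
       expression = expression,
       cell_metadata = data.frame(cell_id = cells, cell_type = cell_type,
                                  stringsAsFactors = FALSE),
       embedding = embedding,
       gene_of_junction = setNames(genes, keys),
       truth = truth)
}

# deterministic stop-free background: "GGC" repeated contains no stop codon
# in any reading frame, so planted ATG/TAA motifs fully control translation
.ggc_background <- function(length) {
  s <- strrep("GGC", ceiling(length / 3))
  substr(s, 1, length)
}

#' Deterministic NMD fixture
#'
#' Builds a six-gene toy genome with hand-placed start and stop codons on
#' a stop-free background so that inserting each gene's alternative
#' segment yields a known outcome: an introduced PTC 80 bp upstream of
#' the final exon-exon junction (NMD yes), 50 bp (no), 30 bp (no), an
#' in-frame stop-free insertion (orf_intact), a non-coding isoform and an
#' isoform incompatible with the insertion (novel_isoform). With
#' \code{strand = "-"} the entire fixture is mirrored (reverse-complement
#' genome, reflected coordinates), which must produce identical calls.
#'
#' @param strand \code{"+"} (default) or \code{"-"}.
#' @return List: \code{genome}, \code{annotation}, \code{events},
#'   \code{diff_splice} (pre-made candidate table), \code{expected}
#'   (truth: event_id, transcript_id, category, nmd, distance).
#' @export
simulate_nmd <- function(strand = "+") {
  tile <- 600L
  chrom <- "chrN"
  glen <- 6L * tile
  seq <- .ggc_background(glen)

  # per-gene design: exon structure, planted motifs, expected call
  # E1 = (1,60); alt segment A = (70, 70+L-1); E2 = (151, 150+b); E3 starts
  # at e3s, length 120; coordinates within the gene tile
  designs <- list(
    list(id = "N1", L = 23L, b = 60L, e3s = 271L, stop_in_alt = TRUE,
         coding = TRUE, expected = c("ptc_introduced", "yes", 80)),
    list(id = "N2", L = 23L, b = 30L, e3s = 241L, stop_in_alt = TRUE,
         coding = TRUE, expected = c("ptc_introduced", "no", 50)),
    list(id = "N3", L = 23L, b = 10L, e3s = 241L, stop_in_alt = TRUE,
         coding = TRUE, expected = c("ptc_introduced", "no", 30)),
    list(id = "N4", L = 12L, b = 60L, e3s = 271L, stop_in_alt = FALSE,
         coding = TRUE, expected = c("orf_intact", "no", NA)),
    list(id = "N5", L = 23L, b = 60L, e3s = 271L, stop_in_alt = FALSE,
         coding = FALSE, expected = c("non_coding", "not_applicable", NA)),
    list(id = "N6", L = 23L, b = 60L, e3s = 271L, stop_in_alt = FALSE,
         coding = TRUE, overlap = TRUE,
         expected = c("novel_isoform", "not_applicable", NA))
  )

  put <- function(seq, pos, motif) {
    substr(seq, pos, pos + nchar(motif) - 1L) <- motif
    seq
  }

  exon_rows <- list(); tx_rows <- list(); gene_rows <- list()
  cds_rows <- list(); event_rows <- list(); expected_rows <- list()
  for (k in seq_along(designs)) {
    d <- designs[[k]]
    off <- (k - 1L) * tile
    e1 <- c(1L, 60L); a <- c(70L, 70L + d$L - 1L)
    e2 <- c(151L, 150L + d$b); e3 <- c(d$e3s, d$e3s + 119L)
    if (isTRUE(d$overlap)) e1 <- c(1L, 100L)  # E1 overlaps the segment
    tid <- paste0(d$id, ".t1")
    if (d$coding) {
      seq <- put(seq, off + 1L, "ATG")
      # annotated stop: last codon of the unmodified ORF, inside E3
      unmod_len <- 60L + d$b + 120L
      stop_cdna <- unmod_len - 2L          # cDNA position of stop start
      e3_cdna_start <- 60L + d$b + 1L
      stop_g <- e3[1] + (stop_cdna - e3_cdna_start)
      seq <- put(seq, off + stop_g, "TAA")
    }
    if (d$stop_in_alt) seq <- put(seq, off + a[1], "TAA")
    exon_rows[[k]] <- data.frame(
      transcript_id = tid, gene_id = d$id, chrom = chrom, strand = "+",
      start = off + c(e1[1], e2[1], e3[1]),
      end = off + c(e1[2], e2[2], e3[2]), stringsAsFactors = FALSE)
    tx_rows[[k]] <- data.frame(
      transcript_id = tid, gene_id = d$id, chrom = chrom, strand = "+",
      start = off + e1[1], end = off + e3[2],
      biotype = if (d$coding) "protein_coding" else "lncRNA",
      stringsAsFactors = FALSE)
    gene_rows[[k]] <- data.frame(
      gene_id = d$id, gene_name = d$id, chrom = chrom, strand = "+",
      start = off + e1[1], end = off + e3[2], stringsAsFactors = FALSE)
    if (d$coding) {
      cds_rows[[k]] <- data.frame(
        transcript_id = tid, gene_id = d$id, chrom = chrom, strand = "+",
        start = off + e1[1], end = off + e1[2], stringsAsFactors = FALSE)
    }
    event_rows[[k]] <- data.frame(
      event_id = paste0(d$id, "|SE"), type = "SE", gene_id = d$id,
      chrom = chrom, strand = "+",
      e1_start = off + e1[1], e1_end = off + e1[2],
      e2_start = off + a[1], e2_end = off + a[2],
      e3_start = off + e2[1], e3_end = off + e2[2],
      e4_start = NA_integer_, e4_end = NA_integer_,
      intron_start = NA_integer_, intron_end = NA_integer_,
      included = "", excluded = "", valid = TRUE, stringsAsFactors = FALSE)
    expected_rows[[k]] <- data.frame(
      event_id = paste0(d$id, "|SE"),
      transcript_id = if (isTRUE(d$overlap)) NA_character_ else tid,
      category = d$expected[1], nmd = d$expected[2],
      ptc_distance_bp = as.integer(d$expected[3]), stringsAsFactors = FALSE)
  }
  exons <- do.call(rbind, exon_rows)
  events <- do.call(rbind, event_rows)
  genes <- do.call(rbind, gene_rows)
  transcripts <- do.call(rbind, tx_rows)
  cds <- do.call(rbind, cds_rows)

  if (strand == "-") {
    # mirror: reverse-complement the genome and reflect all coordinates
    seq <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    refl <- function(df) {
      s <- glen + 1L - df$end; e <- glen + 1L - df$start
      df$start <- s; df$end <- e; df$strand <- "-"
      df
    }
    exons <- refl(exons); genes <- refl(genes)
    transcripts <- refl(transcripts); cds <- refl(cds)
    events$strand <- "-"
    for (cols in list(c("e1_start", "e1_end"), c("e2_start", "e2_end"),
                      c("e3_start", "e3_end"))) {
      s <- glen + 1L - events[[cols[2]]]
      e <- glen + 1L - events[[cols[1]]]
      events[[cols[1]]] <- s; events[[cols[2]]] <- e
    }
  }
  ord <- order(exons$transcript_id,
               ifelse(exons$strand == "-", -exons$start, exons$start))
  exons <- exons[ord, , drop = FALSE]
  exons$exon_rank <- stats::ave(seq_len(nrow(exons)), exons$transcript_id,
                                FUN = seq_along)
  rownames(exons) <- NULL
  genome <- Biostrings::DNAStringSet(seq)
  names(genome) <- chrom
  annotation <- structure(list(genes = genes, transcripts = transcripts,
                               exons = exons, cds = cds),
                          class = "splice_annotation")
  attr(events, "coordinates") <- "internal"
  diff_splice <- data.frame(event_id = events$event_id, delta_psi = 20,
                            fdr = 0.01, significant = TRUE,
                            stringsAsFactors = FALSE)
  list(genome = genome, annotation = annotation, events = events,
       diff_splice = diff_splice, expected = do.call(rbind, expected_rows))
}
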