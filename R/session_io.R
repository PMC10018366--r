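#' Read a STAR SJ.out.tab splice-junction file
#'
#' Parses the tab-separated splice-junction output of STAR for one sample or
#' cell: chromosome, first and last intronic base (1-based inclusive), strand
#' code (0 = unknown, 1 = +, 2 = -), intron motif, annotation flag, unique
#' reads, multi-mapping reads. Junction coordinates are used as-is (they are
#' already on the internal 1-based intronic convention). Zero-count rows are
#' retained.
#'
#' @param path Path to an SJ.out.tab-style file.
#' @param sample_id Identifier recorded on the returned table.
#' @param count_column Which read count to use: \code{"unique"} (column 7,
#'   the default) or \code{"multi"} (column 8).
#' @return A data.frame with columns \code{key}, \code{chrom}, \code{start},
#'   \code{end}, \code{strand}, \code{count}, \code{sample_id}; zero rows for
#'   an empty file.
#' @export
read_star_sj_tab <- function(path, sample_id,
                             count_column = c("unique", "multi")) {
  count_column <- match.arg(count_column)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(key = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), count = integer(),
                      sample_id = character(), stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 7)) {
    stop("malformed SJ line ", which(nf < 7)[1], " in ", path,
         ": expected >= 7 tab-separated columns, got ", nf[nf < 7][1])
  }
  col <- function(i) vapply(fields, `[`, "", i)
  start <- suppressWarnings(as.integer(col(2)))
  end <- suppressWarnings(as.integer(col(3)))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) {
    stop("malformed SJ line ", which(bad)[1], " in ", path,
         ": non-integer coordinates")
  }
  chrom <- col(1)
  strand_code <- col(4)
  strand <- c("0" = "*", "1" = "+", "2" = "-")[strand_code]
  strand[is.na(strand)] <- "*"
  cnt_idx <- if (count_column == "unique") 7L else 8L
  count <- suppressWarnings(as.integer(col(cnt_idx)))
  if (anyNA(count)) {
    stop("malformed SJ line ", which(is.na(count))[1], " in ", path,
         ": non-integer read count")
  }
  key <- sj_key(chrom, start, end)
  if (anyDuplicated(key)) {
    stop("duplicate junction ", key[duplicated(key)][1], " in ", path,
         ": STAR emits unique intron rows; duplicates indicate corruption")
  }
  data.frame(key = key, chrom = chrom, start = start, end = end,
             strand = unname(strand), count = count,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

#' Assemble a junction count matrix from per-sample SJ tables
#'
#' @param sj_tables List of data.frames from [read_star_sj_tab()], one per
#'   cell/sample.
#' @return Integer matrix, junctions (keys) x samples; junctions absent from
#'   a sample get count 0.
#' @export
build_sj_matrix <- function(sj_tables) {
  stopifnot(length(sj_tables) > 0)
  ids <- vapply(sj_tables, function(t) unique(t$sample_id)[1], "")
  if (anyDuplicated(ids)) stop("duplicate sample ids in SJ tables")
  keys <- sort(unique(unlist(lapply(sj_tables, `[[`, "key"))))
  mat <- matrix(0L, nrow = length(keys), ncol = length(ids),
                dimnames = list(keys, ids))
  for (i in seq_along(sj_tables)) {
    t <- sj_tables[[i]]
    mat[t$key, i] <- t$count
  }
  mat
}

#' Read a GTF annotation
#'
#' Imports a GTF 2.2 file (via \pkg{rtracklayer}) into the package's
#' annotation container: data.frames of genes, transcripts (with biotype,
#' taken from \code{transcript_biotype} or \code{transcript_type}), exons
#' ordered along the direction of transcription, and CDS records when
#' present. Exon rows lacking a \code{transcript_id} are skipped with a
#' warning.
#'
#' @param path Path to a GTF file.
#' @return A \code{splice_annotation} object: list with elements
#'   \code{genes}, \code{transcripts}, \code{exons}, \code{cds}.
#' @export
read_gtf <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("failed to read GTF '", path, "': ",
                                          conditionMessage(e)))
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  if (any(df$end < df$start)) stop("GTF record with end < start")
  type <- as.character(df$type)

  ex <- df[type == "exon", , drop = FALSE]
  if (nrow(ex) > 0 && anyNA(ex$transcript_id)) {
    warning(sum(is.na(ex$transcript_id)),
            " exon record(s) lacking transcript_id skipped")
    ex <- ex[!is.na(ex$transcript_id), , drop = FALSE]
  }

  biotype_of <- function(d) {
    if (!is.null(d$transcript_biotype)) d$transcript_biotype
    else if (!is.null(d$transcript_type)) d$transcript_type
    else rep(NA_character_, nrow(d))
  }

  tx_rows <- df[type == "transcript", , drop = FALSE]
  if (nrow(tx_rows) > 0) {
    transcripts <- data.frame(
      transcript_id = tx_rows$transcript_id,
      gene_id = tx_rows$gene_id,
      chrom = tx_rows$seqnames,
      strand = tx_rows$strand,
      start = tx_rows$start,
      end = tx_rows$end,
      biotype = biotype_of(tx_rows),
      stringsAsFactors = FALSE
    )
  } else if (nrow(ex) > 0) {
    # derive transcript spans from exons when transcript rows are absent
    sp <- split(ex, ex$transcript_id)
    transcripts <- do.call(rbind, lapply(sp, function(d) data.frame(
      transcript_id = d$transcript_id[1], gene_id = d$gene_id[1],
      chrom = d$seqnames[1], strand = d$strand[1],
      start = min(d$start), end = max(d$end),
      biotype = biotype_of(d)[1], stringsAsFactors = FALSE)))
  } else {
    transcripts <- data.frame(transcript_id = character(),
                              gene_id = character(), chrom = character(),
                              strand = character(), start = integer(),
                              end = integer(), biotype = character(),
                              stringsAsFactors = FALSE)
    if (nrow(ex) == 0) warning("GTF contains no transcript or exon records ",
                               "with transcript_id; annotation has 0 transcripts")
  }
  rownames(transcripts) <- NULL

  gene_rows <- df[type == "gene", , drop = FALSE]
  if (nrow(gene_rows) > 0) {
    genes <- data.frame(
      gene_id = gene_rows$gene_id,
      gene_name = if (!is.null(gene_rows$gene_name)) gene_rows$gene_name
                  else gene_rows$gene_id,
      chrom = gene_rows$seqnames, strand = gene_rows$strand,
      start = gene_rows$start, end = gene_rows$end,
      stringsAsFactors = FALSE
    )
  } else if (nrow(transcripts) > 0) {
    sp <- split(transcripts, transcripts$gene_id)
    genes <- do.call(rbind, lapply(sp, function(d) data.frame(
      gene_id = d$gene_id[1], gene_name = d$gene_id[1], chrom = d$chrom[1],
      strand = d$strand[1], start = min(d$start), end = max(d$end),
      stringsAsFactors = FALSE)))
  } else {
    genes <- data.frame(gene_id = character(), gene_name = character(),
                        chrom = character(), strand = character(),
                        start = integer(), end = integer(),
                        stringsAsFactors = FALSE)
  }
  rownames(genes) <- NULL

  if (nrow(ex) > 0) {
    exons <- data.frame(
      transcript_id = ex$transcript_id, gene_id = ex$gene_id,
      chrom = ex$seqnames, strand = ex$strand,
      start = ex$start, end = ex$end, stringsAsFactors = FALSE
    )
    # order along transcription: genomic order on +, reversed on -
    ord <- order(exons$transcript_id,
                 ifelse(exons$strand == "-", -exons$start, exons$start))
    exons <- exons[ord, , drop = FALSE]
    exons$exon_rank <- stats::ave(seq_len(nrow(exons)), exons$transcript_id,
                                  FUN = seq_along)
    rownames(exons) <- NULL
  } else {
    exons <- data.frame(transcript_id = character(), gene_id = character(),
                        chrom = character(), strand = character(),
                        start = integer(), end = integer(),
                        exon_rank = integer(), stringsAsFactors = FALSE)
  }

  cds_rows <- df[type == "CDS", , drop = FALSE]
  cds <- if (nrow(cds_rows) > 0) {
    data.frame(transcript_id = cds_rows$transcript_id,
               gene_id = cds_rows$gene_id, chrom = cds_rows$seqnames,
               strand = cds_rows$strand, start = cds_rows$start,
               end = cds_rows$end, stringsAsFactors = FALSE)
  } else {
    data.frame(transcript_id = character(), gene_id = character(),
               chrom = character(), strand = character(), start = integer(),
               end = integer(), stringsAsFactors = FALSE)
  }
  rownames(cds) <- NULL

  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 cds = cds),
            class = "splice_annotation")
}

#' Write a \code{splice_annotation} as GTF
#'
#' Emits gene, transcript, exon and CDS rows with the attribute set the
#' package reads back ([read_gtf()] round-trips exon structures exactly).
#'
#' @param annotation A \code{splice_annotation}.
#' @param path Output path.
#' @export
write_gtf <- function(annotation, path) {
  stopifnot(inherits(annotation, "splice_annotation"))
  attr_gene <- function(g) sprintf('gene_id "%s"; gene_name "%s";',
                                   g$gene_id, g$gene_name)
  attr_tx <- function(t) sprintf(
    'gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
    t$gene_id, t$transcript_id,
    ifelse(is.na(t$biotype), "protein_coding", t$biotype))
  gtf_line <- function(chrom, feat, start, end, strand, attrs) {
    paste(chrom, "scsplice", feat, start, end, ".", strand, ".", attrs,
          sep = "\t")
  }
  lines <- character()
  g <- annotation$genes
  if (nrow(g) > 0)
    lines <- c(lines, gtf_line(g$chrom, "gene", g$start, g$end, g$strand,
                               attr_gene(g)))
  t <- annotation$transcripts
  if (nrow(t) > 0)
    lines <- c(lines, gtf_line(t$chrom, "transcript", t$start, t$end,
                               t$strand, attr_tx(t)))
  e <- annotation$exons
  if (nrow(e) > 0) {
    bt <- t$biotype[match(e$transcript_id, t$transcript_id)]
    at <- sprintf('gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
                  e$gene_id, e$transcript_id,
                  ifelse(is.na(bt), "protein_coding", bt))
    lines <- c(lines, gtf_line(e$chrom, "exon", e$start, e$end, e$strand, at))
  }
  cd <- annotation$cds
  if (nrow(cd) > 0) {
    at <- sprintf('gene_id "%s"; transcript_id "%s";',
                  cd$gene_id, cd$transcript_id)
    lines <- c(lines, gtf_line(cd$chrom, "CDS", cd$start, cd$end, cd$strand,
                               at))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.splice_annotation <- function(x, ...) {
  cat("splice_annotation:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts,", nrow(x$exons), "exons,",
      nrow(x$cds), "CDS records\n")
  invisible(x)
}

# rMATS fromGTF column sets per event type (0-based starts, 1-based ends)
.rmats_required_cols <- list(
  SE = c("GeneID", "chr", "strand", "exonStart_0base", "exonEnd",
         "upstreamES", "upstreamEE", "downstreamES", "downstreamEE"),
  MXE = c("GeneID", "chr", "strand", "X1stExonStart_0base", "X1stExonEnd",
          "X2ndExonStart_0base", "X2ndExonEnd", "upstreamES", "upstreamEE",
          "downstreamES", "downstreamEE"),
  RI = c("GeneID", "chr", "strand", "riExonStart_0base", "riExonEnd",
         "upstreamES", "upstreamEE", "downstreamES", "downstreamEE"),
  A5SS = c("GeneID", "chr", "strand", "longExonStart_0base", "longExonEnd",
           "shortES", "shortEE", "flankingES", "flankingEE"),
  A3SS = c("GeneID", "chr", "strand", "longExonStart_0base", "longExonEnd",
           "shortES", "shortEE", "flankingES", "flankingEE")
)

#' Read rMATS fromGTF event coordinate tables
#'
#' Consumes the per-type tab files rMATS writes (fromGTF.SE.txt etc.), whose
#' exon starts are 0-based and ends 1-based, and converts them once, at this
#' boundary, to the package's uniform 1-based inclusive convention. The
#' result is an internal event table; role columns \code{e1..e4} are mapped
#' per type (SE: e1 = upstream, e2 = alternative, e3 = downstream; MXE: e1 =
#' upstream, e2/e3 = first/second alternative exon, e4 = downstream; RI: e1 =
#' upstream, e2 = downstream, the intron lies between them; A5SS/A3SS: e1 =
#' long exon, e2 = short exon, e3 = flanking exon).
#'
#' @param paths Named character vector or list of file paths; names must be
#'   among SE, MXE, RI, A5SS, A3SS.
#' @return A data.frame of internal-coordinate events with columns
#'   \code{type}, \code{gene_id}, \code{chrom}, \code{strand},
#'   \code{e1_start} .. \code{e4_end}; attribute \code{coordinates =
#'   "internal"}.
#' @export
read_rmats_events <- function(paths) {
  if (length(paths) == 0) stop("no rMATS files supplied")
  types <- names(paths)
  bad <- setdiff(types, names(.rmats_required_cols))
  if (length(bad) > 0 || is.null(types)) {
    stop("unknown event-type label: ",
         paste(if (is.null(types)) "<unnamed>" else bad, collapse = ", "))
  }
  out <- lapply(types, function(ty) {
    df <- read.table(paths[[ty]], sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE, check.names = TRUE)
    req <- .rmats_required_cols[[ty]]
    missing_cols <- setdiff(req, names(df))
    if (length(missing_cols) > 0) {
      stop("rMATS ", ty, " file missing required column: ", missing_cols[1])
    }
    n <- nrow(df)
    ev <- data.frame(type = rep(ty, n), gene_id = df$GeneID, chrom = df$chr,
                     strand = df$strand,
                     e1_start = NA_integer_, e1_end = NA_integer_,
                     e2_start = NA_integer_, e2_end = NA_integer_,
                     e3_start = NA_integer_, e3_end = NA_integer_,
                     e4_start = NA_integer_, e4_end = NA_integer_,
                     stringsAsFactors = FALSE)
    if (n == 0) return(ev)
    p1 <- function(x) as.integer(x) + 1L   # 0-based start -> 1-based
    if (ty == "SE") {
      ev$e1_start <- p1(df$upstreamES); ev$e1_end <- df$upstreamEE
      ev$e2_start <- p1(df$exonStart_0base); ev$e2_end <- df$exonEnd
      ev$e3_start <- p1(df$downstreamES); ev$e3_end <- df$downstreamEE
    } else if (ty == "MXE") {
      ev$e1_start <- p1(df$upstreamES); ev$e1_end <- df$upstreamEE
      ev$e2_start <- p1(df$X1stExonStart_0base); ev$e2_end <- df$X1stExonEnd
      ev$e3_start <- p1(df$X2ndExonStart_0base); ev$e3_end <- df$X2ndExonEnd
      ev$e4_start <- p1(df$downstreamES); ev$e4_end <- df$downstreamEE
    } else if (ty == "RI") {
      ev$e1_start <- p1(df$upstreamES); ev$e1_end <- df$upstreamEE
      ev$e2_start <- p1(df$downstreamES); ev$e2_end <- df$downstreamEE
    } else { # A5SS / A3SS
      ev$e1_start <- p1(df$longExonStart_0base); ev$e1_end <- df$longExonEnd
      ev$e2_start <- p1(df$shortES); ev$e2_end <- df$shortEE
      ev$e3_start <- p1(df$flankingES); ev$e3_end <- df$flankingEE
    }
    ev
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "coordinates") <- "internal"
  res
}

#' Assemble an analysis session
#'
#' Validates and aligns all inputs for one analysis mode. Cell identifiers
#' are intersected across every matrix and the metadata; cells missing from
#' any input are dropped with a warning, and all matrices are re-ordered to
#' one canonical (sorted) cell order, so assembly is independent of input
#' column order.
#'
#' @param mode \code{"plate"} or \code{"droplet"}.
#' @param junction_counts Junctions x cells count matrix (plate: dense;
#'   droplet: STARsolo-style raw SJ counts, sparse accepted).
#' @param expression Genes x cells normalized expression matrix (linear
#'   scale).
#' @param annotation A \code{splice_annotation}.
#' @param cell_metadata Data.frame with a \code{cell_id} column plus
#'   \code{group} (plate) or \code{cell_type} (droplet, required).
#' @param events Optional internal event table (plate).
#' @param intron_coverage Optional introns x cells total-coverage matrix
#'   (plate; required later for RI PSI).
#' @param gene_counts Genes x cells raw count matrix (droplet, required).
#' @param embedding Optional per-cell 2-D coordinate matrix (droplet).
#' @return A \code{splice_session} list.
#' @export
create_session <- function(mode = c("plate", "droplet"),
                           junction_counts, expression, annotation,
                           cell_metadata, events = NULL,
                           intron_coverage = NULL, gene_counts = NULL,
                           embedding = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(annotation, "splice_annotation"),
            is.data.frame(cell_metadata), "cell_id" %in% names(cell_metadata))
  if (anyDuplicated(cell_metadata$cell_id)) {
    stop("duplicate cell ids in cell_metadata")
  }
  if (mode == "droplet") {
    if (is.null(gene_counts)) stop("droplet mode requires gene_counts")
    if (!("cell_type" %in% names(cell_metadata))) {
      stop("droplet mode requires cell-type labels (cell_metadata$cell_type)")
    }
  }
  mats <- list(junction_counts = junction_counts, expression = expression,
               intron_coverage = intron_coverage, gene_counts = gene_counts)
  mats <- mats[!vapply(mats, is.null, TRUE)]
  for (nm in names(mats)) {
    if (is.null(colnames(mats[[nm]]))) stop(nm, " lacks cell (column) names")
    if (anyDuplicated(colnames(mats[[nm]]))) {
      stop("duplicate cell ids in ", nm)
    }
    if (anyDuplicated(rownames(mats[[nm]]))) {
      stop("duplicate row ids in ", nm)
    }
  }
  cell_sets <- c(lapply(mats, colnames), list(meta = cell_metadata$cell_id))
  common <- Reduce(intersect, cell_sets)
  if (length(common) == 0) stop("empty cell intersection across inputs")
  common <- sort(common)
  for (i in seq_along(cell_sets)) {
    dropped <- setdiff(cell_sets[[i]], common)
    if (length(dropped) > 0) {
      warning(length(dropped), " cell(s) dropped from ",
              names(cell_sets)[i], ": absent from other inputs")
    }
  }
  mats <- lapply(mats, function(m) m[, common, drop = FALSE])
  meta <- cell_metadata[match(common, cell_metadata$cell_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (!is.null(embedding)) {
    stopifnot(!is.null(rownames(embedding)))
    embedding <- embedding[common, , drop = FALSE]
  }
  structure(list(
    mode = mode,
    junction_counts = mats$junction_counts,
    expression = mats$expression,
    intron_coverage = mats$intron_coverage,
    gene_counts = mats$gene_counts,
    annotation = annotation,
    events = events,
    cell_metadata = meta,
    embedding = embedding,
    cells = common
  ), class = "splice_session")
}

#' @export
print.splice_session <- function(x, ...) {
  cat("splice_session (", x$mode, " mode): ", length(x$cells), " cells, ",
      nrow(x$junction_counts), " junctions, ",
      if (!is.null(x$expression)) nrow(x$expression) else 0, " genes\n",
      sep = "")
  invisible(x)
}
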