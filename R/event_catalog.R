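# Event catalog: AFE/ALE detection from annotation, junction mapping for all
# seven event types, independent-intron derivation, event validation against
# junction evidence, and droplet junction annotation.

# junction between two exons a (genomically left) and b (right):
# first and last intronic base
.junc_between <- function(a_end, b_start) c(a_end + 1L, b_start - 1L)

.coord_block <- function(events) {
  cols <- c("e1_start", "e1_end", "e2_start", "e2_end", "e3_start", "e3_end",
            "e4_start", "e4_end")
  m <- as.matrix(events[, cols, drop = FALSE])
  apply(m, 1, function(v) paste(v[!is.na(v)], collapse = "-"))
}

#' Detect alternative first/last exon events from annotation
#'
#' For each multi-transcript gene, every unordered pair of distinct first
#' exons (first in the direction of transcription) whose transcripts splice
#' onto a common, coordinate-identical downstream exon yields one AFE event;
#' the last-exon case is symmetric and yields ALE events. The distal member
#' of the pair (further from the shared exon in transcription order) defines
#' the included junction, the proximal member the excluded junction.
#' Duplicate events arising from redundant transcript pairs are collapsed by
#' coordinate block.
#'
#' @param annotation A \code{splice_annotation}.
#' @return Internal event table (columns as in [read_rmats_events()]): e1 =
#'   distal alternative exon, e2 = proximal alternative exon, e3 = shared
#'   exon. Empty when no gene has alternative ends.
#' @export
detect_afe_ale <- function(annotation) {
  stopifnot(inherits(annotation, "splice_annotation"))
  ex <- annotation$exons
  empty <- data.frame(type = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      e1_start = integer(), e1_end = integer(),
                      e2_start = integer(), e2_end = integer(),
                      e3_start = integer(), e3_end = integer(),
                      e4_start = integer(), e4_end = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(ex) == 0) return(empty)
  out <- list()
  for (gid in unique(ex$gene_id)) {
    ge <- ex[ex$gene_id == gid, , drop = FALSE]
    txs <- split(ge, ge$transcript_id)
    txs <- txs[vapply(txs, nrow, 1L) >= 2]  # need a neighbour exon to pair on
    if (length(txs) < 2) next
    strand <- ge$strand[1]
    chrom <- ge$chrom[1]
    ends <- lapply(txs, function(d) {
      # transcription order from coordinates, independent of row order
      d <- d[order(if (strand == "-") -d$start else d$start), ,
             drop = FALSE]
      n <- nrow(d)
      list(first = c(d$start[1], d$end[1]),
           after_first = c(d$start[2], d$end[2]),
           last = c(d$start[n], d$end[n]),
           before_last = c(d$start[n - 1], d$end[n - 1]))
    })
    pairs <- utils::combn(length(ends), 2)
    for (k in seq_len(ncol(pairs))) {
      a <- ends[[pairs[1, k]]]
      b <- ends[[pairs[2, k]]]
      # AFE: distinct first exons, identical exon right after the first
      if (!identical(a$first, b$first) &&
          identical(a$after_first, b$after_first)) {
        # distal = further 5' in transcription order
        distal_is_a <- if (strand == "-") a$first[2] > b$first[2]
                       else a$first[1] < b$first[1]
        d <- if (distal_is_a) a$first else b$first
        p <- if (distal_is_a) b$first else a$first
        out[[length(out) + 1L]] <- data.frame(
          type = "AFE", gene_id = gid, chrom = chrom, strand = strand,
          e1_start = d[1], e1_end = d[2], e2_start = p[1], e2_end = p[2],
          e3_start = a$after_first[1], e3_end = a$after_first[2],
          e4_start = NA_integer_, e4_end = NA_integer_,
          stringsAsFactors = FALSE)
      }
      # ALE: distinct last exons, identical exon right before the last
      if (!identical(a$last, b$last) &&
          identical(a$before_last, b$before_last)) {
        # distal = further 3' in transcription order
        distal_is_a <- if (strand == "-") a$last[1] < b$last[1]
                       else a$last[2] > b$last[2]
        d <- if (distal_is_a) a$last else b$last
        p <- if (distal_is_a) b$last else a$last
        out[[length(out) + 1L]] <- data.frame(
          type = "ALE", gene_id = gid, chrom = chrom, strand = strand,
          e1_start = d[1], e1_end = d[2], e2_start = p[1], e2_end = p[2],
          e3_start = a$before_last[1], e3_end = a$before_last[2],
          e4_start = NA_integer_, e4_end = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  key <- paste(res$type, res$gene_id, .coord_block(res))
  res <- res[!duplicated(key), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "coordinates") <- "internal"
  res
}

#' Map events to their included and excluded junction sets
#'
#' Derives, from the role-tagged exon coordinates of an internal event
#' table, the splice junctions whose reads evidence inclusion and exclusion
#' of the alternative segment: for SE the two flanking junctions of the
#' alternative exon versus the skipping junction; for MXE the two junctions
#' of each alternative exon; for A5SS/A3SS and AFE/ALE one junction per
#' form; for RI the single intron-skipping junction (inclusion is measured
#' from intron coverage, not a junction). Events implying a zero-length
#' junction (adjacent exons) are flagged invalid.
#'
#' @param events Internal event table.
#' @return The table with added columns \code{event_id}, \code{included},
#'   \code{excluded} (semicolon-joined junction keys), \code{intron_start},
#'   \code{intron_end} (RI only) and \code{valid}.
#' @export
map_event_junctions <- function(events) {
  stopifnot(identical(attr(events, "coordinates"), "internal"))
  n <- nrow(events)
  if (n == 0) {
    events$event_id <- character(0)
    events$included <- character(0)
    events$excluded <- character(0)
    events$intron_start <- integer(0)
    events$intron_end <- integer(0)
    events$valid <- logical(0)
    attr(events, "coordinates") <- "internal"
    return(events)
  }
  included <- character(n); excluded <- character(n)
  intron_start <- rep(NA_integer_, n); intron_end <- rep(NA_integer_, n)
  valid <- rep(TRUE, n)
  for (i in seq_len(n)) {
    ev <- events[i, ]
    ch <- ev$chrom
    jn <- function(a_end, b_start) {
      j <- .junc_between(a_end, b_start)
      if (j[1] > j[2]) return(NA_character_)
      sj_key(ch, j[1], j[2])
    }
    between <- function(s1, e1, s2, e2) {
      # junction between two exons regardless of which is left
      if (e1 < s2) jn(e1, s2) else jn(e2, s1)
    }
    inc <- exc <- character()
    if (ev$type == "SE") {
      inc <- c(jn(ev$e1_end, ev$e2_start), jn(ev$e2_end, ev$e3_start))
      exc <- jn(ev$e1_end, ev$e3_start)
    } else if (ev$type == "MXE") {
      inc <- c(jn(ev$e1_end, ev$e2_start), jn(ev$e2_end, ev$e4_start))
      exc <- c(jn(ev$e1_end, ev$e3_start), jn(ev$e3_end, ev$e4_start))
    } else if (ev$type == "RI") {
      j <- .junc_between(ev$e1_end, ev$e2_start)
      if (j[1] > j[2]) {
        exc <- NA_character_
      } else {
        exc <- sj_key(ch, j[1], j[2])
        intron_start[i] <- j[1]; intron_end[i] <- j[2]
      }
    } else if (ev$type %in% c("A5SS", "A3SS")) {
      # e1 = long exon, e2 = short exon, e3 = flanking exon
      inc <- between(ev$e1_start, ev$e1_end, ev$e3_start, ev$e3_end)
      exc <- between(ev$e2_start, ev$e2_end, ev$e3_start, ev$e3_end)
    } else if (ev$type %in% c("AFE", "ALE")) {
      inc <- between(ev$e1_start, ev$e1_end, ev$e3_start, ev$e3_end)
      exc <- between(ev$e2_start, ev$e2_end, ev$e3_start, ev$e3_end)
    } else {
      stop("unknown event type: ", ev$type)
    }
    if (anyNA(inc) || anyNA(exc)) {
      valid[i] <- FALSE
      inc <- inc[!is.na(inc)]; exc <- exc[!is.na(exc)]
    }
    included[i] <- join_sj_set(inc)
    excluded[i] <- join_sj_set(exc)
  }
  events$event_id <- paste(events$gene_id, events$type, events$chrom,
                           events$strand, .coord_block(events), sep = "|")
  events$included <- included
  events$excluded <- excluded
  events$intron_start <- intron_start
  events$intron_end <- intron_end
  events$valid <- valid
  attr(events, "coordinates") <- "internal"
  events
}

#' Derive independent introns for retained-intron quantification
#'
#' A retained-intron candidate qualifies as independent only when its
#' interval shares no base with any annotated exon of any transcript of any
#' gene; reads over exon-overlapping introns cannot be attributed to
#' retention and such introns are discarded.
#'
#' @param events Mapped event table (from [map_event_junctions()])
#'   containing RI events.
#' @param annotation A \code{splice_annotation} supplying the exon catalog.
#' @return Data.frame: \code{intron_id}, \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{length_bp}, \code{skip_junction}.
#' @export
derive_independent_introns <- function(events, annotation) {
  stopifnot(inherits(annotation, "splice_annotation"))
  ri <- events[events$type == "RI" & events$valid, , drop = FALSE]
  empty <- data.frame(intron_id = character(), gene_id = character(),
                      chrom = character(), start = integer(),
                      end = integer(), length_bp = integer(),
                      skip_junction = character(), stringsAsFactors = FALSE)
  if (nrow(ri) == 0) return(empty)
  ex <- annotation$exons
  ex_gr <- GenomicRanges::GRanges(ex$chrom,
                                  IRanges::IRanges(ex$start, ex$end))
  intr_gr <- GenomicRanges::GRanges(ri$chrom,
                                    IRanges::IRanges(ri$intron_start,
                                                     ri$intron_end))
  hits <- GenomicRanges::countOverlaps(intr_gr, ex_gr, minoverlap = 1L)
  keep <- hits == 0
  if (!any(keep)) return(empty)
  ri <- ri[keep, , drop = FALSE]
  data.frame(
    intron_id = ri$event_id,
    gene_id = ri$gene_id,
    chrom = ri$chrom,
    start = ri$intron_start,
    end = ri$intron_end,
    length_bp = ri$intron_end - ri$intron_start + 1L,
    skip_junction = sj_key(ri$chrom, ri$intron_start, ri$intron_end),
    stringsAsFactors = FALSE
  )
}

#' Validate events against junction evidence
#'
#' An event is retained only when every junction in its included and
#' excluded sets is present in the junction count matrix and the event's
#' junctions carry at least \code{min_total_reads} reads summed across all
#' cells. This is a cohort-level pre-filter; the per-cell read floor is
#' applied later during PSI computation.
#'
#' @param events Mapped event table.
#' @param junction_counts Junctions x cells count matrix.
#' @param min_total_reads Minimum summed read support (default 10).
#' @return The retained subset of \code{events}, with a
#'   \code{total_reads} column.
#' @export
validate_events <- function(events, junction_counts, min_total_reads = 10) {
  stopifnot(!is.null(rownames(junction_counts)))
  events <- events[events$valid, , drop = FALSE]
  if (nrow(events) == 0) return(cbind(events, total_reads = integer(0)))
  row_tot <- Matrix::rowSums(junction_counts)
  keys <- mapply(function(i, e) c(i, e), split_sj_set(events$included),
                 split_sj_set(events$excluded), SIMPLIFY = FALSE)
  total <- vapply(keys, function(k) {
    if (!all(k %in% names(row_tot))) return(NA_real_)
    sum(row_tot[k])
  }, 1.0)
  keep <- !is.na(total) & total >= min_total_reads
  out <- events[keep, , drop = FALSE]
  out$total_reads <- total[keep]
  rownames(out) <- NULL
  attr(out, "coordinates") <- "internal"
  out
}

#' Annotate and filter droplet splice junctions against a GTF
#'
#' Each junction's two flanking exonic positions (start - 1 and end + 1)
#' are matched exactly against annotated exon boundaries: a flank matching
#' boundaries of exactly one gene is annotated, of several genes
#' multi-mapped, of none unannotated. A junction is retained only when both
#' flanks are annotated and resolve to the same gene, which becomes the
#' junction's gene.
#'
#' @param junction_keys Character vector of junction keys (or a matrix with
#'   junction-key row names).
#' @param annotation A \code{splice_annotation}.
#' @return Data.frame: \code{key}, \code{label_left}, \code{label_right}
#'   (annotated / multi_mapped / unannotated), \code{class} (retained /
#'   filtered_unannotated / filtered_multimapped / filtered_mixed),
#'   \code{gene_id} (NA unless retained).
#' @export
annotate_sj_droplet <- function(junction_keys, annotation) {
  stopifnot(inherits(annotation, "splice_annotation"))
  if (!is.character(junction_keys)) junction_keys <- rownames(junction_keys)
  jk <- parse_sj_key(junction_keys)
  ex <- annotation$exons
  # exon boundary lookup tables: chrom:pos -> set of genes
  end_map <- split(ex$gene_id, paste(ex$chrom, ex$end, sep = ":"))
  start_map <- split(ex$gene_id, paste(ex$chrom, ex$start, sep = ":"))
  flank_genes <- function(map, chrom, pos) {
    g <- map[[paste(chrom, pos, sep = ":")]]
    if (is.null(g)) character(0) else unique(g)
  }
  n <- length(junction_keys)
  label_left <- label_right <- character(n)
  cls <- character(n)
  gene <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    gl <- flank_genes(end_map, jk$chrom[i], jk$start[i] - 1L)
    gr <- flank_genes(start_map, jk$chrom[i], jk$end[i] + 1L)
    lab <- function(g) if (length(g) == 0) "unannotated"
                       else if (length(g) == 1) "annotated" else "multi_mapped"
    label_left[i] <- lab(gl)
    label_right[i] <- lab(gr)
    if (label_left[i] == "unannotated" || label_right[i] == "unannotated") {
      cls[i] <- "filtered_unannotated"
    } else if (label_left[i] == "multi_mapped" ||
               label_right[i] == "multi_mapped") {
      cls[i] <- "filtered_multimapped"
    } else if (!identical(gl, gr)) {
      cls[i] <- "filtered_mixed"
    } else {
      cls[i] <- "retained"
      gene[i] <- gl
    }
  }
  data.frame(key = junction_keys, label_left = label_left,
             label_right = label_right, class = cls, gene_id = gene,
             stringsAsFactors = FALSE)
}
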