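# Nonsense-mediated decay prediction: insert a differential alternative
# segment into each compatible protein-coding isoform, translate, and test
# whether an introduced premature termination codon lies more than 50 bp
# upstream of the final exon-exon junction.

#' Select candidate events for NMD prediction
#'
#' Candidates are differentially spliced events with an absolute PSI
#' difference above 5 percentage points and FDR below 0.10.
#'
#' @param diff_splice Differential splicing result; either carries an
#'   \code{fdr} column or a \code{significant} flag already encoding the
#'   FDR cut.
#' @param delta_psi_cut Percent-scale cut (default 5).
#' @param fdr_cut FDR cut when an \code{fdr} column is present (default
#'   0.10).
#' @return Character vector of candidate event ids.
#' @export
select_nmd_candidates <- function(diff_splice, delta_psi_cut = 5,
                                  fdr_cut = 0.10) {
  fdr_ok <- if ("fdr" %in% names(diff_splice)) {
    !is.na(diff_splice$fdr) & diff_splice$fdr < fdr_cut
  } else {
    diff_splice$significant
  }
  keep <- fdr_ok & !is.na(diff_splice$delta_psi) &
    abs(diff_splice$delta_psi) > delta_psi_cut
  diff_splice$event_id[keep]
}

# assemble spliced cDNA from genomic blocks (sorted by start); minus-strand
# transcripts are the reverse complement of the plus-strand assembly
.assemble_cdna <- function(genome, chrom, strand, blocks) {
  pieces <- lapply(seq_len(nrow(blocks)), function(i) {
    Biostrings::subseq(genome[[chrom]], blocks$start[i], blocks$end[i])
  })
  cdna <- do.call(Biostrings::xscat, pieces)
  if (strand == "-") cdna <- Biostrings::reverseComplement(cdna)
  as.character(cdna)
}

# cDNA coordinate (in the direction of transcription) of a genomic base
.cdna_pos <- function(blocks, strand, g) {
  ord <- if (strand == "-") rev(seq_len(nrow(blocks))) else
    seq_len(nrow(blocks))
  offset <- 0L
  for (i in ord) {
    s <- blocks$start[i]; e <- blocks$end[i]
    if (g >= s && g <= e) {
      within <- if (strand == "-") e - g + 1L else g - s + 1L
      return(offset + within)
    }
    offset <- offset + (e - s + 1L)
  }
  NA_integer_
}

#' Insert an alternative segment into a transcript and assemble its cDNA
#'
#' The segment must either coincide with an existing exon of the transcript
#' (the transcript already encodes it; assembly is unmodified) or fall
#' entirely between two consecutive exons (within, or exactly filling, an
#' intron); partial overlap with an exon or a position outside the
#' transcript's intron space is an error.
#'
#' @param exons Data.frame of the transcript's exons (\code{start},
#'   \code{end}), any order.
#' @param segment Integer length-2 vector \code{c(start, end)} of the
#'   alternative segment (1-based inclusive).
#' @param genome A \code{DNAStringSet} (names = chromosomes).
#' @param chrom,strand Transcript location.
#' @return List: \code{cdna} (character), \code{blocks} (genomic exon
#'   blocks after insertion, sorted by start), \code{inserted} (logical),
#'   \code{insert_length}.
#' @export
build_modified_transcript <- function(exons, segment, genome, chrom,
                                      strand) {
  blocks <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  s <- segment[1]; e <- segment[2]
  stopifnot(s <= e)
  matches <- blocks$start == s & blocks$end == e
  if (any(matches)) {
    return(list(cdna = .assemble_cdna(genome, chrom, strand, blocks),
                blocks = blocks, inserted = FALSE, insert_length = 0L))
  }
  overlaps <- blocks$start <= e & blocks$end >= s
  if (any(overlaps)) {
    stop("incompatible insertion: segment partially overlaps an exon")
  }
  n <- nrow(blocks)
  gap <- which(blocks$end[-n] < s & blocks$start[-1] > e)
  if (length(gap) == 0) {
    stop("segment outside the transcript's intron space")
  }
  new_blocks <- rbind(blocks, data.frame(start = s, end = e))
  new_blocks <- new_blocks[order(new_blocks$start), , drop = FALSE]
  rownames(new_blocks) <- NULL
  list(cdna = .assemble_cdna(genome, chrom, strand, new_blocks),
       blocks = new_blocks, inserted = TRUE,
       insert_length = e - s + 1L)
}

#' Translate a cDNA and locate the first in-frame stop codon
#'
#' Scans codons from the coding start, locates the first stop (TAA, TAG,
#' TGA), and measures its distance to the final exon-exon junction in
#' transcript coordinates: the junction coordinate is the cDNA position of
#' the last base of the second-to-last exon, and the distance is measured
#' from the last base of the stop codon.
#'
#' @param cdna Character cDNA sequence (direction of transcription).
#' @param coding_start 1-based cDNA position of the first base of the
#'   start codon.
#' @param exon_lengths Exon lengths in transcription order of the
#'   (modified) transcript.
#' @return List: \code{stop_start}, \code{stop_end} (NA when no stop;
#'   flagged \code{nonstop}), \code{junction_pos},
#'   \code{distance_to_junction}.
#' @export
translate_and_locate_ptc <- function(cdna, coding_start, exon_lengths) {
  stopifnot(coding_start >= 1, coding_start <= nchar(cdna))
  junction_pos <- sum(exon_lengths) - exon_lengths[length(exon_lengths)]
  n_codons <- (nchar(cdna) - coding_start + 1L) %/% 3L
  stop_start <- NA_integer_
  if (n_codons > 0) {
    starts <- coding_start + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(cdna, starts, starts + 2L)
    hit <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (length(hit) > 0) stop_start <- starts[hit[1]]
  }
  if (is.na(stop_start)) {
    return(list(stop_start = NA_integer_, stop_end = NA_integer_,
                junction_pos = junction_pos,
                distance_to_junction = NA_integer_, nonstop = TRUE))
  }
  stop_end <- stop_start + 2L
  list(stop_start = stop_start, stop_end = stop_end,
       junction_pos = junction_pos,
       distance_to_junction = junction_pos - stop_end, nonstop = FALSE)
}

#' Predict splicing-associated nonsense-mediated decay
#'
#' For each candidate event (SE, RI, A5SS, A3SS; selected by
#' [select_nmd_candidates()]), the alternative segment is inserted into
#' every protein-coding isoform of the event's gene that is compatible
#' with the insertion, the modified transcript is translated from its
#' annotated start codon, and the first stop codon is compared with the
#' unmodified isoform's stop. Categories: \code{novel_isoform} (no
#' compatible isoform in the annotation), \code{non_coding} (isoform
#' without an open reading frame), \code{ptc_introduced} (first stop
#' differs from the unmodified stop) and \code{orf_intact}. NMD is
#' predicted (\code{yes}) only for introduced PTCs more than 50 bp
#' upstream of the final exon-exon junction.
#'
#' @param events Mapped event table (provides segment coordinates).
#' @param diff_splice Differential splicing result for candidate
#'   selection.
#' @param annotation A \code{splice_annotation} with CDS records.
#' @param genome \code{DNAStringSet} genome.
#' @param delta_psi_cut,fdr_cut Candidate thresholds (defaults 5, 0.10).
#' @return Data.frame: \code{event_id}, \code{transcript_id},
#'   \code{category}, \code{nmd} (yes/no/not_applicable),
#'   \code{ptc_distance_bp}.
#' @export
predict_nmd <- function(events, diff_splice, annotation, genome,
                        delta_psi_cut = 5, fdr_cut = 0.10) {
  cand <- select_nmd_candidates(diff_splice, delta_psi_cut, fdr_cut)
  ev <- events[events$event_id %in% cand &
               events$type %in% c("SE", "RI", "A5SS", "A3SS"), ,
               drop = FALSE]
  out <- list()
  add <- function(event_id, transcript_id, category, nmd, dist) {
    out[[length(out) + 1L]] <<- data.frame(
      event_id = event_id, transcript_id = transcript_id,
      category = category, nmd = nmd, ptc_distance_bp = dist,
      stringsAsFactors = FALSE)
  }
  tx <- annotation$transcripts
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    segment <- .alt_segment(e)
    if (anyNA(segment)) next
    gene_tx <- tx[tx$gene_id == e$gene_id, , drop = FALSE]
    n_compatible <- 0L
    for (j in seq_len(nrow(gene_tx))) {
      tid <- gene_tx$transcript_id[j]
      exons <- annotation$exons[annotation$exons$transcript_id == tid, ,
                                drop = FALSE]
      if (nrow(exons) < 2) next
      cds <- annotation$cds[annotation$cds$transcript_id == tid, ,
                            drop = FALSE]
      coding <- identical(gene_tx$biotype[j], "protein_coding") &&
        nrow(cds) > 0
      mod <- tryCatch(
        build_modified_transcript(exons, segment, genome, e$chrom,
                                  e$strand),
        error = function(err) NULL)
      if (is.null(mod)) next
      n_compatible <- n_compatible + 1L
      if (!coding) {
        add(e$event_id, tid, "non_coding", "not_applicable", NA_integer_)
        next
      }
      # annotated start codon: first CDS base in transcription order
      start_g <- if (e$strand == "-") max(cds$end) else min(cds$start)
      orig_blocks <- exons[order(exons$start), c("start", "end"),
                           drop = FALSE]
      cs_orig <- .cdna_pos(orig_blocks, e$strand, start_g)
      cs_mod <- .cdna_pos(mod$blocks, e$strand, start_g)
      if (is.na(cs_orig) || is.na(cs_mod)) {
        add(e$event_id, tid, "non_coding", "not_applicable", NA_integer_)
        next
      }
      tx_lengths <- function(blocks) {
        l <- blocks$end - blocks$start + 1L
        if (e$strand == "-") rev(l) else l
      }
      cdna_orig <- .assemble_cdna(genome, e$chrom, e$strand, orig_blocks)
      ptc_orig <- translate_and_locate_ptc(cdna_orig, cs_orig,
                                           tx_lengths(orig_blocks))
      ptc_mod <- translate_and_locate_ptc(mod$cdna, cs_mod,
                                          tx_lengths(mod$blocks))
      if (ptc_mod$nonstop) {
        warning("no stop codon in modified transcript ", tid,
                "; categorized orf_intact")
        add(e$event_id, tid, "orf_intact", "no", NA_integer_)
        next
      }
      # expected position of the unmodified stop inside the modified cDNA:
      # shifted by the insertion length when the insertion lies upstream
      shift <- cs_mod - cs_orig
      expected_stop <- if (is.na(ptc_orig$stop_start)) NA_integer_ else {
        s <- ptc_orig$stop_start
        # insertion downstream of the original start shifts downstream
        # positions; locate via genomic mapping of the insertion
        if (mod$inserted) {
          ins_start_cdna <- .cdna_pos(mod$blocks, e$strand, segment[1])
          ins_len <- mod$insert_length
          if (!is.na(ins_start_cdna) && ins_start_cdna <= s + shift)
            s + ins_len else s
        } else s
      }
      introduced <- is.na(expected_stop) ||
        ptc_mod$stop_start != expected_stop
      if (introduced) {
        d <- ptc_mod$distance_to_junction
        add(e$event_id, tid, "ptc_introduced",
            if (!is.na(d) && d > 50) "yes" else "no", d)
      } else {
        add(e$event_id, tid, "orf_intact", "no", NA_integer_)
      }
    }
    if (n_compatible == 0L) {
      add(e$event_id, NA_character_, "novel_isoform", "not_applicable",
          NA_integer_)
    }
  }
  if (length(out) == 0) {
    return(data.frame(event_id = character(), transcript_id = character(),
                      category = character(), nmd = character(),
                      ptc_distance_bp = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# alternative segment coordinates per event type
.alt_segment <- function(e) {
  if (e$type == "SE") return(c(e$e2_start, e$e2_end))
  if (e$type == "RI") return(c(e$intron_start, e$intron_end))
  if (e$type %in% c("A5SS", "A3SS")) {
    # region of the long exon absent from the short exon
    if (e$e1_start == e$e2_start) return(c(e$e2_end + 1L, e$e1_end))
    if (e$e1_end == e$e2_end) return(c(e$e1_start, e$e2_start - 1L))
    return(c(NA_integer_, NA_integer_))
  }
  c(NA_integer_, NA_integer_)
}
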