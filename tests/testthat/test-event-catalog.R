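# AFE/ALE detection from annotation, junction mapping per event type,
# independent-intron derivation, event validation and droplet junction
# annotation

make_annotation <- function(exons) {
  exons$exon_rank <- stats::ave(seq_len(nrow(exons)), exons$transcript_id,
                                FUN = seq_along)
  tx <- do.call(rbind, lapply(split(exons, exons$transcript_id), function(d)
    data.frame(transcript_id = d$transcript_id[1], gene_id = d$gene_id[1],
               chrom = d$chrom[1], strand = d$strand[1],
               start = min(d$start), end = max(d$end),
               biotype = "protein_coding", stringsAsFactors = FALSE)))
  genes <- do.call(rbind, lapply(split(tx, tx$gene_id), function(d)
    data.frame(gene_id = d$gene_id[1], gene_name = d$gene_id[1],
               chrom = d$chrom[1], strand = d$strand[1],
               start = min(d$start), end = max(d$end),
               stringsAsFactors = FALSE)))
  rownames(tx) <- rownames(genes) <- NULL
  structure(list(genes = genes, transcripts = tx, exons = exons,
                 cds = exons[0, ]), class = "splice_annotation")
}

exon_df <- function(tid, gid, starts, ends, strand = "+") {
  d <- data.frame(transcript_id = tid, gene_id = gid, chrom = "chr1",
                  strand = strand, start = starts, end = ends,
                  stringsAsFactors = FALSE)
  d[order(if (strand == "-") -d$start else d$start), ]
}

test_that("a pair of distinct first exons joining a shared exon is one AFE", {
  ann <- make_annotation(rbind(
    exon_df("t1", "g", c(100, 500), c(200, 600)),
    exon_df("t2", "g", c(300, 500), c(380, 600))))
  ev <- detect_afe_ale(ann)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "AFE")
  # distal (more 5' on +) first exon is the included side
  expect_equal(c(ev$e1_start, ev$e1_end), c(100, 200))
  expect_equal(c(ev$e2_start, ev$e2_end), c(300, 380))
  expect_equal(c(ev$e3_start, ev$e3_end), c(500, 600))
})

test_that("transcripts sharing all exon boundaries yield no AFE or ALE", {
  ann <- make_annotation(rbind(
    exon_df("t1", "g", c(100, 500), c(200, 600)),
    exon_df("t2", "g", c(100, 500), c(200, 600))))
  expect_equal(nrow(detect_afe_ale(ann)), 0)
})

test_that("three alternative first exons give all C(3,2) pairs", {
  ann <- make_annotation(rbind(
    exon_df("t1", "g", c(100, 900), c(150, 990)),
    exon_df("t2", "g", c(300, 900), c(350, 990)),
    exon_df("t3", "g", c(500, 900), c(550, 990))))
  ev <- detect_afe_ale(ann)
  expect_equal(sum(ev$type == "AFE"), choose(3, 2))
  # brute-force pair enumerator over distinct first exons
  firsts <- list(c(100, 150), c(300, 350), c(500, 550))
  pairs <- combn(3, 2)
  got <- sort(paste(ev$e1_start, ev$e1_end, ev$e2_start, ev$e2_end))
  want <- sort(apply(pairs, 2, function(p) {
    a <- firsts[[p[1]]]; b <- firsts[[p[2]]]
    paste(a[1], a[2], b[1], b[2])
  }))
  expect_equal(got, want)
})

test_that("AFE/ALE detection is invariant to transcript input order", {
  ex <- rbind(exon_df("t1", "g", c(100, 500, 900), c(200, 600, 990)),
              exon_df("t2", "g", c(300, 500, 900), c(380, 600, 990)),
              exon_df("t3", "g", c(100, 500, 700), c(200, 600, 790)))
  a <- detect_afe_ale(make_annotation(ex))
  b <- detect_afe_ale(make_annotation(ex[rev(seq_len(nrow(ex))), ]))
  key <- function(d) sort(paste(d$type, d$e1_start, d$e1_end, d$e2_start,
                                d$e2_end, d$e3_start, d$e3_end))
  expect_equal(key(a), key(b))
})

test_that("strand mirror swaps alternative-first and alternative-last", {
  L <- 2000
  plus <- rbind(exon_df("t1", "g", c(100, 500), c(200, 600)),
                exon_df("t2", "g", c(300, 500), c(380, 600)))
  minus <- plus
  s <- L + 1 - plus$end; e <- L + 1 - plus$start
  minus$start <- s; minus$end <- e; minus$strand <- "-"
  minus <- minus[order(minus$transcript_id, -minus$start), ]
  ev_p <- detect_afe_ale(make_annotation(plus))
  ev_m <- detect_afe_ale(make_annotation(minus))
  expect_equal(ev_p$type, "AFE")
  # the mirrored gene still varies at its 5' end (transcription now runs
  # right to left), so the call stays AFE; appending the mirror as the
  # 3' structure of a + gene makes it ALE
  expect_equal(ev_m$type, "AFE")
  ale <- rbind(exon_df("t1", "g", c(1400, 1800), c(1500, 1900)),
               exon_df("t2", "g", c(1400, 1620), c(1500, 1700)))
  expect_equal(detect_afe_ale(make_annotation(ale))$type, "ALE")
})

test_that("junction mapping follows the exon-boundary arithmetic per type", {
  sim <- simulate_plate(
    data.frame(type = c("SE", "MXE", "RI", "A5SS", "A3SS", "AFE", "ALE"),
               alpha_g1 = 2, beta_g1 = 2, alpha_g2 = 2, beta_g2 = 2,
               artifact = FALSE, relation = "null", expr_log2fc = 0),
    n_cells_per_group = 3, seed = 1)
  ev <- sim$events
  n_inc <- lengths(strsplit(ev$included, ";", fixed = TRUE))
  n_exc <- lengths(strsplit(ev$excluded, ";", fixed = TRUE))
  expect_equal(n_inc[ev$type == "SE"], 2L, ignore_attr = TRUE)
  expect_equal(n_exc[ev$type == "SE"], 1L, ignore_attr = TRUE)
  expect_equal(n_inc[ev$type == "MXE"], 2L, ignore_attr = TRUE)
  expect_equal(n_exc[ev$type == "MXE"], 2L, ignore_attr = TRUE)
  for (tp in c("A5SS", "A3SS", "AFE", "ALE")) {
    expect_equal(n_inc[ev$type == tp], 1L, ignore_attr = TRUE)
    expect_equal(n_exc[ev$type == tp], 1L, ignore_attr = TRUE)
  }
  # SE: junctions span the first/last intronic bases between role exons
  se <- ev[ev$type == "SE", ]
  expect_equal(
    sort(strsplit(se$included, ";")[[1]]),
    sort(c(sj_key(se$chrom, se$e1_end + 1, se$e2_start - 1),
           sj_key(se$chrom, se$e2_end + 1, se$e3_start - 1))))
  expect_equal(se$excluded,
               sj_key(se$chrom, se$e1_end + 1, se$e3_start - 1))
  # RI: the intron is the inter-exon interval; skip junction spans it
  ri <- ev[ev$type == "RI", ]
  expect_equal(ri$intron_start, ri$e1_end + 1)
  expect_equal(ri$intron_end, ri$e2_start - 1)
  expect_equal(ri$excluded,
               sj_key(ri$chrom, ri$intron_start, ri$intron_end))
})

test_that("abutting exons produce no junction and invalidate the event", {
  ev <- data.frame(type = "SE", gene_id = "g", chrom = "chr1", strand = "+",
                   e1_start = 100L, e1_end = 200L,
                   e2_start = 201L, e2_end = 300L,  # abuts upstream exon
                   e3_start = 401L, e3_end = 500L,
                   e4_start = NA_integer_, e4_end = NA_integer_,
                   stringsAsFactors = FALSE)
  attr(ev, "coordinates") <- "internal"
  mapped <- map_event_junctions(ev)
  expect_false(mapped$valid)
})

test_that("independent introns exclude introns overlapped by any exon", {
  sim <- simulate_plate(
    data.frame(type = c("RI", "RI"), alpha_g1 = 2, beta_g1 = 2,
               alpha_g2 = 2, beta_g2 = 2, artifact = FALSE,
               relation = "null", expr_log2fc = 0),
    n_cells_per_group = 3, seed = 1)
  introns <- derive_independent_introns(sim$events, sim$annotation)
  expect_equal(nrow(introns), 2)
  expect_equal(introns$length_bp,
               sim$events$intron_end - sim$events$intron_start + 1)
  # plant an exon of another transcript inside the first intron
  ann2 <- sim$annotation
  extra <- ann2$exons[1, ]
  extra$transcript_id <- "nested.t"
  extra$start <- sim$events$intron_start[1] + 5
  extra$end <- sim$events$intron_start[1] + 20
  ann2$exons <- rbind(ann2$exons, extra)
  introns2 <- derive_independent_introns(sim$events, ann2)
  expect_equal(nrow(introns2), 1)
  expect_equal(introns2$intron_id, sim$events$event_id[2])
})

test_that("event validation requires presence and ten pooled reads", {
  sim <- simulate_plate(differential_plan(2, 0), n_cells_per_group = 3,
                        seed = 1)
  ev <- sim$events
  jc <- sim$junction_counts
  v <- validate_events(ev, jc)
  expect_equal(v$event_id, ev$event_id)
  expect_true(all(v$total_reads >= 10))
  # removing one junction of event 1 from the matrix drops that event
  drop_key <- strsplit(ev$included[1], ";")[[1]][1]
  v2 <- validate_events(ev, jc[setdiff(rownames(jc), drop_key), ])
  expect_equal(v2$event_id, ev$event_id[2])
  # pooled-count floor is >= 10, tested at the 9/10 boundary
  keys <- unlist(strsplit(c(ev$included[1], ev$excluded[1]), ";"))
  jc9 <- jc; jc9[keys, ] <- 0L; jc9[keys[1], 1] <- 9L
  expect_false(ev$event_id[1] %in% validate_events(ev, jc9)$event_id)
  jc10 <- jc9; jc10[keys[1], 1] <- 10L
  expect_true(ev$event_id[1] %in% validate_events(ev, jc10)$event_id)
})

test_that("droplet junction annotation matches exact flank boundaries", {
  ann <- make_annotation(rbind(
    exon_df("t1", "gA", c(100, 500), c(200, 600)),
    exon_df("t2", "gB", c(1100, 1500), c(1200, 1600)),
    exon_df("t3", "gB", c(100, 500), c(200, 600))))  # gB shares gA exons
  keys <- c(sj_key("chr1", 201, 499),    # both flanks exons of gA and gB
            sj_key("chr1", 201, 1499),   # left gA/gB, right gB only
            sj_key("chr1", 50, 99),      # neither flank annotated
            sj_key("chr1", 201, 480))    # right flank unannotated
  res <- annotate_sj_droplet(keys, ann)
  expect_equal(res$class[1], "filtered_multimapped")
  expect_equal(res$class[3], "filtered_unannotated")
  expect_equal(res$class[4], "filtered_unannotated")
  # a uniquely assignable junction is retained with its gene
  solo <- annotate_sj_droplet(sj_key("chr1", 1201, 1499),
                              make_annotation(
                                exon_df("t2", "gB", c(1100, 1500),
                                        c(1200, 1600))))
  expect_equal(solo$class, "retained")
  expect_equal(solo$gene_id, "gB")
  # flanks annotated to two different genes: filtered as mixed
  mixed <- annotate_sj_droplet(
    sj_key("chr1", 201, 1499),
    make_annotation(rbind(exon_df("t1", "gA", c(100, 2000), c(200, 2100)),
                          exon_df("t2", "gB", c(1100, 1500),
                                  c(1200, 1600)))))
  expect_equal(mixed$class, "filtered_mixed")
})
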