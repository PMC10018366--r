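# splice-junction table reading, GTF round-trips, event-table ingestion and
# session assembly

write_sj_file <- function(lines) {
  f <- withr::local_tempfile(.local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("junction table reader maps strand codes and count columns", {
  f <- write_sj_file(c("chr1\t100\t200\t1\t1\t1\t15\t3\t20",
                       "chr1\t300\t400\t2\t2\t0\t7\t9\t12",
                       "chr2\t10\t20\t0\t0\t0\t2\t5\t8"))
  tab <- read_star_sj_tab(f, "cellA")
  expect_equal(tab$key, c("chr1:100:200", "chr1:300:400", "chr2:10:20"))
  expect_equal(tab$strand, c("+", "-", "*"))
  expect_equal(tab$count, c(15L, 7L, 2L))
  expect_equal(unique(tab$sample_id), "cellA")
  multi <- read_star_sj_tab(f, "cellA", count_column = "multi")
  expect_equal(multi$count, c(3L, 9L, 5L))
})

test_that("junction table reader rejects malformed rows, naming the line", {
  f <- write_sj_file(c("chr1\t100\t200\t1\t1\t1\t15\t3\t20",
                       "chr1\t300"))
  expect_error(read_star_sj_tab(f, "c"), "line 2")
  f2 <- write_sj_file(c("chr1\t100\t200\t1\t1\t1\t15\t3\t20",
                        "chr1\t100\t200\t1\t1\t1\t9\t0\t10"))
  expect_error(read_star_sj_tab(f2, "c"), "duplicate")
})

test_that("empty junction file yields a zero-row table with full schema", {
  f <- write_sj_file(character())
  tab <- read_star_sj_tab(f, "c")
  expect_equal(nrow(tab), 0)
  expect_true(all(c("key", "chrom", "start", "end", "strand", "count",
                    "sample_id") %in% names(tab)))
})

test_that("junction matrix takes the union of keys with zero fill", {
  f1 <- write_sj_file("chr1\t100\t200\t1\t1\t1\t15\t3\t20")
  f2 <- write_sj_file(c("chr1\t100\t200\t1\t1\t1\t4\t0\t9",
                        "chr1\t500\t600\t1\t1\t1\t6\t0\t9"))
  m <- build_sj_matrix(list(read_star_sj_tab(f1, "c1"),
                            read_star_sj_tab(f2, "c2")))
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["chr1:100:200", ], c(c1 = 15L, c2 = 4L))
  expect_equal(m["chr1:500:600", "c1"], 0L)
})

test_that("annotation survives a GTF write/read round-trip", {
  sim <- simulate_plate(differential_plan(4, 0), n_cells_per_group = 5,
                        seed = 1)
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(sim$annotation, f)
  back <- read_gtf(f)
  ord <- function(d) {
    d <- d[do.call(order, d[intersect(c("transcript_id", "gene_id",
                                        "start"), names(d))]), ]
    rownames(d) <- NULL
    d
  }
  for (part in c("genes", "transcripts", "exons")) {
    a <- ord(sim$annotation[[part]]); b <- ord(back[[part]])
    common <- intersect(names(a), names(b))
    expect_equal(b[common], a[common])
  }
})

test_that("event tables convert 0-based starts exactly once at ingestion", {
  header <- paste("ID", "GeneID", "geneSymbol", "chr", "strand",
                  "exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
                  "downstreamES", "downstreamEE", sep = "\t")
  row <- paste("1", "g1", "G1", "chr1", "+", "300", "400", "100", "200",
               "500", "600", sep = "\t")
  f <- withr::local_tempfile()
  writeLines(c(header, row), f)
  ev <- read_rmats_events(list(SE = f))
  # 0-based starts gain 1; 1-based ends are untouched
  expect_equal(ev$e2_start, 301L)
  expect_equal(ev$e2_end, 400L)
  expect_equal(ev$e1_start, 101L)
  expect_equal(ev$e3_end, 600L)
  expect_identical(attr(ev, "coordinates"), "internal")
})

test_that("event table reader requires the documented column schema", {
  f <- withr::local_tempfile()
  writeLines(paste("ID", "GeneID", sep = "\t"), f)
  expect_error(read_rmats_events(list(SE = f)), "column")
})

test_that("session assembly intersects cells and canonicalizes their order", {
  ann <- simulate_plate(differential_plan(1, 0), n_cells_per_group = 2,
                        seed = 1)$annotation
  jc <- matrix(1L, 2, 3, dimnames = list(c("chr1:10:20", "chr1:30:40"),
                                         c("b", "c", "a")))
  expr <- matrix(1, 2, 3, dimnames = list(c("g1", "g2"), c("a", "b", "d")))
  meta <- data.frame(cell_id = c("a", "b", "c", "d"), group = "G1")
  warns <- capture_warnings(
    s <- create_session("plate", junction_counts = jc, expression = expr,
                        annotation = ann, cell_metadata = meta))
  expect_match(warns, "dropped", all = FALSE)
  expect_equal(s$cells, c("a", "b"))
  expect_equal(colnames(s$junction_counts), c("a", "b"))
  expect_equal(colnames(s$expression), c("a", "b"))
})

test_that("session assembly fails with no shared cells or missing labels", {
  ann <- simulate_plate(differential_plan(1, 0), n_cells_per_group = 2,
                        seed = 1)$annotation
  jc <- matrix(1L, 1, 1, dimnames = list("chr1:10:20", "x"))
  expr <- matrix(1, 1, 1, dimnames = list("g1", "y"))
  expect_error(suppressWarnings(
    create_session("plate", junction_counts = jc, expression = expr,
                   annotation = ann,
                   cell_metadata = data.frame(cell_id = c("x", "y"),
                                              group = "G1"))),
    "intersection")
  gc <- matrix(1, 1, 2, dimnames = list("g1", c("x", "y")))
  expect_error(
    create_session("droplet", junction_counts = jc, expression = gc,
                   annotation = ann, gene_counts = gc,
                   cell_metadata = data.frame(cell_id = c("x", "y"),
                                              group = "G1")),
    "cell_type")
})
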