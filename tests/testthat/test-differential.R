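# Distribution-level two-sample tests, plate differential splicing,
# outlier removal, differential expression and the droplet permutation
# scheme

test_that("tie-adjusted rank statistic matches its direct formula", {
  set.seed(41)
  for (i in 1:20) {
    x <- round(runif(sample(5:40, 1)), 2)  # rounding forces ties
    y <- round(runif(sample(5:40, 1)), 2)
    ours <- scsplice:::.ecdf_stat_cpp(sort(x), sort(y), "ad")
    expect_equal(ours, oracle_ad(x, y), tolerance = 1e-10)
  }
})

test_that("ECDF-distance statistic matches its direct formula", {
  set.seed(42)
  for (i in 1:20) {
    x <- runif(sample(5:40, 1))
    y <- runif(sample(5:40, 1)) + 0.1
    ours <- scsplice:::.ecdf_stat_cpp(sort(x), sort(y), "dts")
    expect_equal(ours, oracle_dts(x, y), tolerance = 1e-10)
  }
})

test_that("distribution statistics are invariant to within-tie ordering", {
  x <- c(0.2, 0.2, 0.2, 0.5, 0.7)
  y <- c(0.2, 0.5, 0.5, 0.9, 0.9)
  for (m in c("ad", "dts")) {
    a <- scsplice:::.ecdf_stat_cpp(sort(x), sort(y), m)
    b <- scsplice:::.ecdf_stat_cpp(sort(rev(x)), sort(y), m)
    expect_equal(a, b)
  }
})

test_that("permutation p-values are smoothed and bounded below", {
  set.seed(43)
  x <- rbeta(40, 9, 1); y <- rbeta(40, 1, 9)  # extreme separation
  r <- two_sample_test(x, y, "ad", n_perm = 200)
  expect_equal(r$p_value, 1 / 201)
  r2 <- two_sample_test(x, x, "dts", n_perm = 200)
  expect_gte(r2$p_value, 1 / 201)
  expect_lte(r2$p_value, 1)
})

test_that("tests return NA for groups below two informative cells", {
  r <- two_sample_test(c(0.5), c(0.1, 0.9), "ad")
  expect_true(is.na(r$statistic) && is.na(r$p_value))
})

test_that("location-only tests agree with their reference procedures", {
  set.seed(44)
  x <- rbeta(30, 2, 5); y <- rbeta(30, 5, 2)
  w <- two_sample_test(x, y, "wilcoxon")
  expect_equal(w$p_value, suppressWarnings(wilcox.test(x, y)$p.value))
  k <- two_sample_test(x, y, "ks")
  expect_equal(k$p_value, suppressWarnings(ks.test(x, y)$p.value))
  t0 <- two_sample_test(rep(0.4, 5), rep(0.4, 6), "ttest")
  expect_equal(t0$p_value, 1)  # identical constant groups
})

test_that("events below 25 informative cells per pooled rule are skipped", {
  psi <- matrix(runif(2 * 60), 2, 60,
                dimnames = list(c("eA", "eB"), paste0("c", 1:60)))
  psi["eA", 25:60] <- NA  # 24 informative cells
  gl <- make_group_labels(30, 30, colnames(psi))
  set.seed(45)
  res <- differential_splicing_plate(psi, gl, n_perm = 100)
  expect_equal(res$event_id, "eB")
})

test_that("delta PSI is oriented by the declared group order in percent", {
  psi <- rbind(e1 = c(rep(0.2, 30), rep(0.7, 30)))
  colnames(psi) <- paste0("c", 1:60)
  gl <- make_group_labels(30, 30, colnames(psi))
  set.seed(46)
  res <- differential_splicing_plate(psi, gl, n_perm = 100)
  expect_equal(res$delta_psi, 50)
  set.seed(46)
  flipped <- differential_splicing_plate(psi, gl, n_perm = 100,
                                         group_order = c("G2", "G1"))
  expect_equal(flipped$delta_psi, -50)
  expect_equal(attr(flipped, "groups"), c("G2", "G1"))
})

test_that("either distribution test passing the FDR cut flags the event", {
  set.seed(47)
  n <- 40
  shift <- c(rbeta(n, 4, 8), rbeta(n, 8, 4))
  null1 <- runif(2 * n)
  psi <- rbind(shifted = shift, flat = null1)
  colnames(psi) <- paste0("c", 1:(2 * n))
  gl <- make_group_labels(n, n, colnames(psi))
  res <- differential_splicing_plate(psi, gl, n_perm = 400)
  expect_true(all(c("fdr_ad", "fdr_dts") %in% names(res)))
  sig_union <- (!is.na(res$fdr_ad) & res$fdr_ad < 0.10) |
    (!is.na(res$fdr_dts) & res$fdr_dts < 0.10)
  expect_equal(res$significant, sig_union & !res$outlier_removed)
  expect_true(res$significant[res$event_id == "shifted"])
})

test_that("significance driven by a handful of interior cells is removed", {
  cells <- paste0("c", 1:60)
  gl <- make_group_labels(30, 30, cells)
  # both groups have < 10 interior cells: removed
  drive <- c(rep(0, 25), runif(5, 0.3, 0.45),
             rep(1, 25), runif(5, 0.55, 0.7))
  # one group keeps >= 10 interior cells: retained
  keep <- c(runif(15, 0.1, 0.3), rep(0, 15), runif(15, 0.7, 0.9),
            rep(1, 15))
  psi <- rbind(driven = drive, genuine = keep)
  colnames(psi) <- cells
  res <- data.frame(event_id = c("driven", "genuine"),
                    stringsAsFactors = FALSE)
  out <- remove_outlier_events(res, psi, gl)
  expect_true(out$outlier_removed[out$event_id == "driven"])
  expect_false(out$outlier_removed[out$event_id == "genuine"])
  # the boundary is >= 10 interior cells in at least one group
  nine <- c(runif(9, 0.4, 0.6), rep(0, 21), runif(9, 0.4, 0.6), rep(1, 21))
  ten <- c(runif(10, 0.4, 0.6), rep(0, 20), runif(9, 0.4, 0.6), rep(1, 21))
  psi2 <- rbind(nine = nine, ten = ten)
  colnames(psi2) <- cells
  out2 <- remove_outlier_events(data.frame(event_id = c("nine", "ten")),
                                psi2, gl)
  expect_true(out2$outlier_removed[out2$event_id == "nine"])
  expect_false(out2$outlier_removed[out2$event_id == "ten"])
})

test_that("gene-level test detects the planted fold change with direction", {
  sim <- simulate_plate(differential_plan(10, 6), n_cells_per_group = 40,
                        seed = 48)
  gl <- setNames(sim$cell_metadata$group, sim$cell_metadata$cell_id)
  dg <- differential_genes(sim$expression, gl)
  planted <- sim$truth$gene_id[sim$truth$expr_log2fc > 0]
  expect_true(all(dg$direction[dg$gene_id %in% planted] == "up"))
  nulls <- sim$truth$gene_id[sim$truth$expr_log2fc == 0]
  expect_gte(mean(dg$direction[dg$gene_id %in% nulls] == "ns"), 0.8)
})

test_that("droplet feature filters match exhaustive rate enumeration", {
  set.seed(49)
  n_genes <- 20; n_cells <- 40
  cells <- paste0("c", 1:n_cells)
  gl <- make_group_labels(20, 20, cells)
  gc <- matrix(rbinom(n_genes * n_cells, 1, 0.3) *
                 rpois(n_genes * n_cells, 3),
               n_genes, n_cells,
               dimnames = list(paste0("g", 1:n_genes), cells))
  sj <- matrix(0L, 30, n_cells,
               dimnames = list(paste0("chr1:", 1:30 * 10, ":",
                                      1:30 * 10 + 5), cells))
  gene_of <- setNames(paste0("g", rep(1:n_genes, length.out = 30)),
                      rownames(sj))
  for (i in 1:30) sj[i, ] <- pmin(gc[gene_of[i], ],
                                  rbinom(n_cells, 2, 0.5))
  keep <- droplet_feature_filters(gc, sj, gl, gene_of)
  # plain-loop oracle
  rate <- function(m, idx) rowMeans(m[, idx, drop = FALSE] > 0)
  i1 <- gl == "G1"; i2 <- gl == "G2"
  genes_ok <- rownames(gc)[rate(gc, i1) >= 0.1 & rate(gc, i2) >= 0.1]
  sj_ok <- rownames(sj)[(rate(sj, i1) >= 0.1 | rate(sj, i2) >= 0.1) &
                          gene_of %in% genes_ok]
  expect_equal(keep$genes, genes_ok)
  expect_equal(keep$junctions, sj_ok)
})

test_that("droplet permutation p has the exact discrete lower bound", {
  sim <- simulate_droplet(droplet_plan(20, 3), n_cells_per_group = 60,
                          seed = 50)
  gl <- setNames(sim$cell_metadata$cell_type, sim$cell_metadata$cell_id)
  set.seed(50)
  res <- differential_splicing_droplet(sim$sj_counts, sim$gene_counts,
                                       sim$expression, gl,
                                       sim$gene_of_junction, n_perm = 100)
  expect_true(all(res$p_value >= 1 / 101, na.rm = TRUE))
  expect_equal(min(res$p_value, na.rm = TRUE), 1 / 101)
})

test_that("droplet significance requires expression, effect and p jointly", {
  sim <- simulate_droplet(droplet_plan(30, 4), n_cells_per_group = 80,
                          seed = 51)
  gl <- setNames(sim$cell_metadata$cell_type, sim$cell_metadata$cell_id)
  set.seed(51)
  res <- differential_splicing_droplet(sim$sj_counts, sim$gene_counts,
                                       sim$expression, gl,
                                       sim$gene_of_junction, n_perm = 100)
  manual <- !is.na(res$delta_psi) & !is.na(res$p_value) &
    res$mean_log2_expr > 1.0 & abs(res$delta_psi) > 5 & res$p_value < 0.05
  expect_equal(res$significant, manual)
  truth <- sim$truth$differential_truth[match(res$key, sim$truth$key)]
  expect_true(all(res$significant[truth]))
})
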