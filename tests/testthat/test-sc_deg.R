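test_that("QC thresholds follow the stated bounds", {
  cm <- toy_cells(umi = c(5000, 5000, 700, 22000, 699, 22001, 5000, 5000),
                  genes = c(300, 300, 200, 300, 300, 300, 199, 300),
                  mito = c(0.30, 0.25, 0, 0, 0, 0, 0, 0.249))
  kept <- qc_filter_cells(cm)
  # mito 0.30 and 0.25 removed (strict < 25%), boundary UMI/genes kept
  expect_setequal(kept$cell_data$cell, c("c3", "c4", "c8"))
  rem <- attr(kept, "qc_removed")
  expect_equal(unname(rem["mito"]), 2)
  expect_equal(unname(rem["umi"]), 2)
  expect_equal(unname(rem["genes"]), 1)
})

test_that("QC is the identity when every cell passes", {
  cm <- toy_cells(umi = rep(5000, 4), genes = rep(300, 4),
                  mito = rep(0.05, 4))
  kept <- qc_filter_cells(cm)
  expect_identical(as.matrix(kept$counts), as.matrix(cm$counts))
  expect_equal(unname(attr(kept, "qc_removed")["total"]), 0)
})

test_that("detection and fold-change filters exclude genes before testing", {
  set.seed(1)
  n <- 40
  counts <- matrix(rpois(3 * 2 * n, 5), nrow = 2 * n)
  # gene 1: expressed in exactly 5% of cells in both groups
  counts[, 1] <- 0
  counts[c(1, 2, n + 1, n + 2), 1] <- 3
  cd <- data.frame(cell = paste0("c", 1:(2 * n)),
                   group = rep(c("A", "B"), each = n), mito_frac = 0)
  cm <- cell_matrix(counts, cd)
  de <- group_de(cm, "A", "B", min_frac = 0.10, min_fold = 1.1)
  expect_false("g1" %in% de$gene)
  # genes with fold change inside (1/1.1, 1.1) are also excluded
  norm <- normalize_cells(cm)
  fold <- (expm1(colMeans(as.matrix(norm[1:n, ]))) + 1) /
    (expm1(colMeans(as.matrix(norm[(n + 1):(2 * n), ]))) + 1)
  inside <- colnames(counts) <- paste0("g", seq_len(ncol(counts)))
  excluded <- inside[fold < 1.1 & fold > 1 / 1.1]
  expect_true(all(!excluded %in% de$gene))
})

test_that("small-group p-values equal full rank enumeration", {
  set.seed(7)
  for (rep in 1:5) {
    x <- sample(0:4, 5, replace = TRUE)   # heavy ties
    y <- sample(0:4, 5, replace = TRUE)
    expect_equal(wilcox_exact_p(x, y), oracle_ranksum_p(x, y))
  }
  # tie-free case cross-checked against the standard exact test
  x <- c(1.2, 3.4, 0.5, 9.1, 2.2)
  y <- c(4.4, 5.1, 0.1, 7.7, 8.8)
  expect_equal(wilcox_exact_p(x, y),
               wilcox.test(x, y, exact = TRUE)$p.value)
})

test_that("group_de routes small groups through the exact test", {
  set.seed(3)
  counts <- matrix(rpois(10 * 6, 20), nrow = 10)
  cd <- data.frame(cell = paste0("c", 1:10),
                   group = rep(c("A", "B"), each = 5), mito_frac = 0)
  cm <- cell_matrix(counts, cd)
  de <- group_de(cm, "A", "B", min_frac = 0, min_fold = 1)
  norm <- as.matrix(normalize_cells(cm))
  for (i in seq_len(nrow(de))) {
    j <- match(de$gene[i], cm$genes)
    expect_equal(de$p[i], oracle_ranksum_p(norm[1:5, j], norm[6:10, j]))
  }
})

test_that("identical groups give zero fold change and no significance", {
  set.seed(11)
  counts <- matrix(rpois(20 * 30, 10), nrow = 20)
  counts <- rbind(counts, counts)     # group B duplicates group A
  cd <- data.frame(cell = paste0("c", 1:40),
                   group = rep(c("A", "B"), each = 20), mito_frac = 0)
  de <- group_de(cell_matrix(counts, cd), "A", "B", min_frac = 0,
                 min_fold = 1)
  expect_true(all(de$log2FC == 0))
  expect_true(all(!de$significant))
  expect_true(all(de$padj >= de$p))
})

test_that("results are invariant to gene ordering", {
  cfg <- small_sim(seed = 9)
  cm <- simulate_sc_experiment(cfg)$matrix
  de1 <- group_de(cm, "obese-vehicle", "lean-vehicle")
  perm <- sample(ncol(cm$counts))
  cm2 <- cell_matrix(cm$counts[, perm], cm$cell_data, cm$genes[perm])
  de2 <- group_de(cm2, "obese-vehicle", "lean-vehicle")
  de2 <- de2[match(de1$gene, de2$gene), ]
  expect_equal(de1$p, de2$p)
  expect_equal(de1$padj, de2$padj)
})

test_that("undersized groups raise an error naming the group", {
  counts <- matrix(rpois(5 * 4, 5), nrow = 5)
  cd <- data.frame(cell = paste0("c", 1:5),
                   group = c("A", "A", "A", "B", "B"), mito_frac = 0)
  cm <- cell_matrix(counts, cd)
  expect_error(group_de(cm, "A", "B"), "'B'")
  expect_error(group_de(cm, "A", "C"), "'C'")
})

test_that("marker detection applies the log-fold filter and finds
           planted markers", {
  cfg <- small_sim(seed = 4, frac_marker = 0.05,
                   n_cells_per_group = 150L)
  sc <- simulate_sc_experiment(cfg)
  mk <- cluster_markers(sc$matrix)
  planted <- sc$truth$gene[!is.na(sc$truth$marker_for)]
  found <- unlist(lapply(names(mk), function(k) {
    t1 <- mk[[k]]
    t1$gene[t1$significant]
  }))
  expect_gte(mean(planted %in% found), 0.8)
  # every reported marker clears the 0.25 log2FC bar
  for (t1 in mk) expect_true(all(t1$log2FC >= 0.25))
})

test_that("identical clusters yield no markers and singletons are
           skipped", {
  set.seed(2)
  half <- matrix(rpois(15 * 50, 10), nrow = 15)
  counts <- rbind(half, half)        # cluster t2 duplicates cluster t1
  cd <- data.frame(cell = paste0("c", 1:30),
                   cell_type = rep(c("t1", "t2"), each = 15),
                   group = "A", mito_frac = 0)
  mk <- cluster_markers(cell_matrix(counts, cd))
  sig <- unlist(lapply(mk, function(t1) sum(t1$significant)))
  expect_true(all(sig == 0))
  cd$cell_type[1] <- "lonely"
  expect_warning(cluster_markers(cell_matrix(counts, cd)), "singleton")
})
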