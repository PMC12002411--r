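de_table <- function(gene, lfc, padj) {
  data.frame(gene = gene, log2FC = lfc, padj = padj,
             significant = padj < 0.05, stringsAsFactors = FALSE)
}

test_that("reversal membership follows sign and significance", {
  de_ob <- de_table(c("a", "b", "c", "d"), c(2, -2, 1, 1),
                    c(0.01, 0.01, 0.01, 0.50))
  de_rosi <- de_table(c("a", "b", "c", "d"), c(-1, 3, 1, -1),
                      c(0.01, 0.01, 0.01, 0.01))
  sets <- classify_reversal(de_ob, de_rosi)
  expect_identical(sets$reversed_up, "a")
  expect_identical(sets$reversed_down, "b")
  expect_true("c" %in% sets$ob_up & "c" %in% sets$rosi_up)
  expect_false("d" %in% sets$ob_up)      # not significant in disease
  expect_length(intersect(sets$ob_up, sets$ob_down), 0)
})

test_that("identical contrasts produce empty reversed sets", {
  de <- de_table(letters[1:6], c(2, -2, 1, -1, 3, -3), rep(0.001, 6))
  sets <- classify_reversal(de, de)
  expect_length(sets$reversed_up, 0)
  expect_length(sets$reversed_down, 0)
})

test_that("duplicate identifiers are rejected with examples", {
  de <- de_table(c("a", "a", "b"), c(1, 1, 1), c(0.01, 0.01, 0.01))
  expect_error(classify_reversal(de, de_table("b", 1, 0.1)), "a")
})

test_that("upset counts are exclusive and conserve the union", {
  sets <- list(ob_up = "a", ob_down = "b", rosi_up = "c",
               rosi_down = "d")
  u <- upset_counts(sets)
  expect_equal(nrow(u), 4)
  expect_true(all(u$count == 1))
  # random sets: compare against a brute-force bitmask tally
  set.seed(20)
  for (rep in 1:5) {
    pool <- paste0("g", 1:40)
    sets <- list(ob_up = sample(pool, 15), ob_down = sample(pool, 12),
                 rosi_up = sample(pool, 18), rosi_down = sample(pool, 9))
    u <- upset_counts(sets)
    univ <- unique(unlist(sets))
    expect_equal(sum(u$count), length(univ))
    mask <- sapply(univ, function(g) paste(as.integer(
      c(g %in% sets$ob_up, g %in% sets$ob_down,
        g %in% sets$rosi_up, g %in% sets$rosi_down)), collapse = ""))
    expect_equal(sort(as.integer(u$count)),
                 sort(as.integer(table(mask))))
  }
  empty <- upset_counts(list(ob_up = character(0),
                             ob_down = character(0),
                             rosi_up = character(0),
                             rosi_down = character(0)))
  expect_equal(nrow(empty), 0)
})

test_that("enrichment score arithmetic is exact and linear in scale", {
  expect_identical(enrichment_score(10, 500, 200, 20000), 2)
  expect_identical(enrichment_score(0, 500, 200, 20000), 0)
  expect_equal(enrichment_score(5, 20000, 100), 0.05)
  s1 <- enrichment_score(7, 123, 456, 20000)
  expect_equal(enrichment_score(7, 123, 456, 40000), 2 * s1)
  expect_error(enrichment_score(1, 0, 10), "positive")
  expect_error(enrichment_score(1, 10, 0), "positive")
})

test_that("fisher enrichment matches the standard one-sided exact test", {
  set.seed(31)
  universe <- paste0("g", 1:60)
  for (rep in 1:10) {
    pw <- sample(universe, sample(5:30, 1))
    gs <- sample(universe, sample(5:30, 1))
    res <- fisher_enrichment(gs, list(p1 = pw), universe)
    x <- length(intersect(gs, pw))
    m <- matrix(c(x, length(gs) - x, length(pw) - x,
                  60 - length(gs) - length(pw) + x), 2)
    expect_equal(res$p, fisher.test(m, alternative = "greater")$p.value)
  }
  # disjoint pathway: one-sided p = 1
  res <- fisher_enrichment(paste0("g", 1:10),
                           list(p1 = paste0("g", 31:40)), universe)
  expect_equal(res$p, 1)
  expect_equal(res$overlap, 0)
  expect_equal(res$es, 0)
})

test_that("pathways are conditioned on the universe and empty queries warn", {
  universe <- paste0("g", 1:20)
  res <- fisher_enrichment(paste0("g", 1:5),
                           list(p1 = c(paste0("g", 1:4), "offworld1",
                                       "offworld2")), universe)
  expect_equal(res$pathway_size, 4)       # off-universe members dropped
  expect_warning(out <- fisher_enrichment(character(0),
                                          list(p1 = universe), universe),
                 "empty")
  expect_equal(nrow(out), 0)
})

test_that("pathway mean log2FC averages only significant overlap", {
  de <- de_table(c("a", "b", "c", "d"), c(1, 2, 5, 9),
                 c(0.01, 0.01, 0.01, 0.9))
  expect_equal(pathway_mean_log2fc(c("a", "b"), de), 1.5)
  expect_equal(pathway_mean_log2fc("a", de), 1)
  expect_true(is.na(pathway_mean_log2fc("d", de)))   # d not significant
  set.seed(5)
  de2 <- de_table(paste0("g", 1:50), rnorm(50), runif(50, 0, 0.2))
  pw <- paste0("g", sample(50, 20))
  hit <- de2$gene %in% pw & de2$significant
  expect_equal(pathway_mean_log2fc(pw, de2), mean(de2$log2FC[hit]))
})

test_that("planted reversed genes are recovered from simulated cells", {
  cfg <- sim_config(seed = 6, n_genes = 300L, n_cells_per_group = 500L,
                    effect_log2fc = 2, frac_reversed = 0.1,
                    qc_violation_frac = 0)
  sc <- simulate_sc_experiment(cfg)
  cm <- qc_filter_cells(sc$matrix)
  de_ob <- group_de(cm, "obese-vehicle", "lean-vehicle")
  de_rosi <- group_de(cm, "obese-drug", "obese-vehicle")
  sets <- classify_reversal(de_ob, de_rosi)
  up <- sc$truth$gene[sc$truth$class == "reversed_up"]
  dn <- sc$truth$gene[sc$truth$class == "reversed_down"]
  expect_gte(mean(up %in% sets$reversed_up), 0.8)
  expect_gte(mean(dn %in% sets$reversed_down), 0.8)
})
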