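unif_bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)

test_that("window counting follows the 6nt/1nt sliding rule", {
  kc <- count_kmers("GGGGGGG")
  expect_equal(unname(kc$counts["GGGGGG"]), 2)
  expect_equal(kc$n_windows, 2)
  kc2 <- count_kmers("ACGTAC")
  expect_equal(kc2$n_windows, 1)
  expect_equal(unname(kc2$counts["ACGTAC"]), 1)
  kc3 <- count_kmers(c("ACGTA", "ACGTAC"))   # 5-nt contributes nothing
  expect_equal(kc3$n_windows, 1)
  kcN <- count_kmers("ACGTNACGTACG")   # N at 0-based 4 kills windows 0..4
  expect_equal(kcN$n_windows, 2)
  expect_equal(kcN$n_skipped, 5)
  expect_equal(sum(kc$freq), 1)
  expect_error(count_kmers(character(0)), "empty")
})

test_that("enrichment z matches the pooled two-proportion formula", {
  mk <- function(counts, n) {
    structure(list(counts = counts, n_windows = n, n_skipped = 0,
                   freq = counts / n, k = 6), class = "kmer_counts")
  }
  words <- c("AAAAAA", "CCCCCC")
  fg <- mk(setNames(c(50, 950), words), 1000)
  bg <- mk(setNames(c(10, 990), words), 1000)
  z <- kmer_enrichment_z(fg, bg)
  phat <- (50 + 10) / 2000
  manual <- (0.05 - 0.01) / sqrt(phat * (1 - phat) * (2 / 1000))
  expect_equal(z$z[z$hexamer == "AAAAAA"], manual)
  # equal frequencies give z = 0; absent words give z = 0 by convention
  fg2 <- mk(setNames(c(30, 970, 0), c(words, "GGGGGG")), 1000)
  bg2 <- mk(setNames(c(30, 970, 0), c(words, "GGGGGG")), 1000)
  z2 <- kmer_enrichment_z(fg2, bg2)
  expect_true(all(z2$z == 0))
  # antisymmetry under swapping foreground and background
  z_swap <- kmer_enrichment_z(bg, fg)
  expect_equal(z_swap$z[match(z$hexamer, z_swap$hexamer)], -z$z)
})

test_that("PSSM construction matches the stated stacking rules", {
  m <- build_pssm("GGCGGG", pseudocount = 1, background = unif_bg)
  expect_equal(unname(m$counts["G", ]), c(1, 1, 0, 1, 1, 1))
  expect_equal(unname(m$counts["C", ]), c(0, 0, 1, 0, 0, 0))
  expect_equal(unname(colSums(m$counts)), rep(1, 6))
  expect_equal(unname(colSums(m$freq)), rep(1, 6))
  u <- build_pssm(c("AAAAAA", "CCCCCC", "GGGGGG", "TTTTTT"),
                  pseudocount = 0, background = unif_bg)
  expect_true(all(u$freq == 0.25))
  expect_true(all(u$weights == 0))
  expect_error(build_pssm(c("AAAAAA", "CCCCC")), "mixed")
  expect_error(build_pssm("AAAAAN"), "\\{A,C,G,T\\}")
})

test_that("scanning a uniform model yields no signal", {
  u <- build_pssm(c("AAAAAA", "CCCCCC", "GGGGGG", "TTTTTT"),
                  pseudocount = 0, background = unif_bg)
  s <- scan_sites("ACGTACGTACGT", u, background = unif_bg)
  expect_true(all(s$score == 0))
  expect_true(all(s$p == 1))
  expect_false(any(s$significant))
})

test_that("a perfect match attains p = 1/4096 under a uniform background", {
  m <- build_pssm("GGCGGG", background = unif_bg)
  s <- scan_sites("AAAGGCGGGTTT", m, background = unif_bg)
  hit <- s[s$start == 3, ]
  expect_equal(hit$p, 1 / 4096)
  expect_equal(hit$score, max(s$score))
  expect_true(hit$significant)
  # windows with N are skipped, positions stay 0-based
  sN <- scan_sites("NNNNNNGGCGGG", m, background = unif_bg)
  expect_equal(sN$start, 6)
})

test_that("exact scan p-values equal brute-force word enumeration", {
  set.seed(14)
  words <- replicate(4, paste(sample(c("A", "C", "G", "T"), 6,
                                     replace = TRUE), collapse = ""))
  bg <- c(A = 0.3, C = 0.2, G = 0.35, T = 0.15)
  m <- build_pssm(words, background = bg)
  seqc <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
  s <- scan_sites(seqc, m, background = bg)
  all_words <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")),
                                               6))[, 6:1])
  wscore <- round(vapply(all_words, function(w) {
    b <- strsplit(w, "")[[1]]
    sum(vapply(1:6, function(j) m$weights[b[j], j], numeric(1)))
  }, numeric(1)), 9)
  wprob <- vapply(all_words, function(w) {
    prod(bg[strsplit(w, "")[[1]]])
  }, numeric(1))
  for (i in seq_len(nrow(s)))
    expect_equal(s$p[i], sum(wprob[wscore >= s$score[i] - 1e-12]),
                 tolerance = 1e-12)
})

test_that("significance flag respects the 0.05 boundary strictly", {
  m <- build_pssm("GGCGGG", background = unif_bg)
  s <- scan_sites(paste(rep("ACGT", 30), collapse = ""), m,
                  background = unif_bg)
  expect_identical(s$significant, s$p < 0.05)
  above <- s[s$p >= 0.05, ]
  expect_true(nrow(above) > 0 && !any(above$significant))
})

test_that("feature maps order significant sites and keep empty entries", {
  sites <- list(
    tx1 = data.frame(start = c(10, 3, 7), score = 1, p = 0.01,
                     significant = c(TRUE, TRUE, FALSE)),
    tx2 = data.frame(start = 5, score = 1, p = 0.5,
                     significant = FALSE))
  fm <- feature_map(sites)
  expect_equal(fm$tx1, c(3, 10))
  expect_length(fm$tx2, 0)
  expect_named(fm, c("tx1", "tx2"))
  expect_equal(lengths(fm)[["tx1"]],
               sum(sites$tx1$p < 0.05 & sites$tx1$significant))
})

test_that("z-score correlations behave as Pearson r", {
  za <- data.frame(hexamer = c("AAAAAA", "CCCCCC", "GGGGGG", "TTTTTT"),
                   z = c(1, 2, 3, 4))
  expect_equal(score_correlation(za, za), 1)
  zb <- za
  zb$z <- -za$z
  expect_equal(score_correlation(za, zb), -1)
  expect_error(score_correlation(za[1:2, ], za[1:2, ]), "at least 3")
  set.seed(15)
  zc <- za
  zc$z <- rnorm(4)
  expect_equal(score_correlation(za, zc), cor(za$z, zc$z))
})

test_that("null enrichment exceedances match the binomial expectation", {
  # per-hexamer calibration: across null runs the mean number of
  # hexamers with z > 3 should not exceed 4096 * pnorm(-3) (~5.5) plus
  # Monte-Carlo error
  n_runs <- 20L
  exc <- integer(n_runs)
  for (run in seq_len(n_runs)) {
    cfg0 <- sim_config(seed = 7000L + run, motif_rate = 0)
    tx0 <- simulate_transcripts(cfg0, 200, 200)
    utr0 <- tx0$regions[tx0$regions$region == "5UTR", ]
    fg0 <- utr0$seq[utr0$tx %in% tx0$truth$foreground]
    bg0 <- utr0$seq[!utr0$tx %in% tx0$truth$foreground]
    z0 <- kmer_enrichment_z(count_kmers(fg0), count_kmers(bg0))
    exc[run] <- sum(z0$z > 3)
  }
  expectation <- 4096 * pnorm(-3)
  mc_se <- sd(exc) / sqrt(n_runs)
  expect_lte(mean(exc), expectation + 2 * mc_se)
})

test_that("planted hexamers dominate the enrichment ranking", {
  cfg <- sim_config(seed = 21, motif = "GGCGGG", motif_rate = 2)
  tx <- simulate_transcripts(cfg, 100, 100)
  utr <- tx$regions[tx$regions$region == "5UTR", ]
  fg <- utr$seq[utr$tx %in% tx$truth$foreground]
  bg <- utr$seq[!utr$tx %in% tx$truth$foreground]
  z <- kmer_enrichment_z(count_kmers(fg), count_kmers(bg))
  expect_identical(z$hexamer[1], "GGCGGG")
  expect_gt(z$z[1], 3)
})
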