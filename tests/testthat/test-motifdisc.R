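test_that("occurrence counting is overlapping, degenerate-aware and N-safe", {
  expect_equal(count_occurrences("GCAGCAGCAGC", "GCWGCWGC"),
               list(total = 2L, genes = 1L))
  expect_equal(count_occurrences("GCAGCAGC", "GCWGCWGC")$total, 1L)
  expect_equal(count_occurrences("GCTGCTGC", "GCWGCWGC")$total, 1L)
  expect_equal(count_occurrences(character(0), "ACGT"),
               list(total = 0L, genes = 0L))
  # N in the sequence matches no motif letter, including motif N
  expect_equal(count_occurrences("AANTT", "ANT")$total, 0L)
  expect_equal(count_occurrences("AAATT", "ANT")$total, 2L) # AAT and ATT
  # motif wider than every window
  expect_equal(count_occurrences(c("ACG", "TGA"), "ACGTACGT")$total, 0L)
  # exhaustive sliding-window oracle on random sequences
  set.seed(4)
  for (rep in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    motif <- paste(sample(c("A", "C", "G", "T", "W", "Y", "N"), 5, TRUE),
                   collapse = "")
    sets <- strsplit(Biostrings::IUPAC_CODE_MAP[strsplit(motif, "")[[1]]], "")
    naive <- sum(vapply(1:(60 - 5 + 1), function(off) {
      all(mapply(function(ch, set) ch %in% set,
                 strsplit(substr(s, off, off + 4), "")[[1]], sets))
    }, logical(1)))
    expect_equal(count_occurrences(s, motif)$total, naive)
  }
})

test_that("enrichment ratio follows the length-normalized formula", {
  expect_equal(enrichment_ratio(4, 1000, 10, 10000), 4)
  expect_equal(enrichment_ratio(5, 1000, 5, 1000), 1)
  expect_equal(enrichment_ratio(4, 1000, 10, 20000),
               2 * enrichment_ratio(4, 1000, 10, 10000))
  e <- enrichment_ratio(3, 1000, 0, 1000)
  expect_true(is.infinite(e))
  expect_true(attr(e, "zero_background"))
  expect_error(enrichment_ratio(-1, 10, 1, 10), "negative")
})

test_that("binomial p-value equals the exact tail summation", {
  expect_equal(binom_pvalue(0, 5, 0.1), 1)
  expect_equal(binom_pvalue(3, 5, 0.1), 0.00856, tolerance = 1e-10)
  expect_equal(binom_pvalue(5, 5, 1), 1)
  for (n in c(3, 10, 25)) {
    for (p in c(0.05, 0.3, 0.7)) {
      for (k in 0:n) {
        expect_equal(binom_pvalue(k, n, p), binom_tail_oracle(k, n, p),
                     tolerance = 1e-12)
      }
    }
  }
  # non-increasing in k for fixed n, p
  pv <- binom_pvalue(0:20, 20, 0.2)
  expect_true(all(diff(pv) <= 1e-15))
  expect_error(binom_pvalue(6, 5, 0.1), "lie in")
})

test_that("k-mer discovery recovers a planted motif and respects top_m", {
  reg <- random_background(80 * 300, window_length = 300, seed = 41)
  planted <- "ACGTACGT"
  set.seed(42)
  idx <- sample(nrow(reg), 48) # 60% of the regulon
  substr(reg$seq[idx], 101, 108) <- planted
  bg <- random_background(400 * 300, window_length = 300, seed = 43)
  res <- discover_kmers(reg, bg, k = 8, top_m = 50)
  expect_s3_class(res, "enrichment_results")
  expect_lte(nrow(res), 50)
  expect_lte(match(planted, res$motif), 10)
  expect_true(all(res$pvalue <= 0.001))
  # ranked by p-value
  expect_true(!is.unsorted(res$pvalue))
  res5 <- discover_kmers(reg, bg, k = 8, top_m = 5)
  expect_lte(nrow(res5), 5)
})

test_that("a regulon identical to its background yields no discovery", {
  w <- random_background(200 * 300, window_length = 300, seed = 7)
  res <- discover_kmers(w, w, k = 8, top_m = 50, alpha = 0.001)
  expect_equal(nrow(res), 0)
  # a subset null passes under Bonferroni correction over the 4^k family
  sub <- w[sample(nrow(w), 50), ]
  res_bonf <- discover_kmers(sub, w, k = 8, top_m = 50, alpha = 0.001,
                             bonferroni = TRUE)
  expect_equal(nrow(res_bonf), 0)
})

test_that("IUPAC merging groups Hamming neighbours and keeps distant motifs", {
  m <- merge_to_iupac(c("GCAGCAGC", "GCTGCTGC"), max_mismatch = 2)
  expect_equal(m$motif, "GCWGCWGC")
  expect_equal(m$source, "merged")
  single <- merge_to_iupac("CATGCATG")
  expect_equal(single$motif, "CATGCATG")
  far <- merge_to_iupac(c("AAAAAAAA", "TTTTTTTT"), max_mismatch = 1)
  expect_setequal(far$motif, c("AAAAAAAA", "TTTTTTTT"))
  expect_error(merge_to_iupac(c("ACGT", "ACGTA")), "equal width")
  # reversion: if the degenerate consensus dilutes enrichment below the
  # members' minimum, the group reverts to its members. Here each member is
  # 5-fold enriched, but the union consensus also matches the GCAGCTGC
  # variant that is common in the background only.
  reg <- as_promoter_windows(c("GCAGCAGCAA", "GCTGCTGCAA"), c(0, 10))
  bg <- as_promoter_windows(c("GCAGCAGCAA", "GCTGCTGCAA",
                              rep("GCAGCTGCAA", 8)), c(0, 10))
  rev <- merge_to_iupac(c("GCAGCAGC", "GCTGCTGC"), max_mismatch = 2,
                        regulon_windows = reg, background_windows = bg)
  expect_setequal(rev$motif, c("GCAGCAGC", "GCTGCTGC"))
  # without the background check the same pair merges
  kept <- merge_to_iupac(c("GCAGCAGC", "GCTGCTGC"), max_mismatch = 2)
  expect_equal(kept$motif, "GCWGCWGC")
})

test_that("random background is deterministic with the requested composition", {
  b1 <- random_background(4e5, window_length = 650, seed = 3)
  b2 <- random_background(4e5, window_length = 650, seed = 3)
  expect_identical(b1$seq, b2$seq)
  comp <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  u <- random_background(4e5, composition = comp, window_length = 650,
                         seed = 4)
  freq <- table(strsplit(paste(u$seq, collapse = ""), "")[[1]]) / 4e5
  expect_true(all(abs(freq - 0.25) < 0.005))
  expect_equal(sum(nchar(u$seq)), 4e5)
})

test_that("enrichment is invariant to window concatenation order", {
  w <- random_background(50 * 200, window_length = 200, seed = 12)
  set.seed(13)
  perm <- sample(nrow(w))
  a <- score_motif(w, w[perm, ], "CATGCATG")
  b <- score_motif(w[perm, ], w, "CATGCATG")
  expect_equal(a$enrichment, b$enrichment)
  expect_equal(a$k_reg, b$k_reg)
})

test_that("planted enrichment is at least as high against a random background", {
  ds <- small_dataset(seed = 22, plan = default_motif_plan(prob = 1))
  w <- extract_windows(ds$genome, ds$genes, c(-500, 150))
  storage <- w[w$gene_id %in%
                 names(ds$truth_labels)[ds$truth_labels == "storage"], ]
  vs_genes <- score_motif(storage, w, "CATGCATG")
  rnd <- random_background(sum(nchar(w$seq)),
                           composition = ds$config$base_composition,
                           window_length = 650, seed = 5)
  vs_random <- score_motif(storage, rnd, "CATGCATG")
  expect_gte(vs_random$enrichment, vs_genes$enrichment)
})
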