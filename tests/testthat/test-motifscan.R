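test_that("the bundled CRE catalog carries the expected consensi", {
  cat_ <- load_known_catalog()
  expect_equal(cat_$consensus[cat_$name == "IDRS"], "CCTCCAC")
  expect_equal(cat_$consensus[cat_$name == "IDEF1_binding"], "CATGCATG")
  expect_true(all(cat_$source %in% c("known-Fe", "PLACE-like")))
  # IDE2 bracket classes expand to IUPAC: CA[A/C]G[TC][T/C/A][T/C/A]
  ide2 <- cat_$consensus[cat_$name == "IDE2"]
  expect_equal(ide2, "CAMGYHH")
  expect_equal(count_occurrences("CAAGTTT", ide2)$total, 1L)
  expect_equal(count_occurrences("CACGCCA", ide2)$total, 1L)
  expect_equal(count_occurrences("CAGGTTT", ide2)$total, 0L)
  tmp <- tempfile(fileext = ".tsv")
  write_motif_tsv(cat_, tmp)
  expect_equal(read_motif_tsv(tmp), cat_)
})

test_that("PWM scoring matches closed-form and brute-force references", {
  # deterministic PWM: probability 1 on its consensus, uniform background
  probs <- diag(4)[c(1, 2, 3, 4), ] # consensus ACGT
  p <- pwm("det", probs, background = c(A = .25, C = .25, G = .25, T = .25))
  expect_equal(pwm_max_score(p), 4 * 2) # width x 2 bits
  hit <- pwm_logodds_scan("ACGT", p, threshold_fraction = 1)
  expect_equal(hit$offset, 0L)
  expect_equal(hit$score, 8)
  expect_equal(nrow(pwm_logodds_scan("ACGA", p, threshold_fraction = 1)), 0)
  # N contributes -Inf
  expect_equal(nrow(pwm_logodds_scan("ANGT", p, threshold_fraction = 0.1)), 0)

  set.seed(5)
  raw <- matrix(stats::rgamma(16, 1), 4)
  rp <- pwm("rand", raw / rowSums(raw))
  win <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  got <- pwm_logodds_scan(win, rp, threshold_fraction = 0.8)
  # brute-force enumeration oracle
  lo <- log2(rp$probs / rep(rp$background, each = 4))
  chars <- strsplit(win, "")[[1]]
  naive <- vapply(1:(30 - 4 + 1), function(off) {
    sum(vapply(1:4, function(j) lo[j, chars[off + j - 1]], numeric(1)))
  }, numeric(1))
  want <- which(naive >= 0.8 * pwm_max_score(rp)) - 1L
  expect_equal(got$offset, want)
  expect_equal(got$score, naive[want + 1L], tolerance = 1e-12)
})

test_that("PWM validation and MEME round trip work", {
  expect_error(pwm("bad", matrix(c(0.5, 0.5, 0.2, 0.3), 1)), "sum to 1")
  expect_error(pwm("bad", matrix(c(1, 0, 0, 0), 1),
                   background = c(A = 0, C = 0.5, G = 0.25, T = 0.25)),
               "zero background")
  set.seed(6)
  raw <- matrix(stats::rgamma(24, 1), 6)
  p <- pwm("m1", raw / rowSums(raw))
  tmp <- tempfile(fileext = ".meme")
  write_meme_pwm(list(p), tmp)
  back <- read_meme_pwm(tmp)[["m1"]]
  expect_equal(back$probs, p$probs, tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(back$background, p$background, tolerance = 1e-4)
})

test_that("presence matrix flags planted motifs and respects the window", {
  ds <- small_dataset(seed = 22, plan = default_motif_plan(prob = 1))
  w <- extract_windows(ds$genome, ds$genes, c(-500, 150))
  pm <- presence_matrix(w, load_known_catalog())
  expect_true(all(pm %in% c(0L, 1L)))
  # poly-A windows contain no C-rich catalog motif
  polyA <- as_promoter_windows(strrep("A", 650), c(-500, 150), "pa")
  expect_equal(sum(presence_matrix(polyA, load_known_catalog())["pa",
                     c("IDRS", "IDEF1_binding", "GCGC_box")]), 0L)
  # planted storage genes carry the IDEF1-binding site when the plant
  # position falls inside the search window
  hits <- ds$truth_hits[ds$truth_hits$motif == "CATGCATG" &
                          ds$truth_hits$rel_pos >= -500 &
                          ds$truth_hits$rel_pos <= 150 - 8, ]
  expect_true(all(pm[unique(hits$gene_id), "IDEF1_binding"] == 1L))
  expect_error(presence_matrix(w, rbind(load_known_catalog(),
                                        load_known_catalog()[1, ])),
               "duplicate")
})

test_that("window choice changes presence for TSS-downstream motifs", {
  seq650 <- strrep("T", 650)
  substr(seq650, 551, 558) <- "ATCGATCG" # rel position +50
  full <- as_promoter_windows(seq650, c(-500, 150), "g1")
  upstream <- as_promoter_windows(substr(seq650, 1, 500), c(-500, 0), "g1")
  cat_ <- load_known_catalog()
  expect_equal(presence_matrix(full, cat_)["g1", "DCEp2"], 1L)
  expect_equal(presence_matrix(upstream, cat_)["g1", "DCEp2"], 0L)
})

test_that("presence matrix is idempotent and order-invariant over genes", {
  ds <- small_dataset()
  w <- extract_windows(ds$genome, ds$genes, c(-500, 150))
  cat_ <- load_known_catalog()
  pm <- presence_matrix(w, cat_)
  expect_identical(presence_matrix(w, cat_), pm)
  set.seed(8)
  perm <- sample(nrow(w))
  pm2 <- presence_matrix(w[perm, ], cat_)
  expect_equal(pm2[rownames(pm), ], pm, ignore_attr = TRUE)
})

test_that("background-only presence matches the analytic approximation", {
  bg <- random_background(600 * 650, window_length = 650, seed = 9)
  pm <- presence_matrix(bg, data.frame(name = "probe",
                                       consensus = "ACGTCA", source = "x"))
  p_site <- prod(c(A = 0.26, C = 0.24, G = 0.24, T = 0.26)[
    strsplit("ACGTCA", "")[[1]]])
  analytic <- 1 - (1 - p_site)^(650 - 6 + 1)
  expect_lt(abs(mean(pm) - analytic), 0.03)
})
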