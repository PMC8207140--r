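make_noise_features <- function(n, p, seed) {
  set.seed(seed)
  matrix(stats::rbinom(n * p, 1, 0.3), n, p,
         dimnames = list(sprintf("g%04d", seq_len(n)),
                         sprintf("noise%02d", seq_len(p))))
}

test_that("shadow selection confirms a perfect feature and drops noise", {
  for (s in 1:3) {
    x <- make_noise_features(200, 10, seed = s)
    y <- factor(rep(c("a", "b"), each = 100))
    x <- cbind(signal = as.integer(y == "b"), x,
               flat = rep(1L, 200))
    sel <- shadow_select(x, y, max_iter = 20, seed = s)
    expect_true("signal" %in% sel$confirmed)
    expect_false("flat" %in% sel$confirmed)
    expect_equal(max(sel$importance_scaled), 100)
    expect_setequal(c(sel$confirmed, sel$tentative, sel$rejected),
                    colnames(x))
  }
})

test_that("pure-noise features are overwhelmingly rejected", {
  for (s in 1:2) {
    x <- make_noise_features(300, 30, seed = 10 + s)
    y <- factor(rep(c("a", "b"), each = 150))
    sel <- shadow_select(x, y, max_iter = 40, seed = s)
    expect_gte(length(sel$rejected) / ncol(x), 0.8)
    expect_length(sel$confirmed, 0)
  }
})

test_that("shadow selection validates its inputs", {
  x <- make_noise_features(50, 3, seed = 1)
  expect_error(shadow_select(x, rep("a", 50)), "2 classes")
  expect_error(shadow_select(x[, 0], rep(c("a", "b"), 25)), "feature")
})

test_that("a separable problem is classified perfectly", {
  classes <- regulon_classes()
  y <- factor(rep(classes, each = 40), levels = classes)
  x <- stats::model.matrix(~ y - 1)
  colnames(x) <- paste0("ind_", classes)
  x <- cbind(x, make_noise_features(200, 3, seed = 2))
  r <- fit_and_evaluate(x, y, seed = 1)
  expect_equal(r$balanced_accuracy, 1)
  expect_equal(r$auc_roc, 1)
  expect_true(all(r$confusion[row(r$confusion) != col(r$confusion)] == 0))
  expect_equal(diag(r$enrichment_pct), rep(100, 5), ignore_attr = TRUE)
})

test_that("confusion enrichment normalizes by predicted-class totals", {
  cc <- matrix(c(26, 13, 8, 13, 18), nrow = 1)
  expect_equal(enrichment_matrix(cc)[1, 1], 26 / 78 * 100)
  expect_equal(round(enrichment_matrix(matrix(c(45, 19), 1))[1, 1], 1), 70.3)
  id <- diag(4) * 25
  dimnames(id) <- list(letters[1:4], letters[1:4])
  expect_equal(diag(enrichment_matrix(id)), rep(100, 4), ignore_attr = TRUE)
  with_empty <- rbind(a = c(10, 5), b = c(0, 0))
  colnames(with_empty) <- c("a", "b")
  em <- enrichment_matrix(with_empty)
  expect_equal(attr(em, "empty_rows"), "b")
  expect_equal(unname(em["b", ]), c(0, 0))
  expect_error(enrichment_matrix(matrix(-1)), "nonnegative")
  # rows of a populated confusion always sum to 100
  set.seed(3)
  cc2 <- matrix(stats::rpois(25, 20) + 1, 5)
  expect_equal(unname(rowSums(enrichment_matrix(cc2))), rep(100, 5))
})

test_that("balanced accuracy anchors: constant predictor scores one half", {
  const <- rbind(yes = c(50, 50), no = c(0, 0))
  colnames(const) <- c("yes", "no")
  expect_equal(balanced_accuracy(const), 0.5)
  perfect <- diag(2) * 30
  dimnames(perfect) <- list(c("a", "b"), c("a", "b"))
  expect_equal(balanced_accuracy(perfect), 1)
})

test_that("reports are bit-identical for a fixed seed", {
  x <- make_noise_features(150, 8, seed = 4)
  x[, 1] <- as.integer(rep(c(0, 1, 0), each = 50))
  y <- factor(rep(c("a", "b", "c"), each = 50))
  r1 <- fit_and_evaluate(x, y, seed = 9)
  r2 <- fit_and_evaluate(x, y, seed = 9)
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$probabilities, r2$probabilities)
  expect_identical(r1$balanced_accuracy, r2$balanced_accuracy)
})

test_that("small classes are rejected with the class named", {
  x <- make_noise_features(24, 4, seed = 5)
  y <- factor(c(rep("big", 21), rep("tiny", 3)))
  expect_error(fit_and_evaluate(x, y, folds = 5), "tiny")
})

test_that("binary tissue model hits its anchors", {
  # a single perfectly predictive motif
  y <- factor(rep(c("none", "responsive"), each = 60))
  x <- cbind(motif = as.integer(y == "responsive"),
             make_noise_features(120, 4, seed = 6))
  r <- binary_tissue_model(x, y, seed = 2)
  expect_equal(r$auc_roc, 1)
  expect_equal(r$balanced_accuracy, 1)
  # null labels give chance-level AUC at n = 1000
  set.seed(7)
  xn <- make_noise_features(1000, 10, seed = 7)
  yn <- factor(sample(rep(c("none", "responsive"), each = 500)))
  rn <- binary_tissue_model(xn, yn, seed = 3)
  expect_lt(abs(rn$auc_roc - 0.5), 0.05)
  expect_error(binary_tissue_model(xn, factor(rep("a", 1000))), "2 classes")
})

test_that("a planted-signal tissue response is modeled above 85% accuracy", {
  plan <- do.call(rbind, lapply(c("storage", "uptake", "chelator", "wrky"),
                                function(cl) {
    data.frame(motif = c("CATGCATG", "CTACGTGC"), target_class = cl,
               prob = 0.7, pos_mean = -100, pos_sd = 150)
  }))
  ok <- vapply(1:3, function(s) {
    ds <- generate_dataset(synth_config(n_genes = 600, genes_per_contig = 30,
                                        motif_plan = plan, seed = s))
    w <- extract_windows(ds$genome, ds$genes, c(-500, 150))
    pm <- presence_matrix(w, load_known_catalog())
    y <- factor(ifelse(ds$truth_labels[rownames(pm)] == "none",
                       "none", "responsive"))
    binary_tissue_model(pm, y, seed = s)$balanced_accuracy >= 0.85
  }, logical(1))
  expect_gte(sum(ok), 2)
})
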