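test_that("class templates carry the qualitative response signs", {
  m <- class_templates_default()
  feex <- grep("^FeEx_", colnames(m))
  expect_true(all(m["storage", feex] > 0))
  expect_lt(m["storage", "FeDef_root"], 0)
  expect_true(all(m["none", ] == 0))
  # uptake flips sign against storage in Fe-excess root and Fe-def root
  expect_lt(m["uptake", "FeEx_root"] * m["storage", "FeEx_root"], 0)
  expect_lt(m["uptake", "FeDef_root"] * m["storage", "FeDef_root"], 0)
  expect_true(all(m["uptake", feex] < 0))
  expect_true(all(m["chelator", c(feex, which(colnames(m) == "ZnDef_root"))] > 0))
  expect_gt(m["wrky", "FeEx_stem"], 0)
  expect_lt(m["wrky", "FeDef_root"], 0)
})

test_that("zero noise reproduces the class templates exactly", {
  ds <- small_dataset(seed = 21, noise_sd = 0)
  tmpl <- class_templates_default()
  for (g in sample(rownames(ds$expression), 20)) {
    expect_equal(unname(ds$expression[g, ]),
                 unname(tmpl[ds$truth_labels[g], ]))
  }
})

test_that("probability-one planting marks every target gene", {
  plan <- default_motif_plan(prob = 1)
  ds <- small_dataset(seed = 22, plan = plan)
  storage <- names(ds$truth_labels)[ds$truth_labels == "storage"]
  hit_genes <- ds$truth_hits$gene_id[ds$truth_hits$motif == "CATGCATG"]
  expect_setequal(intersect(storage, hit_genes), storage)
  # planted instances are really present in the promoter at the recorded
  # TSS-relative position
  w <- extract_windows(ds$genome, ds$genes, c(-3000, 2000))
  rownames(w) <- w$gene_id
  hits <- ds$truth_hits[ds$truth_hits$motif == "CATGCATG", ]
  for (i in sample(nrow(hits), 15)) {
    off <- hits$rel_pos[i] + 3000
    expect_equal(substr(w[hits$gene_id[i], "seq"], off + 1, off + 8),
                 "CATGCATG")
  }
  # every truth hit lies inside the promoter span
  span <- ds$config$promoter_span
  expect_true(all(ds$truth_hits$rel_pos >= span$start_rel))
  expect_true(all(ds$truth_hits$rel_pos <= span$end_rel -
                    nchar(ds$truth_hits$motif)))
})

test_that("generation is bit-identical per seed and differs across seeds", {
  cfg <- synth_config(n_genes = 60, genes_per_contig = 30, seed = 5)
  d1 <- tempfile()
  d2 <- tempfile()
  write_dataset(generate_dataset(cfg), d1)
  write_dataset(generate_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  other <- generate_dataset(synth_config(n_genes = 60,
                                         genes_per_contig = 30, seed = 6))
  expect_false(identical(generate_dataset(cfg)$truth_hits, other$truth_hits))
})

test_that("background base frequencies converge to the configuration", {
  cfg <- synth_config(n_genes = 120, genes_per_contig = 60,
                      motif_plan = empty_plan(), seed = 8)
  ds <- generate_dataset(cfg) # 1.2 Mb of background
  freq <- colSums(Biostrings::letterFrequency(ds$genome,
                                              c("A", "C", "G", "T")))
  freq <- freq / sum(freq)
  expect_true(all(abs(freq - cfg$base_composition) < 0.01))
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(class_proportions = c(storage = 0.5, uptake = 0.5,
                                                  chelator = 0, wrky = 0,
                                                  none = 0.5)),
               "sum to 1")
  expect_error(synth_config(base_composition = c(A = 0.5, C = 0.5, G = 0.5,
                                                 T = 0.5)),
               "sum to 1")
  wide <- data.frame(motif = strrep("A", 6000), target_class = "storage",
                     prob = 1, pos_mean = 0, pos_sd = 1)
  expect_error(synth_config(motif_plan = wide), "wider than")
  expect_error(synth_config(promoter_span = c(-20000, 2000)),
               "exceed")
  bad_prob <- default_motif_plan()
  bad_prob$prob <- 1.5
  expect_error(synth_config(motif_plan = bad_prob), "probabilities")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
})

test_that("class apportionment and layout invariants hold", {
  ds <- small_dataset()
  expect_length(ds$truth_labels, 120)
  expect_true(all(table(ds$truth_labels) == 24))
  validate_gene_models(ds$genes, ds$genome) # must not error
  # promoter span fits inside each contig
  span <- ds$config$promoter_span
  lens <- stats::setNames(Biostrings::width(ds$genome), names(ds$genome))
  minus <- ds$genes$strand == "-"
  lo <- ifelse(minus, ds$genes$tss - span$end_rel + 1,
               ds$genes$tss + span$start_rel)
  hi <- ifelse(minus, ds$genes$tss - span$start_rel + 1,
               ds$genes$tss + span$end_rel)
  expect_true(all(lo >= 0 & hi <= lens[ds$genes$contig]))
})

test_that("Fe-level replicates merge back onto the tissue templates", {
  cfg <- synth_config(n_genes = 40, genes_per_contig = 20, noise_sd = 0,
                      fe_levels = c(10, 20, 50, 70), seed = 3)
  ds <- generate_dataset(cfg)
  expect_equal(ncol(ds$expression), 5 * 4 + 2)
  merged <- geometric_mean_merge(ds$expression, fe_level_groups(cfg))
  tmpl <- class_templates_default()
  expect_equal(unname(merged), unname(tmpl[ds$truth_labels, ]),
               ignore_attr = TRUE)
})
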