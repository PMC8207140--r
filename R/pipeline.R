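#' Run the full regulon-to-CRE analysis pipeline
#'
#' Simulate (or accept) a dataset, cluster genes into regulons, discover
#' regulon-enriched k-mers in the -500..+150 search window, build the
#' presence/absence feature matrix from the known catalog plus discovered
#' motifs, select all-relevant motifs with shadow features, fit and
#' cross-validate the expression-type classifier and a binary
#' responsive-vs-none model, compute a positional profile and fold-change
#' coverage for the top motif, and fit the YES/NO flowchart. All report
#' files are written under `out_dir`.
#'
#' @param config A [synth_config]; its seed drives every stochastic step.
#' @param out_dir Output directory.
#' @param dataset Optional pre-generated `synthetic_dataset` (the config of
#'   the dataset is then used).
#' @param search_window TSS-relative motif search window (default -500..+150).
#' @param profile_span Span of the positional profile (default -3000..+2000).
#' @param k K-mer width for discovery.
#' @param top_m Maximum discovered motifs per regulon.
#' @param alpha Discovery p-value cutoff.
#' @param select_iter Shadow-selection iterations.
#' @param folds CV folds.
#' @param n_none Number of least-affected genes taken as the no-response
#'   class (default 100).
#' @return A list with the dataset, regulon assignment, discovery tables,
#'   feature matrix, selection, classifier reports, profile, coverage and
#'   flowchart, plus `files` naming everything written.
#' @export
run_pipeline <- function(config = synth_config(), out_dir = tempfile("crelearn_"),
                         dataset = NULL, search_window = c(-500, 150),
                         profile_span = c(-3000, 2000), k = 8, top_m = 50,
                         alpha = 0.001, select_iter = 50, folds = 5,
                         n_none = 100) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  note <- function(path) {
    files <<- c(files, path)
    path
  }

  ## 1. data
  if (is.null(dataset)) dataset <- generate_dataset(config)
  config <- dataset$config
  write_dataset(dataset, file.path(out_dir, "data"))
  files <- c(files, file.path(out_dir, "data",
                              c("genome.fa", "genes.gff3", "genes.bed",
                                "expression.tsv", "truth.json",
                                "config.yaml")))

  ## 2. expression processing and regulon clustering
  expr <- dataset$expression
  if (!is.null(config$fe_levels)) {
    expr <- geometric_mean_merge(expr, fe_level_groups(config))
  }
  deg <- select_deg(expr, fold_threshold = 2)
  none <- select_no_response(expr, n = n_none)
  regulons <- cluster_regulons(expr, deg, none_genes = none)
  write_regulons_tsv(regulons, note(file.path(out_dir, "regulons.tsv")))
  assignment <- regulons$assignment

  ## 3. promoter windows and per-regulon k-mer discovery
  search_windows <- extract_windows(dataset$genome, dataset$genes,
                                    search_window)
  rownames(search_windows) <- search_windows$gene_id
  responsive <- setdiff(unique(assignment$label), "none")
  discovered <- list()
  for (lab in responsive) {
    reg_genes <- assignment$gene_id[assignment$label == lab]
    res <- discover_kmers(search_windows[search_windows$gene_id %in%
                                           reg_genes, ],
                          search_windows, k = k, top_m = top_m,
                          alpha = alpha)
    if (nrow(res) > 0) res$regulon <- lab
    write_enrichment_tsv(res, note(file.path(out_dir,
                                             paste0("enrichment_", lab,
                                                    ".tsv"))))
    discovered[[lab]] <- res
  }
  disc_all <- do.call(rbind, discovered)

  ## 4. feature matrix: catalog first, then novel discovered k-mers
  catalog <- load_known_catalog()
  novel <- unique(disc_all$motif)
  novel <- setdiff(novel, catalog$consensus)
  motif_set <- rbind(catalog[, c("name", "consensus", "source")],
                     if (length(novel)) data.frame(name = novel,
                                                   consensus = novel,
                                                   source = "discovered"))
  write_motif_tsv(motif_set, note(file.path(out_dir, "motifs.tsv")))
  features <- presence_matrix(search_windows, motif_set)
  write_feature_tsv(features, note(file.path(out_dir, "features.tsv")))

  ## 5. all-relevant selection and classification
  model_genes <- assignment$gene_id
  xmat <- features[model_genes, , drop = FALSE]
  labels <- factor(assignment$label,
                   levels = intersect(regulon_classes(),
                                      unique(assignment$label)))
  selection <- shadow_select(xmat, labels, max_iter = select_iter,
                             seed = config$seed)
  jsonlite::write_json(list(confirmed = selection$confirmed,
                            tentative = selection$tentative,
                            rejected = selection$rejected,
                            importance_scaled =
                              as.list(selection$importance_scaled)),
                       note(file.path(out_dir, "selection.json")),
                       auto_unbox = TRUE, digits = NA)
  model_features <- if (length(selection$confirmed) >= 2) {
    selection$confirmed
  } else {
    colnames(xmat)
  }
  report <- fit_and_evaluate(xmat, labels, folds = folds,
                             seed = config$seed,
                             feature_subset = model_features)
  write_report_json(report, note(file.path(out_dir, "report.json")))

  binary_labels <- factor(ifelse(labels == "none", "none", "responsive"),
                          levels = c("none", "responsive"))
  binary_report <- binary_tissue_model(xmat, binary_labels, folds = folds,
                                       seed = config$seed,
                                       feature_subset = model_features)
  write_report_json(binary_report,
                    note(file.path(out_dir, "report_binary.json")))

  ## 6. positional profile and coverage for the leading motif
  lead_name <- if (length(selection$confirmed)) {
    names(selection$importance_scaled)[
      names(selection$importance_scaled) %in% selection$confirmed][1]
  } else {
    colnames(xmat)[1]
  }
  lead_consensus <- motif_set$consensus[match(lead_name, motif_set$name)]
  wide_windows <- extract_windows(dataset$genome, dataset$genes,
                                  profile_span)
  hits <- motif_hits(wide_windows, lead_consensus)
  lead_regulon <- responsive[which.max(vapply(responsive, function(lab) {
    g <- assignment$gene_id[assignment$label == lab]
    mean(features[g, lead_name])
  }, numeric(1)))]
  set_genes <- assignment$gene_id[assignment$label == lead_regulon]
  profile <- positional_profile(hits, set_genes, dataset$genes$gene_id,
                                span = profile_span)
  utils::write.table(profile, note(file.path(out_dir, "profile.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fe_root_col <- grep("FeEx_root", colnames(expr), value = TRUE)[1]
  coverage <- coverage_by_foldchange(
    stats::setNames(features[model_genes, lead_name], model_genes),
    2^expr[model_genes, fe_root_col])
  utils::write.table(coverage, note(file.path(out_dir, "coverage.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## 7. flowchart on the balanced (undersampled) set
  set.seed(config$seed)
  bal <- sort(undersample_idx(labels))
  flow <- fit_flowchart(xmat[bal, model_features, drop = FALSE], labels[bal])
  writeLines(render_flowchart(flow),
             note(file.path(out_dir, "flowchart.txt")))
  flowchart_to_json(flow, note(file.path(out_dir, "flowchart.json")))
  flow_cv <- cv_flowchart(xmat[, model_features, drop = FALSE], labels,
                          folds = folds, seed = config$seed)

  structure(list(dataset = dataset, regulons = regulons,
                 discovered = discovered, motif_set = motif_set,
                 features = features, selection = selection,
                 report = report, binary_report = binary_report,
                 lead_motif = list(name = lead_name,
                                   consensus = lead_consensus,
                                   regulon = lead_regulon),
                 profile = profile, coverage = coverage, flowchart = flow,
                 flowchart_cv = flow_cv, out_dir = out_dir, files = files),
            class = "crelearn_pipeline")
}

#' @export
print.crelearn_pipeline <- function(x, ...) {
  cat("<crelearn_pipeline> output in", x$out_dir, "\n")
  cat("  regulons:", paste(names(x$discovered), collapse = ", "), "\n")
  cat("  discovered motifs:",
      sum(vapply(x$discovered, nrow, integer(1))), "\n")
  cat(sprintf("  balanced accuracy: %.3f (multiclass), %.3f (binary)\n",
              x$report$balanced_accuracy,
              x$binary_report$balanced_accuracy))
  cat(sprintf("  flowchart CV accuracy: %.3f\n", x$flowchart_cv$accuracy))
  invisible(x)
}
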