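#' Default expression templates for the five regulon classes
#'
#' Returns a 5 x 7 matrix of log2(treated/control) class templates over the
#' seven standard conditions: Fe excess in five tissues (newest leaf, old
#' leaf, stem, discrimination centre, root; each already merged over Fe
#' levels), Fe-deficient root, and Zn-deficient root. Sign structure follows
#' the four co-expression classes described for Fe excess-responsive rice
#' genes: Fe storage genes up under Fe excess in all tissues and down in
#' Fe-deficient roots; Fe uptake genes suppressed under Fe excess
#' (most strongly in roots) and induced in Fe-deficient roots; metal
#' chelator genes up under Fe excess and Zn deficiency; WRKY co-expression
#' genes up in stems under Fe excess and down in Fe-deficient roots. The
#' no-response class is all zeros. Magnitudes are package choices (the source
#' patterns are qualitative) set so that row-centred templates are close to
#' orthogonal, which keeps the classes separable by signed-correlation
#' clustering.
#'
#' @return A numeric matrix with rows `storage`, `uptake`, `chelator`,
#'   `wrky`, `none` and columns named by [default_condition_names()].
#' @export
class_templates_default <- function() {
  conds <- default_condition_names()
  m <- rbind(
    storage  = c( 2.0,  2.0,  2.0,  2.0,  2.0, -2.0, -1.0),
    uptake   = c(-1.0, -1.0, -1.0, -1.0, -2.5,  2.0,  1.0),
    chelator = c( 1.0,  1.0,  1.0,  1.0,  1.0, -1.0,  3.0),
    wrky     = c(-0.5, -0.5,  2.0, -0.5, -0.5, -1.0,  0.0),
    none     = c( 0.0,  0.0,  0.0,  0.0,  0.0,  0.0,  0.0)
  )
  colnames(m) <- conds
  m
}

#' Names of the seven default conditions
#'
#' @return Character vector: Fe excess in five tissues, Fe-deficient root,
#'   Zn-deficient root.
#' @export
default_condition_names <- function() {
  c("FeEx_newest_leaf", "FeEx_old_leaf", "FeEx_stem", "FeEx_DC", "FeEx_root",
    "FeDef_root", "ZnDef_root")
}

#' Class labels used throughout the package
#' @return Character vector of the five regulon class labels.
#' @export
regulon_classes <- function() {
  c("storage", "uptake", "chelator", "wrky", "none")
}

#' Default motif planting plan
#'
#' One diagnostic promoter motif per responsive class, drawn from the known
#' catalog: the IDEF1-binding CATGCATG for Fe storage, the bZIP/bHLH-binding
#' CTACGTGC for Fe uptake, the DCEp1 AGCTAGCT for metal chelator, and the
#' novel Myb binding-like CACCAACC for the WRKY co-expression class. Planted
#' positions are TSS-proximal, Normal(-100, 150) relative to the TSS.
#'
#' @param prob Plant probability per gene of the target class.
#' @return A data.frame with columns `motif`, `target_class`, `prob`,
#'   `pos_mean`, `pos_sd`.
#' @export
default_motif_plan <- function(prob = 0.7) {
  data.frame(
    motif = c("CATGCATG", "CTACGTGC", "AGCTAGCT", "CACCAACC"),
    target_class = c("storage", "uptake", "chelator", "wrky"),
    prob = prob,
    pos_mean = -100,
    pos_sd = 150,
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic dataset generator
#'
#' @param n_genes Number of genes.
#' @param class_proportions Named fractions over the five classes; must sum
#'   to 1.
#' @param promoter_span Length-2 vector, TSS-relative span (half-open) inside
#'   which motifs may be planted; default -3000..+2000.
#' @param base_composition Named per-base probabilities (A, C, G, T) for the
#'   i.i.d. background; must sum to 1. The default A=T=0.26, C=G=0.24 is the
#'   normalized strand-pooled promoter composition used for PWM scanning.
#' @param motif_plan Data.frame as returned by [default_motif_plan()].
#' @param condition_names Condition (column) names of the expression matrix.
#' @param class_means Class x condition log2-ratio template matrix.
#' @param noise_sd Per-condition Gaussian noise, log2 units.
#' @param fe_levels Optional numeric vector of Fe excess levels (e.g.
#'   `c(10, 20, 50, 70)`). When given, each Fe excess tissue column is
#'   expanded into one column per level (same class mean, independent noise),
#'   to be merged back with [geometric_mean_merge()].
#' @param genes_per_contig Genes per synthetic contig.
#' @param gene_length Gene body length in bp.
#' @param contig_spacing Spacing between successive TSSs on a contig.
#' @param seed Integer RNG seed; the full dataset is a deterministic function
#'   of the configuration.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 1500,
                         class_proportions = c(storage = 0.2, uptake = 0.2,
                                               chelator = 0.2, wrky = 0.2,
                                               none = 0.2),
                         promoter_span = c(-3000, 2000),
                         base_composition = c(A = 0.26, C = 0.24,
                                              G = 0.24, T = 0.26),
                         motif_plan = default_motif_plan(),
                         condition_names = default_condition_names(),
                         class_means = class_templates_default(),
                         noise_sd = 0.5,
                         fe_levels = NULL,
                         genes_per_contig = 50,
                         gene_length = 3000,
                         contig_spacing = 10000,
                         seed = 1) {
  stopifnot(n_genes >= 1, genes_per_contig >= 1, gene_length >= 1)
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class_proportions must sum to 1")
  }
  if (!setequal(names(class_proportions), regulon_classes())) {
    stop("class_proportions must be named by the five regulon classes")
  }
  if (abs(sum(base_composition) - 1) > 1e-9) {
    stop("base_composition must sum to 1")
  }
  if (!setequal(names(base_composition), c("A", "C", "G", "T"))) {
    stop("base_composition must be named A, C, G, T")
  }
  span <- as_window_spec(promoter_span)
  if (nrow(motif_plan) > 0) {
    if (any(motif_plan$prob < 0 | motif_plan$prob > 1)) {
      stop("motif plant probabilities must lie in [0, 1]")
    }
    if (any(nchar(motif_plan$motif) > span$length)) {
      stop("motif wider than promoter_span")
    }
    if (!all(motif_plan$target_class %in% regulon_classes())) {
      stop("unknown target_class in motif_plan")
    }
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!identical(dim(class_means),
                 c(length(regulon_classes()), length(condition_names)))) {
    stop("class_means must be ", length(regulon_classes()), " x ",
         length(condition_names))
  }
  # every promoter span must fit in the contig around its TSS
  flank_left <- -span$start_rel
  flank_right <- span$end_rel
  min_flank <- max(flank_left, flank_right, gene_length)
  if (contig_spacing < min_flank) {
    stop("contig_spacing too small for promoter_span/gene_length: ",
         "spans would exceed the generated contig")
  }
  structure(list(n_genes = as.integer(n_genes),
                 class_proportions = class_proportions[regulon_classes()],
                 promoter_span = span,
                 base_composition = base_composition[c("A", "C", "G", "T")],
                 motif_plan = motif_plan,
                 condition_names = condition_names,
                 class_means = class_means,
                 noise_sd = noise_sd,
                 fe_levels = fe_levels,
                 genes_per_contig = as.integer(genes_per_contig),
                 gene_length = as.integer(gene_length),
                 contig_spacing = as.integer(contig_spacing),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Resolve IUPAC degenerate letters uniformly among their allowed bases.
resolve_iupac <- function(consensus) {
  letters_ <- strsplit(consensus, "")[[1]]
  vapply(letters_, function(l) {
    bases <- strsplit(Biostrings::IUPAC_CODE_MAP[[toupper(l)]], "")[[1]]
    if (length(bases) == 1L) bases else sample(bases, 1L)
  }, character(1), USE.NAMES = FALSE) |> paste(collapse = "")
}

#' Generate a synthetic genome, gene models, promoters and expression matrix
#'
#' Background bases are i.i.d. from the configured composition; genes are
#' laid out on contigs of `genes_per_contig` genes with `contig_spacing` bp
#' between successive TSSs, strands drawn uniformly. For each gene of a
#' motif's target class the motif is planted with the configured probability
#' at a TSS-relative position drawn Normal(mean, sd), clipped to the
#' promoter span; planted instances overwrite background bases so that all
#' coordinates stay TSS-aligned. Expression rows are the class template plus
#' i.i.d. Gaussian noise. The whole dataset is deterministic for a fixed
#' seed.
#'
#' @param config A [synth_config].
#' @return A list of class `synthetic_dataset` with elements `genome`
#'   (`DNAStringSet`), `genes` (`gene_models`), `expression` (gene x
#'   condition matrix of log2 ratios), `truth_labels` (named character),
#'   `truth_hits` (data.frame `gene_id`, `motif`, `rel_pos`), and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_genes
  classes <- regulon_classes()

  # class assignment: largest-remainder apportionment, then shuffle
  target <- config$class_proportions * n
  counts <- floor(target)
  rem <- n - sum(counts)
  if (rem > 0) {
    order_frac <- order(target - counts, decreasing = TRUE)
    counts[order_frac[seq_len(rem)]] <- counts[order_frac[seq_len(rem)]] + 1
  }
  labels <- sample(rep(classes, times = counts))
  gene_ids <- sprintf("g%05d", seq_len(n))
  names(labels) <- gene_ids

  # gene layout
  K <- config$genes_per_contig
  contig_idx <- (seq_len(n) - 1L) %/% K
  within_idx <- (seq_len(n) - 1L) %% K
  contigs <- sprintf("ctg%03d", sort(unique(contig_idx)) + 1L)
  contig_of <- contigs[contig_idx + 1L]
  half <- config$contig_spacing %/% 2L
  tss <- within_idx * config$contig_spacing + half
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tes <- ifelse(strand == "-", tss - config$gene_length + 1L,
                tss + config$gene_length - 1L)
  genes <- gene_models_df(gene_ids, contig_of, strand, tss, tes)

  # background contigs
  n_on <- tabulate(contig_idx + 1L)
  contig_len <- n_on * config$contig_spacing
  bases <- names(config$base_composition)
  seqs <- vapply(contig_len, function(L) {
    paste(sample(bases, L, replace = TRUE, prob = config$base_composition),
          collapse = "")
  }, character(1))
  names(seqs) <- contigs

  # plant motifs
  span <- config$promoter_span
  hits <- list()
  plan <- config$motif_plan
  if (!is.null(plan) && nrow(plan) > 0) {
    for (p in seq_len(nrow(plan))) {
      w <- nchar(plan$motif[p])
      target_genes <- which(labels == plan$target_class[p])
      for (gi in target_genes) {
        if (stats::runif(1) >= plan$prob[p]) next
        r <- round(stats::rnorm(1, plan$pos_mean[p], plan$pos_sd[p]))
        r <- min(max(r, span$start_rel), span$end_rel - w)
        inst <- resolve_iupac(plan$motif[p])
        ctg <- contig_of[gi]
        if (strand[gi] == "+") {
          g0 <- tss[gi] + r # 0-based start
          substr(seqs[ctg], g0 + 1L, g0 + w) <- inst
        } else {
          g0 <- tss[gi] - r - w + 1L
          substr(seqs[ctg], g0 + 1L, g0 + w) <- as.character(
            Biostrings::reverseComplement(Biostrings::DNAString(inst)))
        }
        hits[[length(hits) + 1L]] <- data.frame(
          gene_id = gene_ids[gi], motif = plan$motif[p], rel_pos = r,
          stringsAsFactors = FALSE)
      }
    }
  }
  truth_hits <- if (length(hits)) do.call(rbind, hits) else {
    data.frame(gene_id = character(), motif = character(),
               rel_pos = integer(), stringsAsFactors = FALSE)
  }

  # expression matrix
  conds <- expand_condition_names(config)
  expr <- matrix(0, nrow = n, ncol = length(conds),
                 dimnames = list(gene_ids, conds))
  mu <- expand_class_means(config)
  for (i in seq_len(n)) {
    expr[i, ] <- mu[labels[i], ] +
      stats::rnorm(length(conds), 0, config$noise_sd)
  }

  structure(list(genome = Biostrings::DNAStringSet(seqs),
                 genes = genes,
                 expression = expr,
                 truth_labels = labels,
                 truth_hits = truth_hits,
                 config = config),
            class = "synthetic_dataset")
}

# Fe-level expansion: FeEx tissue columns become tissue_x<level> replicates.
expand_condition_names <- function(config) {
  if (is.null(config$fe_levels)) return(config$condition_names)
  unlist(lapply(config$condition_names, function(cn) {
    if (grepl("^FeEx_", cn)) paste0(cn, "_x", config$fe_levels) else cn
  }))
}

expand_class_means <- function(config) {
  if (is.null(config$fe_levels)) return(config$class_means)
  reps <- ifelse(grepl("^FeEx_", config$condition_names),
                 length(config$fe_levels), 1L)
  m <- config$class_means[, rep(seq_along(config$condition_names), reps),
                          drop = FALSE]
  colnames(m) <- expand_condition_names(config)
  m
}

#' Column groups mapping Fe-level-expanded conditions back to tissues
#'
#' @param config A [synth_config] with non-NULL `fe_levels`.
#' @return A named list of column-name groups usable with
#'   [geometric_mean_merge()].
#' @export
fe_level_groups <- function(config) {
  stats::setNames(lapply(config$condition_names, function(cn) {
    if (grepl("^FeEx_", cn)) paste0(cn, "_x", config$fe_levels) else cn
  }), config$condition_names)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>", x$config$n_genes, "genes on",
      length(x$genome), "contigs;",
      ncol(x$expression), "conditions;",
      nrow(x$truth_hits), "planted motif instances\n")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes `genome.fa`, `genes.gff3`, `genes.bed`, `expression.tsv` (gene id
#' plus one log2-ratio column per condition), `truth.json` (labels and
#' planted hits) and `config.yaml`.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(dataset$genome, file.path(dir, "genome.fa"))
  write_gene_models_gff3(dataset$genes, file.path(dir, "genes.gff3"))
  write_gene_models_bed(dataset$genes, file.path(dir, "genes.bed"))
  write_expression_tsv(dataset$expression, file.path(dir, "expression.tsv"))
  truth <- list(labels = as.list(dataset$truth_labels),
                hits = dataset$truth_hits)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- dataset$config
  yaml::write_yaml(list(
    n_genes = cfg$n_genes,
    class_proportions = as.list(cfg$class_proportions),
    promoter_span = c(cfg$promoter_span$start_rel, cfg$promoter_span$end_rel),
    base_composition = as.list(cfg$base_composition),
    motif_plan = cfg$motif_plan,
    condition_names = cfg$condition_names,
    noise_sd = cfg$noise_sd,
    fe_levels = cfg$fe_levels,
    genes_per_contig = cfg$genes_per_contig,
    gene_length = cfg$gene_length,
    contig_spacing = cfg$contig_spacing,
    seed = cfg$seed), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Write / read an expression matrix as TSV
#'
#' @param expression Gene x condition numeric matrix.
#' @param path File path.
#' @return For the reader, a numeric matrix with gene ids as rownames.
#' @export
write_expression_tsv <- function(expression, path) {
  df <- data.frame(gene_id = rownames(expression), expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
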