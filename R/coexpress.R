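#' Merge treatment levels by geometric mean of expression ratios
#'
#' Columns of a log2-ratio matrix mapped to the same output column are
#' averaged arithmetically in log2 space, which equals the log2 of the
#' geometric mean of the underlying ratios. Used to merge the Fe-excess
#' treatment levels of a tissue into one column before network analysis.
#'
#' @param expression Gene x condition matrix of log2 ratios.
#' @param groups Named list; each element is a character vector of input
#'   column names merged into the output column named by the element.
#' @return A gene x group log2-ratio matrix.
#' @examples
#' m <- matrix(c(1, 3), 1, 2, dimnames = list("g1", c("a", "b")))
#' geometric_mean_merge(m, list(ab = c("a", "b"))) # log2 of sqrt(2*8) = 2
#' @export
geometric_mean_merge <- function(expression, groups) {
  stopifnot(is.matrix(expression), is.list(groups), length(groups) > 0)
  out <- vapply(groups, function(cols) {
    if (length(cols) == 0L) stop("empty merge group")
    missing <- setdiff(cols, colnames(expression))
    if (length(missing)) {
      stop("merge group refers to unknown column(s): ",
           paste(missing, collapse = ", "))
    }
    rowMeans(expression[, cols, drop = FALSE])
  }, numeric(nrow(expression)))
  if (nrow(expression) == 1L) out <- matrix(out, nrow = 1L,
                                            dimnames = list(rownames(expression),
                                                            names(groups)))
  out
}

#' Select differentially expressed genes by fold-change threshold
#'
#' A gene is kept iff the maximum over conditions of its absolute log2 ratio
#' reaches `log2(fold_threshold)`. The standard thresholds are 2-fold
#' (|log2| >= 1) and, for Fe-deficient roots, 2.82-fold (|log2| >= 1.5).
#'
#' @param expression Gene x condition log2-ratio matrix.
#' @param fold_threshold Fold-change threshold on the ratio scale (> 1).
#' @return Character vector of gene ids.
#' @export
select_deg <- function(expression, fold_threshold = 2) {
  stopifnot(fold_threshold > 1)
  m <- apply(abs(expression), 1, max)
  rownames(expression)[m >= log2(fold_threshold)]
}

#' Select the least-affected (no-response) genes
#'
#' Returns the `n` genes with the smallest maximum absolute log2 ratio,
#' restricted to genes below two-fold in every condition; ties are broken by
#' gene id so the selection is deterministic. If fewer than `n` genes are
#' eligible, all eligible genes are returned with a warning.
#'
#' @param expression Gene x condition log2-ratio matrix.
#' @param n Number of genes to select (default 100).
#' @return Character vector of gene ids, sorted by gene id.
#' @export
select_no_response <- function(expression, n = 100) {
  m <- apply(abs(expression), 1, max)
  eligible <- which(m < 1) # below two-fold everywhere
  if (length(eligible) < n) {
    warning("only ", length(eligible), " genes below two-fold; returning all")
    n <- length(eligible)
  }
  ids <- rownames(expression)[eligible]
  ord <- order(m[eligible], ids)
  sort(ids[ord][seq_len(n)])
}

#' Topological overlap matrix
#'
#' `TOM[i, j] = (sum_u a[i, u] a[u, j] + a[i, j]) /
#' (min(k_i, k_j) + 1 - a[i, j])` with `k_i = sum_u a[i, u]`, and
#' `TOM[i, i] = 1`. Shared-neighbour similarity used for co-expression
#' clustering.
#'
#' @param adjacency Symmetric matrix with zero diagonal and entries in
#'   `[0, 1]`.
#' @return The TOM matrix (entries in `[0, 1]`, unit diagonal).
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-10)) {
    stop("adjacency must be symmetric")
  }
  if (any(diag(a) != 0)) stop("adjacency must have zero diagonal")
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]")
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Clustering parameters for regulon assignment
#'
#' @param beta Soft-threshold power for the signed adjacency (default 6, the
#'   common signed-network default).
#' @param k_modules Number of modules cut from the dendrogram (default 4).
#' @param linkage Hierarchical linkage (default "average").
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(beta = 6, k_modules = 4, linkage = "average") {
  stopifnot(beta >= 1, k_modules >= 2)
  structure(list(beta = beta, k_modules = as.integer(k_modules),
                 linkage = linkage),
            class = "cluster_params")
}

#' Cluster differentially expressed genes into labeled regulons
#'
#' Builds a signed weighted correlation network on the DEG genes
#' (`a_ij = ((1 + r_ij) / 2)^beta`, Pearson `r` across conditions), converts
#' it to topological overlap, clusters `1 - TOM` by average-linkage
#' hierarchical clustering, and cuts the tree into `k_modules` modules. Each
#' module is labeled by the responsive class template whose cosine
#' similarity with the module's centroid (mean log2-ratio profile) is
#' maximal, with ties resolved greedily so that no label is used twice.
#' Genes supplied in `none_genes` are appended with label `"none"`.
#' Constant-expression (zero-variance) genes are excluded with a warning.
#'
#' @param expression Gene x condition log2-ratio matrix.
#' @param deg_genes Character vector of DEG gene ids to cluster.
#' @param none_genes Optional character vector of no-response gene ids.
#' @param params A [cluster_params].
#' @param templates Class x condition template matrix used for labeling;
#'   defaults to the four responsive rows of [class_templates_default()],
#'   matched to `colnames(expression)`.
#' @return A list of class `regulon_assignment` with `assignment`
#'   (data.frame `gene_id`, `label`, `module_id`), `centroids` (label x
#'   condition matrix), and `params`.
#' @export
cluster_regulons <- function(expression, deg_genes, none_genes = NULL,
                             params = cluster_params(), templates = NULL) {
  stopifnot(inherits(params, "cluster_params"))
  deg_genes <- sort(intersect(deg_genes, rownames(expression)))
  if (length(deg_genes) < params$k_modules) {
    stop("need at least k_modules (", params$k_modules, ") DEG genes")
  }
  x <- expression[deg_genes, , drop = FALSE]
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " constant-expression gene(s) excluded")
    x <- x[v > 0, , drop = FALSE]
    deg_genes <- rownames(x)
  }
  if (is.null(templates)) {
    tmpl <- class_templates_default()
    tmpl <- tmpl[setdiff(rownames(tmpl), "none"), colnames(expression),
                 drop = FALSE]
  } else {
    tmpl <- templates[, colnames(expression), drop = FALSE]
  }

  r <- stats::cor(t(x))
  adj <- ((1 + r) / 2)^params$beta
  diag(adj) <- 0
  tom <- topological_overlap(adj)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = params$linkage)
  modules <- stats::cutree(hc, k = params$k_modules)

  centroids <- t(vapply(seq_len(params$k_modules), function(m) {
    colMeans(x[modules == m, , drop = FALSE])
  }, numeric(ncol(x))))

  # cosine similarity of each module centroid to each class template;
  # greedy unique assignment, best matches first
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sim <- outer(seq_len(nrow(centroids)), seq_len(nrow(tmpl)),
               Vectorize(function(i, j) cosine(centroids[i, ], tmpl[j, ])))
  labels_of_module <- character(nrow(centroids))
  sim_work <- sim
  for (step in seq_len(min(nrow(centroids), nrow(tmpl)))) {
    best <- which(sim_work == max(sim_work), arr.ind = TRUE)[1, ]
    labels_of_module[best[1]] <- rownames(tmpl)[best[2]]
    sim_work[best[1], ] <- -Inf
    sim_work[, best[2]] <- -Inf
  }
  unassigned <- which(labels_of_module == "")
  if (length(unassigned)) {
    labels_of_module[unassigned] <- paste0("module_", unassigned)
  }

  assignment <- data.frame(gene_id = deg_genes,
                           label = labels_of_module[modules],
                           module_id = as.integer(modules),
                           stringsAsFactors = FALSE)
  rownames(centroids) <- labels_of_module
  if (!is.null(none_genes)) {
    none_genes <- sort(setdiff(none_genes, deg_genes))
    if (length(none_genes)) {
      assignment <- rbind(assignment,
                          data.frame(gene_id = none_genes, label = "none",
                                     module_id = 0L, stringsAsFactors = FALSE))
      none_centroid <- colMeans(expression[none_genes, , drop = FALSE])
      centroids <- rbind(centroids, none = none_centroid)
    }
  }
  structure(list(assignment = assignment, centroids = centroids,
                 params = params),
            class = "regulon_assignment")
}

#' @export
print.regulon_assignment <- function(x, ...) {
  cat("<regulon_assignment>\n")
  print(table(x$assignment$label))
  invisible(x)
}

#' Write a regulon assignment as TSV
#'
#' @param assignment A `regulon_assignment`.
#' @param path Output path.
#' @export
write_regulons_tsv <- function(assignment, path) {
  utils::write.table(assignment$assignment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same gene set;
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b Vectors of cluster labels (coerced to factors), same length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
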