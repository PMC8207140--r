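#' Branch composition statistic of the promoter flowchart
#'
#' For a branch of the YES/NO flowchart, the share of one expression type
#' attributable to that branch:
#' `((share of the type within the branch) x (share of all genes in the
#' branch)) / ((overall share of the type) / (overall share of all genes))`,
#' expressed as a percentage. With five balanced classes the overall type
#' share is 0.20, so a branch holding 50% of genes of which 5% are of the
#' type contributes (0.05 * 0.50) / (0.20 / 1.0) = 12.5%.
#'
#' @param p_type_in_branch Fraction of branch genes of the type, in [0, 1].
#' @param p_all_in_branch Fraction of all genes in the branch, in [0, 1].
#' @param p_type_overall Overall fraction of the type (default 0.20).
#' @param p_all_overall Overall fraction of all genes (default 1.0).
#' @return The percentage (raw value; may exceed 100 for concentrated
#'   branches).
#' @examples
#' branch_type_percentage(0.05, 0.50) # 12.5
#' @export
branch_type_percentage <- function(p_type_in_branch, p_all_in_branch,
                                   p_type_overall = 0.20,
                                   p_all_overall = 1.0) {
  args <- c(p_type_in_branch, p_all_in_branch, p_type_overall, p_all_overall)
  if (any(args < 0 | args > 1)) stop("all inputs must lie in [0, 1]")
  if (p_type_overall <= 0) stop("overall type share must be positive")
  (p_type_in_branch * p_all_in_branch) / (p_type_overall / p_all_overall) *
    100
}

flow_node <- function(motif, n, fraction_of_parent, composition,
                      branch_pct, yes = NULL, no = NULL) {
  structure(list(motif = motif, n = n,
                 fraction_of_parent = fraction_of_parent,
                 composition = composition, branch_pct = branch_pct,
                 yes = yes, no = no),
            class = "flow_node")
}

#' Fit an interpretable YES/NO flowchart over motif presence
#'
#' A CART-style classification tree (Gini impurity, fixed maximum depth and
#' minimum leaf size) on binary motif presence features, re-expressed as a
#' flowchart in which every node records its five-class composition (in
#' percent), its share of the parent, and the branch composition statistic
#' of [branch_type_percentage()]. Deterministic given the data.
#'
#' @param features Gene x motif 0/1 matrix or data.frame.
#' @param labels Class labels aligned with the feature rows.
#' @param max_depth Maximum tree depth (default 5).
#' @param min_leaf Minimum genes per leaf (default 10).
#' @return A list of class `flowchart` with `root` (nested `flow_node`s),
#'   `classes`, `n`, and the underlying [rpart::rpart] fit in `fit` (NULL
#'   for a single-class leaf-only chart).
#' @export
fit_flowchart <- function(features, labels, max_depth = 5, min_leaf = 10) {
  x <- as.data.frame(as.matrix(features))
  y <- droplevels(as.factor(labels))
  if (nrow(x) == 0L) stop("empty data")
  stopifnot(nrow(x) == length(y))
  classes <- levels(y)
  if (length(classes) == 1L) {
    comp <- stats::setNames(100, classes)
    root <- flow_node(NULL, length(y), 100, comp,
                      branch_type_percentage(1, 1, 1, 1) * comp / 100)
    return(structure(list(root = root, classes = classes, n = length(y),
                          fit = NULL), class = "flowchart"))
  }
  dat <- cbind(x, .class = y)
  fit <- rpart::rpart(.class ~ ., data = dat, method = "class",
                      control = rpart::rpart.control(
                        maxdepth = max_depth, minbucket = min_leaf,
                        minsplit = 2 * min_leaf, cp = 0, xval = 0,
                        maxcompete = 0, maxsurrogate = 0))
  root <- rpart_to_flow(fit)
  structure(list(root = root, classes = classes, n = length(y), fit = fit),
            class = "flowchart")
}

# Convert an rpart classification fit into nested flow_nodes. rpart numbers
# nodes 1, 2i, 2i+1; the splits matrix has one row per internal node in
# frame order (maxcompete = maxsurrogate = 0). ncat = -1 sends x < cutpoint
# to the left child, ncat = +1 sends x >= cutpoint left; for 0/1 presence
# features the cutpoint is 0.5, so "present" is the YES branch.
rpart_to_flow <- function(fit) {
  frame <- fit$frame
  ids <- as.integer(row.names(frame))
  classes <- attr(fit, "ylevels")
  ncls <- length(classes)
  counts_of <- function(r) {
    cnt <- frame$yval2[r, 1 + seq_len(ncls)]
    stats::setNames(as.numeric(cnt), classes)
  }
  n_root <- frame$n[ids == 1L]
  comp_root <- counts_of(which(ids == 1L)) / n_root
  split_rows <- which(frame$var != "<leaf>")
  # map internal frame row -> splits row (both in frame order)
  split_no <- stats::setNames(seq_along(split_rows), split_rows)
  build <- function(node_id, parent_n) {
    r <- which(ids == node_id)
    n <- frame$n[r]
    counts <- counts_of(r)
    comp <- counts / n * 100
    branch_pct <- vapply(classes, function(cl) {
      branch_type_percentage(comp[[cl]] / 100, n / n_root,
                             comp_root[[cl]], 1.0)
    }, numeric(1))
    frac <- n / parent_n * 100
    if (frame$var[r] == "<leaf>") {
      return(flow_node(NULL, n, frac, comp, branch_pct))
    }
    var <- as.character(frame$var[r])
    ncat <- fit$splits[split_no[[as.character(r)]], "ncat"]
    left <- build(2L * node_id, n)
    right <- build(2L * node_id + 1L, n)
    if (ncat < 0) { # left child is "absent" (x < 0.5)
      yes <- right
      no <- left
    } else {
      yes <- left
      no <- right
    }
    flow_node(var, n, frac, comp, branch_pct, yes = yes, no = no)
  }
  build(1L, n_root)
}

#' Render a flowchart as indented text
#'
#' Each node line shows the YES/NO branch taken, the percentage of the
#' parent's genes following it, and the five-class composition; internal
#' nodes name the motif tested.
#'
#' @param tree A `flowchart`.
#' @param digits Decimal places for percentages.
#' @return A single character string (newline-separated), invisibly also
#'   printed by `print.flowchart`.
#' @export
render_flowchart <- function(tree, digits = 1) {
  stopifnot(inherits(tree, "flowchart"))
  fmt_comp <- function(node) {
    paste(sprintf(paste0("%.", digits, "f"), node$composition),
          collapse = "/")
  }
  lines <- character(0)
  walk <- function(node, indent, label) {
    test <- if (!is.null(node$motif)) {
      paste0(" test ", node$motif, "?")
    } else ""
    lines <<- c(lines, sprintf("%s%s n=%d [%s]%s", indent, label, node$n,
                               fmt_comp(node), test))
    if (!is.null(node$motif)) {
      walk(node$yes, paste0(indent, "  "),
           sprintf("present (YES, %.*f%%):", digits,
                   node$yes$fraction_of_parent))
      walk(node$no, paste0(indent, "  "),
           sprintf("absent (NO, %.*f%%):", digits,
                   node$no$fraction_of_parent))
    }
  }
  walk(tree$root, "", sprintf("all genes (classes: %s)",
                              paste(tree$classes, collapse = "/")))
  paste(lines, collapse = "\n")
}

#' @export
print.flowchart <- function(x, ...) {
  cat(render_flowchart(x), "\n")
  invisible(x)
}

node_to_list <- function(node) {
  out <- list(motif = node$motif, n = node$n,
              fraction_of_parent = node$fraction_of_parent,
              composition = as.list(node$composition),
              branch_pct = as.list(node$branch_pct))
  if (!is.null(node$motif)) {
    out$yes <- node_to_list(node$yes)
    out$no <- node_to_list(node$no)
  }
  out
}

node_from_list <- function(lst) {
  flow_node(lst$motif, as.integer(lst$n),
            as.numeric(lst$fraction_of_parent),
            unlist(lst$composition), unlist(lst$branch_pct),
            yes = if (!is.null(lst$yes)) node_from_list(lst$yes),
            no = if (!is.null(lst$no)) node_from_list(lst$no))
}

#' Lossless JSON serialization of a flowchart
#'
#' @param tree A `flowchart`.
#' @param path Optional path; when given the JSON is written there.
#' @return The JSON string (invisibly when `path` is given).
#' @export
flowchart_to_json <- function(tree, path = NULL) {
  obj <- list(classes = tree$classes, n = tree$n,
              root = node_to_list(tree$root))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' @rdname flowchart_to_json
#' @param json A JSON string or path to a JSON file.
#' @export
flowchart_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- readLines(json)
  obj <- jsonlite::fromJSON(paste(json, collapse = ""),
                            simplifyVector = FALSE)
  structure(list(root = node_from_list(obj$root),
                 classes = unlist(obj$classes), n = as.integer(obj$n),
                 fit = NULL),
            class = "flowchart")
}

#' Cross-validated accuracy of the flowchart tree
#'
#' Undersamples classes to the minority size, then evaluates the CART
#' flowchart by stratified k-fold cross-validation; reports plain accuracy
#' (fraction of held-out genes whose majority-leaf class matches).
#'
#' @param features Gene x motif 0/1 matrix.
#' @param labels Class labels.
#' @param folds CV folds (default 5).
#' @param seed Integer seed.
#' @param max_depth,min_leaf Tree parameters as in [fit_flowchart()].
#' @return A list with `accuracy` and `per_fold`.
#' @export
cv_flowchart <- function(features, labels, folds = 5, seed = 1,
                         max_depth = 5, min_leaf = 10) {
  x <- as.data.frame(as.matrix(features))
  y <- droplevels(as.factor(labels))
  set.seed(seed)
  keep <- sort(undersample_idx(y))
  x <- x[keep, , drop = FALSE]
  y <- y[keep]
  fold_of <- stratified_folds(y, folds)
  per_fold <- numeric(folds)
  correct <- 0L
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    dat <- cbind(x[tr, , drop = FALSE], .class = y[tr])
    fit <- rpart::rpart(.class ~ ., data = dat, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = max_depth, minbucket = min_leaf,
                          minsplit = 2 * min_leaf, cp = 0, xval = 0,
                          maxcompete = 0, maxsurrogate = 0))
    pred <- stats::predict(fit, x[!tr, , drop = FALSE], type = "class")
    per_fold[f] <- mean(pred == y[!tr])
    correct <- correct + sum(pred == y[!tr])
  }
  list(accuracy = correct / length(y), per_fold = per_fold)
}
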