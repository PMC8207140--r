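#' Load the bundled catalog of known cis-regulatory elements
#'
#' A fixture catalog of Fe-homeostasis CREs (IDE1, IDE2, IDRS, the
#' IDEF1- and OsIRO2-binding sites) and PLACE-style elements (W-box,
#' DCEp1/FAM1, DCEp2, EECCRCAH1, GCGC box, bZIP/bHLH, Myb binding-like and
#' degenerate candidates). Bracketed base alternatives are already encoded
#' as IUPAC letters (e.g. IDE2 = CAMGYHH).
#'
#' @return A data.frame with columns `name`, `consensus`, `source`,
#'   `description`.
#' @export
load_known_catalog <- function() {
  path <- system.file("extdata", "known_cres.tsv", package = "crelearn",
                      mustWork = TRUE)
  read_motif_tsv(path)
}

#' Read / write motif catalogs as TSV
#'
#' The TSV carries at least `name`, `consensus`, `source` columns.
#'
#' @param path File path.
#' @param motifs Data.frame of motifs (for the writer).
#' @return For the reader, a data.frame of motifs.
#' @export
read_motif_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  stopifnot(all(c("name", "consensus", "source") %in% names(df)))
  df
}

#' @rdname read_motif_tsv
#' @export
write_motif_tsv <- function(motifs, path) {
  utils::write.table(motifs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a position weight matrix object
#'
#' @param name Motif name.
#' @param probs Width x 4 matrix of per-position base probabilities, columns
#'   A, C, G, T; each row must sum to 1.
#' @param background Named background base probabilities summing to 1. The
#'   default is the normalized strand-pooled promoter composition
#'   A=T=0.26, C=G=0.24.
#' @return An object of class `pwm`.
#' @export
pwm <- function(name, probs,
                background = c(A = 0.26, C = 0.24, G = 0.24, T = 0.26)) {
  probs <- as.matrix(probs)
  colnames(probs) <- toupper(colnames(probs))
  if (!identical(colnames(probs), c("A", "C", "G", "T"))) {
    if (ncol(probs) == 4L) colnames(probs) <- c("A", "C", "G", "T")
    else stop("probs must have 4 columns (A, C, G, T)")
  }
  if (any(abs(rowSums(probs) - 1) > 1e-9)) {
    stop("each PWM row must sum to 1")
  }
  background <- background[c("A", "C", "G", "T")]
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  if (any(background == 0 & apply(probs, 2, max) > 0)) {
    stop("zero background probability with nonzero column probability")
  }
  structure(list(name = name, width = nrow(probs), probs = probs,
                 background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (%d bp), max log-odds score %.3f bits\n",
              x$name, x$width, pwm_max_score(x)))
  invisible(x)
}

#' Maximum attainable log-odds score of a PWM
#'
#' @param x A [pwm].
#' @return Sum over positions of the maximum `log2(p/q)`, in bits.
#' @export
pwm_max_score <- function(x) {
  lo <- log2(x$probs / rep(x$background, each = x$width))
  sum(apply(lo, 1, max))
}

#' Scan a window with a PWM at a fractional score threshold
#'
#' The score at an offset is the sum over motif positions of
#' `log2(p_j(base) / q(base))`; an offset is a hit iff its score reaches
#' `threshold_fraction` times the maximum attainable score. An N in the
#' sequence contributes `-Inf`, so windows of ambiguous sequence never hit.
#'
#' @param window A DNA string (promoter orientation).
#' @param x A [pwm].
#' @param threshold_fraction Fraction of the maximum score in (0, 1].
#' @return data.frame with 0-based `offset` and `score` of each hit.
#' @export
pwm_logodds_scan <- function(window, x, threshold_fraction = 0.8) {
  stopifnot(inherits(x, "pwm"),
            threshold_fraction > 0, threshold_fraction <= 1)
  L <- nchar(window)
  w <- x$width
  if (L < w) {
    return(data.frame(offset = integer(), score = numeric()))
  }
  lo <- log2(x$probs / rep(x$background, each = w)) # w x 4
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  idx <- unname(code[strsplit(toupper(window), "")[[1]]]) # NA for N etc.
  n_off <- L - w + 1L
  scores <- numeric(n_off)
  for (j in seq_len(w)) {
    b <- idx[j:(j + n_off - 1L)]
    contrib <- ifelse(is.na(b), -Inf, lo[cbind(j, b)])
    scores <- scores + contrib
  }
  thr <- threshold_fraction * pwm_max_score(x)
  hit <- which(scores >= thr)
  data.frame(offset = hit - 1L, score = scores[hit])
}

#' Read PWMs from MEME minimal format
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` lines and an
#' optional `Background letter frequencies` line.
#'
#' @param path Path to a MEME minimal text file.
#' @return A named list of [pwm] objects.
#' @export
read_meme_pwm <- function(path) {
  lines <- readLines(path)
  bg <- c(A = 0.26, C = 0.24, G = 0.24, T = 0.26)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1L]), "\\s+")[[1]]
    vals <- as.numeric(toks[seq(2, length(toks), by = 2)])
    names(vals) <- toupper(toks[seq(1, length(toks), by = 2)])
    bg <- vals[c("A", "C", "G", "T")]
  }
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0L) stop("no MOTIF blocks in ", path)
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hdr <- s + grep("letter-probability matrix",
                    lines[(s + 1):length(lines)])[1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    probs <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }))
    probs <- probs / rowSums(probs) # absorb file-precision rounding
    out[[name]] <- pwm(name, probs, bg)
  }
  out
}

#' Write PWMs in MEME minimal format
#'
#' @param pwms A list of [pwm] objects.
#' @param path Output path.
#' @export
write_meme_pwm <- function(pwms, path) {
  bg <- pwms[[1]]$background
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "Background letter frequencies",
             sprintf("A %.5f C %.5f G %.5f T %.5f",
                     bg["A"], bg["C"], bg["G"], bg["T"]), "")
  for (p in pwms) {
    lines <- c(lines, paste("MOTIF", p$name),
               sprintf("letter-probability matrix: alength= 4 w= %d", p$width),
               apply(p$probs, 1, function(r) sprintf(" %.6f %.6f %.6f %.6f",
                                                     r[1], r[2], r[3], r[4])),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Binary motif presence/absence feature matrix
#'
#' One row per gene, one column per motif (catalog order, then any PWMs),
#' entry 1 iff the gene's window contains at least one hit. These
#' presence/absence features are the inputs of the expression-type models.
#'
#' @param windows A `promoter_windows` data.frame (one window per gene).
#' @param motifs Data.frame of IUPAC motifs with `name` and `consensus`
#'   columns (e.g. [load_known_catalog()] or discovery output renamed), or
#'   NULL.
#' @param pwms Optional named list of [pwm] objects.
#' @param threshold_fraction Fractional PWM score threshold.
#' @return An integer 0/1 matrix, genes x features, with the window spec
#'   attached as attribute `"spec"`.
#' @export
presence_matrix <- function(windows, motifs = NULL, pwms = NULL,
                            threshold_fraction = 0.8) {
  feats <- c(if (!is.null(motifs)) motifs$name,
             if (!is.null(pwms)) vapply(pwms, `[[`, character(1), "name"))
  if (length(feats) == 0L) stop("no motifs or PWMs given")
  if (anyDuplicated(feats)) {
    stop("duplicate motif names: ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "))
  }
  n <- nrow(windows)
  m <- matrix(0L, nrow = n, ncol = length(feats),
              dimnames = list(windows$gene_id, feats))
  col <- 0L
  if (!is.null(motifs)) {
    for (i in seq_len(nrow(motifs))) {
      col <- col + 1L
      re <- paste0("(?=", iupac_to_regex(motifs$consensus[i]), ")")
      m[, col] <- as.integer(grepl(re, windows$seq, perl = TRUE))
    }
  }
  if (!is.null(pwms)) {
    for (p in pwms) {
      col <- col + 1L
      m[, col] <- vapply(windows$seq, function(s) {
        as.integer(nrow(pwm_logodds_scan(s, p, threshold_fraction)) > 0L)
      }, integer(1), USE.NAMES = FALSE)
    }
  }
  attr(m, "spec") <- attr(windows, "spec")
  m
}

#' Write / read a binary feature matrix as TSV
#'
#' @param features Gene x motif 0/1 matrix.
#' @param path File path.
#' @return For the reader, an integer matrix with gene ids as rownames.
#' @export
write_feature_tsv <- function(features, path) {
  df <- data.frame(gene_id = rownames(features), features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}
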