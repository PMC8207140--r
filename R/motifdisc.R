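# IUPAC degenerate consensus -> regex character classes. N in the *subject*
# never matches: classes contain only A/C/G/T, so any N in a window breaks
# every match.
iupac_to_regex <- function(consensus) {
  letters_ <- strsplit(toupper(consensus), "")[[1]]
  classes <- vapply(letters_, function(l) {
    bases <- Biostrings::IUPAC_CODE_MAP[[l]]
    if (is.null(bases)) stop("not an IUPAC DNA letter: ", l)
    if (nchar(bases) == 1L) bases else paste0("[", bases, "]")
  }, character(1), USE.NAMES = FALSE)
  paste(classes, collapse = "")
}

# reverse map: sorted base set -> IUPAC letter
iupac_from_bases <- local({
  map <- NULL
  function(bases) {
    if (is.null(map)) {
      keys <- vapply(Biostrings::IUPAC_CODE_MAP, function(s) {
        paste(sort(strsplit(s, "")[[1]]), collapse = "")
      }, character(1))
      map <<- stats::setNames(names(Biostrings::IUPAC_CODE_MAP), keys)
    }
    key <- paste(sort(unique(bases)), collapse = "")
    out <- map[[key]]
    if (is.null(out)) stop("no IUPAC letter for base set ", key)
    out
  }
})

#' All match start offsets of an IUPAC consensus in one sequence
#'
#' Overlapping occurrences are counted; IUPAC letters in the motif match
#' their base sets; an N in the sequence matches nothing.
#'
#' @param seq A DNA string.
#' @param consensus IUPAC consensus motif.
#' @return Integer vector of 0-based match offsets (possibly empty).
#' @export
match_offsets <- function(seq, consensus) {
  re <- paste0("(?=", iupac_to_regex(consensus), ")")
  m <- gregexpr(re, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

#' Count motif occurrences in a set of promoter windows
#'
#' Scans the promoter strand only; overlapping matches are counted.
#'
#' @param windows A `promoter_windows` data.frame (or character vector of
#'   sequences).
#' @param consensus IUPAC consensus motif.
#' @return List with `total` (occurrences over all windows) and `genes`
#'   (number of windows containing at least one occurrence).
#' @examples
#' count_occurrences(c("GCAGCAGCAGC"), "GCWGCWGC") # total 2
#' @export
count_occurrences <- function(windows, consensus) {
  seqs <- window_seqs(windows)
  if (length(seqs) == 0L) return(list(total = 0L, genes = 0L))
  re <- paste0("(?=", iupac_to_regex(consensus), ")")
  counts <- vapply(gregexpr(re, seqs, perl = TRUE), function(m) {
    if (m[1] == -1L) 0L else length(m)
  }, integer(1))
  list(total = sum(counts), genes = sum(counts > 0L))
}

window_seqs <- function(windows) {
  if (is.character(windows)) windows else windows$seq
}

#' Hit positions of a motif in TSS-relative coordinates
#'
#' @param windows A `promoter_windows` data.frame carrying its window spec.
#' @param consensus IUPAC consensus motif.
#' @return data.frame with columns `gene_id`, `rel_pos` (TSS-relative match
#'   start).
#' @export
motif_hits <- function(windows, consensus) {
  spec <- attr(windows, "spec")
  if (is.null(spec)) stop("windows must carry a window spec attribute")
  offs <- lapply(windows$seq, match_offsets, consensus = consensus)
  n <- lengths(offs)
  data.frame(gene_id = rep(windows$gene_id, n),
             rel_pos = unlist(offs, use.names = FALSE) + spec$start_rel,
             stringsAsFactors = FALSE)
}

#' Length-normalized motif enrichment ratio
#'
#' `E = (k_reg / L_reg) / (k_bg / L_bg)`: occurrences per bp in the regulon
#' windows divided by occurrences per bp in the background windows. A zero
#' background count yields `Inf` with attribute `zero_background = TRUE`.
#'
#' @param k_reg,k_bg Occurrence counts in regulon and background.
#' @param L_reg,L_bg Total sequence lengths (bp) of regulon and background.
#' @return The enrichment ratio.
#' @examples
#' enrichment_ratio(4, 1000, 10, 10000) # 4
#' @export
enrichment_ratio <- function(k_reg, L_reg, k_bg, L_bg) {
  if (any(c(k_reg, k_bg) < 0)) stop("negative counts")
  if (any(c(L_reg, L_bg) <= 0)) stop("lengths must be positive")
  if (k_bg == 0) {
    return(structure(Inf, zero_background = TRUE))
  }
  (k_reg / L_reg) / (k_bg / L_bg)
}

#' Upper-tail binomial p-value for per-regulon motif presence
#'
#' `P(X >= k)` for `X ~ Binomial(n, p)`, computed with the stable
#' complementary CDF. `k = 0` gives 1 (the whole mass).
#'
#' @param genes_with_motif Number of regulon genes containing the motif (k).
#' @param n_genes Regulon size (n).
#' @param p_bg_gene Background per-gene presence probability (p).
#' @return The p-value (vectorized over its arguments).
#' @examples
#' binom_pvalue(3, 5, 0.1) # 0.00856
#' @export
binom_pvalue <- function(genes_with_motif, n_genes, p_bg_gene) {
  if (any(genes_with_motif < 0) || any(genes_with_motif > n_genes)) {
    stop("genes_with_motif must lie in [0, n_genes]")
  }
  if (any(p_bg_gene < 0 | p_bg_gene > 1)) stop("p must lie in [0, 1]")
  ifelse(genes_with_motif == 0, 1,
         stats::pbinom(genes_with_motif - 1, n_genes, p_bg_gene,
                       lower.tail = FALSE))
}

# Exact k-mer occurrence totals and per-window presence counts, chunked so
# the 4^k x n_windows count matrix never materializes in full.
kmer_stats <- function(seqs, k, chunk = 200L) {
  n <- length(seqs)
  total <- NULL
  presence <- NULL
  for (i in seq(1L, n, by = chunk)) {
    idx <- i:min(i + chunk - 1L, n)
    m <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(seqs[idx]), width = k)
    tot_i <- colSums(m)
    pres_i <- colSums(m > 0L)
    if (is.null(total)) {
      total <- tot_i
      presence <- pres_i
    } else {
      total <- total + tot_i
      presence <- presence + pres_i
    }
  }
  list(total = total, presence = presence, n_windows = n)
}

#' Discover regulon-enriched exact k-mers
#'
#' Enumerates every exact k-mer present in the regulon windows, scores each
#' with the length-normalized enrichment ratio and the upper-tail binomial
#' test (per-gene presence by default: k = regulon genes containing the
#' k-mer, n = regulon size, p = fraction of background genes containing it),
#' and returns the top candidates passing the significance cutoff, ranked by
#' p-value, then enrichment (descending), then lexicographic k-mer. K-mers
#' absent from the background receive a half-count floor on the background
#' presence estimate for the p-value (the plug-in binomial is degenerate at
#' p = 0); the reported `p_bg_gene` stays the raw fraction.
#'
#' @param regulon_windows Promoter windows of the regulon genes.
#' @param background_windows Background windows (typically all genes, which
#'   may include the regulon, or a random background from
#'   [random_background()]).
#' @param k K-mer width (>= 4; default 8).
#' @param top_m Maximum number of motifs returned (use 50 for the
#'   500-bp-upstream window, 30 for -50..+150).
#' @param alpha Significance cutoff on the binomial p-value (default 0.001,
#'   uncorrected).
#' @param per_gene If `TRUE` (default) the binomial test is on per-gene
#'   presence; if `FALSE`, on occurrence counts over scannable positions.
#' @param bonferroni If `TRUE`, p-values are Bonferroni-corrected over the
#'   4^k possible k-mers before filtering (off by default).
#' @return A data.frame of class `enrichment_results` with columns `motif`,
#'   `width`, `source`, `k_reg`, `L_reg`, `k_bg`, `L_bg`, `enrichment`,
#'   `genes_with_motif`, `n_genes`, `p_bg_gene`, `pvalue`.
#' @export
discover_kmers <- function(regulon_windows, background_windows, k = 8,
                           top_m = 50, alpha = 0.001, per_gene = TRUE,
                           bonferroni = FALSE) {
  stopifnot(k >= 4)
  reg <- window_seqs(regulon_windows)
  bg <- window_seqs(background_windows)
  reg <- reg[nzchar(reg)]
  bg <- bg[nzchar(bg)]
  if (length(reg) == 0L) stop("regulon windows are empty")
  if (length(bg) == 0L || sum(nchar(bg)) == 0L) {
    stop("background has zero total length")
  }
  L_reg <- sum(nchar(reg))
  L_bg <- sum(nchar(bg))
  rs <- kmer_stats(reg, k)
  bs <- kmer_stats(bg, k)
  present <- which(rs$total > 0L)
  if (length(present) == 0L) {
    return(empty_enrichment_results())
  }
  kmers <- names(rs$total)[present]
  k_reg <- unname(rs$total[present])
  k_bg <- unname(bs$total[present])
  enr <- (k_reg / L_reg) / ifelse(k_bg == 0, NA_real_, k_bg / L_bg)
  enr[k_bg == 0] <- Inf
  n_genes <- rs$n_windows
  genes_with <- unname(rs$presence[present])
  p_bg <- unname(bs$presence[present]) / bs$n_windows
  # the plug-in binomial is degenerate for k-mers absent from a finite
  # background (p = 0 would give p-value 0 for any single occurrence);
  # floor the background presence at half a count for the test only
  p_test <- pmax(unname(bs$presence[present]), 0.5) / bs$n_windows
  if (per_gene) {
    pval <- binom_pvalue(genes_with, n_genes, p_test)
  } else {
    # occurrence-based reading: n = scannable positions, p = background
    # occurrence rate per position
    n_pos <- L_reg - (k - 1) * length(reg)
    p_pos <- pmax(k_bg, 0.5) / (L_bg - (k - 1) * length(bg))
    pval <- ifelse(k_reg == 0, 1,
                   stats::pbinom(k_reg - 1, n_pos, pmin(p_pos, 1),
                                 lower.tail = FALSE))
  }
  if (bonferroni) pval <- pmin(pval * 4^k, 1)
  res <- data.frame(motif = kmers, width = k, source = "discovered",
                    k_reg = k_reg, L_reg = L_reg, k_bg = k_bg, L_bg = L_bg,
                    enrichment = enr, genes_with_motif = genes_with,
                    n_genes = n_genes, p_bg_gene = p_bg, pvalue = pval,
                    stringsAsFactors = FALSE)
  res <- res[res$pvalue <= alpha, , drop = FALSE]
  res <- res[order(res$pvalue, -res$enrichment, res$motif), , drop = FALSE]
  res <- utils::head(res, top_m)
  rownames(res) <- NULL
  class(res) <- c("enrichment_results", "data.frame")
  res
}

empty_enrichment_results <- function() {
  res <- data.frame(motif = character(), width = integer(),
                    source = character(), k_reg = numeric(),
                    L_reg = numeric(), k_bg = numeric(), L_bg = numeric(),
                    enrichment = numeric(), genes_with_motif = numeric(),
                    n_genes = numeric(), p_bg_gene = numeric(),
                    pvalue = numeric(), stringsAsFactors = FALSE)
  class(res) <- c("enrichment_results", "data.frame")
  res
}

#' Score a catalog motif against regulon and background windows
#'
#' Computes the same enrichment ratio and binomial p-value as
#' [discover_kmers()] for an arbitrary (possibly degenerate) consensus.
#'
#' @param regulon_windows,background_windows Promoter window sets.
#' @param consensus IUPAC consensus.
#' @param name Motif name (defaults to the consensus).
#' @param source Motif source label.
#' @return A one-row `enrichment_results` data.frame.
#' @export
score_motif <- function(regulon_windows, background_windows, consensus,
                        name = consensus, source = "catalog") {
  reg <- window_seqs(regulon_windows)
  bg <- window_seqs(background_windows)
  cr <- count_occurrences(reg, consensus)
  cb <- count_occurrences(bg, consensus)
  L_reg <- sum(nchar(reg))
  L_bg <- sum(nchar(bg))
  enr <- enrichment_ratio(cr$total, L_reg, cb$total, L_bg)
  p_bg <- cb$genes / length(bg)
  res <- data.frame(motif = name, width = nchar(consensus), source = source,
                    k_reg = cr$total, L_reg = L_reg, k_bg = cb$total,
                    L_bg = L_bg, enrichment = as.numeric(enr),
                    genes_with_motif = cr$genes, n_genes = length(reg),
                    p_bg_gene = p_bg,
                    pvalue = binom_pvalue(cr$genes, length(reg), p_bg),
                    stringsAsFactors = FALSE)
  class(res) <- c("enrichment_results", "data.frame")
  res
}

#' Merge similar fixed-width motifs into degenerate IUPAC consensi
#'
#' Groups motifs by greedy single linkage at Hamming distance
#' `<= max_mismatch` and replaces each group by the per-column IUPAC union
#' of its members' base sets (e.g. GCAGCAGC + GCTGCTGC -> GCWGCWGC). When
#' regulon and background windows are supplied, a merged consensus is kept
#' only if its re-computed enrichment is at least the minimum of its
#' members' enrichments; otherwise the group reverts to its members.
#'
#' @param motifs Character vector of equal-width IUPAC motifs, or an
#'   `enrichment_results` data.frame (whose `enrichment` column is then used
#'   for the reversion test).
#' @param max_mismatch Maximum Hamming distance for single-linkage grouping.
#' @param regulon_windows,background_windows Optional window sets for the
#'   enrichment reversion test.
#' @return A data.frame with columns `motif`, `width`, `source`
#'   (`"merged"` or the input source) and `members` (slash-separated).
#' @export
merge_to_iupac <- function(motifs, max_mismatch = 1,
                           regulon_windows = NULL,
                           background_windows = NULL) {
  if (is.data.frame(motifs)) {
    seqs <- motifs$motif
    enr <- motifs$enrichment
  } else {
    seqs <- as.character(motifs)
    enr <- rep(NA_real_, length(seqs))
  }
  if (length(seqs) == 0L) {
    return(data.frame(motif = character(), width = integer(),
                      source = character(), members = character(),
                      stringsAsFactors = FALSE))
  }
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("all motifs must have equal width")
  mats <- do.call(rbind, strsplit(toupper(seqs), ""))
  n <- length(seqs)
  # single-linkage components under Hamming distance <= max_mismatch
  comp <- seq_len(n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (sum(mats[i, ] != mats[j, ]) <= max_mismatch) {
          old <- comp[j]
          comp[comp == old] <- comp[i]
        }
      }
    }
  }
  have_windows <- !is.null(regulon_windows) && !is.null(background_windows)
  out <- list()
  for (g in unique(comp)) {
    members <- which(comp == g)
    if (length(members) == 1L) {
      out[[length(out) + 1L]] <- data.frame(
        motif = seqs[members], width = w, source = "discovered",
        members = seqs[members], stringsAsFactors = FALSE)
      next
    }
    consensus <- paste(vapply(seq_len(w), function(col) {
      bases <- unique(unlist(strsplit(
        Biostrings::IUPAC_CODE_MAP[mats[members, col]], "")))
      iupac_from_bases(bases)
    }, character(1)), collapse = "")
    keep_merged <- TRUE
    if (have_windows) {
      member_enr <- enr[members]
      if (all(is.na(member_enr))) {
        member_enr <- vapply(seqs[members], function(s) {
          as.numeric(score_motif(regulon_windows, background_windows,
                                 s)$enrichment)
        }, numeric(1))
      }
      merged_enr <- as.numeric(score_motif(regulon_windows,
                                           background_windows,
                                           consensus)$enrichment)
      keep_merged <- merged_enr >= min(member_enr, na.rm = TRUE)
    }
    if (keep_merged) {
      out[[length(out) + 1L]] <- data.frame(
        motif = consensus, width = w, source = "merged",
        members = paste(seqs[members], collapse = "/"),
        stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1L]] <- data.frame(
        motif = seqs[members], width = w, source = "discovered",
        members = seqs[members], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate random background windows
#'
#' An i.i.d. sequence of the requested total length from the given base
#' composition, partitioned into windows of `window_length` bp (any
#' remainder forms a final short window). Deterministic per seed; emulates
#' the "same size of random sequence" background.
#'
#' @param total_length Total background length in bp.
#' @param composition Named base probabilities (A, C, G, T).
#' @param window_length Window size in bp.
#' @param seed Integer seed.
#' @return A `promoter_windows`-style data.frame (`gene_id` = `rnd...`).
#' @export
random_background <- function(total_length, composition = c(A = 0.26,
                                                            C = 0.24,
                                                            G = 0.24,
                                                            T = 0.26),
                              window_length = 650, seed = 1) {
  stopifnot(total_length > 0, window_length > 0)
  set.seed(seed)
  s <- paste(sample(names(composition), total_length, replace = TRUE,
                    prob = composition), collapse = "")
  starts <- seq(1L, total_length, by = window_length)
  seqs <- substring(s, starts, pmin(starts + window_length - 1L, total_length))
  out <- data.frame(gene_id = sprintf("rnd%05d", seq_along(seqs)),
                    seq = seqs, clipped = FALSE, stringsAsFactors = FALSE)
  attr(out, "spec") <- window_spec(0, window_length)
  class(out) <- c("promoter_windows", "data.frame")
  out
}

#' Write enrichment results as TSV
#'
#' @param results An `enrichment_results` data.frame.
#' @param path Output path.
#' @export
write_enrichment_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
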