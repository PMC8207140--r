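#' Positional frequency profile of a motif around the TSS
#'
#' The span is divided into fixed-width windows (default 50 bp over
#' -3000..+2000). For each window the fraction of genes in the set, and of
#' all genes, with at least one motif hit starting inside it is computed,
#' together with their ratio (`relative`). A TSS-proximal regulatory motif
#' shows `relative` peaks near position 0 in the responsive set.
#'
#' @param hits data.frame with `gene_id` and TSS-relative `rel_pos` of every
#'   motif hit (e.g. from [motif_hits()] on -3000..+2000 windows).
#' @param gene_set Character vector of set gene ids (nonempty).
#' @param all_genes Character vector of all gene ids.
#' @param span Length-2 TSS-relative span.
#' @param width Window width in bp; must divide the span length.
#' @return A data.frame of class `positional_profile` with `win_start`,
#'   `win_end`, `set_freq`, `all_freq`, `relative` (0/0 -> 1; x/0 -> Inf,
#'   with such windows flagged in attribute `undefined_relative`).
#' @export
positional_profile <- function(hits, gene_set, all_genes,
                               span = c(-3000, 2000), width = 50) {
  spec <- as_window_spec(span)
  if (spec$length %% width != 0) {
    stop("width (", width, ") must divide the span length (", spec$length,
         ")")
  }
  if (length(gene_set) == 0L) stop("empty gene set")
  gene_set <- unique(gene_set)
  all_genes <- unique(all_genes)
  edges <- seq(spec$start_rel, spec$end_rel, by = width)
  n_win <- length(edges) - 1L
  in_span <- hits$rel_pos >= spec$start_rel & hits$rel_pos < spec$end_rel
  h <- hits[in_span, , drop = FALSE]
  win_of <- (h$rel_pos - spec$start_rel) %/% width + 1L
  freq_of <- function(ids) {
    hh <- h[h$gene_id %in% ids, , drop = FALSE]
    ww <- win_of[h$gene_id %in% ids]
    # fraction of genes with >= 1 hit start in each window
    counts <- vapply(seq_len(n_win), function(w) {
      length(unique(hh$gene_id[ww == w]))
    }, integer(1))
    counts / length(ids)
  }
  set_freq <- freq_of(gene_set)
  all_freq <- freq_of(all_genes)
  relative <- ifelse(all_freq == 0, ifelse(set_freq == 0, 1, Inf),
                     set_freq / all_freq)
  out <- data.frame(win_start = edges[-length(edges)], win_end = edges[-1],
                    set_freq = set_freq, all_freq = all_freq,
                    relative = relative)
  attr(out, "undefined_relative") <- which(all_freq == 0 & set_freq > 0)
  class(out) <- c("positional_profile", "data.frame")
  out
}

#' Default fold-change bin edges
#'
#' Ratio-scale bins reconstructed from the fold levels used for coverage
#' reporting: suppression below 0.2 through induction above 5-fold, with an
#' unregulated 0.66-1.5 band.
#'
#' @return Numeric vector of bin edges spanning (0, Inf).
#' @export
default_foldchange_bins <- function() {
  c(0, 0.2, 0.5, 0.66, 1.5, 2, 3, 5, Inf)
}

#' Motif coverage ratio stratified by expression fold change
#'
#' Genes are binned by their expression ratio (fold change on the ratio
#' scale, i.e. `2^log2ratio`) and for each bin the percentage of genes
#' whose -500..+150 window (or whichever window produced `presence`)
#' contains at least one motif hit is reported.
#'
#' @param presence Named 0/1 vector: per-gene motif presence.
#' @param foldchange Named numeric vector of ratio-scale fold changes for
#'   the same genes; every gene in `presence` must have a value.
#' @param bins Bin edges partitioning (0, Inf);
#'   [default_foldchange_bins()] by default.
#' @return A data.frame of class `coverage_bins` with `bin`, `lo`, `hi`,
#'   `n_genes`, `coverage_pct`.
#' @export
coverage_by_foldchange <- function(presence, foldchange,
                                   bins = default_foldchange_bins()) {
  genes <- names(presence)
  if (is.null(genes)) stop("presence must be a named vector")
  missing <- setdiff(genes, names(foldchange))
  if (length(missing)) {
    stop("gene(s) missing expression value: ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  fc <- foldchange[genes]
  if (any(fc < min(bins)) || any(fc > max(bins))) {
    stop("bins do not cover all observed fold changes")
  }
  bin_idx <- cut(fc, breaks = bins, include.lowest = FALSE, right = FALSE,
                 labels = FALSE)
  # right-open bins except the last, which absorbs the maximum
  bin_idx[is.na(bin_idx)] <- length(bins) - 1L
  n_bins <- length(bins) - 1L
  n_genes <- tabulate(bin_idx, nbins = n_bins)
  cov <- vapply(seq_len(n_bins), function(b) {
    idx <- bin_idx == b
    if (!any(idx)) return(NA_real_)
    mean(presence[idx]) * 100
  }, numeric(1))
  labels <- sprintf("[%g,%g)", bins[-length(bins)], bins[-1])
  out <- data.frame(bin = labels, lo = bins[-length(bins)], hi = bins[-1],
                    n_genes = n_genes, coverage_pct = cov,
                    stringsAsFactors = FALSE)
  class(out) <- c("coverage_bins", "data.frame")
  out
}
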