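#' TSS-relative window specification
#'
#' Defines a half-open window `[start_rel, end_rel)` in coordinates relative
#' to the transcription start site, with the TSS base at relative position 0.
#' Under this convention the widely used "-500 to +150" search window is
#' `window_spec(-500, 150)` and spans 650 bp including the TSS base.
#'
#' @param start_rel Signed start offset in bp (inclusive).
#' @param end_rel Signed end offset in bp (exclusive). Must exceed `start_rel`.
#' @return An object of class `window_spec` with fields `start_rel`,
#'   `end_rel` and `length`.
#' @examples
#' window_spec(-500, 150)$length # 650
#' @export
window_spec <- function(start_rel, end_rel) {
  stopifnot(is.numeric(start_rel), is.numeric(end_rel), length(start_rel) == 1L,
            length(end_rel) == 1L)
  if (start_rel >= end_rel) {
    stop("window_spec: start_rel (", start_rel, ") must be < end_rel (",
         end_rel, ")")
  }
  structure(list(start_rel = as.integer(start_rel),
                 end_rel = as.integer(end_rel),
                 length = as.integer(end_rel - start_rel)),
            class = "window_spec")
}

as_window_spec <- function(x) {
  if (inherits(x, "window_spec")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(window_spec(x[1], x[2]))
  stop("cannot interpret object as a window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> %+d..%+d relative to TSS (%d bp)\n",
              x$start_rel, x$end_rel, x$length))
  invisible(x)
}

#' Read a multi-contig genome from FASTA
#'
#' @param path Path to a (possibly wrapped) FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions; contig name is the first word
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Write a genome to FASTA
#'
#' @param genome A named `DNAStringSet` or named character vector.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(genome, path, width = width)
  invisible(path)
}

as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && !is.null(names(genome))) {
    return(Biostrings::DNAStringSet(genome))
  }
  stop("genome must be a named DNAStringSet or named character vector")
}

#' Read gene models from GFF3 or BED6
#'
#' Gene models carry one TSS/TES pair per gene. Internally all coordinates are
#' 0-based. GFF3 `gene` features (1-based, inclusive) are converted; for BED6
#' the 0-based half-open convention applies. On the minus strand the TSS is
#' the rightmost base of the feature and the TES the leftmost.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @param genome Optional genome; if given, coordinates are validated against
#'   contig lengths and offending records are named in the error.
#' @return A `data.frame` of class `gene_models` with columns `gene_id`,
#'   `contig`, `strand`, `tss`, `tes`.
#' @examples
#' tmp <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tg1\t0\t+", tmp)
#' read_gene_models(tmp)$tss # 100
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "bed"),
                             genome = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  genes <- if (format == "bed") read_bed6(path) else read_gff3_genes(path)
  if (!is.null(genome)) validate_gene_models(genes, genome)
  genes
}

gene_models_df <- function(gene_id, contig, strand, tss, tes) {
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    stop("unknown strand symbol '", strand[which(bad)[1]], "' for gene '",
         gene_id[which(bad)[1]], "'")
  }
  structure(data.frame(gene_id = as.character(gene_id),
                       contig = as.character(contig),
                       strand = strand,
                       tss = as.integer(tss),
                       tes = as.integer(tes),
                       stringsAsFactors = FALSE),
            class = c("gene_models", "data.frame"))
}

read_bed6 <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 6L) stop("BED6 requires 6 columns, found ", ncol(tab))
  start <- as.integer(tab[[2]])
  end <- as.integer(tab[[3]])
  strand <- as.character(tab[[6]])
  tss <- ifelse(strand == "-", end - 1L, start)
  tes <- ifelse(strand == "-", start, end - 1L)
  gene_models_df(tab[[4]], tab[[1]], strand, tss, tes)
}

read_gff3_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) length(f) >= 9 && f[3] == "gene", logical(1))
  fields <- fields[keep]
  if (length(fields) == 0L) stop("no gene features found in ", path)
  contig <- vapply(fields, `[[`, character(1), 1)
  start1 <- as.integer(vapply(fields, `[[`, character(1), 4))
  end1 <- as.integer(vapply(fields, `[[`, character(1), 5))
  strand <- vapply(fields, `[[`, character(1), 7)
  attrs <- vapply(fields, `[[`, character(1), 9)
  ids <- sub("^.*ID=([^;]+).*$", "\\1", attrs)
  # GFF3 1-based inclusive -> 0-based
  start0 <- start1 - 1L
  end0 <- end1 - 1L
  tss <- ifelse(strand == "-", end0, start0)
  tes <- ifelse(strand == "-", start0, end0)
  gene_models_df(ids, contig, strand, tss, tes)
}

#' Validate gene model coordinates against a genome
#'
#' @param genes A `gene_models` data.frame.
#' @param genome Genome sequences.
#' @return `genes`, invisibly, if valid; otherwise an error naming the first
#'   offending record.
#' @export
validate_gene_models <- function(genes, genome) {
  genome <- as_genome(genome)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  missing_ctg <- !genes$contig %in% names(lens)
  if (any(missing_ctg)) {
    stop("gene '", genes$gene_id[which(missing_ctg)[1]],
         "': contig '", genes$contig[which(missing_ctg)[1]], "' not in genome")
  }
  L <- lens[genes$contig]
  bad <- genes$tss < 0L | genes$tss >= L | genes$tes < 0L | genes$tes >= L
  if (any(bad)) {
    i <- which(bad)[1]
    stop("gene '", genes$gene_id[i], "': coordinates beyond contig '",
         genes$contig[i], "' (length ", L[i], ")")
  }
  invisible(genes)
}

#' Write gene models as GFF3
#'
#' @param genes A `gene_models` data.frame.
#' @param path Output path.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  left0 <- ifelse(genes$strand == "-", genes$tes, genes$tss)
  right0 <- ifelse(genes$strand == "-", genes$tss, genes$tes)
  lines <- sprintf("%s\t.\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   genes$contig, left0 + 1L, right0 + 1L, genes$strand,
                   genes$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Write gene models as BED6
#'
#' @param genes A `gene_models` data.frame.
#' @param path Output path.
#' @export
write_gene_models_bed <- function(genes, path) {
  left0 <- ifelse(genes$strand == "-", genes$tes, genes$tss)
  right0 <- ifelse(genes$strand == "-", genes$tss, genes$tes)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   genes$contig, left0, right0 + 1L, genes$gene_id,
                   genes$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Extract strand-aware promoter windows anchored at the TSS
#'
#' For a plus-strand gene the window covers genomic interval
#' `[tss + start_rel, tss + end_rel)`; for a minus-strand gene it covers
#' `(tss - end_rel, tss - start_rel]` and the sequence is reverse-complemented,
#' so that returned sequences always read in the promoter (transcription)
#' orientation. Parts of a window that fall outside the contig are clipped and
#' the window flagged; a window that is empty after clipping is returned as an
#' empty string, not an error.
#'
#' @param genome Genome sequences (named `DNAStringSet` or character vector).
#' @param genes A `gene_models` data.frame (or a single-row list with fields
#'   `gene_id`, `contig`, `strand`, `tss`).
#' @param spec A [window_spec] or length-2 numeric `c(start_rel, end_rel)`.
#' @return A `data.frame` of class `promoter_windows` with columns `gene_id`,
#'   `seq` (uppercase, promoter orientation), `clipped`; the spec is attached
#'   as attribute `"spec"`.
#' @examples
#' genome <- c(chr1 = "AACGTTTT")
#' g <- data.frame(gene_id = "g1", contig = "chr1", strand = "+",
#'                 tss = 2, tes = 7)
#' extract_windows(genome, g, c(-2, 3))$seq # "AACGT"
#' @export
extract_windows <- function(genome, genes, spec) {
  spec <- as_window_spec(spec)
  genome <- as_genome(genome)
  chars <- stats::setNames(as.character(genome), names(genome))
  lens <- nchar(chars)
  missing_ctg <- setdiff(unique(genes$contig), names(chars))
  if (length(missing_ctg)) {
    stop("contig(s) not present in genome: ",
         paste(missing_ctg, collapse = ", "))
  }
  L <- lens[genes$contig]
  minus <- genes$strand == "-"
  # 0-based half-open genomic interval [lo, hi)
  lo <- ifelse(minus, genes$tss - spec$end_rel + 1L, genes$tss + spec$start_rel)
  hi <- ifelse(minus, genes$tss - spec$start_rel + 1L, genes$tss + spec$end_rel)
  lo_c <- pmax(lo, 0L)
  hi_c <- pmin(hi, L)
  clipped <- lo_c > lo | hi_c < hi
  empty <- lo_c >= hi_c
  seqs <- character(nrow(genes))
  nz <- !empty
  if (any(nz)) {
    seqs[nz] <- toupper(substring(chars[genes$contig[nz]],
                                  lo_c[nz] + 1L, hi_c[nz]))
  }
  if (any(minus & nz)) {
    idx <- which(minus & nz)
    seqs[idx] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[idx])))
  }
  out <- data.frame(gene_id = genes$gene_id, seq = seqs,
                    clipped = clipped | empty, stringsAsFactors = FALSE)
  attr(out, "spec") <- spec
  class(out) <- c("promoter_windows", "data.frame")
  out
}

#' @rdname extract_windows
#' @param gene A single gene model (one-row data.frame or list).
#' @export
extract_window <- function(genome, gene, spec) {
  extract_windows(genome, as.data.frame(gene, stringsAsFactors = FALSE), spec)
}

#' Build a promoter-window set from bare sequences
#'
#' Wraps already-extracted (or synthetic) sequences in the
#' `promoter_windows` container used throughout the package, attaching the
#' window spec needed to interpret match offsets as TSS-relative positions.
#'
#' @param seqs Character vector of window sequences.
#' @param spec A [window_spec] or length-2 numeric span.
#' @param gene_ids Gene ids (defaults to `w00001`, ...).
#' @return A `promoter_windows` data.frame.
#' @export
as_promoter_windows <- function(seqs, spec, gene_ids = NULL) {
  spec <- as_window_spec(spec)
  if (is.null(gene_ids)) gene_ids <- sprintf("w%05d", seq_along(seqs))
  out <- data.frame(gene_id = gene_ids, seq = toupper(seqs),
                    clipped = nchar(seqs) < spec$length,
                    stringsAsFactors = FALSE)
  attr(out, "spec") <- spec
  class(out) <- c("promoter_windows", "data.frame")
  out
}

#' Write promoter windows as FASTA
#'
#' Headers follow the `gene_id|start_rel|end_rel` convention.
#'
#' @param windows A `promoter_windows` data.frame from [extract_windows()].
#' @param path Output path.
#' @export
write_windows_fasta <- function(windows, path) {
  spec <- attr(windows, "spec")
  headers <- sprintf("%s|%d|%d", windows$gene_id, spec$start_rel, spec$end_rel)
  keep <- nzchar(windows$seq)
  x <- Biostrings::DNAStringSet(windows$seq[keep])
  names(x) <- headers[keep]
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
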