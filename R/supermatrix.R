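#' Partitioned amino-acid supermatrix
#'
#' The central container of the package: an ordered set of taxa, one state
#' row per taxon, and an ordered gene partition map tiling the columns.
#' States are stored as integer indices into the model alphabet, with `NA`
#' for the single internal missing state (the input symbols `-`, `?` and
#' `X` are all normalized to it).
#'
#' @param x integer matrix, taxa x columns, entries in `1..length(alphabet)`
#'   or `NA`; rownames are the taxon ids.
#' @param partitions data frame with columns `gene_id`, `start`, `end`
#'   (0-based half-open column intervals, in order, tiling the matrix).
#' @param alphabet state alphabet.
#' @return object of class `"supermatrix"`.
#' @export
supermatrix <- function(x, partitions, alphabet = AA_ALPHABET) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop("rows must carry unique taxon ids")
  partitions <- as.data.frame(partitions)
  stopifnot(all(c("gene_id", "start", "end") %in% names(partitions)))
  partitions$gene_id <- as.character(partitions$gene_id)
  partitions$start <- as.integer(partitions$start)
  partitions$end <- as.integer(partitions$end)
  if (anyDuplicated(partitions$gene_id)) stop("duplicate gene_id")
  if (any(partitions$start >= partitions$end)) stop("empty partition")
  ends <- c(0L, partitions$end[-nrow(partitions)])
  if (nrow(partitions) == 0L || partitions$start[1] != 0L ||
      any(partitions$start != ends) ||
      partitions$end[nrow(partitions)] != ncol(x))
    stop("partitions must tile [0, n_columns) exactly, in order")
  if (any(!is.na(x) & (x < 1L | x > length(alphabet))))
    stop("state index out of alphabet range")
  structure(list(x = x, partitions = partitions, alphabet = alphabet),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("supermatrix: %d taxa x %d columns, %d genes, %.1f%% complete\n",
              nrow(x$x), ncol(x$x), nrow(x$partitions),
              100 * mean(!is.na(x$x))))
  invisible(x)
}

#' @export
dim.supermatrix <- function(x) dim(x$x)

#' Taxon ids of a supermatrix
#' @param m a [supermatrix()].
#' @return character vector of taxon ids, in row order.
#' @export
taxa_of <- function(m) rownames(m$x)

# character matrix view (letters, "-" for missing)
as_char_matrix <- function(m) {
  ch <- matrix("-", nrow(m$x), ncol(m$x), dimnames = dimnames(m$x))
  ok <- !is.na(m$x)
  ch[ok] <- m$alphabet[m$x[ok]]
  ch
}

encode_states <- function(chars, alphabet = AA_ALPHABET) {
  idx <- match(toupper(chars), alphabet)
  miss <- toupper(chars) %in% c("-", "?", "X", ".")
  idx[miss] <- NA_integer_
  if (any(is.na(idx) & !miss))
    stop("unknown state symbol(s): ",
         paste(unique(chars[is.na(idx) & !miss]), collapse = " "))
  idx
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Taxa are the union over genes (in order of first appearance); a taxon
#' absent from a gene receives the missing state across that gene's
#' interval. Gene intervals are recorded 0-based half-open, in input order.
#'
#' @param gene_alignments named list: `gene_id` -> named character vector of
#'   equal-length amino-acid sequences (names are taxon ids), or a named
#'   list of per-taxon character vectors of single letters.
#' @param alphabet state alphabet.
#' @return a [supermatrix()].
#' @export
concatenate <- function(gene_alignments, alphabet = AA_ALPHABET) {
  if (length(gene_alignments) == 0L) stop("no gene alignments given")
  ids <- names(gene_alignments)
  if (is.null(ids) || anyDuplicated(ids)) stop("duplicate or missing gene_id")
  seqs <- lapply(gene_alignments, function(g) {
    g <- vapply(g, paste0, character(1), collapse = "")
    if (is.null(names(g)) || anyDuplicated(names(g)))
      stop("sequences must carry unique taxon ids")
    if (length(unique(nchar(g))) != 1L)
      stop("ragged gene alignment (unequal sequence lengths)")
    g
  })
  taxa <- unique(unlist(lapply(seqs, names), use.names = FALSE))
  lens <- vapply(seqs, function(g) nchar(g[[1]]), integer(1))
  total <- sum(lens)
  x <- matrix(NA_integer_, length(taxa), total,
              dimnames = list(taxa, NULL))
  at <- 0L
  for (i in seq_along(seqs)) {
    g <- seqs[[i]]
    cols <- at + seq_len(lens[i])
    for (tx in names(g))
      x[tx, cols] <- encode_states(strsplit(g[[tx]], "")[[1]], alphabet)
    at <- at + lens[i]
  }
  partitions <- data.frame(gene_id = ids,
                           start = cumsum(c(0L, lens[-length(lens)])),
                           end = cumsum(lens))
  supermatrix(x, partitions, alphabet)
}

#' Completeness statistics of a supermatrix
#'
#' Percent of positions with data present: per taxon (over that taxon's
#' row), per gene (over the gene's block), and overall (over all cells).
#' The overall value equals the cell-weighted mean of the per-taxon values.
#'
#' @param matrix a [supermatrix()].
#' @return list of class `"completeness_report"` with `per_taxon`,
#'   `per_gene` (named numeric, percent) and `overall` (percent).
#' @export
completeness_stats <- function(matrix) {
  stopifnot(inherits(matrix, "supermatrix"))
  present <- !is.na(matrix$x)
  per_taxon <- 100 * rowMeans(present)
  p <- matrix$partitions
  per_gene <- vapply(seq_len(nrow(p)), function(i) {
    100 * mean(present[, (p$start[i] + 1L):p$end[i], drop = FALSE])
  }, numeric(1))
  names(per_gene) <- p$gene_id
  structure(list(per_taxon = per_taxon, per_gene = per_gene,
                 overall = 100 * mean(present)),
            class = "completeness_report")
}

#' @export
print.completeness_report <- function(x, ...) {
  cat(sprintf("completeness: overall %.2f%% (taxa %.2f-%.2f%%, %d genes)\n",
              x$overall, min(x$per_taxon), max(x$per_taxon),
              length(x$per_gene)))
  invisible(x)
}

#' Extract columns of a supermatrix
#'
#' Returns a new supermatrix holding the selected columns in the given
#' order. The partition map is recomputed as maximal contiguous runs of
#' columns drawn from the same source gene (run ids are suffixed when a
#' gene contributes several runs).
#'
#' @param matrix a [supermatrix()].
#' @param columns 0-based column indices, in range, without duplicates.
#' @return a [supermatrix()].
#' @export
slice_columns <- function(matrix, columns) {
  stopifnot(inherits(matrix, "supermatrix"))
  columns <- as.integer(columns)
  if (length(columns) == 0L) stop("empty column selection")
  if (anyDuplicated(columns)) stop("duplicate column indices")
  if (any(columns < 0L) || any(columns >= ncol(matrix$x)))
    stop("column index out of range")
  p <- matrix$partitions
  src_gene <- rep.int(p$gene_id, p$end - p$start)[columns + 1L]
  run <- cumsum(c(TRUE, src_gene[-1L] != src_gene[-length(src_gene)]))
  starts <- which(c(TRUE, src_gene[-1L] != src_gene[-length(src_gene)]))
  lens <- tabulate(run)
  gid <- src_gene[starts]
  dup <- stats::ave(seq_along(gid), gid, FUN = seq_along)
  many <- gid %in% gid[duplicated(gid)]
  gid[many] <- paste0(gid[many], ".", dup[many])
  partitions <- data.frame(gene_id = gid,
                           start = cumsum(c(0L, lens[-length(lens)])),
                           end = cumsum(lens))
  supermatrix(matrix$x[, columns + 1L, drop = FALSE], partitions,
              matrix$alphabet)
}

#' Extract one gene's block as a supermatrix
#' @param matrix a [supermatrix()].
#' @param gene_id a gene identifier present in the partition map.
#' @return a single-gene [supermatrix()].
#' @export
gene_block <- function(matrix, gene_id) {
  p <- matrix$partitions
  i <- match(gene_id, p$gene_id)
  if (is.na(i)) stop("unknown gene_id: ", gene_id)
  slice_columns(matrix, p$start[i]:(p$end[i] - 1L))
}

## ---- readers / writers (byte-deterministic) --------------------------------

#' Write a supermatrix as FASTA (one record per taxon)
#' @param matrix a [supermatrix()].
#' @param path output file.
#' @export
write_supermatrix_fasta <- function(matrix, path) {
  ch <- as_char_matrix(matrix)
  lines <- character(2L * nrow(ch))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(ch))
  lines[c(FALSE, TRUE)] <- apply(ch, 1, paste0, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Write per-gene FASTA files plus a partition table
#' @param matrix a [supermatrix()].
#' @param dir output directory (created if needed).
#' @param write_all_missing keep taxa with no data for a gene? default FALSE.
#' @return paths written (invisibly).
#' @export
write_gene_fastas <- function(matrix, dir, write_all_missing = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ch <- as_char_matrix(matrix)
  p <- matrix$partitions
  paths <- character(0)
  for (i in seq_len(nrow(p))) {
    cols <- (p$start[i] + 1L):p$end[i]
    block <- ch[, cols, drop = FALSE]
    keep <- if (write_all_missing) rep(TRUE, nrow(block)) else
      rowSums(block != "-") > 0L
    f <- file.path(dir, paste0(p$gene_id[i], ".fasta"))
    lines <- character(2L * sum(keep))
    lines[c(TRUE, FALSE)] <- paste0(">", rownames(block)[keep])
    lines[c(FALSE, TRUE)] <- apply(block[keep, , drop = FALSE], 1,
                                   paste0, collapse = "")
    writeLines(lines, f)
    paths <- c(paths, f)
  }
  pt <- file.path(dir, "partitions.tsv")
  write_partition_tsv(matrix, pt)
  invisible(c(paths, pt))
}

#' Write the gene partition table (gene_id TAB start TAB end, 0-based half-open)
#' @param matrix a [supermatrix()].
#' @param path output file.
#' @export
write_partition_tsv <- function(matrix, path) {
  p <- matrix$partitions
  writeLines(c("#gene_id\tstart\tend",
               sprintf("%s\t%d\t%d", p$gene_id, p$start, p$end)), path)
  invisible(path)
}

#' Read a partition table written by [write_partition_tsv()]
#' @param path input file.
#' @return data frame with `gene_id`, `start`, `end`.
#' @export
read_partition_tsv <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  data.frame(gene_id = vapply(parts, `[`, "", 1L),
             start = as.integer(vapply(parts, `[`, "", 2L)),
             end = as.integer(vapply(parts, `[`, "", 3L)))
}

#' Read a supermatrix from FASTA plus a partition table
#' @param fasta FASTA file of aligned per-taxon rows.
#' @param partitions partition TSV path, or a partitions data frame; if
#'   omitted the whole matrix is a single gene `"all"`.
#' @param alphabet state alphabet.
#' @return a [supermatrix()].
#' @export
read_supermatrix_fasta <- function(fasta, partitions = NULL,
                                   alphabet = AA_ALPHABET) {
  aa <- Biostrings::readAAStringSet(fasta)
  rows <- as.character(aa)
  lens <- unique(nchar(rows))
  if (length(lens) != 1L) stop("FASTA rows have unequal lengths")
  x <- t(vapply(rows, function(s) encode_states(strsplit(s, "")[[1]], alphabet),
                integer(lens)))
  rownames(x) <- names(aa)
  if (is.null(partitions))
    partitions <- data.frame(gene_id = "all", start = 0L, end = lens)
  else if (is.character(partitions))
    partitions <- read_partition_tsv(partitions)
  supermatrix(x, partitions, alphabet)
}

#' Write a supermatrix in relaxed sequential PHYLIP format
#' @param matrix a [supermatrix()].
#' @param path output file.
#' @export
write_phylip <- function(matrix, path) {
  ch <- as_char_matrix(matrix)
  writeLines(c(sprintf("%d %d", nrow(ch), ncol(ch)),
               paste(rownames(ch), apply(ch, 1, paste0, collapse = ""))),
             path)
  invisible(path)
}

#' Read a relaxed sequential PHYLIP alignment
#' @inheritParams read_supermatrix_fasta
#' @param path input file.
#' @return a [supermatrix()].
#' @export
read_phylip <- function(path, partitions = NULL, alphabet = AA_ALPHABET) {
  ln <- readLines(path)
  hdr <- scan(text = ln[1], what = integer(), n = 2, quiet = TRUE)
  ln <- ln[-1][nzchar(ln[-1])]
  if (length(ln) != hdr[1]) stop("PHYLIP row count disagrees with header")
  parts <- regmatches(ln, regexpr("\\S+", ln))
  seqs <- gsub("\\s", "", substring(ln, nchar(parts) + 1L))
  if (any(nchar(seqs) != hdr[2])) stop("PHYLIP row width disagrees with header")
  x <- t(vapply(seqs, function(s) encode_states(strsplit(s, "")[[1]], alphabet),
                integer(hdr[2])))
  rownames(x) <- parts
  if (is.null(partitions))
    partitions <- data.frame(gene_id = "all", start = 0L, end = hdr[2])
  else if (is.character(partitions))
    partitions <- read_partition_tsv(partitions)
  supermatrix(x, partitions, alphabet)
}
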