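#' Read and write sequence sets as plain character vectors
#'
#' Sequences travel through the package as named character vectors (one
#' string per record); these helpers convert to and from FASTA/FASTQ on disk
#' via Biostrings.
#'
#' @param x named character vector of sequences.
#' @param path file path.
#' @return `read_fasta` returns a named character vector; writers return
#'   `path` invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(is.character(x), !is.null(names(x)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

#' @rdname write_fasta
#' @param qual optional named character vector of quality strings
#'   (Sanger/phred+33); defaults to constant "I" (Q40).
#' @export
write_fastq <- function(x, path, qual = NULL) {
  stopifnot(is.character(x), !is.null(names(x)))
  if (is.null(qual)) qual <- vapply(nchar(x), function(n)
    paste(rep("I", n), collapse = ""), "")
  s <- Biostrings::DNAStringSet(x)
  q <- Biostrings::BStringSet(qual)
  Biostrings::writeXStringSet(s, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fastq <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

#' Write / read gene coordinates as GFF3
#'
#' Internally the package uses 0-based half-open intervals; GFF3 is 1-based
#' closed, converted at this boundary.
#'
#' @param genes data.frame with columns `gene`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @param path file path.
#' @param seqid reference sequence name.
#' @return `read_gff_genes` returns the data.frame form; the writer returns
#'   `path` invisibly.
#' @export
write_gff_genes <- function(genes, path, seqid = "reference") {
  stopifnot(all(c("gene", "start", "end", "strand") %in% names(genes)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  lines <- sprintf("%s\tsagpop\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   seqid, genes$start + 1L, genes$end, genes$strand, genes$gene)
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_gff_genes
#' @export
read_gff_genes <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (!length(ln)) return(data.frame(gene = character(), start = integer(),
                                     end = integer(), strand = character()))
  f <- strsplit(ln, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9L)
  if (length(bad)) stop("malformed GFF3 row at line ", bad[1])
  data.frame(
    gene = sub("^ID=", "", vapply(f, `[[`, "", 9L)),
    start = as.integer(vapply(f, `[[`, "", 4L)) - 1L,
    end = as.integer(vapply(f, `[[`, "", 5L)),
    strand = vapply(f, `[[`, "", 7L))
}

#' Read / write an occurrence matrix as TSV
#'
#' Rows are taxa, columns ortholog clusters, cells 0/1.
#'
#' @param mat binary integer matrix with dimnames.
#' @param path file path.
#' @return `read_occurrence_tsv` returns the matrix; the writer returns
#'   `path` invisibly.
#' @export
write_occurrence_tsv <- function(mat, path) {
  df <- data.frame(taxon = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrence_tsv
#' @export
read_occurrence_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$taxon
  m
}

# Split equal-length sequence strings into a character matrix (rows = taxa).
aln_matrix <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  n <- unique(nchar(seqs))
  if (length(n) != 1L) stop("sequences differ in length")
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

# Collapse a character matrix back into strings.
aln_strings <- function(m) {
  out <- apply(m, 1L, paste, collapse = "")
  names(out) <- rownames(m)
  out
}
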