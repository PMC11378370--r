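#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, case-sensitive,
#'   upper case expected).
#' @return character vector of reverse complements.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## split a sequence into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## remove gap characters
degap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Read a genome FASTA file
#'
#' Reads a (multi-)FASTA file into a named character vector, one element per
#' chromosome/contig, names taken from the first whitespace-delimited token
#' of each header.
#'
#' @param path path to a FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  seqs
}

#' Write a genome FASTA file
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @param width line width (default 60).
#' @export
write_genome <- function(genome, path, width = 60) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Read a gene catalogue
#'
#' The catalogue is tab-separated text with header
#' `id chrom start end strand class`, coordinates 1-based inclusive, strand
#' `+`/`-`, class one of `S0+`, `S1`, `S2`, `S3`, `S4`, `intergene`.
#'
#' @param path path to the TSV file.
#' @return data frame with the six columns.
#' @export
read_catalogue <- function(path) {
  cat <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_catalogue(cat)
  cat
}

#' Write a gene catalogue
#' @param catalogue data frame as from [read_catalogue()].
#' @param path output path.
#' @export
write_catalogue <- function(catalogue, path) {
  write.table(catalogue, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

CONSERVATION_CLASSES <- c("S0+", "S1", "S2", "S3", "S4", "intergene")

validate_catalogue <- function(cat) {
  need <- c("id", "chrom", "start", "end", "strand", "class")
  if (!all(need %in% names(cat)))
    stop("catalogue must have columns: ", paste(need, collapse = " "))
  if (nrow(cat)) {
    if (any(cat$start > cat$end)) stop("catalogue has start > end")
    if (!all(cat$strand %in% c("+", "-"))) stop("catalogue strand must be + or -")
    if (!all(cat$class %in% CONSERVATION_CLASSES))
      stop("unknown conservation class; expected one of ",
           paste(CONSERVATION_CLASSES, collapse = ", "))
  }
  invisible(cat)
}
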