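#' Filter a catalogue by minimum ORF length
#'
#' Short loci give unreliable statistics; entries with
#' `end - start + 1 < min_orf_len` are dropped. The default of 60 nt is the
#' standard cutoff of this analysis.
#'
#' @param catalogue catalogue data frame (see [read_catalogue()]).
#' @param min_orf_len minimum length in nt kept (>= keeps).
#' @return the retained rows, with a named per-class tally of discarded
#'   entries in attribute `"discarded"`.
#' @examples
#' cat <- data.frame(id = "x", chrom = "c", start = 1, end = 59,
#'                   strand = "+", class = "S1")
#' nrow(filter_catalogue(cat, 60))
#' @export
filter_catalogue <- function(catalogue, min_orf_len = 60) {
  stopifnot(min_orf_len >= 0)
  validate_catalogue(catalogue)
  keep <- (catalogue$end - catalogue$start + 1) >= min_orf_len
  tally <- setNames(integer(length(CONSERVATION_CLASSES)), CONSERVATION_CLASSES)
  if (any(!keep)) {
    tb <- table(catalogue$class[!keep])
    tally[names(tb)] <- as.integer(tb)
  }
  out <- catalogue[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "discarded") <- tally
  out
}

#' Extract a locus with flanks from a genome
#'
#' Takes the gene region plus up to `flank` nt on each side, truncating at
#' chromosome ends; minus-strand loci are reverse-complemented after
#' extraction so the ORF reads 5' to 3'. Flanks default to 500 nt.
#'
#' @param genome named character vector of chromosome sequences.
#' @param entry one catalogue row (list or single-row data frame).
#' @param flank flank length in nt.
#' @return object of class `locus`: list with `entry`, `sequence`,
#'   `flank_left`, `flank_right` (as obtained, 5' and 3' of the ORF), and
#'   `orf_offset` (0-based offset of the ORF within the sequence).
#' @export
extract_locus <- function(genome, entry, flank = 500) {
  if (!entry$chrom %in% names(genome))
    stop("unknown chromosome: ", entry$chrom)
  chrom <- genome[[entry$chrom]]
  L <- nchar(chrom)
  if (entry$start < 1 || entry$end > L || entry$start > entry$end)
    stop("coordinates out of range for ", entry$id)
  lo <- as.integer(max(1, entry$start - flank))
  hi <- as.integer(min(L, entry$end + flank))
  seq <- substr(chrom, lo, hi)
  left <- as.integer(entry$start - lo)   # genomic-left flank actually obtained
  right <- as.integer(hi - entry$end)
  if (entry$strand == "-") {
    seq <- revcomp(seq)
    tmp <- left; left <- right; right <- tmp
  }
  structure(list(entry = entry, sequence = seq,
                 flank_left = left, flank_right = right,
                 orf_offset = left),
            class = "locus")
}

gene_region <- function(locus) {
  glen <- locus$entry$end - locus$entry$start + 1L
  c(locus$orf_offset + 1L, locus$orf_offset + glen)
}

#' Find the best orthologous region in each related genome
#'
#' Runs the glocal scan over both strands of every chromosome of every
#' related genome and keeps the single best hit per genome (ties broken by
#' smallest chromosome name, then smallest start, then plus strand). Hits
#' below `score_floor` are recorded as missing.
#'
#' @param locus a [extract_locus()] result (or any list with `$sequence`).
#' @param genomes named list: species -> named chromosome vector.
#' @param scoring a [scoring_scheme()].
#' @param score_floor minimum score kept; the default is
#'   `0.3 * match * nchar(query)`. Use `-Inf` to keep every best hit.
#' @return object of class `orthologue_set`: list with `query` (the locus)
#'   and `hits` (species -> list(sequence, chrom, start, end, strand, score)
#'   or NULL). Minus-strand hit sequences are returned in query orientation.
#' @export
find_orthologue <- function(locus, genomes, scoring = scoring_scheme(),
                            score_floor = NULL) {
  if (length(genomes) == 0) stop("at least one related genome is required")
  query <- locus$sequence
  if (is.null(score_floor))
    score_floor <- 0.3 * scoring$match * nchar(query)
  hits <- vector("list", length(genomes))
  names(hits) <- names(genomes)
  for (sp in names(genomes)) {
    best <- NULL
    for (chrom in sort(names(genomes[[sp]]))) {
      fwd <- genomes[[sp]][[chrom]]
      if (!nzchar(fwd)) next
      for (strand in c("+", "-")) {
        tgt <- if (strand == "+") fwd else revcomp(fwd)
        sc <- glocal_score(query, tgt, scoring)
        if (is.null(best) || sc$score > best$score) {
          best <- list(score = sc$score, end = sc$end, chrom = chrom,
                       strand = strand, target = tgt)
        }
      }
    }
    if (is.null(best) || best$score < score_floor) { hits[sp] <- list(NULL); next }
    st <- glocal_start(query, best$target, best$end, scoring)
    aln <- glocal_align(query, substr(best$target, st$start, best$end), scoring)
    if (aln$score != best$score)
      stop("internal error: windowed glocal score mismatch")
    s <- st$start + aln$target_interval[1] - 1L
    e <- st$start + aln$target_interval[2] - 1L
    hitseq <- degap(aln$target_aligned)
    Lc <- nchar(genomes[[sp]][[best$chrom]])
    if (best$strand == "-") {  # map back to forward-strand coordinates
      tmp <- s
      s <- Lc - e + 1L
      e <- Lc - tmp + 1L
    }
    hits[[sp]] <- list(sequence = hitseq, chrom = best$chrom,
                       start = s, end = e, strand = best$strand,
                       score = aln$score)
  }
  structure(list(query = locus, hits = hits), class = "orthologue_set")
}
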