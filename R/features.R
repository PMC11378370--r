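MUTATION_CLASSES <- c("transition", "transversion",
                      "AT>GC", "GC>AT", "AT>AT", "GC>GC", "indel")

START_RULES <- c("ATG", "A..ATG", "A..ATG.C")

#' Induce the pairwise alignment of two rows of an alignment
#'
#' Takes two rows (ancestral or leaf) of a multiple alignment and removes
#' the columns that are gapped in both; columns gapped in exactly one row
#' are retained as indel evidence.
#'
#' @param aln named gapped rows (an `msa`, possibly augmented with ancestral
#'   rows on the same columns).
#' @param node_a,node_b row names; `node_a` is the older node.
#' @return object of class `induced_pair`: list with `a`, `b` (equal-length
#'   gapped strings) and `cols` (indices of the retained columns in the
#'   input alignment).
#' @export
induce_pair <- function(aln, node_a, node_b) {
  if (!all(c(node_a, node_b) %in% names(aln)))
    stop("alignment is missing row ",
         paste(setdiff(c(node_a, node_b), names(aln)), collapse = ", "))
  ca <- chars(aln[[node_a]]); cb <- chars(aln[[node_b]])
  keep <- !(ca == "-" & cb == "-")
  structure(list(a = paste(ca[keep], collapse = ""),
                 b = paste(cb[keep], collapse = ""),
                 cols = which(keep)),
            class = "induced_pair")
}

## classify aligned differing base pairs into the six substitution classes
classify_substitutions <- function(old, new) {
  out <- setNames(integer(6), MUTATION_CLASSES[1:6])
  if (!length(old)) return(out)
  ts <- is_transition_pair(old, new)
  out["transition"] <- sum(ts)
  out["transversion"] <- sum(!ts)
  old_at <- old %in% c("A", "T")
  new_at <- new %in% c("A", "T")
  out["AT>GC"] <- sum(old_at & !new_at)
  out["GC>AT"] <- sum(!old_at & new_at)
  out["AT>AT"] <- sum(old_at & new_at)
  out["GC>GC"] <- sum(!old_at & !new_at)
  out
}

#' Count and classify mutations between two aligned sequences
#'
#' Aligned mismatching bases are substitutions; a maximal run of columns
#' gapped in exactly one row is one indel event. Substitutions are
#' classified as transition/transversion and by GC pressure (AT>GC, GC>AT,
#' AT>AT, GC>GC); both classifications sum to the same total. Substitution
#' frequencies are percentages of aligned-base columns, the indel frequency
#' a percentage of all retained columns; columns containing an ambiguous
#' base (N) are removed before any counting.
#'
#' @param pair an [induce_pair()] result (direction: `a` older, `b` younger).
#' @return object of class `mutation_counts`: list with `counts` (named,
#'   the seven classes), `freqs` (percent) and `denominators`
#'   (`sub`, `indel`).
#' @export
classify_mutations <- function(pair) {
  stopifnot(inherits(pair, "induced_pair"))
  a <- chars(pair$a); b <- chars(pair$b)
  drop <- a == "N" | b == "N"
  a <- a[!drop]; b <- b[!drop]
  both <- a != "-" & b != "-"
  diffb <- both & a != b
  counts <- c(classify_substitutions(a[diffb], b[diffb]), indel = 0L)
  gap_one <- xor(a == "-", b == "-")
  if (any(gap_one)) {
    r <- rle(gap_one | FALSE)
    ## a run of one-sided gaps switching rows mid-run is two events
    runs <- 0L
    idx <- 1L
    for (k in seq_along(r$lengths)) {
      if (r$values[k]) {
        seg <- (a == "-")[idx:(idx + r$lengths[k] - 1)]
        runs <- runs + 1L + sum(diff(seg) != 0)
      }
      idx <- idx + r$lengths[k]
    }
    counts["indel"] <- runs
  }
  denom_sub <- sum(both)
  denom_indel <- length(a)
  freqs <- c(100 * counts[1:6] / max(denom_sub, 1),
             100 * counts["indel"] / max(denom_indel, 1))
  if (denom_sub == 0) freqs[1:6] <- 0
  structure(list(counts = counts, freqs = freqs,
                 denominators = c(sub = denom_sub, indel = denom_indel)),
            class = "mutation_counts")
}

#' GC content of a sequence
#'
#' Genic mode uses only third codon positions (the positions least
#' constrained by coding and therefore the natural proxy for regional
#' composition); non-genic mode uses the whole region. Ambiguous bases (N)
#' are excluded from numerator and denominator.
#'
#' @param seq DNA string; genic mode requires length divisible by 3.
#' @param mode `"nongenic"` (whole region) or `"genic"` (third codon
#'   positions).
#' @return GC fraction in `[0, 1]`.
#' @examples
#' gc_content("ATGGCGTAA", "genic")    # thirds G,G,A -> 2/3
#' gc_content("ATGGCGTAA", "nongenic") # 4/9
#' @export
gc_content <- function(seq, mode = c("nongenic", "genic")) {
  mode <- match.arg(mode)
  if (!nzchar(seq)) stop("empty sequence")
  cc <- chars(seq)
  if (mode == "genic") {
    if (length(cc) %% 3 != 0)
      stop("genic GC requires a length divisible by 3")
    cc <- cc[seq(3, length(cc), by = 3)]
  }
  cc <- cc[cc != "N"]
  if (!length(cc)) stop("no unambiguous bases")
  sum(cc %in% c("G", "C")) / length(cc)
}

#' Locate the most upstream start codon in a segment under a rule
#'
#' Scans in-frame positions of the segment for the most upstream ATG whose
#' context matches the pattern: `ATG` (bare), `A..ATG` (A at -3) or
#' `A..ATG.C` (A at -3 and C at +4), '.' being any base. Context positions
#' may fall outside the segment (e.g. the -3 base of an ATG at the
#' segment's 5' edge), but must lie within `context`; a Kozak pattern whose
#' context runs off the available sequence does not match.
#'
#' @param context the full sequence the segment lies in.
#' @param seg_start,seg_end 1-based inclusive segment bounds within
#'   `context`; in-frame means `(pos - seg_start) %% 3 == 0`.
#' @param rule one of `"ATG"`, `"A..ATG"`, `"A..ATG.C"`.
#' @return the 1-based position of the A of the matching ATG, or `NA`.
#' @examples
#' locate_start("AAAATGGC", 1, 8, "A..ATG")   # 4
#' locate_start("AAAATGGC", 1, 8, "A..ATG.C") # 4 (position 8 is C)
#' @export
locate_start <- function(context, seg_start, seg_end, rule = "ATG") {
  rule <- match.arg(rule, START_RULES)
  seg_start <- as.integer(seg_start); seg_end <- as.integer(seg_end)
  if (seg_end - seg_start + 1L < 3L) return(NA_integer_)
  pos <- seq.int(seg_start, seg_end - 2L, by = 3L)
  atg <- pos[substring(context, pos, pos + 2L) == "ATG"]
  if (rule != "ATG" && length(atg)) {
    ok3 <- atg - 3L >= 1L & substring(context, atg - 3L, atg - 3L) == "A"
    atg <- atg[ok3]
    if (rule == "A..ATG.C" && length(atg)) {
      ok4 <- atg + 4L <= nchar(context) &
        substring(context, atg + 4L, atg + 4L) == "C"
      atg <- atg[ok4]
    }
  }
  if (!length(atg)) NA_integer_ else as.integer(atg[1])
}

#' Scan a sequence for ORFs
#'
#' For each reading frame, the region is cut into segments bounded by stop
#' codons (TAA/TAG/TGA) or the region ends; a segment yields an ORF when it
#' contains a start codon under the active rule. ORF length runs from the
#' start codon through the stop codon inclusive; a segment truncated by the
#' region end yields an ORF without a stop (`has_stop = FALSE`) ending at
#' its last complete codon.
#'
#' @param seq DNA string (the full context; Kozak context bases may lie
#'   outside `region`).
#' @param rule start-codon rule, see [locate_start()].
#' @param region optional `c(start, end)` restricting the scan (1-based
#'   inclusive); frames are relative to `region[1]`.
#' @return data frame with columns `frame` (0/1/2), `seg_start`, `seg_end`,
#'   `start`, `end`, `length`, `has_stop`; one row per ORF, positions in
#'   `seq` coordinates.
#' @examples
#' scan_orfs("ATGGCGTAA")
#' @export
scan_orfs <- function(seq, rule = "ATG", region = NULL) {
  rule <- match.arg(rule, START_RULES)
  L <- nchar(seq)
  if (is.null(region)) region <- c(1L, L)
  r1 <- as.integer(region[1]); r2 <- as.integer(min(region[2], L))
  out <- list()
  for (frame in 0:2) {
    if (r1 + frame > r2 - 2L) next
    cs <- seq.int(r1 + frame, r2 - 2L, by = 3L)
    codons <- substring(seq, cs, cs + 2L)
    stop_idx <- which(codons %in% c("TAA", "TAG", "TGA"))
    bounds <- c(0L, stop_idx, length(codons) + 1L)
    for (s in seq_len(length(bounds) - 1L)) {
      first <- bounds[s] + 1L                       # codon index of segment start
      last_stop <- bounds[s + 1L] <= length(codons) # segment ends in a stop codon
      last <- if (last_stop) bounds[s + 1L] else length(codons)
      if (first > last) next
      seg_start <- cs[first]
      seg_end <- cs[last] + 2L
      st <- locate_start(seq, seg_start, seg_end, rule)
      if (is.na(st)) next
      out[[length(out) + 1L]] <- data.frame(
        frame = frame, seg_start = seg_start, seg_end = seg_end,
        start = st, end = seg_end, length = seg_end - st + 1L,
        has_stop = last_stop, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(), seg_start = integer(),
                      seg_end = integer(), start = integer(), end = integer(),
                      length = integer(), has_stop = logical()))
  res <- do.call(rbind, out)
  res[order(res$start, res$frame), , drop = FALSE]
}

#' Map a recent ORF to its ancestral counterpart through an alignment
#'
#' Projects the recent ORF onto the alignment columns of an induced pair,
#' scans the ancestral row for ORFs under the same rule, and returns the
#' candidate with a consistent reading frame (codon phase agrees at at
#' least half of the jointly aligned base columns of the overlap, which
#' tolerates frame shifts caused by indels between the nodes) and maximal
#' column overlap; ties go to the most upstream candidate.
#'
#' @param recent_orf one row of [scan_orfs()] output on the younger
#'   (de-gapped `b`) sequence.
#' @param pair an [induce_pair()] result, `a` = ancestor, `b` = recent.
#' @param rule start-codon rule used for both nodes.
#' @return one-row ORF data frame (coordinates on the de-gapped ancestral
#'   sequence), or `NULL` when no overlapping frame-consistent ORF exists.
#' @export
map_ancestral_orf <- function(recent_orf, pair, rule = "ATG") {
  a <- chars(pair$a); b <- chars(pair$b)
  bcol <- which(b != "-")  # alignment column of each recent-sequence position
  acol <- which(a != "-")
  if (recent_orf$end > length(bcol)) return(NULL)
  rcols <- bcol[recent_orf$start:recent_orf$end]
  anc_seq <- paste(a[acol], collapse = "")
  cands <- scan_orfs(anc_seq, rule = rule)
  if (nrow(cands) == 0) return(NULL)
  apos_of_col <- match(seq_along(a), acol)   # column -> ancestral position
  bpos_of_col <- match(seq_along(b), bcol)
  best <- NULL; best_key <- c(-1, Inf)
  for (k in seq_len(nrow(cands))) {
    ccols <- acol[cands$start[k]:cands$end[k]]
    ov <- intersect(rcols, ccols)
    if (!length(ov)) next
    ## phase agreement on columns where both rows have bases
    bb <- bpos_of_col[ov]; aa <- apos_of_col[ov]
    okc <- !is.na(bb) & !is.na(aa)
    if (!any(okc)) next
    agree <- mean((bb[okc] - recent_orf$start) %% 3 ==
                  (aa[okc] - cands$start[k]) %% 3)
    if (agree < 0.5) next
    key <- c(length(ov), cands$start[k])
    if (key[1] > best_key[1] ||
        (key[1] == best_key[1] && key[2] < best_key[2])) {
      best <- cands[k, , drop = FALSE]
      best_key <- key
    }
  }
  best
}

#' Classify an ORF length change
#'
#' @param anc ancestral ORF row (or NULL when no ancestral ORF was found).
#' @param recent recent ORF row, same start-codon rule.
#' @return `"Extend"`, `"Shrink"`, `"NoChange"`, or `NA` when the ancestral
#'   ORF is absent (such loci are tallied separately, not as a change).
#' @export
classify_length_change <- function(anc, recent) {
  if (is.null(anc) || (is.data.frame(anc) && nrow(anc) == 0)) return(NA_character_)
  if (recent$length > anc$length) "Extend"
  else if (recent$length < anc$length) "Shrink"
  else "NoChange"
}

#' Classify a Kozak-signature transition
#'
#' @param anc_has,recent_has does the (ancestral, recent) ORF segment
#'   contain a start matching the Kozak pattern?
#' @return one of `"No"` (neither), `"Retain"` (both), `"Disappear"`
#'   (ancestor only), `"Appear"` (recent only).
#' @export
classify_kozak_transition <- function(anc_has, recent_has) {
  if (is.na(anc_has) || is.na(recent_has)) return(NA_character_)
  if (anc_has && recent_has) "Retain"
  else if (anc_has) "Disappear"
  else if (recent_has) "Appear"
  else "No"
}
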