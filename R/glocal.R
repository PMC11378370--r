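#' Alignment scoring scheme
#'
#' DNA-typical scores: match +5, mismatch -4, with an affine gap penalty of
#' `gap_open + k * gap_extend` for a gap run of length `k`.
#'
#' @param match,mismatch per-column substitution scores.
#' @param gap_open,gap_extend affine gap parameters (negative).
#' @return list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 5, mismatch = -4,
                           gap_open = -12, gap_extend = -4) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' Glocal (global-in-query, local-in-target) alignment
#'
#' Maximises the affine-gap score over all target substrings with the full
#' query aligned: end gaps in the target are free, the query must be fully
#' consumed. This is the alignment mode used to map a locus (with flanks)
#' onto a related genome.
#'
#' @param query,target DNA strings; the query must be non-empty.
#' @param scoring a [scoring_scheme()].
#' @return object of class `glocal_alignment`: list with `query_aligned`,
#'   `target_aligned` (equal-length gapped strings), `target_interval`
#'   (1-based inclusive),
#'   `score`.
#' @examples
#' glocal_align("AC", "TTTTACTTTT")$target_interval
#' @export
glocal_align <- function(query, target, scoring = scoring_scheme()) {
  if (!nzchar(query)) stop("empty query")
  if (!nzchar(target)) stop("empty target")
  res <- glocal_align_cpp(query, target, scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_extend)
  al <- list(query_aligned = res$query_aligned,
             target_aligned = res$target_aligned,
             target_interval = c(res$target_start, res$target_end),
             target_strand = "+",
             score = res$score)
  class(al) <- "glocal_alignment"
  al
}

#' Glocal alignment score against a long target
#'
#' Score-only scan in linear memory, returning the score and the target end
#' position of an optimal alignment. Used by [find_orthologue()] to scan
#' whole chromosomes before running the windowed traceback.
#'
#' @inheritParams glocal_align
#' @return list with `score` and `end`.
#' @export
glocal_score <- function(query, target, scoring = scoring_scheme()) {
  if (!nzchar(query)) stop("empty query")
  glocal_score_cpp(query, target, scoring$match, scoring$mismatch,
                   scoring$gap_open, scoring$gap_extend, FALSE)
}

## locate the start of the optimal alignment ending at `end` by scanning the
## reversed prefix; ties resolved toward the leftmost start
glocal_start <- function(query, target, end, scoring) {
  rq <- revstr(query)
  rt <- revstr(substr(target, 1, end))
  res <- glocal_score_cpp(rq, rt, scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_extend, TRUE)
  list(score = res$score, start = end - res$end + 1L)
}

revstr <- function(x) paste(rev(chars(x)), collapse = "")

#' @export
print.glocal_alignment <- function(x, ...) {
  cat("glocal alignment, score ", x$score, ", target ",
      x$target_interval[1], "..", x$target_interval[2],
      " (", x$target_strand, ")\n", sep = "")
  invisible(x)
}
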