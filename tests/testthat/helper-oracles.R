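# shared test helpers: random inputs and independent scorers

random_seq <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# score an explicit gapped alignment under the package's affine convention
# (gap run of length k costs open + k * extend); written independently of
# the aligner: walks columns and run-length-codes the gaps
score_alignment <- function(qa, ta, scoring = scoring_scheme(),
                            free_target_ends = TRUE) {
  q <- strsplit(qa, "")[[1]]; t <- strsplit(ta, "")[[1]]
  stopifnot(length(q) == length(t))
  sc <- 0
  state <- "none"; runlen <- 0
  flush <- function() if (runlen > 0) scoring$gap_open + runlen * scoring$gap_extend else 0
  runs <- list()
  for (i in seq_along(q)) {
    if (q[i] != "-" && t[i] != "-") {
      sc <- sc + if (q[i] == t[i]) scoring$match else scoring$mismatch
      if (runlen > 0) runs[[length(runs) + 1]] <- list(state = state, len = runlen,
                                                      at_start = FALSE)
      state <- "none"; runlen <- 0
    } else {
      side <- if (q[i] == "-") "q" else "t"
      if (side != state && runlen > 0) {
        runs[[length(runs) + 1]] <- list(state = state, len = runlen)
        runlen <- 0
      }
      state <- side; runlen <- runlen + 1
    }
  }
  if (runlen > 0) runs[[length(runs) + 1]] <- list(state = state, len = runlen)
  for (r in runs) sc <- sc + scoring$gap_open + r$len * scoring$gap_extend
  sc
}

# per-column mutation-count oracle (no vectorisation shared with the
# implementation): walks an induced pair column by column
mutation_counts_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  keep <- !(ca == "N" | cb == "N")
  ca <- ca[keep]; cb <- cb[keep]
  counts <- c(transition = 0, transversion = 0, "AT>GC" = 0, "GC>AT" = 0,
              "AT>AT" = 0, "GC>GC" = 0, indel = 0)
  in_gap <- FALSE; gap_row <- ""
  for (i in seq_along(ca)) {
    x <- ca[i]; y <- cb[i]
    if (x == "-" && y == "-") stop("both-gap column in induced pair")
    if (x == "-" || y == "-") {
      row <- if (x == "-") "a" else "b"
      if (!in_gap || row != gap_row) counts["indel"] <- counts["indel"] + 1
      in_gap <- TRUE; gap_row <- row
      next
    }
    in_gap <- FALSE
    if (x != y) {
      ts <- (x %in% c("A", "G") && y %in% c("A", "G")) ||
            (x %in% c("C", "T") && y %in% c("C", "T"))
      counts[if (ts) "transition" else "transversion"] <-
        counts[if (ts) "transition" else "transversion"] + 1
      xat <- x %in% c("A", "T"); yat <- y %in% c("A", "T")
      cls <- if (xat && !yat) "AT>GC" else if (!xat && yat) "GC>AT"
             else if (xat) "AT>AT" else "GC>GC"
      counts[cls] <- counts[cls] + 1
    }
  }
  counts
}

# random gapped pair with no both-gap column
random_induced_pair <- function(len, p_gap = 0.1, p_n = 0.02) {
  a <- character(len); b <- character(len)
  for (i in seq_len(len)) {
    r <- runif(1)
    if (r < p_gap / 2) { a[i] <- "-"; b[i] <- sample(c("A","C","G","T"), 1) }
    else if (r < p_gap) { b[i] <- "-"; a[i] <- sample(c("A","C","G","T"), 1) }
    else {
      a[i] <- sample(c("A", "C", "G", "T", "N"), 1,
                     prob = c(rep((1 - p_n) / 4, 4), p_n))
      b[i] <- sample(c("A", "C", "G", "T", "N"), 1,
                     prob = c(rep((1 - p_n) / 4, 4), p_n))
    }
  }
  structure(list(a = paste(a, collapse = ""), b = paste(b, collapse = ""),
                 cols = seq_len(len)),
            class = "induced_pair")
}

degap_chr <- function(x) gsub("-", "", x, fixed = TRUE)
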