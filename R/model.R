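BASES <- c("A", "C", "G", "T")

#' HKY substitution model
#'
#' Transition/transversion rate ratio `kappa` plus stationary base
#' frequencies, the minimal parameterisation that reproduces all six
#' substitution classes tracked by the pipeline (transition, transversion,
#' AT>GC, GC>AT, AT>AT, GC>GC). The rate matrix is scaled so one unit of
#' branch length equals one expected substitution per site.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param base_freqs stationary frequencies, named or in A,C,G,T order,
#'   non-negative, summing to 1. `NULL` means "estimate from the data"
#'   (resolved by [reconstruct_ancestors()]).
#' @return object of class `sub_model`.
#' @examples
#' sub_model(kappa = 2)
#' @export
sub_model <- function(kappa = 2, base_freqs = NULL) {
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa <= 0)
    stop("kappa must be a single positive number")
  if (!is.null(base_freqs)) {
    if (length(base_freqs) != 4 || any(base_freqs < 0) ||
        abs(sum(base_freqs) - 1) > 1e-9)
      stop("base_freqs must be 4 non-negative values summing to 1")
    base_freqs <- unname(base_freqs)
  }
  structure(list(kappa = kappa, base_freqs = base_freqs), class = "sub_model")
}

## frequencies for a stationary G+C fraction, A/T and G/C split evenly
gc_base_freqs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

is_transition_pair <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}

## HKY rate matrix (rows = from, cols = to, order A,C,G,T), scaled to one
## expected substitution per site per unit time at stationarity
hky_rate_matrix <- function(kappa, base_freqs) {
  pi <- base_freqs
  Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    r <- pi[j]
    if (is_transition_pair(BASES[i], BASES[j])) r <- r * kappa
    Q[i, j] <- r
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q / scale
}

## transition probability matrix P(t) = exp(Q t) via eigendecomposition
## (HKY has a real spectrum)
hky_prob_matrix <- function(Q, t) {
  if (t < 0) stop("branch length must be non-negative")
  if (t == 0) return(diag(4))
  e <- eigen(Q)
  P <- Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
  P[P < 0] <- 0
  P / rowSums(P)
  }
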