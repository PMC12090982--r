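# Independent oracles used across the suite. These re-derive expected
# results from first principles (explicit if-chains, exhaustive enumeration)
# and deliberately share no code with the package internals.

# Scalar re-statement of the classification rules as a plain decision chain.
oracle_classify <- function(H, N, F, S) {
  if (H > 3 && N <= 2 && F == 0 && S == 0) {
    type <- "HIGH_MANNOSE"
  } else if (H < 4 && N < 3 && S == 0) {
    type <- "PAUCI_MANNOSE"
  } else if (N == 3 && H >= 4) {
    type <- "HYBRID"
  } else if (N >= 4) {
    type <- "COMPLEX"
  } else {
    type <- "UNCLASSIFIED"
  }
  deco <- character(0)
  ambiguous <- FALSE
  if (type %in% c("HYBRID", "COMPLEX")) {
    if (F == 1) deco <- c(deco, "FUCOSYLATED")
    if (F > 1) deco <- c(deco, "MULTI_FUCOSYLATED")
    if (S >= 1) deco <- c(deco, "SIALYLATED")
    if (H == 6 && N == 6) {
      ambiguous <- TRUE
      deco <- c(deco, "BISECTING_OR_TETRA_ANTENNARY")
    } else {
      if (N == H && (N == 5 || N > 6)) deco <- c(deco, "BISECTING")
      if (N >= 6) deco <- c(deco, "TETRA_ANTENNARY")
    }
    if (N > 6 && H > 7) deco <- c(deco, "POLYLACTOSAMINE")
  }
  list(type = type, decorations = sort(deco), ambiguous = ambiguous)
}

# Exhaustive hypergeometric upper tail P(X >= k) from binomial coefficients.
oracle_hyper_tail <- function(k, K, n, N) {
  xs <- k:min(n, K)
  xs <- xs[xs >= max(0, n - (N - K))]
  if (length(xs) == 0) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Exact binomial upper tail P(X >= k) by direct summation.
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  xs <- k:n
  sum(choose(n, xs) * p^xs * (1 - p)^(n - xs))
}

# Random valid composition over the common residue kinds (sometimes with an
# extra exotic symbol) for round-trip property tests.
random_composition <- function() {
  repeat {
    counts <- c(Hex = sample(0:12, 1), HexNAc = sample(0:12, 1),
                dHex = sample(0:4, 1), NeuAc = sample(0:4, 1))
    if (runif(1) < 0.2) counts <- c(counts, Pent = sample(0:2, 1))
    if (sum(counts) > 0) return(glycan_composition(counts))
  }
}

grid_compositions <- function() {
  g <- expand.grid(H = 0:12, N = 0:12, F = 0:4, S = 0:4)
  g[g$H + g$N + g$F + g$S > 0, ]
}
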