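# small helper: run term_enrichment over an artificial index
enrich1 <- function(k, n, K, N) {
  universe <- sprintf("u%02d", seq_len(N))
  query <- universe[seq_len(n)]
  members <- c(universe[seq_len(k)],                 # hits inside the query
               universe[n + seq_len(K - k)])         # the rest outside
  term_enrichment(query, universe, list(T1 = members))
}

test_that("Fisher tail matches exhaustive hypergeometric enumeration", {
  # reference table: N = 20, K = 5, n = 5, k = 4 -> 76/15504
  r <- enrich1(4, 5, 5, 20)
  expect_equal(r$p_fisher, 76 / 15504, tolerance = 1e-12)
  expect_equal(r$p_fisher, oracle_hyper_tail(4, 5, 5, 20), tolerance = 1e-12)

  # degenerate cases
  expect_equal(enrich1(0, 5, 5, 20)$p_fisher, 1)          # P(X >= 0) = 1
  expect_equal(enrich1(5, 5, 5, 5)$p_fisher, 1)           # query = universe

  # every attainable table with N <= 12 (spot grid; the acceptance suite
  # sweeps N <= 25)
  for (N in c(5, 9, 12)) {
    for (n in 1:N) for (K in 0:N) {
      for (k in max(0, n + K - N):min(n, K)) {
        expect_equal(enrich1(k, n, K, N)$p_fisher,
                     oracle_hyper_tail(k, K, n, N), tolerance = 1e-10,
                     label = sprintf("k=%d n=%d K=%d N=%d", k, n, K, N))
      }
    }
  }
})

test_that("EASE removes one hit and is never more significant than Fisher", {
  r <- enrich1(1, 5, 5, 20)
  expect_equal(r$p_ease, 1)  # single hit collapses to P(X >= 0)

  r <- enrich1(4, 5, 5, 20)
  expect_equal(r$p_ease, oracle_hyper_tail(3, 5, 5, 20), tolerance = 1e-12)
  expect_gt(r$p_ease, r$p_fisher)

  pick <- function(lo, hi) { v <- lo:hi; v[sample.int(length(v), 1)] }
  set.seed(1)
  for (i in 1:300) {
    N <- pick(2, 60); K <- pick(1, N)
    n <- pick(1, min(30, N))
    k <- pick(max(0, n + K - N), min(n, K))
    r <- enrich1(k, n, K, N)
    expect_gte(r$p_ease, r$p_fisher)
  }
})

test_that("binomial tail is an explicit sum and approximates Fisher at large N", {
  r <- enrich1(4, 5, 5, 20)   # K/N = 0.25
  expect_equal(r$p_binomial, oracle_binom_tail(4, 5, 0.25), tolerance = 1e-12)
  expect_equal(oracle_binom_tail(4, 5, 0.25), 1 / 64, tolerance = 1e-12)
  expect_equal(enrich1(0, 4, 5, 20)$p_binomial, 1)

  # K = 0 forces k = 0; the degenerate success probability must not fail
  expect_equal(enrich1(0, 5, 0, 20)$p_binomial, 1, tolerance = 1e-12)

  # sampling with/without replacement converge for a tiny query
  big <- stats::phyper(3, 25000, 75000, 10, lower.tail = FALSE)
  expect_equal(stats::pbinom(3, 10, 0.25, lower.tail = FALSE), big,
               tolerance = 1e-3)
})

test_that("KS rank enrichment separates shifted terms and tolerates edge terms", {
  m <- 10
  universe <- sprintf("u%02d", 1:(4 * m))
  members <- universe[1:m]
  ranks <- structure(seq_along(universe), names = universe)
  idx <- list(TOP = members, ALL = universe)

  res <- term_enrichment(universe[1:2], universe, idx, ranks = ranks)
  top <- res[res$term == "TOP", ]
  expect_true(top$ks_testable)
  expect_lt(top$p_ks, 1e-4)   # members hold the top m ranks: D = 1

  # a term spanning the whole universe has no non-members: untestable, no error
  all_row <- res[res$term == "ALL", ]
  expect_false(all_row$ks_testable)
  expect_true(is.na(all_row$p_ks))

  # interleaved ranks (members on odd positions): D = 1/m, comfortably null
  inter <- universe[seq(1, 2 * m, by = 2)]
  ranks2 <- structure(c(seq_len(2 * m), rep(0, 2 * m)), names = universe)
  res2 <- term_enrichment(universe[1:2], universe[1:(2 * m)],
                          list(ODD = inter), ranks = ranks2[1:(2 * m)])
  expect_gt(res2$p_ks, 0.5)

  # permuting rank labels yields roughly uniform p-values
  set.seed(8)
  n_univ <- 40
  u <- sprintf("u%02d", 1:n_univ)
  mem <- u[1:10]
  ps <- replicate(400, {
    r <- structure(sample(n_univ), names = u)
    term_enrichment(u[1:5], u, list(T = mem), ranks = r)$p_ks
  })
  expect_gt(mean(ps > 0.5), 0.3)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("enrichment results are invariant to identifier relabeling", {
  set.seed(3)
  universe <- sprintf("u%02d", 1:30)
  query <- sample(universe, 8)
  idx <- list(A = sample(universe, 12), B = sample(universe, 5))
  base <- term_enrichment(query, universe, idx)

  relabel <- structure(sprintf("x%02d", sample(30)), names = universe)
  res <- term_enrichment(unname(relabel[query]), unname(relabel[universe]),
                         lapply(idx, function(m) unname(relabel[m])))
  expect_equal(res[c("k", "n", "K", "N", "p_fisher", "p_ease", "p_binomial")],
               base[c("k", "n", "K", "N", "p_fisher", "p_ease", "p_binomial")])
})

test_that("input contracts are enforced", {
  expect_error(term_enrichment("a", character(0), list(T = "a")), "universe")
  expect_error(term_enrichment("a", c("a", "b"), list()), "term_index")
  expect_error(term_enrichment("z", c("a", "b"), list(T = "a")),
               "outside the universe")
  expect_error(term_enrichment("a", c("a", "b"), list(T = "z")),
               "outside the universe")
  expect_message(term_enrichment(c("a", "a"), c("a", "b"), list(T = "a")),
                 "duplicate")
})

test_that("Benjamini-Hochberg adjustment matches the hand computation", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(0.2), 0.2)
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_pvalues(numeric(0)), numeric(0))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  expect_true(all(adjust_pvalues(p) >= p))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})
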