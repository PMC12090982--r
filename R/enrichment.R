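#' Term enrichment over a glycan query set
#'
#' Tests each ontology term for over-representation in a query set of glycans
#' relative to a background universe, the way gene-ontology tools test GO
#' terms. Four statistics are computed per term:
#'
#' * **Fisher**: one-sided hypergeometric tail, `P(X >= k)` for
#'   `X ~ Hypergeometric(N, K, n)` where `N` = universe size, `K` = universe
#'   members of the term, `n` = query size, `k` = query members of the term.
#' * **EASE**: the DAVID-style conservative variant; one observed hit is
#'   removed (`k` replaced by `max(k - 1, 0)`) before taking the same tail.
#'   EASE p-values are therefore never smaller than Fisher p-values.
#' * **Binomial**: exact tail `P(X >= k)` for `X ~ Binomial(n, K/N)`.
#' * **Kolmogorov-Smirnov** (when `ranks` is supplied): two-sample KS
#'   comparing the rank distribution of term members against non-members,
#'   with the asymptotic p-value. Terms with no member or no non-member in
#'   the universe are flagged untestable (`NA` p) rather than erroring.
#'
#' @param query Character vector of glycan identifiers; must be a subset of
#'   `universe`. Duplicates are collapsed to a set with a message.
#' @param universe Character vector of background glycan identifiers.
#' @param term_index Named list term -> member identifiers, as produced by
#'   [ontology_terms()]; every member must belong to the universe.
#' @param ranks Optional named numeric vector over the whole universe (e.g. a
#'   co-localization score or abundance rank statistic). Ties are broken by
#'   stable ordering on the identifier so ranks are always distinct.
#' @param ks_mode `"two_sample"` (default) compares members against
#'   non-members; `"uniform"` tests member ranks, rescaled to (0, 1), against
#'   the uniform distribution.
#' @param adjust Multiple-testing adjustment for `q_value`: `"BH"` (default)
#'   or `"bonferroni"`.
#' @param adjust_test Which p-value column feeds `q_value` (default
#'   `"fisher"`).
#'
#' @return A data.frame with one row per term: `term`, `k`, `n`, `K`, `N`,
#'   `odds_ratio`, `p_fisher`, `p_ease`, `p_binomial`, `p_ks`, `ks_testable`,
#'   `q_value`.
#' @examples
#' ont <- ontology_terms(c(a = "Hex:7 HexNAc:2", b = "Hex:3 HexNAc:6",
#'                         c = "Hex:5 HexNAc:4 dHex:1", d = "Hex:3 HexNAc:2"))
#' term_enrichment(query = c("a", "b"), universe = c("a", "b", "c", "d"),
#'                 term_index = ont$index)
#' @export
term_enrichment <- function(query, universe, term_index, ranks = NULL,
                            ks_mode = c("two_sample", "uniform"),
                            adjust = c("BH", "bonferroni"),
                            adjust_test = c("fisher", "ease", "binomial", "ks")) {
  ks_mode <- match.arg(ks_mode)
  adjust <- match.arg(adjust)
  adjust_test <- match.arg(adjust_test)

  if (length(universe) == 0) stop("universe must be non-empty")
  if (length(term_index) == 0 || is.null(names(term_index)))
    stop("term_index must be a non-empty named list")
  universe <- unique(as.character(universe))
  query <- as.character(query)
  if (anyDuplicated(query)) {
    message("collapsing ", sum(duplicated(query)),
            " duplicate query identifier(s) to a set")
    query <- unique(query)
  }
  if (length(query) == 0) stop("query must be non-empty")
  stray <- setdiff(query, universe)
  if (length(stray) > 0)
    stop("query identifiers outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "))
  for (tm in names(term_index)) {
    out <- setdiff(term_index[[tm]], universe)
    if (length(out) > 0)
      stop("term ", tm, " has member(s) outside the universe: ",
           paste(utils::head(out, 5), collapse = ", "))
  }

  N <- length(universe)
  n <- length(query)

  rank_of <- NULL
  if (!is.null(ranks)) {
    if (is.null(names(ranks)) || !all(universe %in% names(ranks)))
      stop("ranks must be a named vector covering the whole universe")
    r <- ranks[universe]
    # stable tie-break on identifier -> distinct integer ranks 1..N
    rank_of <- integer(N)
    rank_of[order(r, universe)] <- seq_len(N)
    names(rank_of) <- universe
  }

  rows <- lapply(names(term_index), function(tm) {
    members <- unique(term_index[[tm]])
    K <- length(members)
    k <- length(intersect(members, query))

    p_fisher <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    k_ease <- max(k - 1L, 0L)
    p_ease <- stats::phyper(k_ease - 1, K, N - K, n, lower.tail = FALSE)
    p_binom <- stats::pbinom(k - 1, n, K / N, lower.tail = FALSE)

    # 2x2 table: query/term membership; Haldane 0.5 only when a cell is 0
    a <- k; b <- n - k; c2 <- K - k; d <- N - K - n + k
    if (min(a, b, c2, d) == 0) {
      a <- a + 0.5; b <- b + 0.5; c2 <- c2 + 0.5; d <- d + 0.5
    }
    or <- (a * d) / (b * c2)

    p_ks <- NA_real_
    testable <- FALSE
    if (!is.null(rank_of)) {
      in_term <- universe %in% members
      if (any(in_term) && any(!in_term)) {
        testable <- TRUE
        if (ks_mode == "two_sample") {
          p_ks <- suppressWarnings(stats::ks.test(
            rank_of[in_term], rank_of[!in_term], exact = FALSE))$p.value
        } else {
          u <- (rank_of[in_term] - 0.5) / N
          p_ks <- suppressWarnings(stats::ks.test(u, "punif"))$p.value
        }
      }
    }

    data.frame(term = tm, k = k, n = n, K = K, N = N, odds_ratio = or,
               p_fisher = p_fisher, p_ease = p_ease, p_binomial = p_binom,
               p_ks = p_ks, ks_testable = testable, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  pcol <- paste0("p_", c(fisher = "fisher", ease = "ease",
                         binomial = "binomial", ks = "ks")[adjust_test])
  res$q_value <- adjust_pvalues(res[[pcol]], method = adjust)
  rownames(res) <- NULL
  res
}

#' Adjust p-values for multiple testing
#'
#' Thin wrapper around [stats::p.adjust()] restricted to the procedures the
#' enrichment interface exposes; `NA` p-values (untestable terms) propagate
#' as `NA` q-values.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @param method `"BH"` (Benjamini-Hochberg step-up, default) or
#'   `"bonferroni"`.
#' @return Adjusted q-values, same length and order as `p`.
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03))  # all 0.03 under BH
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}
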