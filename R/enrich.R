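#' @include utils.R
NULL

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least k members of a K-member set when sampling n features without
#' replacement from a universe of N. Computed via [stats::phyper()]
#' (numerically stable tail evaluation).
#'
#' @param N universe size.
#' @param K gene-set size within the universe.
#' @param n query-list size.
#' @param k observed overlap.
#' @return the upper-tail probability.
#' @examples
#' hypergeomUpper(10, 4, 5, 4) # 6/252
#' @export
hypergeomUpper <- function(N, K, n, k) {
  .assert(
    .isCount(N) && .isCount(K, positive = FALSE) &&
      .isCount(n, positive = FALSE) && .isCount(k, positive = FALSE),
    "N, K, n, k must be non-negative integers (N >= 1)"
  )
  .assert(K <= N && n <= N, "need K <= N and n <= N")
  .assert(k <= min(K, n), "need k <= min(K, n)")
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving with respect to the input indexing (a thin validated
#' wrapper over [stats::p.adjust()]).
#'
#' @param pvals numeric p-values in (0, 1].
#' @return adjusted q-values in the input order; empty input gives empty
#'   output.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03)) # all 0.03
#' @export
bhAdjust <- function(pvals) {
  if (!length(pvals)) {
    return(numeric())
  }
  .assert(
    is.numeric(pvals) && all(is.finite(pvals)) &&
      all(pvals > 0 & pvals <= 1),
    "p-values must lie in (0, 1]"
  )
  p.adjust(pvals, method = "BH")
}

#' Hypergeometric gene-set enrichment of a query list
#'
#' Tests each gene set for over-representation in the query list via the
#' upper-tail hypergeometric probability, with sets intersected with the
#' universe before counting. Every set with at least one universe member
#' is tested (so BH adjustment spans them all); rows with overlap below
#' `minOverlap` are then hidden from the returned table. Sets with no
#' members in the universe are dropped with a message.
#'
#' @param query character vector of gene ids (must be within `universe`).
#' @param universe character vector: all detectable genes of the matching
#'   biotype.
#' @param sets gene-set collection as returned by [readGmt()].
#' @param minOverlap minimum overlap k for a set to be reported.
#' @param direction tag inherited from how the query was built (`"up"`,
#'   `"down"` or `"mixed"`).
#' @return data.frame sorted by p with columns `set`, `k`, `K`, `n`, `N`,
#'   `p`, `q`, `direction`.
#' @export
enrichList <- function(query, universe, sets, minOverlap = 1,
                       direction = c("mixed", "up", "down")) {
  direction <- match.arg(direction)
  .assert(!anyDuplicated(universe), "duplicated ids in universe")
  query <- unique(query)
  bad <- setdiff(query, universe)
  .assert(
    length(bad) == 0,
    "query genes outside the universe: ",
    paste(utils::head(bad, 10), collapse = ", ")
  )
  members <- lapply(sets, intersect, universe)
  empty <- lengths(members) == 0
  if (any(empty)) {
    message(
      sum(empty), " gene set(s) with no universe members excluded: ",
      paste(utils::head(names(sets)[empty], 5), collapse = ", ")
    )
    members <- members[!empty]
  }
  N <- length(universe)
  n <- length(query)
  K <- lengths(members)
  k <- vapply(members, function(m) length(intersect(m, query)), integer(1))
  p <- vapply(seq_along(members), function(i) {
    hypergeomUpper(N, K[[i]], n, k[[i]])
  }, numeric(1))
  q <- bhAdjust(p)
  res <- data.frame(
    set = names(members), k = k, K = K, n = n, N = N, p = p, q = q,
    direction = direction, stringsAsFactors = FALSE, row.names = NULL
  )
  res <- res[res$k >= minOverlap, , drop = FALSE]
  res[order(res$p, res$set, method = "radix"), , drop = FALSE]
}
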