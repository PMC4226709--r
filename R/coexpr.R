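#' @include AllGenerics.R
NULL

#' Pearson correlation with an undefined-value sentinel
#'
#' Standard product-moment coefficient. A zero-variance vector makes the
#' correlation undefined; this returns `NA` (the sentinel excluded and
#' tallied downstream) rather than raising, so constant features never
#' abort a matrix build.
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return a single correlation in \[-1, 1\], or `NA` if undefined.
#' @examples
#' pearsonCor(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 0.8
#' @export
pearsonCor <- function(x, y) {
  .assert(length(x) == length(y), "'x' and 'y' must have equal length")
  .assert(length(x) >= 3, "need at least 3 observations")
  .assert(all(is.finite(x)) && all(is.finite(y)), "values must be finite")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(NA_real_)
  }
  unname(cor(x, y))
}

#' @noRd
.spanColumns <- function(ue, span = c("all", "tumor")) {
  span <- match.arg(span)
  if (span == "all") {
    colnames(ue)
  } else {
    sheet <- sampleSheet(ue)
    sheet$sample[sheet$tissue == "T"]
  }
}

#' Build the trichotomized mRNA x lncRNA correlation matrix
#'
#' Pearson correlations between every dysregulated mRNA (rows) and
#' dysregulated lncRNA (columns) across the chosen sample span, then
#' trichotomized with strict inequalities: +1 where r > cutoff, -1 where
#' r < -cutoff, 0 otherwise (so r equal to the cutoff maps to 0).
#' Zero-variance features yield undefined cells (NA), tallied separately;
#' the positive/negative/none/undefined counts always sum to rows x cols.
#'
#' @param ue a [UlmExperiment-class], normally quantile-normalized.
#' @param mrnaIds,lncIds row and column feature ids. Alternatively pass
#'   `de` to derive them.
#' @param de optional DataFrame from [diffExprTable()]: rows become the
#'   mRNAs and columns the lncRNAs called in either contrast.
#' @param cutoff the |r| threshold (default 0.8).
#' @param span `"all"` samples (default) or `"tumor"` only.
#' @return a [CoexMatrix-class].
#' @export
buildCoexMatrix <- function(ue, mrnaIds = NULL, lncIds = NULL, de = NULL,
                            cutoff = 0.8, span = c("all", "tumor")) {
  span <- match.arg(span)
  if (!is.null(de)) {
    called <- rownames(de)[de$callS != "none" | de$callL != "none"]
    if (is.null(mrnaIds)) {
      mrnaIds <- called[de[called, "biotype"] == "mRNA"]
    }
    if (is.null(lncIds)) lncIds <- called[de[called, "biotype"] == "lncRNA"]
  }
  .assert(
    length(mrnaIds) > 0 && length(lncIds) > 0,
    "empty mRNA row set or lncRNA column set"
  )
  .assert(
    all(c(mrnaIds, lncIds) %in% rownames(ue)),
    "feature ids absent from the experiment"
  )
  cols <- .spanColumns(ue, span)
  .assert(length(cols) >= 3, "need at least 3 samples in the span")
  m <- assay(ue)[, cols, drop = FALSE]
  xm <- t(m[mrnaIds, , drop = FALSE])
  xl <- t(m[lncIds, , drop = FALSE])
  constM <- apply(xm, 2, stats::var) == 0
  constL <- apply(xl, 2, stats::var) == 0
  r <- suppressWarnings(cor(xm, xl))
  r[constM, ] <- NA_real_
  r[, constL] <- NA_real_
  tri <- ifelse(r > cutoff, 1L, ifelse(r < -cutoff, -1L, 0L))
  new("CoexMatrix", r = r, tri = tri, cutoff = cutoff, span = span)
}

#' Per-subtype cis correlation profiles
#'
#' Pearson correlation between each cis lncRNA-mRNA pair across the sample
#' span, summarized per subtype: the r values, positive/negative fractions
#' and a density-style histogram. Undefined correlations (constant
#' features) are excluded and counted. Subtypes with no pairs yield an
#' empty, flagged summary.
#'
#' @param pairs data.frame from [cisPartnerPairs()] (columns lnc, mrna,
#'   subtype).
#' @param ue a [UlmExperiment-class].
#' @param span `"all"` or `"tumor"`.
#' @param bins histogram bins.
#' @return list with `summary` (data.frame: subtype, n, nUndefined,
#'   fracPositive, fracNegative, empty), `values` (named list of r vectors
#'   per subtype) and `density` (named list of histogram tables).
#' @export
cisCorrelationProfile <- function(pairs, ue, span = c("all", "tumor"),
                                  bins = 20) {
  span <- match.arg(span)
  .assert(
    all(c("lnc", "mrna", "subtype") %in% colnames(pairs)),
    "'pairs' needs columns lnc, mrna, subtype"
  )
  .assert(
    all(pairs$lnc %in% rownames(ue)) && all(pairs$mrna %in% rownames(ue)),
    "pair features absent from the experiment"
  )
  cols <- .spanColumns(ue, span)
  m <- assay(ue)[, cols, drop = FALSE]
  subtypes <- .CIS_SUBTYPES
  values <- list()
  density <- list()
  summary <- data.frame(
    subtype = subtypes, n = 0L, nUndefined = 0L,
    fracPositive = NA_real_, fracNegative = NA_real_, empty = TRUE,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(subtypes)) {
    st <- subtypes[i]
    sel <- pairs[pairs$subtype == st, , drop = FALSE]
    if (!nrow(sel)) {
      values[[st]] <- numeric()
      density[[st]] <- data.frame(mid = numeric(), density = numeric())
      next
    }
    r <- vapply(seq_len(nrow(sel)), function(k) {
      pearsonCor(m[sel$lnc[k], ], m[sel$mrna[k], ])
    }, numeric(1))
    und <- sum(is.na(r))
    r <- r[!is.na(r)]
    values[[st]] <- r
    summary$n[i] <- length(r)
    summary$nUndefined[i] <- und
    summary$empty[i] <- length(r) == 0
    if (length(r)) {
      summary$fracPositive[i] <- mean(r > 0)
      summary$fracNegative[i] <- mean(r < 0)
      h <- graphics::hist(r,
        breaks = seq(-1, 1, length.out = bins + 1), plot = FALSE
      )
      density[[st]] <- data.frame(mid = h$mids, density = h$density)
    } else {
      density[[st]] <- data.frame(mid = numeric(), density = numeric())
    }
  }
  list(summary = summary, values = values, density = density)
}

#' Relevance scores of mRNAs against a lncRNA set
#'
#' For each mRNA (row of the correlation matrix), the sum of absolute
#' correlation coefficients over the cutoff-passing cells (tri != 0)
#' restricted to the given lncRNA set. Rows are ranked by descending
#' score with deterministic id tie-break.
#'
#' @param cm a [CoexMatrix-class].
#' @param lncSet character vector of column (lncRNA) ids.
#' @param filtered when `TRUE` (default) only cutoff-passing cells
#'   contribute; `FALSE` sums |r| over all defined cells.
#' @return data.frame ordered by rank with columns `mrna`, `score`,
#'   `rank`.
#' @examples
#' # a row correlating 0.9, -0.85, 0.5 with the set at cutoff 0.8
#' # scores 0.9 + 0.85 = 1.75
#' @export
relevanceScores <- function(cm, lncSet, filtered = TRUE) {
  stopifnot(is(cm, "CoexMatrix"))
  unknown <- setdiff(lncSet, colnames(cm@r))
  .assert(
    length(unknown) == 0,
    "unknown lncRNA ids in set: ", paste(unknown, collapse = ", ")
  )
  r <- cm@r[, lncSet, drop = FALSE]
  tri <- cm@tri[, lncSet, drop = FALSE]
  contrib <- abs(r)
  if (filtered) contrib[tri == 0L] <- 0
  contrib[is.na(contrib)] <- 0
  score <- rowSums(contrib)
  ord <- order(-score, rownames(cm@r), method = "radix")
  data.frame(
    mrna = rownames(cm@r)[ord],
    score = score[ord],
    rank = seq_along(score),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Select top-ranked genes from a relevance ranking
#'
#' @param ranking data.frame from [relevanceScores()].
#' @param mode `"k"` (top k by rank) or `"score_min"` (all genes with
#'   score >= value).
#' @param value k (positive integer) or the minimum score.
#' @return character vector of selected mRNA ids.
#' @export
selectTop <- function(ranking, mode = c("k", "score_min"), value) {
  mode <- match.arg(mode)
  .assert(
    all(c("mrna", "score", "rank") %in% colnames(ranking)),
    "'ranking' must come from relevanceScores()"
  )
  if (mode == "k") {
    .assert(.isCount(value), "'value' must be a positive integer k")
    if (value > nrow(ranking)) {
      warning(
        "k = ", value, " exceeds the ", nrow(ranking),
        " ranked genes; returning all"
      )
      value <- nrow(ranking)
    }
    ranking$mrna[seq_len(value)]
  } else {
    .assert(is.numeric(value) && length(value) == 1, "'value' must be a number")
    ranking$mrna[ranking$score >= value]
  }
}
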