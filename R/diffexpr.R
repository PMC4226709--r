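#' @include AllGenerics.R
NULL

#' @noRd
.contrastPairs <- function(ue, contrast) {
  contrast <- match.arg(contrast, c("S", "L"))
  sheet <- sampleSheet(ue)
  tum <- sheet[sheet$tissue == "T" & sheet$size %in% contrast, , drop = FALSE]
  .assert(nrow(tum) >= 1, "no tumor samples in contrast ", contrast,
    class = "lncomat_pairing_error"
  )
  norm <- sheet[sheet$tissue == "N", , drop = FALSE]
  idx <- match(tum$patient, norm$patient)
  if (anyNA(idx)) {
    .assert(FALSE,
      "unpaired tumor sample(s): ",
      paste(tum$sample[is.na(idx)], collapse = ", "),
      class = "lncomat_pairing_error"
    )
  }
  if (anyDuplicated(norm$patient)) {
    .assert(FALSE, "multiple normal samples for one patient",
      class = "lncomat_pairing_error"
    )
  }
  data.frame(
    tumor = tum$sample, normal = norm$sample[idx], patient = tum$patient,
    stringsAsFactors = FALSE
  )
}

#' Paired log2 fold changes
#'
#' Mean over matched tumor-normal pairs of the per-pair log2 expression
#' difference, for the small-tumor (`"S"`) or large-tumor (`"L"`) contrast.
#' Since the input is log2 scale, a value of 1 is a 2-fold change.
#'
#' @param ue a [UlmExperiment-class].
#' @param contrast `"S"` or `"L"`.
#' @return named numeric vector of log2 fold changes per feature.
#' @export
pairedLog2FC <- function(ue, contrast = c("S", "L")) {
  contrast <- match.arg(contrast)
  pairs <- .contrastPairs(ue, contrast)
  m <- assay(ue)
  d <- m[, pairs$tumor, drop = FALSE] - m[, pairs$normal, drop = FALSE]
  rowMeans(d)
}

#' Paired t-tests per feature
#'
#' Classical paired t statistic on the per-patient tumor-normal
#' differences: t = mean(d) / (sd(d)/sqrt(n)) on n-1 degrees of freedom,
#' two-sided p. Degenerate features (zero difference variance) are never an
#' exception: with nonzero mean difference the p-value is the smallest
#' positive double and with zero mean it is 1, both flagged in the
#' `degenerate` column.
#'
#' @param ue a [UlmExperiment-class].
#' @param contrast `"S"` or `"L"`.
#' @return a [S4Vectors::DataFrame] with columns `t`, `df`, `p`,
#'   `degenerate`, one row per feature.
#' @export
pairedTTest <- function(ue, contrast = c("S", "L")) {
  contrast <- match.arg(contrast)
  pairs <- .contrastPairs(ue, contrast)
  n <- nrow(pairs)
  .assert(n >= 2, "paired t-test needs at least 2 pairs")
  m <- assay(ue)
  d <- m[, pairs$tumor, drop = FALSE] - m[, pairs$normal, drop = FALSE]
  mu <- rowMeans(d)
  s <- sqrt(rowSums((d - mu)^2) / (n - 1))
  t <- mu / (s / sqrt(n))
  p <- 2 * pt(-abs(t), df = n - 1)
  degenerate <- s == 0
  zeroMean <- degenerate & mu == 0
  zeroVar <- degenerate & mu != 0
  t[zeroMean] <- 0
  p[zeroMean] <- 1
  t[zeroVar] <- sign(mu[zeroVar]) * Inf
  p[zeroVar] <- .Machine$double.xmin
  DataFrame(
    t = unname(t), df = rep(n - 1L, length(t)), p = unname(p),
    degenerate = unname(degenerate), row.names = rownames(m)
  )
}

#' Dysregulation calls from fold change and p-value
#'
#' A feature is called `up` when its log2 fold change reaches
#' +log2(`fcThreshold`) (inclusive boundary) with p < `alpha` (strict),
#' `down` symmetrically, else `none`. The study convention of "2-fold
#' change and P < 0.05" corresponds to the defaults.
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @param p matching p-values.
#' @param fcThreshold fold-change threshold on the natural scale (> 0).
#' @param alpha significance level.
#' @return character vector in \{"up", "down", "none"\}, named like
#'   `log2fc`.
#' @examples
#' callDysregulated(c(1.5, 1.5, -1), c(0.01, 0.2, 0.049))
#' @export
callDysregulated <- function(log2fc, p, fcThreshold = 2, alpha = 0.05) {
  .assert(fcThreshold > 0, "'fcThreshold' must be positive")
  .assert(length(log2fc) == length(p), "lengths of 'log2fc' and 'p' differ")
  thr <- log2(fcThreshold)
  call <- rep("none", length(log2fc))
  sig <- p < alpha
  call[sig & log2fc >= thr] <- "up"
  call[sig & log2fc <= -thr] <- "down"
  names(call) <- names(log2fc)
  call
}

#' Differential expression table for both tumor-size contrasts
#'
#' Runs [pairedLog2FC()] and [pairedTTest()] for the small and large
#' contrasts, applies [callDysregulated()], and flags the four signature
#' sets (see [signatureSets()]).
#'
#' @param ue a [UlmExperiment-class] (normalize first; see
#'   [quantileNormalize()]).
#' @param fcThreshold,alpha thresholds passed to [callDysregulated()].
#' @param adjust `"none"` (raw p-values, the study convention) or `"BH"`
#'   for Benjamini-Hochberg adjustment before calling.
#' @param lsFcThreshold large-vs-small fold threshold for sets 2/4.
#' @return a [S4Vectors::DataFrame] with columns `biotype`, `log2fcS`,
#'   `pS`, `callS`, `log2fcL`, `pL`, `callL`, and logical `set1`..`set4`.
#' @export
diffExprTable <- function(ue, fcThreshold = 2, alpha = 0.05,
                          adjust = c("none", "BH"), lsFcThreshold = 2) {
  adjust <- match.arg(adjust)
  fcS <- pairedLog2FC(ue, "S")
  fcL <- pairedLog2FC(ue, "L")
  ttS <- pairedTTest(ue, "S")
  ttL <- pairedTTest(ue, "L")
  pS <- ttS$p
  pL <- ttL$p
  if (adjust == "BH") {
    pS <- bhAdjust(pS)
    pL <- bhAdjust(pL)
  }
  de <- DataFrame(
    biotype = rowData(ue)$biotype,
    log2fcS = fcS, pS = pS,
    callS = callDysregulated(fcS, pS, fcThreshold, alpha),
    log2fcL = fcL, pL = pL,
    callL = callDysregulated(fcL, pL, fcThreshold, alpha),
    row.names = rownames(ue)
  )
  flags <- .signatureFlags(de, lsFcThreshold)
  de$set1 <- flags$set1
  de$set2 <- flags$set2
  de$set3 <- flags$set3
  de$set4 <- flags$set4
  metadata(de) <- list(
    fcThreshold = fcThreshold, alpha = alpha, adjust = adjust,
    lsFcThreshold = lsFcThreshold
  )
  de
}

#' @noRd
.signatureFlags <- function(de, lsFcThreshold = 2) {
  .assert(lsFcThreshold > 0, "'lsFcThreshold' must be positive")
  calledL <- de$callL != "none"
  calledS <- de$callS != "none"
  concordant <- calledL & (!calledS | de$callS == de$callL)
  dramatic <- concordant &
    abs(de$log2fcL - de$log2fcS) >= log2(lsFcThreshold)
  isM <- de$biotype == "mRNA"
  list(
    set1 = isM & calledL & !calledS,
    set2 = isM & dramatic,
    set3 = !isM & calledL & !calledS,
    set4 = !isM & dramatic
  )
}

#' Tumor-size signature sets
#'
#' Set 1 (mRNA) and set 3 (lncRNA): features dysregulated only in large
#' tumors (called in L, not in S). Set 2 (mRNA) and set 4 (lncRNA):
#' features dysregulated more dramatically in large tumors — called in L
#' with a concordant (or sub-threshold) small-tumor change and a
#' large-vs-small fold change of at least `lsFcThreshold` (applied to the
#' log2 fold-change difference).
#'
#' @param de a DataFrame from [diffExprTable()].
#' @param lsFcThreshold large-vs-small fold-change threshold (natural
#'   scale).
#' @return named list of feature id vectors `set1`..`set4`.
#' @export
signatureSets <- function(de, lsFcThreshold = 2) {
  flags <- .signatureFlags(de, lsFcThreshold)
  lapply(flags, function(f) rownames(de)[f])
}

#' Venn partition of dysregulation calls across contrasts
#'
#' Splits the features called in either contrast into disjoint buckets:
#' \{S-only, L-only, both\} x \{up, down\}, with direction-discordant
#' features (up in one contrast, down in the other) reported in their own
#' bucket rather than silently merged. Bucket sizes always sum to the
#' number of features called in S or L.
#'
#' @param callsS,callsL named call vectors (from [callDysregulated()]) on
#'   the same feature universe.
#' @return named list of feature id vectors: `sOnlyUp`, `sOnlyDown`,
#'   `lOnlyUp`, `lOnlyDown`, `bothUp`, `bothDown`, `discordant`.
#' @export
vennPartition <- function(callsS, callsL) {
  .assert(
    !is.null(names(callsS)) && !is.null(names(callsL)) &&
      setequal(names(callsS), names(callsL)) &&
      length(callsS) == length(callsL),
    "call vectors must be named over the same feature universe"
  )
  callsL <- callsL[names(callsS)]
  inS <- callsS != "none"
  inL <- callsL != "none"
  ids <- names(callsS)
  disc <- inS & inL & callsS != callsL
  list(
    sOnlyUp = ids[inS & !inL & callsS == "up"],
    sOnlyDown = ids[inS & !inL & callsS == "down"],
    lOnlyUp = ids[!inS & inL & callsL == "up"],
    lOnlyDown = ids[!inS & inL & callsL == "down"],
    bothUp = ids[inS & inL & !disc & callsS == "up"],
    bothDown = ids[inS & inL & !disc & callsS == "down"],
    discordant = ids[disc]
  )
}

#' Histogram summary of a log2 fold-change distribution
#'
#' Normalized histogram (density integrates to 1) plus the up/down sign
#' mass among called features, mirroring the density-plot view of
#' fold-change distributions.
#'
#' @param log2fc finite numeric vector.
#' @param bins number of histogram bins.
#' @param calls optional call vector; when given, sign mass is computed
#'   over called features only, otherwise over all nonzero values.
#' @return list with `table` (data.frame: mid, density), `upMass`,
#'   `downMass`.
#' @export
fcDensitySummary <- function(log2fc, bins = 50, calls = NULL) {
  .assert(length(log2fc) > 0, "empty fold-change vector")
  .assert(all(is.finite(log2fc)), "fold changes must be finite")
  .assert(.isCount(bins), "'bins' must be a positive integer")
  rng <- range(log2fc)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  h <- graphics::hist(log2fc, breaks = breaks, plot = FALSE)
  if (is.null(calls)) {
    sel <- log2fc[log2fc != 0]
    up <- sum(sel > 0)
    down <- sum(sel < 0)
  } else {
    up <- sum(calls == "up")
    down <- sum(calls == "down")
  }
  tot <- max(up + down, 1L)
  list(
    table = data.frame(mid = h$mids, density = h$density),
    upMass = up / tot,
    downMass = down / tot
  )
}

#' Deterministic feature ordering for heatmap display
#'
#' Average-linkage hierarchical clustering on 1 - Pearson correlation
#' distance, with ties broken deterministically by feature id. Intended
#' only for ordering rows of a heatmap; no cut is applied.
#'
#' @param m numeric matrix, features x samples (constant rows not allowed).
#' @return integer vector: the ordering of rows.
#' @export
featureClusterOrder <- function(m) {
  .assert(is.matrix(m) && nrow(m) >= 2, "need a matrix with >= 2 features")
  v <- apply(m, 1, stats::var)
  .assert(all(v > 0), "constant features cannot be ordered by correlation")
  # order columns of cor input by id first so hclust tie-breaks are stable
  ord <- order(rownames(m), method = "radix")
  r <- cor(t(m[ord, , drop = FALSE]))
  hc <- hclust(as.dist(1 - r), method = "average")
  ord[hc$order]
}
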