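#' @include annotation-io.R
NULL

# Classification priority (fixed order; sense before antisense, exon
# before intron, overlap before proximity):
#   1 exon_sense_overlapping   overlaps an exon of a same-strand gene
#   2 intron_sense_overlapping contained in an intron of a same-strand gene
#   3 natural_antisense        overlaps an exon of an opposite-strand gene
#   4 intronic_antisense       contained in an intron of an opposite-strand
#                              gene
#   5 bidirectional            no gene overlap, divergent head-to-head,
#                              TSS-to-TSS gap <= bidirWindow
#   6 intergenic               otherwise
# A lncRNA straddling an exon/intron boundary overlaps the exon and so
# resolves to the exon category; intronic categories require containment.

# TSS in 0-based half-open terms: start-1 for '+', end for '-' (so a
# divergent pair abutting with no gap has distance 0).
#' @noRd
.tss0 <- function(gr) {
  ifelse(as.character(strand(gr)) == "+", start(gr) - 1L, end(gr))
}

#' Classify lncRNAs by genomic context
#'
#' Assigns each lncRNA one of six subtypes according to its relationship
#' with protein-coding transcripts on the same chromosome, testing the
#' rules in priority order (see source for the rule table). Within the
#' winning rule the partner gene is chosen deterministically: largest
#' exonic overlap, then smallest TSS-to-TSS gap, then lexicographically
#' smallest gene id. lncRNAs on chromosomes that carry no genes are
#' classified intergenic and flagged (with a warning).
#'
#' @param annotation GRanges with `tx_id`, `biotype`, `exons` metadata
#'   (see [readAnnotation()]); both biotypes in one object.
#' @param bidirWindow maximum TSS-to-TSS gap (bp) for the bidirectional
#'   subtype (default 1000, the conventional promoter-sharing window).
#' @return data.frame with columns `lnc`, `subtype`, `partner`, `evidence`
#'   and logical `noGeneChrom`.
#' @examples
#' p <- simParams(nMrna = 30, nLncrna = 12, seed = 3)
#' ann <- simulateAnnotation(p)
#' labels <- classifyLncRNAs(ann$annotation)
#' all(labels$subtype == ann$truth$lncSubtypes$subtype)
#' @export
classifyLncRNAs <- function(annotation, bidirWindow = 1000) {
  .validateAnnotation(annotation)
  .assert(bidirWindow >= 0, "'bidirWindow' must be non-negative")
  genes <- annotation[mcols(annotation)$biotype == "mRNA"]
  lncs <- annotation[mcols(annotation)$biotype == "lncRNA"]
  nL <- length(lncs)
  out <- data.frame(
    lnc = mcols(lncs)$tx_id,
    subtype = rep("intergenic", nL),
    partner = rep(NA_character_, nL),
    evidence = rep("no_relationship", nL),
    noGeneChrom = rep(FALSE, nL),
    stringsAsFactors = FALSE
  )
  if (nL == 0) {
    return(out)
  }
  if (length(genes) == 0) {
    out$noGeneChrom <- TRUE
    warning("no protein-coding genes in annotation; all lncRNAs intergenic")
    return(out)
  }

  geneId <- mcols(genes)$tx_id
  geneTss <- .tss0(genes)
  lncTss <- .tss0(lncs)
  geneStrand <- as.character(strand(genes))
  lncStrand <- as.character(strand(lncs))

  orphan <- !(as.character(seqnames(lncs)) %in%
    unique(as.character(seqnames(genes))))
  out$noGeneChrom <- orphan
  if (any(orphan)) {
    warning(
      sum(orphan),
      " lncRNA(s) on chromosomes without genes; classified intergenic"
    )
  }

  # flat exon and intron GRanges carrying their gene index
  ex <- mcols(genes)$exons
  nEx <- lengths(ex)
  exonGR <- GRanges(
    rep(as.character(seqnames(genes)), nEx),
    unlist(ex, use.names = FALSE)
  )
  mcols(exonGR)$gene <- rep(seq_along(genes), nEx)
  intronList <- lapply(seq_along(genes), function(i) {
    e <- ex[[i]]
    if (length(e) < 2) {
      return(IRanges())
    }
    IRanges(start = end(e)[-length(e)] + 1L, end = start(e)[-1] - 1L)
  })
  nIn <- lengths(intronList)
  intronGR <- GRanges(
    rep(as.character(seqnames(genes)), nIn),
    do.call(c, intronList)
  )
  mcols(intronGR)$gene <- rep(seq_along(genes), nIn)

  # candidate (lnc, gene, category) relationships, strand checked manually
  cand <- list()
  feo <- findOverlaps(lncs, exonGR, ignore.strand = TRUE)
  if (length(feo)) {
    li <- S4Vectors::queryHits(feo)
    gi <- mcols(exonGR)$gene[S4Vectors::subjectHits(feo)]
    ow <- width(pintersect(
      IRanges::ranges(lncs)[li],
      IRanges::ranges(exonGR)[S4Vectors::subjectHits(feo)]
    ))
    same <- lncStrand[li] == geneStrand[gi]
    cand$exon <- data.frame(
      lnc = li, gene = gi, category = ifelse(same, 1L, 3L), overlap = ow
    )
  }
  fin <- findOverlaps(lncs, intronGR, type = "within", ignore.strand = TRUE)
  if (length(fin)) {
    li <- S4Vectors::queryHits(fin)
    gi <- mcols(intronGR)$gene[S4Vectors::subjectHits(fin)]
    same <- lncStrand[li] == geneStrand[gi]
    cand$intron <- data.frame(
      lnc = li, gene = gi, category = ifelse(same, 2L, 4L),
      overlap = width(lncs)[li]
    )
  }
  # bidirectional candidates: near (within window at the TSS level), not
  # overlapping any gene span, divergent orientation
  geneHit <- findOverlaps(lncs, genes, ignore.strand = TRUE)
  overlapsAnyGene <- seq_len(nL) %in% S4Vectors::queryHits(geneHit)
  near <- findOverlaps(lncs, genes,
    maxgap = as.integer(bidirWindow), ignore.strand = TRUE
  )
  if (length(near)) {
    li <- S4Vectors::queryHits(near)
    gi <- S4Vectors::subjectHits(near)
    gap <- abs(geneTss[gi] - lncTss[li])
    divergent <- lncStrand[li] != geneStrand[gi] &
      ifelse(geneStrand[gi] == "+", lncTss[li] <= geneTss[gi],
        lncTss[li] >= geneTss[gi]
      )
    keep <- !overlapsAnyGene[li] & divergent & gap <= bidirWindow &
      as.character(seqnames(lncs))[li] == as.character(seqnames(genes))[gi]
    if (any(keep)) {
      cand$bidir <- data.frame(
        lnc = li[keep], gene = gi[keep], category = 5L, overlap = 0L
      )
    }
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || !nrow(cand)) {
    return(out)
  }

  # aggregate exon overlap per (lnc, gene, category): a lncRNA may overlap
  # several exons of the same gene
  key <- paste(cand$lnc, cand$gene, cand$category)
  agg <- rowsum(cand$overlap, key)
  first <- !duplicated(key)
  cand <- cand[first, , drop = FALSE]
  cand$overlap <- agg[paste(cand$lnc, cand$gene, cand$category), 1]
  cand$gap <- abs(geneTss[cand$gene] - lncTss[cand$lnc])

  # per lncRNA: winning category, then partner tie-break
  ord <- order(
    cand$lnc, cand$category, -cand$overlap, cand$gap, geneId[cand$gene],
    method = "radix"
  )
  cand <- cand[ord, , drop = FALSE]
  best <- cand[!duplicated(cand$lnc), , drop = FALSE]
  lab <- c(
    "exon_sense_overlapping", "intron_sense_overlapping",
    "natural_antisense", "intronic_antisense", "bidirectional"
  )
  out$subtype[best$lnc] <- lab[best$category]
  out$partner[best$lnc] <- geneId[best$gene]
  out$evidence[best$lnc] <- ifelse(
    best$category %in% c(1L, 3L),
    sprintf("exon_overlap=%dbp", best$overlap),
    ifelse(best$category %in% c(2L, 4L),
      sprintf("intron_containment;tss_gap=%d", best$gap),
      sprintf("tss_gap=%d", best$gap)
    )
  )
  out
}

#' Subtype composition of a lncRNA subset
#'
#' Proportions of the six genomic-context subtypes among all labeled
#' lncRNAs or any subset (e.g. the dysregulated ones). Proportions sum
#' to 1.
#'
#' @param labels data.frame from [classifyLncRNAs()].
#' @param subset optional character vector of lncRNA ids.
#' @return named numeric vector over the six subtypes.
#' @export
subtypeFractions <- function(labels, subset = NULL) {
  ids <- labels$lnc
  if (!is.null(subset)) {
    .assert(length(subset) > 0, "empty subset")
    .assert(
      all(subset %in% ids),
      "subset contains unlabeled ids: ",
      paste(utils::head(setdiff(subset, ids), 5), collapse = ", ")
    )
    labels <- labels[ids %in% subset, , drop = FALSE]
  }
  .assert(nrow(labels) > 0, "no labeled lncRNAs")
  tab <- table(factor(labels$subtype, levels = .SUBTYPES))
  setNames(as.numeric(tab) / nrow(labels), .SUBTYPES)
}

#' Cis lncRNA-mRNA partner pairs
#'
#' One pair per lncRNA whose subtype designates a cis partner for the
#' correlation analysis: intronic antisense, natural antisense,
#' bidirectional and intron sense-overlapping. Intergenic (no partner) and
#' exon sense-overlapping lncRNAs are excluded by convention.
#'
#' @param labels data.frame from [classifyLncRNAs()].
#' @return data.frame with columns `lnc`, `mrna`, `subtype`.
#' @export
cisPartnerPairs <- function(labels) {
  keep <- labels$subtype %in% .CIS_SUBTYPES
  data.frame(
    lnc = labels$lnc[keep],
    mrna = labels$partner[keep],
    subtype = labels$subtype[keep],
    stringsAsFactors = FALSE
  )
}
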