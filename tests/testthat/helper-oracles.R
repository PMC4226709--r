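# Independent oracles and fixture builders. These deliberately use naive
# data-frame loops and exhaustive enumeration, sharing no code with the
# package implementations they check.

# ---- brute-force lncRNA classifier -----------------------------------------
# Naive O(n_lnc * n_gene) all-pairs implementation of the subtype rules,
# operating on plain data.frames. Coordinates 1-based closed; exons stored
# as a list of 2-column matrices (start, end).

bruteTss0 <- function(start, end, strand) {
  if (strand == "+") start - 1 else end
}

bruteClassifyOne <- function(lnc, genes, window = 1000) {
  # lnc: list(chrom, start, end, strand); genes: data.frame + exons list
  best <- NULL
  overlapsAny <- FALSE
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    if (g$chrom != lnc$chrom) next
    spanOverlap <- lnc$start <= g$end && g$start <= lnc$end
    if (spanOverlap) overlapsAny <- TRUE
    same <- g$strand == lnc$strand
    ex <- genes$exons[[gi]]
    exOv <- 0
    for (r in seq_len(nrow(ex))) {
      lo <- max(lnc$start, ex[r, 1])
      hi <- min(lnc$end, ex[r, 2])
      if (lo <= hi) exOv <- exOv + (hi - lo + 1)
    }
    inIntron <- FALSE
    if (nrow(ex) > 1) {
      for (r in seq_len(nrow(ex) - 1)) {
        is <- ex[r, 2] + 1
        ie <- ex[r + 1, 1] - 1
        if (is <= ie && lnc$start >= is && lnc$end <= ie) inIntron <- TRUE
      }
    }
    gap <- abs(
      bruteTss0(g$start, g$end, g$strand) -
        bruteTss0(lnc$start, lnc$end, lnc$strand)
    )
    cat4 <- if (exOv > 0 && same) {
      1L
    } else if (inIntron && same) {
      2L
    } else if (exOv > 0 && !same) {
      3L
    } else if (inIntron && !same) {
      4L
    } else {
      NA_integer_
    }
    if (!is.na(cat4)) {
      cand <- list(
        cat = cat4, gene = g$id,
        overlap = if (cat4 %in% c(1L, 3L)) exOv else (lnc$end - lnc$start + 1),
        gap = gap
      )
      best <- bruteBetter(best, cand)
    } else if (!spanOverlap && !same && gap <= window) {
      divergent <- if (g$strand == "+") {
        bruteTss0(lnc$start, lnc$end, lnc$strand) <=
          bruteTss0(g$start, g$end, g$strand)
      } else {
        bruteTss0(lnc$start, lnc$end, lnc$strand) >=
          bruteTss0(g$start, g$end, g$strand)
      }
      if (divergent) {
        best <- bruteBetter(best, list(
          cat = 5L, gene = g$id, overlap = 0, gap = gap
        ))
      }
    }
  }
  if (is.null(best)) {
    return(list(subtype = "intergenic", partner = NA_character_))
  }
  if (best$cat == 5L && overlapsAny) {
    return(list(subtype = "intergenic", partner = NA_character_))
  }
  labels <- c(
    "exon_sense_overlapping", "intron_sense_overlapping",
    "natural_antisense", "intronic_antisense", "bidirectional"
  )
  list(subtype = labels[best$cat], partner = best$gene)
}

bruteBetter <- function(a, b) {
  if (is.null(a)) {
    return(b)
  }
  if (b$cat != a$cat) {
    return(if (b$cat < a$cat) b else a)
  }
  if (b$overlap != a$overlap) {
    return(if (b$overlap > a$overlap) b else a)
  }
  if (b$gap != a$gap) {
    return(if (b$gap < a$gap) b else a)
  }
  if (b$gene < a$gene) b else a
}

bruteClassifyAll <- function(lncs, genes, window = 1000) {
  out <- data.frame(
    lnc = lncs$id, subtype = NA_character_, partner = NA_character_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(lncs))) {
    res <- bruteClassifyOne(
      list(
        chrom = lncs$chrom[i], start = lncs$start[i],
        end = lncs$end[i], strand = lncs$strand[i]
      ),
      genes, window
    )
    out$subtype[i] <- res$subtype
    out$partner[i] <- res$partner
  }
  out
}

# Random small genome in both representations (data.frames for the oracle,
# GRanges annotation for the implementation).
randomGenome <- function(nGenes = 20, nLncs = 15, span = 60000,
                         nChrom = 2) {
  geneChrom <- paste0("chr", sample.int(nChrom, nGenes, replace = TRUE))
  gs <- sample.int(span, nGenes)
  glen <- sample(800:6000, nGenes, replace = TRUE)
  ge <- gs + glen
  gstr <- sample(c("+", "-"), nGenes, replace = TRUE)
  exons <- lapply(seq_len(nGenes), function(i) {
    k <- sample(1:3, 1)
    if (k == 1) {
      return(cbind(gs[i], ge[i]))
    }
    grid <- seq(gs[i] + 2, ge[i] - 2, by = 2)
    cuts <- sort(sample(grid, 2 * (k - 1)))
    starts <- c(gs[i], cuts[seq(2, length(cuts), by = 2)])
    ends <- c(cuts[seq(1, length(cuts), by = 2)], ge[i])
    cbind(starts, ends)
  })
  genes <- data.frame(
    id = sprintf("g%03d", seq_len(nGenes)), chrom = geneChrom,
    start = gs, end = ge, strand = gstr, stringsAsFactors = FALSE
  )
  genes$exons <- exons
  ls <- sample.int(span, nLncs)
  llen <- sample(150:1200, nLncs, replace = TRUE)
  lncs <- data.frame(
    id = sprintf("l%03d", seq_len(nLncs)),
    chrom = paste0("chr", sample.int(nChrom, nLncs, replace = TRUE)),
    start = ls, end = ls + llen,
    strand = sample(c("+", "-"), nLncs, replace = TRUE),
    stringsAsFactors = FALSE
  )
  list(genes = genes, lncs = lncs, annotation = genomeToGRanges(genes, lncs))
}

genomeToGRanges <- function(genes, lncs) {
  gr <- GenomicRanges::GRanges(
    seqnames = c(genes$chrom, lncs$chrom),
    ranges = IRanges::IRanges(
      start = c(genes$start, lncs$start),
      end = c(genes$end, lncs$end)
    ),
    strand = c(genes$strand, lncs$strand)
  )
  S4Vectors::mcols(gr)$tx_id <- c(genes$id, lncs$id)
  S4Vectors::mcols(gr)$biotype <- rep(
    c("mRNA", "lncRNA"), c(nrow(genes), nrow(lncs))
  )
  S4Vectors::mcols(gr)$exons <- IRanges::IRangesList(c(
    lapply(genes$exons, function(m) IRanges::IRanges(m[, 1], m[, 2])),
    mapply(function(s, e) IRanges::IRanges(s, e), lncs$start, lncs$end,
      SIMPLIFY = FALSE
    )
  ))
  names(gr) <- S4Vectors::mcols(gr)$tx_id
  gr
}

# ---- naive relevance-score loop --------------------------------------------
naiveRelevance <- function(r, cutoff, lncSet) {
  score <- numeric(nrow(r))
  names(score) <- rownames(r)
  for (g in seq_len(nrow(r))) {
    s <- 0
    for (l in lncSet) {
      v <- r[g, l]
      if (!is.na(v) && (v > cutoff || v < -cutoff)) s <- s + abs(v)
    }
    score[g] <- s
  }
  score
}

# ---- exhaustive hypergeometric enumeration ---------------------------------
# P(overlap >= k) by enumerating every size-n draw from a universe of N in
# which the first K elements are the 'successes'.
enumHyperUpper <- function(N, K, n, k) {
  if (n == 0) {
    return(if (k == 0) 1 else 0)
  }
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# ---- small experiment builder ----------------------------------------------
# Paired design with nPat patients, each contributing one normal and one
# tumor sample of the given size class.
makeUe <- function(mat, nPat = ncol(mat) / 2, size = "S",
                   biotype = NULL) {
  pat <- sprintf("P%02d", seq_len(nPat))
  samples <- c(paste0(pat, "_N"), paste0(pat, "_", size))
  stopifnot(ncol(mat) == length(samples))
  colnames(mat) <- samples
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("f%03d", seq_len(nrow(mat)))
  }
  if (is.null(biotype)) biotype <- rep("mRNA", nrow(mat))
  sheet <- data.frame(
    sample = samples,
    patient = rep(pat, 2),
    tissue = rep(c("N", "T"), each = nPat),
    size = rep(c(NA, size), each = nPat),
    stringsAsFactors = FALSE
  )
  ulmExperiment(mat, sheet, biotype)
}
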