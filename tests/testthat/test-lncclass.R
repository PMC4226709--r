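# small helper to build an annotation GRanges from terse specs
annotFromSpec <- function(...) {
  rows <- list(...)
  genes <- Filter(function(r) r$biotype == "mRNA", rows)
  lncs <- Filter(function(r) r$biotype == "lncRNA", rows)
  df <- function(rr) {
    data.frame(
      id = vapply(rr, `[[`, "", "id"),
      chrom = vapply(rr, function(r) if (is.null(r$chrom)) "chr1" else r$chrom, ""),
      start = vapply(rr, `[[`, 0, "start"),
      end = vapply(rr, `[[`, 0, "end"),
      strand = vapply(rr, `[[`, "", "strand"),
      stringsAsFactors = FALSE
    )
  }
  g <- df(genes)
  g$exons <- lapply(genes, function(r) {
    if (is.null(r$exons)) cbind(r$start, r$end) else r$exons
  })
  l <- df(lncs)
  genomeToGRanges(g, l)
}

test_that("worked classification examples resolve as specified", {
  # lncRNA inside the intron of an opposite-strand gene. Half-open
  # coordinates (150,250) are 1-based 151..250; the gene occupies 51..350
  # with exons 51..100 and 301..350, so its intron is 101..300.
  ann <- annotFromSpec(
    list(
      id = "gA", biotype = "mRNA", start = 51, end = 350, strand = "+",
      exons = cbind(c(51, 301), c(100, 350))
    ),
    list(id = "lnc1", biotype = "lncRNA", start = 151, end = 250, strand = "-")
  )
  lab <- classifyLncRNAs(ann)
  expect_identical(lab$subtype, "intronic_antisense")
  expect_identical(lab$partner, "gA")

  # divergent promoters 200 bp apart: lnc (4600,4800] on '-', gene
  # starting at half-open 5000 on '+'
  ann2 <- annotFromSpec(
    list(id = "gB", biotype = "mRNA", start = 5001, end = 8000, strand = "+"),
    list(id = "lnc2", biotype = "lncRNA", start = 4601, end = 4800, strand = "-")
  )
  lab2 <- classifyLncRNAs(ann2, bidirWindow = 1000)
  expect_identical(lab2$subtype, "bidirectional")
  expect_identical(lab2$partner, "gB")
  expect_identical(lab2$evidence, "tss_gap=200")
  # and outside the window it is not
  lab2b <- classifyLncRNAs(ann2, bidirWindow = 199)
  expect_identical(lab2b$subtype, "intergenic")

  # far from everything: intergenic
  ann3 <- annotFromSpec(
    list(id = "gC", biotype = "mRNA", start = 100001, end = 105000, strand = "+"),
    list(id = "lnc3", biotype = "lncRNA", start = 1001, end = 1500, strand = "+")
  )
  expect_identical(classifyLncRNAs(ann3)$subtype, "intergenic")
  expect_true(is.na(classifyLncRNAs(ann3)$partner))

  # exon overlap wins over intron dipping (priority order)
  ann4 <- annotFromSpec(
    list(
      id = "gD", biotype = "mRNA", start = 1000, end = 5000, strand = "+",
      exons = cbind(c(1000, 4000), c(2000, 5000))
    ),
    # overlaps exon 1000..2000 and dips into intron 2001..3999
    list(id = "lnc4", biotype = "lncRNA", start = 1900, end = 2500, strand = "+")
  )
  expect_identical(classifyLncRNAs(ann4)$subtype, "exon_sense_overlapping")
})

test_that("classification agrees with the brute-force oracle on random genomes", {
  set.seed(2024)
  nGenomes <- 200
  mismatches <- 0
  for (i in seq_len(nGenomes)) {
    g <- randomGenome(
      nGenes = sample(3:50, 1), nLncs = sample(3:30, 1),
      span = sample(c(20000, 60000, 200000), 1)
    )
    got <- suppressWarnings(classifyLncRNAs(g$annotation, bidirWindow = 1000))
    want <- bruteClassifyAll(g$lncs, g$genes, window = 1000)
    samePartner <- (is.na(got$partner) & is.na(want$partner)) |
      (!is.na(got$partner) & !is.na(want$partner) &
        got$partner == want$partner)
    mismatches <- mismatches +
      sum(got$subtype != want$subtype) + sum(!samePartner)
  }
  expect_identical(mismatches, 0)
})

test_that("every lncRNA receives exactly one label", {
  set.seed(99)
  g <- randomGenome(nGenes = 30, nLncs = 25, span = 40000)
  lab <- suppressWarnings(classifyLncRNAs(g$annotation))
  expect_identical(nrow(lab), 25L)
  expect_true(all(lab$subtype %in% c(
    "intergenic", "intronic_antisense", "natural_antisense",
    "exon_sense_overlapping", "bidirectional", "intron_sense_overlapping"
  )))
  expect_identical(is.na(lab$partner), lab$subtype == "intergenic")
})

test_that("flipping every strand swaps sense and antisense labels", {
  # Flipping the lncRNA strand reverses its relative orientation to every
  # gene, so each single relationship swaps with its antisense
  # counterpart. The property is per relationship: where a lncRNA relates
  # to several genes the priority order re-ranks after the flip, so the
  # check runs on annotations constructed with exactly one relationship
  # per lncRNA. The no-overlap categories stay a closed set: flips cannot
  # create an overlap, but head-to-head becomes tail-to-tail, so
  # bidirectional may fall back to intergenic.
  swap <- c(
    exon_sense_overlapping = "natural_antisense",
    natural_antisense = "exon_sense_overlapping",
    intron_sense_overlapping = "intronic_antisense",
    intronic_antisense = "intron_sense_overlapping"
  )
  mix <- setNames(rep(1 / 6, 6), c(
    "intergenic", "intronic_antisense", "natural_antisense",
    "exon_sense_overlapping", "bidirectional", "intron_sense_overlapping"
  ))
  for (seed in c(8, 80, 800)) {
    p <- simParams(nMrna = 48, nLncrna = 48, subtypeMix = mix, seed = seed)
    ann <- simulateAnnotation(p)$annotation
    lab <- classifyLncRNAs(ann)
    flipped <- ann
    str <- as.character(GenomicRanges::strand(flipped))
    isLnc <- S4Vectors::mcols(flipped)$biotype == "lncRNA"
    GenomicRanges::strand(flipped)[isLnc] <-
      ifelse(str[isLnc] == "+", "-", "+")
    lab2 <- classifyLncRNAs(flipped)
    ov <- lab$subtype %in% names(swap)
    expect_identical(lab2$subtype[ov], unname(swap[lab$subtype[ov]]))
    expect_true(all(
      lab2$subtype[!ov] %in% c("intergenic", "bidirectional")
    ))
    expect_identical(
      lab2$subtype[lab$subtype == "intergenic"],
      rep("intergenic", sum(lab$subtype == "intergenic"))
    )
  }
})

test_that("chromosomes without genes classify intergenic with a warning flag", {
  ann <- annotFromSpec(
    list(id = "gA", biotype = "mRNA", start = 100, end = 2000, strand = "+"),
    list(
      id = "lncX", biotype = "lncRNA", chrom = "chrX",
      start = 500, end = 900, strand = "+"
    )
  )
  expect_warning(lab <- classifyLncRNAs(ann), "without genes")
  expect_identical(lab$subtype, "intergenic")
  expect_true(lab$noGeneChrom)
})

test_that("partner ties break by overlap, then TSS gap, then id", {
  # two same-strand genes with identical single exons overlapping the lnc
  # equally and equal TSS gaps: lexicographically smaller id wins
  ann <- annotFromSpec(
    list(id = "gB", biotype = "mRNA", start = 1000, end = 2000, strand = "+"),
    list(id = "gA", biotype = "mRNA", start = 1000, end = 2000, strand = "+"),
    list(id = "lnc", biotype = "lncRNA", start = 1500, end = 1700, strand = "+")
  )
  expect_identical(classifyLncRNAs(ann)$partner, "gA")

  # larger exonic overlap beats smaller regardless of gap
  ann2 <- annotFromSpec(
    list(id = "gNear", biotype = "mRNA", start = 1600, end = 2600, strand = "+"),
    list(id = "gBig", biotype = "mRNA", start = 900, end = 1900, strand = "+"),
    list(id = "lnc", biotype = "lncRNA", start = 1000, end = 1700, strand = "+")
  )
  expect_identical(classifyLncRNAs(ann2)$partner, "gBig")
})

test_that("subtype fractions and cis pairs follow the conventions", {
  labels <- data.frame(
    lnc = paste0("l", 1:6),
    subtype = c(
      "intergenic", "intronic_antisense", "natural_antisense",
      "exon_sense_overlapping", "bidirectional", "intron_sense_overlapping"
    ),
    partner = c(NA, "g1", "g2", "g3", "g4", "g5"),
    stringsAsFactors = FALSE
  )
  fr <- subtypeFractions(labels)
  expect_equal(unname(fr), rep(1 / 6, 6))
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  fr2 <- subtypeFractions(labels, subset = c("l1", "l2"))
  expect_equal(fr2[["intergenic"]], 0.5)
  expect_error(subtypeFractions(labels, subset = character()), "empty")

  pairs <- cisPartnerPairs(labels)
  expect_setequal(pairs$subtype, c(
    "intronic_antisense", "natural_antisense", "bidirectional",
    "intron_sense_overlapping"
  ))
  expect_false("intergenic" %in% pairs$subtype)
  expect_false("exon_sense_overlapping" %in% pairs$subtype)
  expect_identical(nrow(pairs), 4L)

  allInter <- data.frame(
    lnc = "l1", subtype = "intergenic", partner = NA_character_,
    stringsAsFactors = FALSE
  )
  expect_identical(nrow(cisPartnerPairs(allInter)), 0L)
})
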