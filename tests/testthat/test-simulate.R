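test_that("identical parameters give byte-identical simulations", {
  p <- simParams(nMrna = 40, nLncrna = 16, seed = 123)
  a <- simulateStudy(p)
  b <- simulateStudy(p)
  expect_identical(
    SummarizedExperiment::assay(a$experiment),
    SummarizedExperiment::assay(b$experiment)
  )
  expect_identical(as.data.frame(a$annotation), as.data.frame(b$annotation))
  expect_identical(truthDECalls(a$truth), truthDECalls(b$truth))
  expect_identical(a$geneSets, b$geneSets)
})

test_that("a degenerate all-intergenic mix stays clear of every gene", {
  mix <- c(
    intergenic = 1, intronic_antisense = 0, natural_antisense = 0,
    exon_sense_overlapping = 0, bidirectional = 0,
    intron_sense_overlapping = 0
  )
  p <- simParams(nMrna = 30, nLncrna = 10, subtypeMix = mix, seed = 5)
  ann <- simulateAnnotation(p)
  expect_true(all(ann$truth$lncSubtypes$subtype == "intergenic"))
  gr <- ann$annotation
  genes <- gr[S4Vectors::mcols(gr)$biotype == "mRNA"]
  lncs <- gr[S4Vectors::mcols(gr)$biotype == "lncRNA"]
  d <- GenomicRanges::distanceToNearest(lncs, genes)
  expect_true(all(S4Vectors::mcols(d)$distance >= 1000))
  expect_identical(nrow(ann$truth$cisPairs), 0L)
})

test_that("the classifier recovers every intended subtype at a uniform mix", {
  mix <- setNames(rep(1 / 6, 6), c(
    "intergenic", "intronic_antisense", "natural_antisense",
    "exon_sense_overlapping", "bidirectional", "intron_sense_overlapping"
  ))
  p <- simParams(nMrna = 60, nLncrna = 60, subtypeMix = mix, seed = 21)
  ann <- simulateAnnotation(p)
  labels <- classifyLncRNAs(ann$annotation)
  truth <- ann$truth$lncSubtypes
  expect_identical(labels$lnc, truth$lnc)
  expect_identical(labels$subtype, truth$subtype)
  keep <- truth$subtype != "intergenic"
  expect_identical(labels$partner[keep], truth$partner[keep])
})

test_that("the null model yields identical tumor and normal columns", {
  p <- simParams(
    nMrna = 20, nLncrna = 8,
    fracDeMrnaSmall = 0, fracDeMrnaLarge = 0,
    fracDeLncrnaSmall = 0, fracDeLncrnaLarge = 0,
    noiseSd = 0, patientSd = 0, seed = 3, design = "triplet"
  )
  ann <- simulateAnnotation(p)
  sim <- simulateExpression(ann$annotation, ann$truth, p)
  m <- SummarizedExperiment::assay(sim$experiment)
  sheet <- sampleSheet(sim$experiment)
  for (pat in unique(sheet$patient)) {
    cols <- sheet$sample[sheet$patient == pat]
    expect_equal(m[, cols[1]], m[, cols[2]])
    expect_equal(m[, cols[1]], m[, cols[3]])
  }
  expect_equal(unname(pairedLog2FC(sim$experiment, "S")), rep(0, 28))
  expect_identical(nrow(truthDECalls(sim$truth)), 0L)
})

test_that("a planted cis pair attains its target correlation (Fisher z)", {
  mix <- c(
    intergenic = 0, intronic_antisense = 0, natural_antisense = 0,
    exon_sense_overlapping = 0, bidirectional = 0,
    intron_sense_overlapping = 1
  )
  p <- simParams(
    nPatientsPerGroup = 200, nMrna = 4, nLncrna = 2,
    subtypeMix = mix, cisRho = 0.9,
    subtypeSignProfile = c(intron_sense_overlapping = 1),
    fracDeMrnaSmall = 0, fracDeMrnaLarge = 0,
    fracDeLncrnaSmall = 0, fracDeLncrnaLarge = 0,
    patientSd = 0, noiseSd = 0.4, seed = 17, design = "triplet"
  )
  ann <- simulateAnnotation(p)
  sim <- simulateExpression(ann$annotation, ann$truth, p)
  cp <- truthCisPairs(sim$truth)
  expect_true(all(cp$targetR == 0.9))
  m <- SummarizedExperiment::assay(sim$experiment)
  n <- ncol(m) # 600 samples
  zlim <- atanh(0.9) + c(-1, 1) * qnorm(0.975) / sqrt(n - 3)
  for (i in seq_len(nrow(cp))) {
    r <- cor(m[cp$lnc[i], ], m[cp$mrna[i], ])
    expect_gt(atanh(r), zlim[1])
    expect_lt(atanh(r), zlim[2])
  }
})

test_that("planted DE features are preferentially recovered by the tests", {
  hitsDe <- hitsNull <- 0
  nDe <- nNull <- 0
  for (seed in 1:50) {
    p <- simParams(
      nMrna = 60, nLncrna = 24, fracDeMrnaSmall = 0, fracDeMrnaLarge = 0.2,
      effectLarge = 2, effectSmall = 1, noiseSd = 0.3, seed = seed
    )
    ann <- simulateAnnotation(p)
    sim <- simulateExpression(ann$annotation, ann$truth, p)
    fc <- pairedLog2FC(sim$experiment, "L")
    tt <- pairedTTest(sim$experiment, "L")
    calls <- callDysregulated(fc, tt$p)
    tr <- truthDECalls(sim$truth)
    de <- tr$feature[tr$biotype == "mRNA"]
    mrnas <- names(fc)[featureBiotypes(sim$experiment)[names(fc)] == "mRNA"]
    null <- setdiff(mrnas, de)
    hitsDe <- hitsDe + sum(calls[de] != "none")
    hitsNull <- hitsNull + sum(calls[null] != "none")
    nDe <- nDe + length(de)
    nNull <- nNull + length(null)
  }
  expect_gt(hitsDe / nDe, hitsNull / nNull)
  expect_gt(hitsDe / nDe, 0.5) # planted effect of 2 log2 units is visible
  expect_lt(hitsNull / nNull, 0.05)
})

test_that("direction bias is realized at its planted rate", {
  downs <- total <- 0
  for (seed in 1:20) {
    p <- simParams(
      nMrna = 200, nLncrna = 10, fracDeMrnaLarge = 0.3,
      downBiasMrna = 0.8, seed = seed
    )
    ann <- simulateAnnotation(p)
    sim <- simulateExpression(ann$annotation, ann$truth, p)
    tr <- truthDECalls(sim$truth)
    trm <- tr[tr$biotype == "mRNA", ]
    downs <- downs + sum(trm$direction == "down")
    total <- total + nrow(trm)
  }
  ci <- 0.8 + c(-1, 1) * qnorm(0.995) * sqrt(0.8 * 0.2 / total)
  expect_gt(downs / total, ci[1])
  expect_lt(downs / total, ci[2])
})

test_that("truth manifests are internally consistent", {
  study <- simulateStudy(simParams(nMrna = 80, nLncrna = 40, seed = 31))
  cp <- truthCisPairs(study$truth)
  expect_false(anyDuplicated(cp$lnc) > 0)
  feat <- names(study$annotation)
  expect_true(all(cp$lnc %in% feat) && all(cp$mrna %in% feat))
  ls <- study$truth@lncSubtypes
  expect_setequal(cp$lnc, ls$lnc[ls$subtype %in% c(
    "intronic_antisense", "natural_antisense", "bidirectional",
    "intron_sense_overlapping"
  )])
  # large-tumor effects dominate small-tumor effects in magnitude
  tr <- truthDECalls(study$truth)
  both <- tr[tr$log2fcSmall != 0 & tr$log2fcLarge != 0, ]
  expect_true(all(abs(both$log2fcLarge) > abs(both$log2fcSmall)))
})

test_that("subtype fractions recover the planted mixture", {
  p <- simParams(nMrna = 600, nLncrna = 600, chromLength = 9e6, seed = 13)
  ann <- simulateAnnotation(p)
  labels <- classifyLncRNAs(ann$annotation)
  fr <- subtypeFractions(labels)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  mix <- p@subtypeMix
  for (st in names(mix)) {
    se <- sqrt(mix[[st]] * (1 - mix[[st]]) / 600)
    expect_lt(abs(fr[[st]] - mix[[st]]), qnorm(0.9995) * se + 1e-9)
  }
})

test_that("infeasible placements raise a capacity error", {
  expect_error(
    simulateAnnotation(simParams(nMrna = 1000, chromLength = 200000)),
    class = "lncomat_capacity_error"
  )
  expect_error(
    simulateAnnotation(simParams(nMrna = 10, nLncrna = 20)),
    class = "lncomat_capacity_error"
  )
})

test_that("mismatched annotation and truth are an integrity error", {
  p <- simParams(nMrna = 20, nLncrna = 8, seed = 1)
  ann <- simulateAnnotation(p)
  truth <- ann$truth
  truth$lncSubtypes$lnc[1] <- "no_such_lnc"
  expect_error(
    simulateExpression(ann$annotation, truth, p),
    class = "lncomat_integrity_error"
  )
})
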