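# build a CoexMatrix straight from an r matrix (for scoring tests)
coexFromR <- function(r, cutoff = 0.8) {
  tri <- ifelse(r > cutoff, 1L, ifelse(r < -cutoff, -1L, 0L))
  new("CoexMatrix", r = r, tri = tri, cutoff = cutoff, span = "all")
}

test_that("pearsonCor matches closed forms and flags undefined input", {
  x <- c(1, 2, 3, 5)
  expect_equal(pearsonCor(x, x), 1)
  expect_equal(pearsonCor(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_identical(pearsonCor(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(pearsonCor(c(1, 1, 1), c(1, 2, 3))))
  expect_error(pearsonCor(1:2, 1:2), "at least 3")
  expect_error(pearsonCor(1:4, 1:3), "equal length")
})

test_that("trichotomization uses strict inequalities at the 0.8 boundary", {
  # engineered correlations across 4 samples: r(m1,l1) is exactly 0.8
  m <- rbind(
    m1 = c(1, 2, 3, 4),
    m2 = c(4, 3, 2, 1),
    l1 = c(1, 3, 2, 4),
    l2 = c(1, 2, 3, 4)
  )
  ue <- makeUe(m, nPat = 2, biotype = c("mRNA", "mRNA", "lncRNA", "lncRNA"))
  cm <- buildCoexMatrix(ue, mrnaIds = c("m1", "m2"), lncIds = c("l1", "l2"))
  r <- corMatrix(cm)
  expect_identical(r["m1", "l1"], 0.8)
  expect_identical(triMatrix(cm)["m1", "l1"], 0L) # 0.80 exactly -> no call
  expect_identical(triMatrix(cm)["m1", "l2"], 1L) # r = 1 > 0.8
  expect_identical(triMatrix(cm)["m2", "l2"], -1L) # r = -1 < -0.8
  expect_identical(r["m2", "l1"], -0.8)
  expect_identical(triMatrix(cm)["m2", "l1"], 0L)
})

test_that("tri counts conserve rows x cols including undefined cells", {
  set.seed(11)
  for (i in 1:20) {
    nm <- sample(5:15, 1)
    nl <- sample(4:12, 1)
    mat <- matrix(rnorm(((nm + nl) * 8)), nm + nl, 8)
    rownames(mat) <- c(sprintf("m%02d", 1:nm), sprintf("l%02d", 1:nl))
    mat[2, ] <- 7 # constant mRNA -> an undefined row
    ue <- makeUe(mat,
      nPat = 4,
      biotype = rep(c("mRNA", "lncRNA"), c(nm, nl))
    )
    cm <- buildCoexMatrix(ue,
      mrnaIds = rownames(mat)[1:nm],
      lncIds = rownames(mat)[nm + 1:nl],
      cutoff = runif(1, 0.3, 0.95)
    )
    tc <- triCounts(cm)
    expect_identical(sum(tc), as.integer(nm * nl))
    expect_identical(tc[["undefined"]], as.integer(nl))
    expect_identical(undefinedCount(cm), as.integer(nl))
  }
})

test_that("relevance scores reproduce the worked example and its guards", {
  r <- matrix(c(0.9, -0.85, 0.5), 1, 3,
    dimnames = list("g1", c("l1", "l2", "l3"))
  )
  cm <- coexFromR(r)
  rk <- relevanceScores(cm, c("l1", "l2", "l3"))
  expect_equal(rk$score, 1.75) # 0.9 + 0.85; 0.5 is sub-cutoff

  expect_error(relevanceScores(cm, c("l1", "nope")), "nope")

  # empty set: all scores 0, deterministic id-ordered ranking
  r2 <- matrix(runif(6, -0.5, 0.5), 2, 3,
    dimnames = list(c("gB", "gA"), c("l1", "l2", "l3"))
  )
  rk2 <- relevanceScores(coexFromR(r2), character())
  expect_equal(rk2$score, c(0, 0))
  expect_identical(rk2$mrna, c("gA", "gB"))
  # all sub-cutoff: same degenerate but deterministic ranking
  rk3 <- relevanceScores(coexFromR(r2), c("l1", "l2", "l3"))
  expect_equal(rk3$score, c(0, 0))
  expect_identical(rk3$mrna, c("gA", "gB"))
})

test_that("relevance scores match a naive per-gene loop on random matrices", {
  set.seed(5150)
  for (trial in 1:300) {
    r <- matrix(runif(400, -1, 1), 20, 20,
      dimnames = list(sprintf("g%02d", 1:20), sprintf("l%02d", 1:20))
    )
    if (trial %% 3 == 0) r[sample(400, 5)] <- NA # undefined cells
    cutoff <- sample(c(0.5, 0.8, 0.9), 1)
    cm <- coexFromR(r, cutoff)
    lncSet <- sample(colnames(r), sample(1:20, 1))
    want <- naiveRelevance(r, cutoff, lncSet)
    got <- relevanceScores(cm, lncSet)
    expect_equal(got$score, unname(want[got$mrna]), tolerance = 1e-12)
    # ranking is by descending score with id tie-break
    expect_true(!is.unsorted(rev(got$score)))
  }
})

test_that("raising the cutoff never increases a relevance score", {
  set.seed(88)
  r <- matrix(runif(300, -1, 1), 15, 20,
    dimnames = list(sprintf("g%02d", 1:15), sprintf("l%02d", 1:20))
  )
  lncSet <- sprintf("l%02d", 1:10)
  prev <- NULL
  for (cutoff in c(0.3, 0.5, 0.7, 0.85, 0.95)) {
    sc <- relevanceScores(coexFromR(r, cutoff), lncSet)
    sc <- setNames(sc$score, sc$mrna)[sort(rownames(r))]
    if (!is.null(prev)) expect_true(all(sc <= prev + 1e-12))
    prev <- sc
  }
})

test_that("selectTop enforces its contract", {
  rk <- data.frame(
    mrna = c("a", "b", "c"), score = c(3, 2, 0), rank = 1:3
  )
  expect_identical(selectTop(rk, "k", 2), c("a", "b"))
  expect_error(selectTop(rk, "k", 0))
  expect_warning(out <- selectTop(rk, "k", 10), "exceeds")
  expect_identical(out, c("a", "b", "c"))
  expect_identical(selectTop(rk, "score_min", 1), c("a", "b"))
})

test_that("cis correlation profiles recover planted sign structure", {
  mix <- c(
    intergenic = 0, intronic_antisense = 0.5, natural_antisense = 0,
    exon_sense_overlapping = 0, bidirectional = 0,
    intron_sense_overlapping = 0.5
  )
  p <- simParams(
    nMrna = 120, nLncrna = 120, subtypeMix = mix, cisRho = 0.9,
    subtypeSignProfile = c(
      intron_sense_overlapping = 0.95, intronic_antisense = 0.3
    ),
    seed = 401, design = "triplet"
  )
  ann <- simulateAnnotation(p)
  sim <- simulateExpression(ann$annotation, ann$truth, p)
  labels <- classifyLncRNAs(ann$annotation)
  prof <- cisCorrelationProfile(cisPartnerPairs(labels), sim$experiment)
  s <- prof$summary
  iso <- s[s$subtype == "intron_sense_overlapping", ]
  ia <- s[s$subtype == "intronic_antisense", ]
  expect_gt(iso$fracPositive, 0.8)
  expect_gt(ia$fracNegative, ia$fracPositive)
  # subtypes with no pairs are flagged empty
  bid <- s[s$subtype == "bidirectional", ]
  expect_true(bid$empty)
  expect_identical(bid$n, 0L)
})

test_that("unplanted pairs have near-zero mean correlation", {
  # pairs that share no latent factor: planted r = 0
  set.seed(314)
  n <- 200
  m <- matrix(rnorm(2 * n), 2, n, dimnames = list(c("l1", "m1"), NULL))
  ue <- makeUe(m, nPat = n / 2, biotype = c("lncRNA", "mRNA"))
  pairs <- data.frame(lnc = "l1", mrna = "m1", subtype = "bidirectional")
  prof <- cisCorrelationProfile(pairs, ue)
  r <- prof$values$bidirectional
  expect_lt(abs(r), qnorm(0.995) / sqrt(n - 3))
})

test_that("permuted samples drive |r| > 0.8 to its small-n null level", {
  p <- simParams(nMrna = 150, nLncrna = 60, seed = 77, design = "triplet")
  study <- simulateStudy(p)
  m <- SummarizedExperiment::assay(study$experiment)
  set.seed(99)
  perm <- t(apply(m, 1, sample)) # independent shuffle per feature
  dimnames(perm) <- dimnames(m)
  ue <- ulmExperiment(
    perm, sampleSheet(study$experiment),
    featureBiotypes(study$experiment)
  )
  cm <- buildCoexMatrix(ue,
    mrnaIds = rownames(m)[1:150], lncIds = rownames(m)[151:210]
  )
  frac <- mean(abs(corMatrix(cm)) > 0.8)
  # theoretical two-sided null tail at n = 15 via the t transform
  t0 <- 0.8 * sqrt(13) / sqrt(1 - 0.64)
  p0 <- 2 * pt(-t0, df = 13)
  expect_lt(frac, 10 * p0 + 3 / 9000)
})

test_that("buildCoexMatrix derives row and column sets from DE calls", {
  p <- simParams(
    nMrna = 80, nLncrna = 40, fracDeMrnaLarge = 0.3,
    fracDeLncrnaLarge = 0.3, effectLarge = 3, effectSmall = 1.5,
    seed = 55, design = "triplet"
  )
  ann <- simulateAnnotation(p)
  sim <- simulateExpression(ann$annotation, ann$truth, p)
  ue <- quantileNormalize(sim$experiment)
  de <- diffExprTable(ue)
  called <- rownames(de)[de$callS != "none" | de$callL != "none"]
  cm <- buildCoexMatrix(ue, de = de)
  bio <- featureBiotypes(ue)
  expect_setequal(rownames(corMatrix(cm)), called[bio[called] == "mRNA"])
  expect_setequal(colnames(corMatrix(cm)), called[bio[called] == "lncRNA"])
  expect_error(
    buildCoexMatrix(ue, mrnaIds = character(), lncIds = "x"),
    "empty"
  )
})
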