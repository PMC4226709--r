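#' @include constructors.R
NULL

# Territory geometry of the toy genome. Each gene owns a fixed-width
# territory; its hosted lncRNA (if any) is placed inside that territory at
# offsets chosen so that exactly one subtype definition holds and every
# other gene is more than an order of magnitude beyond the default
# bidirectional window. That makes placements adversarial-safe: the
# classifier cannot pick up an accidental second relationship.
.TERRITORY <- 40000L
.GENE_OFFSET <- 20000L # gene start within its territory
.GENE_LEN <- 5000L # three 1 kb exons separated by two 1 kb introns
.LNC_LEN <- 500L
.BIDIR_GAP <- 200L

#' Simulate a toy annotated genome
#'
#' Places protein-coding genes (three exons each) on evenly spaced
#' territories and one lncRNA per subtype draw inside a host gene's
#' territory, constructed so that each lncRNA satisfies exactly one
#' genomic-context subtype definition under the [classifyLncRNAs()] rules.
#' Intended subtypes and cis partners are recorded as ground truth.
#'
#' @param params a [SimParams-class] object.
#' @return a list with elements `annotation` (a
#'   [GenomicRanges::GRanges] with metadata columns `tx_id`, `biotype` and
#'   an `exons` IRangesList) and `truth` (list with data.frames
#'   `lncSubtypes` and `cisPairs`).
#' @examples
#' ann <- simulateAnnotation(simParams(nMrna = 30, nLncrna = 12, seed = 3))
#' table(ann$truth$lncSubtypes$subtype)
#' @export
simulateAnnotation <- function(params) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  nM <- params@nMrna
  nL <- params@nLncrna
  genesPerChrom <- ceiling(nM / params@nChromosomes)
  if (genesPerChrom * .TERRITORY + .TERRITORY > params@chromLength) {
    .contractError(
      "capacity: ", genesPerChrom, " genes per chromosome need ",
      genesPerChrom * .TERRITORY + .TERRITORY,
      " bp but chromLength is ", params@chromLength,
      class = "lncomat_capacity_error"
    )
  }
  if (nL > nM) {
    .contractError(
      "capacity: each lncRNA needs its own host gene territory (",
      nL, " lncRNAs > ", nM, " genes)",
      class = "lncomat_capacity_error"
    )
  }

  idw <- max(3L, nchar(as.character(max(nM, nL))))
  geneId <- sprintf("mRNA_%0*d", idw, seq_len(nM))
  lncId <- sprintf("lnc_%0*d", idw, seq_len(nL))

  gi <- seq_len(nM) - 1L
  geneChrom <- paste0("chr", gi %/% genesPerChrom + 1L)
  terr <- (gi %% genesPerChrom) * .TERRITORY # 0-based territory start
  g1 <- terr + .GENE_OFFSET + 1L # 1-based gene start
  geneStrand <- ifelse(seq_len(nM) %% 2L == 1L, "+", "-")
  exonRel <- cbind(c(0L, 2000L, 4000L), c(999L, 2999L, 4999L))
  geneExons <- IRangesList(lapply(g1, function(s) {
    IRanges(start = s + exonRel[, 1], end = s + exonRel[, 2])
  }))

  .withSubstream(params@seed, "annotation", {
    subtype <- sample(.SUBTYPES, nL, replace = TRUE, prob = params@subtypeMix[.SUBTYPES])
    intergenicStrand <- sample(c("+", "-"), nL, replace = TRUE)
  })

  host <- seq_len(nL) # one host gene per lncRNA, never shared
  hg1 <- g1[host]
  hstr <- geneStrand[host]
  opp <- ifelse(hstr == "+", "-", "+")
  lncStart <- integer(nL)
  lncEnd <- integer(nL)
  lncStrand <- character(nL)
  for (j in seq_len(nL)) {
    G <- hg1[j]
    switch(subtype[j],
      exon_sense_overlapping = { # straddles exon2 / intron2 boundary
        lncStart[j] <- G + 2600L
        lncEnd[j] <- G + 3099L
        lncStrand[j] <- hstr[j]
      },
      intron_sense_overlapping = { # wholly inside intron1
        lncStart[j] <- G + 1200L
        lncEnd[j] <- G + 1699L
        lncStrand[j] <- hstr[j]
      },
      natural_antisense = {
        lncStart[j] <- G + 2600L
        lncEnd[j] <- G + 3099L
        lncStrand[j] <- opp[j]
      },
      intronic_antisense = {
        lncStart[j] <- G + 1200L
        lncEnd[j] <- G + 1699L
        lncStrand[j] <- opp[j]
      },
      bidirectional = { # divergent, TSS-to-TSS gap of .BIDIR_GAP bp
        if (hstr[j] == "+") {
          lncEnd[j] <- G - .BIDIR_GAP - 1L
          lncStart[j] <- lncEnd[j] - .LNC_LEN + 1L
          lncStrand[j] <- "-"
        } else {
          E <- G + .GENE_LEN - 1L
          lncStart[j] <- E + .BIDIR_GAP + 1L
          lncEnd[j] <- lncStart[j] + .LNC_LEN - 1L
          lncStrand[j] <- "+"
        }
      },
      intergenic = { # far (>= 14 kb) from every gene interval and TSS
        lncStart[j] <- terr[host[j]] + 2001L
        lncEnd[j] <- lncStart[j] + .LNC_LEN - 1L
        lncStrand[j] <- intergenicStrand[j]
      }
    )
  }
  lncChrom <- geneChrom[host]
  lncExons <- IRangesList(mapply(
    function(s, e) IRanges(start = s, end = e),
    lncStart, lncEnd,
    SIMPLIFY = FALSE
  ))

  annotation <- GRanges(
    seqnames = c(geneChrom, lncChrom),
    ranges = IRanges(
      start = c(g1, lncStart),
      end = c(g1 + .GENE_LEN - 1L, lncEnd)
    ),
    strand = c(geneStrand, lncStrand)
  )
  mcols(annotation)$tx_id <- c(geneId, lncId)
  mcols(annotation)$biotype <- rep(c("mRNA", "lncRNA"), c(nM, nL))
  mcols(annotation)$exons <- c(geneExons, lncExons)
  names(annotation) <- mcols(annotation)$tx_id

  partner <- ifelse(subtype == "intergenic", NA_character_, geneId[host])
  lncSubtypes <- data.frame(
    lnc = lncId, subtype = subtype, partner = partner,
    stringsAsFactors = FALSE
  )
  cis <- lncSubtypes[lncSubtypes$subtype %in% .CIS_SUBTYPES, , drop = FALSE]
  cisPairs <- data.frame(
    lnc = cis$lnc, mrna = cis$partner, subtype = cis$subtype,
    targetR = rep(NA_real_, nrow(cis)), stringsAsFactors = FALSE
  )
  list(
    annotation = annotation,
    truth = list(lncSubtypes = lncSubtypes, cisPairs = cisPairs)
  )
}

#' @noRd
.designSheet <- function(params) {
  n <- params@nPatientsPerGroup
  if (params@design == "triplet") {
    pat <- sprintf("P%02d", seq_len(n))
    data.frame(
      sample = c(paste0(pat, "_N"), paste0(pat, "_S"), paste0(pat, "_L")),
      patient = rep(pat, 3),
      tissue = rep(c("N", "T", "T"), each = n),
      size = rep(c(NA, "S", "L"), each = n),
      stringsAsFactors = FALSE
    )
  } else {
    patS <- sprintf("P%02d", seq_len(n))
    patL <- sprintf("P%02d", n + seq_len(n))
    data.frame(
      sample = c(
        paste0(patS, "_N"), paste0(patS, "_S"),
        paste0(patL, "_N"), paste0(patL, "_L")
      ),
      patient = c(patS, patS, patL, patL),
      tissue = rep(c("N", "T", "N", "T"), each = n),
      size = rep(c(NA, "S", NA, "L"), each = n),
      stringsAsFactors = FALSE
    )
  }
}

# Latent-factor loading planting an exact population correlation rho
# between two features that both load on one shared N(0,1) factor on top
# of independent noise with total variance sigma2:
#   r = gamma^2 / (gamma^2 + sigma2)  =>  gamma^2 = rho * sigma2 / (1 - rho)
#' @noRd
.factorLoading <- function(rho, sigma2) {
  if (sigma2 <= 0) {
    return(0)
  }
  sqrt(rho * sigma2 / (1 - rho))
}

#' Simulate paired expression data over a toy annotation
#'
#' Generates log2 expression per the additive model: per-feature baseline,
#' per-feature-per-patient random effect, a planted differential-expression
#' shift in tumor columns (small or large magnitude by size class), shared
#' latent factors planting exact cis-pair and module correlations, and iid
#' Gaussian noise. Matched tumor and normal samples share the patient
#' effect, so paired contrasts cancel it.
#'
#' @param annotation,truth output of [simulateAnnotation()].
#' @param params the same [SimParams-class] used for the annotation.
#' @return list with `experiment` (a [UlmExperiment-class]) and `truth`
#'   (a completed [TruthManifest-class]).
#' @examples
#' p <- simParams(nMrna = 40, nLncrna = 16, seed = 11)
#' ann <- simulateAnnotation(p)
#' sim <- simulateExpression(ann$annotation, ann$truth, p)
#' sim$truth
#' @export
simulateExpression <- function(annotation, truth, params) {
  stopifnot(is(params, "SimParams"))
  feat <- mcols(annotation)$tx_id
  biotype <- mcols(annotation)$biotype
  .assert(
    all(truth$lncSubtypes$lnc %in% feat) &&
      all(truth$cisPairs$mrna %in% feat),
    "annotation and truth reference different feature ids",
    class = "lncomat_integrity_error"
  )
  nFeat <- length(feat)
  sheet <- .designSheet(params)
  nSamp <- nrow(sheet)
  patients <- unique(sheet$patient)
  patIdx <- match(sheet$patient, patients)
  sigma2 <- params@noiseSd^2 + params@patientSd^2

  # planted DE status per biotype, large-set nested with small-set
  pickDE <- function(idx, fracS, fracL) {
    nS <- round(fracS * length(idx))
    nL <- round(fracL * length(idx))
    if (nL >= nS) {
      deL <- sample(idx, nL)
      deS <- if (nS > 0) sample(deL, nS) else integer()
    } else {
      deS <- sample(idx, nS)
      deL <- if (nL > 0) sample(deS, nL) else integer()
    }
    list(S = deS, L = deL)
  }

  deltaS <- numeric(nFeat)
  deltaL <- numeric(nFeat)
  direction <- rep(NA_character_, nFeat)
  .withSubstream(params@seed, "de", {
    mr <- which(biotype == "mRNA")
    ln <- which(biotype == "lncRNA")
    deM <- pickDE(mr, params@fracDeMrnaSmall, params@fracDeMrnaLarge)
    deLn <- pickDE(ln, params@fracDeLncrnaSmall, params@fracDeLncrnaLarge)
    deUnion <- list(
      mRNA = union(deM$S, deM$L),
      lncRNA = union(deLn$S, deLn$L)
    )
    sgn <- numeric(nFeat)
    u <- deUnion$mRNA
    sgn[u] <- ifelse(runif(length(u)) < params@downBiasMrna, -1, 1)
    u <- deUnion$lncRNA
    sgn[u] <- ifelse(runif(length(u)) < params@upBiasLncrna, 1, -1)
    ratio <- params@effectLarge / params@effectSmall
    for (de in list(deM, deLn)) {
      magS <- setNames(
        rgamma(length(de$S), shape = 6, rate = 6 / params@effectSmall), de$S
      )
      deltaS[de$S] <- sgn[de$S] * magS
      inBoth <- intersect(de$S, de$L)
      lOnly <- setdiff(de$L, de$S)
      deltaL[inBoth] <- deltaS[inBoth] * ratio
      deltaL[lOnly] <- sgn[lOnly] *
        rgamma(length(lOnly), shape = 6, rate = 6 / params@effectLarge)
    }
    direction[sgn > 0] <- "up"
    direction[sgn < 0] <- "down"
  })

  # cis-pair correlation signs per subtype profile
  cisPairs <- truth$cisPairs
  .withSubstream(params@seed, "signs", {
    if (nrow(cisPairs)) {
      pPos <- params@subtypeSignProfile[cisPairs$subtype]
      pPos[is.na(pPos)] <- 0.5
      cisPairs$targetR <- ifelse(runif(nrow(cisPairs)) < pPos, 1, -1) *
        params@cisRho
    }
  })

  # optional planted module: intergenic lncRNAs x unpaired mRNAs
  moduleMrnas <- character()
  moduleLncrnas <- character()
  if (params@moduleNMrna > 0 && params@moduleNLncrna > 0) {
    freeM <- setdiff(feat[biotype == "mRNA"], cisPairs$mrna)
    freeL <- truth$lncSubtypes$lnc[truth$lncSubtypes$subtype == "intergenic"]
    .assert(
      length(freeM) >= params@moduleNMrna &&
        length(freeL) >= params@moduleNLncrna,
      "not enough unpaired mRNAs or intergenic lncRNAs to plant the module",
      class = "lncomat_capacity_error"
    )
    .withSubstream(params@seed, "module", {
      moduleMrnas <- sample(freeM, params@moduleNMrna)
      moduleLncrnas <- sample(freeL, params@moduleNLncrna)
    })
  }

  X <- matrix(0, nFeat, nSamp, dimnames = list(feat, sheet$sample))
  .withSubstream(params@seed, "baseline", {
    X[] <- rnorm(nFeat, mean = 8, sd = 1.5)
  })
  .withSubstream(params@seed, "patient", {
    eta <- matrix(
      rnorm(nFeat * length(patients), 0, params@patientSd),
      nFeat, length(patients)
    )
    X <- X + eta[, patIdx, drop = FALSE]
  })
  isS <- sheet$tissue == "T" & sheet$size %in% "S"
  isL <- sheet$tissue == "T" & sheet$size %in% "L"
  X[, isS] <- X[, isS] + deltaS
  X[, isL] <- X[, isL] + deltaL
  .withSubstream(params@seed, "factors", {
    gcis <- .factorLoading(params@cisRho, sigma2)
    if (nrow(cisPairs)) {
      for (i in seq_len(nrow(cisPairs))) {
        f <- rnorm(nSamp)
        li <- match(cisPairs$lnc[i], feat)
        mi <- match(cisPairs$mrna[i], feat)
        X[li, ] <- X[li, ] + gcis * f
        X[mi, ] <- X[mi, ] + sign(cisPairs$targetR[i]) * gcis * f
      }
    }
    if (length(moduleMrnas)) {
      gmod <- .factorLoading(params@moduleRho, sigma2)
      f <- rnorm(nSamp)
      mi <- match(c(moduleMrnas, moduleLncrnas), feat)
      X[mi, ] <- X[mi, ] + rep(gmod * f, each = length(mi))
    }
  })
  .withSubstream(params@seed, "noise", {
    X <- X + matrix(rnorm(nFeat * nSamp, 0, params@noiseSd), nFeat, nSamp)
  })

  planted <- which(deltaS != 0 | deltaL != 0)
  deCalls <- data.frame(
    feature = feat[planted],
    biotype = biotype[planted],
    direction = direction[planted],
    log2fcSmall = deltaS[planted],
    log2fcLarge = deltaL[planted],
    stringsAsFactors = FALSE
  )
  manifest <- new("TruthManifest",
    deCalls = deCalls,
    lncSubtypes = truth$lncSubtypes,
    cisPairs = cisPairs,
    enrichedSets = character(),
    moduleMrnas = moduleMrnas,
    moduleLncrnas = moduleLncrnas,
    moduleRho = params@moduleRho,
    seed = params@seed
  )
  ue <- ulmExperiment(X, sheet, setNames(biotype, feat))
  list(experiment = ue, truth = manifest)
}

#' Simulate a gene-set collection with one planted enriched set
#'
#' Builds `nGenesets` sets of `genesetSize` mRNAs. One set is planted as
#' enriched: `enrichedFraction` of its members are drawn from the
#' down-regulated DE mRNAs of the truth manifest, the remainder at random;
#' all other sets are uniform draws from the mRNA universe.
#'
#' @param truth a [TruthManifest-class] from [simulateExpression()].
#' @param mrnaIds character vector: the mRNA universe.
#' @param params the [SimParams-class] of the run.
#' @return list with `geneSets` (named list of character vectors with a
#'   `descriptions` attribute, as returned by [readGmt()]) and `truth`
#'   (the manifest with `enrichedSets` filled in).
#' @export
simulateGeneSets <- function(truth, mrnaIds, params) {
  stopifnot(is(truth, "TruthManifest"))
  de <- truth@deCalls
  down <- de$feature[de$biotype == "mRNA" & de$direction == "down"]
  down <- intersect(down, mrnaIds)
  nSets <- params@nGenesets
  sz <- params@genesetSize
  .withSubstream(params@seed, "genesets", {
    setNamesVec <- sprintf("GS%02d", seq_len(nSets))
    enrichedName <- sample(setNamesVec, 1)
    sets <- lapply(setNamesVec, function(nm) {
      if (nm == enrichedName) {
        k <- min(round(params@enrichedFraction * sz), length(down))
        planted <- sample(down, k)
        rest <- sample(setdiff(mrnaIds, planted), sz - k)
        sample(c(planted, rest)) # shuffle member order
      } else {
        sample(mrnaIds, sz)
      }
    })
    names(sets) <- setNamesVec
    attr(sets, "descriptions") <- setNames(
      rep("synthetic gene set", nSets), setNamesVec
    )
    truth@enrichedSets <- enrichedName
    list(geneSets = sets, truth = truth)
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining [simulateAnnotation()],
#' [simulateExpression()] and [simulateGeneSets()].
#'
#' @param params a [SimParams-class].
#' @return list with `annotation`, `experiment`, `geneSets` and `truth`.
#' @examples
#' study <- simulateStudy(simParams(nMrna = 60, nLncrna = 24, seed = 5))
#' study$experiment
#' @export
simulateStudy <- function(params) {
  ann <- simulateAnnotation(params)
  sim <- simulateExpression(ann$annotation, ann$truth, params)
  gs <- simulateGeneSets(
    sim$truth,
    mcols(ann$annotation)$tx_id[mcols(ann$annotation)$biotype == "mRNA"],
    params
  )
  list(
    annotation = ann$annotation,
    experiment = sim$experiment,
    geneSets = gs$geneSets,
    truth = gs$truth
  )
}
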