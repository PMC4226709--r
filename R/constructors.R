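#' @include AllClasses.R
NULL

#' Construct simulation parameters
#'
#' Defaults mirror the study design the generator emulates: three matched
#' groups of five samples (myometrium, small tumors <= 3 cm, large tumors
#' >= 10 cm), predominantly down-regulated mRNAs versus predominantly
#' up-regulated lncRNAs, stronger dysregulation in large tumors, an
#' intergenic-majority subtype mixture, and subtype-specific cis
#' correlation sign profiles (intron sense-overlapping overwhelmingly
#' positive, intronic antisense negative-leaning).
#'
#' @param nPatientsPerGroup patients per tumor-size group (default 5).
#' @param nMrna,nLncrna number of protein-coding and lncRNA features.
#' @param nChromosomes,chromLength toy genome geometry in bp.
#' @param fracDeMrnaSmall,fracDeMrnaLarge fraction of mRNAs planted DE in
#'   the small and large contrasts (large superset of small when larger).
#' @param fracDeLncrnaSmall,fracDeLncrnaLarge same for lncRNAs.
#' @param downBiasMrna probability a DE mRNA is down-regulated.
#' @param upBiasLncrna probability a DE lncRNA is up-regulated.
#' @param effectSmall,effectLarge mean planted |log2FC| per contrast.
#' @param noiseSd,patientSd residual and patient random-effect SDs (log2).
#' @param subtypeMix named proportions over the six lncRNA subtypes.
#' @param cisRho target |Pearson r| for planted cis pairs.
#' @param subtypeSignProfile named P(positive correlation) per subtype.
#' @param nGenesets,genesetSize gene-set collection geometry.
#' @param enrichedFraction fraction of the planted enriched set's members
#'   drawn from down-regulated DE mRNAs.
#' @param moduleNMrna,moduleNLncrna,moduleRho optional planted
#'   co-expression module (disabled when the counts are 0).
#' @param design `"disjoint"` or `"triplet"` patient sharing between the
#'   small- and large-tumor groups.
#' @param seed integer base seed.
#' @return a validated [SimParams-class] object.
#' @examples
#' p <- simParams(nMrna = 50, nLncrna = 20, seed = 7)
#' p
#' @export
simParams <- function(nPatientsPerGroup = 5,
                      nMrna = 300,
                      nLncrna = 120,
                      nChromosomes = 3,
                      chromLength = 5e6,
                      fracDeMrnaSmall = 0.08,
                      fracDeMrnaLarge = 0.15,
                      fracDeLncrnaSmall = 0.08,
                      fracDeLncrnaLarge = 0.15,
                      downBiasMrna = 0.75,
                      upBiasLncrna = 0.75,
                      effectSmall = 1.2,
                      effectLarge = 2.0,
                      noiseSd = 0.4,
                      patientSd = 0.3,
                      subtypeMix = c(
                        intergenic = 0.40,
                        intronic_antisense = 0.12,
                        natural_antisense = 0.12,
                        exon_sense_overlapping = 0.12,
                        bidirectional = 0.12,
                        intron_sense_overlapping = 0.12
                      ),
                      cisRho = 0.7,
                      subtypeSignProfile = c(
                        intronic_antisense = 0.30,
                        natural_antisense = 0.35,
                        bidirectional = 0.65,
                        intron_sense_overlapping = 0.95
                      ),
                      nGenesets = 20,
                      genesetSize = 25,
                      enrichedFraction = 0.8,
                      moduleNMrna = 0,
                      moduleNLncrna = 0,
                      moduleRho = 0.9,
                      design = c("disjoint", "triplet"),
                      seed = 1) {
  design <- match.arg(design)
  new("SimParams",
    nPatientsPerGroup = as.integer(nPatientsPerGroup),
    nMrna = as.integer(nMrna),
    nLncrna = as.integer(nLncrna),
    nChromosomes = as.integer(nChromosomes),
    chromLength = as.integer(chromLength),
    fracDeMrnaSmall = fracDeMrnaSmall,
    fracDeMrnaLarge = fracDeMrnaLarge,
    fracDeLncrnaSmall = fracDeLncrnaSmall,
    fracDeLncrnaLarge = fracDeLncrnaLarge,
    downBiasMrna = downBiasMrna,
    upBiasLncrna = upBiasLncrna,
    effectSmall = effectSmall,
    effectLarge = effectLarge,
    noiseSd = noiseSd,
    patientSd = patientSd,
    subtypeMix = subtypeMix[.SUBTYPES],
    cisRho = cisRho,
    subtypeSignProfile = subtypeSignProfile,
    nGenesets = as.integer(nGenesets),
    genesetSize = as.integer(genesetSize),
    enrichedFraction = enrichedFraction,
    moduleNMrna = as.integer(moduleNMrna),
    moduleNLncrna = as.integer(moduleNLncrna),
    moduleRho = moduleRho,
    design = design,
    seed = as.integer(seed)
  )
}

#' Construct a paired tumor-normal expression experiment
#'
#' Bundles a log2 expression matrix with its sample sheet and feature
#' biotypes into a validated [UlmExperiment-class]. The sample sheet must
#' cover every expression column; duplicated feature or sample ids and
#' non-finite values are rejected.
#'
#' @param exprs numeric matrix, features x samples, log2 scale, with
#'   row and column names.
#' @param sampleSheet data.frame with columns `sample`, `patient`,
#'   `tissue` (\code{"N"}/\code{"T"}) and `size` (\code{"S"}/\code{"L"}/NA).
#' @param biotype character vector (`"mRNA"`/`"lncRNA"`), either named by
#'   feature or in row order.
#' @return a [UlmExperiment-class].
#' @examples
#' m <- matrix(rnorm(12, 8), 3, 4,
#'   dimnames = list(
#'     c("g1", "g2", "l1"),
#'     c("P1_N", "P1_S", "P2_N", "P2_S")
#'   )
#' )
#' sheet <- data.frame(
#'   sample = colnames(m), patient = rep(c("P1", "P2"), each = 2),
#'   tissue = rep(c("N", "T"), 2), size = rep(c(NA, "S"), 2)
#' )
#' ue <- ulmExperiment(m, sheet, c("mRNA", "mRNA", "lncRNA"))
#' @export
ulmExperiment <- function(exprs, sampleSheet, biotype) {
  .assert(is.matrix(exprs) && is.numeric(exprs), "'exprs' must be a numeric matrix")
  .assert(
    !is.null(rownames(exprs)) && !is.null(colnames(exprs)),
    "'exprs' must carry feature and sample ids as dimnames"
  )
  if (anyDuplicated(rownames(exprs))) {
    .schemaError(
      "duplicated feature ids: ",
      paste(unique(rownames(exprs)[duplicated(rownames(exprs))]), collapse = ", ")
    )
  }
  if (anyDuplicated(colnames(exprs))) {
    .schemaError("duplicated sample ids")
  }
  need <- c("sample", "patient", "tissue", "size")
  .assert(
    is.data.frame(sampleSheet) && all(need %in% colnames(sampleSheet)),
    "sample sheet needs columns: ", paste(need, collapse = ", ")
  )
  missing <- setdiff(colnames(exprs), sampleSheet$sample)
  if (length(missing)) {
    .schemaError(
      "samples absent from sample sheet: ", paste(missing, collapse = ", ")
    )
  }
  idx <- match(colnames(exprs), sampleSheet$sample)
  cd <- DataFrame(
    patient = as.character(sampleSheet$patient[idx]),
    tissue = as.character(sampleSheet$tissue[idx]),
    size = as.character(sampleSheet$size[idx]),
    row.names = colnames(exprs)
  )
  if (!is.null(names(biotype))) {
    .assert(
      all(rownames(exprs) %in% names(biotype)),
      "named 'biotype' must cover every feature"
    )
    biotype <- biotype[rownames(exprs)]
  } else {
    .assert(
      length(biotype) == nrow(exprs),
      "'biotype' must have one entry per feature"
    )
  }
  bad <- which(!is.finite(exprs))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(exprs))
    .assert(FALSE,
      sprintf(
        "non-finite expression value at feature '%s', sample '%s'",
        rownames(exprs)[i[1]], colnames(exprs)[i[2]]
      ),
      class = "lncomat_value_error"
    )
  }
  se <- SummarizedExperiment(
    assays = list(log2 = exprs),
    colData = cd,
    rowData = DataFrame(biotype = as.character(biotype))
  )
  new("UlmExperiment", se)
}
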