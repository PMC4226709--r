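#' @include utils.R
NULL

#' Simulation parameters for the synthetic study generator
#'
#' An S4 container holding every knob of the synthetic-data generator:
#' study size, genome geometry, differential-expression fractions and
#' direction biases, effect magnitudes for small and large tumors, noise
#' components, the lncRNA subtype mixture, the planted cis-correlation
#' strength and per-subtype sign profile, gene-set planting, and an
#' optional co-expression module. Construct with [simParams()]; all slots
#' are validated.
#'
#' @slot nPatientsPerGroup patients contributing each tumor size class.
#' @slot nMrna,nLncrna feature counts by biotype.
#' @slot nChromosomes,chromLength genome geometry (bp).
#' @slot fracDeMrnaSmall,fracDeMrnaLarge,fracDeLncrnaSmall,fracDeLncrnaLarge
#'   fractions of each biotype planted as differentially expressed in the
#'   small-tumor and large-tumor contrasts.
#' @slot downBiasMrna probability a planted DE mRNA is down-regulated.
#' @slot upBiasLncrna probability a planted DE lncRNA is up-regulated.
#' @slot effectSmall,effectLarge mean |log2 fold change| of planted effects
#'   (log2 units; effectLarge > effectSmall).
#' @slot noiseSd,patientSd residual and per-patient random-effect standard
#'   deviations (log2 units).
#' @slot subtypeMix named proportions over the six lncRNA subtypes; sums
#'   to 1.
#' @slot cisRho target |Pearson r| planted for cis lncRNA-mRNA pairs.
#' @slot subtypeSignProfile named probabilities that a planted cis pair of
#'   that subtype is positively correlated.
#' @slot nGenesets,genesetSize,enrichedFraction gene-set planting: number
#'   of sets, members per set, and the fraction of the planted enriched
#'   set's members drawn from the down-regulated DE mRNAs.
#' @slot moduleNMrna,moduleNLncrna,moduleRho optional planted co-expression
#'   module (0 features disables it): module members share one latent
#'   factor with pairwise correlation moduleRho.
#' @slot design `"disjoint"` (small and large tumors from disjoint
#'   patients, each with a matched normal) or `"triplet"` (each patient
#'   contributes normal, small and large samples).
#' @slot seed integer base seed; all substeps fork deterministically from
#'   it.
#'
#' @seealso [simParams()], [simulateStudy()]
#' @export
setClass("SimParams", representation(
  nPatientsPerGroup = "integer",
  nMrna = "integer",
  nLncrna = "integer",
  nChromosomes = "integer",
  chromLength = "integer",
  fracDeMrnaSmall = "numeric",
  fracDeMrnaLarge = "numeric",
  fracDeLncrnaSmall = "numeric",
  fracDeLncrnaLarge = "numeric",
  downBiasMrna = "numeric",
  upBiasLncrna = "numeric",
  effectSmall = "numeric",
  effectLarge = "numeric",
  noiseSd = "numeric",
  patientSd = "numeric",
  subtypeMix = "numeric",
  cisRho = "numeric",
  subtypeSignProfile = "numeric",
  nGenesets = "integer",
  genesetSize = "integer",
  enrichedFraction = "numeric",
  moduleNMrna = "integer",
  moduleNLncrna = "integer",
  moduleRho = "numeric",
  design = "character",
  seed = "integer"
))

setValidity("SimParams", function(object) {
  msgs <- character()
  props <- c(
    "fracDeMrnaSmall", "fracDeMrnaLarge", "fracDeLncrnaSmall",
    "fracDeLncrnaLarge", "downBiasMrna", "upBiasLncrna", "enrichedFraction"
  )
  for (p in props) {
    if (!.isProportion(slot(object, p))) {
      msgs <- c(msgs, sprintf("'%s' must be a single proportion in [0,1]", p))
    }
  }
  counts <- c(
    "nPatientsPerGroup", "nMrna", "nLncrna", "nChromosomes", "chromLength",
    "nGenesets", "genesetSize"
  )
  for (p in counts) {
    if (!.isCount(slot(object, p))) {
      msgs <- c(msgs, sprintf("'%s' must be a positive integer", p))
    }
  }
  if (!.isCount(object@moduleNMrna, positive = FALSE) ||
    !.isCount(object@moduleNLncrna, positive = FALSE)) {
    msgs <- c(msgs, "module feature counts must be non-negative integers")
  }
  mix <- object@subtypeMix
  if (!setequal(names(mix), .SUBTYPES) || anyNA(mix) || any(mix < 0)) {
    msgs <- c(msgs, "'subtypeMix' must be named proportions over the six subtypes")
  } else if (abs(sum(mix) - 1) > 1e-8) {
    msgs <- c(msgs, "'subtypeMix' must sum to 1")
  }
  sp <- object@subtypeSignProfile
  if (!all(names(sp) %in% .SUBTYPES) || any(sp < 0 | sp > 1)) {
    msgs <- c(msgs, "'subtypeSignProfile' must map subtypes to probabilities")
  }
  if (!(object@effectLarge > object@effectSmall && object@effectSmall > 0)) {
    msgs <- c(msgs, "need effectLarge > effectSmall > 0")
  }
  if (!(object@cisRho > 0 && object@cisRho < 1)) {
    msgs <- c(msgs, "'cisRho' must lie in (0,1)")
  }
  if (!(object@moduleRho > 0 && object@moduleRho < 1)) {
    msgs <- c(msgs, "'moduleRho' must lie in (0,1)")
  }
  if (object@noiseSd < 0 || object@patientSd < 0) {
    msgs <- c(msgs, "standard deviations must be non-negative")
  }
  if (!object@design %in% c("disjoint", "triplet")) {
    msgs <- c(msgs, "'design' must be \"disjoint\" or \"triplet\"")
  }
  if (length(msgs)) msgs else TRUE
})

#' Ground truth manifest of a synthetic run
#'
#' Records everything the generator planted, for recovery tests: per-feature
#' DE calls with signed log2 fold changes for both contrasts, cis pairs with
#' their subtype and signed target correlation, the planted enriched gene
#' sets, the optional co-expression module, and the seed.
#'
#' @slot deCalls data.frame with columns feature, biotype, direction
#'   (up/down), log2fcSmall, log2fcLarge.
#' @slot lncSubtypes data.frame with columns lnc, subtype, partner: the
#'   intended genomic-context subtype of every simulated lncRNA.
#' @slot cisPairs data.frame with columns lnc, mrna, subtype, targetR
#'   (signed; NA until expression is simulated).
#' @slot enrichedSets character vector of planted gene-set names.
#' @slot moduleMrnas,moduleLncrnas ids of planted module members.
#' @slot moduleRho planted module correlation.
#' @slot seed integer seed of the run.
#' @export
setClass("TruthManifest", representation(
  deCalls = "data.frame",
  lncSubtypes = "data.frame",
  cisPairs = "data.frame",
  enrichedSets = "character",
  moduleMrnas = "character",
  moduleLncrnas = "character",
  moduleRho = "numeric",
  seed = "integer"
))

setValidity("TruthManifest", function(object) {
  msgs <- character()
  de <- object@deCalls
  if (nrow(de) && !all(de$direction %in% c("up", "down"))) {
    msgs <- c(msgs, "DE directions must be 'up' or 'down'")
  }
  cp <- object@cisPairs
  if (nrow(cp)) {
    if (!all(cp$subtype %in% .SUBTYPES)) {
      msgs <- c(msgs, "cis pair subtypes outside the known vocabulary")
    }
    if (anyDuplicated(cp$lnc)) {
      msgs <- c(msgs, "each lncRNA may appear in at most one cis pair")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Paired tumor-normal expression experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass for log2
#' expression with the paired study design in `colData` (columns `patient`,
#' `tissue` in \{N, T\}, `size` in \{S, L, NA\}) and feature biotype
#' (`mRNA`/`lncRNA`) in `rowData`. Construct with [ulmExperiment()].
#'
#' @export
setClass("UlmExperiment", contains = "SummarizedExperiment")

setValidity("UlmExperiment", function(object) {
  msgs <- character()
  cd <- colData(object)
  need <- c("patient", "tissue", "size")
  if (!all(need %in% colnames(cd))) {
    return(sprintf(
      "colData must contain columns: %s", paste(need, collapse = ", ")
    ))
  }
  if (!all(cd$tissue %in% c("N", "T"))) {
    msgs <- c(msgs, "tissue must be 'N' (normal) or 'T' (tumor)")
  }
  if (!all(cd$size %in% c("S", "L") | is.na(cd$size))) {
    msgs <- c(msgs, "size must be 'S', 'L' or NA")
  }
  if (any(cd$tissue == "T" & is.na(cd$size))) {
    msgs <- c(msgs, "tumor samples must carry a size class")
  }
  if (!"biotype" %in% colnames(rowData(object))) {
    msgs <- c(msgs, "rowData must contain a 'biotype' column")
  } else if (!all(rowData(object)$biotype %in% c("mRNA", "lncRNA"))) {
    msgs <- c(msgs, "biotype must be 'mRNA' or 'lncRNA'")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object))) {
    msgs <- c(msgs, "feature ids must be present and unique")
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object))) {
    msgs <- c(msgs, "sample ids must be present and unique")
  }
  if (length(assays(object)) && !all(is.finite(assay(object)))) {
    msgs <- c(msgs, "expression values must be finite")
  }
  if (length(msgs)) msgs else TRUE
})

#' Trichotomized mRNA x lncRNA correlation matrix
#'
#' Holds the rectangular Pearson correlation matrix between dysregulated
#' mRNAs (rows) and dysregulated lncRNAs (columns), its trichotomized
#' \{-1, 0, +1\} twin under a symmetric |r| cutoff (strict inequalities),
#' and a tally of undefined cells (zero-variance features). Construct with
#' [buildCoexMatrix()]; access with [corMatrix()], [triMatrix()],
#' [corCutoff()], [undefinedCount()].
#'
#' @slot r numeric matrix of Pearson coefficients (NA where undefined).
#' @slot tri integer matrix in \{-1, 0, +1\} (NA where undefined).
#' @slot cutoff the |r| threshold used.
#' @slot span which samples the correlations were computed across
#'   (`"all"` or `"tumor"`).
#' @export
setClass("CoexMatrix", representation(
  r = "matrix",
  tri = "matrix",
  cutoff = "numeric",
  span = "character"
))

setValidity("CoexMatrix", function(object) {
  msgs <- character()
  if (!identical(dim(object@r), dim(object@tri))) {
    msgs <- c(msgs, "'r' and 'tri' must have identical dimensions")
  }
  if (!(length(object@cutoff) == 1L && object@cutoff > 0)) {
    msgs <- c(msgs, "'cutoff' must be a single positive number")
  }
  ok <- is.na(object@r) | (abs(object@r) <= 1 + 1e-12)
  if (!all(ok)) msgs <- c(msgs, "correlations must lie in [-1, 1]")
  defined <- !is.na(object@r)
  expect <- ifelse(object@r > object@cutoff, 1L,
    ifelse(object@r < -object@cutoff, -1L, 0L)
  )
  if (!identical(
    as.integer(object@tri[defined]), as.integer(expect[defined])
  )) {
    msgs <- c(msgs, "'tri' inconsistent with 'r' under the cutoff")
  }
  if (any(is.na(object@tri) != is.na(object@r))) {
    msgs <- c(msgs, "undefined cells must be NA in both 'r' and 'tri'")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SimParams", function(object) {
  cat(
    "SimParams:", object@nMrna, "mRNAs,", object@nLncrna, "lncRNAs,",
    object@nPatientsPerGroup, "patients/group,",
    sQuote(object@design), "design\n"
  )
  cat(
    "  DE fractions mRNA S/L:", object@fracDeMrnaSmall, "/",
    object@fracDeMrnaLarge, "; lncRNA S/L:", object@fracDeLncrnaSmall,
    "/", object@fracDeLncrnaLarge, "\n"
  )
  cat(
    "  effects S/L:", object@effectSmall, "/", object@effectLarge,
    "log2; noise sd", object@noiseSd, "; patient sd", object@patientSd, "\n"
  )
  cat("  cis rho:", object@cisRho, "; seed:", object@seed, "\n")
})

setMethod("show", "TruthManifest", function(object) {
  cat(
    "TruthManifest:", nrow(object@deCalls), "planted DE features,",
    nrow(object@cisPairs), "cis pairs,",
    length(object@enrichedSets), "enriched set(s)"
  )
  if (length(object@moduleMrnas)) {
    cat(
      ",", length(object@moduleMrnas), "x", length(object@moduleLncrnas),
      "module (rho =", object@moduleRho, ")"
    )
  }
  cat("; seed", object@seed, "\n")
})

setMethod("show", "CoexMatrix", function(object) {
  tab <- triCounts(object)
  cat(
    "CoexMatrix:", nrow(object@r), "mRNAs x", ncol(object@r),
    "lncRNAs, |r| cutoff", object@cutoff,
    sprintf("(span: %s)\n", object@span)
  )
  cat(
    "  positive:", tab[["positive"]], " negative:", tab[["negative"]],
    " none:", tab[["none"]], " undefined:", tab[["undefined"]], "\n"
  )
})
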