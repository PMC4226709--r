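#' @include simulate.R io.R annotation-io.R coexpr.R enrich.R classify.R
NULL

#' @noRd
.configError <- function(...) .assert(FALSE, ..., class = "lncomat_config_error")

#' @noRd
.readConfig <- function(config) {
  if (is.character(config) && length(config) == 1) {
    .assert(file.exists(config), "config file not found: ", config,
      class = "lncomat_config_error"
    )
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  .assert(is.list(config), "config must be a list or a YAML/JSON path",
    class = "lncomat_config_error"
  )
  defaults <- list(
    fcThreshold = 2, alpha = 0.05, adjust = "none", lsFcThreshold = 2,
    cutoff = 0.8, bidirWindow = 1000, span = "all",
    selection = list(mode = "score_min", value = .Machine$double.eps),
    enrich = TRUE, seed = 1
  )
  config <- utils::modifyList(defaults, config)
  with(config, {
    if (!(fcThreshold > 0 && alpha > 0 && alpha < 1 &&
      cutoff > 0 && cutoff < 1 && bidirWindow >= 0)) {
      .configError("a threshold is outside its legal range")
    }
  })
  if (!config$span %in% c("all", "tumor")) {
    .configError("span must be 'all' or 'tumor'")
  }
  simulated <- !is.null(config$simulate)
  if (!simulated) {
    need <- c("expression", "sampleSheet", "annotation")
    miss <- need[!vapply(
      need, function(f) !is.null(config[[f]]), logical(1)
    )]
    if (length(miss)) {
      .configError("config lacks input paths: ", paste(miss, collapse = ", "))
    }
    if (isTRUE(config$enrich) && is.null(config$gmt)) {
      .configError("enrichment requested but no 'gmt' path given")
    }
  }
  config
}

#' Run the full co-expression analysis pipeline
#'
#' Composes the stages in study order: (simulate or read inputs) ->
#' quantile normalization -> paired differential expression for both
#' size contrasts -> lncRNA subtype classification and cis pairing ->
#' per-subtype cis correlation profile -> trichotomized mRNA x lncRNA
#' correlation matrix -> relevance ranking against the large-tumor-specific
#' lncRNA set -> hypergeometric enrichment of the selected genes. Writes
#' one TSV per stage plus a JSON run manifest (effective config, package
#' version, md5 checksums of every output), so any stage can be re-run
#' from its intermediates. Outputs are deterministic given config and
#' seed.
#'
#' @param config a list, or path to a YAML/JSON file. Either `simulate:`
#'   (a list of [simParams()] overrides) or input paths `expression`,
#'   `sampleSheet`, `annotation` (+ `dialect`), `gmt`. Optional
#'   thresholds: `fcThreshold`, `alpha`, `adjust`, `lsFcThreshold`,
#'   `cutoff`, `span`, `bidirWindow`, `selection` (list with `mode`,
#'   `value`), `enrich`, `seed`.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config, outDir) {
  config <- .readConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  emit <- function(df, name) {
    path <- file.path(outDir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  if (!is.null(config$simulate)) {
    simArgs <- config$simulate
    if (isTRUE(simArgs)) simArgs <- list()
    simArgs$seed <- config$seed
    params <- do.call(simParams, simArgs)
    study <- simulateStudy(params)
    annotation <- study$annotation
    ue <- study$experiment
    geneSets <- study$geneSets
    writeExpression(
      ue,
      file.path(outDir, "expression.tsv"),
      file.path(outDir, "samples.tsv")
    )
    writeAnnotation(annotation, file.path(outDir, "annotation.gtf"), "GTF")
    writeGmt(geneSets, file.path(outDir, "genesets.gmt"))
    writeTruthManifest(study$truth, file.path(outDir, "truth.json"))
    outputs <- c(outputs, file.path(
      outDir,
      c("expression.tsv", "samples.tsv", "annotation.gtf", "genesets.gmt", "truth.json")
    ))
  } else {
    dialect <- if (is.null(config$dialect)) "GTF" else config$dialect
    ue <- readExpression(config$expression, config$sampleSheet)
    annotation <- readAnnotation(config$annotation, dialect)
    geneSets <- if (!is.null(config$gmt)) readGmt(config$gmt) else NULL
  }

  ue <- quantileNormalize(ue)
  de <- diffExprTable(ue,
    fcThreshold = config$fcThreshold, alpha = config$alpha,
    adjust = config$adjust, lsFcThreshold = config$lsFcThreshold
  )
  emit(
    data.frame(feature = rownames(de), as.data.frame(de)),
    "diffexpr.tsv"
  )

  labels <- classifyLncRNAs(annotation, bidirWindow = config$bidirWindow)
  emit(labels, "subtypes.tsv")
  pairs <- cisPartnerPairs(labels)
  profile <- cisCorrelationProfile(pairs, ue, span = config$span)
  emit(profile$summary, "cis_profile.tsv")

  called <- rownames(de)[de$callS != "none" | de$callL != "none"]
  calledM <- called[de[called, "biotype"] == "mRNA"]
  calledL <- called[de[called, "biotype"] == "lncRNA"]
  result <- list(
    experiment = ue, de = de, labels = labels, cisProfile = profile
  )
  if (length(calledM) && length(calledL)) {
    cm <- buildCoexMatrix(ue,
      mrnaIds = calledM, lncIds = calledL,
      cutoff = config$cutoff, span = config$span
    )
    emit(
      data.frame(mrna = rownames(corMatrix(cm)), corMatrix(cm),
        check.names = FALSE
      ),
      "comatrix.tsv"
    )
    set3 <- intersect(signatureSets(de, config$lsFcThreshold)$set3, calledL)
    lncSet <- if (length(set3)) set3 else calledL
    ranking <- relevanceScores(cm, lncSet)
    emit(ranking, "ranking.tsv")
    selected <- selectTop(
      ranking, config$selection$mode, config$selection$value
    )
    result$comatrix <- cm
    result$ranking <- ranking
    result$selected <- selected
    if (isTRUE(config$enrich) && !is.null(geneSets) && length(selected)) {
      universe <- rownames(ue)[rowData(ue)$biotype == "mRNA"]
      enr <- enrichList(selected, universe, geneSets)
      emit(enr, "enrichment.tsv")
      result$enrichment <- enr
    }
  } else {
    warning("no dysregulated features; correlation stages skipped")
  }

  manifest <- list(
    package = "lncomat",
    version = as.character(utils::packageVersion("lncomat")),
    config = config[setdiff(names(config), "simulate")],
    simulated = !is.null(config$simulate),
    outputs = lapply(
      stats::setNames(outputs, basename(outputs)),
      function(p) unname(tools::md5sum(p))
    )
  )
  jsonlite::write_json(
    manifest, file.path(outDir, "run_manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  result$manifest <- manifest
  invisible(result)
}
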