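#' @include constructors.R
NULL

#' Read a log2 expression matrix with its sample sheet
#'
#' The expression file is TSV with a `feature` id column, an optional
#' `biotype` column, and one numeric column per sample; the sample sheet is
#' TSV with columns `sample`, `patient`, `tissue`, `size`. Malformed input
#' is rejected rather than coerced: duplicated ids, samples missing from
#' the sheet, and non-numeric or non-finite cells (reported with their row
#' and column) are errors.
#'
#' @param path expression TSV path.
#' @param sampleSheetPath sample sheet TSV path.
#' @param biotype optional named biotype vector, required when the file has
#'   no `biotype` column.
#' @return a [UlmExperiment-class].
#' @seealso [writeExpression()]
#' @export
readExpression <- function(path, sampleSheetPath, biotype = NULL) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  .assert("feature" %in% colnames(tab), "expression TSV needs a 'feature' column",
    class = "lncomat_schema_error"
  )
  if (anyDuplicated(tab$feature)) {
    .schemaError(
      "duplicated feature id(s): ",
      paste(unique(tab$feature[duplicated(tab$feature)]), collapse = ", ")
    )
  }
  fileBiotype <- NULL
  if ("biotype" %in% colnames(tab)) {
    fileBiotype <- setNames(tab$biotype, tab$feature)
  }
  valueCols <- setdiff(colnames(tab), c("feature", "biotype"))
  .assert(length(valueCols) >= 1, "no sample columns found",
    class = "lncomat_schema_error"
  )
  for (cc in valueCols) {
    v <- tab[[cc]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1]
      .assert(FALSE,
        sprintf(
          "non-numeric or non-finite value at feature '%s', sample '%s'",
          tab$feature[bad], cc
        ),
        class = "lncomat_value_error"
      )
    }
  }
  m <- as.matrix(tab[, valueCols, drop = FALSE])
  rownames(m) <- tab$feature
  sheet <- read.delim(sampleSheetPath, stringsAsFactors = FALSE)
  sheet$size[sheet$size %in% c("", "NA")] <- NA
  ulmExperiment(m, sheet, if (is.null(biotype)) fileBiotype else biotype)
}

#' Write a log2 expression matrix and its sample sheet
#'
#' @param ue a [UlmExperiment-class].
#' @param path expression TSV path (columns: feature, biotype, samples).
#' @param sampleSheetPath sample sheet TSV path.
#' @return invisibly, the paths written.
#' @seealso [readExpression()]
#' @export
writeExpression <- function(ue, path, sampleSheetPath) {
  stopifnot(is(ue, "UlmExperiment"))
  # 17 significant digits so the paired reader round-trips bit-identically
  vals <- apply(assay(ue), 2, function(v) sprintf("%.17g", v))
  dimnames(vals) <- dimnames(assay(ue))
  tab <- data.frame(
    feature = rownames(ue),
    biotype = rowData(ue)$biotype,
    vals,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write.table(tab, path,
    sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n"
  )
  write.table(sampleSheet(ue), sampleSheetPath,
    sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n"
  )
  invisible(c(path, sampleSheetPath))
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: set name, description, then member ids.
#' Member lists are deduplicated preserving first occurrence. Lines with
#' fewer than three fields are a parse error; an empty file yields an
#' empty collection.
#'
#' @param path GMT file path.
#' @return a named list of character vectors with a `descriptions`
#'   attribute (named character).
#' @seealso [writeGmt()]
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      .parseError(
        "GMT line ", i, " has fewer than 3 tab-separated fields"
      )
    }
    nm <- fields[1]
    if (nm %in% names(sets)) {
      .parseError("duplicated gene-set name: ", nm)
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) .parseError("gene set '", nm, "' has no members")
    sets[[nm]] <- members
    desc[nm] <- fields[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors; an optional `descriptions`
#'   attribute supplies the second GMT column (default `"na"`).
#' @param path output path.
#' @return invisibly, the path.
#' @seealso [readGmt()]
#' @export
writeGmt <- function(sets, path) {
  .assert(
    is.list(sets) && !is.null(names(sets)) && all(nzchar(names(sets))),
    "'sets' must be a named list of member vectors"
  )
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, unique(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a truth manifest to JSON
#'
#' @param truth a [TruthManifest-class].
#' @param path output JSON path.
#' @return invisibly, the path.
#' @seealso [readTruthManifest()]
#' @export
writeTruthManifest <- function(truth, path) {
  stopifnot(is(truth, "TruthManifest"))
  obj <- list(
    seed = truth@seed,
    de_calls = truth@deCalls,
    lnc_subtypes = truth@lncSubtypes,
    cis_pairs = truth@cisPairs,
    enriched_sets = truth@enrichedSets,
    module = list(
      mrnas = truth@moduleMrnas,
      lncrnas = truth@moduleLncrnas,
      rho = truth@moduleRho
    )
  )
  jsonlite::write_json(obj, path,
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' Read a truth manifest from JSON
#'
#' @param path JSON path written by [writeTruthManifest()].
#' @return a [TruthManifest-class].
#' @export
readTruthManifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  asDf <- function(x, cols) {
    if (is.null(x) || (is.data.frame(x) && !nrow(x)) || !length(x)) {
      return(stats::setNames(
        data.frame(matrix(nrow = 0, ncol = length(cols))), cols
      ))
    }
    as.data.frame(x, stringsAsFactors = FALSE)[, cols, drop = FALSE]
  }
  new("TruthManifest",
    deCalls = asDf(obj$de_calls, c(
      "feature", "biotype", "direction", "log2fcSmall", "log2fcLarge"
    )),
    lncSubtypes = asDf(obj$lnc_subtypes, c("lnc", "subtype", "partner")),
    cisPairs = asDf(obj$cis_pairs, c("lnc", "mrna", "subtype", "targetR")),
    enrichedSets = as.character(obj$enriched_sets),
    moduleMrnas = as.character(obj$module$mrnas),
    moduleLncrnas = as.character(obj$module$lncrnas),
    moduleRho = as.numeric(obj$module$rho),
    seed = as.integer(obj$seed)
  )
}
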