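#' @include utils.R
NULL

# Transcript annotation is carried internally as a GRanges (1-based closed,
# the Bioconductor convention) with metadata columns tx_id, biotype and an
# `exons` IRangesList in absolute coordinates. Only the serializers know
# dialect conventions: BED12 is written 0-based half-open, GTF 1-based
# closed; both readers normalize back on import.

#' @noRd
.validateAnnotation <- function(gr, where = "annotation") {
  st <- as.character(strand(gr))
  if (any(!st %in% c("+", "-"))) {
    .parseError(where, ": strand must be '+' or '-'")
  }
  if (any(width(gr) < 1)) {
    .parseError(where, ": zero-width record (start == end in half-open coordinates)")
  }
  .assert(
    all(c("tx_id", "biotype", "exons") %in% colnames(mcols(gr))),
    where, ": needs tx_id, biotype and exons metadata"
  )
  if (anyDuplicated(mcols(gr)$tx_id)) {
    .parseError(where, ": duplicated transcript ids")
  }
  if (!all(mcols(gr)$biotype %in% c("mRNA", "lncRNA"))) {
    .parseError(where, ": biotype must be 'mRNA' or 'lncRNA'")
  }
  ex <- mcols(gr)$exons
  for (i in seq_along(gr)) {
    e <- ex[[i]]
    .assert(length(e) >= 1, where, ": transcript without exons")
    if (is.unsorted(start(e)) ||
      min(start(e)) < start(gr)[i] || max(end(e)) > end(gr)[i] ||
      (length(e) > 1 && any(start(e)[-1] <= end(e)[-length(e)]))) {
      .contractError(
        where, ": malformed exon structure for ", mcols(gr)$tx_id[i],
        " (exons must be sorted, non-overlapping, within the transcript)"
      )
    }
  }
  invisible(gr)
}

#' Read transcript annotation (BED12 or GTF)
#'
#' Parses via [rtracklayer::import()] and normalizes into the internal
#' transcript representation: a GRanges with `tx_id`, `biotype` and an
#' absolute-coordinate `exons` IRangesList. BED12 block fields become
#' exons; GTF `exon` rows are grouped under their `transcript_id`. The
#' BED12 dialect expects a 13th column `biotype`; GTF carries a `biotype`
#' attribute. Unknown strand characters and zero-width records are parse
#' errors.
#'
#' @param path annotation file.
#' @param dialect `"BED12"` or `"GTF"`.
#' @return a GRanges annotation.
#' @seealso [writeAnnotation()]
#' @export
readAnnotation <- function(path, dialect = c("BED12", "GTF")) {
  dialect <- match.arg(dialect)
  if (dialect == "BED12") {
    gr <- tryCatch(
      rtracklayer::import(path,
        format = "bed", extraCols = c(biotype = "character")
      ),
      error = function(e) .parseError("BED12 parse failure: ", conditionMessage(e))
    )
    out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)), strand = strand(gr))
    mcols(out)$tx_id <- mcols(gr)$name
    mcols(out)$biotype <- mcols(gr)$biotype
    bl <- rtracklayer::blocks(gr) # absolute coordinates
    mcols(out)$exons <- IRangesList(lapply(bl, function(b) {
      IRanges(start(b), end(b))
    }))
  } else {
    gr <- tryCatch(
      rtracklayer::import(path, format = "gtf"),
      error = function(e) .parseError("GTF parse failure: ", conditionMessage(e))
    )
    .assert(
      all(c("type", "transcript_id") %in% colnames(mcols(gr))),
      "GTF must carry type and transcript_id", class = "lncomat_parse_error"
    )
    tx <- gr[mcols(gr)$type == "transcript"]
    exon <- gr[mcols(gr)$type == "exon"]
    .assert(length(tx) > 0, "GTF contains no transcript rows",
      class = "lncomat_parse_error"
    )
    out <- GRanges(seqnames(tx), IRanges(start(tx), end(tx)), strand = strand(tx))
    mcols(out)$tx_id <- mcols(tx)$transcript_id
    mcols(out)$biotype <- mcols(tx)$biotype
    exByTx <- split(exon, factor(
      mcols(exon)$transcript_id,
      levels = mcols(tx)$transcript_id
    ))
    mcols(out)$exons <- IRangesList(lapply(exByTx, function(e) {
      e <- e[order(start(e))]
      IRanges(start(e), end(e))
    }))
  }
  names(out) <- mcols(out)$tx_id
  .validateAnnotation(out, where = path)
  out
}

#' Write transcript annotation (BED12 or GTF)
#'
#' Writes in canonical order (chromosome, start, transcript id). BED12 is
#' emitted as 13 tab-separated columns (standard 12 plus `biotype`), 0-based
#' half-open with exon blocks; GTF as one `transcript` row plus `exon` rows
#' per transcript with `transcript_id` and `biotype` attributes.
#'
#' @param gr annotation GRanges (as from [simulateAnnotation()] or
#'   [readAnnotation()]).
#' @param path output path.
#' @param dialect `"BED12"` or `"GTF"`.
#' @return invisibly, the path.
#' @export
writeAnnotation <- function(gr, path, dialect = c("BED12", "GTF")) {
  dialect <- match.arg(dialect)
  .validateAnnotation(gr)
  ord <- order(
    as.character(seqnames(gr)), start(gr), mcols(gr)$tx_id,
    method = "radix"
  )
  gr <- gr[ord]
  ex <- mcols(gr)$exons
  if (dialect == "BED12") {
    start0 <- start(gr) - 1L
    lines <- vapply(seq_along(gr), function(i) {
      e <- ex[[i]]
      paste(
        c(
          as.character(seqnames(gr))[i], start0[i], end(gr)[i],
          mcols(gr)$tx_id[i], 0L, as.character(strand(gr))[i],
          start0[i], end(gr)[i], "0", length(e),
          paste0(paste(width(e), collapse = ","), ","),
          paste0(paste(start(e) - 1L - start0[i], collapse = ","), ","),
          mcols(gr)$biotype[i]
        ),
        collapse = "\t"
      )
    }, character(1))
    writeLines(lines, path)
  } else {
    attrs <- function(i) {
      sprintf(
        "transcript_id \"%s\"; biotype \"%s\";",
        mcols(gr)$tx_id[i], mcols(gr)$biotype[i]
      )
    }
    lines <- unlist(lapply(seq_along(gr), function(i) {
      e <- ex[[i]]
      c(
        paste(
          c(
            as.character(seqnames(gr))[i], "lncomat", "transcript",
            start(gr)[i], end(gr)[i], ".", as.character(strand(gr))[i],
            ".", attrs(i)
          ),
          collapse = "\t"
        ),
        vapply(seq_along(e), function(k) {
          paste(
            c(
              as.character(seqnames(gr))[i], "lncomat", "exon",
              start(e)[k], end(e)[k], ".", as.character(strand(gr))[i],
              ".", attrs(i)
            ),
            collapse = "\t"
          )
        }, character(1))
      )
    }))
    writeLines(lines, path)
  }
  invisible(path)
}
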