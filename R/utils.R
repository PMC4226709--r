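# internal helpers shared across modules

#' @noRd
.assert <- function(cond, ..., class = "lncomat_contract_error") {
  if (!isTRUE(cond)) {
    stop(structure(
      class = c(class, "error", "condition"),
      list(message = paste0(...), call = sys.call(-1))
    ))
  }
  invisible(TRUE)
}

.contractError <- function(...) .assert(FALSE, ...)

.parseError <- function(...) .assert(FALSE, ..., class = "lncomat_parse_error")

.schemaError <- function(...) .assert(FALSE, ..., class = "lncomat_schema_error")

# Deterministic substream seed derived from a base seed and a stream name.
# Polynomial string hash mod (2^31 - 1); doubles are exact far beyond the
# magnitudes involved, so this is platform stable. Forking the RNG per named
# substep means adding features to one substep never perturbs draws in
# another.
#' @noRd
.substreamSeed <- function(seed, name) {
  m <- 2147483647
  h <- as.numeric(seed %% m)
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% m
  as.integer(h)
}

#' @noRd
.withSubstream <- function(seed, name, expr) {
  set.seed(.substreamSeed(seed, name))
  expr
}

# Canonical lncRNA subtype vocabulary, in classification priority order
# (overlap categories first, then proximity, then the fallback).
.SUBTYPES <- c(
  "exon_sense_overlapping",
  "intron_sense_overlapping",
  "natural_antisense",
  "intronic_antisense",
  "bidirectional",
  "intergenic"
)

# Subtypes whose defining relationship designates a cis mRNA partner that is
# carried into the cis correlation analysis (intergenic has no partner;
# exon sense-overlapping is excluded from the cis profile by convention).
.CIS_SUBTYPES <- c(
  "intronic_antisense", "natural_antisense",
  "bidirectional", "intron_sense_overlapping"
)

#' @noRd
.isProportion <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

#' @noRd
.isCount <- function(x, positive = TRUE) {
  is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == as.integer(x) && (if (positive) x >= 1 else x >= 0)
}
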