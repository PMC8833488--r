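`%||%` <- function(x, y) if (is.null(x)) y else x

#' Canonical variant key
#'
#' Builds the `chrom:pos:ref:alt` string used throughout filter trails,
#' segregation verdicts and simulation truth tables.
#'
#' @param v An `annotated_variant` object, or a chromosome string when the
#'   remaining components are given separately.
#' @param pos,ref,alt Variant components (ignored when `v` is a variant).
#' @return A single string.
#' @export
variant_key <- function(v, pos = NULL, ref = NULL, alt = NULL) {
  if (inherits(v, "annotated_variant")) {
    return(paste(v$chrom, v$pos, v$ref, v$alt, sep = ":"))
  }
  paste(v, pos, ref, alt, sep = ":")
}

# id of the VCF sample column belonging to a family member
sample_id_for <- function(family_id, member_id) {
  paste(family_id, member_id, sep = "_")
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

is_fraction <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1
}

roman <- function(i) as.character(utils::as.roman(i))
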