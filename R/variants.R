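# Annotated multi-sample VCF ingestion and record/sample-level filters.
#
# Annotation encoding is configuration, not code: the INFO field carrying
# per-transcript annotations and the INFO keys holding population allele
# frequencies and CADD PHRED are named in an annotation_spec so the reader
# runs on any VEP/ANNOVAR-style encoding that can be mapped onto it. The
# per-transcript entry format is pipe-separated:
#   allele|consequence|gene|transcript|exon_index|exon_count|biotype|cds_pos
# with entries comma-separated, "." for absent fields, and consequence one
# of stop_gain, frameshift, splice_acceptor, splice_donor, missense,
# synonymous, other. For splice-site entries exon_index is the index of the
# affected (downstream) exon. cds_pos (optional, trailing field) is the
# 1-based CDS coordinate of the first edited base for small indels.

CONSEQUENCE_CLASSES <- c("stop_gain", "frameshift", "splice_acceptor",
                         "splice_donor", "missense", "synonymous", "other")

#' Annotation field mapping for a VCF
#'
#' Declares which INFO keys carry the per-transcript annotation block, the
#' population allele frequencies and the CADD PHRED score.
#'
#' @param ann_field INFO key of the per-transcript annotation block.
#' @param af_fields Named character vector mapping population-source names
#'   to INFO keys (`Number=A` float fields).
#' @param cadd_field INFO key of the CADD PHRED score (or `NULL`).
#' @return An `annotation_spec` object.
#' @export
annotation_spec <- function(ann_field = "ANN",
                            af_fields = c(gnomad_nfe = "AF_GNOMAD_NFE",
                                          thousand_genomes = "AF_1KG"),
                            cadd_field = "CADD_PHRED") {
  stopifnot(is.character(ann_field), length(ann_field) == 1L)
  if (length(af_fields) && is.null(names(af_fields))) {
    stop("af_fields must be a named character vector", call. = FALSE)
  }
  structure(list(ann_field = ann_field, af_fields = af_fields,
                 cadd_field = cadd_field),
            class = "annotation_spec")
}

#' Construct an annotated variant
#'
#' Low-level constructor used by the VCF reader and by tests/simulations
#' that build records directly.
#'
#' @param chrom,pos,ref,alt Variant coordinates and alleles (single ALT).
#' @param qual Record QUAL score.
#' @param annotations Data frame with columns `gene`, `transcript_id`,
#'   `consequence_class`, `exon_index`, `exon_count`, `protein_coding` and
#'   optionally `cds_pos`.
#' @param population_afs Named numeric vector of allele fractions in
#'   `[0,1]`; omit sources the variant is absent from.
#' @param cadd_phred CADD PHRED score or `NA`.
#' @param genotypes Data frame with columns `sample_id`, `allele_count`
#'   (0/1/2 or `NA` for missing) and `depth`.
#' @param sources Character vector of declared population-AF source names
#'   (defaults to the names of `population_afs`).
#' @return An `annotated_variant` object.
#' @export
annotated_variant <- function(chrom, pos, ref, alt, qual, annotations,
                              population_afs = numeric(), cadd_phred = NA_real_,
                              genotypes = data.frame(sample_id = character(),
                                                     allele_count = integer(),
                                                     depth = integer()),
                              sources = names(population_afs)) {
  if (identical(ref, alt)) stop("ref and alt alleles are identical", call. = FALSE)
  if (length(population_afs) && any(population_afs < 0 | population_afs > 1)) {
    stop("population AFs must lie in [0,1]", call. = FALSE)
  }
  if (!"cds_pos" %in% names(annotations)) {
    annotations$cds_pos <- rep(NA_integer_, nrow(annotations))
  }
  both <- !is.na(annotations$exon_index) & !is.na(annotations$exon_count)
  if (any(both & annotations$exon_index > annotations$exon_count)) {
    stop("exon_index exceeds exon_count", call. = FALSE)
  }
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = ref, alt = alt, qual = as.numeric(qual),
                 annotations = annotations,
                 population_afs = population_afs,
                 cadd_phred = as.numeric(cadd_phred),
                 genotypes = genotypes,
                 sources = unique(c(sources, names(population_afs)))),
            class = "annotated_variant")
}

#' @export
print.annotated_variant <- function(x, ...) {
  cat(sprintf("<annotated_variant> %s qual=%.1f %d annotation(s), %d genotype(s)\n",
              variant_key(x), x$qual, nrow(x$annotations), nrow(x$genotypes)))
  invisible(x)
}

parse_ann_block <- function(block, alt, key) {
  entries <- strsplit(block, ",", fixed = TRUE)[[1]]
  rows <- lapply(entries, function(e) {
    f <- strsplit(e, "|", fixed = TRUE)[[1]]
    if (length(f) < 7L) {
      stop("malformed annotation entry '", e, "' at ", key, call. = FALSE)
    }
    if (!(f[1] == alt || f[1] == ".")) return(NULL)
    cls <- if (f[2] %in% CONSEQUENCE_CLASSES) f[2] else "other"
    toint <- function(x) if (x == ".") NA_integer_ else as.integer(x)
    data.frame(gene = f[3], transcript_id = f[4],
               consequence_class = cls,
               exon_index = toint(f[5]), exon_count = toint(f[6]),
               protein_coding = identical(f[7], "protein_coding"),
               cds_pos = if (length(f) >= 8) toint(f[8]) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(gene = character(), transcript_id = character(),
                      consequence_class = character(), exon_index = integer(),
                      exon_count = integer(), protein_coding = logical(),
                      cds_pos = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Read an annotated multi-sample VCF
#'
#' Reads a VCF 4.x file into a list of [annotated_variant()] records, one
#' per ALT allele (multi-allelic records are decomposed). Genotypes carry
#' the per-sample count of the record's ALT allele plus read depth (DP).
#'
#' @param file Path to a VCF file (plain text or bgzipped).
#' @param spec An [annotation_spec()] naming the annotation/AF/CADD INFO
#'   keys; a record or header missing the declared annotation key is a
#'   configuration error.
#' @return List of `annotated_variant` objects.
#' @export
read_annotated_vcf <- function(file, spec = annotation_spec()) {
  if (!file.exists(file)) stop("VCF file not found: ", file, call. = FALSE)
  vcf <- vcfR::read.vcfR(file, verbose = FALSE)
  meta_keys <- unlist(lapply(vcf@meta, function(l) {
    if (grepl("^##INFO=<ID=", l)) sub("^##INFO=<ID=([^,]+),.*$", "\\1", l) else NULL
  }), use.names = FALSE)
  if (!spec$ann_field %in% meta_keys) {
    stop("configuration error: INFO field '", spec$ann_field,
         "' is not declared in the VCF header", call. = FALSE)
  }

  fix <- vcf@fix
  n <- nrow(fix)
  if (is.null(n) || n == 0L) return(list())
  gt_raw <- vcf@gt
  samples <- if (!is.null(gt_raw) && ncol(gt_raw) > 1L) colnames(gt_raw)[-1] else character()

  info_get <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))[[1]]
    if (length(m) == 2L) m[2] else NA_character_
  }

  out <- list()
  for (i in seq_len(n)) {
    chrom <- fix[i, "CHROM"]; pos <- as.integer(fix[i, "POS"])
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    qual <- suppressWarnings(as.numeric(fix[i, "QUAL"]))
    info <- fix[i, "INFO"]
    ann_block <- info_get(info, spec$ann_field)
    if (is.na(ann_block)) {
      stop("configuration error: record ", chrom, ":", pos,
           " carries no '", spec$ann_field, "' INFO field", call. = FALSE)
    }

    fmt <- if (!is.null(gt_raw)) strsplit(gt_raw[i, 1], ":", fixed = TRUE)[[1]] else character()
    gt_idx <- match("GT", fmt); dp_idx <- match("DP", fmt)
    calls <- lapply(samples, function(s) {
      bits <- strsplit(gt_raw[i, s], ":", fixed = TRUE)[[1]]
      gt <- if (!is.na(gt_idx) && length(bits) >= gt_idx) bits[gt_idx] else "./."
      dp <- if (!is.na(dp_idx) && length(bits) >= dp_idx) {
        suppressWarnings(as.integer(bits[dp_idx]))
      } else NA_integer_
      alleles <- strsplit(gt, "[/|]")[[1]]
      list(alleles = alleles, depth = dp)
    })
    names(calls) <- samples

    per_alt <- function(j) {
      alt <- alts[j]
      afs <- vapply(spec$af_fields, function(key) {
        raw <- info_get(info, key)
        if (is.na(raw)) return(NA_real_)
        vals <- suppressWarnings(as.numeric(strsplit(raw, ",", fixed = TRUE)[[1]]))
        if (length(vals) >= j) vals[j] else NA_real_
      }, numeric(1))
      afs <- afs[!is.na(afs)]
      cadd <- NA_real_
      if (!is.null(spec$cadd_field)) {
        raw <- info_get(info, spec$cadd_field)
        if (!is.na(raw)) {
          vals <- suppressWarnings(as.numeric(strsplit(raw, ",", fixed = TRUE)[[1]]))
          cadd <- if (length(vals) >= j) vals[j] else vals[1]
        }
      }
      gts <- data.frame(
        sample_id = samples,
        allele_count = vapply(calls, function(cl) {
          if (any(cl$alleles == ".")) NA_integer_ else sum(cl$alleles == as.character(j))
        }, integer(1)),
        depth = vapply(calls, function(cl) cl$depth %||% NA_integer_, integer(1)),
        stringsAsFactors = FALSE, row.names = NULL
      )
      annotated_variant(chrom, pos, ref, alt, qual,
                        parse_ann_block(ann_block, alt, paste0(chrom, ":", pos)),
                        population_afs = afs, cadd_phred = cadd,
                        genotypes = gts, sources = names(spec$af_fields))
    }
    out <- c(out, lapply(seq_along(alts), per_alt))
  }
  out
}

#' QC thresholds for variant filtering
#'
#' Boundary semantics follow the screening design: QUAL strictly greater
#' than `min_qual`, per-genotype depth at least `min_depth`, population
#' allele frequency strictly below `max_pop_af` and local cohort carrier
#' frequency strictly below `max_local_af`.
#'
#' @param min_qual Minimum QUAL (exclusive). Default 20.
#' @param min_depth Minimum read depth per genotype (inclusive). Default 5.
#' @param max_pop_af Population AF ceiling (exclusive). Default 0.001.
#' @param max_local_af Local cohort carrier-frequency ceiling (exclusive),
#'   guarding against recurrent technical artefacts. Default 0.05.
#' @return A `qc_thresholds` object.
#' @export
qc_thresholds <- function(min_qual = 20, min_depth = 5,
                          max_pop_af = 0.001, max_local_af = 0.05) {
  stopifnot(min_qual >= 0, is_count(min_depth),
            is_fraction(max_pop_af), is_fraction(max_local_af))
  structure(list(min_qual = min_qual, min_depth = min_depth,
                 max_pop_af = max_pop_af, max_local_af = max_local_af),
            class = "qc_thresholds")
}

#' Record/genotype-level quality filter
#'
#' Rejects records whose QUAL does not exceed the threshold, masks
#' genotypes below the depth floor as missing, and rejects records with no
#' surviving genotype. Idempotent.
#'
#' @param v An [annotated_variant()].
#' @param t A [qc_thresholds()].
#' @return The (possibly masked) variant, or `NULL` when rejected.
#' @export
qc_filter <- function(v, t = qc_thresholds()) {
  stopifnot(inherits(v, "annotated_variant"))
  if (is.na(v$qual) || v$qual <= t$min_qual) return(NULL)
  g <- v$genotypes
  if (nrow(g)) {
    low <- !is.na(g$depth) & g$depth < t$min_depth
    g$allele_count[low] <- NA_integer_
    v$genotypes <- g
    if (all(is.na(g$allele_count))) return(NULL)
  }
  v
}

#' Maximum population allele frequency over sources
#'
#' Absence from every requested source is treated as frequency 0 (a novel
#' variant); asking for a source that was never declared for the variant is
#' a configuration error.
#'
#' @param v An [annotated_variant()].
#' @param sources Source names to consider; defaults to all declared.
#' @return Allele fraction in `[0,1]`.
#' @export
max_population_af <- function(v, sources = v$sources) {
  unknown <- setdiff(sources, v$sources)
  if (length(unknown)) {
    stop("configuration error: unknown population AF source(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  present <- intersect(sources, names(v$population_afs))
  if (!length(present)) return(0)
  max(v$population_afs[present])
}

#' Local cohort carrier frequency of a variant
#'
#' Fraction of genotyped samples, cohort-wide, that carry at least one ALT
#' allele of the keyed variant. Used to remove recurrent technical
#' artefacts (dominant-model carrier counting: a homozygous carrier counts
#' once).
#'
#' @param variants List of [annotated_variant()] objects for the whole
#'   cohort.
#' @param key Variant key as produced by [variant_key()].
#' @return Carrier fraction in `[0,1]`.
#' @export
local_cohort_af <- function(variants, key) {
  keys <- vapply(variants, variant_key, character(1))
  hit <- which(keys == key)
  if (!length(hit)) stop("variant ", key, " not found in cohort", call. = FALSE)
  g <- variants[[hit[1]]]$genotypes
  genotyped <- !is.na(g$allele_count)
  if (!any(genotyped)) {
    stop("variant ", key, " has zero genotyped samples", call. = FALSE)
  }
  sum(g$allele_count[genotyped] >= 1L) / sum(genotyped)
}
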