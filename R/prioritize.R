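# Dominant-model prioritization cascade: QC -> local cohort frequency ->
# population frequency -> LOF class -> gene-position exclusions ->
# per-family segregation -> CADD tiering, with a full filter trail.

LOF_CLASSES <- c("stop_gain", "frameshift", "canonical_splice")
CADD_TIERS <- c("top0.1pct", "top1pct", "below20", "unknown")

#' Classify a transcript annotation as loss-of-function
#'
#' Stop gains and frameshifts map to themselves; canonical (intronic
#' plus/minus 1-2) splice acceptor/donor consequences map to
#' `canonical_splice`; everything else is not loss-of-function.
#'
#' @param a One row of an annotation data frame (or a list with a
#'   `consequence_class` element).
#' @return `"stop_gain"`, `"frameshift"`, `"canonical_splice"` or
#'   `NA_character_`.
#' @export
classify_lof <- function(a) {
  switch(a$consequence_class,
         stop_gain = "stop_gain",
         frameshift = "frameshift",
         splice_acceptor = ,
         splice_donor = "canonical_splice",
         NA_character_)
}

#' Last-exon / non-coding exclusion filter
#'
#' Truncating variants in a transcript's final exon typically escape
#' nonsense-mediated decay, and non-protein-coding transcripts cannot be
#' truncated at all; both are excluded. Splice-site annotations are
#' expected to carry the affected (downstream) exon's index, so a
#' canonical acceptor of an internal exon is retained. An exonic
#' consequence with no locatable exon is excluded conservatively.
#'
#' @param a One row of an annotation data frame.
#' @return A list with elements `retained` (logical) and `reason`
#'   (`NA`, `"last_exon"`, `"non_coding"` or `"unlocatable"`).
#' @export
gene_position_filter <- function(a) {
  if (!isTRUE(a$protein_coding)) {
    return(list(retained = FALSE, reason = "non_coding"))
  }
  if (is.na(a$exon_index) || is.na(a$exon_count)) {
    return(list(retained = FALSE, reason = "unlocatable"))
  }
  if (a$exon_index == a$exon_count) {
    return(list(retained = FALSE, reason = "last_exon"))
  }
  list(retained = TRUE, reason = NA_character_)
}

#' CADD PHRED deleteriousness tier
#'
#' Scores above 20 mark the top 1 percent and above 30 the top 0.1 percent
#' of deleterious substitutions (strict inequalities).
#'
#' @param cadd_phred Numeric score or `NA`.
#' @return `"top0.1pct"`, `"top1pct"`, `"below20"` or `"unknown"`.
#' @export
cadd_tier <- function(cadd_phred) {
  if (is.null(cadd_phred) || is.na(cadd_phred)) return("unknown")
  if (cadd_phred > 30) return("top0.1pct")
  if (cadd_phred > 20) return("top1pct")
  "below20"
}

#' Per-family dominant-model segregation filter
#'
#' A variant segregates in a family when every genotyped blood-member case
#' carries at least one ALT allele, no genotyped control carries any, and
#' at least one case carrier exists. Possible carriers and uninformative
#' members are unconstrained, missing genotypes are unconstrained, and
#' affected married-in members (phenocopies, non-blood) are exempt from the
#' carrier requirement and reported separately.
#'
#' @param v An [annotated_variant()] whose genotype sample IDs follow the
#'   `<family_id>_<member_id>` convention (or supply `sample_ids`).
#' @param family A family object.
#' @param roles Role map from [assign_roles()] (computed when `NULL`).
#' @param sample_ids Optional named character vector mapping `member_id` to
#'   VCF sample ID.
#' @return A `segregation_verdict` list with fields `family_id`, `passes`,
#'   `case_carriers`, `case_noncarriers`, `control_carriers`,
#'   `exempt_phenocopies` and `reason`.
#' @export
segregation_filter <- function(v, family, roles = NULL, sample_ids = NULL) {
  if (is.null(roles)) roles <- assign_roles(family)
  m <- family$members
  if (is.null(sample_ids)) {
    sample_ids <- stats::setNames(
      sample_id_for(family$family_id, m$member_id), m$member_id)
  }
  gt <- stats::setNames(v$genotypes$allele_count, v$genotypes$sample_id)
  blood <- family$blood_member_ids

  case_carriers <- 0L; case_noncarriers <- 0L; control_carriers <- 0L
  exempt <- character(); saw_genotyped_case <- FALSE

  for (id in m$member_id) {
    if (!m$genotyped[m$member_id == id]) next
    ac <- gt[sample_ids[[id]]]
    if (length(ac) == 0L || is.na(ac)) next
    role <- roles[[id]]
    carrier <- ac >= 1L
    if (role == "case") {
      if (!(id %in% blood)) {
        exempt <- c(exempt, id)
        next
      }
      saw_genotyped_case <- TRUE
      if (carrier) case_carriers <- case_carriers + 1L
      else case_noncarriers <- case_noncarriers + 1L
    } else if (role == "control" && carrier) {
      control_carriers <- control_carriers + 1L
    }
  }

  if (!saw_genotyped_case) {
    return(structure(list(family_id = family$family_id, passes = FALSE,
                          case_carriers = 0L, case_noncarriers = 0L,
                          control_carriers = control_carriers,
                          exempt_phenocopies = exempt,
                          reason = "no_genotyped_case"),
                     class = "segregation_verdict"))
  }
  passes <- case_noncarriers == 0L && control_carriers == 0L && case_carriers >= 1L
  structure(list(family_id = family$family_id, passes = passes,
                 case_carriers = case_carriers,
                 case_noncarriers = case_noncarriers,
                 control_carriers = control_carriers,
                 exempt_phenocopies = exempt,
                 reason = if (passes) NA_character_ else "non_segregating"),
            class = "segregation_verdict")
}

#' @export
print.segregation_verdict <- function(x, ...) {
  cat(sprintf("<segregation_verdict> %s: %s (case +%d/-%d, control carriers %d%s)\n",
              x$family_id, if (x$passes) "PASS" else paste0("FAIL [", x$reason, "]"),
              x$case_carriers, x$case_noncarriers, x$control_carriers,
              if (length(x$exempt_phenocopies))
                paste0(", exempt: ", paste(x$exempt_phenocopies, collapse = ","))
              else ""))
  invisible(x)
}

# best LOF annotation under most-damaging-transcript logic, or the reason
# no annotation qualifies
best_lof_annotation <- function(ann) {
  if (nrow(ann) == 0L) return(list(ok = FALSE, reason = "lof_class"))
  lof <- vapply(seq_len(nrow(ann)), function(k) {
    classify_lof(ann[k, ]) %||% NA_character_
  }, character(1))
  if (all(is.na(lof))) return(list(ok = FALSE, reason = "lof_class"))
  reasons <- character()
  for (k in which(!is.na(lof))) {
    pf <- gene_position_filter(ann[k, ])
    if (pf$retained) {
      return(list(ok = TRUE, ann = ann[k, ], lof_class = lof[k]))
    }
    reasons <- c(reasons, pf$reason)
  }
  list(ok = FALSE, reason = paste0("gene_position:", reasons[1]))
}

#' Run the full prioritization cascade
#'
#' Applies, per variant: QUAL/depth QC, the local cohort carrier-frequency
#' artefact filter, the population rarity filter, loss-of-function
#' classification, last-exon/non-coding exclusion, per-family segregation
#' filtering, and CADD tiering. A variant becomes a candidate when it
#' passes all variant-level filters and segregates in at least one family.
#' Candidates are ranked by CADD tier, number of passing families, then
#' genomic coordinate.
#'
#' @param variants List of [annotated_variant()] objects, or a path to an
#'   annotated VCF.
#' @param families List of family objects (e.g. from [parse_pedigree()]).
#' @param thresholds A [qc_thresholds()].
#' @param spec An [annotation_spec()], used when `variants` is a path.
#' @param gene_models Optional gene-model data frame (columns `transcript`,
#'   `n_exons`) used to fill in missing `exon_count` annotation fields.
#' @param pop_sources Population AF sources to screen against; defaults to
#'   all sources declared on each variant.
#' @param verbose_trail Record trail rows for rejected variants too.
#' @return A list with `candidates` (ranked data frame), `verdicts` (per
#'   candidate list of `segregation_verdict`s) and `trail` (data frame with
#'   columns `variant`, `filter`, `verdict`, `value`).
#' @export
run_prioritization <- function(variants, families,
                               thresholds = qc_thresholds(),
                               spec = annotation_spec(),
                               gene_models = NULL,
                               pop_sources = NULL,
                               verbose_trail = TRUE) {
  if (is.character(variants)) variants <- read_annotated_vcf(variants, spec)
  if (inherits(families, "lofseg_family")) families <- list(families)

  # sample-ID consistency between PED and VCF
  expected <- unlist(lapply(families, function(f) {
    sample_id_for(f$family_id, f$members$member_id[f$members$genotyped])
  }), use.names = FALSE)
  vcf_samples <- unique(unlist(lapply(variants, function(v) v$genotypes$sample_id)))
  missing_in_vcf <- setdiff(expected, vcf_samples)
  unknown_in_vcf <- setdiff(vcf_samples, unlist(lapply(families, function(f) {
    sample_id_for(f$family_id, f$members$member_id)
  }), use.names = FALSE))
  if (length(missing_in_vcf) || length(unknown_in_vcf)) {
    stop("sample-ID mismatch between PED and VCF; genotyped members absent ",
         "from VCF: [", paste(missing_in_vcf, collapse = ", "),
         "]; VCF samples not in PED: [",
         paste(unknown_in_vcf, collapse = ", "), "]", call. = FALSE)
  }

  roles_by_family <- lapply(families, assign_roles)
  trail <- list()
  note <- function(key, filter, verdict, value = NA) {
    trail[[length(trail) + 1L]] <<- data.frame(
      variant = key, filter = filter, verdict = verdict,
      value = as.character(value), stringsAsFactors = FALSE)
  }

  fill_exon_count <- function(ann) {
    if (is.null(gene_models) || nrow(ann) == 0L) return(ann)
    idx <- match(ann$transcript_id, gene_models$transcript)
    fix <- is.na(ann$exon_count) & !is.na(idx)
    ann$exon_count[fix] <- gene_models$n_exons[idx[fix]]
    ann
  }

  candidates <- list(); verdict_sets <- list()
  for (v in variants) {
    key <- variant_key(v)

    vq <- qc_filter(v, thresholds)
    if (is.null(vq)) {
      if (verbose_trail) note(key, "qc", "reject", v$qual)
      next
    }
    note(key, "qc", "pass", vq$qual)
    v <- vq

    laf <- local_cohort_af(variants, key)
    if (laf >= thresholds$max_local_af) {
      if (verbose_trail) note(key, "local_af", "reject", laf)
      next
    }
    note(key, "local_af", "pass", laf)

    paf <- max_population_af(v, pop_sources %||% v$sources)
    if (paf >= thresholds$max_pop_af) {
      if (verbose_trail) note(key, "population_af", "reject", paf)
      next
    }
    note(key, "population_af", "pass", paf)

    v$annotations <- fill_exon_count(v$annotations)
    sel <- best_lof_annotation(v$annotations)
    if (!sel$ok) {
      if (verbose_trail) note(key, "lof_and_position", "reject", sel$reason)
      next
    }
    note(key, "lof_and_position", "pass", sel$lof_class)

    verdicts <- lapply(seq_along(families), function(i) {
      segregation_filter(v, families[[i]], roles_by_family[[i]])
    })
    passing <- vapply(verdicts, function(x) x$passes, logical(1))
    note(key, "segregation", if (any(passing)) "pass" else "reject",
         sum(passing))
    if (!any(passing)) next

    tier <- cadd_tier(v$cadd_phred)
    note(key, "cadd_tier", "annotate", tier)

    fam_ids <- vapply(families[passing], function(f) f$family_id, character(1))
    candidates[[length(candidates) + 1L]] <- data.frame(
      variant = key, chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
      gene = sel$ann$gene, transcript = sel$ann$transcript_id,
      lof_class = sel$lof_class, cadd_phred = v$cadd_phred, cadd_tier = tier,
      n_families = sum(passing),
      families = paste(fam_ids, collapse = ","),
      stringsAsFactors = FALSE)
    verdict_sets[[key]] <- verdicts
  }

  cand <- if (length(candidates)) do.call(rbind, candidates) else
    data.frame(variant = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), gene = character(),
               transcript = character(), lof_class = character(),
               cadd_phred = numeric(), cadd_tier = character(),
               n_families = integer(), families = character(),
               stringsAsFactors = FALSE)
  if (nrow(cand)) {
    ord <- order(match(cand$cadd_tier, CADD_TIERS), -cand$n_families,
                 cand$chrom, cand$pos)
    cand <- cand[ord, , drop = FALSE]
    rownames(cand) <- NULL
  }
  trail_df <- if (length(trail)) do.call(rbind, trail) else
    data.frame(variant = character(), filter = character(),
               verdict = character(), value = character(),
               stringsAsFactors = FALSE)
  list(candidates = cand, verdicts = verdict_sets, trail = trail_df)
}
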