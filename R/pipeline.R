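# End-to-end orchestration: simulate (or read) -> prioritize ->
# protein consequence for frameshift candidates -> cohort-wide carrier
# association, with TSV outputs and a reproducible run manifest.

read_gene_models <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

read_cds_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' Run the full analysis pipeline
#'
#' Stages: (1) optionally simulate a cohort and write its fixture bundle;
#' (2) parse the pedigree and the annotated VCF; (3) run the
#' prioritization cascade and write the ranked candidates and the filter
#' trail; (4) call protein consequences for frameshift candidates whose
#' annotation carries a CDS coordinate and whose transcript has a CDS in
#' the supplied FASTA; (5) for each candidate, compute the cohort-wide
#' carrier case-control association (cases vs controls across all
#' families, Haldane-corrected since zero control carriers are expected
#' for segregating variants). A `run_manifest.json` captures the seed,
#' configuration hash and output checksums; two runs with the same inputs
#' and seed produce byte-identical outputs.
#'
#' @param out_dir Output directory.
#' @param sim A [sim_config()] to simulate inputs, or `NULL` to read them
#'   from `ped`, `vcf`, `cds`, `gene_models`.
#' @param ped,vcf,cds,gene_models Input paths (ignored when `sim` is
#'   given; `cds`/`gene_models` optional).
#' @param thresholds A [qc_thresholds()].
#' @param spec An [annotation_spec()].
#' @param level Confidence level of the association stage.
#' @param quiet Suppress progress messages.
#' @return A list with `candidates`, `consequences`, `association`,
#'   `trail` data frames and `paths` of all written artifacts.
#' @export
run_pipeline <- function(out_dir, sim = NULL, ped = NULL, vcf = NULL,
                         cds = NULL, gene_models = NULL,
                         thresholds = qc_thresholds(),
                         spec = annotation_spec(), level = 0.95,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message("[lofseg] ", ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(sim)) {
    stopifnot(inherits(sim, "sim_config"))
    say("simulating cohort (", sim$n_families, " families, seed ", sim$seed, ")")
    cohort <- simulate_cohort(sim)
    input_dir <- file.path(out_dir, "input")
    write_fixture_bundle(cohort, input_dir)
    ped <- file.path(input_dir, "pedigree.ped")
    vcf <- file.path(input_dir, "cohort.vcf")
    cds <- file.path(input_dir, "cds.fasta")
    gene_models <- file.path(input_dir, "gene_models.tsv")
  }
  for (p in c(ped, vcf)) {
    if (is.null(p) || !file.exists(p)) {
      stop("input not found before execution: ",
           if (is.null(p)) "ped/vcf path missing" else p, call. = FALSE)
    }
  }

  say("parsing pedigree ", ped)
  families <- parse_pedigree(ped)
  say(length(families), " families")
  say("reading VCF ", vcf)
  variants <- read_annotated_vcf(vcf, spec)
  say(length(variants), " ALT records")

  gm <- if (!is.null(gene_models) && file.exists(gene_models)) {
    read_gene_models(gene_models)
  } else NULL
  res <- run_prioritization(variants, families, thresholds, spec,
                            gene_models = gm)
  rejected <- res$trail[res$trail$verdict == "reject", , drop = FALSE]
  for (f in unique(rejected$filter)) {
    say("filter ", f, ": ", sum(rejected$filter == f), " rejected")
  }
  say(nrow(res$candidates), " candidate variant(s)")

  cds_seqs <- if (!is.null(cds) && file.exists(cds)) read_cds_fasta(cds) else NULL
  consequences <- data.frame(variant = character(), transcript = character(),
                             hgvs_p = character(), category = character(),
                             first_changed_codon = integer(),
                             stop_offset = integer(), stringsAsFactors = FALSE)
  if (!is.null(cds_seqs) && nrow(res$candidates)) {
    key_by_variant <- stats::setNames(variants, vapply(variants, variant_key,
                                                       character(1)))
    for (i in seq_len(nrow(res$candidates))) {
      row <- res$candidates[i, ]
      if (row$lof_class != "frameshift") next
      v <- key_by_variant[[row$variant]]
      ann <- v$annotations[v$annotations$transcript_id == row$transcript, ]
      cp <- ann$cds_pos[1]
      if (is.na(cp) || !row$transcript %in% names(cds_seqs)) next
      del_len <- nchar(v$ref) - nchar(v$alt)
      if (del_len < 1L) next
      pc <- protein_consequence(cds_seqs[[row$transcript]],
                                transcript_edit("del", cp, cp + del_len - 1L))
      consequences <- rbind(consequences, data.frame(
        variant = row$variant, transcript = row$transcript,
        hgvs_p = pc$hgvs_p, category = pc$category,
        first_changed_codon = pc$first_changed_codon,
        stop_offset = pc$stop_offset, stringsAsFactors = FALSE))
    }
    say(nrow(consequences), " protein consequence(s) called")
  }

  roles_all <- lapply(families, assign_roles)
  association <- data.frame()
  if (nrow(res$candidates)) {
    association <- do.call(rbind, lapply(seq_len(nrow(res$candidates)), function(i) {
      v <- variants[[which(vapply(variants, variant_key, character(1)) ==
                           res$candidates$variant[i])[1]]]
      gt <- stats::setNames(v$genotypes$allele_count, v$genotypes$sample_id)
      case_gt <- numeric(); control_gt <- numeric()
      for (f in families) {
        roles <- roles_all[[f$family_id]]
        for (id in f$members$member_id[f$members$genotyped]) {
          sid <- sample_id_for(f$family_id, id)
          if (!sid %in% names(gt)) next
          if (roles[[id]] == "case") case_gt[sid] <- gt[[sid]]
          else if (roles[[id]] == "control") control_gt[sid] <- gt[[sid]]
        }
      }
      tab <- carrier_table(case_gt, control_gt)
      cbind(variant = res$candidates$variant[i],
            carrier_association(tab, level, correct = TRUE),
            stringsAsFactors = FALSE)
    }))
  }

  paths <- list(candidates = file.path(out_dir, "candidates.tsv"),
                trail = file.path(out_dir, "trail.tsv"),
                consequences = file.path(out_dir, "consequences.tsv"),
                association = file.path(out_dir, "association.tsv"),
                manifest = file.path(out_dir, "run_manifest.json"))
  utils::write.table(res$candidates, paths$candidates, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$trail, paths$trail, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(consequences, paths$consequences, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(association, paths$association, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cfg_json <- jsonlite::toJSON(list(
    sim = if (!is.null(sim)) unclass(sim) else NULL,
    thresholds = unclass(thresholds), level = level), auto_unbox = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("lofseg")),
    seed = if (!is.null(sim)) sim$seed else NA,
    config_md5 = unname(tools::md5sum(textConnectionPath(cfg_json, out_dir))),
    inputs = list(ped = ped, vcf = vcf),
    outputs = lapply(paths[c("candidates", "trail", "consequences",
                             "association")],
                     function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(candidates = res$candidates, consequences = consequences,
                 association = association, trail = res$trail,
                 verdicts = res$verdicts, paths = paths))
}

# md5sum needs a file; the serialized run config is kept as an artifact
textConnectionPath <- function(txt, dir) {
  p <- file.path(dir, "run_config.json")
  writeLines(txt, p)
  p
}
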