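# Mendelian cohort simulator: multi-generation autosomal-dominant families
# with a planted heterozygous loss-of-function variant per family,
# phenocopies in married-in spouses, background variation with
# population-style allele frequencies, and incomplete genotyping. Emits
# extended PED + multi-sample VCF + gene-model table + CDS FASTA with a
# known truth table so the whole prioritization stack is testable offline.

#' Simulation configuration
#'
#' Defaults emulate the ascertainment of a high-penetrance familial CRC
#' study: 15 three-generation autosomal-dominant families with at least
#' three confirmed CRC cases each, a planted novel heterozygous LOF variant
#' per family, colonoscopy-detected polyps enriched in carriers, occasional
#' sporadic cases and affected married-in spouses (phenocopies), and
#' incomplete genotyping of the pedigree.
#'
#' @param n_families Number of families.
#' @param generations Pedigree depth (3 or 4).
#' @param mean_sibship Mean number of children per couple (sibship is
#'   `1 + Poisson(mean_sibship - 1)`).
#' @param penetrance_by_70 Probability that a carrier develops CRC by age
#'   70 (onset drawn uniformly on 40-70 and realized only once reached).
#' @param polyp_prob_carrier,polyp_prob_noncarrier Probability of a colonic
#'   polyp diagnosis (onset uniform 35-65) for carriers/non-carriers
#'   without CRC.
#' @param sporadic_crc_rate Probability of CRC by age 75 in blood
#'   non-carriers (onset uniform 45-75).
#' @param phenocopy_rate_married_in Probability of CRC by age 75 in
#'   married-in spouses.
#' @param other_cancer_rate Probability of a non-colorectal cancer in
#'   members aged 55+ (half of whom also have a negative colonoscopy on
#'   record).
#' @param n_local_panel Number of unrelated local reference individuals
#'   added to the cohort (no cancer family history, never carriers of a
#'   planted variant). These emulate the unrelated samples of a
#'   sequencing center's local datasets, which form the denominator of
#'   the 5 percent local artefact filter; without them a single large
#'   pedigree could push its own private variant above the threshold.
#' @param n_background_variants Number of background variants cohort-wide.
#' @param background_af_shape1,background_af_shape2 Beta parameters of the
#'   background allele-frequency distribution (heavy-tailed toward rare).
#' @param genotyping_missing_rate Probability that a member has no DNA
#'   sample (no VCF column); the two earliest-onset cases per family are
#'   always genotyped, mirroring sequencing of affected members.
#' @param genotype_error_rate Per-call probability of flipping
#'   carrier/non-carrier status at the planted variant.
#' @param call_missing_rate Per-call probability of a missing genotype
#'   (`./.`) at the planted variant.
#' @param min_cases Minimum number of CRC cases among blood members
#'   (enforced by rejection sampling).
#' @param max_members Upper bound on family size (rejection sampling;
#'   keeps pedigrees at the scale of drawn clinical pedigrees and stops
#'   the case constraint from selecting only enormous sibships).
#' @param marry_prob Probability that a non-terminal-generation member
#'   acquires a spouse and children.
#' @param seed Integer seed fixing the entire output byte-for-byte.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_families = 15L, generations = 3L,
                       mean_sibship = 3.5, penetrance_by_70 = 0.8,
                       polyp_prob_carrier = 0.5, polyp_prob_noncarrier = 0.15,
                       sporadic_crc_rate = 0.02,
                       phenocopy_rate_married_in = 0.08,
                       other_cancer_rate = 0.05,
                       n_local_panel = 200L,
                       n_background_variants = 300L,
                       background_af_shape1 = 0.2,
                       background_af_shape2 = 50,
                       genotyping_missing_rate = 0.2,
                       genotype_error_rate = 0,
                       call_missing_rate = 0.02,
                       min_cases = 3L, max_members = 30L,
                       marry_prob = 0.85, seed = 1L) {
  stopifnot(is_count(n_families), n_families >= 1,
            is_count(generations), generations >= 2, generations <= 5,
            mean_sibship >= 1,
            is_fraction(penetrance_by_70), is_fraction(polyp_prob_carrier),
            is_fraction(polyp_prob_noncarrier), is_fraction(sporadic_crc_rate),
            is_fraction(phenocopy_rate_married_in),
            is_fraction(other_cancer_rate),
            is_count(n_local_panel), is_count(n_background_variants),
            background_af_shape1 > 0, background_af_shape2 > 0,
            is_fraction(genotyping_missing_rate),
            is_fraction(genotype_error_rate), is_fraction(call_missing_rate),
            is_count(min_cases), is_count(max_members),
            max_members >= 6, is_fraction(marry_prob),
            is_count(abs(seed)))
  structure(list(n_families = as.integer(n_families),
                 generations = as.integer(generations),
                 mean_sibship = mean_sibship,
                 penetrance_by_70 = penetrance_by_70,
                 polyp_prob_carrier = polyp_prob_carrier,
                 polyp_prob_noncarrier = polyp_prob_noncarrier,
                 sporadic_crc_rate = sporadic_crc_rate,
                 phenocopy_rate_married_in = phenocopy_rate_married_in,
                 other_cancer_rate = other_cancer_rate,
                 n_local_panel = as.integer(n_local_panel),
                 n_background_variants = as.integer(n_background_variants),
                 background_af_shape1 = background_af_shape1,
                 background_af_shape2 = background_af_shape2,
                 genotyping_missing_rate = genotyping_missing_rate,
                 genotype_error_rate = genotype_error_rate,
                 call_missing_rate = call_missing_rate,
                 min_cases = as.integer(min_cases),
                 max_members = as.integer(max_members),
                 marry_prob = marry_prob, seed = as.integer(seed)),
            class = "sim_config")
}

#' A noiseless variant of a simulation configuration
#'
#' Zeroes the noise channels that can legitimately break segregation of the
#' planted variant - sporadic cases among blood non-carriers, silent
#' (unexpressed) adult carriers, genotype errors and per-call missingness -
#' while keeping the pedigree structure, the penetrance model and
#' married-in phenocopies (which the segregation filter exempts by
#' design). Under a noiseless configuration every planted variant
#' segregates in its family by construction.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_config` with the noise rates set to zero and full
#'   carrier expressivity (`polyp_prob_carrier = 1`).
#' @export
noiseless <- function(cfg = sim_config()) {
  cfg$sporadic_crc_rate <- 0
  cfg$genotype_error_rate <- 0
  cfg$call_missing_rate <- 0
  cfg$polyp_prob_carrier <- 1
  cfg
}

# one Bernoulli(1/2) meiotic transmission of a heterozygous allele
transmit_allele <- function(parent_carrier) {
  parent_carrier & stats::runif(length(parent_carrier)) < 0.5
}

GEN_BASE_AGE <- c(90, 63, 38, 18, 8)

draw_age <- function(gen) {
  max(16L, as.integer(round(stats::rnorm(1, GEN_BASE_AGE[gen], 4))))
}

draw_events <- function(carrier, married_in, age, cfg) {
  ev <- list()
  crc <- FALSE
  if (carrier) {
    if (stats::runif(1) < cfg$penetrance_by_70) {
      onset <- as.integer(round(stats::runif(1, 40, 70)))
      if (onset <= age) { ev <- c(ev, list(c("crc", "colon", onset))); crc <- TRUE }
    }
  } else {
    rate <- if (married_in) cfg$phenocopy_rate_married_in else cfg$sporadic_crc_rate
    if (stats::runif(1) < rate) {
      onset <- as.integer(round(stats::runif(1, 45, 75)))
      if (onset <= age) { ev <- c(ev, list(c("crc", "colon", onset))); crc <- TRUE }
    }
  }
  if (!crc) {
    if (carrier) {
      # colonoscopy surveillance in CRC families: adenomas in adult
      # carriers are detected by the current age when present at all
      if (age >= 40 && stats::runif(1) < cfg$polyp_prob_carrier) {
        onset <- as.integer(round(stats::runif(1, 40, age)))
        ev <- c(ev, list(c("polyps", "colon", onset)))
      }
    } else if (stats::runif(1) < cfg$polyp_prob_noncarrier) {
      onset <- as.integer(round(stats::runif(1, 35, 65)))
      if (onset <= age) ev <- c(ev, list(c("polyps", "colon", onset)))
    }
  }
  if (!crc && age >= 55 && stats::runif(1) < cfg$other_cancer_rate) {
    site <- sample(c("breast", "prostate", "ovarian", "abdominal cavity"), 1)
    onset <- as.integer(round(stats::runif(1, 50, age)))
    ev <- c(ev, list(c("other_cancer", site, onset)))
    if (stats::runif(1) < 0.5) ev <- c(ev, list(c("unaffected", "colonoscopy_negative", NA)))
  }
  if (!length(ev)) {
    return(data.frame(kind = character(), detail = character(),
                      age = integer(), stringsAsFactors = FALSE))
  }
  data.frame(kind = vapply(ev, `[`, character(1), 1),
             detail = vapply(ev, `[`, character(1), 2),
             age = suppressWarnings(as.integer(vapply(ev, `[`, character(1), 3))),
             stringsAsFactors = FALSE)
}

build_pedigree_once <- function(cfg, family_id) {
  # columns accumulated per member
  rows <- list()
  counter <- integer(cfg$generations)
  add <- function(gen, father, mother, sex, carrier, married_in) {
    counter[gen] <<- counter[gen] + 1L
    id <- paste0(roman(gen), "-", counter[gen])
    rows[[length(rows) + 1L]] <<- list(
      member_id = id, father_id = father, mother_id = mother, sex = sex,
      generation = gen, carrier = carrier, married_in = married_in)
    id
  }

  carrier_founder_is_male <- stats::runif(1) < 0.5
  f1 <- add(1L, NA, NA, "male", carrier_founder_is_male, FALSE)
  f2 <- add(1L, NA, NA, "female", !carrier_founder_is_male, FALSE)
  couples <- list(list(father = f1, mother = f2))

  get_row <- function(id) rows[[which(vapply(rows, function(r) r$member_id, character(1)) == id)]]

  for (gen in 2:cfg$generations) {
    next_couples <- list()
    for (cp in couples) {
      father_carrier <- get_row(cp$father)$carrier
      mother_carrier <- get_row(cp$mother)$carrier
      parent_carrier <- father_carrier || mother_carrier
      nkids <- 1L + stats::rpois(1, cfg$mean_sibship - 1)
      for (k in seq_len(nkids)) {
        sex <- if (stats::runif(1) < 0.5) "male" else "female"
        carrier <- unname(transmit_allele(parent_carrier))
        kid <- add(gen, cp$father, cp$mother, sex, carrier, FALSE)
        if (gen < cfg$generations && stats::runif(1) < cfg$marry_prob) {
          spouse_sex <- if (sex == "male") "female" else "male"
          spouse <- add(gen, NA, NA, spouse_sex, FALSE, TRUE)
          next_couples[[length(next_couples) + 1L]] <-
            if (sex == "male") list(father = kid, mother = spouse)
            else list(father = spouse, mother = kid)
        }
      }
    }
    couples <- next_couples
  }

  n <- length(rows)
  members <- data.frame(
    member_id = vapply(rows, `[[`, character(1), "member_id"),
    father_id = vapply(rows, function(r) as.character(r$father_id), character(1)),
    mother_id = vapply(rows, function(r) as.character(r$mother_id), character(1)),
    sex = vapply(rows, `[[`, character(1), "sex"),
    generation = vapply(rows, `[[`, integer(1), "generation"),
    carrier = vapply(rows, `[[`, logical(1), "carrier"),
    married_in = vapply(rows, `[[`, logical(1), "married_in"),
    stringsAsFactors = FALSE)
  members$current_age <- vapply(members$generation, draw_age, integer(1))
  members$events <- lapply(seq_len(n), function(i) {
    draw_events(members$carrier[i], members$married_in[i],
                members$current_age[i], cfg)
  })
  members
}

#' Simulate one autosomal-dominant family
#'
#' A founder couple introduces a single heterozygous variant; the allele is
#' transmitted with probability 1/2 per meiosis. Phenotype events follow
#' the age-gated penetrance model of [sim_config()]. Families are
#' rejection-sampled until at least `min_cases` blood members have CRC; the
#' two earliest-onset cases are always genotyped ("sequenced"), remaining
#' members are genotyped with probability `1 - genotyping_missing_rate`.
#'
#' @param cfg A [sim_config()].
#' @param family_id Family identifier string.
#' @param seed Optional seed (omit when simulating a cohort from a single
#'   stream).
#' @param max_tries Rejection-sampling bound.
#' @return A list with `family` (a family object) and `truth` (data frame
#'   with `member_id`, `carrier`, `married_in`, `generation`).
#' @export
simulate_family <- function(cfg, family_id = "F01", seed = NULL,
                            max_tries = 2000L) {
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_tries)) {
    members <- build_pedigree_once(cfg, family_id)
    if (nrow(members) > cfg$max_members) next
    is_case <- has_event(members, "crc")
    blood_case <- is_case & !members$married_in
    if (sum(blood_case) < cfg$min_cases) next

    genotyped <- stats::runif(nrow(members)) >= cfg$genotyping_missing_rate
    case_onsets <- vapply(seq_len(nrow(members)), function(i) {
      if (!blood_case[i]) return(Inf)
      as.numeric(min(members$events[[i]]$age[members$events[[i]]$kind == "crc"]))
    }, numeric(1))
    sequenced <- order(case_onsets)[seq_len(min(2L, sum(blood_case)))]
    genotyped[sequenced] <- TRUE
    members$genotyped <- genotyped

    fam <- new_family(family_id, members[, c("member_id", "father_id",
                                             "mother_id", "sex", "genotyped",
                                             "current_age", "events")])
    truth <- members[, c("member_id", "carrier", "married_in", "generation")]
    return(list(family = fam, truth = truth))
  }
  stop("could not satisfy the ", cfg$min_cases,
       "-case constraint in ", max_tries, " attempts; the configuration ",
       "(penetrance/sibship/generations) makes it unreachable", call. = FALSE)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_cds <- function(n_codons) {
  codons <- apply(matrix(sample(c("A", "C", "G", "T"),
                                3L * (n_codons - 2L), replace = TRUE),
                         ncol = 3L), 1L, paste0, collapse = "")
  codons[codons %in% STOP_CODONS] <- "AAC"
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

# a CDS whose +1 and +2 shifted frames both contain a stop codon, so a
# frameshift anywhere early in the sequence truncates the protein
random_cds_with_shifted_stops <- function(n_codons, max_tries = 50L) {
  has_stop_shifted <- function(seq, shift) {
    body <- substr(seq, 1L + shift, nchar(seq))
    n <- nchar(body) - nchar(body) %% 3L
    starts <- seq.int(1L, n - 2L, by = 3L)
    any(substring(body, starts, starts + 2L) %in% STOP_CODONS)
  }
  for (i in seq_len(max_tries)) {
    cds <- random_cds(n_codons)
    if (has_stop_shifted(cds, 1L) && has_stop_shifted(cds, 2L)) return(cds)
  }
  stop("failed to generate a CDS with stops in shifted frames", call. = FALSE)
}

plant_variant <- function(i, fam_sim, cfg) {
  lof_class <- sample(c("frameshift", "stop_gain", "splice_acceptor"), 1,
                      prob = c(0.4, 0.3, 0.3))
  n_exons <- sample(3:12, 1)
  exon_index <- if (n_exons > 1L) sample.int(n_exons - 1L, 1) else 1L
  chrom <- as.character((i - 1L) %% 22L + 1L)
  pos <- i * 5000000L + sample.int(1000000L, 1)
  gene <- sprintf("SGENE%03d", i)
  transcript <- sprintf("SGENE%03dT1", i)
  n_codons <- sample(100:400, 1)
  cds <- random_cds_with_shifted_stops(n_codons)
  cds_pos <- NA_integer_
  if (lof_class == "frameshift") {
    cds_pos <- sample(seq(10L, 3L * n_codons - 60L), 1)
    ref <- paste0(sample(c("A", "C", "G", "T"), 1), substr(cds, cds_pos, cds_pos))
    alt <- substr(ref, 1, 1)
  } else if (lof_class == "stop_gain") {
    ref <- "C"; alt <- "T"
  } else {
    ref <- "G"; alt <- "T"
  }
  list(lof_class = lof_class, chrom = chrom, pos = pos, ref = ref, alt = alt,
       gene = gene, transcript = transcript, n_exons = n_exons,
       exon_index = exon_index, cds = cds, cds_pos = cds_pos,
       cadd = round(stats::runif(1, 25, 44), 1))
}

#' Simulate a complete cohort with planted variants
#'
#' Generates `n_families` pedigrees, plants one novel heterozygous LOF
#' variant per family (LOF class, internal exon, protein-coding transcript,
#' absent from all simulated population sources), adds background variants
#' with Beta-distributed population frequencies and mixed consequence
#' classes, and renders genotypes (with configurable genotype error and
#' per-call missingness at the planted sites) for every genotyped member.
#'
#' @param cfg A [sim_config()]; `cfg$seed` fixes all output byte-for-byte.
#' @return A `sim_cohort` list with elements `families` (list of family
#'   objects), `truth` (per-member carrier truth), `planted` (per-family
#'   planted-variant table), `variants` (list of [annotated_variant()]),
#'   `gene_models` (data frame), `cds` (named character vector of coding
#'   sequences) and `config`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  fams <- lapply(seq_len(cfg$n_families), function(i) {
    simulate_family(cfg, sprintf("F%02d", i))
  })
  families <- lapply(fams, `[[`, "family")
  names(families) <- vapply(families, `[[`, character(1), "family_id")
  truth <- do.call(rbind, lapply(seq_along(fams), function(i) {
    cbind(family_id = families[[i]]$family_id, fams[[i]]$truth,
          stringsAsFactors = FALSE)
  }))

  if (cfg$n_local_panel > 0L) {
    np <- cfg$n_local_panel
    pm <- data.frame(
      member_id = sprintf("P-%03d", seq_len(np)),
      father_id = NA_character_, mother_id = NA_character_,
      sex = sample(c("male", "female"), np, replace = TRUE),
      genotyped = TRUE,
      current_age = sample(50:90, np, replace = TRUE),
      stringsAsFactors = FALSE)
    pm$events <- rep(list(data.frame(kind = character(), detail = character(),
                                     age = integer(),
                                     stringsAsFactors = FALSE)), np)
    families$PANEL <- new_family("PANEL", pm)
    truth <- rbind(truth, data.frame(
      family_id = "PANEL", member_id = pm$member_id, carrier = FALSE,
      married_in = FALSE, generation = NA_integer_,
      stringsAsFactors = FALSE))
  }

  sample_ids <- unlist(lapply(families, function(f) {
    sample_id_for(f$family_id, f$members$member_id[f$members$genotyped])
  }), use.names = FALSE)

  planted <- lapply(seq_len(cfg$n_families), function(i) plant_variant(i, fams[[i]], cfg))

  carrier_by_sample <- function(fam_idx) {
    f <- families[[fam_idx]]; tr <- fams[[fam_idx]]$truth
    ids <- f$members$member_id[f$members$genotyped]
    stats::setNames(tr$carrier[match(ids, tr$member_id)],
                    sample_id_for(f$family_id, ids))
  }

  make_gt <- function(carrier_map) {
    carrier <- rep(FALSE, length(sample_ids))
    names(carrier) <- sample_ids
    carrier[names(carrier_map)] <- carrier_map
    ac <- ifelse(carrier, 1L, 0L)
    if (cfg$genotype_error_rate > 0) {
      flip <- stats::runif(length(ac)) < cfg$genotype_error_rate
      ac[flip] <- 1L - ac[flip]
    }
    if (cfg$call_missing_rate > 0) {
      drop <- stats::runif(length(ac)) < cfg$call_missing_rate
      ac[drop] <- NA_integer_
    }
    data.frame(sample_id = sample_ids, allele_count = ac,
               depth = stats::rpois(length(ac), 30) + 5L,
               stringsAsFactors = FALSE)
  }

  variants <- list()
  planted_rows <- list()
  for (i in seq_along(planted)) {
    p <- planted[[i]]
    ann <- data.frame(gene = p$gene, transcript_id = p$transcript,
                      consequence_class = p$lof_class,
                      exon_index = p$exon_index, exon_count = p$n_exons,
                      protein_coding = TRUE, cds_pos = p$cds_pos,
                      stringsAsFactors = FALSE)
    v <- annotated_variant(p$chrom, p$pos, p$ref, p$alt,
                           qual = round(stats::runif(1, 120, 900), 1),
                           annotations = ann,
                           population_afs = numeric(),
                           cadd_phred = p$cadd,
                           genotypes = make_gt(carrier_by_sample(i)),
                           sources = c("gnomad_nfe", "thousand_genomes"))
    variants[[length(variants) + 1L]] <- v
    planted_rows[[i]] <- data.frame(
      family_id = families[[i]]$family_id, variant = variant_key(v),
      gene = p$gene, transcript = p$transcript, lof_class = p$lof_class,
      cds_pos = p$cds_pos, stringsAsFactors = FALSE)
  }

  bg_classes <- c("missense", "synonymous", "other", "stop_gain",
                  "frameshift", "splice_acceptor")
  bg_probs <- c(0.45, 0.3, 0.1, 0.05, 0.05, 0.05)
  gene_rows <- lapply(seq_along(planted), function(i) {
    p <- planted[[i]]
    data.frame(gene = p$gene, transcript = p$transcript,
               biotype = "protein_coding", strand = "+",
               n_exons = p$n_exons, cds_length = nchar(p$cds),
               stringsAsFactors = FALSE)
  })

  for (j in seq_len(cfg$n_background_variants)) {
    af <- stats::rbeta(1, cfg$background_af_shape1, cfg$background_af_shape2)
    cls <- sample(bg_classes, 1, prob = bg_probs)
    n_exons <- sample(2:15, 1)
    exon_index <- sample.int(n_exons, 1)  # background may hit the last exon
    coding <- stats::runif(1) < 0.9
    gene <- sprintf("BGENE%03d", j)
    ann <- data.frame(gene = gene, transcript_id = paste0(gene, "T1"),
                      consequence_class = cls, exon_index = exon_index,
                      exon_count = n_exons, protein_coding = coding,
                      cds_pos = NA_integer_, stringsAsFactors = FALSE)
    low_qual <- stats::runif(1) < 0.03
    qual <- if (low_qual) round(stats::runif(1, 5, 20), 1)
            else round(stats::runif(1, 30, 1500), 1)
    carrier_p <- 2 * af * (1 - af) + af^2
    carriers <- stats::runif(length(sample_ids)) < carrier_p
    hom_p <- if (carrier_p > 0) af^2 / carrier_p else 0
    ac <- ifelse(carriers,
                 ifelse(stats::runif(length(sample_ids)) < hom_p, 2L, 1L), 0L)
    gts <- data.frame(sample_id = sample_ids, allele_count = ac,
                      depth = stats::rpois(length(sample_ids), 30) + 5L,
                      stringsAsFactors = FALSE)
    cadd <- if (stats::runif(1) < 0.2) NA_real_ else round(stats::runif(1, 0, 38), 1)
    afs <- c(gnomad_nfe = af,
             thousand_genomes = min(1, af * stats::runif(1, 0.5, 1.5)))
    chrom <- as.character(sample.int(22L, 1))
    pos <- 200000000L + j * 10000L + sample.int(9999L, 1)
    variants[[length(variants) + 1L]] <- annotated_variant(
      chrom, pos, "A", "G", qual = qual, annotations = ann,
      population_afs = afs, cadd_phred = cadd, genotypes = gts,
      sources = c("gnomad_nfe", "thousand_genomes"))
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      gene = gene, transcript = paste0(gene, "T1"),
      biotype = if (coding) "protein_coding" else "lncRNA", strand = "+",
      n_exons = n_exons, cds_length = NA_integer_, stringsAsFactors = FALSE)
  }

  ord <- order(as.integer(vapply(variants, `[[`, character(1), "chrom")),
               vapply(variants, `[[`, integer(1), "pos"))
  variants <- variants[ord]

  structure(list(
    families = families, truth = truth,
    planted = do.call(rbind, planted_rows),
    variants = variants,
    gene_models = do.call(rbind, gene_rows),
    cds = stats::setNames(vapply(planted, `[[`, character(1), "cds"),
                          vapply(planted, `[[`, character(1), "transcript")),
    config = cfg), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d families, %d variants (%d planted), %d samples\n",
              length(x$families), length(x$variants), nrow(x$planted),
              nrow(x$variants[[1]]$genotypes)))
  invisible(x)
}

format_info <- function(v) {
  ann <- v$annotations
  entries <- vapply(seq_len(nrow(ann)), function(k) {
    paste(v$alt, ann$consequence_class[k], ann$gene[k], ann$transcript_id[k],
          ifelse(is.na(ann$exon_index[k]), ".", ann$exon_index[k]),
          ifelse(is.na(ann$exon_count[k]), ".", ann$exon_count[k]),
          ifelse(ann$protein_coding[k], "protein_coding", "non_coding"),
          ifelse(is.na(ann$cds_pos[k]), ".", ann$cds_pos[k]),
          sep = "|")
  }, character(1))
  info <- paste0("ANN=", paste(entries, collapse = ","))
  afmap <- c(gnomad_nfe = "AF_GNOMAD_NFE", thousand_genomes = "AF_1KG")
  for (src in names(afmap)) {
    if (src %in% names(v$population_afs)) {
      info <- paste0(info, ";", afmap[src], "=",
                     format(v$population_afs[[src]], digits = 6, scientific = FALSE))
    }
  }
  if (!is.na(v$cadd_phred)) info <- paste0(info, ";CADD_PHRED=", v$cadd_phred)
  info
}

write_cohort_vcf <- function(cohort, path) {
  samples <- cohort$variants[[1]]$genotypes$sample_id
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=lofsegSimulator",
    '##INFO=<ID=ANN,Number=.,Type=String,Description="Per-transcript annotation: allele|consequence|gene|transcript|exon_index|exon_count|biotype|cds_pos">',
    '##INFO=<ID=AF_GNOMAD_NFE,Number=A,Type=Float,Description="Simulated gnomAD NFE allele frequency">',
    '##INFO=<ID=AF_1KG,Number=A,Type=Float,Description="Simulated 1000 Genomes allele frequency">',
    '##INFO=<ID=CADD_PHRED,Number=A,Type=Float,Description="Simulated CADD PHRED score">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(cohort$variants, function(v) {
    gt <- vapply(seq_len(nrow(v$genotypes)), function(k) {
      ac <- v$genotypes$allele_count[k]
      g <- if (is.na(ac)) "./." else c("0/0", "0/1", "1/1")[ac + 1L]
      paste0(g, ":", v$genotypes$depth[k])
    }, character(1))
    paste(c(v$chrom, v$pos, ".", v$ref, v$alt, v$qual, "PASS",
            format_info(v), "GT:DP", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

write_fasta <- function(seqs, path, width = 60L) {
  lines <- unlist(lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    starts <- seq.int(1L, nchar(s), by = width)
    c(paste0(">", nm), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated cohort as a fixture bundle
#'
#' Writes `pedigree.ped`, `cohort.vcf`, `gene_models.tsv`, `cds.fasta` and
#' `truth.tsv` plus a `manifest.json` recording the seed, the full
#' configuration and the MD5 of every file, so a bundle can be validated
#' and regenerated bit-for-bit.
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_fixture_bundle <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir, call. = FALSE)

  paths <- c(ped = file.path(dir, "pedigree.ped"),
             vcf = file.path(dir, "cohort.vcf"),
             gene_models = file.path(dir, "gene_models.tsv"),
             cds = file.path(dir, "cds.fasta"),
             truth = file.path(dir, "truth.tsv"))
  write_pedigree(cohort$families, paths[["ped"]])
  write_cohort_vcf(cohort, paths[["vcf"]])
  utils::write.table(cohort$gene_models, paths[["gene_models"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(as.list(cohort$cds), paths[["cds"]])
  tr <- merge(cohort$truth, cohort$planted[, c("family_id", "variant", "cds_pos")],
              by = "family_id", sort = FALSE)
  utils::write.table(tr, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  manifest <- list(seed = cohort$config$seed,
                   config = unclass(cohort$config),
                   files = as.list(tools::md5sum(unname(paths))))
  names(manifest$files) <- basename(names(manifest$files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Validate a fixture bundle against its manifest
#'
#' @param dir Bundle directory containing `manifest.json`.
#' @return The parsed manifest, invisibly; mismatching or missing files
#'   raise an error.
#' @export
validate_fixture_bundle <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- tryCatch(jsonlite::read_json(mf_path),
                       error = function(e) stop("corrupted manifest: ",
                                                conditionMessage(e), call. = FALSE))
  if (is.null(manifest$files) || is.null(manifest$seed)) {
    stop("corrupted manifest: missing 'files' or 'seed' entries", call. = FALSE)
  }
  for (fname in names(manifest$files)) {
    path <- file.path(dir, fname)
    if (!file.exists(path)) stop("bundle file missing: ", fname, call. = FALSE)
    actual <- unname(tools::md5sum(path))
    if (!identical(actual, manifest$files[[fname]])) {
      stop("bundle file ", fname, " does not match its manifest MD5",
           call. = FALSE)
    }
  }
  invisible(manifest)
}
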