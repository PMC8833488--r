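ann_row <- function(consequence, exon_index = 2L, exon_count = 5L,
                    coding = TRUE) {
  data.frame(gene = "g", transcript_id = "t", consequence_class = consequence,
             exon_index = exon_index, exon_count = exon_count,
             protein_coding = coding, cds_pos = NA_integer_,
             stringsAsFactors = FALSE)
}

test_that("loss-of-function classing covers the three LOF classes only", {
  expect_identical(classify_lof(ann_row("frameshift")), "frameshift")
  expect_identical(classify_lof(ann_row("stop_gain")), "stop_gain")
  expect_identical(classify_lof(ann_row("splice_acceptor")), "canonical_splice")
  expect_identical(classify_lof(ann_row("splice_donor")), "canonical_splice")
  expect_true(is.na(classify_lof(ann_row("missense"))))
  expect_true(is.na(classify_lof(ann_row("synonymous"))))
  expect_true(is.na(classify_lof(ann_row("other"))))
})

test_that("last-exon and non-coding annotations are excluded", {
  last <- gene_position_filter(ann_row("stop_gain", 3L, 3L))
  expect_false(last$retained); expect_identical(last$reason, "last_exon")
  ok <- gene_position_filter(ann_row("stop_gain", 1L, 2L))
  expect_true(ok$retained)
  nc <- gene_position_filter(ann_row("stop_gain", 1L, 2L, coding = FALSE))
  expect_false(nc$retained); expect_identical(nc$reason, "non_coding")
  un <- gene_position_filter(ann_row("stop_gain", NA_integer_, 4L))
  expect_false(un$retained); expect_identical(un$reason, "unlocatable")
  # splice variant annotated with the downstream exon index is retained
  spl <- gene_position_filter(ann_row("splice_acceptor", 2L, 25L))
  expect_true(spl$retained)
})

test_that("CADD tiers use strict >20 / >30 boundaries", {
  expect_identical(cadd_tier(44), "top0.1pct")
  expect_identical(cadd_tier(30.0001), "top0.1pct")
  expect_identical(cadd_tier(24.7), "top1pct")
  expect_identical(cadd_tier(30), "top1pct")
  expect_identical(cadd_tier(20), "below20")
  expect_identical(cadd_tier(NA), "unknown")
  expect_identical(cadd_tier(NULL), "unknown")
})

test_that("the fully segregating family passes the filter", {
  f8 <- parse_pedigree(text = family8_ped())$F8
  v <- fixture_variant(f8, family8_carriers)
  verdict <- segregation_filter(v, f8)
  expect_true(verdict$passes)
  expect_equal(verdict$case_carriers, 2L)        # III-12, IV-11
  expect_equal(verdict$case_noncarriers, 0L)
  expect_equal(verdict$control_carriers, 0L)
  expect_length(verdict$exempt_phenocopies, 0)
})

test_that("an affected married-in spouse is exempt from the carrier rule", {
  f11 <- parse_pedigree(text = family11_ped())$F11
  v <- fixture_variant(f11, family11_carriers, chrom = "19", ref = "G",
                       alt = "T", consequence = "splice_acceptor",
                       exon_index = 2L, exon_count = 25L)
  verdict <- segregation_filter(v, f11)
  expect_true(verdict$passes)
  expect_identical(verdict$exempt_phenocopies, "II-9")
  expect_equal(verdict$case_carriers, 2L)        # II-8, III-5
})

test_that("a carrier control or a non-carrier blood case breaks segregation", {
  f8 <- parse_pedigree(text = family8_ped())$F8
  v_ctrl <- fixture_variant(f8, c(family8_carriers, "IV-8"))
  expect_false(segregation_filter(v_ctrl, f8)$passes)
  v_case <- fixture_variant(f8, setdiff(family8_carriers, "III-12"))
  verdict <- segregation_filter(v_case, f8)
  expect_false(verdict$passes)
  expect_equal(verdict$case_noncarriers, 1L)
})

test_that("a family without genotyped cases cannot pass", {
  ped <- paste("Z\ta\t0\t0\t1\t0\t70\tcrc:colon:50",
               "Z\tb\t0\t0\t2\t1\t68\t.", sep = "\n")
  fz <- parse_pedigree(text = ped)$Z
  v <- fixture_variant(fz, character())
  verdict <- segregation_filter(v, fz)
  expect_false(verdict$passes)
  expect_identical(verdict$reason, "no_genotyped_case")
})

test_that("segregation agrees with the brute-force predicate on all genotype vectors", {
  # compact mixed-role pedigree with 5 genotyped members
  ped <- paste(
    "B\tI-1\t0\t0\t1\t0\t.\tcrc:colon:48",
    "B\tI-2\t0\t0\t2\t0\t82\t.",
    "B\tII-1\tI-1\tI-2\t1\t1\t60\tcrc:colon:55",
    "B\tII-2\tI-1\tI-2\t2\t1\t58\tcrc:colon:50",
    "B\tII-3\tI-1\tI-2\t1\t1\t62\t.",
    "B\tII-4\t0\t0\t2\t1\t59\tcrc:colon:57",
    "B\tII-5\tI-1\tI-2\t2\t1\t56\tpolyps:colon:50",
    sep = "\n")
  fam <- parse_pedigree(text = ped)$B
  roles <- assign_roles(fam)
  genotyped <- fam$members$member_id[fam$members$genotyped]
  states <- list(0L, 1L, NA_integer_)
  grid <- expand.grid(rep(list(1:3), length(genotyped)))
  for (r in seq_len(nrow(grid))) {
    gt <- vapply(seq_along(genotyped),
                 function(j) states[[grid[r, j]]], integer(1))
    names(gt) <- genotyped
    v <- annotated_variant("1", 5L, "A", "G", 100, ann_row("stop_gain"),
                           genotypes = data.frame(
                             sample_id = paste0("B_", genotyped),
                             allele_count = gt, depth = 30L,
                             stringsAsFactors = FALSE))
    expect_identical(segregation_filter(v, fam, roles)$passes,
                     oracle_segregates(gt, roles, fam$blood_member_ids),
                     info = paste(gt, collapse = ","))
  }
})

test_that("verdicts respond monotonically to added evidence", {
  f8 <- parse_pedigree(text = family8_ped())$F8
  base <- fixture_variant(f8, family8_carriers)
  expect_true(segregation_filter(base, f8)$passes)
  # adding a carrier control never preserves a pass
  worse <- fixture_variant(f8, c(family8_carriers, "III-7"))
  expect_false(segregation_filter(worse, f8)$passes)
  # a failing verdict never becomes passing by adding a non-carrier control
  failing <- fixture_variant(f8, setdiff(family8_carriers, "IV-11"))
  expect_false(segregation_filter(failing, f8)$passes)
  g <- failing$genotypes
  g$allele_count[g$sample_id == "F8_IV-9"] <- 0L
  failing$genotypes <- g
  expect_false(segregation_filter(failing, f8)$passes)
})

micro_cohort <- function() {
  f8 <- parse_pedigree(text = family8_ped())$F8
  good <- fixture_variant(f8, family8_carriers, pos = 1000000L)
  common <- fixture_variant(f8, family8_carriers, pos = 2000000L)
  common$population_afs <- c(gnomad_nfe = 0.002)
  last_exon <- fixture_variant(f8, family8_carriers, pos = 3000000L,
                               consequence = "stop_gain",
                               exon_index = 6L, exon_count = 6L)
  low_qual <- fixture_variant(f8, family8_carriers, pos = 4000000L,
                              qual = 15)
  non_lof <- fixture_variant(f8, family8_carriers, pos = 5000000L,
                             consequence = "missense")
  list(f8 = f8, variants = list(good, common, last_exon, low_qual, non_lof))
}

test_that("the cascade keeps the qualifying variant and logs every rejection", {
  mc <- micro_cohort()
  # the family-private carrier fraction (5/10) is irrelevant to what this
  # cohort exercises, so lift the local artefact ceiling for the unit test
  th <- qc_thresholds(max_local_af = 0.9)
  res <- run_prioritization(mc$variants, list(mc$f8), thresholds = th)
  expect_equal(res$candidates$variant, "16:1000000:GC:G")
  expect_equal(res$candidates$lof_class, "frameshift")
  expect_equal(res$candidates$cadd_tier, "top0.1pct")
  tr <- res$trail
  expect_equal(tr$verdict[tr$variant == "16:2000000:GC:G" &
                            tr$filter == "population_af"], "reject")
  expect_match(tr$value[tr$variant == "16:3000000:GC:G" &
                          tr$filter == "lof_and_position"], "last_exon")
  expect_equal(tr$verdict[tr$variant == "16:4000000:GC:G" &
                            tr$filter == "qc"], "reject")
  expect_match(tr$value[tr$variant == "16:5000000:GC:G" &
                          tr$filter == "lof_and_position"], "lof_class")
})

test_that("the candidate set is invariant to variant-level filter order", {
  mc <- micro_cohort()
  th <- qc_thresholds(max_local_af = 0.9)
  res <- run_prioritization(mc$variants, list(mc$f8), thresholds = th)
  # independent unordered evaluation of the same variant-level predicates
  keys <- vapply(mc$variants, variant_key, character(1))
  pass <- vapply(mc$variants, function(v) {
    checks <- c(
      qc = !is.null(qc_filter(v, th)),
      local = local_cohort_af(mc$variants, variant_key(v)) < th$max_local_af,
      pop = max_population_af(v) < th$max_pop_af,
      lofpos = {
        cls <- classify_lof(v$annotations[1, ])
        !is.na(cls) && gene_position_filter(v$annotations[1, ])$retained
      },
      seg = segregation_filter(v, mc$f8)$passes)
    all(sample(checks))  # order scrambled; conjunction unchanged
  }, logical(1))
  expect_setequal(res$candidates$variant, keys[pass])
})

test_that("sample-ID mismatches between PED and VCF are fatal and named", {
  f8 <- parse_pedigree(text = family8_ped())$F8
  v <- fixture_variant(f8, family8_carriers)
  v$genotypes <- v$genotypes[-1, ]  # drop a genotyped member's column
  expect_error(run_prioritization(list(v), list(f8)), "F8_III-3")
})
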