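# Shared fixtures: two CRC pedigrees whose carrier patterns encode the
# canonical segregation situations (a fully segregating four-case family;
# a family with an affected married-in spouse who must be exempt), plus
# variant builders and independent oracles for segregation and
# translation.

family8_ped <- function() paste(
  "F8\tI-1\t0\t0\t1\t0\t.\t.",
  "F8\tI-2\t0\t0\t2\t0\t.\t.",
  "F8\tII-1\t0\t0\t2\t0\t82\t.",
  "F8\tII-2\tI-1\tI-2\t1\t0\t84\t.",
  "F8\tII-3\tI-1\tI-2\t2\t0\t81\tother_cancer:abdominal cavity:70",
  "F8\tII-5\tI-1\tI-2\t2\t0\t79\tcrc:colon:67",
  "F8\tII-6\t0\t0\t1\t0\t84\t.",
  "F8\tII-7\tI-1\tI-2\t1\t0\t80\t.",
  "F8\tIII-3\tII-2\tII-1\t1\t1\t60\tpolyps:colon:55",
  "F8\tIII-4\t0\t0\t2\t0\t75\t.",
  "F8\tIII-5\tII-2\tII-1\t2\t0\t65\tother_cancer:abdominal cavity:63",
  "F8\tIII-7\tII-2\tII-1\t1\t1\t70\t.",
  "F8\tIII-8\t0\t0\t2\t0\t68\t.",
  "F8\tIII-9\tII-5\tII-6\t2\t0\t61\tcrc:colon:58;other_cancer:ovarian:59",
  "F8\tIII-10\t0\t0\t1\t0\t77\t.",
  "F8\tIII-12\tII-5\tII-6\t1\t1\t55\tcrc:colon:49",
  "F8\tIII-13\tII-5\tII-6\t2\t1\t66\tpolyps:colon:61",
  "F8\tIII-15\tII-5\tII-6\t2\t1\t62\tpolyps:colon:56",
  "F8\tIV-4\tIII-3\tIII-4\t1\t1\t47\tpolyps:colon:45",
  "F8\tIV-6\tIII-3\tIII-4\t1\t1\t44\tpolyps:colon:42",
  "F8\tIV-8\tIII-7\tIII-8\t1\t1\t45\t.",
  "F8\tIV-9\tIII-7\tIII-8\t1\t1\t44\t.",
  "F8\tIV-11\tIII-10\tIII-9\t2\t1\t44\tcrc:colon:42",
  sep = "\n")

# carriers of the family-8 frameshift fixture variant among genotyped
family8_carriers <- c("III-3", "III-12", "IV-4", "IV-6", "IV-11")

family11_ped <- function() paste(
  "F11\tI-1\t0\t0\t1\t0\t.\t.",
  "F11\tI-2\t0\t0\t2\t0\t.\t.",
  "F11\tII-1\t0\t0\t1\t0\t80\t.",
  "F11\tII-2\tI-1\tI-2\t2\t0\t78\t.",
  "F11\tII-3\t0\t0\t1\t0\t81\t.",
  "F11\tII-4\tI-1\tI-2\t2\t0\t76\t.",
  "F11\tII-8\tI-1\tI-2\t1\t1\t74\tcrc:colon:69",
  "F11\tII-9\t0\t0\t2\t1\t72\tcrc:colon:66",
  "F11\tIII-3\tII-1\tII-2\t1\t0\t57\tcrc:colon:52",
  "F11\tIII-5\tII-1\tII-2\t1\t1\t48\tcrc:colon:40",
  "F11\tIII-7\tII-3\tII-4\t1\t0\t58\tcrc:colon:55",
  "F11\tIII-1\tII-3\tII-4\t2\t1\t74\tother_cancer:breast:73;unaffected:colonoscopy_negative",
  "F11\tIII-2\t0\t0\t1\t0\t75\t.",
  "F11\tIII-8\tII-8\tII-9\t2\t1\t50\tpolyps:multiple:45",
  "F11\tIV-1\tIII-1\tIII-2\t1\t1\t46\t.",
  "F11\tIV-2\tIII-1\tIII-2\t1\t1\t44\t.",
  sep = "\n")

family11_carriers <- c("II-8", "III-5", "III-8")

# an annotated variant carried (heterozygously) by `carriers` among the
# genotyped members of `family`
fixture_variant <- function(family, carriers, chrom = "16", pos = 1000000L,
                            ref = "GC", alt = "G", qual = 200,
                            consequence = "frameshift", exon_index = 3L,
                            exon_count = 6L, cadd = 33) {
  ids <- family$members$member_id[family$members$genotyped]
  gts <- data.frame(
    sample_id = paste(family$family_id, ids, sep = "_"),
    allele_count = ifelse(ids %in% carriers, 1L, 0L),
    depth = 30L, stringsAsFactors = FALSE)
  ann <- data.frame(gene = "GENE1", transcript_id = "GENE1T1",
                    consequence_class = consequence, exon_index = exon_index,
                    exon_count = exon_count, protein_coding = TRUE,
                    cds_pos = NA_integer_, stringsAsFactors = FALSE)
  annotated_variant(chrom, pos, ref, alt, qual, ann,
                    population_afs = numeric(), cadd_phred = cadd,
                    genotypes = gts,
                    sources = c("gnomad_nfe", "thousand_genomes"))
}

# Independent brute-force evaluation of the dominant-model segregation
# predicate, written directly from its definition.
oracle_segregates <- function(gt, roles, blood) {
  ctrl <- names(roles)[roles == "control"]
  ctrl <- ctrl[ctrl %in% names(gt)]
  if (any(!is.na(gt[ctrl]) & gt[ctrl] >= 1)) return(FALSE)
  bc <- names(roles)[roles == "case"]
  bc <- bc[bc %in% blood & bc %in% names(gt)]
  bc <- bc[!is.na(gt[bc])]
  if (length(bc) == 0) return(FALSE)
  if (any(gt[bc] == 0)) return(FALSE)
  any(gt[bc] >= 1)
}

# Independent translation-based consequence oracle (seqinr route, plain
# codon walk; no shared code with protein_consequence).
oracle_consequence <- function(cds, del_start, del_len) {
  mut <- paste0(substr(cds, 1, del_start - 1),
                substr(cds, del_start + del_len, nchar(cds)))
  tr <- function(s) {
    s <- substr(s, 1, nchar(s) - nchar(s) %% 3)
    if (nchar(s) < 3) return(character())
    seqinr::translate(seqinr::s2c(s))
  }
  trim <- function(a) {
    i <- which(a == "*")
    if (length(i)) a[seq_len(i[1])] else a
  }
  wt <- trim(tr(cds)); mu <- trim(tr(mut))
  if (identical(wt, mu)) return(list(category = "synonymous", stop_offset = NA))
  n <- min(length(wt), length(mu))
  k <- which(wt[seq_len(n)] != mu[seq_len(n)])[1]
  if (is.na(k)) k <- n + 1L
  if (del_len %% 3 == 0) {
    m <- del_len %/% 3
    clean <- length(wt) - m == length(mu) &&
      identical(wt[-(k:(k + m - 1))], mu)
    if (clean) return(list(category = "inframe_del", stop_offset = NA))
    if (k <= length(mu) && mu[k] == "*") {
      return(list(category = "nonsense", stop_offset = NA))
    }
    return(list(category = "inframe_del", stop_offset = NA))
  }
  if (k > length(mu)) return(list(category = "no_stop", stop_offset = NA))
  if (mu[k] == "*") return(list(category = "nonsense", stop_offset = NA))
  st <- which(mu[k:length(mu)] == "*")[1]
  if (is.na(st)) return(list(category = "no_stop", stop_offset = NA))
  list(category = "frameshift", stop_offset = st)
}

random_test_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  body <- replicate(n_codons - 2L, paste(sample(c("A", "C", "G", "T"), 3,
                                                replace = TRUE), collapse = ""))
  body[body %in% stops] <- "GGA"
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

write_mes_tables <- function(dir, values = NULL) {
  # full-format uniform probability tables by default
  lens <- c(4^7, 4^7, 4^7, 4^7, 4^7, 4^3, 4^4, 4^3, 4^4)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(lens)) {
    v <- if (is.null(values)) rep(1 / lens[k], lens[k]) else values[[k]]
    writeLines(format(v, digits = 17), file.path(dir, paste0("me2x3acc", k)))
  }
  dir
}
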