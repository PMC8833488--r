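test_that("the uniform synthetic model scores every window 0", {
  m <- mes_synthetic_model("uniform")
  set.seed(3)
  for (i in 1:10) {
    w <- paste(sample(c("A", "C", "G", "T"), 23, replace = TRUE),
               collapse = "")
    expect_equal(score_acceptor(w, m), 0, tolerance = 1e-12)
  }
})

test_that("window validation rejects bad lengths and alphabets", {
  m <- mes_synthetic_model("uniform")
  expect_error(score_acceptor(strrep("A", 22), m), "23")
  expect_error(score_acceptor(strrep("A", 24), m), "23")
  expect_error(score_acceptor(paste0(strrep("A", 22), "N"), m), "non-ACGT")
})

test_that("scoring matches a direct inclusion-exclusion computation", {
  m <- mes_synthetic_model("random", seed = 5)
  set.seed(8)
  w <- paste(sample(c("A", "C", "G", "T"), 23, replace = TRUE), collapse = "")
  # independent arithmetic straight from the model definition
  rest <- paste0(substr(w, 1, 18), substr(w, 21, 23))
  subsets <- list(c(1, 7), c(8, 7), c(15, 7), c(5, 7), c(12, 7),
                  c(5, 3), c(8, 4), c(12, 3), c(15, 4))
  idx <- function(kmer) {
    code <- c(A = 0, C = 1, G = 2, T = 3)
    ch <- strsplit(kmer, "")[[1]]
    sum(code[ch] * 4^(rev(seq_along(ch)) - 1)) + 1
  }
  p <- vapply(seq_along(subsets), function(k) {
    s <- subsets[[k]]
    m$submodels[[k]][idx(substr(rest, s[1], s[1] + s[2] - 1))]
  }, numeric(1))
  pme <- prod(p[1:5]) / prod(p[6:9])
  pbg <- prod(m$background[strsplit(rest, "")[[1]]])
  s19 <- substr(w, 19, 19); s20 <- substr(w, 20, 20)
  expected <- log2(pme / pbg) +
    log2(m$consensus[[1]][[s19]] / m$background[[s19]]) +
    log2(m$consensus[[2]][[s20]] / m$background[[s20]])
  expect_equal(score_acceptor(w, m), expected, tolerance = 1e-9)
  # submodel evaluation order cannot matter (log-sum reordering)
  reordered <- sum(log2(p[c(3, 1, 5, 2, 4)])) - sum(log2(p[c(8, 6, 9, 7)]))
  expect_equal(sum(log2(p[1:5])) - sum(log2(p[6:9])), reordered,
               tolerance = 1e-9)
})

test_that("the scan scores the canonical window identically to score_acceptor", {
  m <- mes_synthetic_model("random", seed = 2)
  set.seed(21)
  intron <- paste(sample(c("A", "C", "G", "T"), 38, replace = TRUE),
                  collapse = "")
  seq <- paste0(intron, "AG", paste(sample(c("A", "C", "G", "T"), 40,
                                           replace = TRUE), collapse = ""))
  calls <- scan_de_novo_acceptors(seq, canonical_offset = 40,
                                  window_radius = 10, m)
  canonical <- calls[calls$genomic_offset == 0, ]
  expect_equal(canonical$label, "canonical")
  direct <- score_acceptor(substr(seq, 40 - 19, 40 + 3), m)
  expect_identical(canonical$mes_score, direct)
  expect_true(all(diff(calls$mes_score) <= 0))   # sorted by score
  expect_true(all(substr(calls$window, 19, 20) == "AG"))
})

test_that("a window without any AG yields an empty scan", {
  m <- mes_synthetic_model("uniform")
  seq <- strrep("C", 100)
  calls <- scan_de_novo_acceptors(seq, 50, 8, m)
  expect_equal(nrow(calls), 0)
})

test_that("scans that would run off the sequence are errors", {
  m <- mes_synthetic_model("uniform")
  expect_error(scan_de_novo_acceptors(strrep("A", 30), 15, 10, m),
               "exceeds")
})

test_that("model tables load from the published full-table layout", {
  dir <- write_mes_tables(withr::local_tempdir())
  m <- load_mes_acceptor_model(dir,
                               background = c(A = .25, C = .25, G = .25, T = .25),
                               cons1 = c(A = .25, C = .25, G = .25, T = .25),
                               cons2 = c(A = .25, C = .25, G = .25, T = .25))
  expect_s3_class(m, "mes_model")
  expect_identical(m$site_kind, "acceptor23")
  w <- paste0(strrep("G", 18), "AG", "CCT")
  expect_equal(score_acceptor(w, m), 0, tolerance = 1e-9)
})

test_that("truncated or missing tables are named in the error", {
  dir <- write_mes_tables(withr::local_tempdir())
  writeLines("0.5", file.path(dir, "me2x3acc3"))  # truncate table 3
  expect_error(load_mes_acceptor_model(dir), "me2x3acc3")
  dir2 <- withr::local_tempdir()
  expect_error(load_mes_acceptor_model(dir2, background = NULL),
               "me2x3acc1")
})

test_that("sparse down-sampled tables score covered windows and reject others", {
  full_dir <- write_mes_tables(withr::local_tempdir())
  ref <- load_mes_acceptor_model(full_dir,
                                 background = c(A = .25, C = .25, G = .25, T = .25),
                                 cons1 = c(A = .25, C = .25, G = .25, T = .25),
                                 cons2 = c(A = .25, C = .25, G = .25, T = .25))
  w <- paste0(strrep("A", 18), "AG", "TTT")
  rest <- paste0(substr(w, 1, 18), substr(w, 21, 23))
  subsets <- list(c(1, 7), c(8, 7), c(15, 7), c(5, 7), c(12, 7),
                  c(5, 3), c(8, 4), c(12, 3), c(15, 4))
  lens <- c(4^7, 4^7, 4^7, 4^7, 4^7, 4^3, 4^4, 4^3, 4^4)
  sparse_dir <- withr::local_tempdir()
  for (k in seq_along(subsets)) {
    s <- subsets[[k]]
    kmer <- substr(rest, s[1], s[1] + s[2] - 1)
    writeLines(paste(kmer, format(1 / lens[k], digits = 17), sep = "\t"),
               file.path(sparse_dir, paste0("me2x3acc", k)))
  }
  m <- load_mes_acceptor_model(sparse_dir,
                               background = c(A = .25, C = .25, G = .25, T = .25),
                               cons1 = c(A = .25, C = .25, G = .25, T = .25),
                               cons2 = c(A = .25, C = .25, G = .25, T = .25))
  expect_equal(score_acceptor(w, m), score_acceptor(w, ref), tolerance = 1e-9)
  other <- paste0(strrep("C", 18), "AG", "TTT")
  expect_error(score_acceptor(other, m), "not covered")
})

test_that("acceptor shifts translate into CDS deletions", {
  canonical <- list(genomic_offset = 0L)
  edit <- predict_splice_outcome(canonical, list(genomic_offset = 2L),
                                 exon_cds_start = 25L)
  expect_identical(edit$kind, "del")
  expect_identical(edit$cds_start, 25L)
  expect_identical(edit$cds_end, 26L)
  inframe <- predict_splice_outcome(canonical, list(genomic_offset = 3L),
                                    exon_cds_start = 100L)
  expect_identical(c(inframe$cds_start, inframe$cds_end), c(100L, 102L))
  none <- predict_splice_outcome(canonical, list(genomic_offset = 0L), 25L)
  expect_identical(none$kind, "none")
  expect_error(predict_splice_outcome(canonical, list(genomic_offset = -2L), 25L),
               "unsupported")
})

test_that("hand-translated consequence examples reproduce", {
  # ATG AAA CTG ATG TAA = M K L M *; deleting c.4 gives ATG AAC TGA = M N *
  pc <- protein_consequence("ATGAAACTGATGTAA", transcript_edit("del", 4, 4))
  expect_identical(pc$hgvs_p, "p.Lys2Asnfs*2")
  expect_identical(pc$category, "frameshift")
  expect_identical(pc$first_changed_codon, 2L)
  expect_identical(pc$stop_offset, 2L)
  # in-frame single-codon deletion
  pc2 <- protein_consequence("ATGAAATGA", transcript_edit("del", 4, 6))
  expect_identical(pc2$hgvs_p, "p.Lys2del")
  expect_identical(pc2$category, "inframe_del")
  # substitution straight to a stop is nonsense
  pc3 <- protein_consequence("ATGAAACTGTAA",
                             transcript_edit("delins", 4, 6, "TGA"))
  expect_identical(pc3$category, "nonsense")
  expect_identical(pc3$hgvs_p, "p.Lys2Ter")
})

test_that("edits out of bounds error; non-ATG start only warns", {
  expect_error(protein_consequence("ATGAAATGA", transcript_edit("del", 8, 12)),
               "outside")
  pc <- protein_consequence("TTGAAACTGATGTAA", transcript_edit("del", 4, 4))
  expect_true(any(grepl("ATG", pc$warnings)))
})

test_that("consequences agree with the independent translation oracle", {
  set.seed(404)
  for (i in 1:200) {
    cds <- random_test_cds(sample(10:100, 1))
    len <- sample(1:5, 1)
    start <- sample(seq_len(nchar(cds) - len), 1)
    got <- protein_consequence(cds, transcript_edit("del", start,
                                                    start + len - 1L))
    want <- oracle_consequence(cds, start, len)
    expect_identical(got$category, want$category,
                     info = sprintf("cds=%s del=%d..%d", cds, start,
                                    start + len - 1))
    if (want$category == "frameshift") {
      expect_identical(got$stop_offset, as.integer(want$stop_offset))
      expect_true(got$stop_offset >= 2L)
    }
  }
})

test_that("edits of length 0 mod 3 never frameshift", {
  set.seed(77)
  for (i in 1:50) {
    cds <- random_test_cds(sample(12:60, 1))
    len <- sample(c(3L, 6L), 1)
    start <- sample(seq_len(nchar(cds) - len), 1)
    got <- protein_consequence(cds, transcript_edit("del", start,
                                                    start + len - 1L))
    expect_false(got$category == "frameshift")
  }
})
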