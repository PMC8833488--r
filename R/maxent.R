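# Maximum-entropy 3' (acceptor) splice-site model.
#
# The acceptor window is a 23-mer: positions 1-20 intronic, ending with the
# (near-)obligate AG dinucleotide at positions 19-20, then 3 exonic
# positions 21-23. The model scores log2 of the odds of a window under a
# maximum-entropy distribution of real acceptors versus a background
# composition. Following the published model layout, the AG positions are
# scored against per-nucleotide consensus/background frequencies and the
# remaining 21-mer is scored by nine joint submodels over overlapping
# position subsets combined by inclusion-exclusion:
#   P(21-mer) = P1(1:7) P2(8:14) P3(15:21) P4(5:11) P5(12:18) /
#               [P6(5:7) P7(8:11) P8(12:14) P9(15:18)]
# Table files hold one value per k-mer in base-4 lexicographic order
# (A=0, C=1, G=2, T=3, most significant first), one per line; a sparse
# two-column "kmer<TAB>value" layout is also accepted for down-sampled
# tables. Values may be maxent probabilities (default; the scorer divides
# by the background) or precombined probability/background ratios
# (`tables_are_ratios = TRUE`, matching the original score distribution).

ACCEPTOR_SUBSETS <- list(
  c(1L, 7L), c(8L, 7L), c(15L, 7L), c(5L, 7L), c(12L, 7L),  # numerator
  c(5L, 3L), c(8L, 4L), c(12L, 3L), c(15L, 4L)              # denominator
)
ACCEPTOR_NUMERATOR <- 1:5
ACCEPTOR_DENOMINATOR <- 6:9

MES_BACKGROUND <- c(A = 0.27, C = 0.23, G = 0.23, T = 0.27)
MES_CONS1 <- c(A = 0.9903, C = 0.0032, G = 0.0034, T = 0.0030)
MES_CONS2 <- c(A = 0.0027, C = 0.0037, G = 0.9905, T = 0.0030)

kmer_index <- function(kmer) {
  # base-4 rank, A=0 C=1 G=2 T=3, first character most significant
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  chars <- strsplit(kmer, "", fixed = TRUE)[[1]]
  vals <- code[chars]
  if (anyNA(vals)) stop("non-ACGT character in k-mer '", kmer, "'", call. = FALSE)
  sum(vals * 4L^((length(vals) - 1L):0L)) + 1L
}

new_mes_model <- function(submodels, background = MES_BACKGROUND,
                          cons1 = MES_CONS1, cons2 = MES_CONS2,
                          tables_are_ratios = FALSE) {
  stopifnot(length(submodels) == 9L)
  structure(list(site_kind = "acceptor23", submodels = submodels,
                 subsets = ACCEPTOR_SUBSETS, background = background,
                 consensus = list(cons1, cons2),
                 tables_are_ratios = tables_are_ratios),
            class = "mes_model")
}

#' @export
print.mes_model <- function(x, ...) {
  cat(sprintf("<mes_model> %s, 9 submodels (%s)\n", x$site_kind,
              if (x$tables_are_ratios) "probability/background ratios"
              else "maxent probabilities"))
  invisible(x)
}

lookup_submodel <- function(tab, kmer) {
  if (!is.null(names(tab))) {
    val <- tab[kmer]
    if (is.na(val)) {
      stop("k-mer '", kmer, "' is not covered by the (down-sampled) ",
           "model table", call. = FALSE)
    }
    unname(val)
  } else {
    tab[kmer_index(kmer)]
  }
}

#' Load a maximum-entropy acceptor model from table files
#'
#' Expects a directory containing the nine acceptor submodel tables named
#' `me2x3acc1` .. `me2x3acc9` (an optional `.txt` suffix is accepted), each
#' either a full table (one value per line, k-mers in base-4 lexicographic
#' order; lengths 4^7, 4^7, 4^7, 4^7, 4^7, 4^3, 4^4, 4^3, 4^4) or a sparse
#' two-column `kmer<TAB>value` file covering a subset of k-mers.
#'
#' @param dir Directory holding the table files.
#' @param background Per-nucleotide background probabilities.
#' @param cons1,cons2 Consensus nucleotide probabilities for the obligate
#'   AG at window positions 19 and 20.
#' @param tables_are_ratios Set `TRUE` when the table values are already
#'   probability/background ratios (the convention of the original score
#'   distribution); the scorer then skips its own background division.
#' @return An `mes_model` object.
#' @export
load_mes_acceptor_model <- function(dir, background = MES_BACKGROUND,
                                    cons1 = MES_CONS1, cons2 = MES_CONS2,
                                    tables_are_ratios = FALSE) {
  if (!dir.exists(dir)) stop("model directory not found: ", dir, call. = FALSE)
  expected_len <- vapply(ACCEPTOR_SUBSETS, function(s) 4^s[2], numeric(1))
  submodels <- lapply(1:9, function(k) {
    base <- file.path(dir, paste0("me2x3acc", k))
    path <- if (file.exists(base)) base else paste0(base, ".txt")
    if (!file.exists(path)) {
      stop("missing model table file: ", base, "[.txt]", call. = FALSE)
    }
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (any(grepl("\t", lines, fixed = TRUE))) {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      kmers <- toupper(vapply(parts, `[`, character(1), 1L))
      vals <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
      if (anyNA(vals) || any(nchar(kmers) != ACCEPTOR_SUBSETS[[k]][2])) {
        stop("malformed sparse model table: ", path, call. = FALSE)
      }
      stats::setNames(vals, kmers)
    } else {
      vals <- suppressWarnings(as.numeric(lines))
      if (anyNA(vals) || length(vals) != expected_len[k]) {
        stop("malformed or truncated model table: ", path,
             " (expected ", expected_len[k], " values, got ",
             length(vals), ")", call. = FALSE)
      }
      vals
    }
  })
  new_mes_model(submodels, background, cons1, cons2, tables_are_ratios)
}

#' Synthetic maximum-entropy acceptor models
#'
#' `kind = "uniform"` builds a model in which every joint table is the
#' uniform distribution and consensus equals background, so every 23-mer
#' scores exactly 0; it is the closed-form reference point used in tests.
#' `kind = "random"` draws seeded Dirichlet-like submodel tables (uniform
#' Gamma weights, normalized) for property tests.
#'
#' @param kind `"uniform"` or `"random"`.
#' @param seed Seed used for `kind = "random"`.
#' @return An `mes_model`.
#' @export
mes_synthetic_model <- function(kind = c("uniform", "random"), seed = 1L) {
  kind <- match.arg(kind)
  lens <- vapply(ACCEPTOR_SUBSETS, function(s) 4^s[2], numeric(1))
  if (kind == "uniform") {
    submodels <- lapply(lens, function(n) rep(1 / n, n))
    return(new_mes_model(submodels, background = c(A = .25, C = .25, G = .25, T = .25),
                         cons1 = c(A = .25, C = .25, G = .25, T = .25),
                         cons2 = c(A = .25, C = .25, G = .25, T = .25)))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  submodels <- lapply(lens, function(n) {
    w <- stats::rgamma(n, shape = 1)
    w / sum(w)
  })
  new_mes_model(submodels)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

check_window23 <- function(seq23) {
  if (!is.character(seq23) || length(seq23) != 1L) {
    stop("acceptor window must be a single string", call. = FALSE)
  }
  seq23 <- toupper(seq23)
  if (nchar(seq23) != 23L) {
    stop("acceptor window must be exactly 23 nt, got ", nchar(seq23),
         call. = FALSE)
  }
  if (grepl("[^ACGT]", seq23)) {
    stop("acceptor window contains non-ACGT characters", call. = FALSE)
  }
  seq23
}

#' Score a 23-mer acceptor window
#'
#' Returns the log2 odds of the window under the maximum-entropy acceptor
#' model versus background, combining the nine joint submodels by
#' inclusion-exclusion and the obligate-AG positions by their
#' consensus/background odds.
#'
#' @param seq23 A 23-character ACGT string (positions 1-20 intronic,
#'   21-23 exonic).
#' @param model An `mes_model`.
#' @return A single numeric score (log2).
#' @export
score_acceptor <- function(seq23, model) {
  stopifnot(inherits(model, "mes_model"))
  seq23 <- check_window23(seq23)
  s19 <- substr(seq23, 19, 19); s20 <- substr(seq23, 20, 20)
  rest <- paste0(substr(seq23, 1, 18), substr(seq23, 21, 23))

  logp <- vapply(seq_along(model$subsets), function(k) {
    s <- model$subsets[[k]]
    log2(lookup_submodel(model$submodels[[k]], substr(rest, s[1], s[1] + s[2] - 1L)))
  }, numeric(1))
  log_me <- sum(logp[ACCEPTOR_NUMERATOR]) - sum(logp[ACCEPTOR_DENOMINATOR])

  if (!model$tables_are_ratios) {
    chars <- strsplit(rest, "", fixed = TRUE)[[1]]
    log_me <- log_me - sum(log2(model$background[chars]))
  }
  cons_odds <- log2(model$consensus[[1]][[s19]] / model$background[[s19]]) +
    log2(model$consensus[[2]][[s20]] / model$background[[s20]])
  unname(log_me + cons_odds)
}

#' Scan for de novo acceptor sites around a canonical site
#'
#' Slides the 23-mer acceptor window across all offsets within
#' `window_radius` of the canonical 3' intron end and scores every window
#' that satisfies the obligate AG at intronic positions -2/-1. Offsets are
#' reported relative to the canonical intron end (offset 0 = canonical
#' site, positive = downstream/into the exon).
#'
#' @param sequence Genomic-context sequence (ACGT string).
#' @param canonical_offset 1-based position in `sequence` of the last
#'   intronic nucleotide (the G of the canonical AG).
#' @param window_radius Maximum absolute offset to scan.
#' @param model An `mes_model`.
#' @return A data frame with columns `genomic_offset`, `window`,
#'   `mes_score`, `label` (`canonical`/`de_novo`), sorted by score,
#'   possibly empty when no AG falls in the scanned range.
#' @export
scan_de_novo_acceptors <- function(sequence, canonical_offset, window_radius,
                                   model) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) {
    stop("sequence contains non-ACGT characters", call. = FALSE)
  }
  offsets <- seq.int(-window_radius, window_radius)
  starts <- canonical_offset + offsets - 19L
  if (any(starts < 1L) || any(starts + 22L > nchar(sequence))) {
    stop("scan window exceeds the supplied sequence; provide at least ",
         window_radius + 20L, " nt of intron and ", window_radius + 3L,
         " nt of exon context", call. = FALSE)
  }
  rows <- lapply(seq_along(offsets), function(i) {
    w <- substr(sequence, starts[i], starts[i] + 22L)
    if (substr(w, 19, 20) != "AG") return(NULL)
    data.frame(genomic_offset = offsets[i], window = w,
               mes_score = score_acceptor(w, model),
               label = if (offsets[i] == 0L) "canonical" else "de_novo",
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(genomic_offset = integer(), window = character(),
                      mes_score = numeric(), label = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$mes_score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a transcript edit
#'
#' @param kind `"del"`, `"ins"`, `"delins"` or `"none"`.
#' @param cds_start,cds_end 1-based inclusive CDS coordinates of the edited
#'   span (for `ins`, the two flanking positions).
#' @param inserted Inserted sequence (empty for pure deletions).
#' @return A `transcript_edit` object.
#' @export
transcript_edit <- function(kind = c("del", "ins", "delins", "none"),
                            cds_start = NA_integer_, cds_end = NA_integer_,
                            inserted = "") {
  kind <- match.arg(kind)
  if (kind != "none") {
    stopifnot(is_count(cds_start), is_count(cds_end), cds_start <= cds_end)
  }
  structure(list(kind = kind, cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_end),
                 inserted = toupper(inserted)),
            class = "transcript_edit")
}

#' Predict the transcript-level outcome of an acceptor-site shift
#'
#' When a variant damages the canonical acceptor and the strongest
#' alternative lies k nucleotides downstream inside the exon, the spliced
#' transcript loses the first k exonic nucleotides; the edit is expressed
#' in CDS coordinates. Upstream or intronic alternative sites (exon
#' extension, intron retention, exon skipping) are not modelled and raise
#' an error.
#'
#' @param canonical A row (or list) with `genomic_offset` 0 for the
#'   canonical site.
#' @param de_novo A row (or list) with the `genomic_offset` of the used
#'   alternative site.
#' @param exon_cds_start 1-based CDS coordinate of the first nucleotide of
#'   the affected exon.
#' @return A [transcript_edit()]: a deletion of `k` nucleotides starting at
#'   `exon_cds_start`, or `kind = "none"` when the offset is 0.
#' @export
predict_splice_outcome <- function(canonical, de_novo, exon_cds_start) {
  k <- de_novo$genomic_offset
  if (!is.null(canonical$genomic_offset) && canonical$genomic_offset != 0L) {
    stop("canonical call must have genomic_offset 0", call. = FALSE)
  }
  if (k == 0L) return(transcript_edit("none"))
  if (k < 0L) {
    stop("unsupported splice outcome: alternative acceptor upstream of the ",
         "canonical site (exon extension) is not modelled", call. = FALSE)
  }
  transcript_edit("del", cds_start = exon_cds_start,
                  cds_end = exon_cds_start + k - 1L)
}
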