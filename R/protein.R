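# HGVS protein-consequence calling for small CDS edits.

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter", X = "Xaa")

aa3 <- function(aa) unname(AA3[aa])

#' Apply a transcript edit to a coding sequence
#'
#' @param cds Coding sequence (ACGT string starting at the initiator ATG).
#' @param edit A [transcript_edit()].
#' @return The edited sequence.
#' @export
apply_transcript_edit <- function(cds, edit) {
  stopifnot(inherits(edit, "transcript_edit"))
  cds <- toupper(cds)
  n <- nchar(cds)
  if (edit$kind == "none") return(cds)
  if (edit$kind == "ins") {
    if (edit$cds_start < 1L || edit$cds_start > n) {
      stop("insertion point outside the CDS", call. = FALSE)
    }
    return(paste0(substr(cds, 1, edit$cds_start), edit$inserted,
                  substr(cds, edit$cds_start + 1L, n)))
  }
  if (edit$cds_start < 1L || edit$cds_end > n) {
    stop("edit span ", edit$cds_start, "..", edit$cds_end,
         " lies outside the CDS (length ", n, ")", call. = FALSE)
  }
  paste0(substr(cds, 1, edit$cds_start - 1L),
         if (edit$kind == "delins") edit$inserted else "",
         substr(cds, edit$cds_end + 1L, n))
}

translate_aa <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3L
  if (n < 3L) return(character())
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(substr(seq, 1, n)),
                                           no.init.codon = TRUE))
  strsplit(aa, "", fixed = TRUE)[[1]]
}

#' Protein consequence of a CDS edit
#'
#' Applies the edit, translates wild-type and edited sequences and derives
#' the HGVS protein consequence. A length change that is not a multiple of
#' three yields a frameshift `p.<Ref><pos><New>fs*<N>` where the position
#' is the first codon whose residue changes and `N` counts the termination
#' codon of the new reading frame with that first changed residue as 1; a
#' first changed codon that is itself a stop yields a nonsense call; a
#' shifted frame that never reaches a stop is reported as `no_stop`
#' (`fs*?`). In-frame edits are reported as `inframe_del`/`inframe_ins`
#' (clean codon-aligned deletions get `p.Xaa<k>del`-style notation, other
#' in-frame changes a delins description) and edits that leave the protein
#' unchanged as `synonymous`.
#'
#' @param cds Coding sequence starting with ATG, length at least 6.
#' @param edit A [transcript_edit()].
#' @return A `protein_consequence` list with fields `hgvs_p`, `category`,
#'   `first_changed_codon`, `stop_offset` and `warnings`.
#' @export
protein_consequence <- function(cds, edit) {
  cds <- toupper(cds)
  if (nchar(cds) < 6L) stop("CDS shorter than 6 nt", call. = FALSE)
  if (grepl("[^ACGT]", cds)) stop("CDS contains non-ACGT characters", call. = FALSE)
  warnings <- character()
  if (substr(cds, 1, 3) != "ATG") {
    warnings <- c(warnings, "CDS does not start with ATG")
  }
  mut <- apply_transcript_edit(cds, edit)

  wt_aa <- translate_aa(cds)
  wt_stop <- match("*", wt_aa)
  if (!is.na(wt_stop)) wt_aa <- wt_aa[seq_len(wt_stop)]
  mut_aa <- translate_aa(mut)
  mut_stop <- match("*", mut_aa)
  if (!is.na(mut_stop)) mut_aa <- mut_aa[seq_len(mut_stop)]

  result <- function(hgvs, category, k = NA_integer_, stop_offset = NA_integer_) {
    structure(list(hgvs_p = hgvs, category = category,
                   first_changed_codon = as.integer(k),
                   stop_offset = as.integer(stop_offset),
                   warnings = warnings),
              class = "protein_consequence")
  }

  if (edit$kind == "none" || identical(wt_aa, mut_aa)) {
    return(result("p.(=)", "synonymous"))
  }

  shared <- seq_len(min(length(wt_aa), length(mut_aa)))
  diffs <- shared[wt_aa[shared] != mut_aa[shared]]
  k <- if (length(diffs)) diffs[1] else min(length(wt_aa), length(mut_aa)) + 1L

  len_change <- nchar(mut) - nchar(cds)
  if (len_change %% 3L != 0L) {
    # frameshift path
    if (k > length(mut_aa)) {
      # edited frame runs out of sequence before diverging
      return(result("p.?", "no_stop", k))
    }
    new <- mut_aa[k]
    ref <- if (k <= length(wt_aa)) wt_aa[k] else "X"
    if (new == "*") {
      return(result(sprintf("p.%s%dTer", aa3(ref), k), "nonsense", k))
    }
    stop_at <- match("*", mut_aa[k:length(mut_aa)])
    if (is.na(stop_at)) {
      return(result(sprintf("p.%s%d%sfs*?", aa3(ref), k, aa3(new)),
                    "no_stop", k))
    }
    return(result(sprintf("p.%s%d%sfs*%d", aa3(ref), k, aa3(new), stop_at),
                  "frameshift", k, stop_at))
  }

  # in-frame path
  m <- abs(len_change) %/% 3L
  if (len_change < 0L) {
    clean <- length(wt_aa) - m == length(mut_aa) &&
      identical(wt_aa[-(k:(k + m - 1L))], mut_aa)
    if (clean) {
      hgvs <- if (m == 1L) sprintf("p.%s%ddel", aa3(wt_aa[k]), k)
      else sprintf("p.%s%d_%s%ddel", aa3(wt_aa[k]), k,
                   aa3(wt_aa[k + m - 1L]), k + m - 1L)
      return(result(hgvs, "inframe_del", k))
    }
    if (k <= length(mut_aa) && mut_aa[k] == "*") {
      return(result(sprintf("p.%s%dTer", aa3(wt_aa[k]), k), "nonsense", k))
    }
    # deletion with a substituted junction codon: describe as delins
    tail_match <- 0L
    while (tail_match < length(mut_aa) - k &&
           wt_aa[length(wt_aa) - tail_match] == mut_aa[length(mut_aa) - tail_match]) {
      tail_match <- tail_match + 1L
    }
    last_wt <- length(wt_aa) - tail_match
    ins_aa <- mut_aa[k:(length(mut_aa) - tail_match)]
    hgvs <- sprintf("p.%s%d_%s%ddelins%s", aa3(wt_aa[k]), k,
                    aa3(wt_aa[last_wt]), last_wt,
                    paste(aa3(ins_aa), collapse = ""))
    return(result(hgvs, "inframe_del", k))
  }
  if (k <= length(mut_aa) && mut_aa[k] == "*" &&
      (k > length(wt_aa) || wt_aa[k] != "*")) {
    ref <- if (k <= length(wt_aa)) wt_aa[k] else "X"
    return(result(sprintf("p.%s%dTer", aa3(ref), k), "nonsense", k))
  }
  # in-frame insertion/duplication
  ins_aa <- mut_aa[k:(k + m - 1L)]
  hgvs <- sprintf("p.%s%d_%s%dins%s",
                  aa3(if (k > 1L) wt_aa[k - 1L] else "X"), max(k - 1L, 1L),
                  aa3(if (k <= length(wt_aa)) wt_aa[k] else "X"), k,
                  paste(aa3(ins_aa), collapse = ""))
  result(hgvs, "inframe_ins", k)
}

#' @export
print.protein_consequence <- function(x, ...) {
  cat(sprintf("<protein_consequence> %s [%s]%s\n", x$hgvs_p, x$category,
              if (!is.na(x$stop_offset)) sprintf(" stop at fs codon %d", x$stop_offset) else ""))
  invisible(x)
}
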