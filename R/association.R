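# Carrier-frequency case-control association for a single variant:
# 2x2 odds ratio with the Woolf (log-normal) confidence interval.

#' Construct a 2x2 carrier contingency table
#'
#' @param a Case carriers.
#' @param b Control carriers.
#' @param c Case non-carriers.
#' @param d Control non-carriers.
#' @return A `contingency_2x2` object.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (!all(vapply(cells, is_count, logical(1)))) {
    stop("all four cells must be non-negative integers", call. = FALSE)
  }
  structure(as.list(cells), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("<contingency_2x2> cases %d/%d carriers, controls %d/%d carriers\n",
              x$a, x$a + x$c, x$b, x$b + x$d))
  invisible(x)
}

#' Build the carrier table from case and control genotypes
#'
#' A carrier holds at least one ALT allele (dominant model); missing
#' genotypes are excluded from the totals. Case and control sample sets
#' must be disjoint.
#'
#' @param case_genotypes,control_genotypes Named integer vectors of allele
#'   counts (0/1/2, `NA` missing); names are sample IDs.
#' @return A [contingency_2x2()].
#' @export
carrier_table <- function(case_genotypes, control_genotypes) {
  overlap <- intersect(names(case_genotypes), names(control_genotypes))
  if (length(overlap)) {
    stop("case and control sets overlap: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  cs <- case_genotypes[!is.na(case_genotypes)]
  ct <- control_genotypes[!is.na(control_genotypes)]
  contingency_2x2(a = sum(cs >= 1L), b = sum(ct >= 1L),
                  c = sum(cs == 0L), d = sum(ct == 0L))
}

check_cells <- function(t, correct, need = c("b", "c")) {
  stopifnot(inherits(t, "contingency_2x2"))
  cells <- c(a = t$a, b = t$b, c = t$c, d = t$d)
  if (correct) return(cells + 0.5)
  zero <- names(cells)[cells == 0 & names(cells) %in% need]
  if (length(zero)) {
    stop("odds ratio undefined: zero cell(s) ", paste(zero, collapse = ","),
         "; rerun with correct = TRUE for the Haldane-Anscombe correction",
         call. = FALSE)
  }
  cells
}

#' Odds ratio of a 2x2 carrier table
#'
#' @param t A [contingency_2x2()].
#' @param correct Apply the Haldane-Anscombe +0.5 correction to every cell
#'   (off by default; zero denominators raise an error instead).
#' @return The odds ratio `(a*d)/(b*c)`.
#' @export
odds_ratio <- function(t, correct = FALSE) {
  cells <- check_cells(t, correct)
  unname((cells[["a"]] * cells[["d"]]) / (cells[["b"]] * cells[["c"]]))
}

#' Woolf confidence interval for the odds ratio
#'
#' The log-normal approximation
#' `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` with the standard
#' normal quantile `z` for the requested level.
#'
#' @param t A [contingency_2x2()].
#' @param level Confidence level in (0,1); default 0.95.
#' @param correct As in [odds_ratio()]; without it any zero cell errors.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
woolf_ci <- function(t, level = 0.95, correct = FALSE) {
  stopifnot(is_fraction(level), level > 0, level < 1)
  cells <- check_cells(t, correct, need = c("a", "b", "c", "d"))
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(sum(1 / cells))
  unname_ci <- exp(log(or) + c(-1, 1) * z * se)
  c(lower = unname(unname_ci[1]), upper = unname(unname_ci[2]))
}

#' Odds ratio with confidence interval, as a one-row data frame
#'
#' @inheritParams woolf_ci
#' @return Data frame with columns `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `lower`, `upper`, `level`.
#' @export
carrier_association <- function(t, level = 0.95, correct = FALSE) {
  or <- odds_ratio(t, correct)
  ci <- woolf_ci(t, level, correct)
  data.frame(a = t$a, b = t$b, c = t$c, d = t$d,
             odds_ratio = unname(or), lower = ci[["lower"]],
             upper = ci[["upper"]], level = level)
}
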