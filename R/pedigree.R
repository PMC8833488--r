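# Extended-PED pedigrees with phenotype events.
#
# Dialect (tab-separated, '#' comments allowed, one row per individual):
#   family_id  member_id  father_id  mother_id  sex  genotyped  age  events
# father/mother: "0" or "." when absent. sex: 1/male, 2/female, 0/unknown.
# genotyped: 0/1 (whether a DNA sample exists, i.e. a VCF column).
# age: current age in years, "." when unknown.
# events: "." or semicolon-separated descriptors kind:detail:age where kind
# is one of crc, polyps, other_cancer, unaffected; detail is free text (may
# be empty); age is the age at diagnosis or "." (mandatory "." for
# unaffected, which records an explicit negative colonoscopy/screen and
# never carries an age).

EVENT_KINDS <- c("crc", "polyps", "other_cancer", "unaffected")
ROLES <- c("case", "possible_carrier", "control", "uninformative")

new_family <- function(family_id, members) {
  stopifnot(is.data.frame(members))
  fam <- structure(
    list(family_id = family_id, members = members,
         blood_member_ids = character()),
    class = "lofseg_family"
  )
  fam$blood_member_ids <- compute_blood_members(fam)
  fam
}

#' @export
print.lofseg_family <- function(x, ...) {
  m <- x$members
  n_case <- sum(vapply(m$events, function(e) any(e$kind == "crc"), logical(1)))
  cat(sprintf("<lofseg_family> %s: %d members (%d CRC cases, %d genotyped, %d blood)\n",
              x$family_id, nrow(m), n_case, sum(m$genotyped),
              length(x$blood_member_ids)))
  invisible(x)
}

parse_events <- function(field, where) {
  if (is.na(field) || field == "." || field == "") {
    return(data.frame(kind = character(), detail = character(),
                      age = integer(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(field, ";", fixed = TRUE)[[1]]
  rows <- lapply(parts, function(p) {
    bits <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (length(bits) < 1L || length(bits) > 3L) {
      stop("malformed event descriptor '", p, "' at ", where, call. = FALSE)
    }
    kind <- bits[1]
    if (!kind %in% EVENT_KINDS) {
      stop("unknown phenotype event kind '", kind, "' at ", where, call. = FALSE)
    }
    detail <- if (length(bits) >= 2) bits[2] else ""
    age_s <- if (length(bits) >= 3) bits[3] else "."
    age <- if (age_s == "." || age_s == "") NA_integer_ else suppressWarnings(as.integer(age_s))
    if (!is.na(age) && age < 0) stop("negative event age at ", where, call. = FALSE)
    if (kind == "unaffected" && !is.na(age)) {
      stop("'unaffected' events carry no age (", where, ")", call. = FALSE)
    }
    data.frame(kind = kind, detail = detail, age = age, stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  if (sum(ev$kind == "crc") > 1L) {
    stop("more than one CRC event for one individual at ", where, call. = FALSE)
  }
  ev
}

format_events <- function(ev) {
  if (nrow(ev) == 0L) return(".")
  paste(sprintf("%s:%s:%s", ev$kind, ev$detail,
                ifelse(is.na(ev$age), ".", as.character(ev$age))),
        collapse = ";")
}

#' Parse an extended-PED pedigree file
#'
#' Reads the tab-separated extended-PED dialect documented in this package
#' (five standard pedigree columns followed by a genotyped flag, current age
#' and a semicolon-separated phenotype-event list) into one family object
#' per family identifier. Blood membership (the lineage descending from the
#' founding couple, excluding married-in spouses) is computed on
#' construction.
#'
#' @param file Path to a PED file, or a connection. Ignored when `text` is
#'   given.
#' @param text Optional literal PED content as a single string or a
#'   character vector of lines.
#' @return A named list of family objects (names are family IDs). An empty
#'   stream yields an empty list.
#' @seealso [write_pedigree()], [assign_roles()], [youngest_case_age()]
#' @export
parse_pedigree <- function(file, text = NULL) {
  lines <- if (!is.null(text)) {
    unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    readLines(file)
  }
  lines <- trimws(lines, which = "right")
  keep <- nzchar(lines) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  if (length(lines) == 0L) return(structure(list(), names = character()))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 8L)
  if (length(bad)) {
    stop("PED row ", bad[1], " has ", lengths(fields)[bad[1]],
         " columns, expected 8", call. = FALSE)
  }
  tab <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(tab) <- c("family_id", "member_id", "father_id", "mother_id",
                  "sex", "genotyped", "age", "events")

  absent <- function(x) x %in% c("0", ".", "")
  tab$father_id[absent(tab$father_id)] <- NA_character_
  tab$mother_id[absent(tab$mother_id)] <- NA_character_
  tab$sex <- c(`1` = "male", `2` = "female", `0` = "unknown",
               male = "male", female = "female", unknown = "unknown")[tab$sex]
  if (anyNA(tab$sex)) stop("invalid sex code in PED", call. = FALSE)
  tab$genotyped <- tab$genotyped == "1"
  tab$current_age <- ifelse(tab$age == ".", NA_integer_,
                            suppressWarnings(as.integer(tab$age)))
  if (any(!is.na(tab$current_age) & tab$current_age < 0)) {
    stop("negative age in PED", call. = FALSE)
  }

  fams <- split(seq_len(nrow(tab)), tab$family_id)
  out <- lapply(names(fams), function(fid) {
    idx <- fams[[fid]]
    sub <- tab[idx, , drop = FALSE]
    if (anyDuplicated(sub$member_id)) {
      dup <- sub$member_id[duplicated(sub$member_id)][1]
      stop("duplicate member ID '", dup, "' in family ", fid, call. = FALSE)
    }
    for (col in c("father_id", "mother_id")) {
      ref <- sub[[col]]
      dangle <- !is.na(ref) & !(ref %in% sub$member_id)
      if (any(dangle)) {
        row <- which(dangle)[1]
        stop("family ", fid, ", member ", sub$member_id[row],
             ": parent '", ref[row], "' is not a member of the family",
             call. = FALSE)
      }
    }
    events <- lapply(seq_len(nrow(sub)), function(i) {
      parse_events(sub$events[i],
                   sprintf("family %s member %s", fid, sub$member_id[i]))
    })
    members <- data.frame(
      member_id = sub$member_id, father_id = sub$father_id,
      mother_id = sub$mother_id, sex = sub$sex,
      genotyped = sub$genotyped, current_age = sub$current_age,
      stringsAsFactors = FALSE
    )
    members$events <- events
    new_family(fid, members)
  })
  names(out) <- names(fams)
  out
}

#' Write families back to extended-PED
#'
#' Inverse of [parse_pedigree()]; the round trip is lossless.
#'
#' @param families A list of family objects (or a single family).
#' @param file Path or connection to write to.
#' @return `file`, invisibly.
#' @export
write_pedigree <- function(families, file) {
  if (inherits(families, "lofseg_family")) families <- list(families)
  lines <- unlist(lapply(families, function(fam) {
    m <- fam$members
    vapply(seq_len(nrow(m)), function(i) {
      paste(fam$family_id, m$member_id[i],
            ifelse(is.na(m$father_id[i]), "0", m$father_id[i]),
            ifelse(is.na(m$mother_id[i]), "0", m$mother_id[i]),
            c(male = "1", female = "2", unknown = "0")[m$sex[i]],
            ifelse(m$genotyped[i], "1", "0"),
            ifelse(is.na(m$current_age[i]), ".", as.character(m$current_age[i])),
            format_events(m$events[[i]]),
            sep = "\t")
    }, character(1))
  }), use.names = FALSE)
  writeLines(lines, file)
  invisible(file)
}

has_event <- function(members, kind) {
  vapply(members$events, function(e) any(e$kind == kind), logical(1))
}

# Blood membership: lineage founders are the parentless member(s) with the
# greatest number of CRC-case descendants (self included); blood membership
# is their downward closure over parent links. Parentless members outside
# the founding set (married-in spouses) are non-blood, so an affected
# spouse is exempt from the carrier requirement even when one of her
# children is itself a case. With no cases in the family every parentless
# member founds the lineage.
compute_blood_members <- function(family) {
  m <- family$members
  ids <- m$member_id
  if (nrow(m) == 0L) return(character())
  parentless <- is.na(m$father_id) & is.na(m$mother_id)
  is_case <- has_event(m, "crc")

  children_of <- function(id) {
    ids[(!is.na(m$father_id) & m$father_id == id) |
        (!is.na(m$mother_id) & m$mother_id == id)]
  }
  descendants <- function(id) {
    out <- character()
    frontier <- children_of(id)
    while (length(frontier)) {
      out <- union(out, frontier)
      frontier <- setdiff(unlist(lapply(frontier, children_of)), out)
    }
    out
  }

  founders <- ids[parentless]
  if (any(is_case) && length(founders)) {
    ncase <- vapply(founders, function(f) {
      sum(is_case[ids %in% c(f, descendants(f))])
    }, numeric(1))
    if (max(ncase) > 0) founders <- founders[ncase == max(ncase)]
  }

  blood <- founders
  repeat {
    fresh <- ids[!(ids %in% blood) &
                 ((!is.na(m$father_id) & m$father_id %in% blood) |
                  (!is.na(m$mother_id) & m$mother_id %in% blood))]
    if (!length(fresh)) break
    blood <- c(blood, fresh)
  }
  sort(blood)
}

#' Age at diagnosis of the youngest CRC case in a family
#'
#' @param family A family object.
#' @return Integer age in years.
#' @export
youngest_case_age <- function(family) {
  ages <- unlist(lapply(family$members$events, function(e) {
    e$age[e$kind == "crc" & !is.na(e$age)]
  }), use.names = FALSE)
  if (length(ages) == 0L) {
    stop("family ", family$family_id,
         " has no CRC case with a recorded age of diagnosis", call. = FALSE)
  }
  as.integer(min(ages))
}

#' Assign segregation-study roles to family members
#'
#' Members diagnosed with CRC are cases. Members with colonic polyps are
#' possible carriers, as are unaffected offspring of a CRC case who have
#' not yet reached the family's youngest CRC diagnosis age. Members with a
#' non-colorectal cancer count as controls only with an explicit negative
#' colonoscopy on record (an `unaffected` event), otherwise they are
#' uninformative for the colorectal phenotype. Remaining unaffected
#' members are controls when adequately observed - a negative screen on
#' record, or a known age that has reached the family's youngest CRC
#' diagnosis age (members younger than that have not lived through the
#' risk window and stay uninformative rather than constraining the
#' filter). Every member receives exactly one role; the assignment is
#' deterministic.
#'
#' @param family A family object.
#' @return Named character vector mapping `member_id` to one of `case`,
#'   `possible_carrier`, `control`, `uninformative`.
#' @export
assign_roles <- function(family) {
  m <- family$members
  yca <- tryCatch(youngest_case_age(family), error = function(e) NA_integer_)
  crc_by_id <- stats::setNames(has_event(m, "crc"), m$member_id)

  roles <- vapply(seq_len(nrow(m)), function(i) {
    ev <- m$events[[i]]
    if (any(ev$kind == "crc")) return("case")
    if (any(ev$kind == "polyps")) return("possible_carrier")
    parent_ids <- stats::na.omit(c(m$father_id[i], m$mother_id[i]))
    parent_crc <- length(parent_ids) > 0 && any(crc_by_id[parent_ids])
    age <- m$current_age[i]
    if (parent_crc && !is.na(age) && !is.na(yca) && age < yca) {
      return("possible_carrier")
    }
    screened <- any(ev$kind == "unaffected")
    if (any(ev$kind == "other_cancer")) {
      return(if (screened) "control" else "uninformative")
    }
    observed <- screened || (!is.na(age) && (is.na(yca) || age >= yca))
    if (observed) "control" else "uninformative"
  }, character(1))
  stats::setNames(roles, m$member_id)
}
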