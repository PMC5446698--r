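# Rendering of parsed names: canonical and normalized forms, terminal
# authorship, deterministic identifiers and quality scores.

# UUID v5 of "globalnames.org" under the standard DNS namespace; all
# name-string identifiers are v5 digests under this namespace, so the same
# verbatim string always maps to the same identifier everywhere.
DNS_NAMESPACE <- "6ba7b810-9dad-11d1-80b4-00c04fd430c8"
name_namespace <- local({
  ns <- NULL
  function() {
    if (is.null(ns)) ns <<- uuid::UUIDfromName(DNS_NAMESPACE, "globalnames.org")
    ns
  }
})

#' Deterministic UUID v5 identifier for a name-string
#'
#' Computes the UUID version 5 digest of the verbatim name-string under the
#' namespace formed by `"globalnames.org"` in the DNS namespace
#' (`90181196-fecf-5082-a4c1-411d4f314cda`). The identifier is a pure
#' function of the string: equal strings always share an identifier, which
#' makes it usable as a global join key for annotations.
#'
#' @param x character vector of verbatim name-strings.
#' @return character vector of UUIDs.
#' @examples
#' name_uuid("Homo sapiens L.")
#' @export
name_uuid <- function(x) {
  vapply(x, function(s) uuid::UUIDfromName(name_namespace(), s),
         character(1), USE.NAMES = FALSE)
}

#' Quality score from warnings
#'
#' Quality ranges over 1–3 with 1 best: 1 when no warnings were attached,
#' otherwise the maximum warning level (2 = curation nuance, 3 = structural
#' defect).
#'
#' @param warnings list of warnings (each with a `level` field).
#' @return integer in `{1, 2, 3}`.
#' @examples
#' quality_score(list())
#' @export
quality_score <- function(warnings) {
  if (length(warnings) == 0L) return(1L)
  max(vapply(warnings, function(w) as.integer(w$level), integer(1)))
}

# space after each author-initial period: "D.A.Dunlop" -> "D. A. Dunlop"
normalize_author_text <- function(x) {
  gsub("(\\p{Lu}\\p{Ll}{0,2}\\.)(?=[\\p{Lu}])", "\\1 ", x, perl = TRUE)
}

detail_canonical <- function(d) {
  if (!is.null(d$subuninomial)) {
    return(paste(d$uninomial, d$subuninomial))
  }
  if (!is.null(d$uninomial)) return(d$uninomial)
  parts <- c(d$genus, d$specific_epithet$value,
             vapply(d$infraspecific_epithets, `[[`, character(1), "value"))
  paste(parts, collapse = " ")
}

#' Canonical form of a parsed name
#'
#' The latinized elements of the name only — no authors, years, rank markers
#' or annotations — with diacritics folded to ASCII. Hybrid-formula operands
#' are joined with `" × "`; the sign of a named hybrid is dropped. An
#' abbreviated genus in a hybrid-formula operand is kept as written.
#'
#' @param ast a `name_ast` from [parse_name_ast()].
#' @return a single string.
#' @examples
#' canonical_form(parse_name_ast("Homo sapiens L."))
#' @export
canonical_form <- function(ast) {
  stopifnot(inherits(ast, "name_ast"))
  # fold operands individually: the hybrid sign itself must survive folding
  paste(vapply(ast$details,
               function(d) fold_ascii(detail_canonical(d)), character(1)),
        collapse = " × ")
}

# authorship of the lowest-ranked element of a detail, or NULL
detail_terminal_authorship <- function(d) {
  k <- length(d$infraspecific_epithets)
  if (k > 0L) return(d$infraspecific_epithets[[k]]$authorship)
  if (!is.null(d$specific_epithet)) return(d$specific_epithet$authorship)
  d$authorship
}

#' Terminal authorship of a parsed name
#'
#' The authorship attached to the lowest-ranked element: the last
#' infraspecific epithet if any, else the species epithet, else the
#' uninomial. For a hybrid formula the last operand is used. Returns `NA`
#' when no authorship is present anywhere.
#'
#' @param ast a `name_ast`.
#' @return a single string or `NA`.
#' @examples
#' terminal_authorship(
#'   parse_name_ast("Oriastrum lycopodioides Wedd. var. glabriusculum Reiche"))
#' @export
terminal_authorship <- function(ast) {
  stopifnot(inherits(ast, "name_ast"))
  d <- ast$details[[length(ast$details)]]
  au <- detail_terminal_authorship(d)
  if (is.null(au)) NA_character_ else au$verbatim
}

# year of the terminal authorship: combination team first, then basionym
terminal_year <- function(ast) {
  if (!inherits(ast, "name_ast")) return(NA_character_)
  d <- ast$details[[length(ast$details)]]
  au <- detail_terminal_authorship(d)
  if (is.null(au)) return(NA_character_)
  for (team in list(au$combination, au$basionym)) {
    if (!is.null(team) && !is.null(team$year)) return(team$year$value)
  }
  NA_character_
}

normalize_authorship <- function(au) {
  normalize_author_text(au$verbatim)
}

detail_normalized <- function(d) {
  if (!is.null(d$subuninomial)) {
    parts <- c(d$uninomial, d$rank$normalized, d$subuninomial,
               if (!is.null(d$authorship)) normalize_authorship(d$authorship))
    return(paste(parts, collapse = " "))
  }
  if (!is.null(d$uninomial)) {
    parts <- c(d$uninomial,
               if (!is.null(d$authorship)) normalize_authorship(d$authorship),
               if (!is.null(d$annotation)) d$annotation)
    return(paste(parts, collapse = " "))
  }
  parts <- d$genus
  if (!is.null(d$subgenus)) parts <- c(parts, paste0("(", d$subgenus, ")"))
  mid_ann <- !is.null(d$annotation) && d$annotation %in% c("cf.", "aff.")
  if (mid_ann) parts <- c(parts, d$annotation)
  sp <- d$specific_epithet
  parts <- c(parts, sp$value,
             if (!is.null(sp$authorship)) normalize_authorship(sp$authorship))
  for (inf in d$infraspecific_epithets) {
    parts <- c(parts,
               if (!is.null(inf$rank)) inf$rank$normalized,
               inf$value,
               if (!is.null(inf$authorship)) normalize_authorship(inf$authorship))
  }
  if (!is.null(d$annotation) && !mid_ann) parts <- c(parts, d$annotation)
  paste(parts, collapse = " ")
}

#' Normalized form of a parsed name
#'
#' Re-renders the name in a consistent style: single spaces, a space after
#' each author-initial period, rank markers as their canonical abbreviation
#' with trailing period, and the hybrid sign rendered `×`. Everything else is
#' kept verbatim; an ignored tail is dropped.
#'
#' @param ast a `name_ast`.
#' @return a single string.
#' @examples
#' normalized_form(parse_name_ast("Salvelinus fontinalis x Salmo gairdneri"))
#' @export
normalized_form <- function(ast) {
  stopifnot(inherits(ast, "name_ast"))
  body <- paste(vapply(ast$details, detail_normalized, character(1)),
                collapse = " × ")
  if (ast$kind == "named_hybrid") body <- paste0("× ", body)
  body
}
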