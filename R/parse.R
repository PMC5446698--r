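#' Parse scientific name-strings
#'
#' The main pipeline: each raw string is pre-cleaned ([preclean()]), triaged
#' (virus names and structurally hopeless strings never enter the grammar),
#' parsed by the grammar ([parse_name_ast()]) and rendered into its user
#' facing products. Per-string failures never abort the run: an unparseable
#' string yields a row with `parsed = FALSE` and empty forms.
#'
#' @param x character vector of raw name-strings (or a data frame with the
#'   column named by `col`).
#' @param preclean apply the pre-cleaning stage (default `TRUE`); with
#'   `FALSE` the raw string goes to the grammar untouched and dataset fixes
#'   are not attempted.
#' @param col column holding the name-strings when `x` is a data frame.
#' @return A tibble with one row per input, in input order:
#'   `name_string_id` (UUID v5 of the verbatim string), `verbatim`, `parsed`,
#'   `quality` (1–3, `NA` when unparsed), `virus`, `hybrid`, `surrogate`,
#'   `canonical_name`, `normalized`, `terminal_authorship`, `year`, and the
#'   list-columns `warnings`, `details` and `positions` (0-based half-open
#'   code-point offsets into the verbatim string).
#' @examples
#' parse_names(c("Homo sapiens L.", "acid mine drainage metagenome"))
#' @export
parse_names <- function(x, preclean = TRUE, col = "verbatim") {
  if (is.data.frame(x)) x <- x[[col]]
  stopifnot(is.character(x))
  rows <- lapply(x, parse_one, use_preclean = preclean)
  dplyr::bind_rows(rows)
}

#' Parse a single name-string
#'
#' Convenience wrapper around [parse_names()] for one string; returns the
#' full parse result as a list of class `parse_result` (the same content as
#' one row of [parse_names()], plus `parser_version`).
#'
#' @inheritParams parse_names
#' @return a `parse_result` list.
#' @examples
#' parse_name("Carex scirpoidea Michx. subsp. convoluta (Kük.) D.A. Dunlop")
#' @export
parse_name <- function(x, preclean = TRUE) {
  stopifnot(is.character(x), length(x) == 1L)
  row <- parse_one(x, use_preclean = preclean)
  res <- c(as.list(row[, !vapply(row, is.list, logical(1))]),
           lapply(row[, vapply(row, is.list, logical(1))], `[[`, 1L))
  res$parser_version <- parser_version()
  structure(res, class = "parse_result")
}

#' @export
print.parse_result <- function(x, ...) {
  cat("<parse_result> ", x$verbatim, "\n", sep = "")
  if (!x$parsed) {
    cat("  parsed: FALSE", if (x$virus) " (virus)" else "", "\n", sep = "")
  } else {
    cat("  canonical:  ", x$canonical_name, "\n", sep = "")
    cat("  normalized: ", x$normalized, "\n", sep = "")
    if (!is.na(x$terminal_authorship)) {
      cat("  authorship: ", x$terminal_authorship, "\n", sep = "")
    }
    cat("  quality: ", x$quality,
        "  warnings: ", length(x$warnings), "\n", sep = "")
  }
  invisible(x)
}

# characters that only appear through encoding damage: the replacement
# character, C1 control bytes, or byte-escape renderings like "<81>"
GARBAGE_RE <- paste0("[", intToUtf8(0xFFFD), intToUtf8(0x80:0x9F, multiple = FALSE),
                     "]|<[0-9a-fA-F]{2}>")
has_garbage <- function(s) {
  grepl(GARBAGE_RE, s, perl = TRUE)
}

empty_row <- function(raw, id, virus, warns) {
  tibble(
    name_string_id = id, verbatim = raw, parsed = FALSE,
    quality = NA_integer_, virus = virus, hybrid = FALSE, surrogate = FALSE,
    canonical_name = NA_character_, normalized = NA_character_,
    terminal_authorship = NA_character_, year = NA_character_,
    warnings = list(warns), details = list(list()), positions = list(list())
  )
}

parse_one <- function(raw, use_preclean = TRUE) {
  if (is.na(raw)) raw <- ""
  id <- name_uuid(raw)
  if (use_preclean) {
    pc <- preclean_one(raw)
  } else {
    pc <- list(cleaned = raw, fixes = character(0),
               map = seq_len(nchar(raw)) - 1L)
  }
  warns <- lapply(pc$fixes, new_warning)
  if (has_garbage(raw)) warns <- c(warns, list(new_warning("non_ascii_garbage")))

  tri <- triage_name(pc$cleaned)
  if (tri == "virus") return(empty_row(raw, id, virus = TRUE, warns))
  if (tri == "no_parse") return(empty_row(raw, id, virus = FALSE, warns))

  ast <- parse_name_ast(pc$cleaned)
  if (inherits(ast, "name_parse_failure")) {
    return(empty_row(raw, id, virus = FALSE, warns))
  }
  warns <- c(warns, ast$warnings)

  # project element spans from the cleaned string back onto the verbatim one
  positions <- lapply(ast$positions, function(t) {
    list(label = t$label,
         start = pc$map[t$start + 1L],
         end = pc$map[t$end] + 1L)
  })

  tibble(
    name_string_id = id,
    verbatim = raw,
    parsed = TRUE,
    quality = quality_score(warns),
    virus = FALSE,
    hybrid = ast$kind %in% c("named_hybrid", "hybrid_formula"),
    surrogate = detect_surrogate(ast, pc$cleaned),
    canonical_name = canonical_form(ast),
    normalized = normalized_form(ast),
    terminal_authorship = terminal_authorship(ast),
    year = terminal_year(ast),
    warnings = list(warns),
    details = list(lapply(ast$details, detail_public)),
    positions = list(positions)
  )
}

# public (serialization-ready) view of one NameDetail: author names are
# normalized, teams flattened to character vectors
detail_public <- function(d) {
  team_pub <- function(team) {
    if (is.null(team)) return(NULL)
    out <- list(authors = I(as.character(normalize_author_text(team$authors))))
    if (length(team$ex_authors) > 0L) {
      out$ex_authors <- I(as.character(normalize_author_text(team$ex_authors)))
    }
    if (!is.null(team$year)) out$year <- team$year$value
    out
  }
  auth_pub <- function(au) {
    if (is.null(au)) return(NULL)
    out <- list(verbatim = au$verbatim)
    b <- team_pub(au$basionym)
    k <- team_pub(au$combination)
    if (!is.null(b)) out$basionym_authorship <- b
    if (!is.null(k)) out$combination_authorship <- k
    out
  }
  out <- list()
  if (!is.null(d$uninomial)) {
    out$uninomial <- d$uninomial
    if (!is.null(d$rank)) out$rank <- d$rank$normalized
    if (!is.null(d$subuninomial)) out$subuninomial <- d$subuninomial
    if (!is.null(d$authorship)) out$authorship <- auth_pub(d$authorship)
  } else {
    out$genus <- d$genus
    if (!is.null(d$subgenus)) out$subgenus <- d$subgenus
    sp <- d$specific_epithet
    if (!is.null(sp)) {
      out$specific_epithet <- c(
        list(value = sp$value),
        if (!is.null(sp$authorship)) list(authorship = auth_pub(sp$authorship))
      )
    }
    if (length(d$infraspecific_epithets) > 0L) {
      out$infraspecific_epithets <- lapply(d$infraspecific_epithets,
        function(inf) {
          c(list(value = inf$value),
            if (!is.null(inf$rank)) list(rank = inf$rank$normalized),
            if (!is.null(inf$authorship))
              list(authorship = auth_pub(inf$authorship)))
        })
    }
  }
  if (!is.null(d$annotation)) out$annotation <- d$annotation
  if (!is.null(d$ignored_tail)) out$ignored_tail <- d$ignored_tail
  out
}
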