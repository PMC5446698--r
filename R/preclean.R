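#' Pre-clean name-strings before parsing
#'
#' Normalizes corruptions that are common in aggregated biodiversity datasets
#' before the string reaches the grammar: underscores standing in for spaces
#' (`Homo_sapiens`), runs of whitespace, and leading/trailing whitespace.
#' Each applied fix is recorded and later surfaced as a quality warning on the
#' parse result. The operation is total and idempotent: a clean string is a
#' fixed point, and re-cleaning a cleaned string applies no fixes.
#'
#' @param x character vector of raw name-strings.
#' @return A tibble with one row per input: `verbatim`, `cleaned`, `fixes`
#'   (list-column of fix identifiers, empty when the string was untouched) and
#'   `triage` (see [triage_name()]).
#' @examples
#' preclean("Homo_sapiens")
#' preclean("  Carex   scirpoidea ")
#' @export
preclean <- function(x) {
  stopifnot(is.character(x))
  res <- lapply(x, preclean_one)
  tibble(
    verbatim = x,
    cleaned  = vapply(res, `[[`, character(1), "cleaned"),
    fixes    = lapply(res, `[[`, "fixes"),
    triage   = vapply(res, function(r) triage_name(r$cleaned), character(1))
  )
}

# Single-string worker. Besides the cleaned text and fix ids it returns `map`,
# a 0-based offset into the verbatim string for every code point of the
# cleaned string, so element positions found by the grammar can be projected
# back onto the original input.
preclean_one <- function(raw) {
  if (is.na(raw)) raw <- ""
  ch <- strsplit(raw, "", fixed = FALSE)[[1]]
  n <- length(ch)
  if (n == 0L) {
    return(list(cleaned = "", fixes = character(0), map = integer(0)))
  }
  is_letter <- grepl("^\\p{L}$", ch, perl = TRUE)
  is_space  <- grepl("^\\s$", ch, perl = TRUE)
  is_under  <- ch == "_"

  out <- character(0)
  map <- integer(0)
  fixes <- character(0)
  i <- 1L
  while (i <= n) {
    if (is_under[i]) {
      j <- i
      while (j < n && is_under[j + 1L]) j <- j + 1L
      prev_letter <- length(out) > 0L &&
        grepl("^\\p{L}$", out[length(out)], perl = TRUE)
      next_letter <- j < n && is_letter[j + 1L]
      if (prev_letter && next_letter) {
        out <- c(out, " ")
        map <- c(map, i - 1L)
        fixes <- union(fixes, "underscore_as_space")
      } else {
        out <- c(out, ch[i:j])
        map <- c(map, (i:j) - 1L)
      }
      i <- j + 1L
    } else if (is_space[i]) {
      j <- i
      while (j < n && is_space[j + 1L]) j <- j + 1L
      at_edge <- length(out) == 0L || j == n
      if (!at_edge) {
        out <- c(out, " ")
        map <- c(map, i - 1L)
        if (j > i || ch[i] != " ") {
          fixes <- union(fixes, "multiple_spaces_fixed")
        }
      }
      i <- j + 1L
    } else {
      out <- c(out, ch[i])
      map <- c(map, i - 1L)
      i <- i + 1L
    }
  }
  list(cleaned = paste(out, collapse = ""), fixes = fixes, map = map)
}

#' Triage a cleaned name-string
#'
#' Decides whether a string should enter the grammar at all. Virus and
#' virus-like agent names follow naming conventions the grammar does not
#' model, so they are flagged and skipped; strings whose first token does not
#' start with an uppercase letter (after any leading hybrid sign) cannot be
#' code-compliant scientific names and are discarded, mirroring the failure
#' mode of parsers that accept lowercase genera.
#'
#' @param x character vector of cleaned name-strings.
#' @return character vector over `{"none", "virus", "no_parse"}`.
#' @examples
#' triage_name("Vesicular stomatitis Indiana virus")
#' triage_name("acid mine drainage metagenome")
#' triage_name("Homo sapiens")
#' @export
triage_name <- function(x) {
  vapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return("no_parse")
    kw <- paste(VIRUS_KEYWORDS, collapse = "|")
    if (grepl(paste0("\\b(?:", kw, ")\\b"), s, perl = TRUE, ignore.case = TRUE)) {
      return("virus")
    }
    # a leading hybrid sign is legitimate in named hybrids; look past it
    s2 <- sub("^(?:×|[xX](?=\\s))\\s*", "", s, perl = TRUE)
    if (!nzchar(s2) || !grepl("^\\p{Lu}", s2, perl = TRUE)) return("no_parse")
    "none"
  }, character(1), USE.NAMES = FALSE)
}
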