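# Compact JSON and simple TSV renderings of parse results.

result_row_to_list <- function(row) {
  parsed <- row$parsed
  out <- list(name_string_id = row$name_string_id, parsed = parsed)
  if (parsed) out$quality <- as.integer(row$quality)
  out$parser_version <- parser_version()
  out$verbatim <- row$verbatim
  if (parsed) {
    out$normalized <- row$normalized
    out$canonical_name <- row$canonical_name
  }
  out$hybrid <- row$hybrid
  out$surrogate <- row$surrogate
  out$virus <- row$virus
  out$details <- if (parsed) row$details[[1]] else list()
  out$positions <- if (parsed) {
    lapply(row$positions[[1]], function(t) list(t$label, t$start, t$end))
  } else {
    list()
  }
  out$quality_warnings <- lapply(row$warnings[[1]], function(w) {
    list(code = w$code, message = w$message, level = as.integer(w$level))
  })
  out
}

#' Render parse results as compact JSON
#'
#' One single-line JSON document per result, with a fixed key order so output
#' is byte-stable across runs. Unparsed strings carry `"parsed": false` and
#' no `quality`, `normalized` or `canonical_name` keys. Positions are
#' `[label, start, end]` triples with 0-based half-open code-point offsets
#' into the verbatim string. Documents validate against the schema shipped in
#' `inst/extdata/parse-result-schema.json` (see [validate_result_json()]).
#'
#' @param results a tibble from [parse_names()] (or a single `parse_result`).
#' @return character vector of JSON lines, one per result.
#' @examples
#' render_compact_json(parse_names("Homo sapiens L."))
#' @export
render_compact_json <- function(results) {
  results <- as_result_tbl(results)
  vapply(seq_len(nrow(results)), function(i) {
    as.character(jsonlite::toJSON(result_row_to_list(results[i, ]),
                                  auto_unbox = TRUE, null = "null"))
  }, character(1))
}

#' Render parse results as simple tab-separated records
#'
#' One TSV row per result: `name_string_id`, `verbatim`, `canonical_name`,
#' `terminal_authorship`, `year`, `quality`. Fields are empty for unparsed
#' strings. No quoting is applied; tabs cannot occur inside the fields.
#'
#' @param results a tibble from [parse_names()] (or a single `parse_result`).
#' @param header prepend a header row.
#' @return character vector of TSV lines.
#' @examples
#' render_simple(parse_names("Homo sapiens L."))
#' @export
render_simple <- function(results, header = FALSE) {
  results <- as_result_tbl(results)
  blank <- function(x) ifelse(is.na(x), "", as.character(x))
  lines <- paste(
    results$name_string_id,
    blank(results$verbatim),
    blank(results$canonical_name),
    blank(results$terminal_authorship),
    blank(results$year),
    blank(results$quality),
    sep = "\t"
  )
  if (header) {
    lines <- c(paste("name_string_id", "verbatim", "canonical_name",
                     "terminal_authorship", "year", "quality", sep = "\t"),
               lines)
  }
  lines
}

as_result_tbl <- function(results) {
  if (inherits(results, "parse_result")) {
    scalars <- !vapply(results, is.list, logical(1))
    tb <- as_tibble(unclass(results)[scalars])
    tb$parser_version <- NULL
    tb$warnings <- list(results$warnings)
    tb$details <- list(results$details)
    tb$positions <- list(results$positions)
    return(tb)
  }
  stopifnot(is.data.frame(results))
  results
}

schema_path <- function() {
  system.file("extdata", "parse-result-schema.json", package = "taxparse")
}

#' Validate a compact-JSON parse document against the shipped schema
#'
#' A structural validator for the JSON documents produced by
#' [render_compact_json()]: checks required keys, value types, enumerations
#' (quality levels, position labels) and the cross-field invariants (an
#' unparsed document carries no canonical or normalized form; quality is 1
#' exactly when no warnings are present).
#'
#' @param json character vector of single-line JSON documents.
#' @return logical vector; attribute `"errors"` lists the first problem found
#'   for each invalid document.
#' @examples
#' validate_result_json(render_compact_json(parse_names("Homo sapiens")))
#' @export
validate_result_json <- function(json) {
  errs <- character(length(json))
  ok <- vapply(seq_along(json), function(i) {
    doc <- tryCatch(jsonlite::fromJSON(json[i], simplifyVector = FALSE),
                    error = function(e) NULL)
    msg <- validate_result_doc(doc)
    errs[i] <<- msg %||% ""
    is.null(msg)
  }, logical(1))
  attr(ok, "errors") <- errs
  ok
}

POSITION_LABELS <- c("genus", "subgenus", "uninomial", "specific_epithet",
                     "infraspecific_epithet", "rank", "author_word", "year",
                     "annotation", "hybrid_sign")

validate_result_doc <- function(doc) {
  if (is.null(doc)) return("not valid JSON")
  need <- c("name_string_id", "parsed", "parser_version", "verbatim",
            "hybrid", "surrogate", "virus", "details", "positions",
            "quality_warnings")
  missing <- setdiff(need, names(doc))
  if (length(missing) > 0L) {
    return(paste("missing fields:", paste(missing, collapse = ", ")))
  }
  if (!grepl("^[0-9a-f]{8}-[0-9a-f]{4}-5[0-9a-f]{3}-[0-9a-f]{4}-[0-9a-f]{12}$",
             doc$name_string_id)) {
    return("name_string_id is not a UUID v5")
  }
  if (!is.logical(doc$parsed)) return("parsed is not boolean")
  for (f in c("hybrid", "surrogate", "virus")) {
    if (!is.logical(doc[[f]])) return(paste(f, "is not boolean"))
  }
  if (doc$parsed) {
    if (is.null(doc$quality) || !doc$quality %in% 1:3) {
      return("quality of a parsed name must be 1, 2 or 3")
    }
    if (is.null(doc$canonical_name) || is.null(doc$normalized)) {
      return("parsed document lacks canonical/normalized form")
    }
    nwarn <- length(doc$quality_warnings)
    if ((doc$quality == 1L) != (nwarn == 0L)) {
      return("quality 1 must coincide with an empty warning list")
    }
  } else {
    for (f in c("quality", "canonical_name", "normalized")) {
      if (!is.null(doc[[f]])) {
        return(paste("unparsed document must not carry", f))
      }
    }
    if (length(doc$details) != 0L || length(doc$positions) != 0L) {
      return("unparsed document must have empty details and positions")
    }
  }
  n <- nchar(doc$verbatim)
  for (p in doc$positions) {
    if (length(p) != 3L) return("position is not a [label, start, end] triple")
    if (!p[[1]] %in% POSITION_LABELS) {
      return(paste("unknown position label", p[[1]]))
    }
    if (p[[2]] < 0 || p[[3]] > n || p[[2]] >= p[[3]]) {
      return("position offsets outside the verbatim string")
    }
  }
  for (w in doc$quality_warnings) {
    if (!all(c("code", "message", "level") %in% names(w))) {
      return("warning lacks code/message/level")
    }
    if (!w$level %in% 2:3) return("warning level must be 2 or 3")
  }
  NULL
}
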