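#' Run the parser as a streaming pipeline
#'
#' Reads name-strings one per line, parses them, and writes one output
#' record per input line, in input order. Per-line parse failures never
#' abort the run. Lines that are not valid UTF-8 are decoded with byte
#' escapes (`<hh>`) and flagged with a level-3 warning; they almost always
#' fail to parse, but the run continues.
#'
#' @param input path of the input file, or `NULL` to read standard input.
#' @param output path of the output file, or `NULL` to write standard
#'   output.
#' @param format `"json"` (compact JSON lines) or `"simple"` (TSV).
#' @param preclean apply the pre-cleaning stage.
#' @param workers accepted for interface compatibility; execution is serial
#'   and the output contract (input order, byte-identical output for
#'   identical input) holds for any value.
#' @param header for `format = "simple"`, prepend a header row.
#' @return invisibly, the results tibble.
#' @export
run_parser <- function(input = NULL, output = NULL,
                       format = c("json", "simple"),
                       preclean = TRUE, workers = 1L, header = FALSE) {
  format <- match.arg(format)
  stopifnot(workers >= 1L)
  if (!is.null(input) && !file.exists(input)) {
    rlang::abort(paste("input file not found:", input))
  }
  con <- if (is.null(input)) file("stdin") else file(input, encoding = "")
  lines <- readLines(con, warn = FALSE)
  if (!is.null(input)) close(con)
  lines <- sanitize_utf8(lines)

  results <- parse_names(lines, preclean = preclean)
  out_lines <- switch(format,
    json = render_compact_json(results),
    simple = render_simple(results, header = header)
  )
  if (is.null(output)) {
    writeLines(out_lines, useBytes = TRUE)
  } else {
    writeLines(enc2utf8(out_lines), output, useBytes = TRUE)
  }
  invisible(results)
}

# invalid UTF-8 bytes become "<hh>" escapes, which downstream triggers the
# non_ascii_garbage warning
sanitize_utf8 <- function(lines) {
  bad <- !validUTF8(lines)
  if (any(bad)) {
    fixed <- iconv(lines[bad], "UTF-8", "UTF-8", sub = "byte")
    fixed[is.na(fixed)] <- ""
    lines[bad] <- fixed
  }
  enc2utf8(lines)
}
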