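# Evaluation harness: outcome labelling against a gold standard and the
# standard retrieval metrics over the resulting confusion counts.

norm_cmp <- function(x) {
  out <- fold_ascii(squish(ifelse(is.na(x), "", x)))
  out
}

#' Label parse outcomes against a gold standard
#'
#' A parsed name counts as a true positive only when both its canonical form
#' and its terminal authorship match the gold record (after whitespace
#' normalization and ASCII folding; comparison is case-sensitive). A parsed
#' name with either field wrong — or parsed although the gold standard deems
#' the string unparseable — is a false positive. A string correctly
#' discarded from parsing is a true negative; one wrongly discarded is a
#' false negative.
#'
#' @param results tibble from [parse_names()].
#' @param gold tibble with columns `verbatim`, `parseable`, `canonical`,
#'   `terminal_authorship` (empty/`NA` allowed when `parseable` is `FALSE`).
#' @return character vector over `{"tp", "tn", "fp", "fn"}`, one per row.
#' @export
label_outcome <- function(results, gold) {
  stopifnot(nrow(results) == nrow(gold))
  if (!all(results$verbatim == gold$verbatim)) {
    rlang::abort("results and gold must list the same verbatim strings in the same order")
  }
  parsed <- results$parsed
  ok <- norm_cmp(results$canonical_name) == norm_cmp(gold$canonical) &
    norm_cmp(results$terminal_authorship) == norm_cmp(gold$terminal_authorship)
  dplyr::case_when(
    parsed & gold$parseable & ok ~ "tp",
    parsed                       ~ "fp",
    !parsed & !gold$parseable    ~ "tn",
    TRUE                         ~ "fn"
  )
}

#' Tally outcome labels into confusion counts
#'
#' @param outcomes character vector over `{"tp", "tn", "fp", "fn"}`.
#' @return one-row tibble with `n_tp`, `n_tn`, `n_fp`, `n_fn`.
#' @examples
#' tally_outcomes(c("tp", "tp", "fp"))
#' @export
tally_outcomes <- function(outcomes) {
  stopifnot(all(outcomes %in% c("tp", "tn", "fp", "fn")))
  tibble(
    n_tp = sum(outcomes == "tp"),
    n_tn = sum(outcomes == "tn"),
    n_fp = sum(outcomes == "fp"),
    n_fn = sum(outcomes == "fn")
  )
}

#' Precision, recall, accuracy and F1 from confusion counts
#'
#' Accuracy is the proportion of all results that were correct,
#' `(tp + tn) / (tp + tn + fp + fn)`; precision is `tp / (tp + fp)`; recall
#' is `tp / (tp + fn)`; F1 is the harmonic mean of precision and recall,
#' computed from their unrounded values. A metric whose denominator is zero
#' is undefined and reported as `NA`, never as 0. Values are rounded half-up
#' to `digits` decimals.
#'
#' @param counts one-row data frame (or named list/vector) with `n_tp`,
#'   `n_tn`, `n_fp`, `n_fn`.
#' @param digits decimals to round to (default 3).
#' @return one-row tibble with `precision`, `recall`, `accuracy`, `f1`.
#' @examples
#' compute_metrics(tibble::tibble(n_tp = 955, n_tn = 12, n_fp = 32, n_fn = 1))
#' @export
compute_metrics <- function(counts, digits = 3L) {
  counts <- as.list(counts)
  tp <- as.numeric(counts$n_tp)
  tn <- as.numeric(counts$n_tn)
  fp <- as.numeric(counts$n_fp)
  fn <- as.numeric(counts$n_fn)
  stopifnot(all(c(tp, tn, fp, fn) >= 0))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  accuracy <- ratio(tp + tn, tp + tn + fp + fn)
  f1 <- f_measure(precision, recall, digits = digits)
  tibble(
    precision = round_half_up(precision, digits),
    recall = round_half_up(recall, digits),
    accuracy = round_half_up(accuracy, digits),
    f1 = f1
  )
}

#' F1 measure from precision and recall
#'
#' The balanced harmonic mean `2 P R / (P + R)`, rounded half-up.
#'
#' @param precision,recall values in `[0, 1]`.
#' @param digits decimals to round to.
#' @return numeric value (or `NA` when undefined).
#' @examples
#' f_measure(0.534, 1.0, digits = 4)
#' @export
f_measure <- function(precision, recall, digits = 3L) {
  if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    return(NA_real_)
  }
  round_half_up(2 * precision * recall / (precision + recall), digits)
}

#' Accuracy of non-parseable string detection
#'
#' Among the strings a parser discarded, the proportion it was right to
#' discard.
#'
#' @param correct_discards number of discarded strings that are indeed not
#'   scientific names.
#' @param total_discards total number of discarded strings (> 0).
#' @param digits decimals to round to (default 3).
#' @return a proportion in `[0, 1]`, or `NA` when `total_discards` is zero.
#' @examples
#' discard_accuracy(1129, 1131)
#' @export
discard_accuracy <- function(correct_discards, total_discards, digits = 3L) {
  stopifnot(correct_discards >= 0, total_discards >= correct_discards)
  if (total_discards == 0) return(NA_real_)
  round_half_up(correct_discards / total_discards, digits)
}

#' Evaluate parse results against a gold standard
#'
#' Joins results and gold records by verbatim string, labels every outcome
#' ([label_outcome()]), tallies the confusion counts and computes the four
#' metrics. The returned object supports [tidy()], [glance()], [autoplot()]
#' and `print()`.
#'
#' @param results tibble from [parse_names()].
#' @param gold gold-standard tibble with columns `verbatim`, `parseable`,
#'   `canonical`, `terminal_authorship`.
#' @return an object of class `name_evaluation`: a list with `data` (the
#'   joined per-name table with an `outcome` column), `counts` and `metrics`.
#' @examples
#' corpus <- generate_corpus(50, seed = 1)
#' ev <- evaluate_names(parse_names(corpus$name), as_gold(corpus))
#' glance(ev)
#' @export
evaluate_names <- function(results, gold) {
  stopifnot(is.data.frame(results), is.data.frame(gold))
  gold <- dplyr::rename_with(gold, tolower)
  need <- c("verbatim", "parseable", "canonical", "terminal_authorship")
  missing <- setdiff(need, names(gold))
  if (length(missing) > 0L) {
    rlang::abort(paste("gold standard lacks columns:",
                       paste(missing, collapse = ", ")))
  }
  gold_cols <- dplyr::select(gold, dplyr::all_of(need))
  names(gold_cols) <- c("verbatim", "parseable_gold", "canonical_gold",
                        "terminal_authorship_gold")
  if (nrow(results) == nrow(gold_cols) &&
      all(results$verbatim == gold_cols$verbatim)) {
    # aligned row-by-row: pair positionally, which stays correct even when
    # the same name-string occurs more than once
    joined <- dplyr::bind_cols(results, gold_cols[-1])
  } else {
    gold_cols <- dplyr::distinct(gold_cols, .data$verbatim,
                                 .keep_all = TRUE)
    joined <- dplyr::inner_join(results, gold_cols, by = "verbatim")
    if (nrow(joined) < nrow(results)) {
      rlang::abort("some parsed strings have no gold record")
    }
  }
  joined$outcome <- label_outcome(
    joined, dplyr::tibble(verbatim = joined$verbatim,
                          parseable = joined$parseable_gold,
                          canonical = joined$canonical_gold,
                          terminal_authorship = joined$terminal_authorship_gold))
  counts <- tally_outcomes(joined$outcome)
  structure(
    list(data = joined, counts = counts, metrics = compute_metrics(counts)),
    class = "name_evaluation"
  )
}

#' @export
print.name_evaluation <- function(x, ...) {
  cat("<name_evaluation> ", nrow(x$data), " name-strings\n", sep = "")
  cat(sprintf("  tp %d  tn %d  fp %d  fn %d\n",
              x$counts$n_tp, x$counts$n_tn, x$counts$n_fp, x$counts$n_fn))
  m <- x$metrics
  cat(sprintf("  precision %.3f  recall %.3f  accuracy %.3f  f1 %.3f\n",
              m$precision, m$recall, m$accuracy, m$f1))
  invisible(x)
}

#' @rdname evaluate_names
#' @param x a `name_evaluation` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.name_evaluation <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @rdname evaluate_names
#' @exportS3Method generics::glance
glance.name_evaluation <- function(x, ...) {
  dplyr::bind_cols(x$counts, x$metrics,
                   tibble(n = nrow(x$data)))
}

#' @rdname evaluate_names
#' @param object a `name_evaluation` object.
#' @exportS3Method ggplot2::autoplot
autoplot.name_evaluation <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$value)),
                       vjust = -0.4, size = 3.2) +
    ggplot2::scale_y_continuous(limits = c(0, 1.05),
                                expand = ggplot2::expansion(mult = c(0, 0))) +
    ggplot2::labs(x = NULL, y = "value",
                  title = "Parser evaluation metrics") +
    ggplot2::theme_minimal()
}

#' Read a gold-standard TSV file
#'
#' Expected columns (tab-separated, with header): `verbatim`, `parseable`
#' (`true`/`false`), `canonical`, `terminal_authorship`.
#'
#' @param path file path.
#' @return tibble suitable for [evaluate_names()].
#' @export
read_gold_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE, encoding = "UTF-8",
                          na.strings = NULL)
  df$parseable <- tolower(as.character(df$parseable)) %in% c("true", "t", "1")
  as_tibble(df)
}
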