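#' Quality profile of a batch of parse results
#'
#' Bar chart of the quality distribution (1 = flawless, 2 = curation
#' nuances, 3 = structural defects, unparsed shown separately), a quick
#' visual check of how well-formed a dataset's name-strings are.
#'
#' @param results tibble from [parse_names()].
#' @return a ggplot object.
#' @examples
#' plot_quality(parse_names(c("Homo sapiens", "Homo_sapiens", "x y")))
#' @export
plot_quality <- function(results) {
  df <- dplyr::mutate(
    results,
    grade = factor(ifelse(is.na(.data$quality), "unparsed",
                          as.character(.data$quality)),
                   levels = c("1", "2", "3", "unparsed"))
  )
  df <- dplyr::count(df, .data$grade, .drop = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$grade, y = .data$n)) +
    ggplot2::geom_col(fill = "grey35", width = 0.65) +
    ggplot2::labs(x = "quality", y = "name-strings",
                  title = "Name-string quality profile") +
    ggplot2::theme_minimal()
}
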