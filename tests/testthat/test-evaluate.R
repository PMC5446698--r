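test_that("metric formulas reproduce published benchmark arithmetic", {
  # counts and printed metrics for two independently reported parsers serve
  # as the arithmetic oracle for the formulas
  gbif <- compute_metrics(tibble::tibble(n_tp = 955, n_tn = 12,
                                         n_fp = 32, n_fn = 1))
  expect_equal(gbif$precision, 0.968)
  expect_equal(gbif$recall, 0.999)
  expect_equal(gbif$accuracy, 0.967)
  expect_equal(gbif$f1, 0.983)

  biod <- compute_metrics(tibble::tibble(n_tp = 971, n_tn = 13,
                                         n_fp = 16, n_fn = 0))
  expect_equal(biod$precision, 0.984)
  expect_equal(biod$recall, 1.0)
  expect_equal(biod$accuracy, 0.984)
  expect_equal(biod$f1, 0.992)

  expect_equal(f_measure(0.534, 1.0, digits = 4), 0.6962)
})

test_that("discard accuracy reproduces published detection rates", {
  expect_equal(discard_accuracy(1129, 1131), 0.998)
  expect_equal(discard_accuracy(940, 1082), 0.869)
  expect_equal(discard_accuracy(1152, 1161), 0.992)
  expect_equal(discard_accuracy(5, 5), 1.0)
  expect_true(is.na(discard_accuracy(0, 0)))
})

test_that("a perfect classifier scores 1 and zero denominators yield NA", {
  perfect <- compute_metrics(list(n_tp = 10, n_tn = 0, n_fp = 0, n_fn = 0))
  expect_equal(unlist(perfect), c(precision = 1, recall = 1,
                                  accuracy = 1, f1 = 1))
  none <- compute_metrics(list(n_tp = 0, n_tn = 5, n_fp = 0, n_fn = 0))
  expect_true(is.na(none$precision))
  expect_true(is.na(none$recall))
  expect_equal(none$accuracy, 1)
})

test_that("metric invariants hold over random confusion counts", {
  set.seed(42)
  for (i in 1:200) {
    counts <- list(n_tp = sample(0:500, 1), n_tn = sample(0:50, 1),
                   n_fp = sample(0:50, 1), n_fn = sample(0:50, 1))
    m <- compute_metrics(counts)
    vals <- unlist(m)
    expect_true(all(is.na(vals) | (vals >= 0 & vals <= 1)))
    if (!any(is.na(vals))) {
      expect_lte(m$f1, max(m$precision, m$recall) + 5e-4)
      if (m$precision == m$recall) {
        expect_equal(m$f1, m$precision, tolerance = 1e-3)
      }
    }
  }
})

test_that("outcome labelling follows the canonical/authorship double check", {
  gold <- tibble::tibble(
    verbatim = c("Oriastrum lycopodioides Wedd. var. glabriusculum Reiche",
                 "Vesicular stomatitis Indiana virus",
                 "Homo sapiens L."),
    parseable = c(TRUE, FALSE, TRUE),
    canonical = c("Oriastrum lycopodioides glabriusculum", "", "Homo sapiens"),
    terminal_authorship = c("Reiche", "", "L."))
  res <- parse_names(gold$verbatim)
  expect_equal(label_outcome(res, gold), c("tp", "tn", "tp"))

  # wrong terminal authorship in gold turns a parse into a false positive
  gold2 <- gold
  gold2$terminal_authorship[1] <- "Wedd."
  expect_equal(label_outcome(res, gold2)[1], "fp")

  # parsed but gold says non-parseable is a false positive; unparsed but
  # parseable is a false negative
  gold3 <- gold
  gold3$parseable[3] <- FALSE
  gold3$canonical[3] <- ""
  gold3$terminal_authorship[3] <- ""
  expect_equal(label_outcome(res, gold3)[3], "fp")
  gold4 <- gold
  gold4$parseable[2] <- TRUE
  gold4$canonical[2] <- "Vesicular stomatitis"
  expect_equal(label_outcome(res, gold4)[2], "fn")
})

test_that("tallying preserves totals", {
  expect_equal(unlist(tally_outcomes(c("tp", "tp", "fp"))),
               c(n_tp = 2L, n_tn = 0L, n_fp = 1L, n_fn = 0L))
  expect_equal(unlist(tally_outcomes(character(0))),
               c(n_tp = 0L, n_tn = 0L, n_fp = 0L, n_fn = 0L))
  set.seed(1)
  labels <- sample(c("tp", "tn", "fp", "fn"), 1000, replace = TRUE)
  expect_equal(sum(unlist(tally_outcomes(labels))), 1000L)
})

test_that("evaluate_names produces tidy, glance and plot views", {
  corpus <- generate_corpus(200, seed = 3)
  ev <- evaluate_names(parse_names(corpus$name), as_gold(corpus))
  td <- tidy(ev)
  expect_setequal(td$metric, c("precision", "recall", "accuracy", "f1"))
  gl <- glance(ev)
  expect_equal(gl$n, 200L)
  expect_equal(gl$n_tp + gl$n_tn + gl$n_fp + gl$n_fn, 200L)
  p <- ggplot2::autoplot(ev)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_quality(parse_names(corpus$name)), "ggplot")
})

test_that("gold TSV round-trips through write and read", {
  corpus <- generate_corpus(40, seed = 9, corruption_rate = 0.4)
  names_path <- tempfile(fileext = ".txt")
  gold_path <- tempfile(fileext = ".tsv")
  write_corpus(corpus, names_path, gold_path)
  gold <- read_gold_tsv(gold_path)
  expect_equal(nrow(gold), 40L)
  expect_equal(gold$verbatim, readLines(names_path, encoding = "UTF-8"))
  ev <- evaluate_names(parse_names(gold$verbatim), gold)
  expect_equal(nrow(ev$data), 40L)
})
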