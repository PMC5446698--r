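test_that("canonical form strips authority, ranks and annotations", {
  expect_equal(canonical_form(parse_name_ast(carex)),
               "Carex scirpoidea convoluta")
  expect_equal(canonical_form(parse_name_ast(
    "Oriastrum lycopodioides Wedd. var. glabriusculum Reiche")),
    "Oriastrum lycopodioides glabriusculum")
  expect_equal(canonical_form(parse_name_ast("Homo sapiens L.")),
               "Homo sapiens")
})

test_that("canonical form folds diacritics and keeps the hybrid sign", {
  expect_equal(parse_names("Leptochloöpsis virgata")$canonical_name,
               "Leptochloopsis virgata")
  expect_equal(parse_names("Isoëtes lacustris L.")$canonical_name,
               "Isoetes lacustris")
  expect_equal(
    parse_names("Salvelinus fontinalis x Salmo gairdneri")$canonical_name,
    "Salvelinus fontinalis × Salmo gairdneri")
  expect_equal(parse_names("× Agropogon littoralis")$canonical_name,
               "Agropogon littoralis")
})

test_that("canonical output stays within the canonical alphabet", {
  inputs <- c(carex, complex_names, "Homo sapiens L.",
              "Isoëtes lacustris L.", "× Agropogon littoralis",
              "Acanthocephala declivis variety guianensis Osborn, 1904")
  res <- parse_names(inputs)
  expect_true(all(res$parsed))
  expect_true(all(grepl("^[A-Za-z ×.-]+$", res$canonical_name)))
  expect_false(any(grepl("\\d|\\(|var\\.|subsp\\.", res$canonical_name)))
})

test_that("terminal authorship belongs to the lowest-ranked element", {
  expect_equal(terminal_authorship(parse_name_ast(
    "Oriastrum lycopodioides Wedd. var. glabriusculum Reiche")), "Reiche")
  expect_equal(terminal_authorship(parse_name_ast(carex)),
               "(Kük.) D.A. Dunlop")
  expect_equal(terminal_authorship(parse_name_ast("Homo sapiens")),
               NA_character_)
})

test_that("normalized form standardizes spacing, signs and rank markers", {
  expect_equal(
    parse_names("Carex scirpoidea Michx. subsp. convoluta (Kük.) D.A.Dunlop")$normalized,
    "Carex scirpoidea Michx. subsp. convoluta (Kük.) D. A. Dunlop")
  expect_equal(
    parse_names("Salvelinus fontinalis x Salmo gairdneri")$normalized,
    "Salvelinus fontinalis × Salmo gairdneri")
  expect_equal(
    parse_names("Oriastrum lycopodioides Wedd. ssp. glabriusculum Reiche")$normalized,
    "Oriastrum lycopodioides Wedd. subsp. glabriusculum Reiche")
  # already-normalized input is a fixed point
  norm <- "Carex scirpoidea Michx. subsp. convoluta (Kük.) D. A. Dunlop"
  expect_equal(parse_names(norm)$normalized, norm)
})

test_that("re-parsing the normalized form preserves canonical and authorship", {
  corpus <- generate_corpus(300, seed = 11)
  res <- parse_names(corpus$name)
  parsed <- res[res$parsed, ]
  res2 <- parse_names(parsed$normalized)
  expect_true(all(res2$parsed))
  expect_equal(res2$canonical_name, parsed$canonical_name)
  # authorship comparison modulo author-initial spacing, which normalization
  # itself standardizes
  norm_auth <- function(x) gsub("(\\p{Lu}\\p{Ll}{0,2}\\.)(?=[\\p{Lu}])",
                                "\\1 ", x, perl = TRUE)
  expect_equal(norm_auth(res2$terminal_authorship),
               norm_auth(parsed$terminal_authorship))
})

test_that("name identifiers are deterministic UUID v5 digests", {
  # pinned against an independent UUID v5 implementation
  expect_equal(name_uuid("Homo sapiens L."),
               "8b13e169-4434-576a-b335-da174b2861bd")
  expect_equal(name_uuid(carex),
               "203213f3-99d1-5f5e-810a-4453c4d220cb")
  expect_equal(name_uuid("Homo sapiens L."), name_uuid("Homo sapiens L."))
  expect_false(name_uuid("Homo sapiens") == name_uuid("Homo sapiens L."))
})

test_that("quality is the maximum warning level, 1 when clean", {
  expect_equal(quality_score(list()), 1L)
  w2 <- list(list(code = "x", message = "m", level = 2L))
  w23 <- c(w2, list(list(code = "y", message = "m", level = 3L)))
  expect_equal(quality_score(w2), 2L)
  expect_equal(quality_score(w23), 3L)
})

test_that("quality matches the warning set on real parses", {
  res <- parse_names(c("Homo sapiens L.", "Homo_sapiens",
                       "Pieris japonica (Thunb.) D. Don ex G. Don"))
  expect_equal(res$quality, c(1L, 3L, 2L))
  for (i in seq_len(nrow(res))) {
    w <- res$warnings[[i]]
    expect_equal(res$quality[i],
                 if (length(w) == 0L) 1L
                 else max(vapply(w, `[[`, integer(1), "level")))
  }
})
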