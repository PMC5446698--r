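test_that("the recombined-infraspecies worked example decomposes fully", {
  ast <- parse_name_ast(carex)
  expect_s3_class(ast, "name_ast")
  expect_equal(ast$kind, "trinomial_or_deeper")
  d <- ast$details[[1]]
  expect_equal(d$genus, "Carex")
  expect_equal(d$specific_epithet$value, "scirpoidea")
  expect_equal(d$specific_epithet$authorship$verbatim, "Michx.")
  inf <- d$infraspecific_epithets
  expect_length(inf, 1L)
  expect_equal(inf[[1]]$value, "convoluta")
  expect_equal(inf[[1]]$rank$normalized, "subsp.")
  au <- inf[[1]]$authorship
  expect_equal(au$basionym$authors, "Kük.")
  expect_equal(au$combination$authors, "D.A. Dunlop")
  expect_length(ast$warnings, 0L)
})

test_that("hybrid formulae recurse into full name parses", {
  ast <- parse_name_ast("Salvelinus fontinalis x Salmo gairdneri")
  expect_equal(ast$kind, "hybrid_formula")
  expect_length(ast$details, 2L)
  expect_equal(ast$details[[1]]$genus, "Salvelinus")
  expect_equal(ast$details[[2]]$genus, "Salmo")

  ast2 <- parse_name_ast(
    "Echinocereus fasciculatus var. bonkerae × E. fasciculatus var. fasciculatus")
  expect_equal(ast2$kind, "hybrid_formula")
  expect_length(ast2$details, 2L)
  expect_equal(ast2$details[[2]]$genus, "E.")
  for (d in ast2$details) expect_length(d$infraspecific_epithets, 1L)
})

test_that("hybrid-formula operands re-parse standalone to identical details", {
  cases <- list(
    c("Salvelinus fontinalis", "Salmo gairdneri"),
    c("Echinocereus fasciculatus var. bonkerae",
      "E. fasciculatus var. fasciculatus")
  )
  formulas <- c("Salvelinus fontinalis x Salmo gairdneri",
                "Echinocereus fasciculatus var. bonkerae × E. fasciculatus var. fasciculatus")
  for (i in seq_along(formulas)) {
    whole <- parse_name_ast(formulas[i])
    for (j in 1:2) {
      alone <- parse_name_ast(cases[[i]][j], abbrev_ok = TRUE)
      expect_equal(alone$details[[1]], whole$details[[j]])
    }
  }
})

test_that("a leading hybrid sign yields a named hybrid with one detail", {
  ast <- parse_name_ast("× Agropogon littoralis")
  expect_equal(ast$kind, "named_hybrid")
  expect_length(ast$details, 1L)
  expect_equal(ast$details[[1]]$genus, "Agropogon")
  expect_equal(parse_name_ast("Homo sapiens")$kind, "binomial")
})

test_that("infrageneric uninomial constructs parse with rank and authorship", {
  ast <- parse_name_ast("Eucalyptus subser. Regulares Brooker")
  d <- ast$details[[1]]
  expect_equal(d$uninomial, "Eucalyptus")
  expect_equal(d$rank$normalized, "subser.")
  expect_equal(d$subuninomial, "Regulares")
  expect_equal(d$authorship$verbatim, "Brooker")
})

test_that("multi-infraspecific names keep epithet order and glued ranks", {
  ast <- parse_name_ast("Erigeron peregrinus ssp.callianthemus var. eucallianthemus")
  d <- ast$details[[1]]
  expect_equal(vapply(d$infraspecific_epithets, `[[`, character(1), "value"),
               c("callianthemus", "eucallianthemus"))
  expect_equal(d$infraspecific_epithets[[1]]$rank$normalized, "subsp.")
})

test_that("year rule honours prioritized alternatives and bounds", {
  expect_equal(rule_year("1753")$value, "1753")
  expect_false(rule_year("1753")$approximate)
  y <- rule_year("190?")
  expect_equal(y$value, "190?")
  expect_true(y$approximate)
  expect_equal(vapply(y$warnings, `[[`, character(1), "code"),
               "year_with_question_mark")
  expect_equal(y$warnings[[1]]$level, 2L)
  expect_null(rule_year("1621"))
  expect_null(rule_year(as.character(as.integer(format(Sys.Date(), "%Y")) + 5L)))
  expect_equal(rule_year("1900: 25")$value, "1900")
  expect_equal(rule_year("1900a")$value, "1900")
  expect_equal(rule_year("(1900)")$value, "1900")
  yb <- rule_year("[1972]")
  expect_true(yb$approximate)
  expect_equal(vapply(yb$warnings, `[[`, character(1), "code"),
               "bracketed_year")
})

test_that("rank markers normalize and flag spelled-out forms", {
  expect_equal(rule_rank_marker("subsp.")$normalized, "subsp.")
  expect_equal(rule_rank_marker("ssp.")$normalized, "subsp.")
  v <- rule_rank_marker("variety")
  expect_equal(v$normalized, "var.")
  expect_equal(vapply(v$warnings, `[[`, character(1), "code"),
               "spelled_out_rank")
  expect_equal(rule_rank_marker("fo.")$normalized, "f.")
  expect_null(rule_rank_marker("subspp"))
})

test_that("authorship rule handles basionym, teams, years and suffixes", {
  a <- rule_authorship("(Kük.) D.A. Dunlop")
  expect_equal(a$basionym_authors, "Kük.")
  expect_equal(a$combination_authors, "D.A. Dunlop")

  b <- rule_authorship("Miller, 1900")
  expect_equal(b$combination_authors, "Miller")
  expect_equal(b$combination_year, "1900")

  c3 <- rule_authorship("O. Bolòs & Vigo")
  expect_equal(c3$combination_authors, c("O. Bolòs", "Vigo"))

  d <- rule_authorship("Domanski, Orlos & Skirg.")
  expect_equal(d$combination_authors, c("Domanski", "Orlos", "Skirg."))

  e <- rule_authorship("(Choisy) Hall. fil.")
  expect_equal(e$combination_authors, "Hall. fil.")

  f <- rule_authorship("Miller ex Vohra")
  expect_equal(f$combination_authors, "Vohra")
  expect_equal(f$combination_ex_authors, "Miller")
  expect_true("ex_author" %in% vapply(f$warnings, `[[`, character(1), "code"))
})

test_that("injected spaces in hyphenated author abbreviations are repaired", {
  res <- parse_names("Hieracium nobile subsp. perclusum (Arv. -Touv.) O. Bolòs & Vigo")
  expect_true(res$parsed)
  expect_equal(res$terminal_authorship, "(Arv.-Touv.) O. Bolòs & Vigo")
  expect_true("author_space_injected" %in% warning_codes(res))
  expect_equal(res$quality, 3L)
})

test_that("filial suffix after an author word is not read as a rank marker", {
  res <- parse_names("Jacquemontia spiciflora (Choisy) Hall. fil.")
  expect_true(res$parsed)
  expect_equal(res$canonical_name, "Jacquemontia spiciflora")
  expect_equal(res$terminal_authorship, "(Choisy) Hall. fil.")
})

test_that("surrogate codes and negation annotations are distinguished", {
  res <- parse_names("Coleoptera sp. BOLD:AAV0432")
  expect_true(res$parsed)
  expect_true(res$surrogate)
  expect_equal(res$details[[1]][[1]]$annotation, "sp.")

  res2 <- parse_names("Gambierodiscus aff toxicus")
  expect_true(res2$parsed)
  expect_false(res2$surrogate)
  expect_equal(res2$details[[1]][[1]]$annotation, "aff.")

  res3 <- parse_names("Homo sapiens")
  expect_false(res3$surrogate)
  expect_null(res3$details[[1]][[1]]$annotation)
})

test_that("a single trailing token is ignored with a level-3 warning", {
  res <- parse_names("Myosorex muricauda (Miller, 1900).")
  expect_true(res$parsed)
  expect_equal(res$canonical_name, "Myosorex muricauda")
  expect_equal(res$terminal_authorship, "(Miller, 1900)")
  expect_true("ignored_tail" %in% warning_codes(res))
  expect_equal(res$quality, 3L)
})

test_that("parse failure is a value, never an error, with a furthest offset", {
  f <- parse_name_ast("")
  expect_s3_class(f, "name_parse_failure")
  garbage <- c("(?)", "123 456", "Atysa (?) frontalis", "Aus bus cus dus X !!",
               "Papillaria amblyacis (M<81>ll.Hal.) A.Jaeger",
               "ÿþ", "Aus ..", paste(rep("Aus", 40), collapse = " "))
  for (g in garbage) {
    expect_error(ast <- parse_name_ast(g), NA)
    if (inherits(ast, "name_parse_failure")) {
      expect_true(ast$far >= 0L)
    }
  }
})

test_that("parsing is deterministic", {
  inputs <- c(carex, complex_names, "Homo sapiens L.")
  for (x in inputs) {
    expect_identical(parse_name_ast(x), parse_name_ast(x))
  }
  j1 <- render_compact_json(parse_names(inputs))
  j2 <- render_compact_json(parse_names(inputs))
  expect_identical(j1, j2)
})

test_that("mojibake inside a non-ignorable token defeats the parse", {
  res <- parse_names("Campylium gollanii C. M?ller ex Vohra 1970 [1972]")
  expect_false(res$parsed)
  res2 <- parse_names("Papillaria amblyacis (M<81>ll.Hal.) A.Jaeger")
  expect_false(res2$parsed)
  expect_true("non_ascii_garbage" %in% warning_codes(res2))
})

test_that("spans are within bounds, ordered, and reconstruct their tokens", {
  inputs <- c(carex, complex_names, "Homo_sapiens", "Homo sapiens L.",
              "Eucalyptus subser. Regulares Brooker",
              "× Agropogon littoralis", "  Carex   scirpoidea ")
  for (x in inputs) {
    res <- parse_names(x)
    if (!res$parsed) next
    pos <- res$positions[[1]]
    starts <- vapply(pos, `[[`, numeric(1), "start")
    ends <- vapply(pos, `[[`, numeric(1), "end")
    expect_true(all(starts >= 0 & ends <= nchar(x) & starts < ends))
    expect_true(all(diff(starts) > 0))
    # a genus/epithet span must extract exactly the element value
    for (p in pos) {
      txt <- substring(x, p$start + 1, p$end)
      if (p$label %in% c("genus", "uninomial")) {
        expect_true(grepl("^\\p{Lu}", txt, perl = TRUE), label = txt)
      }
      if (p$label %in% c("specific_epithet", "infraspecific_epithet")) {
        expect_true(grepl("^\\p{Ll}", txt, perl = TRUE), label = txt)
      }
    }
  }
})

test_that("genus and epithet alphabets reject malformed tokens", {
  expect_false(parse_names("atysa frontalis")$parsed)
  expect_false(parse_names("A2us bus")$parsed)
  # a single letter cannot be an epithet; it is left as an ignored tail
  res <- parse_names("Aus b")
  expect_equal(res$canonical_name, "Aus")
  expect_true("ignored_tail" %in% warning_codes(res))
})
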