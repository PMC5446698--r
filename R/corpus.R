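# Seeded synthetic corpus generator. Name material is synthesized from
# Latin-like syllables rather than drawn from taxon dictionaries, matching
# the parser's own dictionary-free stance: nothing the generator emits is in
# any reference list the grammar could secretly rely on. Authors come from a
# small pool that deliberately includes diacritics, initials, hyphenated
# abbreviations and multi-part names.

SYL_ONSETS <- c("b", "c", "ch", "d", "f", "g", "l", "m", "n", "p", "ph",
                "r", "s", "t", "th", "v", "z", "st", "cr", "pl", "tr")
SYL_VOWELS <- c("a", "e", "i", "o", "u", "a", "e", "i", "o", "ae")
EPITHET_SUFFIXES <- c("us", "a", "um", "is", "ii", "ensis", "oides",
                      "atus", "ella", "icus", "alis", "ianus")

AUTHOR_POOL <- c("Kük.", "Michx.", "L.", "DC.", "Brooker", "Reiche",
                 "Wedd.", "Miller", "Osborn", "Dunlop", "D.A. Dunlop",
                 "O. Bolòs", "Vigo", "Arv.-Touv.", "Pilát", "Domanski",
                 "Orlos", "Skirg.", "Thwaites", "Vohra", "Agardh",
                 "Breuning", "Leconte", "Kützing", "C. Agardh")

NON_NAME_WORDS <- c("acid", "mine", "drainage", "metagenome", "agricultural",
                    "soil", "bacterium", "alpha", "proteobacterium",
                    "anaerobic", "enrichment", "culture", "clone", "band",
                    "rhizosphere", "bovine", "rumen", "symbiont", "archaeon",
                    "photosynthetic", "anoxygenic", "barley", "endosymbiont")

CORRUPTION_OPS <- c("underscore_join", "author_space_injection",
                    "mojibake_char", "trailing_period",
                    "bracketed_second_year", "double_space")

DEFAULT_MIX <- c(uninomial = 0.12, binomial = 0.55, infraspecies_1 = 0.20,
                 infraspecies_2 = 0.05, named_hybrid = 0.02,
                 hybrid_formula = 0.03, surrogate = 0.02, non_name = 0.01)

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

syllable <- function() paste0(sample(SYL_ONSETS, 1), sample(SYL_VOWELS, 1))

# the syllable model can coin triage keywords ("Phage"); resample those
safe_word <- function(make) {
  for (i in 1:20) {
    w <- make()
    if (!tolower(w) %in% VIRUS_KEYWORDS) return(w)
  }
  w
}

gen_genus <- function() {
  safe_word(function() {
    w <- paste(replicate(sample(2:3, 1), syllable()), collapse = "")
    paste0(toupper(substring(w, 1, 1)), substring(w, 2))
  })
}

gen_epithet <- function() {
  safe_word(function() {
    paste0(paste(replicate(sample(1:2, 1), syllable()), collapse = ""),
           sample(EPITHET_SUFFIXES, 1))
  })
}

gen_year <- function() sample(1753:2016, 1)

# one authorship string; forms mirror real usage: single author, teams with
# "&" or commas, parenthesized basionym with recombination, attached years,
# ex-authors
gen_authorship <- function() {
  a <- function() sample(AUTHOR_POOL, 1)
  form <- sample(7L, 1)
  switch(form,
    a(),                                               # Miller
    paste0(a(), " & ", a()),                           # A & B
    paste0(a(), ", ", a(), " & ", a()),                # A, B & C
    paste0("(", a(), ") ", a()),                       # (X) Y
    paste0(a(), ", ", gen_year()),                     # A, 1900
    paste0("(", a(), ", ", gen_year(), ")"),           # (X, 1900)
    paste0(a(), " ex ", a())                           # A ex B
  )
}

gen_record <- function(class) {
  g <- gen_genus()
  maybe_auth <- function(p) if (stats::runif(1) < p) gen_authorship() else ""
  join <- function(...) squish(paste(...))
  rank <- function() sample(c("var.", "subsp.", "f."), 1)
  rec <- function(name, canonical, authorship) {
    list(name = name, canonical = canonical,
         terminal_authorship = authorship, parseable = TRUE, class = class)
  }
  switch(class,
    uninomial = {
      au <- maybe_auth(0.6)
      rec(join(g, au), g, au)
    },
    binomial = {
      e <- gen_epithet()
      au <- maybe_auth(0.8)
      rec(join(g, e, au), paste(g, e), au)
    },
    infraspecies_1 = {
      e1 <- gen_epithet(); e2 <- gen_epithet()
      au1 <- maybe_auth(0.5); au2 <- maybe_auth(0.8)
      rec(join(g, e1, au1, rank(), e2, au2),
          paste(g, e1, e2), au2)
    },
    infraspecies_2 = {
      e1 <- gen_epithet(); e2 <- gen_epithet(); e3 <- gen_epithet()
      au <- maybe_auth(0.8)
      rec(join(g, e1, rank(), e2, rank(), e3, au),
          paste(g, e1, e2, e3), au)
    },
    named_hybrid = {
      e <- gen_epithet()
      au <- maybe_auth(0.5)
      rec(join("×", g, e, au), paste(g, e), au)
    },
    hybrid_formula = {
      g2 <- gen_genus()
      e1 <- gen_epithet(); e2 <- gen_epithet()
      au1 <- maybe_auth(0.4); au2 <- maybe_auth(0.4)
      sign <- sample(c("x", "×"), 1)
      rec(join(g, e1, au1, sign, g2, e2, au2),
          paste(paste(g, e1), paste(g2, e2), sep = " × "), au2)
    },
    surrogate = {
      code <- if (stats::runif(1) < 0.5) {
        paste0("BOLD:", paste(sample(LETTERS, 3, TRUE), collapse = ""),
               sample(1000:9999, 1))
      } else {
        paste0(paste(sample(LETTERS, 2, TRUE), collapse = ""),
               sample(100:999, 1))
      }
      rec(join(g, "sp.", code), g, "")
    },
    non_name = {
      phrase <- paste(sample(NON_NAME_WORDS, sample(3:5, 1)), collapse = " ")
      if (stats::runif(1) < 0.5) {
        phrase <- paste0(phrase, " ",
                         paste(sample(LETTERS, 2, TRUE), collapse = ""),
                         sample(10:99, 1))
      }
      list(name = phrase, canonical = "", terminal_authorship = "",
           parseable = FALSE, class = class)
    },
    rlang::abort(paste("unknown class", class))
  )
}

op_applicable <- function(name, op, parseable) {
  if (!parseable) return(FALSE)
  switch(op,
    underscore_join = grepl("\\p{L} \\p{L}", name, perl = TRUE),
    author_space_injection = grepl("\\.-\\p{Lu}", name, perl = TRUE),
    mojibake_char = grepl("[&,]| ex | 1[789]\\d\\d", name, perl = TRUE) &&
      grepl("\\p{Lu}\\p{Ll}+", name, perl = TRUE),
    trailing_period = !endsWith(name, ".") &&
      # a period after a plain surname is indistinguishable from an
      # abbreviated author, so only defect-inject where it is recoverable
      !grepl("^\\p{Lu}", sub(".* ", "", name), perl = TRUE),
    bracketed_second_year = grepl("(?:1[789]|20)\\d\\d$", name, perl = TRUE),
    double_space = grepl(" ", name, fixed = TRUE),
    FALSE
  )
}

#' Apply one corruption operator to a name-string
#'
#' Each operator emulates a defect class observed in aggregated name data:
#' underscores joining name elements, an injected space inside a hyphenated
#' author abbreviation, a miscoded character inside an author word, a stray
#' period after the authorship, an additional year in square brackets, and
#' doubled spaces. The returned `expected_warnings` are the warning codes the
#' parser emits when it recovers from the defect; `expected_parseable` is
#' `FALSE` for the one unrecoverable operator (`mojibake_char`), whose
#' damaged token cannot be read as any name element.
#'
#' @param name a well-formed name-string.
#' @param op one of `underscore_join`, `author_space_injection`,
#'   `mojibake_char`, `trailing_period`, `bracketed_second_year`,
#'   `double_space`.
#' @param seed unused (all operators are deterministic); kept so corruption
#'   calls are interface-compatible with seeded generators.
#' @return list with `text`, `expected_warnings` (character vector) and
#'   `expected_parseable`.
#' @examples
#' corrupt_name("Homo sapiens", "underscore_join")
#' @export
corrupt_name <- function(name, op, seed = NULL) {
  op <- match.arg(op, CORRUPTION_OPS)
  out <- switch(op,
    underscore_join = list(
      text = gsub("(?<=\\p{L}) (?=\\p{L})", "_", name, perl = TRUE),
      expected_warnings = "underscore_as_space",
      expected_parseable = TRUE),
    author_space_injection = list(
      text = sub("\\.-(?=\\p{Lu})", ". -", name, perl = TRUE),
      expected_warnings = "author_space_injected",
      expected_parseable = TRUE),
    mojibake_char = list(
      text = sub("(\\p{Lu}\\p{Ll})\\p{Ll}(\\p{Ll}*[\\.,]? (?:&|ex|\\d|\\p{Lu}))",
                 "\\1?\\2", name, perl = TRUE),
      expected_warnings = character(0),
      expected_parseable = FALSE),
    trailing_period = list(
      text = paste0(name, "."),
      expected_warnings = "ignored_tail",
      expected_parseable = TRUE),
    bracketed_second_year = {
      yr <- as.integer(stringr::str_extract(name, "\\d{4}$"))
      list(text = paste0(name, " [", min(yr + 2L, 2016L), "]"),
           expected_warnings = "bracketed_year",
           expected_parseable = TRUE)
    },
    double_space = list(
      text = sub(" ", "  ", name, fixed = TRUE),
      expected_warnings = "multiple_spaces_fixed",
      expected_parseable = TRUE)
  )
  if (identical(out$text, name)) {
    out$expected_warnings <- character(0)
    out$expected_parseable <- TRUE
  }
  out
}

#' Generate a seeded synthetic corpus with gold records
#'
#' Emulates a random sample of aggregated name-strings: a mixture of
#' well-formed names of graded complexity, hybrid notations, surrogate
#' names, lowercase non-name phrases, and (optionally) corrupted variants
#' produced by [corrupt_name()]. Gold canonical forms and terminal
#' authorships are computed from the construction, never by parsing, so the
#' corpus is an independent standard for end-to-end parser evaluation.
#' Output is deterministic for a fixed seed.
#'
#' @param n number of name-strings.
#' @param seed RNG seed.
#' @param mix named proportions over the classes `uninomial`, `binomial`,
#'   `infraspecies_1`, `infraspecies_2`, `named_hybrid`, `hybrid_formula`,
#'   `surrogate`, `non_name`; must sum to 1.
#' @param corruption_rate probability that a parseable name is corrupted.
#' @param corruption_ops operators to draw from (see [corrupt_name()]).
#' @return tibble with columns `name`, `class`, `parseable`, `canonical`,
#'   `terminal_authorship`, `corrupted`, `corruption_op`,
#'   `expected_warnings` (list-column).
#' @examples
#' generate_corpus(5, seed = 42)
#' @export
generate_corpus <- function(n, seed,
                            mix = DEFAULT_MIX,
                            corruption_rate = 0,
                            corruption_ops = CORRUPTION_OPS) {
  stopifnot(n >= 1, corruption_rate >= 0, corruption_rate <= 1)
  if (is.null(names(mix)) || !all(names(mix) %in% names(DEFAULT_MIX))) {
    rlang::abort("mix must be named with the corpus classes")
  }
  if (abs(sum(mix) - 1) > 1e-8) rlang::abort("mix proportions must sum to 1")
  corruption_ops <- match.arg(corruption_ops, CORRUPTION_OPS,
                              several.ok = TRUE)
  with_seed(seed, {
    classes <- sample(names(mix), n, replace = TRUE, prob = mix)
    recs <- lapply(classes, gen_record)
    corrupted <- logical(n)
    op_used <- rep(NA_character_, n)
    exp_warn <- vector("list", n)
    for (i in seq_len(n)) {
      exp_warn[[i]] <- character(0)
      if (recs[[i]]$parseable && stats::runif(1) < corruption_rate) {
        ok_ops <- corruption_ops[vapply(corruption_ops, function(op) {
          op_applicable(recs[[i]]$name, op, recs[[i]]$parseable)
        }, logical(1))]
        if (length(ok_ops) > 0L) {
          op <- if (length(ok_ops) == 1L) ok_ops else sample(ok_ops, 1)
          cr <- corrupt_name(recs[[i]]$name, op)
          if (!identical(cr$text, recs[[i]]$name)) {
            recs[[i]]$name <- cr$text
            corrupted[i] <- TRUE
            op_used[i] <- op
            exp_warn[[i]] <- cr$expected_warnings
            if (!cr$expected_parseable) {
              recs[[i]]$parseable <- FALSE
              recs[[i]]$canonical <- ""
              recs[[i]]$terminal_authorship <- ""
            } else if (op == "bracketed_second_year") {
              # the parser keeps the bracketed year inside the verbatim
              # authorship, so the gold terminal authorship gains it too
              suffix <- sub(".*( \\[\\d{4}\\])$", "\\1", cr$text)
              recs[[i]]$terminal_authorship <-
                paste0(recs[[i]]$terminal_authorship, suffix)
            }
          }
        }
      }
    }
    tibble(
      name = vapply(recs, `[[`, character(1), "name"),
      class = classes,
      parseable = vapply(recs, `[[`, logical(1), "parseable"),
      canonical = vapply(recs, `[[`, character(1), "canonical"),
      terminal_authorship = vapply(recs, `[[`, character(1),
                                   "terminal_authorship"),
      corrupted = corrupted,
      corruption_op = op_used,
      expected_warnings = exp_warn
    )
  })
}

#' Convert a generated corpus to a gold-standard table
#'
#' @param corpus tibble from [generate_corpus()].
#' @return tibble with the gold columns expected by [evaluate_names()].
#' @export
as_gold <- function(corpus) {
  tibble(
    verbatim = corpus$name,
    parseable = corpus$parseable,
    canonical = fold_ascii(corpus$canonical),
    terminal_authorship = corpus$terminal_authorship
  )
}

#' Write a corpus as a name list and a gold TSV
#'
#' @param corpus tibble from [generate_corpus()].
#' @param names_path path for the plain name list (one name per line).
#' @param gold_path path for the gold TSV (`verbatim`, `parseable`,
#'   `canonical`, `terminal_authorship`).
#' @return invisibly, the gold tibble.
#' @export
write_corpus <- function(corpus, names_path, gold_path) {
  gold <- as_gold(corpus)
  writeLines(enc2utf8(corpus$name), names_path, useBytes = TRUE)
  lines <- c(
    paste("verbatim", "parseable", "canonical", "terminal_authorship",
          sep = "\t"),
    paste(gold$verbatim, ifelse(gold$parseable, "true", "false"),
          gold$canonical, gold$terminal_authorship, sep = "\t")
  )
  writeLines(enc2utf8(lines), gold_path, useBytes = TRUE)
  invisible(gold)
}
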