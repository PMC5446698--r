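# Parsing expression grammar for scientific name-strings.
#
# Every rule is a function of (s, pos) returning NULL on no-match or a list
# with `end` (next 1-based code-point position) plus rule-specific fields,
# `toks` (semantic position labels, 0-based half-open) and `warns` (quality
# warnings). Alternatives are tried in a fixed order and the first match wins
# (ordered choice); repetition is greedy; failed alternatives leave no trace,
# so warnings and positions only ever come from the committed parse.

# anchored regex match at pos; spans are code points (substring() is
# character-based on UTF-8 strings)
rx <- function(s, pos, pattern) {
  if (pos > nchar(s)) return(NULL)
  m <- regexpr(paste0("^(?:", pattern, ")"), substring(s, pos), perl = TRUE)
  if (m[1] == -1L) return(NULL)
  len <- attr(m, "match.length")
  list(text = if (len == 0L) "" else substring(s, pos, pos + len - 1L),
       end = pos + len)
}

tok <- function(label, start_pos, end_pos) {
  list(label = label, start = start_pos - 1L, end = end_pos - 1L)
}

r_ws <- function(s, pos) rx(s, pos, " +")

# -- words -------------------------------------------------------------------

CAPWORD_RE <- "\\p{Lu}\\p{Ll}+(?:-\\p{Ll}+)?(?![\\p{L}\\d])"
EPITHET_RE <- "\\p{Ll}[\\p{Ll}-]*\\p{Ll}(?![\\p{L}\\d])"

r_capword <- function(s, pos) rx(s, pos, CAPWORD_RE)

# words that can never be epithets: annotations, team separators, and rank
# markers when immediately followed by their period
r_epithet <- function(s, pos) {
  m <- rx(s, pos, EPITHET_RE)
  if (is.null(m)) return(NULL)
  if (m$text %in% c("sp", "spp", "cf", "aff", "et", "ex")) return(NULL)
  nxt <- if (m$end <= nchar(s)) substring(s, m$end, m$end) else ""
  if (nxt == "." &&
      paste0(tolower(m$text), ".") %in% names(RANK_MAP)) {
    return(NULL)
  }
  m
}

# -- rank markers ------------------------------------------------------------

RANK_RE <- paste0(
  "(?:nothosubsp|nothovar|subspecies|subsect|subser|subvar|subgen|variety|",
  "convar|subsp|forma|form|sect|subf|ser|ssp|var|fo|cv|f)\\.?")

r_rank_marker <- function(s, pos) {
  m <- rx(s, pos, RANK_RE)
  if (is.null(m)) return(NULL)
  t <- m$text
  nxt <- if (m$end <= nchar(s)) substring(s, m$end, m$end) else ""
  if (endsWith(t, ".")) {
    # a glued epithet ("ssp.callianthemus") is tolerated
    if (nzchar(nxt) && !grepl("^[\\s\\p{L}]$", nxt, perl = TRUE)) return(NULL)
  } else {
    if (nxt != " ") return(NULL)
  }
  key <- tolower(t)
  if (!key %in% names(RANK_MAP)) return(NULL)
  warns <- list()
  if (key %in% SPELLED_OUT_RANKS) warns <- list(new_warning("spelled_out_rank"))
  list(end = m$end, verbatim = t, normalized = unname(RANK_MAP[[key]]),
       warns = warns, toks = list(tok("rank", pos, m$end)))
}

#' Match a rank marker at the start of a fragment
#'
#' Recognizes abbreviated and spelled-out infraspecific and infrageneric rank
#' markers and reports the canonical abbreviation (`ssp.` and `subspecies`
#' normalize to `subsp.`, `variety` to `var.`, `forma`/`fo.` to `f.`).
#' Spelled-out forms carry a level-2 warning.
#'
#' @param fragment text beginning at a token boundary.
#' @return `NULL` when no rank marker starts the fragment, otherwise a list
#'   with `verbatim`, `normalized` and `warnings`.
#' @examples
#' rule_rank_marker("subsp.")
#' rule_rank_marker("variety")
#' @export
rule_rank_marker <- function(fragment) {
  # allow matching a bare marker at end of string by padding the boundary
  m <- r_rank_marker(paste0(fragment, " "), 1L)
  if (is.null(m)) return(NULL)
  list(verbatim = m$verbatim, normalized = m$normalized,
       warnings = m$warns)
}

# -- years -------------------------------------------------------------------

YEAR_CORE_RE <- "[12][0-9?][0-9?][0-9?]"

year_in_range <- function(value) {
  lo <- suppressWarnings(as.integer(gsub("?", "9", value, fixed = TRUE)))
  hi <- suppressWarnings(as.integer(gsub("?", "0", value, fixed = TRUE)))
  current <- as.integer(format(Sys.Date(), "%Y"))
  !is.na(lo) && !is.na(hi) && lo >= YEAR_MIN && hi <= current
}

r_year_core <- function(s, pos) {
  m <- rx(s, pos, YEAR_CORE_RE)
  if (is.null(m)) return(NULL)
  if (!year_in_range(m$text)) return(NULL)
  m
}

# prioritized alternatives: range, parenthesized, year with page, year with
# letter, bracketed year, plain year; an optional second year in square
# brackets may trail any of them
r_year <- function(s, pos) {
  res <- NULL
  # year range
  m <- r_year_core(s, pos)
  if (!is.null(m)) {
    m2 <- rx(s, m$end, "-")
    if (!is.null(m2)) {
      m3 <- r_year_core(s, m2$end)
      if (!is.null(m3) && is.null(rx(s, m3$end, "[\\p{L}\\d]"))) {
        res <- list(end = m3$end, value = m$text, approximate = FALSE,
                    year_end = m3$end)
      }
    }
  }
  # parenthesized
  if (is.null(res)) {
    m <- rx(s, pos, "\\( *")
    if (!is.null(m)) {
      m2 <- r_year_core(s, m$end)
      if (!is.null(m2)) {
        m3 <- rx(s, m2$end, " *\\)")
        if (!is.null(m3)) {
          res <- list(end = m3$end, value = m2$text, approximate = FALSE,
                      year_end = m3$end)
        }
      }
    }
  }
  # year with page reference ("1900: 25")
  if (is.null(res)) {
    m <- r_year_core(s, pos)
    if (!is.null(m)) {
      m2 <- rx(s, m$end, " *: *\\d+(?!\\d)")
      if (!is.null(m2)) {
        res <- list(end = m2$end, value = m$text, approximate = FALSE,
                    year_end = m2$end)
      }
    }
  }
  # year with letter ("1900a")
  if (is.null(res)) {
    m <- r_year_core(s, pos)
    if (!is.null(m)) {
      m2 <- rx(s, m$end, "[a-z](?![\\p{L}\\d])")
      if (!is.null(m2)) {
        res <- list(end = m2$end, value = m$text, approximate = FALSE,
                    year_end = m2$end)
      }
    }
  }
  # bracketed year
  bracketed <- FALSE
  if (is.null(res)) {
    m <- rx(s, pos, "\\[")
    if (!is.null(m)) {
      m2 <- r_year_core(s, m$end)
      if (!is.null(m2)) {
        m3 <- rx(s, m2$end, "\\]")
        if (!is.null(m3)) {
          res <- list(end = m3$end, value = m2$text, approximate = TRUE,
                      year_end = m3$end)
          bracketed <- TRUE
        }
      }
    }
  }
  # plain year
  if (is.null(res)) {
    m <- r_year_core(s, pos)
    if (!is.null(m) && is.null(rx(s, m$end, "[\\p{L}\\d]"))) {
      res <- list(end = m$end, value = m$text, approximate = FALSE,
                  year_end = m$end)
    }
  }
  if (is.null(res)) return(NULL)

  warns <- list()
  if (grepl("?", res$value, fixed = TRUE)) {
    warns <- c(warns, list(new_warning("year_with_question_mark")))
    res$approximate <- TRUE
  }
  if (bracketed) warns <- c(warns, list(new_warning("bracketed_year")))

  # an additional year in square brackets ("1970 [1972]") is recorded as a
  # defect; the primary year stands
  m <- rx(s, res$end, " *\\[")
  if (!is.null(m)) {
    m2 <- r_year_core(s, m$end)
    if (!is.null(m2)) {
      m3 <- rx(s, m2$end, "\\]")
      if (!is.null(m3)) {
        res$end <- m3$end
        warns <- c(warns, list(new_warning("bracketed_year")))
      }
    }
  }
  list(end = res$end, verbatim = substring(s, pos, res$end - 1L),
       value = res$value, approximate = res$approximate,
       warns = warns, toks = list(tok("year", pos, res$year_end)))
}

#' Match a publication year at the start of a fragment
#'
#' Tries, in order: a year range, a parenthesized year, a year with page
#' reference (`1900: 25`), a year with letter suffix (`1900a`), a bracketed
#' year, and a plain year. Years lie in `[1753, current year]`; one or two
#' digits may be replaced by question marks when the exact year is unknown,
#' which marks the year approximate and attaches a level-2 warning.
#'
#' @param fragment text starting at a candidate year position.
#' @return `NULL` on no match, otherwise a list with `verbatim`, `value`
#'   (4 characters, possibly containing `?`), `approximate` and `warnings`.
#' @examples
#' rule_year("1753")
#' rule_year("190?")
#' rule_year("1621")
#' @export
rule_year <- function(fragment) {
  m <- r_year(fragment, 1L)
  if (is.null(m)) return(NULL)
  list(verbatim = m$verbatim, value = m$value, approximate = m$approximate,
       warnings = m$warns)
}

# -- authors -----------------------------------------------------------------

ABBREV_PIECE_RE <-
  "(?:\\p{Lu}[\\p{Lu}\\p{Ll}]{0,8}\\.)(?:-?\\p{Lu}[\\p{Lu}\\p{Ll}]{0,8}\\.)*(?!\\p{Ll})"
SURNAME_RE <- "\\p{Lu}'?\\p{Ll}+(?:[-']\\p{Lu}?\\p{Ll}+)*(?![\\p{L}\\d])"
PARTICLE_RE <- "(?:van|von|der|den|de|du|la|le|ter|ten|zu|d')(?= ?\\p{Lu})"

r_author_piece <- function(s, pos) {
  m <- rx(s, pos, ABBREV_PIECE_RE)
  if (!is.null(m)) return(c(m, list(initials = grepl(
    "^(?:\\p{Lu}\\p{Ll}?\\.)+$", m$text, perl = TRUE))))
  m <- rx(s, pos, SURNAME_RE)
  if (!is.null(m)) return(c(m, list(initials = FALSE)))
  NULL
}

# One author: optional lowercase particles, then one or more pieces. Initials
# may be followed by a space-separated surname or further initials; glued
# pieces ("D.A.Dunlop") are joined without widening the span. With
# `repair = TRUE` an injected space before a hyphenated continuation
# ("Arv. -Touv.") is absorbed with a level-3 warning.
r_author_name <- function(s, pos, repair = TRUE) {
  toks <- list()
  warns <- list()
  parts <- character(0)
  p <- pos
  repeat {
    m <- rx(s, p, paste0(PARTICLE_RE, " "))
    if (is.null(m)) break
    parts <- c(parts, sub(" $", "", m$text))
    toks <- c(toks, list(tok("author_word", p, m$end - 1L)))
    p <- m$end
  }
  piece <- r_author_piece(s, p)
  if (is.null(piece)) return(NULL)
  text <- piece$text
  toks <- c(toks, list(tok("author_word", p, piece$end)))
  p <- piece$end
  last_initials <- piece$initials
  repeat {
    # glued continuation after a period: "D.A.Dunlop"
    if (endsWith(text, ".")) {
      nxt <- r_author_piece(s, p)
      if (!is.null(nxt)) {
        text <- paste0(text, nxt$text)
        toks[[length(toks)]]$end <- nxt$end - 1L
        p <- nxt$end
        last_initials <- nxt$initials
        next
      }
    }
    # injected space inside a hyphenated abbreviation: "Arv. -Touv."
    if (repair && endsWith(text, ".")) {
      sp <- rx(s, p, " +(?=-\\p{Lu})")
      if (!is.null(sp)) {
        hy <- rx(s, sp$end, "-")
        nxt <- r_author_piece(s, hy$end)
        if (!is.null(nxt)) {
          text <- paste0(text, "-", nxt$text)
          warns <- c(warns, list(new_warning("author_space_injected")))
          toks <- c(toks, list(tok("author_word", sp$end, nxt$end)))
          p <- nxt$end
          last_initials <- FALSE
          next
        }
      }
    }
    # space-separated continuation: initials before a surname ("O. Bolòs"),
    # or a multi-word author name ("Capitalized Words"); team separators and
    # lowercase tokens end the author
    sp <- rx(s, p, " +")
    if (!is.null(sp)) {
      nxt <- r_author_piece(s, sp$end)
      if (!is.null(nxt)) {
        parts <- c(parts, text)
        text <- nxt$text
        toks <- c(toks, list(tok("author_word", sp$end, nxt$end)))
        p <- nxt$end
        last_initials <- nxt$initials
        next
      }
    }
    break
  }
  parts <- c(parts, text)
  # filial suffix: "f." after an author word means filius, unless an epithet
  # follows (then it is a rank marker for the next name element)
  m <- rx(s, p, " +(?:fil\\.|f\\.)(?! *\\p{Ll})")
  if (!is.null(m)) {
    suffix <- sub("^ +", "", m$text)
    parts <- c(parts, suffix)
    ws_len <- nchar(m$text) - nchar(suffix)
    toks <- c(toks, list(tok("author_word", p + ws_len, m$end)))
    p <- m$end
  }
  list(end = p, text = paste(parts, collapse = " "), toks = toks,
       warns = warns)
}

# author team: authors joined by ",", "&" or "et"; "ex" splits off the
# ex-team; an optional trailing year (with optional comma) attaches to the
# team
r_author_team <- function(s, pos, repair = TRUE) {
  a <- r_author_name(s, pos, repair)
  if (is.null(a)) return(NULL)
  authors <- a$text
  ex_authors <- character(0)
  toks <- a$toks
  warns <- a$warns
  p <- a$end
  repeat {
    save <- p
    sep <- rx(s, p, " *, *| +& +| +et +| +ex +")
    if (is.null(sep)) break
    is_ex <- grepl(" ex ", paste0(" ", squish(sep$text), " "), fixed = TRUE)
    nxt <- r_author_name(s, sep$end, repair)
    if (is.null(nxt)) { p <- save; break }
    if (is_ex) {
      ex_authors <- c(ex_authors, authors)
      authors <- nxt$text
      warns <- c(warns, list(new_warning("ex_author")))
    } else {
      authors <- c(authors, nxt$text)
    }
    toks <- c(toks, nxt$toks)
    warns <- c(warns, nxt$warns)
    p <- nxt$end
  }
  year <- NULL
  m <- rx(s, p, " *, +| +")
  if (!is.null(m)) {
    y <- r_year(s, m$end)
    if (!is.null(y)) {
      year <- y
      toks <- c(toks, y$toks)
      warns <- c(warns, y$warns)
      p <- y$end
    }
  }
  list(end = p, authors = authors, ex_authors = ex_authors, year = year,
       toks = toks, warns = warns)
}

# full authorship: optional parenthesized basionym team, then an optional
# combination team
r_authorship <- function(s, pos, repair = TRUE) {
  basionym <- NULL
  combination <- NULL
  toks <- list()
  warns <- list()
  p <- pos
  m <- rx(s, p, "\\( *")
  if (!is.null(m)) {
    team <- r_author_team(s, m$end, repair)
    if (is.null(team)) return(NULL)
    m2 <- rx(s, team$end, " *\\)")
    if (is.null(m2)) return(NULL)
    basionym <- team
    toks <- c(toks, team$toks)
    warns <- c(warns, team$warns)
    p <- m2$end
    save <- p
    sp <- rx(s, p, " +")
    if (!is.null(sp)) {
      comb <- r_author_team(s, sp$end, repair)
      if (!is.null(comb)) {
        combination <- comb
        toks <- c(toks, comb$toks)
        warns <- c(warns, comb$warns)
        p <- comb$end
      } else {
        p <- save
      }
    }
  } else {
    comb <- r_author_team(s, p, repair)
    if (is.null(comb)) return(NULL)
    combination <- comb
    toks <- c(toks, comb$toks)
    warns <- c(warns, comb$warns)
    p <- comb$end
  }
  verbatim <- substring(s, pos, p - 1L)
  # drop repaired injected spaces from the verbatim rendering
  verbatim <- gsub("(?<=\\.) +(?=-)", "", verbatim, perl = TRUE)
  list(end = p, verbatim = verbatim, basionym = basionym,
       combination = combination, toks = toks, warns = warns)
}

#' Match an authorship at the start of a fragment
#'
#' Parses an optional parenthesized basionym author team followed by an
#' optional combination team. Teams split on `&`, `et` and commas, support
#' `ex` sub-teams, filial suffixes (`fil.`, and `f.` when following an author
#' word), hyphenated abbreviations, and a trailing year with optional comma.
#'
#' @param fragment text beginning after an epithet or uninomial.
#' @return `NULL` on no match, otherwise a list with `verbatim`,
#'   `basionym_authors`, `combination_authors` (character vectors),
#'   `year` (or `NA`) and `warnings`.
#' @examples
#' rule_authorship("(Kük.) D.A. Dunlop")
#' rule_authorship("Miller, 1900")
#' @export
rule_authorship <- function(fragment) {
  m <- r_authorship(fragment, 1L)
  if (is.null(m)) return(NULL)
  team_year <- function(team) {
    if (is.null(team) || is.null(team$year)) NA_character_ else team$year$value
  }
  list(
    verbatim = m$verbatim,
    basionym_authors = if (is.null(m$basionym)) character(0)
                       else m$basionym$authors,
    basionym_ex_authors = if (is.null(m$basionym)) character(0)
                          else m$basionym$ex_authors,
    combination_authors = if (is.null(m$combination)) character(0)
                          else m$combination$authors,
    combination_ex_authors = if (is.null(m$combination)) character(0)
                             else m$combination$ex_authors,
    basionym_year = team_year(m$basionym),
    combination_year = team_year(m$combination),
    warnings = m$warns
  )
}

# -- annotations -------------------------------------------------------------

# cf./aff. between genus and epithet mark an approximate identification;
# sp./spp./s.l./s.str. trail a name
r_mid_annotation <- function(s, pos) {
  m <- rx(s, pos, "(?:cf|aff)\\.?(?= )")
  if (is.null(m)) return(NULL)
  norm <- paste0(sub("\\.$", "", m$text), ".")
  list(end = m$end, verbatim = m$text, normalized = norm,
       toks = list(tok("annotation", pos, m$end)))
}

r_tail_annotation <- function(s, pos) {
  m <- rx(s, pos, "s\\.l\\.|s\\.str\\.|(?:spp|sp)\\.?(?![\\p{L}\\d])")
  if (is.null(m)) return(NULL)
  norm <- if (grepl("^s\\.", m$text)) m$text
          else paste0(sub("\\.$", "", m$text), ".")
  list(end = m$end, verbatim = m$text, normalized = norm,
       toks = list(tok("annotation", pos, m$end)))
}

# -- name details ------------------------------------------------------------

new_detail <- function() {
  list(genus = NULL, subgenus = NULL, uninomial = NULL,
       rank = NULL, subuninomial = NULL,
       specific_epithet = NULL, infraspecific_epithets = list(),
       annotation = NULL, authorship = NULL, ignored_tail = NULL)
}

# one name (uninomial, binomial, or deeper), without hybrid handling
r_name <- function(s, pos, abbrev_ok = FALSE, repair = TRUE) {
  toks <- list()
  warns <- list()
  d <- new_detail()
  kind <- "uninomial"

  gm <- r_capword(s, pos)
  genus_abbrev <- FALSE
  if (is.null(gm) && abbrev_ok) {
    gm <- rx(s, pos, "\\p{Lu}\\.(?= )")
    genus_abbrev <- !is.null(gm)
  }
  if (is.null(gm)) return(NULL)
  head_word <- gm$text
  head_start <- pos
  p <- gm$end

  # subgenus: "(Capitalized)". A parenthesized capitalized word is only a
  # subgenus when an epithet follows; otherwise it is a basionym author team
  # ("Palotrae (Breuning) Arv.-Touv.") and is left for the authorship rule.
  m <- rx(s, p, " +\\((?=\\p{Lu})")
  if (!is.null(m)) {
    sub_m <- r_capword(s, m$end)
    if (!is.null(sub_m)) {
      cl <- rx(s, sub_m$end, "\\)")
      if (!is.null(cl)) {
        la <- rx(s, cl$end, " +")
        if (!is.null(la) && !is.null(r_epithet(s, la$end))) {
          d$subgenus <- sub_m$text
          toks <- c(toks, list(tok("subgenus", m$end, sub_m$end)))
          p <- cl$end
        }
      }
    }
  }

  # infrageneric construct: "Eucalyptus subser. Regulares [authorship]"
  save <- p
  sp <- rx(s, p, " +")
  if (!is.null(sp)) {
    rk <- r_rank_marker(s, sp$end)
    if (!is.null(rk) && rk$normalized %in% UNINOMIAL_RANKS) {
      sp2 <- rx(s, rk$end, " +")
      if (!is.null(sp2)) {
        un <- r_capword(s, sp2$end)
        if (!is.null(un)) {
          d$uninomial <- head_word
          d$rank <- list(verbatim = rk$verbatim, normalized = rk$normalized)
          d$subuninomial <- un$text
          toks <- c(toks, list(tok("uninomial", head_start, gm$end)),
                    rk$toks, list(tok("uninomial", sp2$end, un$end)))
          warns <- c(warns, rk$warns)
          p <- un$end
          au <- NULL
          sp3 <- rx(s, p, " +")
          if (!is.null(sp3)) au <- r_authorship(s, sp3$end, repair)
          if (!is.null(au)) {
            d$authorship <- au
            toks <- c(toks, au$toks)
            warns <- c(warns, au$warns)
            p <- au$end
          }
          return(list(end = p, detail = d, kind = "uninomial",
                      toks = toks, warns = warns))
        }
      }
    }
  }
  p <- save

  # approximate-identification annotation between genus and epithet
  sp <- rx(s, p, " +")
  if (!is.null(sp)) {
    ann <- r_mid_annotation(s, sp$end)
    if (!is.null(ann)) {
      d$annotation <- ann$normalized
      toks <- c(toks, ann$toks)
      p <- ann$end
      kind <- "approximation"
    }
  }

  # species epithet and deeper
  save <- p
  sp <- rx(s, p, " +")
  ep <- if (is.null(sp)) NULL else r_epithet(s, sp$end)
  if (!is.null(ep)) {
    d$genus <- head_word
    toks <- c(toks, list(tok("genus", head_start, gm$end)),
              list(tok("specific_epithet", sp$end, ep$end)))
    epithet <- list(value = ep$text, rank = NULL, authorship = NULL)
    p <- ep$end
    sp2 <- rx(s, p, " +")
    if (!is.null(sp2)) {
      au <- r_authorship(s, sp2$end, repair)
      if (!is.null(au)) {
        epithet$authorship <- au
        toks <- c(toks, au$toks)
        warns <- c(warns, au$warns)
        p <- au$end
      }
    }
    d$specific_epithet <- epithet
    kind <- if (kind == "approximation") "approximation" else "binomial"

    # infraspecific parts: [rank] epithet [authorship], repeated
    repeat {
      save2 <- p
      sp3 <- rx(s, p, " +")
      if (is.null(sp3)) break
      q <- sp3$end
      rank <- r_rank_marker(s, q)
      rank_toks <- list()
      rank_warns <- list()
      if (!is.null(rank)) {
        if (rank$normalized %in% UNINOMIAL_RANKS) { p <- save2; break }
        rank_toks <- rank$toks
        rank_warns <- rank$warns
        q <- rank$end
        sp4 <- rx(s, q, " +")
        if (!is.null(sp4)) q <- sp4$end
      }
      ep2 <- r_epithet(s, q)
      if (is.null(ep2)) { p <- save2; break }
      inf <- list(value = ep2$text,
                  rank = if (is.null(rank)) NULL else
                    list(verbatim = rank$verbatim,
                         normalized = rank$normalized),
                  authorship = NULL)
      toks <- c(toks, rank_toks,
                list(tok("infraspecific_epithet", q, ep2$end)))
      warns <- c(warns, rank_warns)
      p <- ep2$end
      sp5 <- rx(s, p, " +")
      if (!is.null(sp5)) {
        au2 <- r_authorship(s, sp5$end, repair)
        if (!is.null(au2)) {
          inf$authorship <- au2
          toks <- c(toks, au2$toks)
          warns <- c(warns, au2$warns)
          p <- au2$end
        }
      }
      d$infraspecific_epithets <- c(d$infraspecific_epithets, list(inf))
    }
    if (length(d$infraspecific_epithets) > 0L &&
        kind != "approximation") kind <- "trinomial_or_deeper"
  } else {
    p <- save
    if (genus_abbrev) return(NULL)  # an abbreviated genus needs an epithet
    d$uninomial <- head_word
    toks <- c(toks, list(tok("uninomial", head_start, gm$end)))
    sp <- rx(s, p, " +")
    if (!is.null(sp)) {
      au <- r_authorship(s, sp$end, repair)
      if (!is.null(au)) {
        d$authorship <- au
        toks <- c(toks, au$toks)
        warns <- c(warns, au$warns)
        p <- au$end
      }
    }
  }

  # trailing annotation ("sp.", "spp.", "s.l.", "s.str.")
  if (is.null(d$annotation)) {
    sp <- rx(s, p, " +")
    if (!is.null(sp)) {
      ann <- r_tail_annotation(s, sp$end)
      if (!is.null(ann)) {
        d$annotation <- ann$normalized
        toks <- c(toks, ann$toks)
        p <- ann$end
      }
    }
  }

  list(end = p, detail = d, kind = kind, toks = toks, warns = warns)
}

code_like <- function(token) {
  grepl("^BOLD:", token) ||
    (grepl("^[A-Za-z0-9:_/-]+$", token) && grepl("[0-9]", token))
}

# parse one operand to completion; a single unconsumed trailing token is
# tolerated as ignored_tail (level-3 warning, except a recognized surrogate
# code after sp./spp.)
parse_operand <- function(s, pos, abbrev_ok = FALSE, repair = TRUE,
                          allow_tail = TRUE) {
  nm <- r_name(s, pos, abbrev_ok, repair)
  if (is.null(nm)) return(list(failed = TRUE, far = pos - 1L))
  p <- nm$end
  n <- nchar(s)
  if (p <= n) {
    if (!allow_tail) return(list(failed = TRUE, far = p - 1L))
    rest <- substring(s, p)
    tail_txt <- sub("^ +", "", rest)
    if (grepl(" ", tail_txt, fixed = TRUE) || !nzchar(tail_txt)) {
      return(list(failed = TRUE, far = p - 1L))
    }
    nm$detail$ignored_tail <- tail_txt
    surrogate_code <- !is.null(nm$detail$annotation) &&
      nm$detail$annotation %in% c("sp.", "spp.") && code_like(tail_txt)
    if (!surrogate_code) {
      nm$warns <- c(nm$warns, list(new_warning("ignored_tail")))
    }
    p <- n + 1L
  }
  nm$end <- p
  nm
}

#' Parse a cleaned name-string into an abstract syntax tree
#'
#' The top of the grammar. Ordered choice over: a named hybrid (leading
#' hybrid sign), a hybrid formula (infix hybrid sign; each operand is parsed
#' by the full name grammar, with abbreviated genera permitted in later
#' operands), and a plain name. A parse succeeds only when the whole input is
#' consumed, except for a single trailing token which is kept as
#' `ignored_tail` with a level-3 warning. The function is total and
#' deterministic: it never raises on arbitrary input, and identical input
#' yields an identical tree.
#'
#' @param cleaned a single cleaned name-string (see [preclean()]).
#' @param abbrev_ok allow an abbreviated genus (`E.`) at the head; used
#'   internally for hybrid-formula operands.
#' @return A list of class `name_ast` with `kind` (one of `uninomial`,
#'   `binomial`, `trinomial_or_deeper`, `named_hybrid`, `hybrid_formula`,
#'   `approximation`), `details`, `warnings`, `positions` (cleaned-string
#'   code-point offsets, 0-based half-open) and `consumed`; or a list of
#'   class `name_parse_failure` carrying `far`, the furthest offset reached.
#' @examples
#' parse_name_ast("Carex scirpoidea Michx. subsp. convoluta")
#' parse_name_ast("Salvelinus fontinalis x Salmo gairdneri")$kind
#' @export
parse_name_ast <- function(cleaned, abbrev_ok = FALSE) {
  stopifnot(is.character(cleaned), length(cleaned) == 1L)
  failure <- function(far) {
    structure(list(failed = TRUE, far = far), class = "name_parse_failure")
  }
  if (is.na(cleaned) || !nzchar(cleaned)) return(failure(0L))
  s <- cleaned
  n <- nchar(s)

  # named hybrid: leading hybrid sign
  m <- rx(s, 1L, "(?:×|[xX](?= ))")
  if (!is.null(m)) {
    sp <- rx(s, m$end, " *")
    op <- parse_operand(s, sp$end, abbrev_ok = FALSE)
    if (isTRUE(op$failed)) return(failure(op$far))
    return(structure(list(
      kind = "named_hybrid",
      details = list(op$detail),
      warnings = op$warns,
      positions = c(list(tok("hybrid_sign", 1L, m$end)), op$toks),
      consumed = n
    ), class = "name_ast"))
  }

  # hybrid formula: split on isolated infix hybrid signs
  sign_m <- gregexpr(" (?:×|[xX]) ", s, perl = TRUE)[[1]]
  if (sign_m[1] != -1L) {
    starts <- as.integer(sign_m)
    lens <- attr(sign_m, "match.length")
    details <- list()
    toks <- list()
    warns <- list()
    op_start <- 1L
    ok <- TRUE
    far <- 0L
    for (i in seq_along(starts)) {
      seg_end <- starts[i] - 1L
      seg <- substring(s, op_start, seg_end)
      op <- parse_operand(seg, 1L, abbrev_ok = (i > 1L), allow_tail = FALSE)
      if (isTRUE(op$failed)) { ok <- FALSE; far <- op_start - 1L + op$far; break }
      details <- c(details, list(op$detail))
      toks <- c(toks, lapply(op$toks, function(t) {
        t$start <- t$start + op_start - 1L
        t$end <- t$end + op_start - 1L
        t
      }))
      warns <- c(warns, op$warns)
      toks <- c(toks, list(tok("hybrid_sign", starts[i] + 1L,
                               starts[i] + 2L)))
      op_start <- starts[i] + lens[i]
    }
    if (ok) {
      seg <- substring(s, op_start)
      op <- parse_operand(seg, 1L, abbrev_ok = TRUE, allow_tail = TRUE)
      if (isTRUE(op$failed)) {
        far <- op_start - 1L + op$far
      } else {
        details <- c(details, list(op$detail))
        toks <- c(toks, lapply(op$toks, function(t) {
          t$start <- t$start + op_start - 1L
          t$end <- t$end + op_start - 1L
          t
        }))
        warns <- c(warns, op$warns)
        return(structure(list(
          kind = "hybrid_formula",
          details = details,
          warnings = warns,
          positions = toks,
          consumed = n
        ), class = "name_ast"))
      }
    }
    return(failure(far))
  }

  # plain name
  op <- parse_operand(s, 1L, abbrev_ok = abbrev_ok, allow_tail = TRUE)
  if (isTRUE(op$failed)) return(failure(op$far))
  structure(list(
    kind = op$kind,
    details = list(op$detail),
    warnings = op$warns,
    positions = op$toks,
    consumed = n
  ), class = "name_ast")
}

#' Detect a surrogate name
#'
#' A surrogate is a placeholder standing in for a proper scientific name,
#' e.g. a barcode-index code after `sp.` (`Coleoptera sp. BOLD:AAV0432`).
#' Detection fires on a `BOLD:` token anywhere in the string, or on an
#' `sp.`/`spp.` annotation followed by a code-like token (mixed case or
#' digits). The `cf.`/`aff.` annotations mark approximate identifications
#' instead and do not make a name a surrogate.
#'
#' @param ast a `name_ast` (or parse failure).
#' @param cleaned the cleaned string the AST was parsed from.
#' @return logical flag.
#' @examples
#' ast <- parse_name_ast("Coleoptera sp. BOLD:AAV0432")
#' detect_surrogate(ast, "Coleoptera sp. BOLD:AAV0432")
#' @export
detect_surrogate <- function(ast, cleaned) {
  if (grepl("\\bBOLD:", cleaned, perl = TRUE)) return(TRUE)
  if (inherits(ast, "name_parse_failure")) return(FALSE)
  for (d in ast$details) {
    if (!is.null(d$annotation) && d$annotation %in% c("sp.", "spp.") &&
        !is.null(d$ignored_tail) && code_like(d$ignored_tail)) {
      return(TRUE)
    }
  }
  FALSE
}
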