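# Candidate term extraction: the headword rule and the three linguistic
# patterns.
#
# Pattern 1 drops the headword from a headword-anchored noun phrase and
# keeps the reduction only when it recurs elsewhere in the same abstract as
# a noun phrase in its own right (the recurrence is what certifies that the
# reduced phrase is used as a named entity).
#
# Pattern 2 matches appositive definitions: "X, a/an/the ... HEADWORD".
#
# Pattern 3 matches hyponymy templates: "X is/are/was/were/as DT ...
# HEADWORD", the generalization of the 40 alignment-learned "is a"
# templates shipped with the package.

.P2_DETS <- c("a", "an", "the")
.P3_LINKS <- c("is", "are", "was", "were", "as")

#' Headword of a term
#'
#' The headword is the last word of the term, or, when a preposition is
#' present, the last word before the first preposition ("inhibitor of
#' kinase" has headword "inhibitor").
#'
#' @param term A non-empty term string.
#' @return The headword (surface form, original case).
#' @export
headword_of <- function(term) {
  words <- strsplit(trimws(term), "\\s+")[[1]]
  if (length(words) == 0 || !nzchar(words[[1]])) stop("empty term")
  lex <- .tagger_lexicon()
  tags <- unname(lex[tolower(words)])
  prep <- which(!is.na(tags) & tags == "PREP")
  if (length(prep) > 0 && prep[[1]] > 1) {
    return(words[[prep[[1]] - 1L]])
  }
  words[[length(words)]]
}

# Build one row of the candidate data.frame from an X noun phrase.
.candidate_row <- function(np, record_id, headword, pattern) {
  surface <- paste(np$tokens$surface, collapse = " ")
  data.frame(
    text = paste(np$tokens$lemma, collapse = " "),
    surface = surface,
    headword = headword,
    pattern = as.integer(pattern),
    record_id = record_id,
    sentence_index = np$sentence_index,
    start = np$start,
    end = np$end,
    stringsAsFactors = FALSE)
}

.empty_candidates <- function() {
  data.frame(text = character(0), surface = character(0),
             headword = character(0), pattern = integer(0),
             record_id = character(0), sentence_index = integer(0),
             start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}

# Deduplicate candidates within a record on normalized text.
.dedup_candidates <- function(df) {
  if (nrow(df) == 0) return(df)
  df[!duplicated(df$text), , drop = FALSE]
}

# Does the lemma (or lowered surface) sequence `key` occur in sentence s at
# some span that the chunker recognizes as exactly that noun phrase?
# Returns a list of (sentence_index, start) for every such occurrence.
.np_occurrences <- function(record, key, match) {
  k <- length(key)
  hits <- list()
  for (s in record$sentences) {
    toks <- s$tokens
    seqv <- if (match == "lemma") toks$lemma else tolower(toks$surface)
    n <- length(seqv)
    if (n < k) next
    for (p in seq_len(n - k + 1L)) {
      if (!all(seqv[p:(p + k - 1L)] == key)) next
      last <- p + k - 1L
      if (toks$tag[last] != "NOUN") next
      np <- extract_noun_phrase(s, last)
      if (is.null(np)) next
      if (np$start == p && np$end == last + 1L) {
        hits[[length(hits) + 1L]] <- list(sentence = s$index, start = p)
      }
    }
  }
  hits
}

#' Pattern 1: headword removal with in-abstract verification
#'
#' For every noun phrase anchored at the headword with at least two tokens,
#' the phrase minus its headword becomes a candidate if and only if the
#' reduced phrase also occurs elsewhere in the same record as a
#' chunker-recognized noun phrase (not merely as a substring), at a span
#' different from the source phrase.  Duplicates within a record are
#' collapsed.
#'
#' @param record A tagged \code{\link{abstract_record}}.
#' @param headword Headword string.
#' @param match \code{"lemma"} (default) or \code{"surface"}: how both the
#'   headword and the recurrence are compared.
#' @return Candidate \code{data.frame} (columns \code{text}, \code{surface},
#'   \code{headword}, \code{pattern}, \code{record_id},
#'   \code{sentence_index}, \code{start}, \code{end}).
#' @export
pattern1_candidates <- function(record, headword,
                                match = c("lemma", "surface")) {
  match <- match.arg(match)
  nps <- find_headword_noun_phrases(record, headword, match = match)
  hw_lemma <- lemmatize(headword)
  rows <- list()
  for (np in nps) {
    k <- nrow(np$tokens)
    if (k < 2) next
    red <- np$tokens[seq_len(k - 1L), , drop = FALSE]
    if (red$lemma[nrow(red)] == hw_lemma) next    # candidate may not end with the headword
    key <- if (match == "lemma") red$lemma else tolower(red$surface)
    occ <- .np_occurrences(record, key, match)
    elsewhere <- Filter(function(o) {
      !(o$sentence == np$sentence_index && o$start == np$start)
    }, occ)
    if (length(elsewhere) == 0) next
    red_np <- structure(
      list(tokens = red, head_index = np$start + k - 2L,
           sentence_index = np$sentence_index,
           start = np$start, end = np$start + k - 1L),
      class = "noun_phrase")
    rows[[length(rows) + 1L]] <-
      .candidate_row(red_np, record$record_id, headword, 1L)
  }
  .dedup_candidates(if (length(rows)) do.call(rbind, rows) else
    .empty_candidates())
}

# Shared matcher for patterns 2 and 3.  For each headword token position h,
# walk left over the defining run, check the determiner / link tokens, then
# chunk X.  `gap` bounds the number of tokens strictly between the
# determiner and the headword.
.defined_by_headword <- function(record, headword, pattern,
                                 match, gap, enumeration_guard) {
  key <- if (match == "lemma") lemmatize(headword) else tolower(headword)
  hw_lemma <- lemmatize(headword)
  rows <- list()
  for (s in record$sentences) {
    toks <- s$tokens
    n <- nrow(toks)
    seqv <- if (match == "lemma") toks$lemma else tolower(toks$surface)
    hits <- which(toks$tag == "NOUN" & seqv == key)
    for (h in hits) {
      if (h < n && toks$tag[h + 1L] == "NOUN") next
      # defining run: contiguous ADJ/NOUN/NUM (plus -ly adverbs for the
      # hyponymy pattern) ending at the headword
      r <- h
      ok_tag <- function(i) {
        toks$tag[i] %in% .NP_TAGS ||
          (pattern == 3L && toks$tag[i] == "OTHER" &&
             grepl("ly$", tolower(toks$surface[i])))
      }
      while (r > 1 && ok_tag(r - 1L)) r <- r - 1L
      if (h - r > gap) next
      det_pos <- r - 1L
      if (det_pos < 1 ||
          !(tolower(toks$surface[det_pos]) %in% .P2_DETS)) next
      if (pattern == 2L) {
        comma_pos <- det_pos - 1L
        if (comma_pos < 1 || toks$tag[comma_pos] != "PUNCT" ||
            toks$surface[comma_pos] != ",") next
        anchor <- comma_pos - 1L
      } else {
        link_pos <- det_pos - 1L
        if (link_pos < 1 ||
            !(tolower(toks$surface[link_pos]) %in% .P3_LINKS)) next
        anchor <- link_pos - 1L
      }
      x <- .chunk_left(s, anchor)
      if (is.null(x)) next
      if (x$tokens$lemma[nrow(x$tokens)] == hw_lemma) next
      if (enumeration_guard && .in_enumeration(s, h, key, match)) next
      rows[[length(rows) + 1L]] <-
        .candidate_row(x, record$record_id, headword, pattern)
    }
  }
  .dedup_candidates(if (length(rows)) do.call(rbind, rows) else
    .empty_candidates())
}

# List-context heuristic: the defining phrase is immediately followed by a
# comma, another ADJ/NOUN/NUM run, and a repetition of the same headword
# ("the 35S rRNA gene, the NTS1 spacer, the 5S rRNA gene, ...").
.in_enumeration <- function(sentence, h, key, match) {
  toks <- sentence$tokens
  n <- nrow(toks)
  if (h >= n || toks$surface[h + 1L] != ",") return(FALSE)
  i <- h + 2L
  steps <- 0L
  while (i <= n && steps < 8L) {
    if (toks$tag[i] == "NOUN") {
      seqi <- if (match == "lemma") toks$lemma[i] else tolower(toks$surface[i])
      if (seqi == key) return(TRUE)
    }
    if (!(toks$tag[i] %in% c(.NP_TAGS, "DET", "PUNCT"))) return(FALSE)
    i <- i + 1L
    steps <- steps + 1L
  }
  FALSE
}

#' Pattern 2: appositive definitions
#'
#' Matches "X, a/an/the ... HEADWORD": a noun phrase X immediately followed
#' by a comma, a determiner, and a contiguous ADJ/NOUN/NUM run ending at
#' the headword.  X is chunked left-maximally from the token before the
#' comma and must not itself end with the headword; pronouns and bare
#' determiners are rejected.
#'
#' @inheritParams pattern1_candidates
#' @param gap Maximum number of tokens between the determiner and the
#'   headword (default 6).
#' @param enumeration_guard When \code{TRUE}, matches inside list contexts
#'   ("the A gene, the B spacer, the C gene") are discarded.  Off by
#'   default.
#' @return Candidate \code{data.frame}; see \code{\link{pattern1_candidates}}.
#' @export
pattern2_candidates <- function(record, headword,
                                match = c("lemma", "surface"),
                                gap = 6L, enumeration_guard = FALSE) {
  match <- match.arg(match)
  if (is.null(record$sentences)) stop("record is not tagged; run tag_record()")
  .defined_by_headword(record, headword, 2L, match, gap, enumeration_guard)
}

#' Pattern 3: "is a" hyponymy templates
#'
#' Matches "X is/are/was/were/as DT ... HEADWORD": a noun phrase X followed
#' by a link token, a determiner, optional ADJ/NOUN/NUM or adverbial
#' modifiers, and the headword.  This generalizes the 40 alignment-learned
#' templates available through \code{\link{load_pattern_table}}.
#'
#' @inheritParams pattern2_candidates
#' @return Candidate \code{data.frame}; see \code{\link{pattern1_candidates}}.
#' @export
pattern3_candidates <- function(record, headword,
                                match = c("lemma", "surface"),
                                gap = 6L, enumeration_guard = FALSE) {
  match <- match.arg(match)
  if (is.null(record$sentences)) stop("record is not tagged; run tag_record()")
  .defined_by_headword(record, headword, 3L, match, gap, enumeration_guard)
}

#' Load the packaged "is a" template table
#'
#' The package ships the 40 alignment-learned hyponymy templates (one per
#' line, with X and Y placeholders).  Loading enforces the count invariant.
#'
#' @param path Path to a template file; defaults to the packaged fixture.
#' @return A \code{pattern_table}: character vector of 40 templates.
#' @export
load_pattern_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pattern_table.tsv",
                        package = "termenrich", mustWork = TRUE)
  }
  templates <- readLines(path, encoding = "UTF-8", warn = FALSE)
  templates <- templates[nzchar(trimws(templates))]
  if (length(templates) != 40L) {
    stop("pattern table must contain exactly 40 templates, found ",
         length(templates))
  }
  structure(templates, class = "pattern_table")
}

#' Parse a hyponymy template into its generalized form
#'
#' Decomposes a template "X <connective> <determiner> <modifiers> Y" into
#' its parts.  Recognized connectives are the copulas (is/are/was/were,
#' normalized to is/are), "as", "such as", "and other", and the bare
#' determiner form ("X a new Y").  Used to verify that every packaged
#' template instantiates the generalized "X is/are/as DT ... Y" pattern.
#'
#' @param template A single template string containing X and Y placeholders.
#' @return List with \code{parsed} (logical), \code{connective},
#'   \code{determiner}, \code{modifiers}.
#' @export
parse_template <- function(template) {
  bad <- list(parsed = FALSE, connective = NA_character_,
              determiner = NA_character_, modifiers = character(0))
  w <- strsplit(trimws(template), "\\s+")[[1]]
  if (length(w) < 2 || w[[1]] != "X" || w[[length(w)]] != "Y") return(bad)
  mid <- w[-c(1, length(w))]
  connective <- NA_character_
  if (length(mid) >= 1 && mid[[1]] %in% c("is", "was")) {
    connective <- "is"; mid <- mid[-1]
  } else if (length(mid) >= 1 && mid[[1]] %in% c("are", "were")) {
    connective <- "are"; mid <- mid[-1]
  } else if (length(mid) >= 1 && mid[[1]] == "as") {
    connective <- "as"; mid <- mid[-1]
  } else if (length(mid) >= 2 && mid[[1]] == "such" && mid[[2]] == "as") {
    connective <- "such as"; mid <- mid[-(1:2)]
  } else if (length(mid) >= 2 && mid[[1]] == "and" && mid[[2]] == "other") {
    connective <- "and other"; mid <- mid[-(1:2)]
  } else if (length(mid) >= 1 && mid[[1]] %in% .P2_DETS) {
    connective <- ""                       # bare appositive-like form
  }
  if (is.na(connective)) return(bad)
  determiner <- ""
  if (length(mid) >= 1 && mid[[1]] %in% .P2_DETS) {
    determiner <- mid[[1]]; mid <- mid[-1]
  }
  if (length(mid) > 6) return(bad)
  list(parsed = TRUE, connective = connective,
       determiner = determiner, modifiers = mid)
}
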