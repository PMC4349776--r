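# Tokenization, sentence splitting, and the built-in rule tagger.
#
# A tagger is any total function: character vector of tokens in, character
# vector of tags of equal length out, with tags drawn from the closed set
# below.  The built-in rule tagger combines a closed-class lexicon
# (determiners, prepositions, copulas/auxiliaries, conjunctions, pronouns,
# a few frequent adjectives) with suffix rules and a default of NOUN, which
# is the right default for the noun-heavy abstracts this package targets.

.TAGSET <- c("NOUN", "ADJ", "NUM", "DET", "PREP", "VERB", "PUNCT", "OTHER")

.tagger_env <- new.env(parent = emptyenv())

.tagger_lexicon <- function() {
  if (is.null(.tagger_env$lex)) {
    path <- system.file("extdata", "tagger_lexicon.tsv",
                        package = "termenrich", mustWork = TRUE)
    df <- read.delim(path, stringsAsFactors = FALSE)
    .tagger_env$lex <- setNames(df$tag, df$word)
  }
  .tagger_env$lex
}

# Abbreviations that a following period does not end a sentence after.
.abbrev_guard <- c(
  "e.g", "i.e", "al", "etc", "fig", "figs", "vs", "cf", "dr", "no",
  "approx", "ca", "spp", "sp", "st"
)

#' Tokenize text
#'
#' Splits on whitespace, then detaches leading and trailing punctuation
#' runs as individual \code{PUNCT} tokens.  Internal punctuation (hyphens
#' in "actin-binding", digits and letters in "21kDa") is kept inside the
#' token.
#'
#' @param text A single string.
#' @return Character vector of tokens.
#' @export
tokenize <- function(text) {
  raw <- strsplit(trimws(text), "\\s+")[[1]]
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0) return(character(0))
  out <- character(0)
  for (w in raw) {
    m <- regmatches(w, regexec("^([[:punct:]]*?)([[:alnum:]].*[[:alnum:]]|[[:alnum:]])?([[:punct:]]*)$", w))[[1]]
    if (length(m) == 0) { out <- c(out, w); next }
    lead <- m[[2]]; core <- m[[3]]; trail <- m[[4]]
    if (nzchar(lead)) out <- c(out, strsplit(lead, "")[[1]])
    if (!is.na(core) && nzchar(core)) out <- c(out, core)
    if (nzchar(trail)) out <- c(out, strsplit(trail, "")[[1]])
  }
  out
}

#' Split text into sentences
#'
#' A sentence break is a period, question mark or exclamation mark followed
#' by whitespace and an upper-case letter or digit, unless the preceding
#' word is on a short abbreviation guard list ("e.g.", "et al.", "Fig.").
#'
#' @param text A single string.
#' @return Character vector of sentence strings (possibly length 0).
#' @export
split_sentences <- function(text) {
  text <- trimws(text)
  if (!nzchar(text)) return(character(0))
  pos <- gregexpr("[.?!](?=\\s+[A-Z0-9])", text, perl = TRUE)[[1]]
  if (pos[1] == -1) return(text)
  keep <- vapply(pos, function(p) {
    prev <- sub(".*?([A-Za-z.]+)$", "\\1", substr(text, max(1, p - 12), p - 1))
    !(tolower(sub("\\.$", "", prev)) %in% .abbrev_guard)
  }, logical(1))
  pos <- pos[keep]
  if (length(pos) == 0) return(text)
  starts <- c(1, pos + 1)
  ends <- c(pos, nchar(text))
  out <- trimws(substring(text, starts, ends))
  out[nzchar(out)]
}

#' Built-in rule part-of-speech tagger
#'
#' Satisfies the tagger contract: a total function from a token vector to an
#' equal-length tag vector over the closed tag set
#' \code{NOUN, ADJ, NUM, DET, PREP, VERB, PUNCT, OTHER}.  Rules, in order:
#' punctuation-only tokens are \code{PUNCT}; lexicon lookup (case-folded);
#' digit-initial tokens (including mixed alphanumerics like "21kDa") are
#' \code{NUM}; hyphenated tokens ending in \code{-ing}/\code{-ed} are
#' \code{ADJ}, other hyphenated tokens \code{NOUN}; derivational adjective
#' suffixes (\code{-al, -ous, -ive, -ic, -ile, -ary, -ful, -less}) and
#' participial \code{-ing}/\code{-ed} give \code{ADJ}; \code{-ly} gives
#' \code{OTHER} (adverb); everything else is \code{NOUN}.
#'
#' @param tokens Character vector of tokens.
#' @return Character vector of tags, same length as \code{tokens}.
#' @export
rule_tagger <- function(tokens) {
  if (length(tokens) == 0) return(character(0))
  lex <- .tagger_lexicon()
  vapply(tokens, function(tok) {
    low <- tolower(tok)
    if (!grepl("[[:alnum:]]", tok)) return("PUNCT")
    hit <- lex[low]
    if (!is.na(hit)) return(unname(hit))
    if (grepl("^[0-9]", tok)) return("NUM")
    if (grepl("-", tok, fixed = TRUE)) {
      return(if (grepl("(ing|ed)$", low)) "ADJ" else "NOUN")
    }
    if (nchar(low) >= 5 && grepl("(ing|ed)$", low)) return("ADJ")
    if (nchar(low) >= 4 &&
        grepl("(al|ous|ive|ic|ile|ary|ful|less)$", low)) return("ADJ")
    if (nchar(low) >= 4 && grepl("ly$", low)) return("OTHER")
    "NOUN"
  }, character(1), USE.NAMES = FALSE)
}

#' Tag a sentence
#'
#' Tokenizes a sentence and applies a tagger satisfying the contract, then
#' attaches lemmas.  Errors if the sentence has no tokens or the tagger
#' returns a vector of the wrong length or with tags outside the closed set.
#'
#' @param sentence_text A single sentence string.
#' @param tagger Tagger function; default \code{\link{rule_tagger}}.
#' @param index Position of the sentence within its record (1-based).
#' @return A \code{tagged_sentence}: list with \code{tokens} (data.frame of
#'   \code{surface}, \code{lemma}, \code{tag}) and \code{index}.
#' @export
tag_sentence <- function(sentence_text, tagger = rule_tagger, index = 1L) {
  toks <- tokenize(sentence_text)
  if (length(toks) == 0) stop("empty sentence cannot be tagged")
  tags <- tagger(toks)
  if (length(tags) != length(toks)) {
    stop("tagger returned ", length(tags), " tags for ",
         length(toks), " tokens")
  }
  if (!all(tags %in% .TAGSET)) {
    stop("tagger produced tags outside the closed tag set: ",
         paste(setdiff(tags, .TAGSET), collapse = ", "))
  }
  structure(
    list(tokens = data.frame(surface = toks,
                             lemma = lemmatize(toks),
                             tag = tags,
                             stringsAsFactors = FALSE),
         index = as.integer(index)),
    class = "tagged_sentence")
}

#' Tag an abstract record
#'
#' Splits the title and body into sentences (title sentences first, then
#' body sentences, preserving order) and tags each one.
#'
#' @param record An \code{\link{abstract_record}}.
#' @param tagger Tagger function; default \code{\link{rule_tagger}}.
#' @return The record with its \code{sentences} element filled.
#' @export
tag_record <- function(record, tagger = rule_tagger) {
  stopifnot(inherits(record, "abstract_record"))
  sents <- c(split_sentences(record$title), split_sentences(record$body))
  record$sentences <- lapply(seq_along(sents), function(i) {
    tag_sentence(sents[[i]], tagger = tagger, index = i)
  })
  record
}

#' Tag every record of a corpus
#'
#' @param corpus List of \code{\link{abstract_record}} objects.
#' @param tagger Tagger function; default \code{\link{rule_tagger}}.
#' @return List of tagged records.
#' @export
tag_corpus <- function(corpus, tagger = rule_tagger) {
  lapply(corpus, tag_record, tagger = tagger)
}
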