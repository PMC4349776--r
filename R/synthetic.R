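# Seeded synthetic data: corpora with entities planted via each linguistic
# pattern, and vocabularies whose positive class carries learnable
# character-level morphology (a suffix signal, mimicking cues like -ase for
# enzymes).  Templates draw on a closed word lexicon with known tags so the
# built-in rule tagger is exact on generated text; this isolates
# pattern-logic testing from tagger noise.

.sim_adjectives <- c(
  "viral", "epithelial", "clinical", "renal", "mitochondrial", "bacterial",
  "metabolic", "chronic", "genomic", "cardiac", "hepatic", "synaptic",
  "infectious", "adhesive")

.sim_syllables <- c(
  "ta", "bel", "vor", "rin", "mak", "lod", "pen", "sur", "tem", "gol",
  "fir", "zan", "mol", "dar", "kep", "lun")

.sim_distractors <- c(
  "The experimental results were analyzed carefully .",
  "These findings suggest further work on the topic .",
  "Samples were collected during the second phase .",
  "The measurements were repeated under identical conditions .")

#' Specification for synthetic corpora and vocabularies
#'
#' @param n_records Number of abstracts to generate.
#' @param headwords Headwords used for planting (each planted instance
#'   draws one of these).
#' @param p1_rate,p2_rate,p3_rate Per-record probability of planting one
#'   instance of each pattern.
#' @param foil_rate Per-record probability of planting an unverified
#'   pattern-1 phrase (a headword phrase whose reduction never recurs, so
#'   the extractor must not emit it).
#' @param n_pos,n_neg Vocabulary sizes per class.
#' @param pos_suffixes,neg_suffixes Disjoint morphology pools; positive
#'   terms end in a positive suffix, negative terms in a negative one.
#' @param noise Label-flip probability in \code{[0, 1)}.
#' @param seed Integer seed fixing all randomness.
#' @return A validated \code{sim_spec} object.
#' @export
sim_spec <- function(n_records = 50L,
                     headwords = c("protein", "disease", "cell"),
                     p1_rate = 0.6, p2_rate = 0.6, p3_rate = 0.6,
                     foil_rate = 0.3,
                     n_pos = 2000L, n_neg = 2000L,
                     pos_suffixes = c("ase", "olin", "idase", "erin"),
                     neg_suffixes = c("itis", "osis", "emia", "oid"),
                     noise = 0, seed = 1L) {
  rates <- c(p1_rate, p2_rate, p3_rate, foil_rate)
  stopifnot(n_records >= 0, all(rates >= 0 & rates <= 1),
            noise >= 0, noise < 1, length(headwords) >= 1)
  for (p in pos_suffixes) for (q in neg_suffixes) {
    if (endsWith(p, q) || endsWith(q, p)) {
      stop("positive and negative suffix pools overlap: ", p, " / ", q)
    }
  }
  structure(
    list(n_records = as.integer(n_records), headwords = headwords,
         p1_rate = p1_rate, p2_rate = p2_rate, p3_rate = p3_rate,
         foil_rate = foil_rate,
         n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         pos_suffixes = pos_suffixes, neg_suffixes = neg_suffixes,
         noise = noise, seed = as.integer(seed)),
    class = "sim_spec")
}

# Pronounceable lowercase stem from random syllables (2 or 3).
.sim_stem <- function(n_syl = sample(2:3, 1)) {
  paste(sample(.sim_syllables, n_syl, replace = TRUE), collapse = "")
}

# A capitalized entity name for the X slot of patterns 2/3.
.sim_entity <- function() {
  s <- .sim_stem()
  paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
}

#' Generate a synthetic corpus with planted pattern instances
#'
#' Each record is assembled from sentence templates: a pattern-1 planting
#' puts "\code{<X> <headword>}" in the body and the bare \code{<X>} in the
#' title (the recurrence that pattern 1 requires); pattern-2 plantings are
#' appositives ("\code{<E>, a <adj> <noun> <headword>, was studied ...}");
#' pattern-3 plantings are copular definitions ("\code{<E> is a <adj>
#' <headword> ...}").  Unverified pattern-1 foils and distractor sentences
#' are mixed in.  The returned ground truth is exhaustive: extractors run
#' on the corpus must recover exactly these candidates.
#'
#' @param spec A \code{\link{sim_spec}}.
#' @return List with \code{records} (untagged
#'   \code{\link{abstract_record}}s) and \code{truth} (data.frame:
#'   \code{record_id}, \code{pattern}, \code{headword}, \code{text},
#'   \code{surface}, \code{sentence_index}, \code{start}, \code{end}).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  records <- vector("list", spec$n_records)
  truth <- list()
  add_truth <- function(rid, pattern, hw, surface, sent, start, end) {
    truth[[length(truth) + 1L]] <<- data.frame(
      record_id = rid, pattern = as.integer(pattern), headword = hw,
      text = normalize_phrase(surface), surface = surface,
      sentence_index = as.integer(sent), start = as.integer(start),
      end = as.integer(end), stringsAsFactors = FALSE)
  }
  for (i in seq_len(spec$n_records)) {
    rid <- sprintf("SYN%04d", i)
    plant1 <- stats::runif(1) < spec$p1_rate
    plant2 <- stats::runif(1) < spec$p2_rate
    plant3 <- stats::runif(1) < spec$p3_rate
    foil <- stats::runif(1) < spec$foil_rate
    adjs <- sample(.sim_adjectives, 4)
    body <- character(0)
    sent_no <- 1L                       # sentence 1 is always the title
    if (plant1) {
      hw <- sample(spec$headwords, 1)
      x <- paste(adjs[[1]], .sim_stem())
      title <- paste("Studies of", x)
      body <- c(body, paste("The", x, hw, "was examined in detail ."))
      sent_no <- sent_no + 1L
      add_truth(rid, 1L, hw, x, sent_no, 2L, 4L)
    } else {
      title <- "A general report on current methods"
    }
    if (foil) {
      hw <- sample(spec$headwords, 1)
      x <- paste(adjs[[2]], .sim_stem())
      body <- c(body, paste("The", x, hw, "was observed once ."))
      sent_no <- sent_no + 1L
    }
    if (plant2) {
      hw <- sample(spec$headwords, 1)
      e <- .sim_entity()
      def <- paste(adjs[[3]], .sim_stem())
      body <- c(body,
                paste0(e, " , a ", def, " ", hw, " , was studied in culture ."))
      sent_no <- sent_no + 1L
      add_truth(rid, 2L, hw, e, sent_no, 1L, 2L)
    }
    if (plant3) {
      hw <- sample(spec$headwords, 1)
      e <- .sim_entity()
      link <- sample(c("is", "are", "was"), 1)
      body <- c(body, paste(e, link, "a", adjs[[4]], hw, "in many organisms ."))
      sent_no <- sent_no + 1L
      add_truth(rid, 3L, hw, e, sent_no, 1L, 2L)
    }
    body <- c(body, sample(.sim_distractors, 1))
    records[[i]] <- abstract_record(rid, title, paste(body, collapse = " "))
  }
  truth_df <- if (length(truth)) do.call(rbind, truth) else data.frame(
    record_id = character(0), pattern = integer(0), headword = character(0),
    text = character(0), surface = character(0),
    sentence_index = integer(0), start = integer(0), end = integer(0),
    stringsAsFactors = FALSE)
  list(records = records, truth = truth_df)
}

#' Generate a synthetic labeled vocabulary
#'
#' Positive terms end in a suffix from the positive pool, negative terms in
#' one from the (disjoint) negative pool, so the two classes are separable
#' from character n-gram and headword-suffix features.  A fraction
#' \code{noise} of labels is flipped independently; at \code{noise = 0.5}
#' the labels carry no signal at all.
#'
#' @param spec A \code{\link{sim_spec}}.
#' @return \code{data.frame} with columns \code{term}, \code{category}
#'   (\code{"TARGET"} or \code{"OTHER"}, before noise), \code{label}
#'   (after noise).
#' @export
generate_vocabulary <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed + 1L)
  make_terms <- function(n, suffixes) {
    out <- character(0)
    while (length(out) < n) {
      batch <- vapply(seq_len(n), function(i) {
        word <- paste0(.sim_stem(), sample(suffixes, 1))
        if (stats::runif(1) < 0.3) {
          paste(sample(.sim_adjectives, 1), word)
        } else word
      }, character(1))
      out <- unique(c(out, batch))
    }
    out[seq_len(n)]
  }
  pos <- make_terms(spec$n_pos, spec$pos_suffixes)
  neg <- make_terms(spec$n_neg, spec$neg_suffixes)
  df <- data.frame(
    term = c(pos, neg),
    category = rep(c("TARGET", "OTHER"), c(spec$n_pos, spec$n_neg)),
    label = rep(c(1L, -1L), c(spec$n_pos, spec$n_neg)),
    stringsAsFactors = FALSE)
  if (spec$noise > 0) {
    flip <- stats::runif(nrow(df)) < spec$noise
    df$label[flip] <- -df$label[flip]
  }
  df
}

#' Write a generated vocabulary as a TSV readable by read_vocabulary
#' @param vocab Output of \code{\link{generate_vocabulary}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  write.table(vocab[, c("term", "category")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
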