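# Shared fixtures: hand-tagged sentences, random tagged sentences, and the
# brute-force noun-phrase oracle used for chunker equivalence checks.

# Build a tagged_sentence with explicitly supplied tags (bypasses the rule
# tagger so tests control the tag sequence exactly).
make_tagged <- function(tokens, tags, index = 1L) {
  tag_sentence(paste(tokens, collapse = " "),
               tagger = function(t) tags, index = index)
}

# Random tagged sentence over the closed tag set; surfaces are synthetic
# word forms, punctuation tokens get "," as surface.
random_tagged_sentence <- function(n, index = 1L) {
  tags <- sample(c("NOUN", "ADJ", "NUM", "DET", "PREP", "VERB", "PUNCT",
                   "OTHER"),
                 n, replace = TRUE,
                 prob = c(0.35, 0.2, 0.05, 0.1, 0.1, 0.1, 0.05, 0.05))
  tokens <- ifelse(tags == "PUNCT", ",",
                   paste0("w", seq_len(n), sample(letters, n, TRUE)))
  make_tagged(tokens, tags, index = index)
}

# Independent oracle: maximal ADJ/NOUN/NUM run ending at head position h,
# computed by explicit enumeration over all left start points.
np_oracle_span <- function(tags, h) {
  ok <- tags %in% c("ADJ", "NOUN", "NUM")
  if (tags[h] != "NOUN") return(NULL)
  if (h < length(tags) && tags[h + 1L] == "NOUN") return(NULL)
  starts <- Filter(function(s) all(ok[s:h]), seq_len(h))
  c(start = min(starts), end = h + 1L)
}

# A tiny abstract with pattern instances used across extraction tests.
figure_corpus <- function() {
  r1 <- abstract_record("F1", "Infantile autism in young children",
    "The infantile autism disease was studied in several patients .")
  r2 <- abstract_record("F2", "Regulation of actin dynamics",
    paste("Coflin , a 21kDa actin-binding protein , controls actin dynamics .",
          "ArhGAP9 , a novel MAP kinase docking protein , was characterized ."))
  r3 <- abstract_record("F3", "Tubulin cofactors",
    paste("TBCE is a tubulin polymerizing protein .",
          "Cholangiocytes are the epithelial cells of the bile ducts ."))
  tag_corpus(list(r1, r2, r3))
}

# Featurize + vectorize a vocabulary data.frame.
vocab_matrix <- function(vocab) {
  sets <- lapply(vocab$term, function(t) featurize(t, headword_of(t)))
  vectorize(sets)
}
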