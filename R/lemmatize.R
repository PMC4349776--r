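# Words that look plural but are not, or whose singular the suffix rules
# would mangle.  Kept deliberately small: the lemmatizer is a rule backend
# behind a pluggable interface, not a full morphological analyzer.
.lemma_invariant <- c(
  "species", "series", "as", "is", "was", "its", "this", "thus", "has",
  "lens", "aids", "pancreas", "diabetes", "rabies", "herpes", "measles",
  "caries", "bias", "atlas", "gas", "plus", "minus", "various", "previous",
  "numerous", "homologous", "analogous", "endogenous", "exogenous"
)

.lemma_irregular <- c(
  mice = "mouse", men = "man", women = "woman", feet = "foot",
  teeth = "tooth", children = "child", analyses = "analysis",
  hypotheses = "hypothesis", diagnoses = "diagnosis", nuclei = "nucleus",
  foci = "focus", loci = "locus", fungi = "fungus", bacteria = "bacterium",
  mitochondria = "mitochondrion", criteria = "criterion", data = "data",
  viruses = "virus", statuses = "status", stimuli = "stimulus"
)

#' Lemmatize a token
#'
#' Case-folds to lower case and strips regular English plural endings with a
#' small irregular/invariant exception list.  The function is deterministic
#' and idempotent: \code{lemmatize(lemmatize(x)) == lemmatize(x)}.
#'
#' The rule backend handles \code{-ies -> -y}, sibilant plurals
#' (\code{-xes/-zes/-ches/-shes/-sses -> drop es}), and bare \code{-s}
#' stripping; words ending in
#' \code{-ss}, \code{-us} or \code{-is} are left alone (so "class", "virus"
#' and "analysis" are fixed points).
#'
#' @param token Character vector of tokens.
#' @param backend Lemmatizer backend; only \code{"rule"} is built in.  A
#'   function \code{character -> character} may be supplied instead.
#' @return Character vector of lemmas, same length as \code{token}.
#' @examples
#' lemmatize(c("cells", "Diseases", "viruses", "protein", "bodies"))
#' @export
lemmatize <- function(token, backend = "rule") {
  if (is.function(backend)) return(backend(token))
  if (!identical(backend, "rule")) {
    stop("unknown lemmatizer backend: ", backend)
  }
  x <- tolower(token)
  irr <- match(x, names(.lemma_irregular))
  hit <- !is.na(irr)
  x[hit] <- unname(.lemma_irregular[irr[hit]])
  todo <- !hit & !(x %in% .lemma_invariant) & nchar(x) > 3 &
    grepl("s$", x) & !grepl("(ss|us|is)$", x)
  y <- x[todo]
  y <- ifelse(grepl("ies$", y) & nchar(y) > 4, sub("ies$", "y", y),
       ifelse(grepl("(x|z|ch|sh|ss)es$", y), sub("es$", "", y),
              sub("s$", "", y)))
  x[todo] <- y
  x
}

#' Normalize a phrase for matching
#'
#' Case-folds, collapses whitespace, and lemmatizes each word.  This is the
#' canonical form used for candidate deduplication, known-term filtering and
#' pattern-1 recurrence matching.
#'
#' @param phrase Character vector of phrases.
#' @return Character vector of normalized phrases.
#' @export
normalize_phrase <- function(phrase) {
  vapply(phrase, function(p) {
    w <- strsplit(tolower(trimws(p)), "\\s+")[[1]]
    paste(lemmatize(w), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}
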