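# Character n-gram features for candidate phrases.
#
# Four feature families, all binary:
#   * basic:  within-word letter trigrams               ("mos", "osa", ...)
#   * prefix: first two and three characters of a word, "$"-marked
#             ("mo$", "mos$")
#   * headword: the same two families computed from the headword carry a
#             "!h" marker ("vir!h", "vi$!h") so that headword evidence is
#             kept separate from the rest of the phrase
#   * suffix: last 3, 4 and 5 characters of the headword, "!s"-marked
#             ("ase!s"), emitted only when the headword has more than five
#             characters (suffixes like -ase are strong category cues)
#
# Trigrams never cross word boundaries.  Phrases are case-folded before
# featurization; digits and internal hyphens are kept as literal characters.

.word_features <- function(w, marker = "") {
  n <- nchar(w)
  out <- character(0)
  if (n >= 2) out <- c(out, paste0(substr(w, 1, 2), "$", marker))
  if (n >= 3) {
    out <- c(out, paste0(substr(w, 1, 3), "$", marker))
    tg <- substring(w, seq_len(n - 2L), seq_len(n - 2L) + 2L)
    out <- c(out, paste0(tg, marker))
  }
  out
}

#' Featurize a phrase
#'
#' Produces the binary feature set for a candidate phrase and its headword.
#' Words of the phrase equal to the headword (case-folded) contribute their
#' trigram and prefix features with the headword marker \code{"!h"}; all
#' other words contribute unmarked trigrams and \code{"$"}-marked prefixes.
#' If the headword is not a word of the phrase it is featurized separately
#' with the headword marker.  Headwords longer than five characters
#' additionally contribute their last 3, 4 and 5 characters as
#' \code{"!s"}-marked suffix features.
#'
#' @param phrase Non-empty phrase (normalization to lower case is applied).
#' @param headword The phrase's headword; defaults to
#'   \code{\link{headword_of}(phrase)}.
#' @return A \code{feature_set}: sorted character vector of unique feature
#'   strings.
#' @examples
#' featurize("mosaic virus")   # the 11 features of the worked example
#' @export
featurize <- function(phrase, headword = headword_of(phrase)) {
  phrase <- tolower(trimws(phrase))
  if (!nzchar(phrase)) stop("empty phrase cannot be featurized")
  hw <- tolower(trimws(headword))
  words <- strsplit(phrase, "\\s+")[[1]]
  feats <- character(0)
  for (w in words) {
    feats <- c(feats, .word_features(w, if (w == hw) "!h" else ""))
  }
  if (!(hw %in% words)) {
    feats <- c(feats, .word_features(hw, "!h"))
  }
  nh <- nchar(hw)
  if (nh > 5) {
    feats <- c(feats, paste0(substring(hw, nh - c(2L, 3L, 4L)), "!s"))
  }
  structure(sort(unique(feats)), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set> ", length(x), " features: ",
      paste(unclass(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Vectorize feature sets into a sparse binary matrix
#'
#' Builds (or reuses) a stable feature-to-column index and encodes each
#' feature set as a binary row.  With a supplied index (the prediction
#' path), features absent from the index are dropped.
#'
#' @param feature_sets List of \code{\link{featurize}} outputs (character
#'   vectors).
#' @param index Optional existing feature index (character vector of
#'   feature names in column order) from a trained model.
#' @return List with \code{matrix} (a \code{dgCMatrix},
#'   rows = phrases, columns = features) and \code{index}.
#' @export
vectorize <- function(feature_sets, index = NULL) {
  if (is.null(index)) {
    index <- sort(unique(unlist(feature_sets, use.names = FALSE)))
  }
  lookup <- setNames(seq_along(index), index)
  per_row <- lapply(feature_sets, function(fs) {
    cols <- lookup[unclass(fs)]
    unname(cols[!is.na(cols)])
  })
  jj <- unlist(per_row, use.names = FALSE)
  ii <- rep.int(seq_along(per_row), lengths(per_row))
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(length(feature_sets), length(index)),
                            dimnames = list(NULL, index))
  list(matrix = m, index = index)
}

#' Write a feature index as TSV
#' @param index Character vector of feature names in column order.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_feature_index <- function(index, path) {
  write.table(data.frame(feature = index, column = seq_along(index)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
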