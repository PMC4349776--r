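# End-to-end orchestration: tag corpus -> run patterns per headword ->
# dedupe -> classify -> split into known vs new terms against the existing
# vocabulary.

#' Run configuration for the extraction pipeline
#'
#' @param headwords Character vector of headwords (at least one).
#' @param patterns Subset of \code{c(1, 2, 3)}: which extractors to run.
#' @param models A single \code{model_params} object applied to every
#'   headword, or a named list mapping each headword to its model.
#' @param vocabulary Vocabulary \code{data.frame} as returned by
#'   \code{\link{read_vocabulary}} or \code{\link{generate_vocabulary}}
#'   (columns \code{term}, \code{label}); its positive entries define the
#'   known-term set.  May be \code{NULL} (every kept term counts as new).
#' @param threshold Decision threshold; candidates with decision value
#'   strictly greater are retained (default 0; raise it to trade recall
#'   for precision).
#' @param match \code{"lemma"} or \code{"surface"} matching for headwords
#'   and pattern-1 recurrences.
#' @param gap Token gap cap for patterns 2 and 3.
#' @param enumeration_guard Discard list-context matches (default off).
#' @param stopwords Optional character vector of normalized terms to drop
#'   (hook for filtering over-general terms); default empty.
#' @return A validated \code{run_config} object.
#' @export
run_config <- function(headwords, patterns = c(1L, 2L, 3L), models = NULL,
                       vocabulary = NULL, threshold = 0,
                       match = c("lemma", "surface"), gap = 6L,
                       enumeration_guard = FALSE, stopwords = character(0)) {
  match <- match.arg(match)
  stopifnot(length(headwords) >= 1, length(patterns) >= 1,
            all(patterns %in% 1:3))
  structure(
    list(headwords = headwords, patterns = as.integer(patterns),
         models = models, vocabulary = vocabulary, threshold = threshold,
         match = match, gap = as.integer(gap),
         enumeration_guard = enumeration_guard, stopwords = stopwords),
    class = "run_config")
}

.model_for <- function(config, headword) {
  m <- config$models
  if (is.null(m)) return(NULL)
  if (inherits(m, "model_params")) return(m)
  if (is.list(m)) {
    if (is.null(m[[headword]])) {
      stop("no classifier model mapped to headword: ", headword)
    }
    return(m[[headword]])
  }
  stop("models must be a model_params object or a named list of them")
}

#' Run the extraction pipeline
#'
#' For every record and headword, runs the enabled pattern extractors;
#' deduplicates candidates on (headword, normalized text); scores each
#' unique term with the classifier (features are computed from the term
#' and its own headword) and keeps those above the decision threshold;
#' finally partitions the kept terms into those already present in the
#' positive vocabulary (known) and new ones.
#'
#' @param corpus List of \code{\link{abstract_record}}s (tagged records
#'   are used as-is; untagged ones are tagged with the default tagger).
#' @param config A \code{\link{run_config}}.  If \code{config$models} is
#'   \code{NULL} every candidate passes the classifier stage unscored.
#' @return List with \code{candidates} (data.frame of kept terms with
#'   \code{decision} and \code{status} in \code{known/new}) and
#'   \code{report} (an \code{extraction_report}).
#' @export
run_extraction <- function(corpus, config) {
  stopifnot(inherits(config, "run_config"))
  corpus <- lapply(corpus, function(r) {
    if (is.null(r$sentences)) tag_record(r) else r
  })
  pieces <- list()
  for (rec in corpus) {
    for (hw in config$headwords) {
      for (p in config$patterns) {
        cand <- switch(as.character(p),
          "1" = pattern1_candidates(rec, hw, match = config$match),
          "2" = pattern2_candidates(rec, hw, match = config$match,
                                    gap = config$gap,
                                    enumeration_guard = config$enumeration_guard),
          "3" = pattern3_candidates(rec, hw, match = config$match,
                                    gap = config$gap,
                                    enumeration_guard = config$enumeration_guard))
        if (nrow(cand)) pieces[[length(pieces) + 1L]] <- cand
      }
    }
  }
  cand <- if (length(pieces)) do.call(rbind, pieces) else .empty_candidates()
  # pattern provenance for the report, before cross-pattern dedup
  pattern_counts <- setNames(integer(3), as.character(1:3))
  if (nrow(cand)) {
    per <- table(cand$pattern[!duplicated(cand[c("headword", "text", "pattern")])])
    pattern_counts[names(per)] <- as.integer(per)
  }
  uniq <- cand[!duplicated(cand[c("headword", "text")]), , drop = FALSE]
  if (length(config$stopwords) && nrow(uniq)) {
    uniq <- uniq[!(uniq$text %in% config$stopwords), , drop = FALSE]
  }
  if (nrow(uniq) && !is.null(config$models)) {
    scores <- numeric(nrow(uniq))
    for (hw in unique(uniq$headword)) {
      rows <- which(uniq$headword == hw)
      model <- .model_for(config, hw)
      sets <- lapply(uniq$text[rows],
                     function(t) featurize(t, headword_of(t)))
      X <- vectorize(sets, index = model$feature_index)$matrix
      scores[rows] <- decision(model, X)
    }
    uniq$decision <- scores
    uniq <- uniq[uniq$decision > config$threshold, , drop = FALSE]
  } else if (nrow(uniq)) {
    uniq$decision <- NA_real_
  } else {
    uniq$decision <- numeric(0)
  }
  known_terms <- if (!is.null(config$vocabulary)) {
    unique(config$vocabulary$term[config$vocabulary$label == 1L])
  } else character(0)
  uniq$status <- ifelse(uniq$text %in% known_terms, "known", "new")
  report <- structure(
    list(total = nrow(uniq),
         known = sum(uniq$status == "known"),
         new = sum(uniq$status == "new"),
         per_pattern = pattern_counts,
         per_headword = if (nrow(uniq)) table(uniq$headword) else
           table(character(0))),
    class = "extraction_report")
  rownames(uniq) <- NULL
  list(candidates = uniq, report = report)
}

#' @export
print.extraction_report <- function(x, ...) {
  cat("<extraction_report>\n",
      "  unique terms kept: ", x$total, "\n",
      "  already known:     ", x$known, "\n",
      "  new terms:         ", x$new, "\n",
      "  per pattern (pre-dedup): ",
      paste(names(x$per_pattern), x$per_pattern, sep = "=", collapse = " "),
      "\n", sep = "")
  invisible(x)
}
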