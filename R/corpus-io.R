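# Corpus, vocabulary and candidate I/O.  The canonical dialect is UTF-8
# tab-separated text with a header row and no quoting; the MEDLINE reader
# parses TI/AB fields of nlm-format records only.

#' Construct an abstract record
#'
#' @param record_id PMID-like identifier, unique within a corpus.
#' @param title Title text.
#' @param body Abstract body text.
#' @return An object of class \code{abstract_record}.  The \code{sentences}
#'   element is \code{NULL} until the record is tagged with
#'   \code{\link{tag_record}}.
#' @export
abstract_record <- function(record_id, title, body) {
  stopifnot(length(record_id) == 1, nzchar(record_id))
  structure(
    list(record_id = as.character(record_id),
         title = as.character(title),
         body = as.character(body),
         sentences = NULL),
    class = "abstract_record")
}

#' @export
print.abstract_record <- function(x, ...) {
  cat("<abstract_record>", x$record_id, "\n  title:", x$title, "\n")
  if (!is.null(x$sentences)) {
    cat("  tagged:", length(x$sentences), "sentences\n")
  }
  invisible(x)
}

#' Read a corpus of abstracts
#'
#' Two plain-text formats are supported: a TSV with columns
#' \code{record_id}, \code{title}, \code{body}, and MEDLINE-style records
#' (\code{PMID-}, \code{TI  -}, \code{AB  -} fields, records separated by
#' blank lines, continuation lines indented).
#'
#' @param path Path to the corpus file.
#' @param format \code{"tsv"} or \code{"medline"}.
#' @return List of \code{\link{abstract_record}} objects.
#' @export
read_abstracts <- function(path, format = c("tsv", "medline")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path)
  recs <- if (format == "tsv") .read_abstracts_tsv(path) else
    .read_abstracts_medline(path)
  ids <- vapply(recs, `[[`, character(1), "record_id")
  if (anyDuplicated(ids)) {
    stop("duplicate record_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  recs
}

.read_abstracts_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0) return(list())
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  need <- c("record_id", "title", "body")
  if (!identical(header[seq_along(need)], need)) {
    stop("TSV header must start with: ", paste(need, collapse = ", "))
  }
  out <- vector("list", length(lines) - 1L)
  for (i in seq_along(out)) {
    f <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L || !nzchar(f[[1]])) {
      stop("malformed corpus row at line ", i + 1L, " of ", path)
    }
    out[[i]] <- abstract_record(f[[1]], f[[2]], f[[3]])
  }
  out
}

.read_abstracts_medline <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  recs <- list()
  cur <- NULL
  field <- ""
  flush <- function(cur) {
    if (is.null(cur) || is.null(cur$PMID)) return(NULL)
    abstract_record(cur$PMID,
                    if (is.null(cur$TI)) "" else cur$TI,
                    if (is.null(cur$AB)) "" else cur$AB)
  }
  for (ln in c(lines, "")) {
    if (!nzchar(trimws(ln))) {
      r <- flush(cur)
      if (!is.null(r)) recs[[length(recs) + 1L]] <- r
      cur <- NULL
      field <- ""
      next
    }
    if (grepl("^\\s+", ln)) {            # continuation of previous field
      if (nzchar(field) && !is.null(cur[[field]])) {
        cur[[field]] <- paste(cur[[field]], trimws(ln))
      }
      next
    }
    m <- regmatches(ln, regexec("^([A-Z]{2,4})\\s*-\\s?(.*)$", ln))[[1]]
    if (length(m) == 3) {
      if (is.null(cur)) cur <- list()
      field <- m[[2]]
      if (field %in% c("PMID", "TI", "AB")) {
        cur[[field]] <- m[[3]]
      } else {
        field <- ""                      # field we do not track
      }
    }
  }
  recs
}

#' Write a corpus of abstracts as TSV
#'
#' Newlines and tabs inside fields are normalized to single spaces so the
#' round trip \code{read_abstracts(write_abstracts(x))} is the identity on
#' normalized records.
#'
#' @param records List of \code{\link{abstract_record}} objects.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_abstracts <- function(records, path) {
  clean <- function(x) gsub("[\t\r\n]+", " ", x)
  lines <- c("record_id\ttitle\tbody",
             vapply(records, function(r) {
               paste(r$record_id, clean(r$title), clean(r$body), sep = "\t")
             }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a labeled vocabulary
#'
#' Reads a TSV with columns \code{term} and \code{category} and assigns the
#' binary label used for classifier training: \code{+1} when the category is
#' in \code{positive_categories}, \code{-1} otherwise.  Terms are normalized
#' (case-folded, whitespace-collapsed) and lemmatized; the original surface
#' form is retained in the \code{surface} column.  Entries whose term is
#' empty after normalization are skipped with a warning.
#'
#' @param path Path to the vocabulary TSV.
#' @param positive_categories Character vector of category names forming the
#'   positive class.
#' @return \code{data.frame} with columns \code{term} (normalized),
#'   \code{surface}, \code{category}, \code{label}.
#' @export
read_vocabulary <- function(path, positive_categories) {
  if (!file.exists(path)) stop("vocabulary file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, quote = "",
                   colClasses = "character")
  if (!all(c("term", "category") %in% names(df))) {
    stop("vocabulary TSV must have columns: term, category")
  }
  norm <- normalize_phrase(df$term)
  keep <- nzchar(norm)
  if (any(!keep)) {
    warning(sum(!keep), " vocabulary entries with empty terms skipped")
  }
  data.frame(
    term = norm[keep],
    surface = df$term[keep],
    category = df$category[keep],
    label = ifelse(df$category[keep] %in% positive_categories, 1L, -1L),
    stringsAsFactors = FALSE)
}

#' Write extracted candidate terms as TSV
#'
#' @param candidates Candidate \code{data.frame} as returned by the pattern
#'   extractors or \code{\link{run_extraction}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  cols <- intersect(
    c("text", "surface", "headword", "pattern", "record_id",
      "sentence_index", "start", "end", "decision", "status"),
    names(candidates))
  write.table(candidates[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
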