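# Article/sentence data model and plain-text ingestion.

ROB_PROPERTIES <- c("seq_gen", "alloc_conc", "blind")
ROB_SOURCES <- c("fulltext", "pubmed_title", "pubmed_title_abstract")

# Sentence-final punctuation is a boundary only when followed by whitespace
# and an uppercase letter or digit, and the token before the period is not a
# known abbreviation.
.abbreviations <- c(
  "vs", "et al", "al", "fig", "figs", "ref", "refs", "eq", "eqs", "no",
  "nos", "dr", "mr", "mrs", "ms", "prof", "st", "jr", "sr", "etc", "e.g",
  "i.e", "cf", "ca", "approx", "vol", "pp", "ed", "eds"
)

#' Normalize text for quotation matching
#'
#' Lower-cases, maps typographic (curly) quotes and dashes to their ASCII
#' forms, replaces all remaining punctuation with spaces and collapses
#' whitespace. Reviewer quotations frequently carry typographic quotes that
#' the article text does not (or vice versa); matching is performed on this
#' canonical form.
#'
#' @param text Character vector.
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalize_text("“Sealed, opaque envelopes.”")
normalize_text <- function(text) {
  x <- tolower(text)
  x <- gsub("[‘’‚‛]", "'", x)
  x <- gsub("[“”„‟]", "\"", x)
  x <- gsub("[‐‑‒–—―]", "-", x)
  x <- gsub("[^[:alnum:]]+", " ", x)
  trimws(gsub("[[:space:]]+", " ", x))
}

#' Split document text into sentences
#'
#' Deterministic rule-based splitter: a sentence ends at `.`, `!` or `?`
#' followed by whitespace and an uppercase letter or digit, unless the word
#' preceding a period is a common abbreviation ("vs.", "et al.", "Fig.",
#' "ref.", ...). The concatenation of the returned sentences reconstructs
#' the input up to inter-sentence whitespace.
#'
#' @param text A single character string (possibly empty).
#' @return A data frame with columns `index` (0-based), `text` and
#'   `normalized` (see [normalize_text()]); zero rows for empty input.
#' @export
#' @examples
#' segment_sentences("A double-blind trial. Allocation used sealed envelopes (ref. 4). Done.")
segment_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(index = integer(), text = character(),
                      normalized = character(), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  # candidate boundaries: terminator (+ closing quotes/brackets) then
  # whitespace then uppercase/digit
  m <- gregexpr("[.!?][\"'’”)\\]]*[[:space:]]+(?=[[:upper:][:digit:]])",
                text, perl = TRUE)[[1]]
  starts <- 1L
  if (m[1] != -1L) {
    ends_at <- as.integer(m) + attr(m, "match.length") - 1L
    keep <- logical(length(m))
    for (k in seq_along(m)) {
      pos <- as.integer(m[k])
      if (substr(text, pos, pos) != ".") { keep[k] <- TRUE; next }
      before <- substr(text, max(1L, pos - 12L), pos - 1L)
      tok <- regmatches(before, regexpr("[[:alpha:].]+$", before))
      tok <- if (length(tok)) tolower(sub("\\.$", "", tok)) else ""
      two <- regmatches(before, regexpr("[[:alpha:]]+ [[:alpha:]]+$", before))
      two <- if (length(two)) tolower(two) else ""
      keep[k] <- !(tok %in% .abbreviations || two %in% .abbreviations ||
                     nchar(tok) == 1L)  # single initials, "J. Smith"
    }
    starts <- c(1L, ends_at[keep] + 1L)
  }
  stops <- c(starts[-1L] - 1L, nchar(text))
  sent <- trimws(substring(text, starts, stops))
  sent <- sent[nzchar(sent)]
  data.frame(index = seq_along(sent) - 1L, text = sent,
             normalized = normalize_text(sent), stringsAsFactors = FALSE)
}

#' Construct an article document
#'
#' Builds the ordered sentence list according to the feature source:
#' `pubmed_title` uses the title only, `pubmed_title_abstract` the title and
#' abstract, and `fulltext` title, abstract and body.
#'
#' @param article_id Unique identifier string.
#' @param title,abstract,body Character strings (abstract/body may be empty).
#' @param source One of `"fulltext"`, `"pubmed_title"`,
#'   `"pubmed_title_abstract"`.
#' @return An object of class `rob_article`.
#' @export
article_document <- function(article_id, title, abstract = "", body = "",
                             source = "fulltext") {
  stopifnot(is.character(article_id), length(article_id) == 1L,
            nzchar(article_id))
  source <- match.arg(source, ROB_SOURCES)
  parts <- switch(source,
    fulltext = c(title, abstract, body),
    pubmed_title = title,
    pubmed_title_abstract = c(title, abstract))
  segs <- lapply(parts, segment_sentences)
  sentences <- do.call(rbind, segs)
  sentences$index <- seq_len(nrow(sentences)) - 1L
  structure(list(article_id = article_id, title = title,
                 abstract = abstract, body = body, source = source,
                 sentences = sentences),
            class = "rob_article")
}

#' Re-derive an article's sentences from a different feature source
#'
#' @param article A `rob_article`.
#' @param source Target feature source.
#' @return A new `rob_article` with sentences rebuilt from the requested
#'   source.
#' @export
with_source <- function(article, source) {
  stopifnot(inherits(article, "rob_article"))
  article_document(article$article_id, article$title, article$abstract,
                   article$body, source = source)
}

#' @export
print.rob_article <- function(x, ...) {
  cat(sprintf("<rob_article %s> source=%s, %d sentences\n",
              x$article_id, x$source, nrow(x$sentences)))
  invisible(x)
}

.as_corpus <- function(articles) {
  ids <- vapply(articles, `[[`, "", "article_id")
  if (anyDuplicated(ids))
    stop("duplicate article_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(articles, names = ids, class = "rob_corpus")
}

#' Assemble a corpus from article documents
#' @param articles List of `rob_article` objects with unique ids.
#' @return An object of class `rob_corpus` (a named list of articles).
#' @export
corpus <- function(articles) .as_corpus(articles)

#' @export
print.rob_corpus <- function(x, ...) {
  cat(sprintf("<rob_corpus> %d articles, %d sentences\n", length(x),
              sum(vapply(x, function(a) nrow(a$sentences), 0L))))
  invisible(x)
}

#' Read a corpus from a JSONL file
#'
#' One JSON object per line with keys `article_id`, `title`, `abstract`,
#' `body`, `source`. Sentences are segmented on read according to `source`.
#'
#' @param path Path to a JSONL file.
#' @return A `rob_corpus`.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  arts <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop("malformed JSONL at line ", i,
                                             ": ", conditionMessage(e)))
    need <- c("article_id", "title", "abstract", "body", "source")
    if (!all(need %in% names(obj)))
      stop("malformed JSONL at line ", i, ": missing key(s) ",
           paste(setdiff(need, names(obj)), collapse = ", "))
    arts[[i]] <- article_document(obj$article_id, obj$title, obj$abstract,
                                  obj$body, source = obj$source)
  }
  .as_corpus(arts)
}

#' Write a corpus to a JSONL file
#' @param corp A `rob_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corp, path) {
  stopifnot(inherits(corp, "rob_corpus"))
  lines <- vapply(corp, function(a) {
    jsonlite::toJSON(a[c("article_id", "title", "abstract", "body",
                         "source")], auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Export the sentence table of a corpus
#' @param corp A `rob_corpus`.
#' @return Data frame with columns `article_id`, `sentence_index`, `text`.
#' @export
sentence_table <- function(corp) {
  stopifnot(inherits(corp, "rob_corpus"))
  out <- lapply(corp, function(a)
    data.frame(article_id = a$article_id, sentence_index = a$sentences$index,
               text = a$sentences$text, stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
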