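# Label inference from Cochrane-style assessment records: a sentence is
# relevant if it contains a reviewer quotation; every sentence of an article
# attached to a "no information" study is not-relevant; all others are
# unlabelled. Article labels collapse high/unclear judgements into not-low.

ROB_JUDGEMENTS <- c("low", "high", "unclear")

#' Construct an assessment record
#'
#' One study/property judgement with its supporting quotations or a
#' "no information" flag, referencing one or more article ids.
#'
#' @param study_id Study identifier.
#' @param property One of `"seq_gen"`, `"alloc_conc"`, `"blind"`.
#' @param judgement One of `"low"`, `"high"`, `"unclear"`.
#' @param quotations Character vector of quoted text spans (may be empty).
#' @param no_information Logical; `TRUE` means the reviewer stated no
#'   relevant information was found. Incompatible with quotations.
#' @param referenced_article_ids Character vector of article ids.
#' @return An object of class `rob_record`.
#' @export
assessment_record <- function(study_id, property, judgement,
                              quotations = character(0),
                              no_information = FALSE,
                              referenced_article_ids = character(0)) {
  property <- match.arg(property, ROB_PROPERTIES)
  if (!judgement %in% ROB_JUDGEMENTS)
    stop("unknown judgement: ", judgement)
  quotations <- as.character(quotations)
  quotations <- quotations[nzchar(quotations)]
  if (no_information && length(quotations))
    stop("no_information record cannot carry quotations (study ",
         study_id, ")")
  structure(list(study_id = study_id, property = property,
                 judgement = judgement, quotations = quotations,
                 no_information = isTRUE(no_information),
                 referenced_article_ids = as.character(referenced_article_ids)),
            class = "rob_record")
}

#' Read assessment records from a JSONL file
#' @param path Path to JSONL with keys `study_id`, `property`, `judgement`,
#'   `quotations`, `no_information`, `referenced_article_ids`.
#' @return List of `rob_record` objects.
#' @export
read_records <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop("malformed JSONL at line ", i,
                                             ": ", conditionMessage(e)))
    assessment_record(obj$study_id, obj$property, obj$judgement,
                      unlist(obj$quotations),
                      isTRUE(obj$no_information),
                      unlist(obj$referenced_article_ids))
  })
}

#' Write assessment records to a JSONL file
#' @param records List of `rob_record` objects.
#' @param path Output path.
#' @export
write_records <- function(records, path) {
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(list(study_id = r$study_id, property = r$property,
                          judgement = r$judgement,
                          quotations = r$quotations,
                          no_information = r$no_information,
                          referenced_article_ids = r$referenced_article_ids),
                     auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Match a quotation against an article's sentences
#'
#' Two-stage deterministic rule on normalized text ([normalize_text()]).
#' Stage 1: any sentence containing the full quotation matches. Stage 2
#' (only if stage 1 finds nothing): any sentence sharing a contiguous
#' normalized substring of at least `overlap_chars` characters with the
#' quotation matches; this recovers quotations that span sentence
#' boundaries or differ typographically from the extracted text.
#'
#' @param article A `rob_article`.
#' @param quotation Non-empty character string.
#' @param overlap_chars Minimum shared substring length for stage 2.
#' @return Integer vector of 0-based sentence indices (possibly empty).
#' @export
match_quotation <- function(article, quotation, overlap_chars = 30L) {
  stopifnot(inherits(article, "rob_article"),
            is.character(quotation), length(quotation) == 1L,
            nzchar(quotation))
  q <- normalize_text(quotation)
  if (!nzchar(q)) return(integer(0))
  sn <- article$sentences$normalized
  hit <- grepl(q, sn, fixed = TRUE)
  if (any(hit)) return(article$sentences$index[hit])
  # stage 2: sliding windows of the quotation
  nq <- nchar(q)
  if (nq < overlap_chars) return(integer(0))
  hit <- logical(length(sn))
  for (start in seq_len(nq - overlap_chars + 1L)) {
    win <- substr(q, start, start + overlap_chars - 1L)
    hit <- hit | grepl(win, sn, fixed = TRUE)
    if (all(hit)) break
  }
  article$sentences$index[hit]
}

.records_for <- function(records, property, article_id) {
  Filter(function(r) r$property == property &&
           article_id %in% r$referenced_article_ids, records)
}

#' Infer sentence relevance labels for one article and property
#'
#' Sentences matched by any quotation are `relevant`; if the article belongs
#' to a study where "no information" was stated, all its sentences are
#' `not_relevant`; otherwise sentences are `unlabelled`. An article both
#' matched by a quotation and flagged no-information for the same property
#' is corrupt input and raises an error.
#'
#' @param article A `rob_article`.
#' @param records List of `rob_record` objects (any property; filtered
#'   internally to `property` and to records referencing this article).
#' @param property Risk-of-bias property.
#' @return Character vector, one of `"relevant"`, `"not_relevant"`,
#'   `"unlabelled"` per sentence.
#' @export
infer_sentence_labels <- function(article, records, property) {
  property <- match.arg(property, ROB_PROPERTIES)
  recs <- .records_for(records, property, article$article_id)
  n <- nrow(article$sentences)
  lab <- rep("unlabelled", n)
  rel_idx <- integer(0)
  no_info <- FALSE
  for (r in recs) {
    if (r$no_information) no_info <- TRUE
    for (q in r$quotations)
      rel_idx <- union(rel_idx, match_quotation(article, q))
  }
  if (length(rel_idx) && no_info)
    stop("conflicting records for article ", article$article_id,
         ", property ", property,
         ": quotation matched but no_information stated")
  if (no_info) lab[] <- "not_relevant"
  lab[match(rel_idx, article$sentences$index)] <- "relevant"
  lab
}

#' Collapse a reviewer judgement into the binary article label
#'
#' `low` stays `low`; `high` and `unclear` collapse to `not_low`, since a
#' reviewer chiefly needs to single out the studies at low risk of bias.
#'
#' @param judgement Character vector with values in `low`, `high`,
#'   `unclear`.
#' @return Character vector with values `low` / `not_low`.
#' @export
infer_article_label <- function(judgement) {
  bad <- setdiff(unique(judgement), ROB_JUDGEMENTS)
  if (length(bad)) stop("unknown judgement: ", paste(bad, collapse = ", "))
  ifelse(judgement == "low", "low", "not_low")
}

#' Assemble the sentence-level training dataset
#'
#' Two labelling regimes. `relevant_not`: positives are relevant sentences,
#' negatives are not-relevant sentences, unlabelled sentences are excluded.
#' `relevant_rest`: positives are relevant sentences and every other
#' sentence (not-relevant or unlabelled) is a negative, so all sentences
#' are used.
#'
#' @param corp A `rob_corpus`.
#' @param records List of `rob_record` objects.
#' @param property Risk-of-bias property.
#' @param scheme `"relevant_not"` or `"relevant_rest"`.
#' @return Data frame with columns `article_id`, `sentence_index`, `text`,
#'   `class` (the three-way label) and `y` (0/1).
#' @export
build_sentence_dataset <- function(corp, records, property,
                                   scheme = c("relevant_not",
                                              "relevant_rest")) {
  scheme <- match.arg(scheme)
  property <- match.arg(property, ROB_PROPERTIES)
  stopifnot(inherits(corp, "rob_corpus"))
  parts <- lapply(corp, function(a) {
    cls <- infer_sentence_labels(a, records, property)
    data.frame(article_id = a$article_id,
               sentence_index = a$sentences$index,
               text = a$sentences$text, class = cls,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, parts)
  rownames(d) <- NULL
  if (scheme == "relevant_not") d <- d[d$class != "unlabelled", , drop = FALSE]
  d$y <- as.integer(d$class == "relevant")
  if (!sum(d$y) || all(d$y == 1L))
    stop("untrainable sentence dataset for ", property, " (", scheme,
         "): need both positive and negative examples")
  d
}

#' Assemble the article-level training dataset
#'
#' An article enters the dataset only if a record referencing it states
#' "no information" or has at least one quotation found in the article
#' text. Its binary label collapses the record judgement via
#' [infer_article_label()]. Text is taken from the requested feature
#' source.
#'
#' @param corp A `rob_corpus`.
#' @param records List of `rob_record` objects.
#' @param property Risk-of-bias property.
#' @param source Feature source (`"fulltext"`, `"pubmed_title"`,
#'   `"pubmed_title_abstract"`).
#' @return Data frame with columns `article_id`, `text`, `label`, `y`
#'   (1 = low).
#' @export
build_article_dataset <- function(corp, records, property,
                                  source = "fulltext") {
  property <- match.arg(property, ROB_PROPERTIES)
  source <- match.arg(source, ROB_SOURCES)
  stopifnot(inherits(corp, "rob_corpus"))
  rows <- list()
  for (a in corp) {
    recs <- .records_for(records, property, a$article_id)
    lab <- NA_character_
    for (r in recs) {
      qualifies <- r$no_information ||
        any(vapply(r$quotations,
                   function(q) length(match_quotation(a, q)) > 0L, TRUE))
      if (qualifies) { lab <- infer_article_label(r$judgement); break }
    }
    if (is.na(lab)) next
    av <- if (a$source == source) a else with_source(a, source)
    rows[[a$article_id]] <- data.frame(
      article_id = a$article_id,
      text = paste(av$sentences$text, collapse = " "),
      label = lab, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("no articles qualify for the ", property, " dataset")
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  d$y <- as.integer(d$label == "low")
  if (!sum(d$y) || all(d$y == 1L))
    stop("untrainable article dataset for ", property,
         ": need both low and not_low articles")
  d
}

#' Class distribution of a binary label vector
#' @param labels Character vector of labels.
#' @return Data frame with columns `label`, `n`, `proportion`.
#' @export
label_distribution <- function(labels) {
  tab <- table(labels)
  data.frame(label = names(tab), n = as.integer(tab),
             proportion = as.numeric(tab) / length(labels),
             stringsAsFactors = FALSE)
}
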