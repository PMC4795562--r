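# Seed-reproducible synthetic corpora with the statistical structure the
# pipeline assumes: background sentences drawn from a Zipf-distributed
# nonsense vocabulary, per-property signal phrases planted in low /
# not-low articles, assessment records carrying the planted phrase as a
# quotation (or a no-information flag when nothing was reported), and a
# gold annotation for end-to-end checks.

.signal_phrases <- list(
  seq_gen = list(
    adequate = c(
      "computer generated randomisation list prepared centrally before enrolment",
      "random number table used to generate the allocation sequence",
      "randomisation sequence generated by repeated coin tossing procedure"),
    inadequate = c(
      "allocation sequence determined by alternation of hospital admission order",
      "sequence generation based on date of birth of each participant")),
  alloc_conc = list(
    adequate = c(
      "sequentially numbered sealed opaque envelopes concealed the allocation",
      "central telephone randomisation service concealed upcoming assignments"),
    inadequate = c(
      "allocation list openly available to recruiting staff during enrolment",
      "assignment envelopes were transparent and unsealed before recruitment")),
  blind = list(
    adequate = c(
      "double blind design with identical placebo tablets for both groups",
      "participants and study personnel masked to treatment assignment throughout"),
    inadequate = c(
      "open label study without any blinding of participants or personnel",
      "outcome assessors were fully aware of the treatment allocation")))

.syllables <- c("ba", "do", "mi", "ta", "re", "lo", "ka", "ne", "su", "vi",
                "po", "ga", "zu", "fe", "ri", "co", "na", "mu", "sal",
                "pre", "tic", "dor", "ven", "qua", "lin", "hos", "ter")

#' Configuration for the synthetic corpus generator
#'
#' Defaults define the generator's standing study conditions: 200 articles
#' of 6-12 sentences over a 500-word Zipf(1.1) background vocabulary, half
#' the articles at low risk per property (`p_low`), 90% of judgements
#' supported by a reported method phrase (`p_report`; the rest become
#' no-information cases), and typographic noise on 10% of recorded
#' quotations.
#'
#' @param n_articles Number of articles.
#' @param sentences_range Length-2 integer range of body sentences per
#'   article.
#' @param vocab_size Background vocabulary size.
#' @param zipf_exponent Zipf exponent of background word frequencies.
#' @param p_low Prevalence of low-risk articles per property.
#' @param p_report Probability that a judgement is supported by a planted
#'   phrase (else the record states no information).
#' @param noise Fraction of recorded quotations carrying typographic
#'   variation (curly quotes, stray hyphenation).
#' @param signal_location Where planted sentences go: `"body"`, `"title"`
#'   or `"abstract"`.
#' @param properties Risk-of-bias properties to simulate.
#' @param seed Integer seed; all generation is deterministic given it.
#' @return List of class `rob_synth_config`.
#' @export
synthetic_config <- function(n_articles = 200L,
                             sentences_range = c(6L, 12L),
                             vocab_size = 500L, zipf_exponent = 1.1,
                             p_low = 0.5, p_report = 0.9, noise = 0.1,
                             signal_location = c("body", "title",
                                                 "abstract"),
                             properties = ROB_PROPERTIES, seed = 1L) {
  signal_location <- match.arg(signal_location)
  probs <- c(p_low = p_low, p_report = p_report, noise = noise)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  stopifnot(n_articles >= 1L, length(sentences_range) == 2L,
            sentences_range[1] >= 1L,
            sentences_range[2] >= sentences_range[1],
            vocab_size >= 50L, zipf_exponent > 0,
            all(properties %in% ROB_PROPERTIES))
  structure(list(n_articles = as.integer(n_articles),
                 sentences_range = as.integer(sentences_range),
                 vocab_size = as.integer(vocab_size),
                 zipf_exponent = zipf_exponent, p_low = p_low,
                 p_report = p_report, noise = noise,
                 signal_location = signal_location,
                 properties = properties, seed = as.integer(seed)),
            class = "rob_synth_config")
}

.background_vocab <- function(vocab_size) {
  words <- character(0)
  taboo <- c(.rob_stopwords,
             unlist(lapply(.signal_phrases, function(p)
               unlist(strsplit(unlist(p), " ")))))
  while (length(words) < vocab_size) {
    k <- sample(2:3, 1L)
    w <- paste(sample(.syllables, k, replace = TRUE), collapse = "")
    if (nchar(w) > 2L && !(w %in% words) && !(w %in% taboo))
      words <- c(words, w)
  }
  words
}

.bg_sentence <- function(vocab, probs, n_words = NULL) {
  if (is.null(n_words)) n_words <- sample(6:14, 1L)
  w <- sample(vocab, n_words, replace = TRUE, prob = probs)
  s <- paste(w, collapse = " ")
  paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)), ".")
}

.capitalize <- function(s)
  paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))

# typographic variation: curly quotes around the phrase plus a stray
# hyphen splitting the final word (exercises the overlap matcher)
.noisy_quotation <- function(phrase) {
  words <- strsplit(phrase, " ", fixed = TRUE)[[1]]
  last <- words[length(words)]
  cut <- max(2L, nchar(last) %/% 2L)
  words[length(words)] <- paste0(substr(last, 1, cut), "-",
                                 substr(last, cut + 1L, nchar(last)))
  paste0("“", paste(words, collapse = " "), "”")
}

#' Generate a synthetic corpus with assessment records and gold annotation
#'
#' Per article and property a latent low/not-low state is drawn
#' (`p_low`); its judgement is `low` when the state is low, otherwise
#' `high` or `unclear`. With probability `p_report` the judgement is
#' supported: an adequate-method (low) or inadequate-method (not-low)
#' phrase is planted as a sentence and recorded verbatim as the
#' quotation; otherwise the record states no information. Deterministic
#' given `config$seed`.
#'
#' @param config A `rob_synth_config`.
#' @return List with elements `corpus` (`rob_corpus`), `records` (list of
#'   `rob_record`), `gold` (data frame: `article_id`, `property`, `label`,
#'   `judgement`, `no_information`, `quotation`, `planted_text`, and
#'   list-column `relevant_idx` of 0-based sentence indices).
#' @export
generate_corpus <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "rob_synth_config"))
  withr::with_seed(config$seed, .generate_corpus_impl(config))
}

.generate_corpus_impl <- function(config) {
  vocab <- .background_vocab(config$vocab_size)
  probs <- (seq_along(vocab))^(-config$zipf_exponent)
  probs <- probs / sum(probs)

  articles <- vector("list", config$n_articles)
  records <- list()
  gold_rows <- list()

  for (i in seq_len(config$n_articles)) {
    art_id <- sprintf("art%04d", i)
    study_id <- sprintf("study%04d", i)
    title_s <- .bg_sentence(vocab, probs, n_words = sample(5:8, 1L))
    abstract_s <- replicate(sample(2:3, 1L), .bg_sentence(vocab, probs))
    n_body <- sample(config$sentences_range[1]:config$sentences_range[2], 1L)
    body_s <- replicate(n_body, .bg_sentence(vocab, probs))

    planted <- list()  # per property: planted sentence text + quotation
    for (prop in config$properties) {
      low <- stats::runif(1) < config$p_low
      judgement <- if (low) "low" else sample(c("high", "unclear"), 1L)
      reported <- stats::runif(1) < config$p_report
      if (reported) {
        pool <- .signal_phrases[[prop]][[if (low) "adequate" else "inadequate"]]
        phrase <- .capitalize(sample(pool, 1L))
        sentence <- paste0(phrase, ".")
        quotation <- if (stats::runif(1) < config$noise)
          .noisy_quotation(phrase) else phrase
        planted[[prop]] <- list(sentence = sentence, quotation = quotation,
                                judgement = judgement, low = low,
                                no_information = FALSE)
      } else {
        planted[[prop]] <- list(sentence = NA_character_,
                                quotation = NA_character_,
                                judgement = judgement, low = low,
                                no_information = TRUE)
      }
    }

    plant_texts <- unlist(lapply(planted, function(p) p$sentence))
    plant_texts <- plant_texts[!is.na(plant_texts)]
    if (length(plant_texts)) {
      tgt <- switch(config$signal_location,
                    body = "body", title = "title", abstract = "abstract")
      if (tgt == "body") {
        pos <- sort(sample.int(length(body_s) + 1L, length(plant_texts)))
        for (j in seq_along(plant_texts))
          body_s <- append(body_s, plant_texts[j],
                           after = pos[j] - 1L + (j - 1L))
      } else if (tgt == "abstract") {
        abstract_s <- c(abstract_s, plant_texts)
      } else {
        title_s <- paste(c(title_s, plant_texts), collapse = " ")
      }
    }

    art <- article_document(art_id, title = paste(title_s, collapse = " "),
                            abstract = paste(abstract_s, collapse = " "),
                            body = paste(body_s, collapse = " "),
                            source = "fulltext")
    articles[[i]] <- art

    for (prop in config$properties) {
      p <- planted[[prop]]
      rel_idx <- integer(0)
      if (!p$no_information) {
        rel_idx <- art$sentences$index[art$sentences$text == p$sentence]
      }
      records[[length(records) + 1L]] <- assessment_record(
        study_id, prop, p$judgement,
        quotations = if (p$no_information) character(0) else p$quotation,
        no_information = p$no_information,
        referenced_article_ids = art_id)
      gold_rows[[length(gold_rows) + 1L]] <- data.frame(
        article_id = art_id, property = prop,
        label = if (p$low) "low" else "not_low",
        judgement = p$judgement, no_information = p$no_information,
        quotation = if (p$no_information) NA_character_ else p$quotation,
        planted_text = p$sentence, stringsAsFactors = FALSE)
      gold_rows[[length(gold_rows)]]$relevant_idx <- I(list(rel_idx))
    }
  }

  gold <- do.call(rbind, gold_rows)
  rownames(gold) <- NULL
  list(corpus = .as_corpus(articles), records = records, gold = gold)
}

#' Disagreement-study fixture
#'
#' The default returns the six published disagreement counts used to
#' derive the triage threshold: 11/123, 26/123 and 41/123 (sequence
#' generation, allocation concealment, blinding; Hartling and colleagues)
#' and 8/28, 19/46 and 20/31 (Lensen and colleagues).
#'
#' @param spec Optional data frame with columns `source`, `property`,
#'   `disagreements`, `comparisons`; `NULL` gives the default fixture, a
#'   zero-row data frame gives an empty fixture.
#' @return A `rob_disagreements` data frame.
#' @export
generate_disagreement_fixture <- function(spec = NULL) {
  if (is.null(spec)) {
    return(disagreement_studies(
      source = rep(c("hartling2009", "lensen2021"), each = 3L),
      property = rep(c("seq_gen", "alloc_conc", "blind"), 2L),
      disagreements = c(11L, 26L, 41L, 8L, 19L, 20L),
      comparisons = c(123L, 123L, 123L, 28L, 46L, 31L)))
  }
  if (nrow(spec) == 0L)
    return(structure(data.frame(source = character(),
                                property = character(),
                                disagreements = integer(),
                                comparisons = integer(),
                                stringsAsFactors = FALSE),
                     class = c("rob_disagreements", "data.frame")))
  disagreement_studies(spec$source, spec$property, spec$disagreements,
                       spec$comparisons)
}

#' Write a gold annotation as JSON
#' @param gold Gold data frame from [generate_corpus()].
#' @param path Output path.
#' @export
write_gold <- function(gold, path) {
  obj <- lapply(seq_len(nrow(gold)), function(i)
    list(article_id = gold$article_id[i], property = gold$property[i],
         label = gold$label[i], judgement = gold$judgement[i],
         no_information = gold$no_information[i],
         quotation = gold$quotation[i],
         planted_text = gold$planted_text[i],
         relevant_idx = gold$relevant_idx[[i]]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
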