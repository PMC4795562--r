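# Bag-of-words featurization: lowercase -> tokenize on non-alphanumeric
# boundaries -> drop stop words -> drop tokens of length <= 2 -> Porter stem.
# The minimum-count filter acts on stems, after stemming has merged counts.

#' Preprocess text into stemmed tokens
#'
#' Tokens are maximal runs of letters/digits (so hyphenated words split:
#' "double-blind" gives "double" and "blind"). Stop words and tokens of one
#' or two characters are removed before stemming, so that e.g. "random" and
#' "Random" map to one stem and function words never reach the model.
#'
#' @param text Character string.
#' @return Character vector of stems (possibly empty).
#' @export
#' @examples
#' preprocess_tokens("Patients were randomized using computer-generated sequences")
preprocess_tokens <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- tolower(text)
  toks <- regmatches(x, gregexpr("[[:alnum:]]+", x))[[1]]
  toks <- toks[!(toks %in% .rob_stopwords) & nchar(toks) > 2L]
  porter_stem(toks)
}

#' Build a vocabulary from training token lists
#'
#' Keeps stems whose total count across the training units is at least
#' `min_count` ("fewer than ten times" are dropped at the default). Terms
#' are sorted so indexing is stable across runs.
#'
#' @param token_lists List of character vectors as returned by
#'   [preprocess_tokens()].
#' @param min_count Minimum total stem count (default 10).
#' @return An object of class `rob_vocabulary` with fields `terms`,
#'   `counts`, `min_count`.
#' @export
build_vocabulary <- function(token_lists, min_count = 10L) {
  stopifnot(length(token_lists) >= 1L, min_count >= 1L)
  counts <- table(unlist(token_lists, use.names = FALSE))
  counts <- counts[counts >= min_count]
  if (!length(counts)) stop("empty vocabulary after filtering")
  terms <- sort(names(counts))
  structure(list(terms = terms,
                 counts = as.integer(counts[terms]),
                 min_count = as.integer(min_count)),
            class = "rob_vocabulary")
}

#' @export
print.rob_vocabulary <- function(x, ...) {
  cat(sprintf("<rob_vocabulary> %d terms, min_count=%d\n",
              length(x$terms), x$min_count))
  invisible(x)
}

#' Vectorize token lists against a vocabulary
#'
#' Absolute occurrence counts per in-vocabulary stem; out-of-vocabulary
#' stems are ignored. Counts are raw integers, not frequencies or tf-idf.
#'
#' @param token_lists List of character vectors (one per unit).
#' @param vocab A `rob_vocabulary`.
#' @return Sparse count matrix (`Matrix::dgCMatrix`), one row per unit, one
#'   column per vocabulary term.
#' @export
vectorize <- function(token_lists, vocab) {
  stopifnot(inherits(vocab, "rob_vocabulary"))
  V <- length(vocab$terms)
  n <- length(token_lists)
  ii <- integer(0); jj <- integer(0); xx <- integer(0)
  for (r in seq_len(n)) {
    j <- match(token_lists[[r]], vocab$terms)
    j <- j[!is.na(j)]
    if (!length(j)) next
    tab <- table(j)
    ii <- c(ii, rep.int(r, length(tab)))
    jj <- c(jj, as.integer(names(tab)))
    xx <- c(xx, as.integer(tab))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = as.numeric(xx),
                       dims = c(n, V),
                       dimnames = list(NULL, vocab$terms))
}

#' Write a vocabulary as TSV (term, index, training_count)
#' @param vocab A `rob_vocabulary`.
#' @param path Output path.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "rob_vocabulary"))
  utils::write.table(
    data.frame(term = vocab$terms,
               index = seq_along(vocab$terms) - 1L,
               training_count = vocab$counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
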