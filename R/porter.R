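# Porter's suffix-stripping algorithm (1980), original definition.
#
# A word is [C](VC)^m[V]; m is the "measure" of a stem. Letters a,e,i,o,u
# are vowels; y is a vowel when preceded by a consonant, a consonant when
# word-initial or preceded by a vowel. Within each step only the
# longest-matching suffix rule is considered; if its condition fails no
# shorter rule of that step is tried.

.p_is_cons <- function(chars) {
  n <- length(chars)
  cons <- !(chars %in% c("a", "e", "i", "o", "u"))
  if (n == 0L) return(logical(0))
  for (i in seq_len(n)) {
    if (chars[i] == "y") cons[i] <- if (i == 1L) TRUE else !cons[i - 1L]
  }
  cons
}

.p_measure <- function(stem) {
  chars <- strsplit(stem, "", fixed = TRUE)[[1]]
  cons <- .p_is_cons(chars)
  if (!length(cons)) return(0L)
  # count v->c transitions
  r <- rle(cons)
  forms <- r$values
  m <- 0L
  for (i in seq_along(forms))
    if (i > 1L && forms[i] && !forms[i - 1L]) m <- m + 1L
  m
}

.p_has_vowel <- function(stem) {
  chars <- strsplit(stem, "", fixed = TRUE)[[1]]
  any(!.p_is_cons(chars))
}

.p_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  a <- substr(word, n - 1L, n - 1L); b <- substr(word, n, n)
  if (a != b) return(FALSE)
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  .p_is_cons(chars)[n]
}

# *o: stem ends cvc where the final c is not w, x or y
.p_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  cons <- .p_is_cons(chars)
  cons[n] && !cons[n - 1L] && cons[n - 2L] &&
    !(chars[n] %in% c("w", "x", "y"))
}

.p_ends <- function(word, suffix) {
  ns <- nchar(suffix); nw <- nchar(word)
  nw > ns && substr(word, nw - ns + 1L, nw) == suffix
}

.p_chop <- function(word, suffix) substr(word, 1L, nchar(word) - nchar(suffix))

# rule table steps 2-4: list of c(suffix, replacement); condition on measure
# of the stem left after removing the suffix.
.p_step2 <- list(
  c("ational", "ate"), c("tional", "tion"), c("enci", "ence"),
  c("anci", "ance"), c("izer", "ize"), c("abli", "able"), c("alli", "al"),
  c("entli", "ent"), c("eli", "e"), c("ousli", "ous"), c("ization", "ize"),
  c("ation", "ate"), c("ator", "ate"), c("alism", "al"), c("iveness", "ive"),
  c("fulness", "ful"), c("ousness", "ous"), c("aliti", "al"),
  c("iviti", "ive"), c("biliti", "ble"))
.p_step3 <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", ""))
.p_step4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
              "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
              "ous", "ive", "ize")

.p_apply_table <- function(word, rules, min_m) {
  best <- NULL; best_len <- -1L
  for (r in rules) {
    if (.p_ends(word, r[1]) && nchar(r[1]) > best_len) {
      best <- r; best_len <- nchar(r[1])
    }
  }
  if (is.null(best)) return(word)
  stem <- .p_chop(word, best[1])
  if (.p_measure(stem) > min_m - 1L) paste0(stem, best[2]) else word
}

.porter1 <- function(word) {
  if (nchar(word) <= 2L) return(word)
  w <- word

  # step 1a
  if (.p_ends(w, "sses")) w <- .p_chop(w, "es")
  else if (.p_ends(w, "ies")) w <- .p_chop(w, "es")
  else if (!.p_ends(w, "ss") && .p_ends(w, "s")) w <- .p_chop(w, "s")

  # step 1b
  if (.p_ends(w, "eed")) {
    if (.p_measure(.p_chop(w, "eed")) > 0L) w <- .p_chop(w, "d")
  } else {
    fired <- FALSE
    if (.p_ends(w, "ed") && .p_has_vowel(.p_chop(w, "ed"))) {
      w <- .p_chop(w, "ed"); fired <- TRUE
    } else if (.p_ends(w, "ing") && .p_has_vowel(.p_chop(w, "ing"))) {
      w <- .p_chop(w, "ing"); fired <- TRUE
    }
    if (fired) {
      if (.p_ends(w, "at") || .p_ends(w, "bl") || .p_ends(w, "iz")) {
        w <- paste0(w, "e")
      } else if (.p_double_cons(w) &&
                 !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
        w <- substr(w, 1L, nchar(w) - 1L)
      } else if (.p_measure(w) == 1L && .p_cvc(w)) {
        w <- paste0(w, "e")
      }
    }
  }

  # step 1c
  if (.p_ends(w, "y") && .p_has_vowel(.p_chop(w, "y")))
    w <- paste0(.p_chop(w, "y"), "i")

  # steps 2-3
  w <- .p_apply_table(w, .p_step2, min_m = 1L)
  w <- .p_apply_table(w, .p_step3, min_m = 1L)

  # step 4: longest matching suffix, removed when m(stem) > 1; "ion"
  # additionally requires the stem to end in s or t
  best <- ""; for (s in .p_step4) if (.p_ends(w, s) && nchar(s) > nchar(best)) best <- s
  if (nzchar(best)) {
    stem <- .p_chop(w, best)
    ok <- .p_measure(stem) > 1L
    if (best == "ion")
      ok <- ok && substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")
    if (ok) w <- stem
  }

  # step 5a
  if (.p_ends(w, "e")) {
    stem <- .p_chop(w, "e")
    m <- .p_measure(stem)
    if (m > 1L || (m == 1L && !.p_cvc(stem))) w <- stem
  }
  # step 5b
  if (.p_measure(w) > 1L && .p_double_cons(w) &&
      substr(w, nchar(w), nchar(w)) == "l")
    w <- substr(w, 1L, nchar(w) - 1L)

  w
}

#' Porter stem a vector of lower-case tokens
#'
#' Implements the original suffix-stripping algorithm. Tokens of one or two
#' characters are returned unchanged, as the algorithm specifies.
#'
#' @param tokens Character vector of lower-case tokens.
#' @return Character vector of stems, same length.
#' @export
#' @examples
#' porter_stem(c("randomized", "blinding", "allocation"))
porter_stem <- function(tokens) {
  if (!length(tokens)) return(character(0))
  vapply(tokens, .porter1, "", USE.NAMES = FALSE)
}
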