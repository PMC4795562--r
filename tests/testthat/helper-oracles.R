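# Independent oracles and tiny fixtures used across test files.

# exhaustive pair-counting AUC: wins + half-ties over all pos/neg pairs
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# textbook two-tailed t-tests on fold AUC vectors
paired_t_oracle <- function(a, b) {
  d <- a - b; n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  2 * pt(-abs(t), df = n - 1)
}

welch_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  2 * pt(-abs(t), df = df)
}

# numerical gradient of the per-example log loss at (w, b)
numeric_logloss_grad <- function(w, b, x, y, eps = 1e-6) {
  loss <- function(w, b) {
    s <- 1 / (1 + exp(-(sum(w * x) + b)))
    -(y * log(s) + (1 - y) * log(1 - s))
  }
  gw <- vapply(seq_along(w), function(j) {
    wp <- w; wp[j] <- wp[j] + eps
    wm <- w; wm[j] <- wm[j] - eps
    (loss(wp, b) - loss(wm, b)) / (2 * eps)
  }, 0)
  gb <- (loss(w, b + eps) - loss(w, b - eps)) / (2 * eps)
  list(gw = gw, gb = gb)
}

# three-article fixture with one quotation-supported study, one
# no-information study and one unreferenced article
tiny_fixture <- function() {
  a1 <- article_document(
    "a1", title = "A randomised controlled trial.",
    abstract = "Background sentence one. Background sentence two.",
    body = paste("Allocation was concealed using sealed opaque envelopes.",
                 "Patients recovered quickly.",
                 "Outcomes were assessed at week six."))
  a2 <- article_document(
    "a2", title = "Another trial.",
    abstract = "Abstract text here.",
    body = "Methods were described elsewhere. Results were mixed.")
  a3 <- article_document(
    "a3", title = "A third study.",
    abstract = "Nothing notable.",
    body = "Plain body sentence. Another plain body sentence.")
  recs <- list(
    assessment_record("s1", "alloc_conc", "low",
                      quotations = "sealed opaque envelopes",
                      referenced_article_ids = "a1"),
    assessment_record("s2", "alloc_conc", "unclear",
                      no_information = TRUE,
                      referenced_article_ids = "a2"))
  list(corpus = corpus(list(a1, a2, a3)), records = recs)
}

# small random sparse count matrix with binary labels
random_counts <- function(n, V, seed) {
  withr::with_seed(seed, {
    X <- Matrix::Matrix(matrix(stats::rpois(n * V, 0.4), n, V),
                        sparse = TRUE)
    colnames(X) <- paste0("t", seq_len(V))
    y <- stats::rbinom(n, 1, 0.5)
    if (all(y == y[1])) y[1] <- 1 - y[1]
    list(X = X, y = y)
  })
}
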