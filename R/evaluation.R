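# Stratified 10-fold cross-validation, AUC / ROC machinery, fold-averaged
# ROC curves with pointwise bounds, the three sentence-labelling
# experiments (A/B/C), the feature-source comparison, fold t-tests,
# permutation p-values and calibration tables.

#' Stratified k-fold split at the unit (article) level
#'
#' Units are assigned to folds so that every fold's class counts are within
#' one unit of the proportional share, and the test sets partition the
#' units. Deterministic given `seed`.
#'
#' @param unit_ids Character vector of unit identifiers (e.g. article ids).
#' @param strata Class label per unit (used only for stratification).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return List of `k` lists with fields `fold_id` (0-based), `train`,
#'   `test` (unit id vectors).
#' @export
stratified_kfold <- function(unit_ids, strata, k = 10L, seed = 1L) {
  stopifnot(length(unit_ids) == length(strata),
            !anyDuplicated(unit_ids))
  k <- as.integer(k)
  if (k > length(unit_ids)) stop("k exceeds the number of units")
  if (any(table(strata) < k))
    stop("need at least k units in every class for stratification")
  fold_of <- withr::with_seed(seed, {
    f <- integer(length(unit_ids))
    for (cl in unique(strata)) {
      idx <- which(strata == cl)
      idx <- idx[sample.int(length(idx))]
      f[idx] <- rep_len(seq_len(k), length(idx))  # round-robin deal
    }
    f
  })
  lapply(seq_len(k), function(j)
    list(fold_id = j - 1L,
         train = unit_ids[fold_of != j],
         test = unit_ids[fold_of == j]))
}

#' Area under the ROC curve (rank form)
#'
#' Probability that a randomly chosen positive example is scored above a
#' randomly chosen negative one, with ties credited one half
#' (Mann-Whitney statistic).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1 or logical).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (!n_pos || !n_neg) stop("AUC requires both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve from a threshold sweep
#'
#' Standard score-sorted sweep over unique thresholds; the curve starts at
#' (0, 0) and ends at (1, 1), and its trapezoidal area equals [auc()].
#'
#' @inheritParams auc
#' @return An object of class `rob_roc`: data frame with columns `fpr`,
#'   `tpr`, `threshold` plus attributes `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (!n_pos || !n_neg) stop("ROC requires both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  cut <- which(!duplicated(s, fromLast = TRUE) &
                 seq_along(s) <= length(s))  # last position of each score
  tp <- cumsum(y)[cut]; fp <- cumsum(1L - y)[cut]
  d <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos),
                  threshold = c(Inf, s[cut]))
  structure(d, class = c("rob_roc", "data.frame"),
            n_pos = n_pos, n_neg = n_neg)
}

#' Trapezoidal area under a ROC curve
#' @param roc A `rob_roc`.
#' @return Numeric area.
#' @export
roc_area <- function(roc) {
  stopifnot(inherits(roc, "rob_roc"))
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

# interpolate TPR/FPR of one fold at a predicted-positive rate r in [0,1]
.rate_interp <- function(scores, labels, rates) {
  n <- length(scores)
  ord <- order(scores, decreasing = TRUE)
  y <- as.integer(labels)[ord]
  n_pos <- sum(y); n_neg <- n - n_pos
  tp <- c(0L, cumsum(y)); fp <- c(0L, cumsum(1L - y))
  m <- rates * n  # fractional number predicted positive
  lo <- pmin(floor(m), n); hi <- pmin(lo + 1, n); fr <- m - lo
  tpr <- (tp[lo + 1L] * (1 - fr) + tp[pmin(hi, n) + 1L] * fr) / n_pos
  fpr <- (fp[lo + 1L] * (1 - fr) + fp[pmin(hi, n) + 1L] * fr) / n_neg
  list(tpr = tpr, fpr = fpr)
}

# equalize a fold's class counts to (n_pos, n_neg) by seeded duplication /
# removal of randomly selected examples
.equalize_fold <- function(scores, labels, n_pos, n_neg) {
  labels <- as.integer(labels)
  out_s <- numeric(0); out_y <- integer(0)
  for (cls in c(1L, 0L)) {
    target <- if (cls == 1L) n_pos else n_neg
    idx <- which(labels == cls)
    while (length(idx) > target)
      idx <- idx[-sample.int(length(idx), 1L)]
    while (length(idx) < target)
      idx <- c(idx, idx[sample.int(length(idx), 1L)])
    out_s <- c(out_s, scores[idx]); out_y <- c(out_y, labels[idx])
  }
  list(scores = out_s, labels = out_y)
}

#' Average ROC curves across CV folds on a common rate grid
#'
#' Rate-oriented averaging: each fold's ROC is parameterized by the
#' proportion of test examples predicted positive; at every grid rate the
#' TPR and FPR are interpolated per fold and averaged, with
#' normal-approximation pointwise bounds (mean +/- z * sd / sqrt(folds)).
#' With `equalize_counts` the folds' test sets are first brought to a
#' constant number of examples of each label by seed-determined random
#' duplication/removal.
#'
#' @param folds List of per-fold `list(scores =, labels =)`.
#' @param grid_size Number of rate grid points (>= 2).
#' @param equalize_counts Logical; equalize per-fold class counts first.
#' @param seed Seed for the equalization resampling.
#' @param conf_level Coverage of the pointwise bounds (default 0.95).
#' @return Data frame of class `rob_avg_roc` with columns `rate`,
#'   `mean_fpr`, `mean_tpr`, `tpr_lo`, `tpr_hi`, `fpr_lo`, `fpr_hi`.
#' @export
average_roc <- function(folds, grid_size = 101L, equalize_counts = FALSE,
                        seed = 1L, conf_level = 0.95) {
  stopifnot(length(folds) >= 2L)
  if (grid_size < 2L) stop("grid_size must be at least 2")
  if (equalize_counts) {
    n_pos <- max(vapply(folds, function(f) sum(f$labels == 1L), 0L))
    n_neg <- max(vapply(folds, function(f) sum(f$labels == 0L), 0L))
    folds <- withr::with_seed(seed,
      lapply(folds, function(f)
        .equalize_fold(f$scores, f$labels, n_pos, n_neg)))
  }
  rates <- seq(0, 1, length.out = grid_size)
  tprs <- vapply(folds, function(f)
    .rate_interp(f$scores, f$labels, rates)$tpr, numeric(grid_size))
  fprs <- vapply(folds, function(f)
    .rate_interp(f$scores, f$labels, rates)$fpr, numeric(grid_size))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  nf <- length(folds)
  m_t <- rowMeans(tprs); m_f <- rowMeans(fprs)
  se_t <- apply(tprs, 1, stats::sd) / sqrt(nf)
  se_f <- apply(fprs, 1, stats::sd) / sqrt(nf)
  structure(data.frame(rate = rates, mean_fpr = m_f, mean_tpr = m_t,
                       tpr_lo = m_t - z * se_t, tpr_hi = m_t + z * se_t,
                       fpr_lo = m_f - z * se_f, fpr_hi = m_f + z * se_f),
            class = c("rob_avg_roc", "data.frame"))
}

# tokenize each sentence once and cache
.tokenize_sentences <- function(d) lapply(d$text, preprocess_tokens)

# fit on a token list + labels, score another token list
.fit_and_score <- function(train_tokens, train_y, test_tokens, config,
                           seed, min_count, property) {
  vocab <- build_vocabulary(train_tokens, min_count = min_count)
  Xtr <- vectorize(train_tokens, vocab)
  Xte <- vectorize(test_tokens, vocab)
  model <- sgd_train(Xtr, train_y, config, seed = seed,
                     property = property)
  list(model = model, scores = predict_score(model, Xte), vocab = vocab)
}

#' Run the sentence-level labelling-regime experiments
#'
#' Three paired tests on identical article-grouped folds. Test A trains and
#' tests under relevant/rest; test B trains and tests under relevant/not;
#' test C trains under relevant/rest and tests on the relevant/not test
#' set, so B vs C is a paired comparison on the same test examples. All
#' sentences of an article stay in one fold; folds are stratified on
#' whether the article contains a relevant sentence.
#'
#' @param corp A `rob_corpus`.
#' @param records List of `rob_record` objects.
#' @param property Risk-of-bias property.
#' @param seed Integer seed (folds + SGD shuffles).
#' @param k Number of folds (default 10).
#' @param min_count Vocabulary threshold, rebuilt on each fold's training
#'   portion.
#' @param config Sentence-level `rob_train_config`.
#' @return List of class `rob_cv_suite`: per-test `rob_cv_result` objects
#'   (`A`, `B`, `C`), plus `folds` and per-fold test scores for ROC
#'   averaging.
#' @export
run_sentence_experiments <- function(corp, records, property, seed = 1L,
                                     k = 10L, min_count = 10L,
                                     config = train_config("sentence")) {
  property <- match.arg(property, ROB_PROPERTIES)
  rest <- build_sentence_dataset(corp, records, property, "relevant_rest")
  rest$tokens <- .tokenize_sentences(rest)
  art_ids <- unique(rest$article_id)
  has_rel <- vapply(art_ids, function(id)
    any(rest$class[rest$article_id == id] == "relevant"), TRUE)
  folds <- stratified_kfold(art_ids, ifelse(has_rel, "rel", "none"),
                            k = k, seed = seed)
  res <- list(A = numeric(k), B = numeric(k), C = numeric(k))
  fold_scores <- list(A = list(), B = list(), C = list())
  for (j in seq_len(k)) {
    tr <- rest$article_id %in% folds[[j]]$train
    te <- !tr
    labelled_tr <- tr & rest$class != "unlabelled"
    labelled_te <- te & rest$class != "unlabelled"
    # A: relevant/rest both sides
    fitA <- .fit_and_score(rest$tokens[tr], rest$y[tr], rest$tokens[te],
                           config, seed + j, min_count, property)
    res$A[j] <- auc(fitA$scores, rest$y[te])
    fold_scores$A[[j]] <- list(scores = fitA$scores, labels = rest$y[te])
    # B: relevant/not both sides
    fitB <- .fit_and_score(rest$tokens[labelled_tr], rest$y[labelled_tr],
                           rest$tokens[labelled_te], config, seed + j,
                           min_count, property)
    res$B[j] <- auc(fitB$scores, rest$y[labelled_te])
    fold_scores$B[[j]] <- list(scores = fitB$scores,
                               labels = rest$y[labelled_te])
    # C: A's model evaluated on B's test examples
    vocabA <- fitA$vocab
    XteC <- vectorize(rest$tokens[labelled_te], vocabA)
    sC <- predict_score(fitA$model, XteC)
    res$C[j] <- auc(sC, rest$y[labelled_te])
    fold_scores$C[[j]] <- list(scores = sC, labels = rest$y[labelled_te])
  }
  out <- lapply(names(res), function(tag) cv_result(res[[tag]], tag))
  names(out) <- names(res)
  structure(c(out, list(folds = folds, fold_scores = fold_scores)),
            class = "rob_cv_suite")
}

#' Run the article-level feature-source comparison
#'
#' One cross-validation per feature source on identical folds (stratified
#' on the article label), so source comparisons are paired.
#'
#' @param corp A `rob_corpus`.
#' @param records List of `rob_record` objects.
#' @param property Risk-of-bias property.
#' @param sources Feature sources to compare.
#' @param seed Integer seed.
#' @param k Number of folds.
#' @param min_count Vocabulary threshold per training fold.
#' @param config Article-level `rob_train_config`.
#' @return List of class `rob_cv_suite`: one `rob_cv_result` per source,
#'   plus `folds` and per-source/fold test scores.
#' @export
run_article_experiments <- function(corp, records, property,
                                    sources = ROB_SOURCES, seed = 1L,
                                    k = 10L, min_count = 10L,
                                    config = train_config("article")) {
  property <- match.arg(property, ROB_PROPERTIES)
  sources <- match.arg(sources, ROB_SOURCES, several.ok = TRUE)
  base <- build_article_dataset(corp, records, property, "fulltext")
  folds <- stratified_kfold(base$article_id, base$label, k = k, seed = seed)
  out <- list()
  fold_scores <- list()
  for (src in sources) {
    d <- build_article_dataset(corp, records, property, src)
    d <- d[match(base$article_id, d$article_id), , drop = FALSE]
    tokens <- lapply(d$text, preprocess_tokens)
    aucs <- numeric(k)
    fs <- list()
    for (j in seq_len(k)) {
      tr <- d$article_id %in% folds[[j]]$train
      te <- !tr
      fit <- .fit_and_score(tokens[tr], d$y[tr], tokens[te], config,
                            seed + j, min_count, property)
      aucs[j] <- auc(fit$scores, d$y[te])
      fs[[j]] <- list(scores = fit$scores, labels = d$y[te])
    }
    out[[src]] <- cv_result(aucs, src)
    fold_scores[[src]] <- fs
  }
  structure(c(out, list(folds = folds, fold_scores = fold_scores)),
            class = "rob_cv_suite")
}

#' Bundle per-fold AUCs into a CV result
#' @param aucs Numeric vector of per-fold AUC values.
#' @param tag Experiment tag (`"A"`, `"B"`, `"C"` or a feature source).
#' @return Object of class `rob_cv_result` with `aucs`, `mean`, `sd`,
#'   `tag`.
#' @export
cv_result <- function(aucs, tag = NA_character_) {
  structure(list(aucs = aucs, mean = mean(aucs), sd = stats::sd(aucs),
                 tag = tag), class = "rob_cv_result")
}

#' @export
print.rob_cv_result <- function(x, ...) {
  cat(sprintf("<rob_cv_result %s> mean AUC %.3f (sd %.3f) over %d folds\n",
              x$tag, x$mean, x$sd, length(x$aucs)))
  invisible(x)
}

#' Compare two CV AUC vectors with a two-tailed t-test
#'
#' Paired when the folds are matched (tests B vs C, or two feature sources
#' on identical folds), unpaired otherwise (tests A vs B, which score
#' different test sets). A zero-variance comparison is flagged degenerate
#' and reported as p = 1.
#'
#' @param cv_a,cv_b `rob_cv_result` objects (or numeric AUC vectors).
#' @param paired Logical.
#' @return List with `t`, `df`, `p_value`, `degenerate`.
#' @export
compare_auc <- function(cv_a, cv_b, paired = FALSE) {
  a <- if (inherits(cv_a, "rob_cv_result")) cv_a$aucs else cv_a
  b <- if (inherits(cv_b, "rob_cv_result")) cv_b$aucs else cv_b
  if (paired) {
    stopifnot(length(a) == length(b))
    d <- a - b
    if (stats::sd(d) == 0)
      return(list(t = NA_real_, df = length(d) - 1L, p_value = 1,
                  degenerate = TRUE))
    tt <- stats::t.test(a, b, paired = TRUE)
  } else {
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(list(t = NA_real_, df = NA_real_, p_value = 1,
                  degenerate = TRUE))
    tt <- stats::t.test(a, b, paired = FALSE)
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, degenerate = FALSE)
}

#' Permutation p-value for an observed AUC
#'
#' Labels are permuted `B` times; `p = (1 + #\{AUC_perm >= AUC_obs\}) /
#' (B + 1)`, the proportion of random models achieving at least the
#' observed ranking performance (add-one correction avoids p = 0).
#'
#' @inheritParams auc
#' @param B Number of permutations.
#' @param seed Integer seed.
#' @return List with `p_value`, `observed`, `B`.
#' @export
permutation_pvalue <- function(scores, labels, B = 999L, seed = 1L) {
  stopifnot(B >= 1L)
  obs <- auc(scores, labels)
  exceed <- withr::with_seed(seed, {
    sum(vapply(seq_len(B), function(b)
      auc(scores, sample(labels)) >= obs, TRUE))
  })
  list(p_value = (1 + exceed) / (B + 1), observed = obs, B = as.integer(B))
}

#' Calibration table over equal-width score bins
#'
#' Scores are binned on `[0, 1]`; a well-calibrated model has observed
#' positive fraction close to the mean score in every occupied bin (a set
#' of articles scored 0.8 should be about 80% low).
#'
#' @inheritParams auc
#' @param n_bins Number of equal-width bins (>= 2).
#' @return Data frame with columns `bin`, `lower`, `upper`, `count`,
#'   `mean_score`, `observed` (positive fraction; `NA` for empty bins).
#' @export
calibration_table <- function(scores, labels, n_bins = 10L) {
  stopifnot(n_bins >= 2L, all(scores >= 0), all(scores <= 1))
  labels <- as.integer(labels)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(findInterval(scores, edges, rightmost.closed = TRUE), n_bins)
  count <- tabulate(bin, nbins = n_bins)
  ms <- rep(NA_real_, n_bins); ob <- rep(NA_real_, n_bins)
  for (b in which(count > 0L)) {
    ms[b] <- mean(scores[bin == b])
    ob[b] <- mean(labels[bin == b])
  }
  data.frame(bin = seq_len(n_bins), lower = edges[-(n_bins + 1L)],
             upper = edges[-1L], count = count, mean_score = ms,
             observed = ob)
}
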