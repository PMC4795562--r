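# Single-reviewer triage: the calibrated score s is compared with fixed
# thresholds t and 1-t, where t estimates the proportion of correct human
# assignments derived from published inter-reviewer disagreement counts.
# s >= t -> low with one reviewer; s <= 1-t -> not-low with one reviewer;
# otherwise two reviewers as usual.

#' Construct disagreement-study records
#'
#' @param source Character vector of study labels.
#' @param property Risk-of-bias property per row.
#' @param disagreements,comparisons Integer counts per row,
#'   `0 <= disagreements <= comparisons`, `comparisons > 0`.
#' @return Data frame of class `rob_disagreements`.
#' @export
disagreement_studies <- function(source, property, disagreements,
                                 comparisons) {
  stopifnot(length(source) == length(property),
            length(source) == length(disagreements),
            length(source) == length(comparisons),
            all(comparisons > 0),
            all(disagreements >= 0), all(disagreements <= comparisons),
            all(property %in% ROB_PROPERTIES))
  structure(data.frame(source = source, property = property,
                       disagreements = as.integer(disagreements),
                       comparisons = as.integer(comparisons),
                       stringsAsFactors = FALSE),
            class = c("rob_disagreements", "data.frame"))
}

#' Read disagreement studies from CSV
#' @param path CSV with columns source, property, disagreements,
#'   comparisons.
#' @return A `rob_disagreements` data frame.
#' @export
read_disagreements <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  disagreement_studies(d$source, d$property, d$disagreements,
                       d$comparisons)
}

#' Proportion of assessments with reviewer disagreement
#'
#' Pooled by default: total disagreements over total comparisons across
#' studies and properties. The unweighted mean of the per-study fractions
#' is available via `method = "mean"`; the pooled form is the default
#' because it reproduces the published 26.4% from the printed counts,
#' which the unweighted mean (about 33%) does not.
#'
#' @param studies A `rob_disagreements` data frame.
#' @param method `"pooled"` or `"mean"`.
#' @return Proportion in `[0, 1]`.
#' @export
pooled_disagreement <- function(studies, method = c("pooled", "mean")) {
  method <- match.arg(method)
  stopifnot(nrow(studies) >= 1L)
  if (sum(studies$comparisons) == 0) stop("zero total comparisons")
  if (method == "pooled")
    sum(studies$disagreements) / sum(studies$comparisons)
  else
    mean(studies$disagreements / studies$comparisons)
}

#' Incorrect-assignment rate implied by a disagreement proportion
#'
#' Where two reviewers disagree exactly one of the two assignments is
#' wrong; assuming agreeing reviewers are both correct, the incorrect
#' fraction of all assignments is half the disagreement proportion.
#'
#' @param d Disagreement proportion in `[0, 1]`.
#' @return `d / 2`.
#' @export
incorrect_assignment_rate <- function(d) {
  stopifnot(d >= 0, d <= 1)
  d / 2
}

#' Triage thresholds from an incorrect-assignment rate
#'
#' `t = 1 - e` is the probability at which a model assignment is at least
#' as likely correct as a human reviewer's; the lower cut-off is `1 - t =
#' e`.
#'
#' @param e Incorrect-assignment rate, `0 <= e < 0.5`.
#' @return Object of class `rob_thresholds` with `t_upper`, `t_lower`.
#' @export
thresholds_from_error <- function(e) {
  stopifnot(e >= 0)
  if (e >= 0.5) stop("incorrect-assignment rate >= 0.5: threshold not meaningful")
  structure(list(t_upper = 1 - e, t_lower = e), class = "rob_thresholds")
}

#' Triage thresholds from a fixed t
#' @param t Upper threshold in (0.5, 1].
#' @return A `rob_thresholds`.
#' @export
triage_thresholds <- function(t = 0.868) {
  stopifnot(t > 0.5, t <= 1)
  structure(list(t_upper = t, t_lower = 1 - t), class = "rob_thresholds")
}

#' @export
print.rob_thresholds <- function(x, ...) {
  cat(sprintf("<rob_thresholds> low if s >= %.3f, not_low if s <= %.3f\n",
              x$t_upper, x$t_lower))
  invisible(x)
}

#' Classify articles by calibrated score
#'
#' `s >= t` is triaged `low`; `s <= 1 - t` is triaged `not_low`; anything
#' between goes to `two_reviewers`. Boundaries are inclusive.
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param thresholds A `rob_thresholds`.
#' @return Character vector of decisions.
#' @export
triage_article <- function(scores, thresholds) {
  stopifnot(inherits(thresholds, "rob_thresholds"),
            all(scores >= 0), all(scores <= 1))
  ifelse(scores >= thresholds$t_upper, "low",
         ifelse(scores <= thresholds$t_lower, "not_low", "two_reviewers"))
}

#' Summarize triage workload and precision
#'
#' Per side: percentage of articles triaged to a single reviewer and the
#' precision of those decisions against the true labels. A side with no
#' triaged article has undefined (`NA`) precision, never 0.
#'
#' @param decisions Character vector from [triage_article()].
#' @param true_labels Character vector with values `low` / `not_low`.
#' @return List with `pct_low`, `precision_low`, `pct_not_low`,
#'   `precision_not_low`, `pct_total`, `n`.
#' @export
triage_summary <- function(decisions, true_labels) {
  stopifnot(length(decisions) == length(true_labels), length(decisions) >= 1L)
  n <- length(decisions)
  is_low <- decisions == "low"; is_not <- decisions == "not_low"
  prec <- function(sel, lab)
    if (!any(sel)) NA_real_ else mean(true_labels[sel] == lab)
  list(pct_low = 100 * mean(is_low),
       precision_low = prec(is_low, "low"),
       pct_not_low = 100 * mean(is_not),
       precision_not_low = prec(is_not, "not_low"),
       pct_total = 100 * (mean(is_low) + mean(is_not)),
       n = n)
}

#' Adjust a calibrated score for a change in class prevalence
#'
#' When the deployment prevalence of low articles differs from the
#' training prevalence, scores are corrected on the odds scale:
#' `odds(s') = odds(s) * odds(target) / odds(train)`. Degenerate scores 0
#' and 1 are returned unchanged.
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param train_prevalence,target_prevalence Class prevalences in (0, 1).
#' @return Adjusted scores.
#' @export
prior_shift_adjust <- function(scores, train_prevalence,
                               target_prevalence) {
  stopifnot(train_prevalence > 0, train_prevalence < 1,
            target_prevalence > 0, target_prevalence < 1,
            all(scores >= 0), all(scores <= 1))
  ratio <- (target_prevalence / (1 - target_prevalence)) /
    (train_prevalence / (1 - train_prevalence))
  out <- scores
  inner <- scores > 0 & scores < 1
  odds <- scores[inner] / (1 - scores[inner]) * ratio
  out[inner] <- odds / (1 + odds)
  out
}
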