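# Biomarker-performance statistics: pair-counting ROC AUC, sensitivity and
# specificity at a cutoff, paired bootstrap AUC comparison, 2x2 contingency
# effect sizes (Haldane-corrected odds ratio, Fisher exact test), and the
# correlation / group-comparison tests used alongside the RAD51 score.

check_two_classes <- function(labels) {
  labels <- as.logical(labels)
  if (any(is.na(labels))) abort("labels contain NA")
  if (!any(labels) || all(labels))
    abort("both classes must be present", class = "rad51score_single_class")
  labels
}

#' Pair-counting ROC AUC
#'
#' The Mann-Whitney form: over all responder/non-responder pairs, concordant
#' pairs count 1, ties 0.5, divided by \eqn{n_1 n_2}. `direction = "low"`
#' means low scores indicate responders (the RAD51-score direction);
#' `"high"` the opposite (the HRD-score direction).
#'
#' @param scores numeric scores.
#' @param labels logical responder labels (same length).
#' @param direction `"low"` or `"high"`.
#' @return AUC in \[0,1\].
#' @export
roc_auc <- function(scores, labels, direction = c("low", "high")) {
  direction <- match.arg(direction)
  labels <- check_two_classes(labels)
  stopifnot(length(scores) == length(labels), !any(is.na(scores)))
  s <- if (direction == "low") -scores else scores
  r <- rank(s)  # midranks handle ties as half-counts
  n1 <- sum(labels); n2 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Sensitivity and specificity at a score cutoff
#'
#' Test-positive means score <= cutoff when low scores indicate responders
#' (the cutoff is inclusive, matching the HRR call), score >= cutoff
#' otherwise.
#'
#' @inheritParams roc_auc
#' @param cutoff score cutoff.
#' @return c(sensitivity, specificity) in percent.
#' @export
sens_spec_at_cutoff <- function(scores, labels, cutoff,
                                direction = c("low", "high")) {
  direction <- match.arg(direction)
  labels <- check_two_classes(labels)
  pos <- if (direction == "low") scores <= cutoff else scores >= cutoff
  c(sensitivity = 100 * sum(pos & labels) / sum(labels),
    specificity = 100 * sum(!pos & !labels) / sum(!labels))
}

#' Paired bootstrap comparison of two AUCs
#'
#' Models are resampled with replacement within each class (stratified), the
#' AUC difference is recomputed per replicate, the 95 percent CI is the
#' 2.5/97.5 percentile of the bootstrap differences, and the two-sided p
#' comes from the normal approximation \eqn{D / sd(D^*)} on the bootstrap
#' distribution.
#'
#' @param score_a,score_b paired scores on identical models.
#' @param labels logical responder labels.
#' @param directions length-2 `"low"`/`"high"` directions for the two scores.
#' @param n_boot bootstrap replicates (>= 100).
#' @param seed integer seed (results reproducible under a fixed seed).
#' @param conf_level confidence level for the percentile interval.
#' @return list(`auc1`, `auc2`, `difference`, `ci_low`, `ci_high`,
#'   `p_value`, `n_boot`, `seed`).
#' @export
compare_auc_bootstrap <- function(score_a, score_b, labels,
                                  directions = c("low", "high"),
                                  n_boot = 2000, seed = 1L,
                                  conf_level = 0.95) {
  if (length(score_a) != length(score_b) ||
      length(score_a) != length(labels))
    abort("scores must be paired on identical models")
  if (n_boot < 100) abort("n_boot must be >= 100")
  labels <- check_two_classes(labels)
  auc1 <- roc_auc(score_a, labels, directions[1])
  auc2 <- roc_auc(score_b, labels, directions[2])
  D <- auc1 - auc2
  i1 <- which(labels); i2 <- which(!labels)
  dstar <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(i1, replace = TRUE), sample(i2, replace = TRUE))
    lab <- labels[idx]
    roc_auc(score_a[idx], lab, directions[1]) -
      roc_auc(score_b[idx], lab, directions[2])
  }, numeric(1)))
  alpha <- (1 - conf_level) / 2
  ci <- unname(quantile(dstar, c(alpha, 1 - alpha), type = 7))
  sdd <- sd(dstar)
  p <- if (sdd == 0) as.numeric(D == 0) else
    2 * pnorm(-abs(D) / sdd)
  list(auc1 = auc1, auc2 = auc2, difference = D,
       ci_low = min(ci[1], D), ci_high = max(ci[2], D),
       p_value = p, n_boot = n_boot, seed = seed)
}

as_2x2 <- function(table) {
  x <- if (is.matrix(table)) as.vector(t(table)) else as.numeric(table)
  if (length(x) != 4 || any(x < 0) || sum(x) == 0)
    abort("need a 2x2 table of non-negative counts (a, b, c, d)")
  x
}

#' Odds ratio of a 2x2 table with Woolf confidence interval
#'
#' With the Haldane-Anscombe correction, 0.5 is added to every cell (the
#' default; required when any cell is zero), then
#' \eqn{OR = a'd'/(b'c')} with the Woolf log-scale interval
#' \eqn{\exp(\ln OR \pm z \sqrt{1/a' + 1/b' + 1/c' + 1/d'})}.
#'
#' @param table 2x2 matrix (rows = exposure, cols = outcome) or c(a, b, c, d).
#' @param correction `"haldane"` (default) or `"none"`.
#' @param conf_level confidence level (default 0.95).
#' @return list(`or`, `ci_low`, `ci_high`).
#' @export
odds_ratio_2x2 <- function(table, correction = c("haldane", "none"),
                           conf_level = 0.95) {
  correction <- match.arg(correction)
  x <- as_2x2(table)
  if (correction == "none" && any(x == 0))
    abort("zero cell: use correction = 'haldane'")
  if (correction == "haldane") x <- x + 0.5
  or <- (x[1] * x[4]) / (x[2] * x[3])
  z <- -stats::qnorm((1 - conf_level) / 2)
  se <- sqrt(sum(1 / x))
  list(or = or, ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se))
}

#' Fisher exact test (two-sided) for a 2x2 table
#'
#' Enumerates the hypergeometric support with the margins fixed and sums the
#' probabilities of all tables no more probable than the observed one.
#'
#' @param table 2x2 matrix or c(a, b, c, d).
#' @return two-sided p value.
#' @export
fisher_exact_p <- function(table) {
  x <- as_2x2(table)
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  r1 <- a + b; c1 <- a + c; n <- sum(x)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Correlation with significance test
#'
#' @param x,y paired numeric vectors (n >= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return list(`r`, `p`).
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3)
    abort("need paired vectors of length >= 3")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance input")
  ct <- suppressWarnings(cor.test(x, y, method = method))
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Two-group comparison tests
#'
#' @param x,y the two groups (paired for `"t_paired"`).
#' @param test `"mann_whitney"`, `"t_paired"` or `"t_unpaired"`.
#' @return list(`statistic`, `p`), two-sided.
#' @export
compare_groups <- function(x, y,
                           test = c("mann_whitney", "t_paired",
                                    "t_unpaired")) {
  test <- match.arg(test)
  if (test == "t_paired" && length(x) != length(y))
    abort("paired test needs equal-length vectors")
  if (length(x) < 2 || length(y) < 2) abort("groups must have >= 2 values")
  if (test == "t_paired" && sd(x - y) == 0) {
    # degenerate paired case: constant differences carry no evidence either
    # way when zero, certainty when non-zero
    return(list(statistic = if (all(x == y)) 0 else sign(x[1] - y[1]) * Inf,
                p = as.numeric(all(x == y))))
  }
  res <- switch(test,
    mann_whitney = suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = FALSE)),
    t_paired = t.test(x, y, paired = TRUE),
    t_unpaired = t.test(x, y))
  list(statistic = unname(res$statistic), p = res$p.value)
}

#' Biomarker discrimination report for a cohort
#'
#' Joins the ROC AUC, sensitivity/specificity at the cutoff, the responder x
#' test-positive 2x2 table with its Haldane-corrected odds ratio, and the
#' Fisher exact p into one summary.
#'
#' @param cohort data.frame with `responder` (logical) and the score column.
#' @param cutoff score cutoff (default 10).
#' @param score name of the score column (default `"rad51_score"`).
#' @param direction `"low"` or `"high"`.
#' @return a `discrimination_report` list: `n`, `n_responders`, `score`,
#'   `cutoff`, `auc`, `sensitivity`, `specificity`, `table` (a, b, c, d =
#'   responder/test+, responder/test-, non-responder/test+,
#'   non-responder/test-), `odds_ratio`, `or_ci_low`, `or_ci_high`,
#'   `fisher_p`.
#' @export
discriminate_report <- function(cohort, cutoff = 10, score = "rad51_score",
                                direction = c("low", "high")) {
  direction <- match.arg(direction)
  if (!score %in% names(cohort)) abort(sprintf("no column '%s'", score))
  s <- cohort[[score]]
  labels <- check_two_classes(cohort$responder)
  ss <- sens_spec_at_cutoff(s, labels, cutoff, direction)
  pos <- if (direction == "low") s <= cutoff else s >= cutoff
  tab <- c(a = sum(labels & pos), b = sum(labels & !pos),
           c = sum(!labels & pos), d = sum(!labels & !pos))
  or <- odds_ratio_2x2(tab, "haldane")
  structure(list(
    n = length(s), n_responders = sum(labels), score = score,
    cutoff = cutoff, auc = roc_auc(s, labels, direction),
    sensitivity = unname(ss[1]), specificity = unname(ss[2]),
    table = unname(tab), odds_ratio = or$or, or_ci_low = or$ci_low,
    or_ci_high = or$ci_high, fisher_p = fisher_exact_p(tab)),
    class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf("Discrimination of %s at cutoff %g (n = %d, %d responders)\n",
              x$score, x$cutoff, x$n, x$n_responders))
  cat(sprintf("  AUC = %.3f; sensitivity = %.1f%%; specificity = %.1f%%\n",
              x$auc, x$sensitivity, x$specificity))
  cat(sprintf("  2x2 (a,b,c,d) = %s; OR = %.3g (95%% CI %.3g-%.3g); Fisher p = %.3g\n",
              paste(x$table, collapse = ","), x$odds_ratio, x$or_ci_low,
              x$or_ci_high, x$fisher_p))
  invisible(x)
}
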