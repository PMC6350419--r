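# Per-stage evaluation of the final classifier across the simulated
# progression, with exact binomial / rank-sum significance and
# Benjamini-Hochberg control across stages within each performance
# measure, yielding the earliest stage at which network degradation is
# detectable.

#' Upper-tail exact binomial p-value
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`; the one-tailed test that a
#' proportion of correct calls exceeds chance.
#'
#' @param k_correct Number of correct predictions (0..n).
#' @param n Number of trials (>= 1).
#' @param p0 Chance level (default 0.5).
#' @return The p-value.
#' @export
binomial_pvalue <- function(k_correct, n, p0 = 0.5) {
  if (n < 1 || k_correct < 0 || k_correct > n ||
      k_correct != round(k_correct) || n != round(n)) {
    stop("need 0 <= k_correct <= n with n >= 1 (integers)", call. = FALSE)
  }
  stats::pbinom(k_correct - 1, n, p0, lower.tail = FALSE)
}

#' One-sided rank-sum p-value for AUC significance
#'
#' Wilcoxon rank-sum test that patient scores stochastically exceed control
#' scores: exact when both groups have at most 10 untied observations,
#' normal approximation with tie correction otherwise.
#'
#' @param scores_controls,scores_patients Classifier scores per group.
#' @return The one-sided p-value.
#' @export
auc_pvalue <- function(scores_controls, scores_patients) {
  if (length(scores_controls) == 0 || length(scores_patients) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  ties <- anyDuplicated(c(scores_controls, scores_patients)) > 0
  use_exact <- !ties && length(scores_controls) <= 10 &&
    length(scores_patients) <= 10
  suppressWarnings(
    stats::wilcox.test(scores_patients, scores_controls,
                       alternative = "greater", exact = use_exact,
                       correct = TRUE)$p.value)
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up procedure at level `q`: with sorted p-values `p(1) <= ... <=
#' p(m)`, find the largest rank `r` with `p(r) <= r q / m` and flag the `r`
#' smallest p-values.
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Logical flags aligned with `pvalues`.
#' @export
fdr_adjust <- function(pvalues, q = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH") <= q
}

#' Classifier performance at one stage
#'
#' Scores both groups with the trained model and reports AUC plus
#' sensitivity, specificity and accuracy at the ROC optimal point (closest
#' to the top-left corner), together with the underlying counts needed for
#' the binomial tests.
#'
#' @param model A [fit_final_model()] result.
#' @param X_controls,X_patients Feature-matrix rows for each group.
#' @return One-row tibble with metrics, counts and raw scores attached as
#'   attributes `scores_controls` / `scores_patients`.
#' @export
stage_metrics <- function(model, X_controls, X_patients) {
  if (nrow(X_controls) == 0 || nrow(X_patients) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  sc <- predict_scores(model, X_controls)
  sp <- predict_scores(model, X_patients)
  scores <- c(sc, sp)
  y <- c(rep(0L, length(sc)), rep(1L, length(sp)))
  roc <- roc_analysis(scores, y)
  thr <- roc$optimal$threshold
  k_sens <- sum(sp >= thr)
  k_spec <- sum(sc < thr)
  out <- tibble::tibble(
    auc = roc$auc,
    sensitivity = roc$optimal$sensitivity,
    specificity = roc$optimal$specificity,
    accuracy = roc$optimal$accuracy,
    k_sens = k_sens, n_pat = length(sp),
    k_spec = k_spec, n_ctrl = length(sc),
    k_acc = k_sens + k_spec, n_all = length(y))
  attr(out, "scores_controls") <- sc
  attr(out, "scores_patients") <- sp
  out
}

# Feature matrices per stage from a list of per-subject stage series.
# Returns a list keyed by stage index (as character) of samples x features
# matrices, in subject order.
stage_feature_tables <- function(series_list, region_table,
                                 damping = 0.85) {
  labels <- region_table$label
  stages <- vapply(series_list[[1]]$stages, `[[`, integer(1), "stage")
  out <- list()
  for (s in stages) {
    X <- t(vapply(series_list, function(ss) {
      rec <- NULL
      for (r in ss$stages) if (r$stage == s) rec <- r
      if (is.null(rec)) stop(sprintf("subject %s has no stage %d",
                                     ss$subject_id, s), call. = FALSE)
      subject_features(rec$W, region_labels = labels, damping = damping)
    }, numeric(5L * length(labels))))
    out[[as.character(s)]] <- X
  }
  out
}

#' Evaluate the classifier across all simulated stages
#'
#' Computes per-stage performance of a trained classifier on simulated
#' control and patient groups, tests each measure's significance (one-sided
#' rank-sum on scores for AUC; upper-tail binomial against chance for
#' sensitivity, specificity and accuracy, each on its own denominator),
#' applies Benjamini-Hochberg control across stages within each measure,
#' and locates the cutoff stage: the largest stage index that is
#' significant together with every later (smaller-index) stage, so that
#' detection is contiguous down to the full-disease stage.
#'
#' @param model A [fit_final_model()] result.
#' @param staged_controls,staged_patients Lists keyed by stage (character
#'   index) of feature matrices, e.g. from per-stage feature extraction of
#'   the two simulated arms. Both must cover the same stages.
#' @param q FDR level (default 0.05).
#' @return List of class `stage_report` with `table` (one row per stage:
#'   metrics, p-values, significance flags) and `cutoff` (named list per
#'   measure; `NA` when the final stage itself is not significant).
#' @export
evaluate_stages <- function(model, staged_controls, staged_patients,
                            q = 0.05) {
  stages <- sort(as.integer(names(staged_controls)), decreasing = TRUE)
  if (!setequal(names(staged_controls), names(staged_patients))) {
    stop("control and patient stage sets differ", call. = FALSE)
  }
  rows <- vector("list", length(stages))
  for (k in seq_along(stages)) {
    s <- as.character(stages[k])
    if (is.null(staged_patients[[s]])) {
      stop("missing stage ", s, " in patients", call. = FALSE)
    }
    m <- stage_metrics(model, staged_controls[[s]], staged_patients[[s]])
    rows[[k]] <- tibble::tibble(
      stage = stages[k], m,
      p_auc = auc_pvalue(attr(m, "scores_controls"),
                         attr(m, "scores_patients")),
      p_sens = binomial_pvalue(m$k_sens, m$n_pat),
      p_spec = binomial_pvalue(m$k_spec, m$n_ctrl),
      p_acc = binomial_pvalue(m$k_acc, m$n_all))
  }
  tab <- dplyr::bind_rows(rows)
  for (meas in c("auc", "sens", "spec", "acc")) {
    tab[[paste0("sig_", meas)]] <- fdr_adjust(tab[[paste0("p_", meas)]], q)
  }
  cutoff <- lapply(c(auc = "auc", sens = "sens", spec = "spec", acc = "acc"),
                   function(meas) {
    sig <- tab[[paste0("sig_", meas)]][order(tab$stage)]  # stage 0 first
    if (!sig[1]) return(NA_integer_)
    run <- which(!sig)
    if (length(run) == 0) max(tab$stage) else sort(tab$stage)[min(run) - 1L]
  })
  structure(list(table = tab, cutoff = cutoff, q = q),
            class = "stage_report")
}

#' @export
print.stage_report <- function(x, ...) {
  cat(sprintf("<stage_report> %d stages; cutoff (auc %s, acc %s)\n",
              nrow(x$table), x$cutoff$auc, x$cutoff$acc))
  invisible(x)
}
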