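# Classification metrics (one-vs-rest confusion counts; precision, recall,
# F1, accuracy), support-weighted averaging, per-subject quartile aggregation,
# the cascaded test protocol, and the paired sensor-reduction comparison.

#' One-vs-rest confusion counts
#'
#' For each class c: TP = both true and predicted are c; FP = predicted c,
#' true not; FN = true c, predicted not; TN = neither. For every class
#' TP+FP+TN+FN equals the total number of predictions.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param classes Class vocabulary (order fixes the output rows).
#' @return A data.frame of class `exohar_confusion`: class, TP, FP, TN, FN,
#'   support.
#' @export
confusion <- function(y_true, y_pred, classes) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  classes <- as.character(classes)
  if (!all(y_true %in% classes) || !all(y_pred %in% classes))
    stop("label outside the class vocabulary")
  tab <- table(factor(y_true, classes), factor(y_pred, classes))
  n <- length(y_true)
  tp <- diag(tab)
  fp <- colSums(tab) - tp
  fn <- rowSums(tab) - tp
  structure(data.frame(class = classes, TP = as.integer(tp),
                       FP = as.integer(fp), TN = as.integer(n - tp - fp - fn),
                       FN = as.integer(fn),
                       support = as.integer(rowSums(tab)),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("exohar_confusion", "data.frame"))
}

#' Per-class and aggregate metrics from confusion counts
#'
#' Pr = TP/(TP+FP), Re = TP/(TP+FN), F1 = 2*Pr*Re/(Pr+Re),
#' Ac = (TP+TN)/(TP+TN+FP+FN). Undefined 0/0 ratios are reported as 0 and
#' flagged (`degenerate`). The aggregate accuracy equals correct/total;
#' weighted scores are support-weighted means of the per-class scores (macro
#' means are also returned).
#'
#' @param counts An `exohar_confusion`.
#' @return A list of class `exohar_report`: `per_class` data.frame and
#'   scalars `accuracy`, `weighted_precision`, `weighted_recall`,
#'   `weighted_f1`, `macro_f1`, `n`.
#' @export
metrics_from_counts <- function(counts) {
  stopifnot(inherits(counts, "exohar_confusion"))
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  pr <- safe_div(counts$TP, counts$TP + counts$FP)
  re <- safe_div(counts$TP, counts$TP + counts$FN)
  f1 <- safe_div(2 * pr * re, pr + re)
  ac <- safe_div(counts$TP + counts$TN,
                 counts$TP + counts$TN + counts$FP + counts$FN)
  degenerate <- (counts$TP + counts$FP == 0) | (counts$TP + counts$FN == 0) |
    (pr + re == 0)
  per_class <- data.frame(class = counts$class, precision = pr, recall = re,
                          f1 = f1, accuracy = ac, support = counts$support,
                          degenerate = degenerate, stringsAsFactors = FALSE)
  n <- sum(counts$support)
  w <- if (n > 0) counts$support / n else rep(0, nrow(counts))
  structure(list(
    per_class = per_class,
    accuracy = if (n > 0) sum(counts$TP) / n else 0,
    weighted_precision = sum(w * pr), weighted_recall = sum(w * re),
    weighted_f1 = sum(w * f1),
    macro_f1 = mean(f1), n = n,
    degenerate = any(degenerate)),
    class = "exohar_report")
}

#' @export
print.exohar_report <- function(x, ...) {
  cat(sprintf("<exohar_report> n=%d  Ac=%.4f  wPr=%.4f  wRe=%.4f  wF1=%.4f%s\n",
              x$n, x$accuracy, x$weighted_precision, x$weighted_recall,
              x$weighted_f1, if (x$degenerate) "  [degenerate classes]" else ""))
  print(x$per_class, digits = 4)
  invisible(x)
}

#' Metrics directly from label vectors
#'
#' @inheritParams confusion
#' @return An `exohar_report`.
#' @export
score_labels <- function(y_true, y_pred, classes) {
  metrics_from_counts(confusion(y_true, y_pred, classes))
}

# ---- cascaded evaluation -----------------------------------------------------

#' Evaluate the trained pair of models under the cascaded test protocol
#'
#' HAR heads are evaluated on the HAR test split (all of D3): the action head
#' on every window, the interaction head on windows whose ground truth is
#' `INTERACT`. The payload model is evaluated on the payload test split
#' (10% of D1 + 50% of D3) on windows *gated* by the chosen mode:
#' `"predicted"` keeps windows where the HAR model predicts `INTERACT` (as
#' deployed; windows without a ground-truth payload are flagged and dropped
#' from the metric), `"truth"` keeps windows whose true action is `INTERACT`.
#'
#' @param suite One configuration's entry from [train_subject_suite()]
#'   (list with `har`, `payload`, `splits`).
#' @param fspec Zero-lag [filter_spec()] for offline evaluation.
#' @param eval_stride Window stride for evaluation (1 = per-sample).
#' @param mode Gating mode, `"predicted"` or `"truth"`.
#' @return A list of class `exohar_evaluation` with `exohar_report`s
#'   `action`, `interaction`, `payload` and bookkeeping counts.
#' @export
evaluate_cascaded <- function(suite, fspec = filter_spec(), eval_stride = 1,
                              mode = c("predicted", "truth")) {
  mode <- match.arg(mode)
  har <- suite$har; pay <- suite$payload
  if (har$sensor_config != pay$sensor_config)
    stop("model configuration mismatch")
  cfg <- har$sensor_config
  wspec <- window_spec(har$config$window$length, eval_stride)

  # HAR heads on the HAR test split
  hwins <- bind_windows(lapply(suite$splits$HAR$test, slice_windows,
                               sensor_config = cfg, scaler = har$scaler,
                               fspec = fspec, wspec = wspec))
  hp <- predict_model(har, hwins$x)
  act_pred <- classify(hp$action)
  action_report <- score_labels(hwins$action, act_pred, ACTIONS)
  gt_int <- hwins$action == "INTERACT"
  interaction_report <- if (any(gt_int))
    score_labels(hwins$interaction[gt_int],
                 classify(hp$interaction[gt_int, , drop = FALSE]),
                 INTERACTIONS)
  else structure(list(per_class = NULL, accuracy = NA, weighted_f1 = NA,
                      n = 0, degenerate = TRUE), class = "exohar_report")

  # payload on the payload test split, gated
  pwins <- bind_windows(lapply(suite$splits$PAYLOAD$test, slice_windows,
                               sensor_config = cfg, scaler = pay$scaler,
                               fspec = fspec, wspec = wspec))
  if (mode == "predicted") {
    # the gate is the HAR model's own action prediction on the same windows,
    # rescaled for the HAR scaler
    hwins2 <- bind_windows(lapply(suite$splits$PAYLOAD$test, slice_windows,
                                  sensor_config = cfg, scaler = har$scaler,
                                  fspec = fspec, wspec = wspec))
    gate <- classify(predict_model(har, hwins2$x)$action) == "INTERACT"
  } else {
    gate <- pwins$action == "INTERACT"
  }
  has_truth <- !is.na(pwins$payload)
  usable <- gate & has_truth
  payload_report <- if (any(usable)) {
    pp <- predict_model(pay, pwins$x[, , usable, drop = FALSE])
    score_labels(as.character(pwins$payload[usable]), classify(pp$payload),
                 as.character(PAYLOADS))
  } else structure(list(per_class = NULL, accuracy = NA, weighted_f1 = NA,
                        n = 0, degenerate = TRUE), class = "exohar_report")

  structure(list(action = action_report, interaction = interaction_report,
                 payload = payload_report, mode = mode,
                 n_gated = sum(gate), n_gated_without_truth = sum(gate & !has_truth),
                 sensor_config = cfg),
            class = "exohar_evaluation")
}

#' @export
print.exohar_evaluation <- function(x, ...) {
  cat(sprintf("<exohar_evaluation> %s gating, %s configuration\n",
              x$mode, x$sensor_config))
  for (h in c("action", "interaction", "payload")) {
    r <- x[[h]]
    cat(sprintf("  %-11s n=%6d  Ac=%s  wF1=%s\n", h, r$n,
                formatC(r$accuracy, digits = 4, format = "f"),
                formatC(r$weighted_f1, digits = 4, format = "f")))
  }
  invisible(x)
}

# ---- per-subject aggregation -------------------------------------------------

#' Quartiles of per-subject scores
#'
#' Convention: linear interpolation between order statistics
#' (`stats::quantile`, type 7).
#'
#' @param scores Numeric vector, one score per subject.
#' @return A list of class `exohar_distribution`: `scores`, `q1`, `median`,
#'   `q3`, `n`.
#' @export
aggregate_subjects <- function(scores) {
  stopifnot(length(scores) >= 1)
  q <- unname(quantile(scores, c(0.25, 0.5, 0.75), type = 7, na.rm = TRUE))
  structure(list(scores = scores, q1 = q[1], median = q[2], q3 = q[3],
                 n = length(scores)),
            class = "exohar_distribution")
}

#' @export
print.exohar_distribution <- function(x, ...) {
  cat(sprintf("<exohar_distribution> n=%d  Q1=%.4f  median=%.4f  Q3=%.4f\n",
              x$n, x$q1, x$median, x$q3))
  invisible(x)
}

# ---- sensor-reduction comparison ---------------------------------------------

#' Paired comparison of two sensor configurations
#'
#' Given per-subject scores of the same metric under two configurations,
#' tests the paired differences: Shapiro-Wilk at alpha = 0.05 decides between
#' the paired t-test (normal differences) and the two-sided Wilcoxon
#' signed-rank test. The Bonferroni-corrected p-value for the family of three
#' configuration pairs is `p* = 3 * p`; significance is declared when the raw
#' p is below 0.05/3 (about 0.0167). All-zero differences leave the tests
#' undefined: flagged, not significant.
#'
#' @param scores_a,scores_b Equal-length per-subject score vectors (paired by
#'   subject), N >= 3.
#' @param labels Length-2 character vector naming the configurations.
#' @param n_comparisons Family size for the Bonferroni correction (default 3).
#' @param family_alpha Family-wise significance level (default 0.05).
#' @return A list of class `exohar_comparison`: normality decision, test
#'   used, `p`, `p_star`, `significant`, `degenerate`.
#' @export
compare_configurations <- function(scores_a, scores_b,
                                   labels = c("A", "B"),
                                   n_comparisons = 3, family_alpha = 0.05) {
  if (length(scores_a) != length(scores_b)) stop("paired vectors must match")
  if (length(scores_a) < 3) stop("need at least 3 paired scores")
  d <- scores_a - scores_b
  threshold <- family_alpha / n_comparisons
  if (all(d == 0)) {
    return(structure(list(labels = labels, normal = NA, test = NA_character_,
                          p = NA_real_, p_star = NA_real_,
                          threshold = threshold, significant = FALSE,
                          degenerate = TRUE),
                     class = "exohar_comparison"))
  }
  sw <- stats::shapiro.test(d)
  normal <- sw$p.value >= 0.05
  if (normal) {
    ht <- stats::t.test(scores_a, scores_b, paired = TRUE)
    test <- "paired-t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(scores_a, scores_b,
                                              paired = TRUE))
    test <- "wilcoxon-signed-rank"
  }
  p <- unname(ht$p.value)
  structure(list(labels = labels, normal = normal, shapiro_p = sw$p.value,
                 test = test, p = p, p_star = n_comparisons * p,
                 threshold = threshold, significant = p < threshold,
                 degenerate = FALSE),
            class = "exohar_comparison")
}

#' @export
print.exohar_comparison <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<exohar_comparison> %s vs %s: all differences zero (flagged, not significant)\n",
                x$labels[1], x$labels[2]))
    return(invisible(x))
  }
  cat(sprintf("<exohar_comparison> %s vs %s: %s, p=%.4g, p*=%.4g (%ssignificant at raw p < %.4f)\n",
              x$labels[1], x$labels[2], x$test, x$p, x$p_star,
              if (x$significant) "" else "not ", x$threshold))
  invisible(x)
}

#' All pairwise configuration comparisons for one head
#'
#' @param score_matrix Numeric matrix: rows = subjects, columns =
#'   configurations (named).
#' @param family_alpha Family-wise alpha.
#' @return A list of `exohar_comparison`, one per unordered pair.
#' @export
compare_all_configurations <- function(score_matrix, family_alpha = 0.05) {
  cfgs <- colnames(score_matrix)
  pairs <- utils::combn(cfgs, 2, simplify = FALSE)
  out <- lapply(pairs, function(pr)
    compare_configurations(score_matrix[, pr[1]], score_matrix[, pr[2]],
                           labels = pr, n_comparisons = length(pairs),
                           family_alpha = family_alpha))
  names(out) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  out
}
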