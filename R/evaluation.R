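.check_scores <- function(scores) {
  stopifnot(inherits(scores, "score_set") || is.data.frame(scores))
  if (!all(c("score", "label") %in% names(scores)))
    stop("scores must have 'score' and 'label' columns", call. = FALSE)
  if (!all(scores$label %in% c(0, 1)))
    stop("labels must be 0/1", call. = FALSE)
  if (length(unique(scores$label)) < 2)
    stop("need at least one case and one control", call. = FALSE)
  invisible(scores)
}

# Mann-Whitney AUC (ties count one half) via midranks; fast path used in
# simulation loops. Identical to the trapezoidal ROC area.
.auc_rank <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC with a DeLong 95% confidence interval
#'
#' The AUC is the Mann-Whitney probability that a random case outscores a
#' random control (ties counted one half); the confidence interval uses the
#' DeLong variance estimator.
#'
#' @param scores A `score_set` (or data.frame with `score`, `label`).
#' @return List with `auc`, `ci_lower`, `ci_upper`, `n_cases`, `n_controls`.
#' @export
auc_ci <- function(scores) {
  .check_scores(scores)
  roc <- pROC::roc(response = scores$label, predictor = scores$score,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(roc, method = "delong"))
  list(auc = as.numeric(pROC::auc(roc)),
       ci_lower = ci[1], ci_upper = ci[3],
       n_cases = sum(scores$label == 1), n_controls = sum(scores$label == 0))
}

#' Odds ratio per standard deviation of score
#'
#' Univariable logistic regression of outcome on the score standardized by
#' the full-sample SD (control-only SD available via `sd_scope`); the OR is
#' `exp` of the coefficient, with a Wald 95% CI.
#'
#' @param scores A `score_set`.
#' @param sd_scope `"pooled"` (default) or `"controls"`.
#' @return List with `or`, `ci_lower`, `ci_upper`, `coef`, `se`.
#' @export
or_per_sd <- function(scores, sd_scope = c("pooled", "controls")) {
  .check_scores(scores)
  sd_scope <- match.arg(sd_scope)
  s <- if (sd_scope == "pooled") stats::sd(scores$score) else
    stats::sd(scores$score[scores$label == 0])
  if (!is.finite(s) || s <= 0) stop("score variance must be positive", call. = FALSE)
  x <- scores$score / s
  fit <- suppressWarnings(stats::glm(scores$label ~ x, family = stats::binomial()))
  co <- summary(fit)$coefficients
  if (!fit$converged || !is.finite(co["x", 2]) || co["x", 2] > 50)
    stop("complete separation: logistic fit did not stabilise", call. = FALSE)
  b <- co["x", 1]; se <- co["x", 2]
  list(or = exp(b), ci_lower = exp(b - 1.96 * se), ci_upper = exp(b + 1.96 * se),
       coef = b, se = se)
}

#' Youden-optimal operating point
#'
#' Sweeps thresholds over midpoints between adjacent distinct score values
#' (classification rule: `score > threshold`) and returns the point
#' maximizing Youden's J = sensitivity + specificity - 1. Ties in J are
#' broken toward the smallest qualifying threshold (maximizing sensitivity).
#'
#' @param scores A `score_set`.
#' @return List with `threshold`, `sensitivity`, `specificity`, `j`.
#' @export
youden_point <- function(scores) {
  .check_scores(scores)
  s <- scores$score; y <- scores$label
  u <- sort(unique(s))
  if (length(u) == 1L) {
    warning("all scores identical; degenerate operating point (J = 0)")
    return(list(threshold = u, sensitivity = 1, specificity = 0, j = 0))
  }
  cand <- (u[-1] + u[-length(u)]) / 2
  sens <- vapply(cand, function(t) mean(s[y == 1] > t), numeric(1))
  spec <- vapply(cand, function(t) mean(s[y == 0] <= t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1]  # candidates ascend, so first = smallest
  list(threshold = cand[best], sensitivity = sens[best],
       specificity = spec[best], j = j[best])
}

#' AUC of a binary classifier from its sensitivity and specificity
#'
#' For a single-threshold (binary) classifier the ROC curve is two line
#' segments and its area reduces to `(sensitivity + specificity) / 2`.
#'
#' @param sensitivity,specificity Operating characteristics in `[0, 1]`.
#' @return The binary-classifier AUC.
#' @export
binary_auc <- function(sensitivity, specificity) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(specificity >= 0 & specificity <= 1))
  (sensitivity + specificity) / 2
}

#' Centile-based high-risk classification
#'
#' Thresholds at the given centile of the CONTROL score distribution
#' (type-7 quantile); individuals whose score strictly exceeds the
#' threshold are labelled high risk. With distinct control scores and a
#' control count divisible by `100/(100-centile)` this pins specificity at
#' `centile/100` by construction (0.8 at the 80th centile).
#'
#' @param scores A `score_set`.
#' @param centile Centile of the control distribution, in (0, 100)
#'   (default 80).
#' @return List with `threshold`, `high_risk` (logical per individual),
#'   `sensitivity`, `specificity`, `auc_binary`
#'   (= `(sensitivity+specificity)/2`), `or`, `or_ci`, and counts.
#' @export
binary_high_risk <- function(scores, centile = 80) {
  .check_scores(scores)
  if (centile <= 0 || centile >= 100)
    stop("centile must be in (0, 100)", call. = FALSE)
  ctrl <- scores$score[scores$label == 0]
  if (length(ctrl) < 5) stop("need at least 5 controls", call. = FALSE)
  thr <- as.numeric(stats::quantile(ctrl, centile / 100, type = 7))
  hi <- scores$score > thr
  sens <- mean(hi[scores$label == 1])
  spec <- mean(!hi[scores$label == 0])
  # 2x2 odds ratio with Wald CI (Haldane correction only when a cell is 0)
  a <- sum(hi & scores$label == 1); b <- sum(!hi & scores$label == 1)
  c_ <- sum(hi & scores$label == 0); d <- sum(!hi & scores$label == 0)
  cc <- if (any(c(a, b, c_, d) == 0)) 0.5 else 0
  lor <- log((a + cc) * (d + cc) / ((b + cc) * (c_ + cc)))
  se <- sqrt(1 / (a + cc) + 1 / (b + cc) + 1 / (c_ + cc) + 1 / (d + cc))
  list(threshold = thr, high_risk = hi,
       sensitivity = sens, specificity = spec,
       auc_binary = binary_auc(sens, spec),
       or = exp(lor), or_ci = exp(lor + c(-1.96, 1.96) * se),
       n_high_cases = a, n_high_controls = c_)
}

#' AUC of a joint two-score logistic model
#'
#' Fits outcome on both scores jointly and reports the AUC (with DeLong CI)
#' of the fitted linear predictor — the "both PRSs as separate variables in
#' one model" comparison.
#'
#' @param a,b `score_set` objects over the same individuals in the same
#'   order.
#' @return As [auc_ci()].
#' @export
joint_model_auc <- function(a, b) {
  .check_scores(a); .check_scores(b)
  if (nrow(a) != nrow(b) || !identical(a$id, b$id) ||
      !identical(a$label, b$label))
    stop("score sets must cover the same individuals in the same order",
         call. = FALSE)
  fit <- suppressWarnings(stats::glm(a$label ~ a$score + b$score,
                                     family = stats::binomial()))
  lp <- as.numeric(stats::predict(fit, type = "link"))
  auc_ci(data.frame(score = lp, label = a$label))
}

#' High-risk overlap between two scores
#'
#' Applies the centile high-risk rule to each score independently and
#' cross-tabulates the flags within cases and within controls — which
#' individuals do the two scores agree are high risk?
#'
#' @param a,b `score_set` objects over the same individuals.
#' @param centile Centile for [binary_high_risk()].
#' @return An `overlap_report`: per stratum (`cases`, `controls`) counts of
#'   `both`, `only_a`, `only_b`, `neither`, plus the score labels.
#' @export
overlap_analysis <- function(a, b, centile = 80) {
  .check_scores(a); .check_scores(b)
  if (nrow(a) != nrow(b) || !identical(a$id, b$id) ||
      !identical(a$label, b$label))
    stop("score sets must cover the same individuals in the same order",
         call. = FALSE)
  fa <- binary_high_risk(a, centile)$high_risk
  fb <- binary_high_risk(b, centile)$high_risk
  tab <- function(sel) {
    c(both = sum(fa[sel] & fb[sel]), only_a = sum(fa[sel] & !fb[sel]),
      only_b = sum(!fa[sel] & fb[sel]), neither = sum(!fa[sel] & !fb[sel]))
  }
  structure(list(cases = tab(a$label == 1), controls = tab(a$label == 0),
                 centile = centile,
                 label_a = attr(a, "model_label") %||% "a",
                 label_b = attr(b, "model_label") %||% "b"),
            class = "overlap_report")
}

#' Full discrimination report for one score set
#'
#' Bundles the continuous AUC (DeLong CI), OR per SD, the Youden operating
#' point, and the centile-rule binary classification into one report.
#'
#' @param scores A `score_set`.
#' @param centile Centile for the binary high-risk rule.
#' @return An `eval_report` list.
#' @export
eval_report <- function(scores, centile = 80) {
  .check_scores(scores)
  bin <- binary_high_risk(scores, centile)
  bin$high_risk <- NULL
  bin$centile <- centile
  structure(list(
    model = attr(scores, "model_label") %||% "score",
    n_variants_used = attr(scores, "n_variants_used"),
    auc = auc_ci(scores),
    or_per_sd = or_per_sd(scores),
    youden = youden_point(scores),
    binary = bin,
    n_cases = sum(scores$label == 1),
    n_controls = sum(scores$label == 0)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("PRS evaluation: %s (%s variants)\n", x$model,
              x$n_variants_used %||% "?"))
  cat(sprintf("  cases/controls: %d / %d\n", x$n_cases, x$n_controls))
  cat(sprintf("  AUC (continuous): %.3f [%.3f to %.3f]\n",
              x$auc$auc, x$auc$ci_lower, x$auc$ci_upper))
  cat(sprintf("  OR per SD: %.2f [%.2f to %.2f]\n",
              x$or_per_sd$or, x$or_per_sd$ci_lower, x$or_per_sd$ci_upper))
  cat(sprintf("  Youden: threshold %.4g, sensitivity %.3f, specificity %.3f\n",
              x$youden$threshold, x$youden$sensitivity, x$youden$specificity))
  cat(sprintf("  Binary (>%g%% centile of controls): sens %.3f, spec %.3f, AUC %.3f\n",
              x$binary$centile %||% 80,
              x$binary$sensitivity, x$binary$specificity, x$binary$auc_binary))
  invisible(x)
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("High-risk overlap at the %g%% centile (%s vs %s)\n",
              x$centile, x$label_a, x$label_b))
  m <- rbind(cases = x$cases, controls = x$controls)
  print(m)
  invisible(x)
}
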