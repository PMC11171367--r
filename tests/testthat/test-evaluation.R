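mk_scores <- function(case_scores, control_scores) {
  structure(data.frame(
    id = sprintf("i%03d", seq_len(length(case_scores) + length(control_scores))),
    score = c(case_scores, control_scores),
    label = rep(c(1L, 0L), c(length(case_scores), length(control_scores)))),
    class = c("score_set", "data.frame"))
}

test_that("AUC equals exhaustive pair counting, with ties at one half", {
  s <- mk_scores(c(2, 3, 4), c(1, 2, 3))
  expect_equal(auc_ci(s)$auc, 7 / 9)
  expect_equal(auc_ci(s)$auc, auc_pair_count(s$score, s$label))
  # perfect separation
  expect_equal(suppressWarnings(auc_ci(mk_scores(c(5, 6), c(1, 2)))$auc), 1)
  # random small inputs: pROC-based estimate == brute-force enumeration
  set.seed(12)
  for (i in 1:20) {
    n1 <- sample(2:30, 1); n0 <- sample(2:30, 1)
    sc <- mk_scores(sample(1:10, n1, TRUE), sample(1:10, n0, TRUE))
    expect_equal(auc_ci(sc)$auc, auc_pair_count(sc$score, sc$label))
  }
  # permuted labels have no signal
  set.seed(13)
  big <- mk_scores(stats::rnorm(1000), stats::rnorm(1000))
  expect_gt(auc_ci(big)$auc, 0.45)
  expect_lt(auc_ci(big)$auc, 0.55)
  # CI contains the estimate
  ci <- auc_ci(big)
  expect_true(ci$ci_lower <= ci$auc && ci$auc <= ci$ci_upper)
  expect_error(auc_ci(mk_scores(numeric(), c(1, 2))), "case")
})

test_that("binormal scores recover the closed-form AUC", {
  set.seed(14)
  s <- mk_scores(stats::rnorm(5000, 1), stats::rnorm(5000, 0))
  expect_lt(abs(auc_ci(s)$auc - stats::pnorm(1 / sqrt(2))), 0.02)
})

test_that("odds ratio per SD matches the Gaussian-shift slope identity", {
  set.seed(15)
  s <- mk_scores(stats::rnorm(10000, 1), stats::rnorm(10000, 0))
  fit <- or_per_sd(s)
  # equal-variance Gaussians: logit slope per unit score = delta/sigma^2 = 1
  expect_equal(fit$coef / stats::sd(s$score), 1, tolerance = 0.1)
  # scale invariance
  s2 <- s; s2$score <- 2 * s2$score
  expect_equal(or_per_sd(s2)$or, fit$or, tolerance = 1e-9)
  # no association
  set.seed(16)
  s0 <- mk_scores(stats::rnorm(5000), stats::rnorm(5000))
  expect_gt(or_per_sd(s0)$or, 0.9)
  expect_lt(or_per_sd(s0)$or, 1.1)
  # complete separation is reported, not silently returned
  expect_error(or_per_sd(mk_scores(rep(10, 50) + stats::runif(50),
                                   rep(0, 50) + stats::runif(50))),
               "separation")
})

test_that("the Youden point maximizes J with the smallest-threshold tie-break", {
  y <- youden_point(mk_scores(c(4.5, 5.5, 6, 7), c(1, 2, 3, 4, 5)))
  expect_equal(y$j, 0.8)
  expect_equal(y$sensitivity, 1)
  expect_equal(y$specificity, 0.8)
  expect_equal(y$threshold, 4.25)
  # perfect separation: J = 1
  expect_equal(youden_point(mk_scores(c(10, 11), c(1, 2)))$j, 1)
  # constructed tie: J identical at two thresholds, the smaller one wins
  tie <- mk_scores(c(2, 4), c(1, 3))
  # thresholds 1.5, 2.5, 3.5 give J = 0.5, 0, 0.5 -> pick 1.5
  expect_equal(youden_point(tie)$threshold, 1.5)
  expect_warning(ydeg <- youden_point(mk_scores(c(1, 1), c(1, 1))), "identical")
  expect_equal(ydeg$j, 0)
})

test_that("the centile rule pins specificity and the binary AUC identity holds", {
  s <- mk_scores(c(5, 9, 10), 1:10)
  b <- binary_high_risk(s, 80)
  expect_equal(b$threshold, 8.2)              # type-7 quantile of 1..10
  expect_equal(b$sensitivity, 2 / 3)
  expect_equal(b$specificity, 0.8)
  expect_equal(b$auc_binary, (2 / 3 + 0.8) / 2)
  # continuous controls, n divisible by 5 -> specificity exactly 0.8
  set.seed(17)
  s2 <- mk_scores(stats::rnorm(123, 0.4), stats::rnorm(1000))
  b2 <- binary_high_risk(s2, 80)
  expect_identical(b2$specificity, 0.8)
  expect_equal(b2$auc_binary, (b2$sensitivity + b2$specificity) / 2)
  expect_error(binary_high_risk(s2, 0), "centile")
  expect_error(binary_high_risk(s2, 100), "centile")
  expect_error(binary_high_risk(mk_scores(1:3, 1:4), 80), "5 controls")
})

test_that("joint two-score models behave like nested information", {
  set.seed(18)
  n <- 2500
  lab <- rep(c(1L, 0L), each = n)
  a <- structure(data.frame(id = sprintf("i%04d", 1:(2 * n)),
                            score = stats::rnorm(2 * n, lab * 0.8),
                            label = lab),
                 class = c("score_set", "data.frame"))
  # identical second score adds nothing (collinear)
  expect_equal(joint_model_auc(a, a)$auc, auc_ci(a)$auc, tolerance = 1e-9)
  # independent noise second score adds (asymptotically) nothing
  b <- a; b$score <- stats::rnorm(2 * n)
  expect_equal(joint_model_auc(a, b)$auc, auc_ci(a)$auc, tolerance = 0.02)
  # two independent informative scores: joint at least as good as the best
  c_ <- a; c_$score <- stats::rnorm(2 * n, lab * 0.8)
  expect_gte(joint_model_auc(a, c_)$auc,
             max(auc_ci(a)$auc, auc_ci(c_)$auc) - 0.01)
  # mismatched individuals
  bad <- b[c(2:(2 * n), 1), ]
  expect_error(joint_model_auc(a, bad), "same individuals")
})

test_that("high-risk overlap cross-tabulates flags correctly", {
  set.seed(19)
  n <- 3000
  lab <- rep(c(1L, 0L), each = n)
  mk <- function(score) structure(
    data.frame(id = sprintf("i%04d", 1:(2 * n)), score = score, label = lab),
    class = c("score_set", "data.frame"))
  a <- mk(stats::rnorm(2 * n, lab * 0.5))
  ov_self <- overlap_analysis(a, a, 80)
  expect_identical(unname(ov_self$cases[c("only_a", "only_b")]), c(0L, 0L))
  expect_identical(unname(ov_self$controls[c("only_a", "only_b")]), c(0L, 0L))
  # cells partition each stratum
  b <- mk(stats::rnorm(2 * n))
  ov <- overlap_analysis(a, b, 80)
  expect_identical(sum(ov$cases), as.integer(n))
  expect_identical(sum(ov$controls), as.integer(n))
  # independent scores: both-flagged controls ~ 0.2^2
  expect_lt(abs(ov$controls[["both"]] / n - 0.04), 0.01)
  # anti-correlated scores flag (nearly) disjoint control sets
  ov_neg <- overlap_analysis(a, mk(-a$score), 80)
  fa <- binary_high_risk(a, 80)$high_risk
  fb <- binary_high_risk(mk(-a$score), 80)$high_risk
  ctrl <- lab == 0
  expect_identical(ov_neg$controls[["both"]], sum(fa[ctrl] & fb[ctrl]))
  expect_lte(ov_neg$controls[["both"]], 2L)
})

test_that("monotone-equivalent scores keep AUC while perturbed weights move flags", {
  panel <- make_reference_panel(ld_block_spec(10, 3, 0.2, c(0.1, 0.5)),
                                600, seed = 91)
  v <- panel$variants
  set.seed(92)
  w <- stats::rnorm(nrow(v), 0, 0.25)
  model <- prs_model(v$id, v$effect_allele, v$other_allele, w, "orig")
  coh <- make_cohort(panel, model, "case_control", 700, 700, seed = 93)
  s1 <- score_cohort(model, coh)
  # doubling is a positive monotone transform: same AUC, same flags
  cmp2 <- compare_weightings(model,
                             prs_model(v$id, v$effect_allele, v$other_allele,
                                       2 * w, "x2"), coh)
  expect_equal(cmp2$report_a$auc$auc, cmp2$report_b$auc$auc, tolerance = 1e-12)
  expect_identical(cmp2$discordant_controls, 0)
  # small weight noise: AUC nearly unchanged, yet some flags differ
  set.seed(94)
  noisy <- prs_model(v$id, v$effect_allele, v$other_allele,
                     w + stats::rnorm(length(w), 0, 0.05 * stats::sd(w)),
                     "noisy")
  cmp <- compare_weightings(model, noisy, coh)
  expect_lt(abs(cmp$report_a$auc$auc - cmp$report_b$auc$auc), 0.01)
  expect_gt(cmp$discordant_controls + cmp$discordant_cases, 0)
  expect_error(compare_weightings(model, prs_model("zz", "A", "G", 1), coh),
               "different variants")
})
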