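test_that("the SMR statistic matches hand arithmetic and its limits", {
  # null numerator
  s0 <- compute_smr(0, 0.05, 0.8, 0.1)
  expect_identical(s0$b_smr, 0)
  expect_identical(s0$t_smr, 0)
  expect_identical(s0$p_smr, 1)
  # hand-computed example: z_zy = 6, z_zx = 8 => T = 36*64/100 = 23.04
  s <- compute_smr(0.3, 0.05, 0.8, 0.1)
  expect_equal(s$b_smr, 0.375, tolerance = 1e-12)
  expect_equal(s$t_smr, 23.04, tolerance = 1e-9)
  expect_equal(s$p_smr, stats::pchisq(23.04, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(s$se_smr, 0.375 / sqrt(23.04), tolerance = 1e-12)
  # se_zx -> 0: the QTL side becomes exact, T -> z_zy^2 and p -> p_zy
  sl <- compute_smr(0.3, 0.05, 0.8, 1e-9)
  expect_equal(sl$t_smr, 36, tolerance = 1e-3)
  expect_equal(sl$p_smr, 2 * stats::pnorm(-6), tolerance = 1e-6)
  # not computable
  expect_false(compute_smr(0.3, 0.05, 0, 0.1)$ok)
  expect_false(compute_smr(0.3, Inf, 0.8, 0.1)$ok)
})

test_that("T_SMR never exceeds either squared z-score and p is flip-invariant", {
  set.seed(4)
  for (i in 1:1000) {
    b_zy <- stats::rnorm(1); se_zy <- stats::rexp(1) + 0.01
    b_zx <- stats::rnorm(1); se_zx <- stats::rexp(1) + 0.01
    if (b_zx == 0) next
    s <- compute_smr(b_zy, se_zy, b_zx, se_zx)
    expect_lte(s$t_smr, min((b_zy / se_zy)^2, (b_zx / se_zx)^2) + 1e-12)
    sf <- compute_smr(-b_zy, se_zy, -b_zx, se_zx)
    expect_equal(sf$p_smr, s$p_smr, tolerance = 1e-12)
    expect_equal(sf$b_smr, s$b_smr, tolerance = 1e-12)
    expect_equal(sign(s$b_smr), sign(b_zy) * sign(b_zx))
  }
})

test_that("weighted chi-square tails agree with exact chi-square oracles", {
  expect_lt(abs(weighted_chisq_tail(1, stats::qchisq(0.95, 1)) - 0.05), 1e-6)
  expect_lt(abs(weighted_chisq_tail(c(1, 1), stats::qchisq(0.95, 2)) - 0.05),
            1e-6)
  expect_identical(weighted_chisq_tail(c(0.3, 2), 0), 1)
  expect_error(weighted_chisq_tail(numeric(), 1), "non-empty")
  expect_error(weighted_chisq_tail(c(1, -1), 1), "positive")
  # equal weights w: Q = w * chisq_k exactly, for both methods
  set.seed(9)
  for (i in 1:20) {
    k <- sample(1:20, 1)
    w <- stats::rexp(1) + 0.05
    q <- w * stats::qchisq(stats::runif(1, 0.5, 0.999), k)
    exact <- stats::pchisq(q / w, k, lower.tail = FALSE)
    expect_lt(abs(weighted_chisq_tail(rep(w, k), q) - exact), 1e-4)
    expect_lt(abs(weighted_chisq_tail(rep(w, k), q, method = "ltz") - exact),
              1e-3)
  }
})

test_that("unequal-weight tails match a Monte-Carlo oracle", {
  set.seed(11)
  for (i in 1:5) {
    k <- sample(2:10, 1)
    w <- stats::rexp(k) + 0.05
    draws <- colSums(w * matrix(stats::rchisq(k * 50000, 1), k))
    q <- stats::quantile(draws, 0.9, names = FALSE)
    mc <- mean(draws > q)
    mc_sd <- sqrt(mc * (1 - mc) / 50000)
    expect_lt(abs(weighted_chisq_tail(w, q) - mc), 3 * mc_sd + 1e-6)
  }
})

test_that("instrument selection follows the eligibility and ranking rules", {
  panel <- calib_panel()
  arch <- architecture_spec("pleiotropy",
                            causal_variant_id = panel$variants$id[13],
                            b_zx = 0.6, b_xy = 0.4)
  q <- make_qtl_study(panel, arch, 1500, list(probe = "pr", gene = "G"),
                      seed = 77)
  top <- q$snp[which.min(q$p)]
  cfg <- heidi_config(max_instruments = 5)
  sel <- select_instruments(q, panel, top, cfg)
  # oracle: direct re-derivation of the rule set
  r2 <- as.numeric(stats::cor(panel$dosages[, top], panel$dosages[, q$snp]))^2
  elig <- q$snp != top & q$p < cfg$instrument_p_max &
    r2 >= cfg$r2_min & r2 <= cfg$r2_max
  expected <- q$snp[elig][order(q$p[elig])][seq_len(min(5, sum(elig)))]
  expect_identical(sel, expected)
  expect_false(top %in% sel)
  expect_lte(length(sel), 5)
  # r2 window boundary: nothing eligible when the window excludes everything
  none <- select_instruments(q, panel, top,
                             heidi_config(r2_min = 0.9999, r2_max = 1))
  expect_identical(none, character())
  expect_error(select_instruments(q, panel, "nope"), "not in panel")
})

test_that("HEIDI is exact in the degenerate single-instrument case", {
  # equal ratio estimates and independent instrument: T = 0, p = 1
  ld <- diag(2)
  out <- compute_heidi(b_zy = c(0.2, 0.1), se_zy = c(0.05, 0.05),
                       b_zx = c(0.4, 0.2), se_zx = c(0.04, 0.04),
                       ld = ld, min_instruments = 1)
  expect_equal(out$t_heidi, 0)
  expect_identical(out$p_heidi, 1)
  # below the instrument floor the p-value is absent
  out2 <- compute_heidi(b_zy = c(0.2, 0.1), se_zy = c(0.05, 0.05),
                        b_zx = c(0.4, 0.2), se_zx = c(0.04, 0.04),
                        ld = ld, min_instruments = 3)
  expect_true(is.na(out2$p_heidi))
})

test_that("allele harmonization flips, strand-flips, and drops ambiguity", {
  # same orientation
  h <- harmonize_effect("A", "C", "A", "C", 0.3, eaf = 0.2)
  expect_true(h$ok); expect_equal(h$b, 0.3); expect_equal(h$eaf, 0.2)
  # swapped alleles negate the effect and reflect the frequency
  h <- harmonize_effect("A", "C", "C", "A", 0.3, eaf = 0.2)
  expect_true(h$ok); expect_equal(h$b, -0.3); expect_equal(h$eaf, 0.8)
  # strand flip (A/C vs T/G)
  h <- harmonize_effect("A", "C", "T", "G", 0.3, eaf = 0.2)
  expect_true(h$ok); expect_equal(h$b, 0.3)
  # mismatched pair is irreconcilable
  expect_false(harmonize_effect("A", "C", "A", "G", 0.3)$ok)
  # palindromic with informative frequencies resolves by frequency
  h <- harmonize_effect("A", "T", "A", "T", 0.3, eaf = 0.2, target_eaf = 0.25)
  expect_true(h$ok); expect_equal(h$b, 0.3)
  h <- harmonize_effect("A", "T", "A", "T", 0.3, eaf = 0.8, target_eaf = 0.25)
  expect_true(h$ok); expect_equal(h$b, -0.3)
  # palindromic near 0.5 is dropped
  expect_false(harmonize_effect("A", "T", "A", "T", 0.3, eaf = 0.52,
                                target_eaf = 0.49)$ok)
})

test_that("the scan passes strong pleiotropy and rejects null batches", {
  panel <- calib_panel()
  arch <- architecture_spec("pleiotropy",
                            causal_variant_id = panel$variants$id[13],
                            b_zx = 0.6, b_xy = 0.4)
  # sized so that z_zx ~ 15 and z_zy ~ 8 at the causal variant
  sc <- scan_one_probe(panel, arch, seed = 201, n_cases = 6000,
                       n_controls = 6000)
  expect_true(sc$passed[1])
  expect_lt(sc$p_smr[1], 5e-8)
  expect_gt(sc$p_heidi[1], 0.05)
  # null probes: nothing passes
  null_sc <- scan_one_probe(panel, architecture_spec("null"), seed = 202)
  expect_false(any(null_sc$passed))
  # determinism of the full scan
  sc2 <- scan_one_probe(panel, arch, seed = 201, n_cases = 6000,
                        n_controls = 6000)
  expect_identical(sc, sc2)
})
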