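make_snps <- function(n, prefix) sprintf("%s_%04d", prefix, seq_len(n))

test_that("model union reproduces size arithmetic and enforces weight identity", {
  # 313-variant established score, 149-variant functional score, 5 shared
  shared <- make_snps(5, "shared")
  a_ids <- c(make_snps(308, "gw"), shared)
  b_ids <- c(shared, make_snps(144, "fn"))
  set.seed(1)
  w <- stats::rnorm(length(unique(c(a_ids, b_ids))))
  names(w) <- unique(c(a_ids, b_ids))
  a <- prs_model(a_ids, "A", "C", w[a_ids], "gwas")
  b <- prs_model(b_ids, "A", "C", w[b_ids], "functional")
  comb <- combine_models(a, b)
  expect_identical(nrow(comb), 457L)
  # idempotence and disjoint additivity
  expect_identical(nrow(combine_models(a, a)), nrow(a))
  d1 <- prs_model(make_snps(10, "x"), "A", "G", rep(0.1, 10))
  d2 <- prs_model(make_snps(7, "y"), "A", "G", rep(0.2, 7))
  expect_identical(nrow(combine_models(d1, d2)), 17L)
  # conflicting weights on a shared variant must error, never silently pick
  b_bad <- prs_model(b_ids, "A", "C",
                     ifelse(b_ids == shared[1], w[b_ids] + 1, w[b_ids]))
  expect_error(combine_models(a, b_bad), "conflicting weights")
  # a swapped-orientation duplicate with negated weight is the same weight
  a2 <- prs_model(shared[1], "C", "A", -w[shared[1]])
  expect_identical(nrow(combine_models(a2, prs_model(shared[1], "A", "C",
                                                     w[shared[1]]))), 1L)
})

test_that("functional model construction collects unique passing top SNPs", {
  gwas <- structure(data.frame(SNP = make_snps(6, "s"), A1 = "A", A2 = "G",
                               freq = 0.3, b = seq(0.1, 0.6, by = 0.1),
                               se = 0.01, p = 1e-10, n = 1000),
                    class = c("gwas_summary", "data.frame"))
  scan1 <- data.frame(probe = c("p1", "p2", "p3"),
                      top_snp = make_snps(6, "s")[1:3],
                      passed = c(TRUE, TRUE, FALSE))
  scan2 <- data.frame(probe = c("q1", "q2"),
                      top_snp = c(make_snps(6, "s")[1], make_snps(6, "s")[4]),
                      passed = c(TRUE, TRUE))
  m <- build_functional_model(list(scan1, scan2), gwas)
  expect_identical(nrow(m), 3L)               # s1 appears once (both scans)
  expect_setequal(m$snp, make_snps(6, "s")[c(1, 2, 4)])
  expect_equal(m$weight, gwas$b[match(m$snp, gwas$SNP)])
  # nothing passed -> empty model
  empty <- build_functional_model(data.frame(top_snp = "s_0001",
                                             passed = FALSE), gwas)
  expect_identical(nrow(empty), 0L)
  # passing variant missing from the GWAS table -> error listing it
  bad <- data.frame(top_snp = "unknown_snp", passed = TRUE)
  expect_error(build_functional_model(bad, gwas), "unknown_snp")
})

test_that("greedy LD pruning keeps the earlier variant and is idempotent", {
  # A-B and B-C tightly linked, A-C moderately: greedy retains {A, C}
  set.seed(33)
  n <- 4000
  A <- stats::rnorm(n)
  B <- A + stats::rnorm(n, 0, 0.33)
  C <- B + stats::rnorm(n, 0, 0.33)
  D <- stats::rnorm(n)             # independent fourth variant
  dos <- cbind(A, B, C, D)
  v <- data.frame(chrom = "1", pos = c(100L, 200L, 300L, 400L),
                  id = c("vA", "vB", "vC", "vD"),
                  effect_allele = "A", other_allele = "G",
                  stringsAsFactors = FALSE)
  panel <- as_ref_panel(v, dos)
  r2 <- stats::cor(dos)^2
  stopifnot(r2["A", "B"] > 0.9, r2["B", "C"] > 0.9, r2["A", "C"] < 0.9)
  model <- prs_model(v$id, "A", "G", c(0.1, 0.2, 0.3, 0.4))
  pruned <- ld_prune(model, panel, r2_threshold = 0.9)
  expect_identical(pruned$snp, c("vA", "vC", "vD"))
  # idempotence and subset property
  expect_identical(ld_prune(pruned, panel, 0.9)$snp, pruned$snp)
  expect_true(all(pruned$snp %in% model$snp))
  # an identical pair keeps exactly the earlier variant
  panel2 <- as_ref_panel(v[1:2, ], cbind(A, A))
  m2 <- prs_model(c("vA", "vB"), "A", "G", c(1, 2))
  expect_identical(ld_prune(m2, panel2, 0.9)$snp, "vA")
  # nothing linked -> unchanged
  expect_identical(nrow(ld_prune(prs_model(c("vA", "vD"), "A", "G", c(1, 2)),
                                 panel, 0.9)), 2L)
  expect_error(ld_prune(prs_model("zz", "A", "G", 1), panel), "absent")
})

test_that("scoresum arithmetic, imputation, and allele recoding are exact", {
  v <- data.frame(chrom = "1", pos = c(10L, 20L), id = c("v1", "v2"),
                  effect_allele = c("A", "C"), other_allele = c("G", "T"),
                  stringsAsFactors = FALSE)
  dos <- rbind(c(2, 1), c(0, 0), c(1, 2), c(2, 2))
  coh <- manual_cohort(dos, c(1L, 0L, 1L, 0L), v)
  model <- prs_model(c("v1", "v2"), c("A", "C"), c("G", "T"), c(0.5, -1))
  s <- score_cohort(model, coh)
  expect_equal(s$score, c(0.5 * 2 - 1, 0, 0.5 - 2, 1 - 2))
  expect_identical(attr(s, "n_variants_used"), 2L)
  # all-zero dosages score zero
  coh0 <- manual_cohort(matrix(0, 3, 2), c(1L, 0L, 0L), v)
  expect_equal(score_cohort(model, coh0)$score, rep(0, 3))
  # linearity: doubling weights doubles every score
  s2 <- score_cohort(prs_model(model$snp, model$effect_allele,
                               model$other_allele, 2 * model$weight), coh)
  expect_equal(s2$score, 2 * s$score)
  # recoding effect/other (beta -> -beta, x -> 2 - x) shifts scores by a
  # constant, so discrimination is untouched
  rec <- prs_model(model$snp, model$other_allele, model$effect_allele,
                   -model$weight)
  sr <- score_cohort(rec, coh)
  expect_equal(diff(range((sr$score - s$score))), 0, tolerance = 1e-12)
  expect_equal(auc_ci(sr)$auc, auc_ci(s)$auc)
  # variants absent from the cohort are skipped and counted
  model3 <- prs_model(c("v1", "v2", "v9"), c("A", "C", "A"),
                      c("G", "T", "G"), c(0.5, -1, 3))
  s3 <- score_cohort(model3, coh)
  expect_identical(attr(s3, "n_variants_skipped"), 1L)
  expect_equal(s3$score, s$score)
})

test_that("missing dosages are imputed at twice the cohort frequency", {
  v <- data.frame(chrom = "1", pos = c(10L, 20L), id = c("v1", "v2"),
                  effect_allele = c("A", "C"), other_allele = c("G", "T"),
                  stringsAsFactors = FALSE)
  dos <- rbind(c(2, NA), c(0, 1), c(NA, 2), c(2, 1))
  coh <- manual_cohort(dos, c(1L, 0L, 1L, 0L), v)
  model <- prs_model(c("v1", "v2"), c("A", "C"), c("G", "T"), c(0.5, -1))
  s <- score_cohort(model, coh)
  # brute-force oracle: mean-impute each column, then dot product
  imp <- apply(dos, 2, function(col) { col[is.na(col)] <- mean(col, na.rm = TRUE); col })
  oracle <- as.numeric(imp %*% c(0.5, -1))
  expect_equal(s$score, oracle)
  # exact dot product when nothing is missing (generative cohort)
  spec <- ld_block_spec(2, 5, 0.3, c(0.1, 0.5))
  panel <- make_reference_panel(spec, 500, seed = 81)
  pv <- panel$variants
  w <- prs_model(pv$id, pv$effect_allele, pv$other_allele,
                 stats::rnorm(nrow(pv), 0, 0.1))
  coh2 <- make_cohort(panel, w, "case_control", 150, 150, missing_rate = 0,
                      seed = 82)
  sc <- score_cohort(w, coh2)
  brute <- as.numeric(coh2$dosages[, w$snp] %*% w$weight)
  expect_equal(sc$score, brute)
})

test_that("weight files round-trip, including the 3-column plink layout", {
  m <- prs_model(c("rs1", "rs2"), c("A", "C"), c("G", "T"), c(0.12, -0.3),
                 "demo")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_prs_model(m, path)
  back <- read_prs_model(path)
  expect_equal(as.data.frame(back), as.data.frame(m), ignore_attr = TRUE)
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp\teffect_allele\tweight", "rs1\tA\t0.5"), p3)
  m3 <- read_prs_model(p3)
  expect_identical(m3$snp, "rs1")
  expect_true(is.na(m3$other_allele))
  expect_equal(m3$weight, 0.5)
})
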