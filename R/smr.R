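#' HEIDI instrument-selection configuration
#'
#' Controls which cis-SNPs besides the top QTL SNP serve as dependent
#' instruments in the heterogeneity test. Defaults follow the conventions of
#' the reference SMR software: candidate instruments need QTL
#' p < 1.57e-3 (roughly |z| > 3.16), LD with the top SNP inside
#' `[r2_min, r2_max]` (too-low r2 carries no information about a shared
#' causal variant; too-high r2 makes the covariance matrix near-singular),
#' at most `max_instruments` kept (smallest QTL p first), and at least
#' `min_instruments` required to report a p-value at all.
#'
#' @param instrument_p_max QTL p-value ceiling for candidate instruments.
#' @param r2_min,r2_max LD bounds (squared correlation with the top SNP).
#' @param max_instruments Cap on instruments used.
#' @param min_instruments Floor below which `p_heidi` is reported `NA`.
#' @return An object of class `heidi_config`.
#' @export
heidi_config <- function(instrument_p_max = 1.57e-3,
                         r2_min = 0.05, r2_max = 0.9,
                         max_instruments = 20L, min_instruments = 3L) {
  if (!(r2_min > 0 && r2_min < r2_max && r2_max <= 1))
    stop("need 0 < r2_min < r2_max <= 1", call. = FALSE)
  if (!(max_instruments >= min_instruments && min_instruments >= 1))
    stop("need max_instruments >= min_instruments >= 1", call. = FALSE)
  structure(list(instrument_p_max = instrument_p_max,
                 r2_min = r2_min, r2_max = r2_max,
                 max_instruments = as.integer(max_instruments),
                 min_instruments = as.integer(min_instruments)),
            class = "heidi_config")
}

#' The SMR test for a single variant
#'
#' Combines the GWAS effect `b_zy` (variant on disease) and the QTL effect
#' `b_zx` (variant on molecular trait) into the two-sample Mendelian
#' randomization ratio estimate `b_smr = b_zy / b_zx` and the statistic
#' \deqn{T_{SMR} = \frac{z_{zy}^2 z_{zx}^2}{z_{zy}^2 + z_{zx}^2},}
#' which is compared to a chi-square with 1 df; the standard error is
#' `|b_smr| / sqrt(T_SMR)`. Both effects must refer to the same effect
#' allele (see [harmonize_effect()]).
#'
#' @param b_zy,se_zy GWAS per-allele log-odds effect and its SE.
#' @param b_zx,se_zx QTL per-allele effect and its SE.
#' @return A list with `b_smr`, `se_smr`, `t_smr`, `p_smr`, and `ok`
#'   (`FALSE` when the statistic is not computable, e.g. `b_zx = 0` or a
#'   non-finite SE).
#' @export
compute_smr <- function(b_zy, se_zy, b_zx, se_zx) {
  if (!all(is.finite(c(b_zy, se_zy, b_zx, se_zx))) || b_zx == 0 ||
      se_zy <= 0 || se_zx <= 0) {
    return(list(b_smr = NA_real_, se_smr = NA_real_, t_smr = NA_real_,
                p_smr = NA_real_, ok = FALSE))
  }
  z_zy2 <- (b_zy / se_zy)^2
  z_zx2 <- (b_zx / se_zx)^2
  b_smr <- b_zy / b_zx
  if (z_zy2 == 0) {
    return(list(b_smr = 0, se_smr = Inf, t_smr = 0, p_smr = 1, ok = TRUE))
  }
  t_smr <- z_zy2 * z_zx2 / (z_zy2 + z_zx2)
  p_smr <- stats::pchisq(t_smr, df = 1, lower.tail = FALSE)
  list(b_smr = b_smr, se_smr = abs(b_smr) / sqrt(t_smr),
       t_smr = t_smr, p_smr = p_smr, ok = TRUE)
}

#' Upper-tail probability of a positively weighted sum of chi-squares
#'
#' Computes `P(sum_i w_i X_i > q)` for independent 1-df chi-squares `X_i` —
#' the null distribution of the HEIDI statistic given the LD-induced
#' correlation of its components. The default method integrates Imhof's
#' inversion formula numerically; `"ltz"` applies the Liu-Tang-Zhang
#' moment-matching approximation (a non-central chi-square matched to the
#' first four cumulants), which is faster but only approximate in the far
#' tail.
#'
#' @param weights Positive weights (typically eigenvalues of a correlation
#'   matrix).
#' @param q Statistic value (>= 0).
#' @param method `"imhof"` (default) or `"ltz"`.
#' @return The tail probability, clamped to `(1e-300, 1]`.
#' @export
weighted_chisq_tail <- function(weights, q, method = c("imhof", "ltz")) {
  method <- match.arg(method)
  if (!length(weights)) stop("weights must be non-empty", call. = FALSE)
  if (any(!is.finite(weights) | weights <= 0))
    stop("weights must be positive and finite", call. = FALSE)
  if (!is.finite(q) || q < 0) stop("q must be a non-negative number", call. = FALSE)
  if (q == 0) return(1)
  p <- switch(method,
              imhof = .imhof_tail(weights, q),
              ltz = .ltz_tail(weights, q))
  min(max(p, 1e-300), 1)
}

# Imhof (1961) inversion for Q = sum w_i chisq_1:
# P(Q > q) = 1/2 + (1/pi) * Int_0^Inf sin(theta(u)) / (u * rho(u)) du
# The integrand oscillates at frequency <= (sum(w)+q)/2 with an algebraically
# decaying envelope 1/(u*rho(u)); composite Simpson on [0, U] with a fixed
# number of nodes per oscillation is robust where generic adaptive
# quadrature stalls. U is chosen so the truncated oscillatory tail
# (~ envelope/frequency at U) is negligible.
.imhof_tail <- function(w, q) {
  k <- length(w)
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(w, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(w^2, u^2))))
    out <- sin(theta) / (u * rho)
    out[u == 0] <- 0.5 * (sum(w) - q)
    out
  }
  rho1 <- function(u) exp(0.25 * sum(log1p(w^2 * u^2)))
  freq <- (sum(w) + q) / 2
  U <- 1
  while (2 / (U * rho1(U) * max(q, 0.5)) > 1e-8 && U < 1e7) U <- U * 1.5
  n <- max(4096L, ceiling(U * freq / pi * 24))
  n <- min(n, 2^22L)
  if (n %% 2L == 1L) n <- n + 1L
  h <- U / n
  # evaluate in blocks to bound the k x n working memory
  tot_ends <- integrand(c(0, U))
  s4 <- 0; s2 <- 0
  block <- 200000L
  idx <- 1L
  while (idx <= n - 1L) {
    hi <- min(idx + block - 1L, n - 1L)
    u <- (idx:hi) * h
    fu <- integrand(u)
    odd <- ((idx:hi) %% 2L) == 1L
    s4 <- s4 + sum(fu[odd]); s2 <- s2 + sum(fu[!odd])
    idx <- hi + 1L
  }
  val <- h / 3 * (tot_ends[1] + tot_ends[2] + 4 * s4 + 2 * s2)
  0.5 + val / pi
}

# Liu-Tang-Zhang (2009) moment matching: approximate Q by a scaled
# non-central chi-square agreeing in skewness and (where possible) kurtosis.
.ltz_tail <- function(w, q) {
  c1 <- sum(w); c2 <- sum(w^2); c3 <- sum(w^3); c4 <- sum(w^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / s1
    delta <- 0
    l <- c2^3 / c3^2
  }
  mu_q <- c1; sigma_q <- sqrt(2 * c2)
  mu_x <- l + delta; sigma_x <- sqrt(2) * a
  tstar <- (q - mu_q) / sigma_q
  stats::pchisq(tstar * sigma_x + mu_x, df = l, ncp = delta, lower.tail = FALSE)
}

#' Select HEIDI instruments for a probe
#'
#' Applies the [heidi_config()] rules: candidates must be cis variants of
#' the probe other than the top SNP, with QTL p below
#' `instrument_p_max` and panel r^2 with the top SNP inside
#' `[r2_min, r2_max]`; survivors are ranked by ascending QTL p and truncated
#' to `max_instruments`.
#'
#' @param qtl_probe `qtl_dataset` rows for a single probe.
#' @param panel A `ref_panel` (LD source).
#' @param top_snp The probe's minimum-p QTL variant.
#' @param cfg A [heidi_config()].
#' @return Character vector of instrument ids (possibly empty).
#' @export
select_instruments <- function(qtl_probe, panel, top_snp, cfg = heidi_config()) {
  stopifnot(inherits(panel, "ref_panel"))
  if (!top_snp %in% panel$variants$id)
    stop("top SNP not in panel: ", top_snp, call. = FALSE)
  cand <- qtl_probe[qtl_probe$snp != top_snp &
                    qtl_probe$snp %in% panel$variants$id &
                    is.finite(qtl_probe$se) &
                    qtl_probe$p < cfg$instrument_p_max, , drop = FALSE]
  if (!nrow(cand)) return(character())
  r <- as.numeric(stats::cor(panel$dosages[, top_snp],
                             panel$dosages[, cand$snp, drop = FALSE]))
  r2 <- r^2
  cand <- cand[r2 >= cfg$r2_min & r2 <= cfg$r2_max, , drop = FALSE]
  if (!nrow(cand)) return(character())
  cand <- cand[order(cand$p), , drop = FALSE]
  utils::head(cand$snp, cfg$max_instruments)
}

#' The HEIDI heterogeneity test
#'
#' Under pleiotropy (a single causal variant shared by the molecular trait
#' and disease), every cis-SNP in LD with it estimates the same mediated
#' effect `b_xy = b_zy / b_zx`; under linkage the estimates disagree. HEIDI
#' tests the homogeneity of the ratio estimates across instruments: for each
#' instrument `i`, `d_i = b_xy(i) - b_xy(top)` is standardized by its
#' delta-method SE (GWAS and QTL samples independent; cross-SNP covariances
#' proportional to the signed LD correlation), and
#' `T_HEIDI = sum_i z_d(i)^2` is referred to its null — a weighted sum of
#' 1-df chi-squares with weights the eigenvalues of the correlation matrix
#' of the `z_d` vector.
#'
#' @param b_zy,se_zy GWAS effects/SEs for `c(top_snp, instruments)`, all
#'   harmonized to the same effect alleles as the QTL effects.
#' @param b_zx,se_zx QTL effects/SEs, same order.
#' @param ld Signed correlation matrix over `c(top_snp, instruments)`
#'   (top SNP first), oriented to the same effect alleles.
#' @param min_instruments Floor below which `p_heidi` is `NA`.
#' @param method Tail method passed to [weighted_chisq_tail()].
#' @return A list with `p_heidi`, `t_heidi`, `n_snps` (instruments used).
#' @export
compute_heidi <- function(b_zy, se_zy, b_zx, se_zx, ld,
                          min_instruments = 1L, method = "imhof") {
  k <- length(b_zy)
  stopifnot(length(se_zy) == k, length(b_zx) == k, length(se_zx) == k,
            is.matrix(ld), nrow(ld) == k, ncol(ld) == k)
  m <- k - 1L  # instruments (index 1 is the top SNP)
  if (m < min_instruments)
    return(list(p_heidi = NA_real_, t_heidi = NA_real_, n_snps = m))
  b_xy <- b_zy / b_zx
  # covariance of the ratio estimates (delta method; two independent samples)
  V <- ld * outer(se_zy, se_zy) / outer(b_zx, b_zx) +
    ld * outer(se_zx, se_zx) * outer(b_zy, b_zy) / outer(b_zx^2, b_zx^2)
  d <- b_xy[-1] - b_xy[1]
  Cd <- V[-1, -1, drop = FALSE] -
    outer(V[-1, 1], rep(1, m)) - outer(rep(1, m), V[1, -1]) + V[1, 1]
  vd <- diag(Cd)
  if (any(!is.finite(vd) | vd <= 0))
    stop("invalid LD/covariance structure in HEIDI", call. = FALSE)
  z <- d / sqrt(vd)
  t_heidi <- sum(z^2)
  Rd <- Cd / outer(sqrt(vd), sqrt(vd))
  ev <- eigen(Rd, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > 1e-8]
  if (!length(ev))
    stop("singular correlation structure in HEIDI", call. = FALSE)
  p <- if (t_heidi <= 0) 1 else weighted_chisq_tail(ev, t_heidi, method = method)
  list(p_heidi = p, t_heidi = t_heidi, n_snps = m)
}

# --- allele harmonization ---------------------------------------------------

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

.is_palindromic <- function(a1, a2) .COMP[a1] == a2

#' Harmonize a summary-statistic record to a target effect allele
#'
#' Reconciles `(a1, a2)` with `(target_a1, target_a2)` allowing an allele
#' swap, a strand flip, or both. A swap negates the effect and reflects the
#' frequency. Palindromic variants (A/T, C/G) are strand-ambiguous: they are
#' resolved by comparing allele frequencies when both are available and
#' informative (`|eaf - 0.5| > 0.08`), otherwise dropped.
#'
#' @param target_a1,target_a2 Effect/other allele to harmonize to.
#' @param a1,a2 Record's effect/other allele.
#' @param b Record's effect estimate.
#' @param eaf Record's effect-allele frequency (optional).
#' @param target_eaf Target-side effect-allele frequency (optional; used for
#'   palindromic resolution).
#' @return A list with `b`, `eaf`, and `ok` (`FALSE` when irreconcilable).
#' @export
harmonize_effect <- function(target_a1, target_a2, a1, a2, b, eaf = NA,
                             target_eaf = NA) {
  fail <- list(b = NA_real_, eaf = NA_real_, ok = FALSE)
  same <- a1 == target_a1 & a2 == target_a2
  swap <- a1 == target_a2 & a2 == target_a1
  if (!same && !swap) {
    # try strand flip
    a1 <- unname(.COMP[a1]); a2 <- unname(.COMP[a2])
    if (anyNA(c(a1, a2))) return(fail)
    same <- a1 == target_a1 & a2 == target_a2
    swap <- a1 == target_a2 & a2 == target_a1
    if (!same && !swap) return(fail)
  }
  if (.is_palindromic(target_a1, target_a2)) {
    # both strand interpretations match; use frequency to disambiguate
    if (is.na(eaf) || is.na(target_eaf) ||
        abs(eaf - 0.5) <= 0.08 || abs(target_eaf - 0.5) <= 0.08)
      return(fail)
    freq_agree <- (eaf > 0.5) == (target_eaf > 0.5)
    swap <- !freq_agree
  }
  if (swap) list(b = -b, eaf = if (is.na(eaf)) NA_real_ else 1 - eaf, ok = TRUE)
  else list(b = b, eaf = eaf, ok = TRUE)
}

# orient panel dosages of `snps` to given effect alleles; returns the signed
# correlation matrix in that orientation
.oriented_ld <- function(panel, snps, effect_alleles) {
  X <- panel$dosages[, snps, drop = FALSE]
  pv <- panel$variants[match(snps, panel$variants$id), ]
  flip <- effect_alleles != pv$effect_allele
  X[, flip] <- 2 - X[, flip, drop = FALSE]
  stats::cor(X)
}

#' Genome-wide SMR + HEIDI scan over all probes
#'
#' For each probe of the QTL dataset: restrict to variants shared with the
#' GWAS summary and the LD panel (after allele harmonization of the GWAS
#' effect onto the QTL effect allele), take the minimum-QTL-p variant as the
#' top SNP, compute the SMR statistic there, select HEIDI instruments with
#' [select_instruments()], and compute the HEIDI p-value when enough
#' instruments survive. A probe passes when `p_smr < smr_p_threshold` and
#' `p_heidi > heidi_p_threshold`.
#'
#' @param gwas A `gwas_summary`.
#' @param qtl A `qtl_dataset` (one or more probes; rbind probes together).
#' @param panel A `ref_panel` for LD.
#' @param smr_p_threshold SMR significance filter (default 5e-8).
#' @param heidi_p_threshold HEIDI heterogeneity filter (default 0.05).
#' @param cfg A [heidi_config()].
#' @param heidi_method Tail method for the HEIDI null.
#' @return An `smr_scan` data.frame: `probe, gene, top_snp, b_smr, se_smr,
#'   p_smr, p_heidi, n_heidi_snps, passed`, with attributes
#'   `n_probes_skipped` (no shared variants) and `n_records_dropped`
#'   (irreconcilable alleles).
#' @export
run_smr_scan <- function(gwas, qtl, panel,
                         smr_p_threshold = 5e-8, heidi_p_threshold = 0.05,
                         cfg = heidi_config(), heidi_method = "imhof") {
  stopifnot(inherits(panel, "ref_panel"))
  probes <- unique(qtl$probe)
  res <- vector("list", length(probes))
  n_skipped <- 0L
  n_dropped <- 0L
  for (pi in seq_along(probes)) {
    qp <- qtl[qtl$probe == probes[pi], , drop = FALSE]
    gi <- match(qp$snp, gwas$SNP)
    keep <- !is.na(gi) & qp$snp %in% panel$variants$id
    qp <- qp[keep, , drop = FALSE]; gi <- gi[keep]
    if (!nrow(qp)) { n_skipped <- n_skipped + 1L; next }
    # harmonize GWAS effects onto the QTL effect alleles
    hb <- numeric(nrow(qp)); hok <- logical(nrow(qp))
    for (j in seq_len(nrow(qp))) {
      h <- harmonize_effect(qp$a1[j], qp$a2[j],
                            gwas$A1[gi[j]], gwas$A2[gi[j]], gwas$b[gi[j]],
                            eaf = gwas$freq[gi[j]], target_eaf = qp$freq[j])
      hb[j] <- h$b; hok[j] <- h$ok
    }
    n_dropped <- n_dropped + sum(!hok)
    ok <- hok & is.finite(qp$se) & is.finite(gwas$se[gi]) & qp$se > 0
    qp <- qp[ok, , drop = FALSE]
    hb <- hb[ok]; gse <- gwas$se[gi][ok]
    if (!nrow(qp)) { n_skipped <- n_skipped + 1L; next }
    ti <- which.min(qp$p)
    top <- qp$snp[ti]
    smr <- compute_smr(hb[ti], gse[ti], qp$b[ti], qp$se[ti])
    instr <- select_instruments(qp, panel, top, cfg)
    p_heidi <- NA_real_; n_heidi <- length(instr)
    if (length(instr) >= cfg$min_instruments) {
      sel <- match(c(top, instr), qp$snp)
      ld <- .oriented_ld(panel, qp$snp[sel], qp$a1[sel])
      hd <- compute_heidi(hb[sel], gse[sel], qp$b[sel], qp$se[sel], ld,
                          min_instruments = cfg$min_instruments,
                          method = heidi_method)
      p_heidi <- hd$p_heidi
      n_heidi <- hd$n_snps
    }
    passed <- isTRUE(smr$ok) && !is.na(smr$p_smr) &&
      smr$p_smr < smr_p_threshold &&
      !is.na(p_heidi) && p_heidi > heidi_p_threshold
    res[[pi]] <- data.frame(
      probe = probes[pi], gene = qp$gene[1], top_snp = top,
      b_smr = smr$b_smr, se_smr = smr$se_smr, p_smr = smr$p_smr,
      p_heidi = p_heidi, n_heidi_snps = n_heidi, passed = passed,
      stringsAsFactors = FALSE
    )
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    warning("no probes shared variants with the GWAS summary and panel")
    out <- data.frame(probe = character(), gene = character(),
                      top_snp = character(), b_smr = numeric(),
                      se_smr = numeric(), p_smr = numeric(),
                      p_heidi = numeric(), n_heidi_snps = integer(),
                      passed = logical(), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, res)
  }
  attr(out, "n_probes_skipped") <- n_skipped
  attr(out, "n_records_dropped") <- n_dropped
  class(out) <- c("smr_scan", "data.frame")
  out
}
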