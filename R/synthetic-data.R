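#' Specify the LD-block structure of a simulated reference panel
#'
#' Variants are organised into independent blocks; within a block every pair
#' of haplotypes has (approximately) the same allelic correlation
#' `within_block_corr`, emulating the local LD that both the HEIDI test and
#' LD pruning rely on. Blocks are placed on separate chromosomes so that
#' cis-windows never straddle two blocks.
#'
#' @param n_blocks Number of independent LD blocks.
#' @param block_size Number of variants per block.
#' @param within_block_corr Target pairwise haplotype correlation r, in
#'   `[0, 1)`. This is the correlation of allele indicators (and hence of
#'   genotype dosages), not of the underlying Gaussian copula.
#' @param maf_range Closed interval within (0, 0.5] from which per-variant
#'   minor allele frequencies are drawn uniformly.
#' @return An object of class `ld_block_spec`.
#' @export
ld_block_spec <- function(n_blocks, block_size, within_block_corr = 0,
                          maf_range = c(0.1, 0.5)) {
  stopifnot(length(n_blocks) == 1L, length(block_size) == 1L)
  if (n_blocks < 1 || block_size < 1)
    stop("n_blocks and block_size must be positive", call. = FALSE)
  if (!is.numeric(within_block_corr) || within_block_corr < 0 ||
      within_block_corr >= 1)
    stop("within_block_corr must lie in [0, 1)", call. = FALSE)
  if (length(maf_range) != 2L || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must be an ordered interval within (0, 0.5]", call. = FALSE)
  structure(list(n_blocks = as.integer(n_blocks),
                 block_size = as.integer(block_size),
                 within_block_corr = within_block_corr,
                 maf_range = as.numeric(maf_range)),
            class = "ld_block_spec")
}

#' Specify a genetic architecture linking a molecular trait to disease
#'
#' Three modes cover the hypotheses the SMR/HEIDI framework distinguishes:
#' `pleiotropy` (one causal variant drives both the molecular trait and
#' disease liability, with the disease effect equal to `b_zx * b_xy` by the
#' mediation identity), `linkage` (the QTL variant and the disease variant
#' are distinct but correlated), and `null` (no effects anywhere).
#'
#' @param mode One of `"pleiotropy"`, `"linkage"`, `"null"`.
#' @param causal_variant_id Variant driving the molecular trait.
#' @param b_zx Per-allele effect of the causal variant on the molecular trait.
#' @param b_xy Effect of the molecular trait on disease log-odds
#'   (pleiotropy mode).
#' @param b_zy_direct Per-allele direct effect on disease log-odds
#'   (linkage mode), attached to `direct_variant_id`.
#' @param direct_variant_id Disease-affecting variant for linkage mode; must
#'   differ from `causal_variant_id`.
#' @param trait_noise_sd Residual SD of the molecular trait.
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(mode = c("pleiotropy", "linkage", "null"),
                              causal_variant_id = NULL,
                              b_zx = 0, b_xy = 0,
                              b_zy_direct = 0, direct_variant_id = NULL,
                              trait_noise_sd = 1) {
  mode <- match.arg(mode)
  if (mode == "null") {
    b_zx <- 0; b_xy <- 0; b_zy_direct <- 0
  }
  if (mode != "null" && is.null(causal_variant_id))
    stop("causal_variant_id is required unless mode = 'null'", call. = FALSE)
  if (mode == "linkage") {
    if (is.null(direct_variant_id))
      stop("linkage mode requires direct_variant_id", call. = FALSE)
    if (identical(direct_variant_id, causal_variant_id))
      stop("linkage mode requires the disease variant to differ from the QTL variant",
           call. = FALSE)
  }
  if (trait_noise_sd <= 0) stop("trait_noise_sd must be positive", call. = FALSE)
  structure(list(mode = mode, causal_variant_id = causal_variant_id,
                 b_zx = b_zx, b_xy = b_xy, b_zy_direct = b_zy_direct,
                 direct_variant_id = direct_variant_id,
                 trait_noise_sd = trait_noise_sd),
            class = "architecture_spec")
}

# Bivariate standard normal CDF P(Z1 < t1, Z2 < t2) with correlation rho,
# by conditioning on Z1 (adequate accuracy for copula calibration).
.pbinorm <- function(t1, t2, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(t1) * stats::pnorm(t2))
  f <- function(z) stats::pnorm((t2 - rho * z) / sqrt(1 - rho^2)) * stats::dnorm(z)
  stats::integrate(f, -8, t1, rel.tol = 1e-9)$value
}

# Solve for the latent Gaussian correlation that yields allele-indicator
# (phi) correlation `target_r` when both margins are Bernoulli(p).
.calibrate_latent_rho <- function(target_r, p) {
  if (target_r <= 0) return(0)
  t <- stats::qnorm(p)
  phi_of <- function(rho) {
    (.pbinorm(t, t, rho) - p^2) / (p * (1 - p)) - target_r
  }
  # phi is increasing in rho; phi(1) = 1 for equal margins
  stats::uniroot(phi_of, lower = target_r, upper = 1 - 1e-9,
                 tol = 1e-8, extendInt = "no")$root
}

# Draw n haplotypes for one block: latent equicorrelated Gaussians
# thresholded at per-variant MAF quantiles. Returns n x m 0/1 matrix.
.draw_block_haplotypes <- function(n, maf, latent_rho) {
  m <- length(maf)
  if (latent_rho <= 0) {
    z <- matrix(stats::rnorm(n * m), n, m)
  } else {
    shared <- stats::rnorm(n)
    z <- sqrt(latent_rho) * shared +
      sqrt(1 - latent_rho) * matrix(stats::rnorm(n * m), n, m)
  }
  thr <- stats::qnorm(maf)
  (z < rep(thr, each = n)) * 1L
}

.ALLELES <- c("A", "C", "G", "T")

#' Generate an LD-structured reference panel
#'
#' Simulates `n_individuals` diploid genotypes (dosages 0/1/2) under a
#' Gaussian-copula haplotype model with Hardy-Weinberg sampling: per block,
#' haplotype allele indicators share an equicorrelated latent Gaussian whose
#' correlation is calibrated so that the realised allele correlation matches
#' `spec$within_block_corr`; the two haplotypes of an individual are
#' independent, so genotype dosages inherit the same correlation. The panel
#' records its generative parameters so that downstream generators can
#' resample new individuals from the same population.
#'
#' @param spec An [ld_block_spec()].
#' @param n_individuals Panel size (>= 2).
#' @param seed Integer seed; the panel is a pure function of `(spec,
#'   n_individuals, seed)`.
#' @return An object of class `ref_panel`: a list with `variants`
#'   (data.frame: chrom, pos, id, effect_allele, other_allele), `dosages`
#'   (n x m matrix, columns named by variant id), `maf` (generative MAFs),
#'   and the copula parameters needed for resampling.
#' @export
make_reference_panel <- function(spec, n_individuals, seed) {
  if (!inherits(spec, "ld_block_spec")) stop("spec must be an ld_block_spec", call. = FALSE)
  if (n_individuals < 2) stop("n_individuals must be >= 2", call. = FALSE)
  set.seed(as.integer(seed))
  nb <- spec$n_blocks; bs <- spec$block_size
  m <- nb * bs
  block <- rep(seq_len(nb), each = bs)
  # Tightly linked variants necessarily have near-identical allele
  # frequencies (the phi coefficient of two Bernoullis with unequal margins
  # is bounded below 1), so within-block MAF dispersion shrinks as the LD
  # target grows: blocks share a base MAF with per-variant jitter scaled by
  # (1 - r).
  base_maf <- stats::runif(nb, spec$maf_range[1], spec$maf_range[2])
  half_width <- diff(spec$maf_range) / 2
  jitter <- stats::runif(m, -half_width, half_width) *
    (1 - spec$within_block_corr)
  maf <- pmin(pmax(base_maf[block] + jitter, spec$maf_range[1]),
              spec$maf_range[2])
  # one latent rho per block, calibrated at the block's mean MAF
  latent_rho <- vapply(seq_len(nb), function(b) {
    .calibrate_latent_rho(spec$within_block_corr, mean(maf[block == b]))
  }, numeric(1))
  al <- t(vapply(seq_len(m), function(j) sample(.ALLELES, 2), character(2)))
  variants <- data.frame(
    chrom = as.character(block),
    pos = rep(seq_len(bs), nb) * 1000L,
    id = sprintf("snp_b%02d_v%03d", block, rep(seq_len(bs), nb)),
    effect_allele = al[, 1], other_allele = al[, 2],
    stringsAsFactors = FALSE
  )
  panel <- structure(list(variants = variants, maf = maf, block = block,
                          latent_rho = latent_rho, spec = spec,
                          seed = as.integer(seed)),
                     class = "ref_panel")
  panel$dosages <- resample_dosages(panel, n_individuals, seed = seed + 1L)
  emp <- colMeans(panel$dosages) / 2
  if (any(emp <= 0 | emp >= 1)) {
    # avoid monomorphic panel columns: redraw the offending haplotypes once
    panel$dosages <- resample_dosages(panel, n_individuals, seed = seed + 2L)
  }
  panel
}

#' Resample genotype dosages from a panel's generative model
#'
#' Draws a fresh sample of individuals from the same haplotype population
#' that produced the panel (not a bootstrap of panel rows).
#'
#' @param panel A `ref_panel`.
#' @param n Number of individuals to draw.
#' @param seed Integer seed.
#' @return An `n x m` dosage matrix with columns named by variant id.
#' @export
resample_dosages <- function(panel, n, seed) {
  stopifnot(inherits(panel, "ref_panel"))
  if (is.null(panel$block))
    stop("panel lacks generative parameters; build it with make_reference_panel()",
         call. = FALSE)
  set.seed(as.integer(seed))
  m <- length(panel$maf)
  x <- matrix(0L, n, m)
  for (b in unique(panel$block)) {
    idx <- which(panel$block == b)
    h1 <- .draw_block_haplotypes(n, panel$maf[idx], panel$latent_rho[b])
    h2 <- .draw_block_haplotypes(n, panel$maf[idx], panel$latent_rho[b])
    x[, idx] <- h1 + h2
  }
  colnames(x) <- panel$variants$id
  x
}

# fast marginal OLS of y on each column of X; returns b, se, p
.marginal_ols <- function(X, y) {
  n <- length(y)
  xm <- colMeans(X)
  ym <- mean(y)
  sxx <- colSums(X^2) - n * xm^2
  sxy <- as.numeric(crossprod(X, y)) - n * xm * ym
  syy <- sum(y^2) - n * ym^2
  b <- sxy / sxx
  sse <- pmax(syy - b * sxy, 0)
  se <- sqrt(sse / ((n - 2) * sxx))
  tstat <- b / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  mono <- sxx <= 0
  b[mono] <- 0; se[mono] <- Inf; p[mono] <- 1
  list(b = b, se = se, p = p)
}

#' Simulate a cis-QTL study for one probe
#'
#' Draws an independent study sample from the panel's population, simulates
#' the molecular trait (expression or methylation level) from the
#' architecture, and runs per-variant simple linear regressions of trait on
#' dosage over the probe's cis window, mimicking the marginal summary
#' statistics distributed by eQTL/mQTL consortia.
#'
#' @param panel A `ref_panel`.
#' @param arch An [architecture_spec()]; its `causal_variant_id` must be in
#'   the panel (ignored for `mode = "null"`, where a null probe centred on
#'   `probe_meta$pos` is simulated).
#' @param n_study QTL study sample size.
#' @param probe_meta List with `probe`, `gene`, and optionally `chrom`/`pos`
#'   (defaults: the causal variant's location).
#' @param seed Integer seed.
#' @param cis_window Window width in bp centred on the probe (default 2 Mb).
#' @param include_p_max Optional p-value cap emulating "lite" QTL releases
#'   that only distribute significant records; `NULL` keeps everything.
#' @return A `qtl_dataset` data.frame with columns
#'   `probe, probe_chr, probe_bp, gene, snp, snp_chr, snp_bp, a1, a2, freq,
#'   b, se, p` and a `truth` attribute recording the generative parameters.
#' @export
make_qtl_study <- function(panel, arch, n_study, probe_meta, seed,
                           cis_window = 2e6, include_p_max = NULL) {
  stopifnot(inherits(panel, "ref_panel"), inherits(arch, "architecture_spec"))
  v <- panel$variants
  if (arch$mode != "null") {
    ci <- match(arch$causal_variant_id, v$id)
    if (is.na(ci)) stop("unknown causal variant: ", arch$causal_variant_id, call. = FALSE)
    probe_chr <- probe_meta$chrom %||% v$chrom[ci]
    probe_bp <- probe_meta$pos %||% v$pos[ci]
  } else {
    probe_chr <- probe_meta$chrom %||% v$chrom[1]
    probe_bp <- probe_meta$pos %||% v$pos[1]
  }
  cis <- which(v$chrom == probe_chr & abs(v$pos - probe_bp) <= cis_window / 2)
  if (!length(cis)) stop("no panel variants in the probe's cis window", call. = FALSE)
  X <- resample_dosages(panel, n_study, seed = seed)
  g <- if (arch$mode == "null") 0 else arch$b_zx * X[, arch$causal_variant_id]
  y <- g + stats::rnorm(n_study, 0, arch$trait_noise_sd)
  fit <- .marginal_ols(X[, cis, drop = FALSE], y)
  out <- data.frame(
    probe = probe_meta$probe, probe_chr = probe_chr, probe_bp = probe_bp,
    gene = probe_meta$gene,
    snp = v$id[cis], snp_chr = v$chrom[cis], snp_bp = v$pos[cis],
    a1 = v$effect_allele[cis], a2 = v$other_allele[cis],
    freq = colMeans(X[, cis, drop = FALSE]) / 2,
    b = fit$b, se = fit$se, p = fit$p,
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(include_p_max)) out <- out[out$p < include_p_max, , drop = FALSE]
  attr(out, "truth") <- list(arch = arch, n_study = n_study, seed = seed)
  class(out) <- c("qtl_dataset", "data.frame")
  out
}

# vectorised per-variant logistic regression (intercept + one dosage),
# Newton-Raphson across variants simultaneously
.marginal_logistic <- function(X, y, max_iter = 30L, tol = 1e-10) {
  n <- length(y); m <- ncol(X)
  a <- rep(stats::qlogis(mean(y)), m)
  b <- rep(0, m)
  sx <- colSums(X)
  active <- apply(X, 2, stats::var) > 0
  for (it in seq_len(max_iter)) {
    eta <- sweep(X * rep(b, each = n), 2, a, `+`)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    r <- y - mu
    g1 <- colSums(r); g2 <- colSums(r * X)
    h11 <- colSums(w); h12 <- colSums(w * X); h22 <- colSums(w * X^2)
    det <- h11 * h22 - h12^2
    da <- (h22 * g1 - h12 * g2) / det
    db <- (h11 * g2 - h12 * g1) / det
    da[!active] <- 0; db[!active] <- 0
    a <- a + da; b <- b + db
    if (max(abs(c(da, db)), na.rm = TRUE) < tol) break
  }
  eta <- sweep(X * rep(b, each = n), 2, a, `+`)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  h11 <- colSums(w); h12 <- colSums(w * X); h22 <- colSums(w * X^2)
  det <- h11 * h22 - h12^2
  se <- sqrt(h11 / det)
  bad <- !active | !is.finite(se) | se <= 0 | abs(b) > 20
  b[bad] <- 0; se[bad] <- Inf
  p <- 2 * stats::pnorm(-abs(b / se))
  p[bad] <- 1
  list(b = b, se = se, p = p)
}

#' Simulate a case-control GWAS and its marginal summary statistics
#'
#' Individuals are drawn from the panel's population; disease status follows
#' a logistic model whose log-odds are linear in dosage (pleiotropy mode
#' contributes `b_zx * b_xy` at the causal variant via the mediation
#' identity; linkage mode attaches `b_zy_direct` to a distinct variant).
#' Sampling continues until the requested case and control counts are met,
#' then a marginal logistic regression is fitted per variant, yielding
#' COJO-style summary records.
#'
#' @param panel A `ref_panel`.
#' @param arch A single [architecture_spec()] or a list of them; effects add
#'   on the log-odds scale.
#' @param n_cases,n_controls Requested counts (each >= 50 for stable fits).
#' @param seed Integer seed.
#' @param prevalence Baseline disease probability at the dosage centroid
#'   used while sampling (sampling design only; marginal effects are
#'   unaffected by it under the logistic model).
#' @return A `gwas_summary` data.frame with columns
#'   `SNP, A1, A2, freq, b, se, p, n`; monomorphic variants keep their row
#'   with non-finite `se` and a `p = 1` sentinel.
#' @export
make_gwas_study <- function(panel, arch, n_cases, n_controls, seed,
                            prevalence = 0.2) {
  stopifnot(inherits(panel, "ref_panel"))
  if (n_cases < 50 || n_controls < 50)
    stop("need at least 50 cases and 50 controls", call. = FALSE)
  archs <- if (inherits(arch, "architecture_spec")) list(arch) else arch
  m <- length(panel$maf)
  beta <- rep(0, m)
  names(beta) <- panel$variants$id
  for (a in archs) {
    stopifnot(inherits(a, "architecture_spec"))
    if (a$mode == "pleiotropy") {
      beta[a$causal_variant_id] <- beta[a$causal_variant_id] + a$b_zx * a$b_xy
    } else if (a$mode == "linkage") {
      beta[a$direct_variant_id] <- beta[a$direct_variant_id] + a$b_zy_direct
    }
  }
  alpha <- stats::qlogis(prevalence) - sum(beta * 2 * panel$maf)
  n_total <- n_cases + n_controls
  set.seed(as.integer(seed))
  Xc <- matrix(0L, 0, m); Xk <- matrix(0L, 0, m)
  budget <- 60L
  batch_seed <- sample.int(.Machine$integer.max, budget)
  for (it in seq_len(budget)) {
    nb <- max(2L * n_total, 200L)
    X <- resample_dosages(panel, nb, seed = batch_seed[it])
    set.seed(batch_seed[it] %% 1000003L + it)
    pr <- stats::plogis(alpha + as.numeric(X %*% beta))
    d <- stats::rbinom(nb, 1, pr)
    if (nrow(Xc) < n_cases) Xc <- rbind(Xc, X[d == 1, , drop = FALSE])
    if (nrow(Xk) < n_controls) Xk <- rbind(Xk, X[d == 0, , drop = FALSE])
    if (nrow(Xc) >= n_cases && nrow(Xk) >= n_controls) break
  }
  if (nrow(Xc) < n_cases || nrow(Xk) < n_controls)
    stop("retry budget exceeded while sampling cases/controls", call. = FALSE)
  X <- rbind(Xc[seq_len(n_cases), , drop = FALSE],
             Xk[seq_len(n_controls), , drop = FALSE])
  y <- rep(c(1L, 0L), c(n_cases, n_controls))
  fit <- .marginal_logistic(X, y)
  out <- data.frame(
    SNP = panel$variants$id,
    A1 = panel$variants$effect_allele, A2 = panel$variants$other_allele,
    freq = colMeans(X) / 2, b = fit$b, se = fit$se, p = fit$p,
    n = n_total, stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "truth") <- list(beta = beta, archs = archs, n_cases = n_cases,
                             n_controls = n_controls, seed = seed)
  class(out) <- c("gwas_summary", "data.frame")
  out
}

#' Simulate an individual-level cohort with outcomes driven by a true PRS
#'
#' Draws genotypes from the panel population, computes each individual's
#' true polygenic score from `true_weights`, and assigns the outcome from a
#' logistic model with that score as linear predictor. Sampling continues
#' until the requested case and non-case counts are reached. Missing
#' genotypes are inserted completely at random.
#'
#' @param panel A `ref_panel`.
#' @param true_weights A [prs_model()] whose variants are all in the panel.
#' @param design `"case_control"` (prevalent disease) or `"prospective"`
#'   (incident cases within follow-up); the generative mechanics are
#'   identical, the label records the study design.
#' @param n_cases,n_noncases Requested counts (each >= 1).
#' @param missing_rate Fraction of dosage entries set missing (MCAR).
#' @param seed Integer seed.
#' @param prevalence Baseline outcome probability at the dosage centroid.
#' @return A `cohort_data` object: `dosages` (n x m over all panel
#'   variants), `labels` (0/1), `design`, `eaf` (empirical effect-allele
#'   frequencies), `variants`.
#' @export
make_cohort <- function(panel, true_weights,
                        design = c("case_control", "prospective"),
                        n_cases, n_noncases, missing_rate = 0, seed,
                        prevalence = NULL) {
  stopifnot(inherits(panel, "ref_panel"), inherits(true_weights, "prs_model"))
  design <- match.arg(design)
  if (n_cases < 1 || n_noncases < 1)
    stop("need at least one case and one non-case", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  miss <- setdiff(true_weights$snp, panel$variants$id)
  if (length(miss))
    stop("true_weights variants absent from panel: ", paste(miss, collapse = ", "),
         call. = FALSE)
  n_total <- n_cases + n_noncases
  if (is.null(prevalence))
    prevalence <- if (design == "prospective") max(0.02, n_cases / n_total) else
      min(0.5, max(0.05, n_cases / n_total))
  # orient weights onto panel dosage coding
  idx <- match(true_weights$snp, panel$variants$id)
  w <- true_weights$weight
  flip <- true_weights$effect_allele != panel$variants$effect_allele[idx]
  alpha <- stats::qlogis(prevalence) -
    sum(ifelse(flip, -w, w) * 2 * panel$maf[idx]) - sum(2 * w[flip])
  set.seed(as.integer(seed))
  Xc <- NULL; Xk <- NULL
  budget <- 60L
  batch_seed <- sample.int(.Machine$integer.max, budget)
  for (it in seq_len(budget)) {
    nb <- max(2L * n_total, 200L)
    X <- resample_dosages(panel, nb, seed = batch_seed[it])
    xs <- X[, idx, drop = FALSE]
    xs[, flip] <- 2 - xs[, flip, drop = FALSE]
    eta <- alpha + as.numeric(xs %*% w)
    set.seed(batch_seed[it] %% 1000003L + it)
    d <- stats::rbinom(nb, 1, stats::plogis(eta))
    if (is.null(Xc)) Xc <- X[0, , drop = FALSE]
    if (is.null(Xk)) Xk <- X[0, , drop = FALSE]
    if (nrow(Xc) < n_cases) Xc <- rbind(Xc, X[d == 1, , drop = FALSE])
    if (nrow(Xk) < n_noncases) Xk <- rbind(Xk, X[d == 0, , drop = FALSE])
    if (nrow(Xc) >= n_cases && nrow(Xk) >= n_noncases) break
  }
  if (nrow(Xc) < n_cases || nrow(Xk) < n_noncases)
    stop("retry budget exceeded while sampling the cohort; ",
         "check effect sizes and prevalence", call. = FALSE)
  X <- rbind(Xc[seq_len(n_cases), , drop = FALSE],
             Xk[seq_len(n_noncases), , drop = FALSE])
  labels <- rep(c(1L, 0L), c(n_cases, n_noncases))
  X <- matrix(as.numeric(X), nrow(X), ncol(X), dimnames = dimnames(X))
  if (missing_rate > 0) {
    nmiss <- stats::rbinom(1, length(X), missing_rate)
    X[sample.int(length(X), nmiss)] <- NA_real_
  }
  rownames(X) <- sprintf("ind_%05d", seq_len(nrow(X)))
  structure(list(dosages = X, labels = labels, design = design,
                 eaf = colMeans(X, na.rm = TRUE) / 2,
                 variants = panel$variants,
                 truth = list(weights = true_weights, seed = seed,
                              prevalence = prevalence)),
            class = "cohort_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap observed dosages as an LD reference panel
#'
#' Builds a `ref_panel` directly from a genotype matrix (e.g. read from a
#' VCF or dosage TSV). Such a panel supports every LD-based operation
#' (instrument selection, HEIDI, pruning) but not population resampling,
#' which requires a generatively constructed panel from
#' [make_reference_panel()].
#'
#' @param variants Data.frame with `chrom, pos, id, effect_allele,
#'   other_allele`.
#' @param dosages n x m dosage matrix, columns in `variants` order.
#' @return A `ref_panel` (without copula parameters).
#' @export
as_ref_panel <- function(variants, dosages) {
  stopifnot(is.data.frame(variants), is.matrix(dosages),
            nrow(variants) == ncol(dosages))
  colnames(dosages) <- variants$id
  structure(list(variants = variants, dosages = dosages,
                 maf = colMeans(dosages, na.rm = TRUE) / 2,
                 block = NULL, latent_rho = NULL, spec = NULL, seed = NA),
            class = "ref_panel")
}
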