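#' Construct a PRS model (variant weights)
#'
#' A PRS model is an ordered table of variants with effect/other alleles and
#' per-allele weights on the log-odds scale; an individual's score is the
#' scoresum \eqn{\sum_k \beta_k x_k} with \eqn{x_k} the effect-allele dosage
#' in `[0, 2]`.
#'
#' @param snp Variant ids (unique).
#' @param effect_allele,other_allele Allele labels per variant.
#' @param weight Finite per-allele weights.
#' @param label Model name.
#' @return An object of class `prs_model` (a data.frame).
#' @export
prs_model <- function(snp, effect_allele, other_allele, weight,
                      label = "prs") {
  if (anyDuplicated(snp))
    stop("variant ids must be unique within a model", call. = FALSE)
  if (length(weight) && !all(is.finite(weight)))
    stop("weights must be finite", call. = FALSE)
  out <- data.frame(snp = as.character(snp),
                    effect_allele = as.character(effect_allele),
                    other_allele = as.character(other_allele),
                    weight = as.numeric(weight),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "label") <- label
  class(out) <- c("prs_model", "data.frame")
  out
}

.relabel <- function(model, label) { attr(model, "label") <- label; model }

#' Build the functional PRS model from SMR/HEIDI scan results
#'
#' Collects the top SNPs of all probes that passed both the SMR significance
#' filter and the HEIDI heterogeneity filter (union over any number of
#' scans, e.g. eQTL and mQTL), de-duplicates them, and weights each variant
#' by its GWAS log-odds effect.
#'
#' @param scan A `smr_scan` data.frame (from [run_smr_scan()]) or a list of
#'   them; rows with `passed == TRUE` contribute their `top_snp`.
#' @param gwas A `gwas_summary` providing weights and allele orientation.
#' @param label Model name.
#' @return A `prs_model`; empty when no probe passed.
#' @export
build_functional_model <- function(scan, gwas, label = "functional") {
  scans <- if (is.data.frame(scan)) list(scan) else scan
  if (!length(scans) || !all(vapply(scans, is.data.frame, logical(1))))
    stop("scan must be a data.frame or list of data.frames", call. = FALSE)
  snps <- unique(unlist(lapply(scans, function(s) s$top_snp[s$passed])))
  if (!length(snps))
    return(prs_model(character(), character(), character(), numeric(), label))
  idx <- match(snps, gwas$SNP)
  if (anyNA(idx))
    stop("passing variants missing from GWAS summary: ",
         paste(snps[is.na(idx)], collapse = ", "), call. = FALSE)
  prs_model(snps, gwas$A1[idx], gwas$A2[idx], gwas$b[idx], label)
}

#' Union of two PRS models
#'
#' Shared variants must carry identical weights (same weight source); the
#' result keeps `a`'s entries followed by `b`'s entries not already present.
#'
#' @param a,b `prs_model` objects.
#' @param label Model name for the union.
#' @return A `prs_model` with `|a| + |b| - |a intersect b|` entries.
#' @export
combine_models <- function(a, b, label = "combined") {
  stopifnot(inherits(a, "prs_model"), inherits(b, "prs_model"))
  shared <- intersect(a$snp, b$snp)
  if (length(shared)) {
    ia <- match(shared, a$snp); ib <- match(shared, b$snp)
    wa <- a$weight[ia]; wb <- b$weight[ib]
    # align orientation before comparing weights
    flip <- a$effect_allele[ia] != b$effect_allele[ib]
    wb[flip] <- -wb[flip]
    bad <- abs(wa - wb) > 1e-12
    if (any(bad))
      stop("conflicting weights for shared variants: ",
           paste(shared[bad], collapse = ", "), call. = FALSE)
  }
  extra <- b[!b$snp %in% shared, , drop = FALSE]
  out <- rbind(as.data.frame(a), as.data.frame(extra))
  prs_model(out$snp, out$effect_allele, out$other_allele, out$weight, label)
}

# r^2 matrix between model variants computed from panel dosages
.panel_r2 <- function(panel, snps) {
  X <- panel$dosages[, snps, drop = FALSE]
  stats::cor(X)^2
}

#' Greedily prune a PRS model by LD
#'
#' Scans variants in genomic order (chromosome, then position); a variant is
#' dropped when its squared correlation with any already-retained variant
#' exceeds `r2_threshold`. Deterministic; the earlier variant in genomic
#' order is always the one kept.
#'
#' @param model A `prs_model` whose variants are all in the panel.
#' @param panel A `ref_panel` supplying dosage correlations.
#' @param r2_threshold Retained pairs must have r^2 <= this value
#'   (default 0.9).
#' @return The pruned `prs_model` (a subset of the input).
#' @export
ld_prune <- function(model, panel, r2_threshold = 0.9) {
  stopifnot(inherits(model, "prs_model"), inherits(panel, "ref_panel"))
  if (!nrow(model)) return(model)
  idx <- match(model$snp, panel$variants$id)
  if (anyNA(idx))
    stop("model variants absent from panel: ",
         paste(model$snp[is.na(idx)], collapse = ", "), call. = FALSE)
  ord <- order(panel$variants$chrom[idx], panel$variants$pos[idx])
  snps <- model$snp[ord]
  r2 <- .panel_r2(panel, snps)
  keep <- logical(length(snps))
  for (i in seq_along(snps)) {
    keep[i] <- !any(r2[i, keep] > r2_threshold)
  }
  kept <- snps[keep]
  out <- model[model$snp %in% kept, , drop = FALSE]
  out <- out[order(match(out$snp, kept)), , drop = FALSE]
  prs_model(out$snp, out$effect_allele, out$other_allele, out$weight,
            attr(model, "label"))
}

# Align a model's entries onto a cohort's dosage columns.
# Returns oriented (effect-allele) dosage matrix with missing entries
# imputed at 2*EAF, the weight vector, and bookkeeping counts.
.align_model_to_cohort <- function(model, cohort) {
  hit <- model$snp %in% colnames(cohort$dosages)
  n_skipped <- sum(!hit)
  mod <- model[hit, , drop = FALSE]
  if (!nrow(mod)) stop("no model variants present in the cohort", call. = FALSE)
  X <- cohort$dosages[, mod$snp, drop = FALSE]
  cv <- cohort$variants[match(mod$snp, cohort$variants$id), ]
  same <- mod$effect_allele == cv$effect_allele & mod$other_allele == cv$other_allele
  swapped <- mod$effect_allele == cv$other_allele & mod$other_allele == cv$effect_allele
  drop <- !(same | swapped)
  if (any(drop)) {
    warning(sum(drop), " variant(s) dropped: alleles irreconcilable with cohort")
    mod <- mod[!drop, , drop = FALSE]
    X <- X[, !drop, drop = FALSE]
    swapped <- swapped[!drop]
  }
  if (!nrow(mod)) stop("no model variants present in the cohort", call. = FALSE)
  X[, swapped] <- 2 - X[, swapped, drop = FALSE]
  # mean imputation = 2 * effect-allele frequency in this cohort
  if (anyNA(X)) {
    cm <- colMeans(X, na.rm = TRUE)
    for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- cm[j]
  }
  list(X = X, w = mod$weight, snps = mod$snp, n_skipped = n_skipped)
}

#' Score a cohort with a PRS model (scoresum semantics)
#'
#' Computes \eqn{\sum_k \beta_k x_k} per individual over the model variants
#' present in the cohort. Effect alleles are reconciled against the cohort's
#' allele coding (dosage flipped to `2 - x` where the model's effect allele
#' is the cohort's other allele); missing dosages are imputed at twice the
#' cohort effect-allele frequency; model variants absent from the cohort are
#' skipped and counted.
#'
#' @param model A `prs_model`.
#' @param cohort A `cohort_data`.
#' @return A `score_set` data.frame (`id`, `score`, `label`) with
#'   attributes `model_label`, `n_variants_used`, `n_variants_skipped`.
#' @export
score_cohort <- function(model, cohort) {
  stopifnot(inherits(model, "prs_model"), inherits(cohort, "cohort_data"))
  al <- .align_model_to_cohort(model, cohort)
  score <- as.numeric(al$X %*% al$w)
  out <- data.frame(id = rownames(cohort$dosages), score = score,
                    label = cohort$labels, stringsAsFactors = FALSE)
  attr(out, "model_label") <- attr(model, "label")
  attr(out, "n_variants_used") <- length(al$w)
  attr(out, "n_variants_skipped") <- al$n_skipped
  class(out) <- c("score_set", "data.frame")
  out
}

#' Read / write plink-style weight files
#'
#' Tab-delimited `snp effect_allele other_allele weight`; the plink
#' `--score` three-column layout (`snp effect_allele weight`) is accepted on
#' read, with the other allele recorded as `NA`.
#'
#' @param path File path.
#' @param label Model name attached on read.
#' @return `read_prs_model` returns a `prs_model`.
#' @export
read_prs_model <- function(path, label = basename(path)) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(d) == 3L) {
    names(d) <- c("snp", "effect_allele", "weight")
    d$other_allele <- NA_character_
  }
  prs_model(d$snp, d$effect_allele, d$other_allele, d$weight, label)
}

#' @rdname read_prs_model
#' @param model A `prs_model` to write.
#' @export
write_prs_model <- function(model, path) {
  stopifnot(inherits(model, "prs_model"))
  utils::write.table(as.data.frame(model), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
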