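#' Read / write GWAS summary statistics (COJO ".ma" dialect)
#'
#' Tab-delimited with header `SNP A1 A2 freq b se p n`.
#'
#' @param path File path.
#' @return `read_gwas_ma` returns a `gwas_summary` data.frame.
#' @export
read_gwas_ma <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("SNP", "A1", "A2", "freq", "b", "se", "p", "n")
  if (!all(need %in% names(d)))
    stop("GWAS summary file must have columns: ", paste(need, collapse = " "),
         call. = FALSE)
  d <- d[need]
  class(d) <- c("gwas_summary", "data.frame")
  d
}

#' @rdname read_gwas_ma
#' @param gwas A `gwas_summary` to write.
#' @export
write_gwas_ma <- function(gwas, path) {
  utils::write.table(as.data.frame(gwas), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write molecular-QTL summary statistics
#'
#' Tab-delimited with header
#' `probe probe_chr probe_bp gene snp snp_chr snp_bp a1 a2 freq b se p`
#' (the flat "query" layout of SMR tooling).
#'
#' @param path File path.
#' @return `read_qtl_tsv` returns a `qtl_dataset` data.frame.
#' @export
read_qtl_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(probe_chr = "character",
                                        snp_chr = "character"))
  need <- c("probe", "probe_chr", "probe_bp", "gene", "snp", "snp_chr",
            "snp_bp", "a1", "a2", "freq", "b", "se", "p")
  if (!all(need %in% names(d)))
    stop("QTL summary file must have columns: ", paste(need, collapse = " "),
         call. = FALSE)
  d <- d[need]
  class(d) <- c("qtl_dataset", "data.frame")
  d
}

#' @rdname read_qtl_tsv
#' @param qtl A `qtl_dataset` to write.
#' @export
write_qtl_tsv <- function(qtl, path) {
  utils::write.table(as.data.frame(qtl), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write genotype dosages as a tab-delimited matrix
#'
#' Variants as rows: `snp chrom pos effect_allele other_allele` followed by
#' one column per individual holding the effect-allele dosage (missing as
#' `NA`). Cohort labels, if present, go to a sibling two-column file.
#'
#' @param x A `ref_panel` or `cohort_data`.
#' @param path Output path for the dosage matrix.
#' @param labels_path Optional path for `id<TAB>label` outcome labels
#'   (cohorts only).
#' @export
write_dosage_tsv <- function(x, path, labels_path = NULL) {
  if (inherits(x, "ref_panel")) {
    dos <- x$dosages; v <- x$variants
  } else if (inherits(x, "cohort_data")) {
    dos <- x$dosages; v <- x$variants
  } else stop("x must be a ref_panel or cohort_data", call. = FALSE)
  ids <- rownames(dos)
  if (is.null(ids)) ids <- sprintf("ind_%05d", seq_len(nrow(dos)))
  out <- data.frame(snp = v$id, chrom = v$chrom, pos = v$pos,
                    effect_allele = v$effect_allele,
                    other_allele = v$other_allele,
                    t(dos), check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out)[-(1:5)] <- ids
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path) && inherits(x, "cohort_data")) {
    utils::write.table(data.frame(id = ids, label = x$labels), labels_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a genotype dosage matrix (TSV or VCF) as a cohort
#'
#' Dosage TSVs are the layout written by [write_dosage_tsv()]. VCFs are read
#' through `vcfR`: the `DS` FORMAT field is used when present, otherwise
#' dosages are derived from `GT` allele counts (ALT allele = effect allele).
#'
#' @param path Dosage TSV or VCF (`.vcf` / `.vcf.gz`) path.
#' @param labels Optional 0/1 outcome vector, or path to an
#'   `id<TAB>label` file; when absent all labels are set to 0.
#' @param design Study design label for the resulting cohort.
#' @return A `cohort_data`.
#' @export
read_cohort <- function(path, labels = NULL,
                        design = c("case_control", "prospective")) {
  design <- match.arg(design)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    parsed <- .read_vcf_dosages(path)
  } else {
    d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
    v <- data.frame(chrom = d$chrom, pos = d$pos, id = d$snp,
                    effect_allele = d$effect_allele,
                    other_allele = d$other_allele, stringsAsFactors = FALSE)
    dos <- t(as.matrix(d[, -(1:5), drop = FALSE]))
    colnames(dos) <- v$id
    parsed <- list(variants = v, dosages = dos)
  }
  lab <- rep(0L, nrow(parsed$dosages))
  if (!is.null(labels)) {
    if (is.character(labels) && length(labels) == 1L) {
      lf <- utils::read.delim(labels, stringsAsFactors = FALSE)
      lab <- lf$label[match(rownames(parsed$dosages), lf$id)]
    } else lab <- as.integer(labels)
  }
  structure(list(dosages = parsed$dosages, labels = lab, design = design,
                 eaf = colMeans(parsed$dosages, na.rm = TRUE) / 2,
                 variants = parsed$variants),
            class = "cohort_data")
}

.read_vcf_dosages <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(vcf)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  v <- data.frame(chrom = fx[, "CHROM"], pos = as.integer(fx[, "POS"]),
                  id = fx[, "ID"], effect_allele = fx[, "ALT"],
                  other_allele = fx[, "REF"], stringsAsFactors = FALSE)
  fmt <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":")))
  if ("DS" %in% fmt) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ds <- apply(gt, 2, function(g) {
      vapply(strsplit(g, "[/|]"), function(a)
        if (anyNA(a) || any(a == ".")) NA_real_ else sum(a != "0"), numeric(1))
    })
  }
  if (!is.matrix(ds)) ds <- matrix(ds, nrow = nrow(v))
  dos <- t(ds)
  colnames(dos) <- v$id
  if (is.null(rownames(dos))) rownames(dos) <- colnames(vcf@gt)[-1]
  list(variants = v, dosages = dos)
}

#' Write per-individual scores
#'
#' Tab-delimited `id score n_variants_used label`.
#'
#' @param scores A `score_set`.
#' @param path Output path.
#' @export
write_scores_tsv <- function(scores, path) {
  stopifnot(inherits(scores, "score_set"))
  out <- data.frame(id = scores$id, score = scores$score,
                    n_variants_used = attr(scores, "n_variants_used"),
                    label = scores$label)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write SMR scan results
#'
#' Tab-delimited `probe gene top_snp b_smr se_smr p_smr p_heidi
#' n_heidi_snps passed`.
#'
#' @param scan An `smr_scan`.
#' @param path Output path.
#' @export
write_smr_scan <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
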