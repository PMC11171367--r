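#' Configuration for an end-to-end pipeline run
#'
#' Collects every tunable of the simulate -> SMR -> build-PRS -> score ->
#' evaluate -> subsample pipeline. By default the pipeline simulates its
#' inputs (a desk-scale emulation of a breast-cancer-style analysis:
#' a large case-control GWAS, eQTL and mQTL summary sets, and case-control
#' plus prospective scoring cohorts); alternatively, file paths for
#' pre-existing inputs can be supplied.
#'
#' @param out_dir Output directory (created; must not exist unless
#'   `overwrite = TRUE`).
#' @param seed Master seed; every stage derives its stream from it.
#' @param smr_p_threshold,heidi_p_threshold SMR and HEIDI filters
#'   (defaults 5e-8 and 0.05).
#' @param prune_r2 LD-pruning threshold for the pruned functional score
#'   (default 0.9).
#' @param gwas_clump_r2 LD threshold used when building the GWAS PRS from
#'   the summary statistics (default 0.2).
#' @param gwas_model_p GWAS significance filter for the GWAS PRS
#'   (default 5e-8).
#' @param centile High-risk centile (default 80).
#' @param heidi A [heidi_config()].
#' @param sim List of simulation sizes (see [simulate_study()]).
#' @param subsample_iterations Iterations for the variant-subsampling stage.
#' @param gwas_path,eqtl_path,mqtl_path,panel_path,cohort_path,labels_path
#'   Optional paths to pre-existing inputs; when all are given, simulation
#'   is skipped.
#' @param overwrite Allow writing into an existing directory.
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L,
                       smr_p_threshold = 5e-8, heidi_p_threshold = 0.05,
                       prune_r2 = 0.9, gwas_clump_r2 = 0.2,
                       gwas_model_p = 5e-8, centile = 80,
                       heidi = heidi_config(), sim = list(),
                       subsample_iterations = 100L,
                       gwas_path = NULL, eqtl_path = NULL, mqtl_path = NULL,
                       panel_path = NULL, cohort_path = NULL,
                       labels_path = NULL, overwrite = FALSE) {
  if (smr_p_threshold <= 0 || smr_p_threshold >= 1 ||
      heidi_p_threshold <= 0 || heidi_p_threshold >= 1)
    stop("p-value thresholds must lie in (0, 1)", call. = FALSE)
  if (prune_r2 <= 0 || prune_r2 > 1 || gwas_clump_r2 <= 0 || gwas_clump_r2 > 1)
    stop("r2 thresholds must lie in (0, 1]", call. = FALSE)
  if (centile <= 0 || centile >= 100) stop("centile must be in (0, 100)", call. = FALSE)
  stopifnot(inherits(heidi, "heidi_config"))
  paths <- list(gwas = gwas_path, eqtl = eqtl_path, mqtl = mqtl_path,
                panel = panel_path, cohort = cohort_path, labels = labels_path)
  given <- !vapply(paths, is.null, logical(1))
  if (any(given) && !all(given[c("gwas", "eqtl", "mqtl", "panel", "cohort")]))
    stop("either provide gwas/eqtl/mqtl/panel/cohort paths together, or none",
         call. = FALSE)
  for (p in paths[given]) if (!file.exists(p))
    stop("input file does not exist: ", p, call. = FALSE)
  sim_defaults <- list(n_blocks = 12L, block_size = 25L,
                       within_block_corr = 0.55, maf_range = c(0.1, 0.5),
                       n_panel = 1000L, n_qtl_eqtl = 2000L, n_qtl_mqtl = 1200L,
                       n_gwas_cases = 8000L, n_gwas_controls = 8000L,
                       n_cohort_cases = 1780L, n_cohort_controls = 1690L,
                       missing_rate = 0.01,
                       modes_eqtl = c("pleiotropy", "pleiotropy", "pleiotropy",
                                      "linkage", "null", "null"),
                       modes_mqtl = c("pleiotropy", "pleiotropy", "pleiotropy",
                                      "linkage", "null", "null"))
  sim <- utils::modifyList(sim_defaults, sim)
  if (sim$n_blocks < length(sim$modes_eqtl) + length(sim$modes_mqtl))
    stop("sim$n_blocks must cover one block per probe", call. = FALSE)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 smr_p_threshold = smr_p_threshold,
                 heidi_p_threshold = heidi_p_threshold,
                 prune_r2 = prune_r2, gwas_clump_r2 = gwas_clump_r2,
                 gwas_model_p = gwas_model_p, centile = centile,
                 heidi = heidi, sim = sim,
                 subsample_iterations = as.integer(subsample_iterations),
                 paths = paths, simulate = !all(given),
                 overwrite = isTRUE(overwrite)),
            class = "run_config")
}

# deterministic substream seeds below 2^31
.spawn_seeds <- function(master, n) {
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max, n)
}

#' Simulate a complete desk-scale study
#'
#' Builds one LD-structured panel in which each block hosts one molecular
#' probe, assigns architectures (pleiotropy, linkage, null) across blocks,
#' and generates: eQTL and mQTL summary sets, a case-control GWAS over all
#' variants with every architecture contributing to liability, and a
#' case-control scoring cohort whose outcome is driven by the true disease
#' effects (pleiotropy-mediated effects plus direct linkage effects).
#'
#' @param seed Master seed.
#' @param sim Simulation sizes as in [run_config()].
#' @param modes_eqtl,modes_mqtl Architecture modes per probe (recycled over
#'   blocks); defaults mix strong pleiotropy, linkage, and null probes.
#' @return A list with `panel`, `eqtl`, `mqtl`, `gwas`, `cohort`,
#'   `true_model` (the generative disease weights), and `archs`.
#' @export
simulate_study <- function(seed = 1L, sim = list(),
                           modes_eqtl = NULL, modes_mqtl = NULL) {
  if (!is.null(modes_eqtl)) sim$modes_eqtl <- modes_eqtl
  if (!is.null(modes_mqtl)) sim$modes_mqtl <- modes_mqtl
  cfg <- run_config(out_dir = tempfile(), seed = seed, sim = sim)$sim
  modes_eqtl <- cfg$modes_eqtl
  modes_mqtl <- cfg$modes_mqtl
  n_probes <- length(modes_eqtl) + length(modes_mqtl)
  if (cfg$n_blocks < n_probes)
    stop("need at least one block per probe", call. = FALSE)
  seeds <- .spawn_seeds(seed, 6 + n_probes)
  spec <- ld_block_spec(cfg$n_blocks, cfg$block_size, cfg$within_block_corr,
                        cfg$maf_range)
  panel <- make_reference_panel(spec, cfg$n_panel, seed = seeds[1])
  v <- panel$variants
  mid <- ceiling(cfg$block_size / 2)
  probe_modes <- c(modes_eqtl, modes_mqtl)
  archs <- vector("list", n_probes)
  set.seed(seeds[2])
  for (k in seq_len(n_probes)) {
    blk <- which(panel$block == k)
    causal <- v$id[blk[mid]]
    mode <- probe_modes[k]
    if (mode == "pleiotropy") {
      archs[[k]] <- architecture_spec("pleiotropy", causal_variant_id = causal,
                                      b_zx = 0.6, b_xy = 0.4)
    } else if (mode == "linkage") {
      direct <- v$id[blk[mid + 2L]]
      archs[[k]] <- architecture_spec("linkage", causal_variant_id = causal,
                                      b_zx = 0.6, b_zy_direct = 0.25,
                                      direct_variant_id = direct)
    } else {
      archs[[k]] <- architecture_spec("null", causal_variant_id = causal)
    }
  }
  is_eqtl <- seq_len(n_probes) <= length(modes_eqtl)
  qtl_list <- vector("list", n_probes)
  for (k in seq_len(n_probes)) {
    meta <- list(probe = sprintf("%s_probe_%02d",
                                 if (is_eqtl[k]) "expr" else "meth", k),
                 gene = sprintf("GENE%02d", k))
    qtl_list[[k]] <- make_qtl_study(
      panel, archs[[k]],
      n_study = if (is_eqtl[k]) cfg$n_qtl_eqtl else cfg$n_qtl_mqtl,
      probe_meta = meta, seed = seeds[6 + k])
  }
  bind_qtl <- function(lst) {
    out <- do.call(rbind, lapply(lst, as.data.frame))
    class(out) <- c("qtl_dataset", "data.frame")
    out
  }
  eqtl <- bind_qtl(qtl_list[is_eqtl])
  mqtl <- bind_qtl(qtl_list[!is_eqtl])
  gwas <- make_gwas_study(panel, archs, cfg$n_gwas_cases, cfg$n_gwas_controls,
                          seed = seeds[3])
  beta <- attr(gwas, "truth")$beta
  nz <- which(beta != 0)
  true_model <- prs_model(names(beta)[nz],
                          v$effect_allele[match(names(beta)[nz], v$id)],
                          v$other_allele[match(names(beta)[nz], v$id)],
                          beta[nz], label = "true")
  cohort <- make_cohort(panel, true_model, design = "case_control",
                        n_cases = cfg$n_cohort_cases,
                        n_noncases = cfg$n_cohort_controls,
                        missing_rate = cfg$missing_rate, seed = seeds[4])
  list(panel = panel, eqtl = eqtl, mqtl = mqtl, gwas = gwas,
       cohort = cohort, true_model = true_model, archs = archs)
}

#' Build a GWAS PRS from summary statistics
#'
#' Emulates the construction of an established GWAS score: keep variants
#' significant at `p_threshold`, LD-clump greedily in genomic order at
#' `clump_r2`, and weight by the GWAS log-odds effect.
#'
#' @param gwas A `gwas_summary`.
#' @param panel A `ref_panel` for clumping LD.
#' @param p_threshold Significance filter (default 5e-8).
#' @param clump_r2 Clumping threshold (default 0.2).
#' @param label Model name.
#' @return A `prs_model`.
#' @export
build_gwas_model <- function(gwas, panel, p_threshold = 5e-8, clump_r2 = 0.2,
                             label = "gwas") {
  sig <- gwas[is.finite(gwas$se) & gwas$p < p_threshold, , drop = FALSE]
  sig <- sig[order(sig$p), , drop = FALSE]
  if (!nrow(sig))
    return(prs_model(character(), character(), character(), numeric(), label))
  model <- prs_model(sig$SNP, sig$A1, sig$A2, sig$b, label)
  ld_prune(model, panel, r2_threshold = clump_r2)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

.report_as_list <- function(r) {
  r[c("model", "n_variants_used", "auc", "or_per_sd", "youden", "binary",
      "n_cases", "n_controls")]
}

#' Run the full pipeline
#'
#' Executes simulate -> SMR scans (eQTL and mQTL) -> PRS construction
#' (functional, GWAS, combined, LD-pruned functional) -> cohort scoring ->
#' evaluation (per-score reports, joint model, high-risk overlap) ->
#' variant subsampling -> weight-sensitivity comparison, writing every
#' artifact plus a provenance record (config, seed, stage attrition counts,
#' and an md5 content hash per file) into `cfg$out_dir`. Reruns with an
#' identical config are bit-identical; no timestamps enter any artifact.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the run directory, provenance, and the
#'   in-memory results.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$out_dir
  if (dir.exists(out) && !cfg$overwrite && length(list.files(out)))
    stop("output directory exists and is non-empty: ", out, call. = FALSE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(paste("FAILED at stage:", name), conditionMessage(e)),
                 file.path(out, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  seeds <- .spawn_seeds(cfg$seed, 4)

  ## stage: inputs ------------------------------------------------------
  inputs <- stage("simulate", {
    if (cfg$simulate) {
      s <- simulate_study(seed = seeds[1], sim = cfg$sim)
      say("simulate: %d variants, GWAS %d+%d, cohort %d+%d",
          nrow(s$panel$variants), cfg$sim$n_gwas_cases,
          cfg$sim$n_gwas_controls, cfg$sim$n_cohort_cases,
          cfg$sim$n_cohort_controls)
      write_gwas_ma(s$gwas, file.path(out, "gwas.ma.tsv"))
      write_qtl_tsv(s$eqtl, file.path(out, "eqtl.tsv"))
      write_qtl_tsv(s$mqtl, file.path(out, "mqtl.tsv"))
      write_dosage_tsv(s$cohort, file.path(out, "cohort.dosage.tsv"),
                       file.path(out, "cohort.labels.tsv"))
      s
    } else {
      pc <- read_cohort(cfg$paths$panel)
      list(gwas = read_gwas_ma(cfg$paths$gwas),
           eqtl = read_qtl_tsv(cfg$paths$eqtl),
           mqtl = read_qtl_tsv(cfg$paths$mqtl),
           panel = as_ref_panel(pc$variants, pc$dosages),
           cohort = read_cohort(cfg$paths$cohort, cfg$paths$labels))
    }
  })

  ## stage: smr ---------------------------------------------------------
  scans <- stage("smr", {
    sc_e <- run_smr_scan(inputs$gwas, inputs$eqtl, inputs$panel,
                         cfg$smr_p_threshold, cfg$heidi_p_threshold,
                         cfg$heidi)
    sc_m <- run_smr_scan(inputs$gwas, inputs$mqtl, inputs$panel,
                         cfg$smr_p_threshold, cfg$heidi_p_threshold,
                         cfg$heidi)
    write_smr_scan(sc_e, file.path(out, "smr_eqtl.tsv"))
    write_smr_scan(sc_m, file.path(out, "smr_mqtl.tsv"))
    raw <- sum(sc_e$passed) + sum(sc_m$passed)
    uniq <- length(unique(c(sc_e$top_snp[sc_e$passed],
                            sc_m$top_snp[sc_m$passed])))
    say("smr: eQTL %d/%d probes passed, mQTL %d/%d; passing variants raw %d, unique %d",
        sum(sc_e$passed), nrow(sc_e), sum(sc_m$passed), nrow(sc_m), raw, uniq)
    list(eqtl = sc_e, mqtl = sc_m)
  })

  ## stage: build-prs ---------------------------------------------------
  models <- stage("build-prs", {
    functional <- build_functional_model(list(scans$eqtl, scans$mqtl),
                                         inputs$gwas, label = "functional")
    gwas_model <- build_gwas_model(inputs$gwas, inputs$panel,
                                   cfg$gwas_model_p, cfg$gwas_clump_r2)
    combined <- combine_models(gwas_model, functional, label = "combined")
    pruned <- .relabel(ld_prune(functional, inputs$panel, cfg$prune_r2),
                       "functional_pruned")
    for (m in list(functional, gwas_model, combined, pruned))
      write_prs_model(m, file.path(out, paste0("model_", attr(m, "label"), ".tsv")))
    say("build-prs: functional %d, gwas %d, combined %d, pruned %d variants",
        nrow(functional), nrow(gwas_model), nrow(combined), nrow(pruned))
    list(functional = functional, gwas = gwas_model, combined = combined,
         pruned = pruned)
  })

  ## stage: score + evaluate -------------------------------------------
  evals <- stage("evaluate", {
    usable <- Filter(function(m) nrow(m) > 0, models)
    score_sets <- lapply(usable, score_cohort, cohort = inputs$cohort)
    for (nm in names(score_sets))
      write_scores_tsv(score_sets[[nm]], file.path(out, paste0("scores_", nm, ".tsv")))
    reports <- lapply(score_sets, eval_report, centile = cfg$centile)
    extra <- list()
    if (all(c("functional", "gwas") %in% names(score_sets))) {
      extra$joint_auc <- joint_model_auc(score_sets$gwas, score_sets$functional)
      ov <- overlap_analysis(score_sets$gwas, score_sets$functional, cfg$centile)
      extra$overlap <- list(cases = as.list(ov$cases),
                            controls = as.list(ov$controls),
                            centile = ov$centile)
    }
    .write_json(c(lapply(reports, .report_as_list), extra),
                file.path(out, "evaluation.json"))
    for (nm in names(reports))
      say("evaluate: %s AUC %.3f [%.3f, %.3f]", nm, reports[[nm]]$auc$auc,
          reports[[nm]]$auc$ci_lower, reports[[nm]]$auc$ci_upper)
    list(scores = score_sets, reports = reports, extra = extra)
  })

  ## stage: subsample ---------------------------------------------------
  subs <- stage("subsample", {
    big <- models$gwas; small <- models$functional
    if (nrow(big) >= 2 && nrow(small) >= 1 && nrow(big) > nrow(small)) {
      ss <- subsample_auc(big, inputs$cohort, i = max(1L, nrow(small)),
                          iterations = cfg$subsample_iterations,
                          seed = seeds[2])
      .write_json(list(i = ss$i, iterations = ss$iterations,
                       median = ss$median, iqr = ss$iqr, range = ss$range,
                       auc_values = ss$auc_values),
                  file.path(out, "subsample.json"))
      say("subsample: i=%d median AUC %.3f (IQR %.3f-%.3f)", ss$i, ss$median,
          ss$iqr[1], ss$iqr[2])
      ss
    } else {
      say("subsample: skipped (model sizes %d vs %d)", nrow(big), nrow(small))
      NULL
    }
  })

  ## stage: compare-weights --------------------------------------------
  cmp <- stage("compare-weights", {
    if (nrow(models$gwas) >= 2) {
      set.seed(seeds[3])
      alt <- models$gwas
      alt$weight <- alt$weight +
        stats::rnorm(nrow(alt), 0, 0.05 * stats::sd(alt$weight))
      alt <- prs_model(alt$snp, alt$effect_allele, alt$other_allele,
                       alt$weight, label = "gwas_altweights")
      write_prs_model(alt, file.path(out, "model_gwas_altweights.tsv"))
      cw <- compare_weightings(models$gwas, alt, inputs$cohort,
                               centile = cfg$centile)
      .write_json(list(
        auc_original = cw$report_a$auc, auc_alt = cw$report_b$auc,
        overlap = list(cases = as.list(cw$overlap$cases),
                       controls = as.list(cw$overlap$controls)),
        discordant_cases = cw$discordant_cases,
        discordant_controls = cw$discordant_controls),
        file.path(out, "compare_weights.json"))
      say("compare-weights: AUC %.3f vs %.3f, discordant controls %.3f",
          cw$report_a$auc$auc, cw$report_b$auc$auc, cw$discordant_controls)
      cw
    } else NULL
  })

  ## provenance ---------------------------------------------------------
  writeLines(log_lines, file.path(out, "run.log"))
  cfg_json <- file.path(out, "config.json")
  # out_dir is machine-specific and excluded so identical analyses hash
  # identically regardless of where they were written
  cfg_list <- cfg[setdiff(names(cfg), c("heidi", "out_dir"))]
  cfg_list$heidi <- unclass(cfg$heidi)
  .write_json(cfg_list, cfg_json)
  files <- setdiff(list.files(out), "provenance.json")
  hashes <- as.list(tools::md5sum(file.path(out, files)))
  names(hashes) <- files
  prov <- list(config_hash = unname(tools::md5sum(cfg_json)),
               seed = cfg$seed, files = hashes)
  .write_json(prov, file.path(out, "provenance.json"))
  invisible(list(dir = out, provenance = prov, inputs = inputs,
                 scans = scans, models = models, evals = evals,
                 subsample = subs, compare = cmp))
}

#' Compare two weightings of the same variant set
#'
#' Scores the cohort under the original and alternative weights for an
#' identical variant list, and reports both evaluation reports, the
#' high-risk overlap, and the fraction of individuals whose high-risk flag
#' differs between the two weightings — the "same variants, different
#' weights" sensitivity analysis.
#'
#' @param model_variants A `prs_model` (original weights).
#' @param alt_weights A `prs_model` over exactly the same variant ids.
#' @param cohort A `cohort_data`.
#' @param centile Centile for the high-risk rule.
#' @return List with `report_a`, `report_b`, `overlap`,
#'   `discordant_cases`, `discordant_controls`.
#' @export
compare_weightings <- function(model_variants, alt_weights, cohort,
                               centile = 80) {
  stopifnot(inherits(model_variants, "prs_model"),
            inherits(alt_weights, "prs_model"))
  d1 <- setdiff(model_variants$snp, alt_weights$snp)
  d2 <- setdiff(alt_weights$snp, model_variants$snp)
  if (length(d1) || length(d2))
    stop("weight sets cover different variants; only in first: [",
         paste(d1, collapse = ", "), "], only in second: [",
         paste(d2, collapse = ", "), "]", call. = FALSE)
  sa <- score_cohort(model_variants, cohort)
  sb <- score_cohort(alt_weights, cohort)
  fa <- binary_high_risk(sa, centile)$high_risk
  fb <- binary_high_risk(sb, centile)$high_risk
  list(report_a = eval_report(sa, centile), report_b = eval_report(sb, centile),
       overlap = overlap_analysis(sa, sb, centile),
       discordant_cases = mean((fa != fb)[sa$label == 1]),
       discordant_controls = mean((fa != fb)[sa$label == 0]))
}

#' Score-distribution density plot by case status
#'
#' Optional ggplot2 figure comparing the score distributions of cases and
#' controls for one or more score sets.
#'
#' @param ... Named `score_set` objects.
#' @return A ggplot object.
#' @export
plot_score_density <- function(...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  sets <- list(...)
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- paste0("score", seq_along(sets))
  d <- do.call(rbind, lapply(names(sets), function(nm) {
    data.frame(model = nm, score = sets[[nm]]$score,
               status = factor(sets[[nm]]$label, c(0, 1),
                               c("control", "case")))
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = score, fill = status)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::facet_wrap(~model, scales = "free") +
    ggplot2::theme_minimal()
}
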