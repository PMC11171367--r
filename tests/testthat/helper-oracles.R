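# Independent oracles used across test files.

# Exhaustive Mann-Whitney AUC: enumerate every case/control pair,
# ties count one half.
auc_pair_count <- function(score, label) {
  cs <- score[label == 1]; ks <- score[label == 0]
  tot <- 0
  for (c_ in cs) tot <- tot + sum(c_ > ks) + 0.5 * sum(c_ == ks)
  tot / (length(cs) * length(ks))
}

# One simulated probe: QTL study + case-control GWAS on a fixed panel,
# scanned with SMR/HEIDI. Used for calibration and recovery experiments.
scan_one_probe <- function(panel, arch, seed, n_qtl = 1500,
                           n_cases = 2500, n_controls = 2500) {
  q <- make_qtl_study(panel, arch, n_qtl,
                      list(probe = "pr", gene = "G"), seed = seed)
  g <- make_gwas_study(panel, arch, n_cases, n_controls, seed = seed + 1L)
  run_smr_scan(g, q, panel)
}

# Shared mid-LD single-block panel for probe-level experiments.
calib_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- ld_block_spec(1, 25, 0.55, c(0.1, 0.5))
      cache <<- make_reference_panel(spec, 1000, seed = 100)
    }
    cache
  }
})

# Probe-level replicate experiments on the shared panel, memoized because
# both the calibration and the parameter-recovery checks consume them.
probe_replicates <- local({
  cache <- list()
  function(mode, n_reps) {
    key <- paste0(mode, "_", n_reps)
    if (!is.null(cache[[key]])) return(cache[[key]])
    panel <- calib_panel()
    v <- panel$variants$id
    arch <- if (mode == "pleiotropy") {
      architecture_spec("pleiotropy", causal_variant_id = v[13],
                        b_zx = 0.6, b_xy = 0.4)
    } else {
      architecture_spec("linkage", causal_variant_id = v[13], b_zx = 0.6,
                        b_zy_direct = 0.25, direct_variant_id = v[15])
    }
    set.seed(20240901)
    seeds <- sample.int(1e8, n_reps)
    out <- do.call(rbind, lapply(seeds, function(s) {
      sc <- scan_one_probe(panel, arch, seed = s)
      data.frame(p_heidi = sc$p_heidi[1], b_smr = sc$b_smr[1])
    }))
    cache[[key]] <<- out
    out
  }
})

# Minimal hand-built cohort for scoring arithmetic tests.
manual_cohort <- function(dosages, labels, variants) {
  rownames(dosages) <- sprintf("ind_%03d", seq_len(nrow(dosages)))
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages, labels = labels, design = "case_control",
                 eaf = colMeans(dosages, na.rm = TRUE) / 2,
                 variants = variants),
            class = "cohort_data")
}
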