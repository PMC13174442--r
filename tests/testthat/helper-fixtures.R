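# Shared fixtures: small generator configs and hand-built matrices.

small_config <- function(seed = 1L, ...) {
  args <- list(
    n_genes = 300L,
    mini_cohorts = data.frame(
      name = c("NS1", "RS1"),
      assay = c("nanostring", "rnaseq"),
      n_patients = c(12L, 12L), stringsAsFactors = FALSE),
    panel_size = 120L, n_planted_pfs_genes = 5L,
    n_planted_assay_genes = 4L, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(generator_config, args)
}

# deterministic tiny expression matrix
toy_expr <- function(values, unit = "raw_count", assay = "rnaseq",
                     genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  expr_mat(m, unit = unit, assay = assay)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_meta <- function(patients, cohort = "C1", assay = "rnaseq",
                     pfs = NULL) {
  do.call(rbind, lapply(c("pre", "post"), function(tp)
    data.frame(sample_id = paste0(patients, "_", tp),
               patient_id = patients, mini_cohort = cohort,
               assay = assay, timepoint = tp,
               pfs_months = pfs %||% rep(12, length(patients)),
               pfs_event = 1L, stringsAsFactors = FALSE)))
}

toy_fc <- function(values, genes = NULL, patients = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- patients %||% paste0("p", seq_len(ncol(m)))
  paired_l2fc(m, pseudocount = 1, unit = "CPM")
}
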