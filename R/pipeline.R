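#' Dichotomize progression-free survival into classes
#'
#' The modeling outcome is fixed at 12 months (the combined cohort's
#' median PFS): `"long"` for PFS > 12 months, `"short"` otherwise.
#'
#' @param meta sample metadata with `patient_id` and `pfs_months`.
#' @param threshold months (default 12).
#' @return named character vector per patient.
#' @export
pfs_class_labels <- function(meta, threshold = 12) {
  m <- meta[!duplicated(meta$patient_id), ]
  stats::setNames(ifelse(m$pfs_months > threshold, "long", "short"),
                  m$patient_id)
}

#' Pipeline configuration
#'
#' Exactly one of `generator` (a [generator_config()]) or `input_dir`
#' (a directory produced by [write_cohort()]) must be supplied.
#'
#' @param generator a [generator_config()], or NULL.
#' @param input_dir directory of expression/metadata files, or NULL.
#' @param outdir output directory.
#' @param seed master seed; every stochastic stage derives a sub-seed.
#' @param fs feature-selection settings: `B`, `top_m`, `max_features`.
#' @param lod detection-limit settings: `n_bins`, `loose_drop`,
#'   `strict_floor`, `filter` (apply LOD filter before ranking).
#' @param model model settings: `architectures`, `loocv` (run the
#'   leave-one-out scan for k; otherwise use all candidates).
#' @param stages character vector of stages to run, in pipeline order.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(generator = NULL, input_dir = NULL,
                            outdir = tempfile("crossfc_run_"),
                            seed = 1L,
                            fs = list(B = 200L, top_m = 50L,
                                      max_features = 25L),
                            lod = list(n_bins = 10L, loose_drop = 0.05,
                                       strict_floor = 0.7, filter = TRUE),
                            model = list(architectures = "lasso_logistic",
                                         loocv = TRUE),
                            stages = c("simulate", "harmonize", "select",
                                       "train", "validate", "network")) {
  if (is.null(generator) == is.null(input_dir))
    stop("exactly one of generator / input_dir must be given")
  structure(list(generator = generator, input_dir = input_dir,
                 outdir = outdir, seed = as.integer(seed), fs = fs,
                 lod = lod, model = model, stages = stages),
            class = "pipeline_config")
}

read_cohort_dir <- function(dir) {
  meta <- utils::read.delim(file.path(dir, "metadata.tsv"),
                            stringsAsFactors = FALSE)
  cohorts <- list()
  for (cn in unique(meta$mini_cohort)) {
    assay <- meta$assay[meta$mini_cohort == cn][1L]
    cohorts[[cn]] <- list(
      pre = read_expression(file.path(dir, paste0("expr_", cn, "_pre.tsv")),
                            unit = "raw_count", assay = assay),
      post = read_expression(file.path(dir, paste0("expr_", cn, "_post.tsv")),
                             unit = "raw_count", assay = assay))
  }
  list(cohorts = cohorts, meta = meta, truth = NULL, gene_model = NULL)
}

# CPM-normalize a measured cohort matrix (counts) or pass intensities
to_cpm <- function(m) {
  if (m$unit == "raw_count") normalize_expression(m, "CPM") else m
}

#' Run the full analysis pipeline
#'
#' Stages run in order simulate -> harmonize -> select -> train ->
#' validate -> network, each writing its outputs under
#' `cfg$outdir/<stage>/`; the returned manifest records every output file
#' with an md5 checksum, so a rerun with the same config and seed can be
#' verified bit-identical.  Any stage error aborts with the stage name;
#' the partial manifest is attached to the condition.
#'
#' @param cfg a [pipeline_config()].
#' @return manifest list: per-stage outputs, file checksums, seeds and
#'   package version.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed,
                   version = as.character(utils::packageVersion("crossfc")),
                   stages = list(), files = character(0))
  state <- new.env()
  add_files <- function(stage, paths) {
    sums <- tools::md5sum(paths)
    manifest$stages[[stage]] <<- list(outputs = unname(paths),
                                      checksums = unname(sums))
    manifest$files <<- c(manifest$files, sums)
  }
  run_stage <- function(stage, fun) {
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## simulate / ingest -------------------------------------------------
  run_stage("simulate", function() {
    if (!is.null(cfg$generator)) {
      state$sim <- generate_cohort(cfg$generator)
      d <- file.path(cfg$outdir, "simulate")
      paths <- write_cohort(state$sim, d)
    } else {
      state$sim <- read_cohort_dir(cfg$input_dir)
      paths <- file.path(cfg$input_dir, "metadata.tsv")
    }
    add_files("simulate", paths)
  })
  if (!"simulate" %in% cfg$stages && is.null(state$sim))
    stop("pipeline requires the simulate/ingest stage")
  sim <- state$sim
  meta <- sim$meta
  bulk <- names(sim$cohorts)[vapply(sim$cohorts, function(co)
    is.null(co$sc), logical(1))]
  labels <- pfs_class_labels(meta)

  # per-cohort paired log2FC on the CPM scale
  fc_by_cohort <- lapply(sim$cohorts[bulk], function(co) {
    compute_log2fc(to_cpm(co$pre), to_cpm(co$post),
                   meta[meta$sample_id %in% c(sample_ids(co$pre),
                                              sample_ids(co$post)), ])
  })
  panel_genes <- Reduce(intersect, lapply(fc_by_cohort, rownames))
  fc_all <- do.call(cbind, lapply(fc_by_cohort, function(fc)
    unclass(fc)[panel_genes, , drop = FALSE]))
  fc_all <- paired_l2fc(fc_all, pseudocount = 1, unit = "CPM")
  state$fc_by_cohort <- fc_by_cohort
  state$fc_all <- fc_all

  ## harmonize ----------------------------------------------------------
  if ("harmonize" %in% cfg$stages) run_stage("harmonize", function() {
    d <- file.path(cfg$outdir, "harmonize")
    dir.create(d, showWarnings = FALSE)
    paths <- character(0)
    # dynamic-range diagnostics across assays
    assay_of <- vapply(bulk, function(cn)
      meta$assay[meta$mini_cohort == cn][1L], character(1))
    fc_by_assay <- lapply(split(bulk, assay_of), function(cns)
      abs(unlist(lapply(state$fc_by_cohort[cns], as.numeric))))
    if (length(fc_by_assay) >= 2L) {
      drt <- dynamic_range_test(fc_by_assay)
      p <- file.path(d, "dynamic_range.tsv")
      utils::write.table(drt, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- c(paths, p)
    }
    # PCA overlap of cohorts in log2FC space
    po <- pca_overlap(state$fc_by_cohort)
    p <- file.path(d, "pca_overlap.tsv")
    utils::write.table(
      data.frame(sample = rownames(po$embedding), po$embedding,
                 label = po$labels),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    # double-assay concordance and limits of detection
    if (!is.null(cfg$generator)) {
      da <- generate_double_assay(cfg$generator)
      ns <- to_cpm(da$nanostring)
      rs <- to_cpm(da$rnaseq_gene)
      rho <- gene_correlations(rs, ns)
      me <- apply(log2(ns$values + 1), 1L, stats::median)
      iq <- apply(log2(ns$values + 1), 1L, stats::IQR)
      ct <- concordance_table(cbind(cpm = rho), me, iq)
      state$limits <- estimate_detection_limits(
        ct, n_bins = cfg$lod$n_bins, loose_drop = cfg$lod$loose_drop,
        strict_floor = cfg$lod$strict_floor)
      state$median_expr <- me; state$expr_iqr <- iq
      p1 <- file.path(d, "concordance.tsv")
      utils::write.table(ct, p1, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      p2 <- file.path(d, "detection_limits.json")
      jsonlite::write_json(state$limits[1:4], p2, auto_unbox = TRUE,
                           digits = NA)
      paths <- c(paths, p1, p2)
    }
    add_files("harmonize", paths)
  })

  ## select -------------------------------------------------------------
  if ("select" %in% cfg$stages) run_stage("select", function() {
    d <- file.path(cfg$outdir, "select"); dir.create(d, showWarnings = FALSE)
    split <- make_holdout_split(meta[meta$patient_id %in% colnames(fc_all), ],
                                labels,
                                seed = derive_seed(cfg$seed, "holdout"))
    state$split <- split
    cohort_of <- stats::setNames(meta$mini_cohort[match(colnames(fc_all),
                                                        meta$patient_id)],
                                 colnames(fc_all))
    fc_tr <- paired_l2fc(unclass(fc_all)[, split$train, drop = FALSE],
                         1, "CPM")
    pft <- bootstrap_predictive_frequency(
      fc_tr, labels, cohort_of, B = cfg$fs$B, top_m = cfg$fs$top_m,
      seed = derive_seed(cfg$seed, "bootstrap"))
    excl <- character(0)
    if (isTRUE(cfg$lod$filter) && !is.null(state$limits))
      excl <- genes_below_lod(state$limits, state$median_expr,
                              state$expr_iqr)
    state$candidates <- rank_candidates(pft, exclude = excl,
                                        max_features = cfg$fs$max_features)
    state$pft <- pft
    p <- file.path(d, "predictive_frequency.tsv")
    utils::write.table(pft, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p2 <- file.path(d, "candidates.txt")
    writeLines(state$candidates, p2)
    add_files("select", c(p, p2))
  })

  ## train --------------------------------------------------------------
  if ("train" %in% cfg$stages) run_stage("train", function() {
    d <- file.path(cfg$outdir, "train"); dir.create(d, showWarnings = FALSE)
    fc_tr <- paired_l2fc(unclass(fc_all)[, state$split$train, drop = FALSE],
                         1, "CPM")
    if (isTRUE(cfg$model$loocv)) {
      sel <- loocv_select_k(fc_tr, labels, state$candidates,
                            architectures = cfg$model$architectures)
      k <- sel$k; arch <- sel$architecture
      state$loocv <- sel
    } else {
      k <- length(state$candidates); arch <- cfg$model$architectures[1L]
    }
    model <- fit_final(fc_tr, labels, state$candidates[seq_len(k)], arch)
    state$model <- model
    subsets <- c(list(train_val = state$split$train,
                      holdout = state$split$holdout),
                 split(colnames(fc_all),
                       meta$mini_cohort[match(colnames(fc_all),
                                              meta$patient_id)]))
    ev <- suppressWarnings(evaluate_model(model, fc_all, labels, subsets))
    state$eval <- ev
    p1 <- file.path(d, "model.json")
    jsonlite::write_json(
      list(architecture = model$architecture, genes = model$genes,
           coefficients = as.list(model$coefficients),
           intercept = model$intercept, k = model$k, seed = cfg$seed),
      p1, auto_unbox = TRUE, digits = NA)
    p2 <- file.path(d, "evaluation.tsv")
    utils::write.table(ev$report, p2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add_files("train", c(p1, p2))
  })

  ## validate -----------------------------------------------------------
  if ("validate" %in% cfg$stages) run_stage("validate", function() {
    d <- file.path(cfg$outdir, "validate"); dir.create(d, showWarnings = FALSE)
    genes <- state$model$genes[state$model$coefficients != 0]
    if (length(genes) < 1L) genes <- state$model$genes[1L]
    fc_sub <- lapply(state$fc_by_cohort, function(fc)
      paired_l2fc(unclass(fc)[intersect(genes, rownames(fc)), ,
                              drop = FALSE], 1, "CPM"))
    dc <- directionality_concordance(fc_sub, labels)
    p1 <- file.path(d, "directionality.tsv")
    utils::write.table(dc$records, p1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    # survival association of pre-treatment expression
    pre_expr <- do.call(cbind, lapply(sim$cohorts[bulk], function(co) {
      v <- to_cpm(co$pre)$values
      v[intersect(genes, rownames(v)), , drop = FALSE]
    }))
    pre_meta <- meta[match(colnames(pre_expr), meta$sample_id), ]
    colnames(pre_expr) <- pre_meta$patient_id
    cx <- cox_univariate(log2(pre_expr + 1), pre_meta$pfs_months,
                         pre_meta$pfs_event)
    p2 <- file.path(d, "cox.tsv")
    utils::write.table(cx, p2, sep = "\t", quote = FALSE, row.names = FALSE)
    g1 <- genes[1L]
    km <- km_median_split(log2(pre_expr[g1, ] + 1), pre_meta$pfs_months,
                          pre_meta$pfs_event)
    p3 <- file.path(d, "km.tsv")
    utils::write.table(
      data.frame(gene = g1, group = rep(c("low", "high"),
                                        km$fit$strata),
                 time = km$fit$time, surv = km$fit$surv,
                 logrank_p = km$p),
      p3, sep = "\t", quote = FALSE, row.names = FALSE)
    state$validate <- list(directionality = dc, cox = cx, km = km)
    add_files("validate", c(p1, p2, p3))
  })

  ## network ------------------------------------------------------------
  if ("network" %in% cfg$stages) run_stage("network", function() {
    d <- file.path(cfg$outdir, "network"); dir.create(d, showWarnings = FALSE)
    rs <- bulk[vapply(bulk, function(cn)
      meta$assay[meta$mini_cohort == cn][1L] == "rnaseq", logical(1))]
    if (!length(rs)) rs <- bulk[1L]
    pre_m <- do.call(cbind, lapply(sim$cohorts[rs], function(co)
      log2(to_cpm(co$pre)$values + 1)))
    post_m <- do.call(cbind, lapply(sim$cohorts[rs], function(co)
      log2(to_cpm(co$post)$values + 1)))
    focal <- state$model$genes[which.max(abs(state$model$coefficients))]
    vr <- apply(pre_m, 1L, stats::var)
    top <- union(focal, names(sort(vr, decreasing = TRUE))[1:min(100,
                                                                 nrow(pre_m))])
    tom_pre <- tom_similarity(build_adjacency(pre_m[top, ]))
    tom_post <- tom_similarity(build_adjacency(post_m[top, ]))
    fd <- focal_delta(tom_pre, tom_post, focal)
    p <- file.path(d, "focal_delta.tsv")
    utils::write.table(fd, p, sep = "\t", quote = FALSE, row.names = FALSE)
    state$network <- fd
    add_files("network", p)
  })

  manifest$state <- state
  class(manifest) <- "crossfc_manifest"
  mp <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(
    list(seed = manifest$seed, version = manifest$version,
         stages = manifest$stages),
    mp, auto_unbox = TRUE, digits = NA)
  manifest
}

#' Write a human-readable run report
#'
#' One markdown plus one JSON report whose numbers are taken directly
#' from the stage results in the manifest.
#'
#' @param manifest result of [run_pipeline()].
#' @param path output path without extension (writes `.md` and `.json`).
#' @return invisible list with the report contents.
#' @export
write_report <- function(manifest, path) {
  st <- manifest$state
  if (is.null(st$eval)) stop("missing train stage output")
  rep <- list(seed = manifest$seed,
              auroc = st$eval$report,
              selected_genes = st$model$genes,
              nonzero_genes = st$model$genes[st$model$coefficients != 0],
              architecture = st$model$architecture,
              detection_limits = if (!is.null(st$limits))
                st$limits[1:4] else NULL)
  md <- c("# crossfc run report", "",
          sprintf("- seed: %d", rep$seed),
          sprintf("- architecture: %s", rep$architecture),
          sprintf("- selected genes (k=%d): %s", length(rep$selected_genes),
                  paste(rep$selected_genes, collapse = ", ")),
          if (length(rep$nonzero_genes))
            sprintf("- nonzero-coefficient genes: %s",
                    paste(rep$nonzero_genes, collapse = ", "))
          else "- nonzero-coefficient genes: none selected",
          "", "## AUROC by subset", "",
          sprintf("- %s: %s (n=%d)", rep$auroc$subset,
                  formatC(rep$auroc$auroc, digits = 3, format = "f"),
                  rep$auroc$n))
  if (!is.null(rep$detection_limits))
    md <- c(md, "", "## Limits of detection", "",
            sprintf("- %s: %.4g", names(rep$detection_limits),
                    unlist(rep$detection_limits)))
  writeLines(md, paste0(path, ".md"))
  jsonlite::write_json(rep[names(rep) != "auroc_roc"],
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(rep)
}
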