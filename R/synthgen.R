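#' @keywords internal
#' Deterministic sub-seed derivation: one user seed fans out to named
#' sub-streams so that stages and mini-cohorts draw from independent,
#' reproducible streams.  Always returns an integer < 2^31.
derive_seed <- function(seed, tag) {
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 31 + k) %% 2147480009
  as.integer(((seed %% 2147480009) * 48271 + h) %% 2147480009)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[1L] <- 1
  g / sum(g)
}

#' Configuration for the synthetic multi-assay cohort generator
#'
#' Defaults emulate the study conditions the pipeline targets: six bulk
#' mini-cohorts (three NanoString, three RNA-seq) of 35/17/31/15/20/22
#' paired patients, a 770-gene probe panel inside a 2000-gene space,
#' planted progression-free-survival (PFS) effects of one log2 unit, and
#' per-assay detection floors below which measurements are
#' background-dominated.
#'
#' @param n_genes number of genes in the full (RNA-seq) gene space.
#' @param mini_cohorts data.frame with columns `name`, `assay`
#'   (`rnaseq`/`nanostring`/`microarray`/`scrnaseq`) and `n_patients`
#'   (each >= 2).
#' @param panel_size number of genes on the probe panel (<= `n_genes`);
#'   NanoString cohorts measure only panel genes.
#' @param n_planted_pfs_genes,pfs_effect_size number of planted PFS
#'   biomarkers and the difference (log2 units) in mean post/pre
#'   fold-change between long- and short-PFS classes.
#' @param n_planted_assay_genes,assay_offset number of planted
#'   assay-discriminative genes and the constant per-assay background
#'   offset (log2 units) they carry.
#' @param detection_floor named per-assay vector (CPM-like units): below
#'   this abundance measurements are noise-dominated.  The measurement
#'   model adds a background whose expected level equals the floor.
#' @param microarray_compression concavity of the microarray response on
#'   the log scale, in (0, 1]; 1 = no compression.
#' @param isoforms_per_gene isoforms simulated per gene (>= 1).
#' @param patient_effect_sd,residual_sd natural-log standard deviations of
#'   the per-patient (shared pre/post) and per-sample random effects.
#' @param batch_background_sd natural-log sd of the per-(cohort, gene)
#'   batch multiplier on the measurement background (shared by the pre
#'   and post runs of a cohort).
#' @param background_jitter_sd natural-log sd of the per-(gene, sample)
#'   fluctuation of the measurement background; this is what makes
#'   below-floor genes noise-dominated and decorrelated across assays.
#' @param assay_genes_below_floor place planted assay genes among
#'   below-floor panel genes (mirrors the observation that
#'   assay-discriminative genes sit below the limits of detection).
#' @param planted_pfs_genes,planted_assay_genes optional explicit gene id
#'   vectors; must be disjoint.
#' @param sc_cells_per_sample,sc_cell_types cells per sample and number of
#'   cell types for single-cell cohorts.
#' @param seed integer RNG seed.
#' @return validated `generator_config` list.
#' @export
generator_config <- function(n_genes = 2000,
                             mini_cohorts = data.frame(
                               name = c("NS-A", "NS-B", "NS-C",
                                        "RS-A", "RS-B", "RS-C"),
                               assay = c("nanostring", "nanostring",
                                         "nanostring", "rnaseq", "rnaseq",
                                         "rnaseq"),
                               n_patients = c(35L, 17L, 31L, 15L, 20L, 22L),
                               stringsAsFactors = FALSE),
                             panel_size = 770L,
                             n_planted_pfs_genes = 15L,
                             pfs_effect_size = 1.0,
                             n_planted_assay_genes = 12L,
                             assay_offset = 1.0,
                             detection_floor = c(rnaseq = 1, nanostring = 5,
                                                 microarray = 0, scrnaseq = 0),
                             microarray_compression = 0.5,
                             isoforms_per_gene = 2L,
                             patient_effect_sd = 0.5,
                             residual_sd = 0.3,
                             batch_background_sd = 0.5,
                             background_jitter_sd = 0.5,
                             assay_genes_below_floor = TRUE,
                             planted_pfs_genes = NULL,
                             planted_assay_genes = NULL,
                             sc_cells_per_sample = 200L,
                             sc_cell_types = 4L,
                             poisson_noise = TRUE,
                             microarray_noise_sd = 0.1,
                             seed = 1L) {
  stopifnot(n_genes >= 1, panel_size <= n_genes,
            all(mini_cohorts$n_patients >= 2),
            all(mini_cohorts$assay %in% c("rnaseq", "nanostring",
                                          "microarray", "scrnaseq")),
            microarray_compression > 0, microarray_compression <= 1,
            isoforms_per_gene >= 1,
            patient_effect_sd >= 0, residual_sd >= 0,
            batch_background_sd >= 0)
  if (!is.null(planted_pfs_genes) && !is.null(planted_assay_genes) &&
      length(intersect(planted_pfs_genes, planted_assay_genes)))
    stop("planted PFS and assay gene sets must be disjoint")
  cfg <- list(n_genes = as.integer(n_genes), mini_cohorts = mini_cohorts,
              panel_size = as.integer(panel_size),
              n_planted_pfs_genes = as.integer(n_planted_pfs_genes),
              pfs_effect_size = pfs_effect_size,
              n_planted_assay_genes = as.integer(n_planted_assay_genes),
              assay_offset = assay_offset,
              detection_floor = detection_floor,
              microarray_compression = microarray_compression,
              isoforms_per_gene = as.integer(isoforms_per_gene),
              patient_effect_sd = patient_effect_sd,
              residual_sd = residual_sd,
              batch_background_sd = batch_background_sd,
              background_jitter_sd = background_jitter_sd,
              assay_genes_below_floor = assay_genes_below_floor,
              planted_pfs_genes = planted_pfs_genes,
              planted_assay_genes = planted_assay_genes,
              sc_cells_per_sample = as.integer(sc_cells_per_sample),
              sc_cell_types = as.integer(sc_cell_types),
              poisson_noise = isTRUE(poisson_noise),
              microarray_noise_sd = microarray_noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

# Gene-level scaffolding shared by all generator entry points: baseline
# abundances, panel membership, planted gene sets, isoform structure and
# probe placement.  Deterministic given config$seed.
gene_universe <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "genes"))
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  mu <- stats::rnorm(cfg$n_genes, mean = 4, sd = 2)   # ln CPM-like scale
  names(mu) <- genes
  panel <- sort(sample(genes, cfg$panel_size))
  max_floor <- max(cfg$detection_floor)

  if (is.null(cfg$planted_pfs_genes)) {
    # biomarkers are well-measured genes: draw from the upper half of
    # panel expression so they sit above every detection floor
    cand <- panel[mu[panel] >= stats::median(mu[panel])]
    pfs_genes <- sort(sample(cand, cfg$n_planted_pfs_genes))
  } else pfs_genes <- cfg$planted_pfs_genes
  pfs_sign <- sample(c(-1, 1), length(pfs_genes), replace = TRUE)
  names(pfs_sign) <- pfs_genes

  if (is.null(cfg$planted_assay_genes)) {
    pool <- setdiff(panel, pfs_genes)
    if (cfg$assay_genes_below_floor && max_floor > 0) {
      low <- pool[exp(mu[pool]) < max_floor]
      if (length(low) >= cfg$n_planted_assay_genes) pool <- low
    }
    assay_genes <- sort(sample(pool, min(cfg$n_planted_assay_genes,
                                         length(pool))))
  } else assay_genes <- cfg$planted_assay_genes
  if (length(intersect(pfs_genes, assay_genes)))
    stop("planted PFS and assay gene sets overlap")
  assay_sign <- sample(c(-1, 1), length(assay_genes), replace = TRUE)
  names(assay_sign) <- assay_genes

  # isoform structure: exons of 200 bp; isoform 1 has 3 exons, later
  # isoforms drop one internal exon and append a distal one, so isoforms
  # differ in both composition and length
  ex <- list(); usage <- list()
  for (i in seq_len(cfg$n_genes)) {
    g <- genes[i]; base <- (i - 1) * 10000
    starts1 <- base + c(0, 500, 1000)
    for (k in seq_len(cfg$isoforms_per_gene)) {
      iso <- paste0(g, ".", k)
      starts <- if (k == 1) starts1 else c(starts1[-2], base + 1500 + 300 * k)
      ex[[iso]] <- data.frame(gene = g, isoform = iso, contig = "chr1",
                              start = starts, end = starts + 200,
                              stringsAsFactors = FALSE)
    }
    usage[[g]] <- rdirichlet1(rep(2, cfg$isoforms_per_gene))
  }
  exons <- do.call(rbind, ex)
  rownames(exons) <- NULL
  # probe on the first exon (shared by all isoforms) for half the panel,
  # and on the distal exon of isoform 2 (probe-specific isoform) for the
  # rest, so probe-matched and highest-expressed isoforms can disagree
  probes <- NULL
  if (length(panel)) {
    on_distal <- rep(c(FALSE, TRUE), length.out = length(panel))
    rows <- lapply(seq_along(panel), function(j) {
      g <- panel[j]
      e <- exons[exons$gene == g, ]
      tgt <- if (on_distal[j] && cfg$isoforms_per_gene > 1)
        e[nrow(e), ] else e[1L, ]
      data.frame(gene = g, contig = "chr1", start = tgt$start + 50,
                 end = tgt$start + 150, stringsAsFactors = FALSE)
    })
    probes <- do.call(rbind, rows)
  }
  list(genes = genes, mu = mu, panel = panel,
       pfs_effect = pfs_sign * cfg$pfs_effect_size,
       assay_effect = assay_sign * cfg$assay_offset,
       exons = exons, probes = probes,
       usage = do.call(rbind, usage))
}

# ln-scale true abundance for one cohort and timepoint: baseline +
# per-patient effect (shared across timepoints, so it cancels in paired
# log2FC) + planted post-treatment shifts + per-sample residual.
true_abundance <- function(uni, cfg, patients, patient_eff, long_class,
                           timepoint) {
  n <- length(patients)
  ln <- matrix(uni$mu, nrow = cfg$n_genes, ncol = n,
               dimnames = list(uni$genes, patients))
  ln <- ln + patient_eff
  if (timepoint == "post" && length(uni$pfs_effect)) {
    shift <- outer(uni$pfs_effect * log(2), as.numeric(long_class))
    ln[names(uni$pfs_effect), ] <- ln[names(uni$pfs_effect), ] + shift
  }
  ln + matrix(stats::rnorm(length(ln), 0, cfg$residual_sd), nrow(ln), n)
}

#' Apply an assay-specific measurement model to true abundances
#'
#' Count assays (RNA-seq, NanoString) draw Poisson counts around an
#' efficiency-scaled target of `true + background`, where the background
#' defaults to the assay's detection floor: genes far above the floor are
#' measured faithfully, genes below it are background-dominated.
#' Microarray applies a strictly monotone concave power
#' (`microarray_compression`) on the log scale plus log-normal intensity
#' noise.  scRNA-seq draws per-cell multinomial counts with capture
#' efficiency proportional to `abundance^0.3` (preferential capture of
#' high expressors) and labels cells by type.
#'
#' @param true_abundance non-negative gene x sample matrix (CPM-like
#'   scale).
#' @param assay assay tag.
#' @param config a [generator_config()].
#' @param background optional gene x sample matrix (or per-gene vector) of
#'   background levels overriding the constant floor.
#' @param depth expected total counts per sample (count assays).
#' @param noise_sd log-normal intensity noise sd (microarray).
#' @param seed RNG seed.
#' @return for bulk assays an [expr_mat()] (`raw_count` or `intensity`);
#'   for `scrnaseq` a list with sparse `counts` (gene x cell) and a
#'   `cell_labels` data.frame.
#' @export
apply_assay_bias <- function(true_abundance, assay, config,
                             background = NULL, depth = NULL,
                             noise_sd = config$microarray_noise_sd,
                             seed = 1L) {
  stopifnot(all(true_abundance >= 0))
  if (!assay %in% c("rnaseq", "nanostring", "microarray", "scrnaseq"))
    stop("unknown assay tag: ", assay)
  set.seed(seed)
  G <- nrow(true_abundance); S <- ncol(true_abundance)
  floor_a <- config$detection_floor[[assay]]
  if (is.null(background)) background <- matrix(floor_a, G, S)
  if (is.vector(background)) background <- matrix(background, G, S)

  if (assay %in% c("rnaseq", "nanostring")) {
    if (is.null(depth)) depth <- if (assay == "rnaseq") 2e7 else 5e6
    # background-limited response: below the detection floor the assay
    # reads fluctuating background (probe chemistry, lane effects), not
    # signal, so below-floor genes are noise-dominated while well-
    # expressed genes are measured faithfully
    if (any(background > 0)) {
      if (config$background_jitter_sd > 0)
        background <- background *
          exp(matrix(stats::rnorm(G * S, 0, config$background_jitter_sd),
                     G, S))
      target <- pmax(true_abundance, background)
    } else target <- true_abundance
    sc <- depth / colSums(target)
    lam <- sweep(target, 2L, sc, "*")
    counts <- if (config$poisson_noise)
      matrix(stats::rpois(G * S, lam), G, S) else lam
    dimnames(counts) <- dimnames(true_abundance)
    return(expr_mat(counts, unit = "raw_count", assay = assay))
  }
  if (assay == "microarray") {
    y <- log1p(true_abundance + background)^config$microarray_compression
    noise <- if (noise_sd > 0)
      matrix(stats::rnorm(G * S, 0, noise_sd), G, S) else 0
    out <- expm1(y) * exp(noise)
    dimnames(out) <- dimnames(true_abundance)
    return(expr_mat(out, unit = "intensity", assay = "microarray"))
  }
  # scrnaseq: cells per sample, multinomial capture
  n_cells <- config$sc_cells_per_sample
  n_types <- config$sc_cell_types
  type_names <- paste0("ct", seq_len(n_types))
  # per-type marker modulation drawn once per call (deterministic by seed)
  type_mod <- matrix(1, G, n_types)
  for (t in seq_len(n_types))
    type_mod[sample.int(G, max(1L, round(0.1 * G))), t] <- 4
  counts_list <- list(); labels <- list()
  for (s in seq_len(S)) {
    props <- rdirichlet1(rep(3, n_types))
    types <- sample(type_names, n_cells, replace = TRUE, prob = props)
    cell_tot <- stats::rpois(n_cells, 2000)
    cm <- matrix(0, G, n_cells)
    for (ci in seq_len(n_cells)) {
      t <- match(types[ci], type_names)
      w <- (true_abundance[, s] * type_mod[, t])^1.3  # capture ~ x^0.3
      if (sum(w) == 0) next
      cm[, ci] <- stats::rmultinom(1L, cell_tot[ci], w)
    }
    cid <- paste0(colnames(true_abundance)[s], "_c", seq_len(n_cells))
    colnames(cm) <- cid
    counts_list[[s]] <- Matrix::Matrix(cm, sparse = TRUE)
    labels[[s]] <- data.frame(cell_id = cid,
                              sample_id = colnames(true_abundance)[s],
                              cell_type = types, stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, counts_list)
  rownames(counts) <- rownames(true_abundance)
  list(counts = counts, cell_labels = do.call(rbind, labels))
}

#' Generate a multi-cohort, multi-assay paired pre/post study
#'
#' Every patient contributes exactly one pre- and one post-treatment
#' sample to exactly one mini-cohort.  Gene abundances follow log-normal
#' baselines with patient random effects; planted PFS genes shift post
#' samples of the long-PFS class by `pfs_effect_size` log2 units; planted
#' assay genes carry constant per-assay background offsets; PFS months are
#' exponential with median 12 and are monotone in the latent that drives
#' the planted shifts, so planted-gene log2FC is monotonically associated
#' with PFS.  Bit-deterministic given `config$seed`.
#'
#' @param config a [generator_config()].
#' @return list with elements `cohorts` (per mini-cohort: `pre`/`post`
#'   [expr_mat()]s, plus `sc` for single-cell cohorts), `meta` (sample
#'   metadata), `gene_model` (a [gene_model()]), and `truth` (planted
#'   effects, floors, isoform usage, PFS classes).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  uni <- gene_universe(config)
  cohorts <- list(); meta <- list()
  truth_class <- character(0)
  for (r in seq_len(nrow(config$mini_cohorts))) {
    cname <- config$mini_cohorts$name[r]
    assay <- config$mini_cohorts$assay[r]
    n <- config$mini_cohorts$n_patients[r]
    set.seed(derive_seed(config$seed, paste0("cohort:", cname)))
    patients <- sprintf("%s_P%03d", cname, seq_len(n))
    # balanced latent grid: u > 0.5 <=> long PFS class, balanced within 1
    u <- sample((seq_len(n) - 0.5) / n)
    pfs <- -12 * log(1 - u) / log(2)          # exponential, median 12
    long <- pfs > 12
    pfi <- pmax(0, pfs - 2 - stats::rexp(n, 1 / 2))
    os <- pfs + stats::rexp(n, 1 / 20)

    genes_meas <- if (assay %in% c("nanostring", "microarray"))
      uni$panel else uni$genes
    patient_eff <- matrix(stats::rnorm(config$n_genes * n, 0,
                                       config$patient_effect_sd),
                          config$n_genes, n)
    # batch background: one per (cohort, gene) multiplier, shared by the
    # pre and post runs so it cancels in paired log2FC; the planted assay
    # genes additionally carry a constant per-assay offset on the post
    # run's background, which is what makes them assay-discriminative on
    # the log2FC scale
    bg_base <- config$detection_floor[[assay]] *
      exp(stats::rnorm(length(genes_meas), 0, config$batch_background_sd))
    names(bg_base) <- genes_meas
    mats <- list()
    for (tp in c("pre", "post")) {
      ln <- true_abundance(uni, config, patients, patient_eff, long, tp)
      tr <- exp(ln)[genes_meas, , drop = FALSE]
      colnames(tr) <- paste0(patients, "_", tp)
      bg <- bg_base
      if (assay == "nanostring" && tp == "post" &&
          length(uni$assay_effect)) {
        tgt <- intersect(names(uni$assay_effect), genes_meas)
        bg[tgt] <- bg[tgt] * 2^uni$assay_effect[tgt]
      }
      mats[[tp]] <- apply_assay_bias(
        tr, assay = if (assay == "scrnaseq") "scrnaseq" else assay,
        config = config, background = bg,
        seed = derive_seed(config$seed, paste0(cname, ":", tp)))
    }
    if (assay == "scrnaseq") {
      sc <- list(pre = mats$pre, post = mats$post)
      pb <- lapply(sc, function(x)
        pseudobulk(x$counts, x$cell_labels, group = "all"))
      cohorts[[cname]] <- list(pre = pb$pre, post = pb$post, sc = sc)
    } else {
      cohorts[[cname]] <- list(pre = mats$pre, post = mats$post)
    }
    for (tp in c("pre", "post"))
      meta[[paste(cname, tp)]] <- data.frame(
        sample_id = paste0(patients, "_", tp), patient_id = patients,
        mini_cohort = cname, assay = assay, timepoint = tp,
        pfs_months = pfs, pfs_event = 1L,
        pfi_months = if (assay == "scrnaseq") pfi else NA_real_,
        os_months = os, os_event = 1L, stringsAsFactors = FALSE)
    cl <- ifelse(long, "long", "short"); names(cl) <- patients
    truth_class <- c(truth_class, cl)
  }
  truth <- list(planted_pfs_genes = uni$pfs_effect,
                planted_assay_genes = uni$assay_effect,
                true_detection_floor = config$detection_floor,
                true_isoform_usage = uni$usage,
                panel_genes = uni$panel,
                pfs_class = truth_class,
                seed = config$seed)
  list(cohorts = cohorts, meta = do.call(rbind, c(meta, make.row.names = FALSE)),
       gene_model = gene_model(uni$exons, uni$probes), truth = truth)
}

#' Generate a double-assay cohort (same samples on RNA-seq and NanoString)
#'
#' Emulates sequential sections of the same tumors measured with both
#' platforms: one set of true abundances, measured independently with
#' RNA-seq at isoform resolution (with per-exon counts) and NanoString at
#' probe resolution.  NanoString's per-gene target is the summed abundance
#' of isoforms overlapping the probe.
#'
#' @param config a [generator_config()].
#' @param n_samples number of tumor samples (default 24).
#' @param replicate tag varying the measurement-noise stream while keeping
#'   the underlying tissue identical (for cross-replicate noise studies).
#' @param emit_exons also draw per-exon counts (needed only for the
#'   exon-based counting mode; skipping them is faster).
#' @return list with `rnaseq_iso` (isoform-level [expr_mat()]),
#'   `rnaseq_exon` (exon-level count matrix, rows `"<isoform>:<i>"`),
#'   `rnaseq_gene` (all-isoform gene counts), `nanostring` (panel-gene
#'   [expr_mat()]), `gene_model`, `truth`, and per-gene `true_abundance`.
#' @export
generate_double_assay <- function(config, n_samples = 24L, replicate = "r1",
                                  emit_exons = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  uni <- gene_universe(config)
  set.seed(derive_seed(config$seed, "double:tissue"))
  samples <- sprintf("D%03d", seq_len(n_samples))
  ln <- matrix(uni$mu, config$n_genes, n_samples,
               dimnames = list(uni$genes, samples))
  ln <- ln + matrix(stats::rnorm(length(ln), 0, config$patient_effect_sd),
                    nrow(ln), ncol(ln)) +
    matrix(stats::rnorm(length(ln), 0, config$residual_sd),
           nrow(ln), ncol(ln))
  tr <- exp(ln)
  n_iso <- config$isoforms_per_gene
  iso_ids <- as.vector(t(outer(uni$genes, seq_len(n_iso),
                               function(g, k) paste0(g, ".", k))))
  iso_tr <- tr[rep(seq_len(config$n_genes), each = n_iso), , drop = FALSE] *
    as.vector(t(uni$usage))
  rownames(iso_tr) <- iso_ids

  set.seed(derive_seed(config$seed, paste0("double:rnaseq:", replicate)))
  rna <- apply_assay_bias(iso_tr, "rnaseq", config,
                          background = config$detection_floor[["rnaseq"]] / n_iso,
                          seed = derive_seed(config$seed,
                                             paste0("double:rna:", replicate)))
  # exon-level split of isoform counts, proportional to exon length
  gm <- gene_model(uni$exons, uni$probes)
  exon_counts <- NULL
  if (emit_exons) {
    set.seed(derive_seed(config$seed, paste0("double:exon:", replicate)))
    exon_rows <- list()
    by_iso <- split(gm$exons, gm$exons$isoform)
    for (iso in iso_ids) {
      e <- by_iso[[iso]]
      w <- (e$end - e$start) / sum(e$end - e$start)
      cnt <- rna$values[iso, ]
      sp <- vapply(cnt, function(nn) stats::rmultinom(1L, nn, w)[, 1L],
                   numeric(nrow(e)))
      sp <- matrix(sp, nrow = nrow(e))
      rownames(sp) <- paste0(iso, ":", seq_len(nrow(e)))
      exon_rows[[iso]] <- sp
    }
    exon_counts <- do.call(rbind, exon_rows)
    colnames(exon_counts) <- samples
  }

  # NanoString: probe-targeted abundance = isoforms overlapping the probe
  panel <- uni$panel
  ns_tr <- matrix(0, length(panel), n_samples,
                  dimnames = list(panel, samples))
  for (g in panel) {
    ov <- probe_overlap_bp(gm, g)
    hit <- unique(ov$isoform[ov$overlap > 0])
    ns_tr[g, ] <- colSums(iso_tr[hit, , drop = FALSE])
  }
  ns <- apply_assay_bias(ns_tr, "nanostring", config,
                         seed = derive_seed(config$seed,
                                            paste0("double:ns:", replicate)))
  truth <- list(planted_pfs_genes = uni$pfs_effect,
                planted_assay_genes = uni$assay_effect,
                true_detection_floor = config$detection_floor,
                true_isoform_usage = uni$usage,
                panel_genes = panel, seed = config$seed)
  list(rnaseq_iso = rna, rnaseq_exon = exon_counts,
       rnaseq_gene = aggregate_counts(rna, gm, "all_isoforms"),
       nanostring = ns, gene_model = gm, truth = truth,
       true_abundance = tr)
}

#' Write generator outputs to plain-text files
#'
#' Expression TSVs per cohort/timepoint, metadata TSV, BED-like annotation
#' (0-based, half-open), MTX triplet + cell-label TSV for single-cell
#' cohorts, and the ground truth as JSON.
#'
#' @param sim result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisible vector of written paths.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (cn in names(sim$cohorts)) {
    for (tp in c("pre", "post")) {
      p <- file.path(dir, paste0("expr_", cn, "_", tp, ".tsv"))
      write_expression(sim$cohorts[[cn]][[tp]], p)
      paths <- c(paths, p)
      sc <- sim$cohorts[[cn]]$sc
      if (!is.null(sc)) {
        mp <- file.path(dir, paste0("sc_", cn, "_", tp, ".mtx"))
        Matrix::writeMM(sc[[tp]]$counts, mp)
        writeLines(rownames(sc[[tp]]$counts),
                   file.path(dir, paste0("sc_", cn, "_", tp, ".rows.txt")))
        writeLines(colnames(sc[[tp]]$counts),
                   file.path(dir, paste0("sc_", cn, "_", tp, ".cols.txt")))
        utils::write.table(sc[[tp]]$cell_labels,
                           file.path(dir, paste0("sc_", cn, "_", tp,
                                                 "_cells.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        paths <- c(paths, mp)
      }
    }
  }
  mpth <- file.path(dir, "metadata.tsv")
  utils::write.table(sim$meta, mpth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bed <- sim$gene_model$exons
  bedp <- file.path(dir, "annotation.bed")
  utils::write.table(
    data.frame(bed$contig, bed$start, bed$end,
               paste0(bed$gene, "|", bed$isoform), 0, "+"),
    bedp, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  tp <- file.path(dir, "truth.json")
  tr <- sim$truth
  tr$true_isoform_usage <- NULL   # large; regenerable from seed
  for (f in c("planted_pfs_genes", "planted_assay_genes",
              "true_detection_floor", "pfs_class"))
    tr[[f]] <- as.list(tr[[f]])
  jsonlite::write_json(tr, tp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mpth, bedp, tp))
}
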