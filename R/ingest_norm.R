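#' Normalize a raw-count expression matrix
#'
#' Standard library-size normalizations.  CPM divides each column by its
#' library size (times 1e6); RPKM additionally divides by gene length in
#' kilobases; TPM computes the per-kilobase rate first and renormalizes
#' each column to sum to 1e6.
#'
#' @param m an [expr_mat()] with `unit = "raw_count"`.
#' @param method `"CPM"`, `"RPKM"` or `"TPM"`.
#' @param lengths named numeric vector of feature lengths in bp (required
#'   for RPKM/TPM), names covering all genes of `m`.
#' @return an [expr_mat()] in the requested unit.
#' @export
normalize_expression <- function(m, method = c("CPM", "RPKM", "TPM"),
                                 lengths = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(m, "expr_mat"))
  if (m$unit != "raw_count")
    stop("normalize_expression expects raw counts, got unit '", m$unit, "'")
  v <- m$values
  lib <- colSums(v)
  if (any(lib == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(v)[lib == 0], collapse = ", "))
  if (method == "CPM") {
    out <- sweep(v, 2L, lib, "/") * 1e6
  } else {
    if (is.null(lengths)) stop(method, " requires feature lengths")
    len <- as.numeric(lengths[rownames(v)])
    if (anyNA(len)) stop("missing length for gene(s): ",
                         paste(rownames(v)[is.na(len)], collapse = ", "))
    rate <- v / (len / 1e3)          # reads per kilobase
    if (method == "RPKM") {
      out <- sweep(rate, 2L, lib, "/") * 1e6
    } else {
      out <- sweep(rate, 2L, colSums(rate), "/") * 1e6
    }
  }
  expr_mat(out, unit = method, assay = m$assay)
}

#' Scale expression per gene within one assay
#'
#' Percentile scaling maps each gene's values to \[0, 1\] by midrank
#' ((rank - 1) / (n - 1), ties averaged); a constant gene maps to 0.5
#' everywhere.  Z-scoring centers and scales per gene; a constant gene maps
#' to 0.  Both operate across the samples of a single assay, which is the
#' scope in which cross-assay harmonization applies them.
#'
#' @param m an [expr_mat()] with at least 2 samples.
#' @param mode `"percentile"` or `"zscore"`.
#' @return an [expr_mat()] with `unit = "scaled"`.
#' @export
within_assay_scale <- function(m, mode = c("percentile", "zscore")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "expr_mat"))
  v <- m$values
  if (ncol(v) < 2L) stop("scaling requires at least 2 samples")
  n <- ncol(v)
  if (mode == "percentile") {
    out <- t(apply(v, 1L, function(x) (rank(x) - 1) / (n - 1)))
  } else {
    mu <- rowMeans(v)
    sd <- apply(v, 1L, stats::sd)
    out <- (v - mu) / ifelse(sd == 0, 1, sd)
    out[sd == 0, ] <- 0
  }
  dimnames(out) <- dimnames(v)
  expr_mat(out, unit = "scaled", assay = m$assay)
}

#' Paired post/pre log2 fold-changes
#'
#' Computes, per gene and patient, `log2(post + pseudocount) -
#' log2(pre + pseudocount)`.  Sample-to-patient pairing is taken from the
#' metadata table; every patient must contribute exactly one pre and one
#' post sample.
#'
#' @param pre,post [expr_mat()] objects with identical unit and assay.
#' @param meta data.frame with columns `sample_id`, `patient_id`,
#'   `timepoint` (`"pre"`/`"post"`).
#' @param pseudocount positive offset guaranteeing finiteness (default 1,
#'   on the normalized scale).  0 is allowed only if all values are
#'   strictly positive.
#' @return a `paired_l2fc` object: gene x patient numeric matrix with
#'   attributes `pseudocount` and `unit`.
#' @export
compute_log2fc <- function(pre, post, meta, pseudocount = 1) {
  stopifnot(inherits(pre, "expr_mat"), inherits(post, "expr_mat"))
  if (pre$unit != post$unit || pre$assay != post$assay)
    stop("unit/assay mismatch between pre and post matrices")
  if (!identical(rownames(pre$values), rownames(post$values)))
    stop("pre and post must share the same gene space")
  pm <- meta[meta$timepoint == "pre", ]
  qm <- meta[meta$timepoint == "post", ]
  patients <- intersect(pm$patient_id, qm$patient_id)
  miss <- setdiff(union(pm$patient_id, qm$patient_id), patients)
  if (length(miss))
    stop("unpaired patient(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(pm$patient_id) || anyDuplicated(qm$patient_id))
    stop("a patient has more than one sample at a timepoint")
  pre_s <- pm$sample_id[match(patients, pm$patient_id)]
  post_s <- qm$sample_id[match(patients, qm$patient_id)]
  a <- pre$values[, pre_s, drop = FALSE]
  b <- post$values[, post_s, drop = FALSE]
  if (pseudocount <= 0 && (any(a <= 0) || any(b <= 0)))
    stop("pseudocount 0 requires strictly positive values")
  fc <- log2(b + pseudocount) - log2(a + pseudocount)
  colnames(fc) <- patients
  paired_l2fc(fc, pseudocount = pseudocount, unit = pre$unit)
}

#' Construct a paired log2FC object
#' @param fc gene x patient numeric matrix
#' @param pseudocount pseudocount used
#' @param unit source unit
#' @export
paired_l2fc <- function(fc, pseudocount, unit) {
  fc <- as.matrix(fc)
  if (any(!is.finite(fc))) stop("log2FC must be finite everywhere")
  structure(fc, pseudocount = pseudocount, unit = unit,
            class = c("paired_l2fc", "matrix", "array"))
}

#' Pseudobulk single-cell counts
#'
#' Sums integer counts over cells within each (sample, group) combination.
#' `group = "cell_type"` produces one column per sample and cell type,
#' named `"<sample>|<cell_type>"`; `group = "all"` sums all cells of a
#' sample.  Empty groups are dropped with a message.
#'
#' @param sc_counts gene x cell matrix (dense or `Matrix` sparse) of
#'   integer counts; colnames are cell ids.
#' @param cell_labels data.frame with columns `cell_id`, `sample_id`,
#'   `cell_type` covering every cell.
#' @param group `"cell_type"` or `"all"`.
#' @return an [expr_mat()] with `unit = "raw_count"`,
#'   `assay = "scrnaseq_pseudobulk"`.
#' @export
pseudobulk <- function(sc_counts, cell_labels, group = c("cell_type", "all")) {
  group <- match.arg(group)
  cells <- colnames(sc_counts)
  if (!all(cells %in% cell_labels$cell_id))
    stop("unlabeled cell(s): ",
         paste(utils::head(setdiff(cells, cell_labels$cell_id)), collapse = ", "))
  lab <- cell_labels[match(cells, cell_labels$cell_id), ]
  key <- if (group == "cell_type")
    paste(lab$sample_id, lab$cell_type, sep = "|") else lab$sample_id
  groups <- sort(unique(key))
  out <- vapply(groups, function(g) {
    idx <- which(key == g)
    as.numeric(Matrix::rowSums(sc_counts[, idx, drop = FALSE]))
  }, numeric(nrow(sc_counts)))
  rownames(out) <- rownames(sc_counts)
  expr_mat(out, unit = "raw_count", assay = "scrnaseq_pseudobulk")
}

#' Gene model: isoforms, exons and an optional probe region
#'
#' @param exons data.frame with columns `gene`, `isoform`, `contig`,
#'   `start`, `end` (0-based, half-open); exons within an isoform must be
#'   sorted and non-overlapping.
#' @param probes optional data.frame with columns `gene`, `contig`,
#'   `start`, `end`: one probe interval per gene.  A probe must overlap at
#'   least one exon of its gene.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(exons, probes = NULL) {
  stopifnot(all(c("gene", "isoform", "contig", "start", "end") %in%
                  names(exons)))
  if (any(exons$end <= exons$start)) stop("empty or inverted exon interval")
  for (iso in unique(exons$isoform)) {
    e <- exons[exons$isoform == iso, ]
    e <- e[order(e$start), ]
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)]))
      stop("overlapping exons in isoform ", iso)
  }
  if (!is.null(probes)) {
    for (i in seq_len(nrow(probes))) {
      g <- probes$gene[i]
      e <- exons[exons$gene == g, ]
      ov <- pmin(e$end, probes$end[i]) - pmax(e$start, probes$start[i])
      if (!nrow(e) || all(ov <= 0))
        stop("probe for gene ", g, " overlaps no exon")
    }
  }
  structure(list(exons = exons, probes = probes), class = "gene_model")
}

#' Isoform length in bp (sum of exon lengths)
#' @param gm a [gene_model()]
#' @return named numeric vector per isoform
#' @export
isoform_lengths <- function(gm) {
  tapply(gm$exons$end - gm$exons$start, gm$exons$isoform, sum)
}

probe_overlap_bp <- function(gm, gene) {
  p <- gm$probes[gm$probes$gene == gene, ]
  if (!nrow(p)) return(NULL)
  e <- gm$exons[gm$exons$gene == gene, ]
  ov <- pmax(0, pmin(e$end, p$end[1L]) - pmax(e$start, p$start[1L]))
  data.frame(isoform = e$isoform, exon_index = ave(e$start, e$isoform,
                                                   FUN = seq_along),
             overlap = ov)
}

#' Aggregate isoform-level counts to gene level under a counting mode
#'
#' `all_isoforms` sums all isoforms of a gene; `highest_expressed_isoform`
#' keeps the isoform with the highest mean count; `probe_matched_isoform`
#' keeps the isoform with the largest probe overlap in bp;
#' `probe_matched_exon` keeps only the counts of the single exon with the
#' largest probe overlap (requires an exon-level matrix).  Ties in probe
#' overlap are broken by the lexicographically smallest isoform id (then
#' earliest exon) and reported via a message.
#'
#' @param iso an [expr_mat()] whose rows are isoform ids.
#' @param gm a [gene_model()] resolving every isoform.
#' @param mode counting mode, see Description.
#' @param exon_counts exon-level matrix with rownames
#'   `"<isoform>:<exon_index>"`, required for `probe_matched_exon`.
#' @return gene-level [expr_mat()] (same unit/assay).
#' @export
aggregate_counts <- function(iso, gm,
                             mode = c("all_isoforms",
                                      "highest_expressed_isoform",
                                      "probe_matched_isoform",
                                      "probe_matched_exon"),
                             exon_counts = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(iso, "expr_mat"), inherits(gm, "gene_model"))
  iso2gene <- unique(gm$exons[, c("gene", "isoform")])
  unknown <- setdiff(rownames(iso$values), iso2gene$isoform)
  if (length(unknown))
    stop("isoform(s) absent from gene model: ",
         paste(utils::head(unknown), collapse = ", "))
  genes <- sort(unique(iso2gene$gene[iso2gene$isoform %in%
                                       rownames(iso$values)]))
  if (startsWith(mode, "probe") && is.null(gm$probes))
    stop("mode '", mode, "' requires probe intervals")
  pick_rows <- function(g) {
    isos <- sort(iso2gene$isoform[iso2gene$gene == g &
                                    iso2gene$isoform %in% rownames(iso$values)])
    switch(mode,
      all_isoforms = iso$values[isos, , drop = FALSE],
      highest_expressed_isoform = {
        mu <- rowMeans(iso$values[isos, , drop = FALSE])
        best <- isos[which.max(mu)]  # first (lexicographic) on ties
        iso$values[best, , drop = FALSE]
      },
      probe_matched_isoform = {
        ov <- probe_overlap_bp(gm, g)
        if (is.null(ov)) stop("no probe interval for gene ", g)
        tot <- tapply(ov$overlap, ov$isoform, sum)[isos]
        best <- isos[tot == max(tot)]
        if (length(best) > 1L)
          message("probe-overlap tie for gene ", g, "; chose ", min(best))
        iso$values[min(best), , drop = FALSE]
      },
      probe_matched_exon = {
        if (is.null(exon_counts)) stop("probe_matched_exon needs exon_counts")
        ov <- probe_overlap_bp(gm, g)
        ov <- ov[order(-ov$overlap, ov$isoform, ov$exon_index), ]
        key <- paste0(ov$isoform[1L], ":", ov$exon_index[1L])
        if (!key %in% rownames(exon_counts))
          stop("exon counts missing row ", key)
        exon_counts[key, colnames(iso$values), drop = FALSE]
      })
  }
  out <- matrix(0, length(genes), ncol(iso$values),
                dimnames = list(genes, colnames(iso$values)))
  for (g in genes) out[g, ] <- colSums(pick_rows(g))
  expr_mat(out, unit = iso$unit, assay = iso$assay)
}
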