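#' Per-gene Spearman correlation between two assays
#'
#' For each shared gene, the midrank-tied Spearman correlation of its
#' values across paired samples measured on both platforms.  Genes that
#' are constant in either matrix are masked (NA).
#'
#' @param a,b [expr_mat()] objects sharing genes.
#' @param paired_samples optional 2-column matrix/data.frame mapping
#'   sample ids of `a` to ids of `b`; defaults to the shared colnames.
#' @return named numeric vector of rho per shared gene (NA where masked).
#' @export
gene_correlations <- function(a, b, paired_samples = NULL) {
  stopifnot(inherits(a, "expr_mat"), inherits(b, "expr_mat"))
  genes <- intersect(gene_ids(a), gene_ids(b))
  if (!length(genes)) stop("no shared genes")
  if (is.null(paired_samples)) {
    s <- intersect(sample_ids(a), sample_ids(b))
    paired_samples <- cbind(s, s)
  }
  paired_samples <- as.matrix(paired_samples)
  if (nrow(paired_samples) < 4L) {
    warning("fewer than 4 paired samples: correlations masked")
    return(stats::setNames(rep(NA_real_, length(genes)), genes))
  }
  va <- a$values[genes, paired_samples[, 1L], drop = FALSE]
  vb <- b$values[genes, paired_samples[, 2L], drop = FALSE]
  rho <- vapply(seq_along(genes), function(i) {
    x <- va[i, ]; y <- vb[i, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = "spearman")
  }, numeric(1))
  stats::setNames(rho, genes)
}

#' Assemble a per-gene concordance table
#'
#' @param rho_variants gene x variant matrix of Spearman rho values, one
#'   column per (counting mode x normalization) preprocessing variant.
#' @param median_expr named per-gene median expression (reference assay,
#'   normalized unit).
#' @param expr_iqr named per-gene interquartile range of expression.
#' @return `concordance_table` data.frame.
#' @export
concordance_table <- function(rho_variants, median_expr, expr_iqr) {
  rho_variants <- as.matrix(rho_variants)
  genes <- rownames(rho_variants)
  stopifnot(!is.null(genes))
  out <- data.frame(gene = genes,
                    median_expr = as.numeric(median_expr[genes]),
                    expr_iqr = as.numeric(expr_iqr[genes]),
                    rho_variants, check.names = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("concordance_table", "data.frame")
  out
}

# Change-point scan shared by expression- and range-based cutoffs: genes
# are split into quantile bins of `metric`; scanning from the
# highest-expression bin downward, the loose cutoff is the lower edge of
# the first bin whose median rho falls more than `loose_drop` below the
# median rho of the top 3 bins, and the strict cutoff the lower edge of
# the first bin whose median rho drops below `strict_floor`.  No decline
# means cutoff 0.
lod_scan <- function(metric, rho, n_bins, loose_drop, strict_floor) {
  ok <- is.finite(metric) & is.finite(rho)
  metric <- metric[ok]; rho <- rho[ok]
  edges <- unique(stats::quantile(metric, probs = seq(0, 1, length.out =
                                                        n_bins + 1)))
  bin <- cut(metric, edges, include.lowest = TRUE, labels = FALSE)
  nb <- length(edges) - 1L
  med <- vapply(seq_len(nb), function(b) stats::median(rho[bin == b]),
                numeric(1))
  ref <- stats::median(med[seq(nb, max(1L, nb - 2L))])
  loose <- strict <- 0
  for (b in seq(nb, 1L)) {          # highest bin downward
    if (loose == 0 && med[b] < ref - loose_drop) loose <- edges[b]
    if (strict == 0 && med[b] < strict_floor) strict <- edges[b]
  }
  list(loose = unname(loose), strict = unname(strict),
       edges = unname(edges), bin_median_rho = med)
}

#' Estimate limits of detection from a concordance table
#'
#' Formalizes the "clear (strict) or starting (loose) decline in
#' cross-assay correlation" criterion: genes are binned into expression
#' (and, independently, range) quantile bins; the per-bin median rho is
#' scanned from the best-measured bin downward.  The strict cutoff is
#' anchored to correlation coefficients falling below `strict_floor`
#' (default 0.7); the loose cutoff to a drop of `loose_drop` below the
#' median rho of the top 3 bins.
#'
#' @param ct a [concordance_table()]; the first rho variant column is
#'   used unless `rho` is given.
#' @param n_bins number of quantile bins (default 10).
#' @param loose_drop,strict_floor scan parameters.
#' @param rho optional explicit per-gene rho vector.
#' @return `detection_limits` list with `strict_expression`,
#'   `loose_expression`, `strict_range`, `loose_range` and the bin
#'   diagnostics used to derive them.
#' @export
estimate_detection_limits <- function(ct, n_bins = 10, loose_drop = 0.05,
                                      strict_floor = 0.7, rho = NULL) {
  stopifnot(inherits(ct, "concordance_table"))
  if (nrow(ct) < n_bins * 5L)
    stop("need at least ", n_bins * 5L, " genes to bin reliably")
  if (is.null(rho)) rho <- ct[[4L]]
  ex <- lod_scan(ct$median_expr, rho, n_bins, loose_drop, strict_floor)
  rg <- lod_scan(ct$expr_iqr, rho, n_bins, loose_drop, strict_floor)
  structure(list(strict_expression = ex$strict,
                 loose_expression = ex$loose,
                 strict_range = rg$strict, loose_range = rg$loose,
                 expression_bins = ex, range_bins = rg,
                 n_bins = n_bins, loose_drop = loose_drop,
                 strict_floor = strict_floor),
            class = "detection_limits")
}

#' Genes falling below the limits of detection
#' @param limits a `detection_limits` object.
#' @param median_expr,expr_iqr named per-gene vectors on the scale used to
#'   estimate the limits.
#' @param which `"strict"` or `"loose"` cutoffs.
#' @return character vector of gene ids below either cutoff.
#' @export
genes_below_lod <- function(limits, median_expr, expr_iqr = NULL,
                            which = c("strict", "loose")) {
  which <- match.arg(which)
  e_cut <- limits[[paste0(which, "_expression")]]
  r_cut <- limits[[paste0(which, "_range")]]
  low <- names(median_expr)[median_expr < e_cut]
  if (!is.null(expr_iqr))
    low <- union(low, names(expr_iqr)[expr_iqr < r_cut])
  low
}

#' Classify per-gene cross-assay concordance
#'
#' `consistent_high` if rho >= `high` under every preprocessing variant,
#' `consistent_low` if below under every variant, otherwise
#' `preprocessing_dependent`.
#'
#' @param ct a [concordance_table()] (or a gene x variant rho matrix)
#'   with >= 2 variants per gene.
#' @param high threshold (default 0.85).
#' @return named factor per gene.
#' @export
classify_gene_concordance <- function(ct, high = 0.85) {
  rho <- if (inherits(ct, "concordance_table"))
    as.matrix(ct[, -(1:3), drop = FALSE]) else as.matrix(ct)
  if (ncol(rho) < 2L) stop("need >= 2 preprocessing variants")
  cls <- apply(rho, 1L, function(r) {
    r <- r[is.finite(r)]
    if (!length(r)) return(NA_character_)
    if (all(r >= high)) "consistent_high"
    else if (all(r < high)) "consistent_low"
    else "preprocessing_dependent"
  })
  genes <- if (inherits(ct, "concordance_table")) ct$gene else rownames(rho)
  factor(stats::setNames(cls, genes),
         levels = c("consistent_high", "consistent_low",
                    "preprocessing_dependent"))
}

#' Flag genes whose counting mode improves cross-assay concordance
#'
#' A counting mode is flagged better when its rho exceeds the other
#' mode's by more than `delta` in at least two of the three
#' normalizations.  Flagged genes are annotated with whether their counts
#' fall below the detection limits under either mode.
#'
#' @param rho_iso,rho_exon gene x 3 matrices of rho under the
#'   isoform-based and exon-based counting modes (columns =
#'   normalizations).
#' @param delta improvement threshold (default 0.05).
#' @param limits optional `detection_limits`; with `median_expr_iso` /
#'   `median_expr_exon` enables the below-limit attribution.
#' @param median_expr_iso,median_expr_exon named per-gene medians.
#' @return data.frame with `gene`, `flag` in
#'   `{isoform_better, exon_better, neither}`, `below_lod`.
#' @export
counting_improvement <- function(rho_iso, rho_exon, delta = 0.05,
                                 limits = NULL, median_expr_iso = NULL,
                                 median_expr_exon = NULL) {
  rho_iso <- as.matrix(rho_iso); rho_exon <- as.matrix(rho_exon)
  stopifnot(ncol(rho_iso) == 3L, ncol(rho_exon) == 3L,
            identical(rownames(rho_iso), rownames(rho_exon)))
  gain_iso <- rho_iso - rho_exon
  flag <- apply(gain_iso, 1L, function(g) {
    if (sum(g > delta, na.rm = TRUE) >= 2L) "isoform_better"
    else if (sum(-g > delta, na.rm = TRUE) >= 2L) "exon_better"
    else "neither"
  })
  below <- rep(NA, nrow(rho_iso))
  if (!is.null(limits)) {
    lowi <- genes_below_lod(limits, median_expr_iso)
    lowe <- genes_below_lod(limits, median_expr_exon)
    below <- rownames(rho_iso) %in% union(lowi, lowe)
  }
  data.frame(gene = rownames(rho_iso), flag = flag, below_lod = below,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare per-gene log2FC between two counting modes
#'
#' @param fc_a,fc_b `paired_l2fc` matrices over the same genes and
#'   patients.
#' @param outlier absolute difference in mean log2FC flagging a gene
#'   (default 5).
#' @return list with per-gene means and differences, the least-squares
#'   `r_squared` between the two mode means, and the `outliers` gene ids.
#' @export
compare_isoform_log2fc <- function(fc_a, fc_b, outlier = 5.0) {
  stopifnot(identical(dimnames(fc_a), dimnames(fc_b)))
  ma <- rowMeans(fc_a); mb <- rowMeans(fc_b)
  fit <- stats::lm(mb ~ ma)
  diffs <- mb - ma
  list(per_gene = data.frame(gene = rownames(fc_a), mean_a = ma,
                             mean_b = mb, diff = diffs, row.names = NULL),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       outliers = rownames(fc_a)[abs(diffs) >= outlier])
}

#' Cliff's delta effect size
#'
#' `delta = [#(x_i > y_j) - #(x_i < y_j)] / (|x| |y|)`, the nonparametric
#' effect size P(x > y) - P(x < y), in \[-1, 1\].
#'
#' @param x,y nonempty numeric samples.
#' @return delta.
#' @export
cliffs_delta <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty input")
  # O((n+m) log(n+m)) via joint midranks: sum of ranks of x in the pooled
  # sample recovers #(x>y) - #(x<y) without forming the n x m grid
  r <- rank(c(x, y))
  rx <- sum(r[seq_along(x)])
  n <- as.numeric(length(x)); m <- as.numeric(length(y))
  u_greater_minus_less <- 2 * (rx - n * (n + 1) / 2) - n * m
  u_greater_minus_less / (n * m)
}

#' Pairwise dynamic-range comparison of |log2FC| across groups
#'
#' Two-sided Wilcoxon-Mann-Whitney tests for every pair of groups with
#' Benjamini-Hochberg adjustment over the pairs, Cliff's delta effect
#' sizes, and the significance tiers used for assay dynamic-range
#' diagnostics: `***` adj p < 0.001 with |delta| >= 0.474, `**` adj
#' p < 0.01 and `*` adj p < 0.05 with |delta| >= 0.33.
#'
#' @param fc_by_group named list of numeric vectors (e.g. |log2FC| pooled
#'   per assay), each with >= 2 values.
#' @return data.frame per pair: `group1`, `group2`, `p`, `p_adj`,
#'   `cliffs_delta`, `label`.
#' @export
dynamic_range_test <- function(fc_by_group) {
  if (length(fc_by_group) < 2L) stop("need >= 2 groups")
  if (any(lengths(fc_by_group) < 2L)) stop("group with < 2 values")
  nm <- names(fc_by_group)
  pairs <- utils::combn(nm, 2L)
  res <- apply(pairs, 2L, function(pr) {
    x <- fc_by_group[[pr[1L]]]; y <- fc_by_group[[pr[2L]]]
    p <- stats::wilcox.test(x, y, exact = FALSE)$p.value
    c(p = p, delta = cliffs_delta(x, y))
  })
  p_adj <- stats::p.adjust(res["p", ], method = "BH")
  delta <- res["delta", ]
  label <- ifelse(p_adj < 0.001 & abs(delta) >= 0.474, "***",
           ifelse(p_adj < 0.01 & abs(delta) >= 0.33, "**",
           ifelse(p_adj < 0.05 & abs(delta) >= 0.33, "*", "")))
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
             p = res["p", ], p_adj = p_adj, cliffs_delta = delta,
             label = label, row.names = NULL, stringsAsFactors = FALSE)
}

#' PCA overlap of assays with a silhouette mixing score
#'
#' Projects all samples (columns) of the supplied matrices into a common
#' centered PCA and scores how separable the assay labels are in the
#' top-2 PC plane by their mean silhouette width: values near 0 mean the
#' assays are well mixed, values near 1 that they separate.
#'
#' @param matrices named list of gene x sample matrices (or `paired_l2fc`
#'   / [expr_mat()] objects) sharing a gene space; names give assay (or
#'   cohort) labels.
#' @param scaled apply per-gene percentile scaling within each matrix
#'   before combining.
#' @return list with `embedding` (samples x 2), `silhouette` (mean
#'   width), `labels`.
#' @export
pca_overlap <- function(matrices, scaled = FALSE) {
  if (length(matrices) < 2L) stop("silhouette undefined for one group")
  vals <- lapply(matrices, function(m) {
    v <- if (inherits(m, "expr_mat")) m$values else unclass(m)
    if (scaled) {
      n <- ncol(v)
      v <- t(apply(v, 1L, function(x) (rank(x) - 1) / (n - 1)))
    }
    v
  })
  genes <- Reduce(intersect, lapply(vals, rownames))
  if (!length(genes)) stop("no shared gene space")
  x <- do.call(cbind, lapply(vals, function(v) v[genes, , drop = FALSE]))
  labels <- rep(names(matrices), vapply(vals, ncol, integer(1)))
  if (ncol(x) < 3L) stop("need at least 3 samples")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  emb <- pc$x[, 1:2, drop = FALSE]
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(emb))
  list(embedding = emb, silhouette = mean(sil[, "sil_width"]),
       labels = labels)
}
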