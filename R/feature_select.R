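#' One-way ANOVA F statistic per gene
#'
#' Vectorized closed form `F = (SSB / df_B) / (SSW / df_W)` for a binary
#' grouping.  Degenerate genes with zero within-class variance but
#' unequal class means return `Inf` (a warning reports how many); zero
#' between- and within-class variance returns 0.
#'
#' @param values numeric vector (one gene) or gene x sample matrix.
#' @param labels binary factor/vector over samples, each class with >= 2
#'   samples.
#' @return F statistic (vector if `values` is a matrix).
#' @export
f_score <- function(values, labels) {
  x <- if (is.matrix(values)) values else matrix(values, nrow = 1L)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly 2 classes")
  n1 <- sum(labels == levels(labels)[1L])
  n2 <- sum(labels == levels(labels)[2L])
  if (min(n1, n2) < 2L) stop("each class needs >= 2 samples")
  i1 <- labels == levels(labels)[1L]
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, !i1, drop = FALSE])
  gm <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- rowSums((x[, i1, drop = FALSE] - m1)^2) +
    rowSums((x[, !i1, drop = FALSE] - m2)^2)
  dfw <- n1 + n2 - 2L
  f <- ifelse(ssw == 0, ifelse(ssb == 0, 0, Inf), ssb / (ssw / dfw))
  if (any(is.infinite(f)))
    warning(sum(is.infinite(f)),
            " gene(s) with zero within-class variance: F = Inf")
  if (is.matrix(values)) stats::setNames(f, rownames(values)) else f[[1L]]
}

#' Consensus feature selection across mini-cohorts
#'
#' Intersection over mini-cohorts of each cohort's top-k genes by ANOVA
#' F-score (ties broken by gene id, ascending).  An empty intersection
#' returns an empty set with a warning; a single cohort degenerates to
#' that cohort's top-k (reported via message).
#'
#' @param fc_by_cohort named list of `paired_l2fc` (or gene x patient
#'   matrices) sharing a gene space.
#' @param labels named binary vector over all patients.
#' @param k per-cohort top size.
#' @return character vector of selected gene ids (sorted).
#' @export
consensus_select <- function(fc_by_cohort, labels, k) {
  if (length(fc_by_cohort) == 1L)
    message("single mini-cohort: consensus degenerates to its top-k")
  tops <- lapply(fc_by_cohort, function(fc) {
    fc <- unclass(fc)
    f <- f_score(fc, labels[colnames(fc)])
    ord <- order(-f, names(f))
    names(f)[ord][seq_len(min(k, length(f)))]
  })
  sel <- Reduce(intersect, tops)
  if (!length(sel)) warning("empty consensus intersection")
  sort(sel)
}

#' Bootstrap predictive frequency of genes
#'
#' For each of `B` bootstrap replicates, an equal number of patients
#' (the smaller class count) is drawn with replacement within each label
#' class, with per-patient weights inversely proportional to the size of
#' the patient's mini-cohort (normalized within class), so that small
#' mini-cohorts are represented equally with large ones.  Per replicate,
#' the `top_m` genes by ANOVA F-score are recorded (ties broken by gene
#' id).  A gene's predictive frequency is the proportion of replicates in
#' which it was recorded.
#'
#' @param fc `paired_l2fc` (or gene x patient matrix).
#' @param labels named binary vector per patient.
#' @param cohort_of named vector mapping patient id to mini-cohort.
#' @param B number of bootstrap replicates.
#' @param top_m size of the recorded top list (typically 100 for
#'   genome-wide spaces, 50 for panel-sized ones).
#' @param seed RNG seed; the draw stream consumes, for each replicate and
#'   each class in sorted label order, one `sample()` call of size
#'   `n_draw` over the class's patients.
#' @return `predictive_frequency` data.frame: `gene`, `frequency`,
#'   `mean_f`, `rank` (by frequency, mean F, gene id).
#' @export
bootstrap_predictive_frequency <- function(fc, labels, cohort_of, B = 200L,
                                           top_m = 100L, seed = 1L) {
  x <- unclass(fc)
  patients <- colnames(x)
  labels <- as.factor(labels[patients])
  if (nlevels(labels) != 2L || any(table(labels) == 0))
    stop("both label classes must be present")
  if (top_m > nrow(x)) stop("top_m exceeds gene count")
  cls <- levels(labels)
  n_draw <- min(table(labels))
  ids_by_class <- split(patients, labels)
  w_by_class <- lapply(ids_by_class, function(ids) {
    w <- 1 / table(cohort_of[patients])[cohort_of[ids]]
    as.numeric(w / sum(w))
  })
  genes <- rownames(x)
  hits <- numeric(nrow(x)); fsum <- numeric(nrow(x))
  names(hits) <- names(fsum) <- genes
  set.seed(seed)
  for (b in seq_len(B)) {
    draw <- unlist(lapply(cls, function(cl)
      sample(ids_by_class[[cl]], n_draw, replace = TRUE,
             prob = w_by_class[[cl]])), use.names = FALSE)
    lab <- factor(rep(cls, each = n_draw))
    f <- suppressWarnings(f_score(x[, draw, drop = FALSE], lab))
    top <- order(-f, genes)[seq_len(top_m)]
    hits[top] <- hits[top] + 1
    fsum <- fsum + ifelse(is.finite(f), f, 0)
  }
  freq <- hits / B
  mean_f <- fsum / B
  ord <- order(-freq, -mean_f, genes)
  out <- data.frame(gene = genes, frequency = freq, mean_f = mean_f,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$rank <- match(seq_len(nrow(out)), ord)
  class(out) <- c("predictive_frequency", "data.frame")
  out
}

#' Rank candidate genes for modeling
#'
#' Optionally removes genes below the limits of detection or outside the
#' probe panel, then takes the top `max_features` genes by (frequency,
#' mean F, gene id) lexicographic order.
#'
#' @param pft a `predictive_frequency` table.
#' @param exclude gene ids to drop (e.g. from [genes_below_lod()]).
#' @param panel optional gene set to restrict to.
#' @param max_features cap on the candidate list (default 25).
#' @return ordered character vector of candidate gene ids.
#' @export
rank_candidates <- function(pft, exclude = NULL, panel = NULL,
                            max_features = 25L) {
  stopifnot(nrow(pft) > 0)
  keep <- !(pft$gene %in% exclude)
  if (!is.null(panel)) keep <- keep & pft$gene %in% panel
  t2 <- pft[keep, , drop = FALSE]
  if (!nrow(t2)) stop("all genes filtered out")
  ord <- order(-t2$frequency, -t2$mean_f, t2$gene)
  t2$gene[ord][seq_len(min(max_features, nrow(t2)))]
}

#' Spearman correlation between two predictive-frequency tables
#'
#' @param t1,t2 `predictive_frequency` tables with >= 4 shared genes.
#' @return midrank Spearman rho of frequencies over shared genes.
#' @export
compare_frequency_tables <- function(t1, t2) {
  shared <- intersect(t1$gene, t2$gene)
  if (length(shared) < 4L) stop("fewer than 4 shared genes")
  stats::cor(t1$frequency[match(shared, t1$gene)],
             t2$frequency[match(shared, t2$gene)], method = "spearman")
}
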