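#' Directionality concordance of genes across mini-cohorts
#'
#' For each gene and mini-cohort, the difference between the median
#' log2FC of long-PFS and short-PFS patients, its sign, and a Welch
#' t-test p-value with the tier symbols used for reporting (. < 0.1,
#' * < 0.05, ** < 0.01, *** < 0.001).  Cohorts containing a single class
#' are excluded with a message.  The consistency class is `all_agree`
#' when every nonzero sign matches the majority sign, `one_disagrees`
#' when exactly one cohort differs, otherwise `inconsistent`.
#'
#' @param fc_by_cohort named list of `paired_l2fc` (gene x patient).
#' @param labels named vector per patient with values `"long"`/`"short"`
#'   (or any two levels; the second sorted level is "long").
#' @return list with `records` (long data.frame per gene x cohort) and
#'   `consistency` (named factor per gene).
#' @export
directionality_concordance <- function(fc_by_cohort, labels) {
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2L) stop("labels must have two classes")
  long_lv <- lv[2L]
  usable <- list()
  for (nm in names(fc_by_cohort)) {
    pats <- colnames(fc_by_cohort[[nm]])
    if (length(unique(labels[pats])) < 2L) {
      message("cohort ", nm, " has one class; excluded")
      next
    }
    usable[[nm]] <- fc_by_cohort[[nm]]
  }
  if (length(usable) < 2L) stop("need >= 2 cohorts with both classes")
  genes <- Reduce(intersect, lapply(usable, rownames))
  rows <- list()
  for (nm in names(usable)) {
    fc <- unclass(usable[[nm]])[genes, , drop = FALSE]
    lab <- labels[colnames(fc)]
    iL <- lab == long_lv
    for (g in genes) {
      x <- fc[g, iL]; y <- fc[g, !iL]
      d <- stats::median(x) - stats::median(y)
      p <- tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA)
      rows[[paste(g, nm)]] <- data.frame(
        gene = g, mini_cohort = nm, median_long = stats::median(x),
        median_short = stats::median(y), diff = d,
        sign = sign(d), p = p,
        tier = if (is.na(p)) "" else if (p < 0.001) "***"
               else if (p < 0.01) "**" else if (p < 0.05) "*"
               else if (p < 0.1) "." else "",
        stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, c(rows, make.row.names = FALSE))
  consistency <- vapply(genes, function(g) {
    s <- rec$sign[rec$gene == g]
    s <- s[s != 0]
    if (!length(s)) return("all_agree")
    maj <- if (sum(s > 0) >= sum(s < 0)) 1 else -1
    nd <- sum(s != maj)
    if (nd == 0) "all_agree" else if (nd == 1) "one_disagrees"
    else "inconsistent"
  }, character(1))
  list(records = rec,
       consistency = factor(consistency,
                            levels = c("all_agree", "one_disagrees",
                                       "inconsistent")))
}

#' Univariate Cox proportional-hazards association per gene
#'
#' Partial-likelihood fit with Efron tie handling; expression is
#' standardized before fitting so hazard ratios are per standard
#' deviation.  P-values are Benjamini-Hochberg adjusted across genes.
#' Monotone-likelihood fits (perfect separation) are flagged and their
#' confidence intervals reported as unbounded.
#'
#' @param expr gene x patient matrix (or named vector for one gene).
#' @param time,event survival times and event indicators (>= 10 patients,
#'   >= 3 events).
#' @return data.frame per gene: `hazard_ratio`, `ci_lower`, `ci_upper`,
#'   `p`, `p_adj`, `direction`, `flagged`.
#' @export
cox_univariate <- function(expr, time, event) {
  x <- if (is.matrix(expr)) expr else matrix(expr, nrow = 1L,
                                             dimnames = list("gene", NULL))
  if (length(time) < 10L) stop("need >= 10 patients")
  if (sum(event) < 3L) stop("need >= 3 events")
  rows <- lapply(rownames(x), function(g) {
    z <- as.numeric(x[g, ])
    s <- stats::sd(z)
    z <- if (s > 0) (z - mean(z)) / s else z * 0
    flagged <- FALSE
    fit <- withCallingHandlers(
      survival::coxph(survival::Surv(time, event) ~ z, ties = "efron"),
      warning = function(w) {
        if (grepl("infinite|converge", conditionMessage(w)))
          flagged <<- TRUE
        invokeRestart("muffleWarning")
      })
    sm <- summary(fit)
    hr <- unname(sm$conf.int[1L, "exp(coef)"])
    ci <- unname(sm$conf.int[1L, c("lower .95", "upper .95")])
    p <- unname(sm$coefficients[1L, "Pr(>|z|)"])
    if (s == 0) { hr <- 1; ci <- c(NA, NA); p <- 1 }
    if (flagged) ci <- c(0, Inf)
    data.frame(gene = g, hazard_ratio = hr, ci_lower = ci[1L],
               ci_upper = ci[2L], p = p,
               direction = ifelse(hr >= 1, "risk", "protective"),
               flagged = flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Kaplan-Meier curves from a median expression split
#'
#' Splits patients at the median expression (ties assigned to the low
#' group), estimates a Kaplan-Meier curve per group and tests the split
#' with a two-sided log-rank test.
#'
#' @param expression named numeric vector per patient (non-constant).
#' @param time,event survival data (>= 10 patients).
#' @return list with `fit` (a `survfit` object), `p` (log-rank),
#'   `groups` (factor), `n` per group.
#' @export
km_median_split <- function(expression, time, event) {
  if (length(expression) < 10L) stop("need >= 10 patients")
  if (stats::sd(expression) == 0)
    stop("constant expression: median split undefined")
  med <- stats::median(expression)
  grp <- factor(ifelse(expression > med, "high", "low"),
                levels = c("low", "high"))
  fit <- survival::survfit(survival::Surv(time, event) ~ grp)
  lr <- survival::survdiff(survival::Surv(time, event) ~ grp)
  p <- stats::pchisq(lr$chisq, df = 1L, lower.tail = FALSE)
  list(fit = fit, p = p, groups = grp, n = table(grp))
}

#' Correlation of cell-type log2FC with platinum-free interval
#'
#' For each gene and cell type, the Spearman correlation and ordinary
#' least-squares fit of pseudobulk log2FC against `log(PFI + 1)`.
#' Patients lacking the cell type are dropped for that cell type (with a
#' message); cell types with fewer than `min_n` remaining patients are
#' skipped.
#'
#' @param fc_by_celltype named list (cell type -> gene x patient
#'   `paired_l2fc`).
#' @param pfi named vector of platinum-free intervals in months (>= 0).
#' @param min_n minimum patients per cell type (default 5).
#' @return data.frame per (gene, cell_type): `rho`, `slope`, `p`, `n`.
#' @export
celltype_pfi_correlation <- function(fc_by_celltype, pfi, min_n = 5L) {
  rows <- list()
  for (ct in names(fc_by_celltype)) {
    fc <- unclass(fc_by_celltype[[ct]])
    pats <- intersect(colnames(fc), names(pfi)[!is.na(pfi)])
    if (length(pats) < ncol(fc))
      message("cell type ", ct, ": ", ncol(fc) - length(pats),
              " patient(s) dropped")
    if (length(pats) < min_n) next
    lp <- log(pfi[pats] + 1)
    for (g in rownames(fc)) {
      y <- fc[g, pats]
      fit <- suppressWarnings(summary(stats::lm(y ~ lp)))
      rows[[paste(g, ct)]] <- data.frame(
        gene = g, cell_type = ct,
        rho = suppressWarnings(stats::cor(y, lp, method = "spearman")),
        slope = fit$coefficients["lp", "Estimate"],
        p = fit$coefficients["lp", "Pr(>|t|)"],
        n = length(pats), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
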