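#' ROC curve points
#'
#' True- and false-positive rates at every distinct score threshold
#' (descending), prepended with (0, 0).
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels binary labels; the positive class is the second factor
#'   level (or `positive`).
#' @param positive optional positive-class value.
#' @return data.frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels, positive = NULL) {
  labels <- as.factor(labels)
  if (is.null(positive)) positive <- levels(labels)[nlevels(labels)]
  y <- labels == positive
  np <- sum(y); nn <- sum(!y)
  if (np == 0 || nn == 0) stop("both classes required for a ROC curve")
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(scores >= t & y) / np, numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & !y) / nn, numeric(1))
  data.frame(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of the ROC curve over distinct score
#' thresholds; tied scores contribute diagonal segments, so the result
#' equals the midrank Mann-Whitney statistic U / (n1 n2).  Returns NA
#' with a warning when only one class is present.
#'
#' @inheritParams roc_points
#' @return AUROC in \[0, 1\], or NA if undefined.
#' @export
auroc <- function(scores, labels, positive = NULL) {
  labels <- as.factor(labels)
  if (is.null(positive)) positive <- levels(labels)[nlevels(labels)]
  y <- labels == positive
  if (sum(y) == 0 || sum(!y) == 0) {
    warning("AUROC undefined with a single class")
    return(NA_real_)
  }
  rp <- roc_points(scores, labels, positive)
  sum(diff(rp$fpr) * (utils::head(rp$tpr, -1) + utils::tail(rp$tpr, -1)) / 2)
}

#' Stratified hold-out split
#'
#' Reserves `max(10, ceil(0.10 N))` patients for final testing, allocated
#' greedily so that the hold-out's class, mini-cohort and PFS-tertile
#' proportions each match the full cohort within one patient.
#'
#' @param meta patient-level data.frame with `patient_id`, `mini_cohort`
#'   and `pfs_months` columns.
#' @param labels named binary vector per patient (the modeling outcome).
#' @param seed RNG seed for within-stratum draws.
#' @return list with `train` and `holdout` patient id vectors.
#' @export
make_holdout_split <- function(meta, labels, seed = 1L) {
  meta <- meta[!duplicated(meta$patient_id), ]
  n <- nrow(meta)
  if (n < 20L) stop("need at least 20 patients to split")
  n_hold <- max(10L, ceiling(0.10 * n))
  tert <- cut(rank(meta$pfs_months, ties.method = "first"),
              breaks = 3, labels = c("T1", "T2", "T3"))
  cls <- as.character(labels[meta$patient_id])
  coh <- as.character(meta$mini_cohort)
  trt <- as.character(tert)
  frac <- n_hold / n
  set.seed(seed)
  # greedy allocation: repeatedly take the patient whose class, cohort
  # and PFS-tertile are all still under their proportional targets,
  # preferring the largest combined deficit
  tgt_cls <- frac * table(cls); tgt_coh <- frac * table(coh)
  tgt_trt <- frac * table(trt)
  got_cls <- tgt_cls * 0; got_coh <- tgt_coh * 0; got_trt <- tgt_trt * 0
  avail <- sample(meta$patient_id)   # seeded shuffle for tie-breaking
  hold <- character(0)
  for (step in seq_len(n_hold)) {
    idx <- match(avail, meta$patient_id)
    deficit <- (tgt_cls[cls[idx]] - got_cls[cls[idx]]) +
      (tgt_coh[coh[idx]] - got_coh[coh[idx]]) +
      (tgt_trt[trt[idx]] - got_trt[trt[idx]])
    pick <- avail[which.max(deficit)]
    i <- match(pick, meta$patient_id)
    got_cls[cls[i]] <- got_cls[cls[i]] + 1
    got_coh[coh[i]] <- got_coh[coh[i]] + 1
    got_trt[trt[i]] <- got_trt[trt[i]] + 1
    hold <- c(hold, pick)
    avail <- setdiff(avail, pick)
  }
  dev <- max(abs(got_cls - tgt_cls), abs(got_coh - tgt_coh))
  if (dev > 1)
    warning("stratum too small for exact representation; ",
            "best-effort allocation (max deviation ",
            format(dev, digits = 2), ")")
  list(train = setdiff(meta$patient_id, hold), holdout = hold)
}

# Standardize columns=genes feature matrix with train statistics
std_fit <- function(x) {
  mu <- colMeans(x); sd <- apply(x, 2L, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}
std_apply <- function(x, st) sweep(sweep(x, 2L, st$mu), 2L, st$sd, "/")

# Single-architecture fit on a standardized feature matrix.  Regularized
# logistic models pick lambda on the glmnet path by BIC (deviance +
# df log n), a deterministic in-sample criterion; the SVM is linear with
# cost 1 so its coefficients stay comparable to the logistic ones.
fit_arch <- function(x, y, architecture) {
  y <- as.factor(y)
  if (architecture %in% c("lasso_logistic", "ridge_logistic")) {
    if (ncol(x) == 1L) {   # glmnet needs >= 2 features; plain logistic
      fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
      b <- unname(stats::coef(fit))
      b[!is.finite(b)] <- 0
      return(list(architecture = architecture,
                  coefficients = stats::setNames(b[2L], colnames(x)),
                  intercept = b[1L], lambda = 0, levels = levels(y)))
    }
    alpha <- if (architecture == "lasso_logistic") 1 else 0
    fit <- suppressWarnings(
      glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                     nlambda = 30, standardize = FALSE))
    dev <- (1 - fit$dev.ratio) * fit$nulldev
    bic <- dev + fit$df * log(nrow(x))
    j <- which.min(bic)
    b <- as.numeric(fit$beta[, j])
    list(architecture = architecture, coefficients =
           stats::setNames(b, rownames(fit$beta)),
         intercept = fit$a0[[j]], lambda = fit$lambda[j],
         levels = levels(y))
  } else if (architecture == "svm") {
    fit <- e1071::svm(x, y, kernel = "linear", cost = 1, scale = FALSE)
    w <- drop(t(fit$coefs) %*% fit$SV)
    # orient decision values so larger = second level
    flip <- if (fit$labels[1L] == 2L) 1 else -1
    list(architecture = "svm",
         coefficients = stats::setNames(flip * w, colnames(x)),
         intercept = flip * -fit$rho, levels = levels(y))
  } else stop("unknown architecture: ", architecture)
}

score_arch <- function(par, x) {
  drop(x %*% par$coefficients) + par$intercept
}

#' Choose the gene count k and architecture by leave-one-out CV
#'
#' For each k in `k_grid` and each architecture, every training patient
#' is left out in turn, the model is fit on the rest using the top-k
#' candidate genes, and the held-out patient is scored; the AUROC over
#' pooled leave-one-out predictions is recorded.  The maximizing (k,
#' architecture) is selected, ties resolved toward smaller k then the
#' architecture order lasso < ridge < svm (so logistic regression is
#' reported when it ties the SVM).
#'
#' @param fc `paired_l2fc` (gene x patient) restricted to training
#'   patients, or a full matrix plus `train` ids.
#' @param labels named binary vector.
#' @param candidates ordered candidate gene list (from
#'   [rank_candidates()]).
#' @param architectures subset of
#'   `c("lasso_logistic", "ridge_logistic", "svm")`.
#' @param k_grid candidate k values (default `1:length(candidates)`).
#' @return list with `k`, `architecture`, `auroc`, and the full `curve`
#'   data.frame (k, architecture, auroc).
#' @export
loocv_select_k <- function(fc, labels, candidates,
                           architectures = c("lasso_logistic",
                                             "ridge_logistic", "svm"),
                           k_grid = NULL) {
  stopifnot(length(candidates) > 0)
  x_all <- t(unclass(fc)[candidates, , drop = FALSE])
  patients <- rownames(x_all)
  if (length(patients) < 10L) stop("need >= 10 training patients")
  y <- as.factor(labels[patients])
  if (is.null(k_grid)) k_grid <- seq_along(candidates)
  arch_order <- c("lasso_logistic", "ridge_logistic", "svm")
  architectures <- arch_order[arch_order %in% architectures]
  curve <- expand.grid(k = k_grid, architecture = architectures,
                       stringsAsFactors = FALSE)
  curve$auroc <- NA_real_
  for (r in seq_len(nrow(curve))) {
    k <- curve$k[r]; arch <- curve$architecture[r]
    xs <- x_all[, seq_len(k), drop = FALSE]
    sc <- vapply(seq_along(patients), function(i) {
      xtr <- xs[-i, , drop = FALSE]; ytr <- y[-i]
      if (nlevels(droplevels(ytr)) < 2L)
        return(mean(ytr == levels(y)[2L]))   # prior-probability fallback
      st <- std_fit(xtr)
      par <- fit_arch(std_apply(xtr, st), ytr, arch)
      # intercept excluded: a per-fold prior shift would otherwise leak
      # the left-out label into pooled LOO rankings
      drop(std_apply(xs[i, , drop = FALSE], st) %*% par$coefficients)
    }, numeric(1))
    curve$auroc[r] <- auroc(sc, y)
  }
  best <- curve[order(-curve$auroc, curve$k,
                      match(curve$architecture, arch_order)), ][1L, ]
  list(k = best$k, architecture = best$architecture, auroc = best$auroc,
       curve = curve)
}

#' Fit the final classifier on the full training set
#'
#' @param fc `paired_l2fc` (gene x patient).
#' @param labels named binary vector; the second factor level is treated
#'   as the positive class.
#' @param genes gene panel (<= 25).
#' @param architecture one of `"lasso_logistic"`, `"ridge_logistic"`,
#'   `"svm"`.
#' @param outcome label describing the outcome (`"pfs_class"` or
#'   `"assay"`).
#' @return a `fitted_model` with signed coefficients, intercept, the
#'   standardization used, training ids and metadata.
#' @export
fit_final <- function(fc, labels, genes, architecture = "lasso_logistic",
                      outcome = "pfs_class") {
  stopifnot(length(genes) <= 25L)
  x <- t(unclass(fc)[genes, , drop = FALSE])
  y <- as.factor(labels[rownames(x)])
  st <- std_fit(x)
  par <- fit_arch(std_apply(x, st), y, architecture)
  if (any(!is.finite(par$coefficients)))
    stop("non-finite coefficients: fit did not converge")
  structure(list(architecture = architecture, genes = genes,
                 coefficients = par$coefficients,
                 intercept = par$intercept, lambda = par$lambda,
                 standardize = st, k = length(genes),
                 training_ids = rownames(x), outcome = outcome,
                 levels = par$levels),
            class = "fitted_model")
}

#' @export
predict.fitted_model <- function(object, fc, type = c("score", "class"),
                                 ...) {
  type <- match.arg(type)
  x <- t(unclass(fc)[object$genes, , drop = FALSE])
  sc <- score_arch(object, std_apply(x, object$standardize))
  if (type == "score") return(sc)
  factor(ifelse(sc > 0, object$levels[2L], object$levels[1L]),
         levels = object$levels)
}

#' Evaluate a fitted model on labeled subsets
#'
#' AUROC (midrank; ties averaged) plus ROC points per subset, with
#' subsets containing a single class masked (NA) rather than erroring.
#'
#' @param model a `fitted_model`.
#' @param fc `paired_l2fc` covering all evaluated patients.
#' @param labels named binary vector.
#' @param subsets named list of patient id vectors (e.g. train, holdout,
#'   one per mini-cohort).
#' @return list with `report` data.frame (subset, auroc, n), `roc` (list
#'   of ROC point frames) and `scores` per patient.
#' @export
evaluate_model <- function(model, fc, labels, subsets) {
  sc_all <- predict(model, fc)
  names(sc_all) <- colnames(fc)
  rep_rows <- list(); rocs <- list()
  for (nm in names(subsets)) {
    ids <- intersect(subsets[[nm]], names(sc_all))
    y <- as.factor(labels[ids])
    a <- if (nlevels(droplevels(y)) < 2L) {
      warning("subset '", nm, "' has one class: AUROC masked")
      NA_real_
    } else auroc(sc_all[ids], y)
    rep_rows[[nm]] <- data.frame(subset = nm, auroc = a,
                                 n = length(ids))
    rocs[[nm]] <- if (!is.na(a)) roc_points(sc_all[ids], y) else NULL
  }
  list(report = do.call(rbind, c(rep_rows, make.row.names = FALSE)),
       roc = rocs, scores = sc_all)
}
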