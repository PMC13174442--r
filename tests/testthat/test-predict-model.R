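test_that("AUROC equals the Mann-Whitney U identity (ties included)", {
  u_auc <- function(scores, y) {
    # U / (n1 n0) with midranks
    r <- rank(scores)
    n1 <- sum(y); n0 <- sum(!y)
    (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  set.seed(1)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    scores <- sample(1:8, n, replace = TRUE) + rnorm(n, 0, 0.01 *
                                                       rbinom(1, 1, 0.5))
    lab <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
    expect_equal(auroc(scores, lab), u_auc(scores, y))
  }
  # perfect ordering
  expect_equal(auroc(1:10, rep(c("a", "b"), each = 5), positive = "b"), 1)
  expect_warning(a <- auroc(1:4, rep("a", 4)), "single class")
  expect_true(is.na(a))
})

test_that("AUROC agrees with an external ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  for (i in 1:20) {
    n <- 30
    y <- factor(sample(c("a", "b"), n, replace = TRUE,
                       prob = c(0.4, 0.6)))
    if (nlevels(droplevels(y)) < 2) next
    s <- rnorm(n) + (y == "b")
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, levels = c("a", "b"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(auroc(s, y, positive = "b"), ref)
  }
})

test_that("permuted labels give AUROC 0.5 on average", {
  set.seed(3)
  scores <- rnorm(60)
  aucs <- replicate(500, {
    lab <- sample(rep(c("a", "b"), 30))
    auroc(scores, lab, positive = "b")
  })
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 1e-12)
})

test_that("hold-out split sizes follow the max(10, 10%) rule", {
  mk_meta <- function(n, n_cohorts = 4) {
    data.frame(patient_id = paste0("p", seq_len(n)),
               mini_cohort = rep(paste0("C", seq_len(n_cohorts)),
                                 length.out = n),
               pfs_months = rexp(n, 1 / 12), stringsAsFactors = FALSE)
  }
  set.seed(4)
  m120 <- mk_meta(120)
  lab120 <- setNames(rep(c("long", "short"), 60), m120$patient_id)
  sp <- make_holdout_split(m120, lab120, seed = 1)
  expect_length(sp$holdout, 12)
  expect_length(intersect(sp$train, sp$holdout), 0)
  expect_setequal(c(sp$train, sp$holdout), m120$patient_id)

  m60 <- mk_meta(60)
  lab60 <- setNames(rep(c("long", "short"), 30), m60$patient_id)
  expect_length(make_holdout_split(m60, lab60, seed = 1)$holdout, 10)
  expect_error(make_holdout_split(mk_meta(15),
                                  setNames(rep(c("a", "b"), c(8, 7)),
                                           paste0("p", 1:15)), 1),
               "20 patients")
})

test_that("hold-out class and cohort proportions track the full cohort", {
  set.seed(5)
  n <- 140
  meta <- data.frame(patient_id = paste0("p", 1:n),
                     mini_cohort = rep(c("A", "B", "C", "D", "E", "F"),
                                       times = c(35, 17, 31, 15, 20, 22)),
                     pfs_months = rexp(n, 1 / 12))
  lab <- setNames(rep(c("long", "short"), 70), meta$patient_id)
  sp <- make_holdout_split(meta, lab, seed = 9)
  h <- sp$holdout
  frac <- length(h) / n
  # class proportions within 1 patient of proportional
  for (cl in c("long", "short"))
    expect_lte(abs(sum(lab[h] == cl) - frac * sum(lab == cl)), 1)
  for (co in unique(meta$mini_cohort)) {
    n_co <- sum(meta$mini_cohort == co)
    got <- sum(meta$mini_cohort[match(h, meta$patient_id)] == co)
    expect_lte(abs(got - frac * n_co), 1)
  }
  # deterministic given seed
  expect_identical(sp, make_holdout_split(meta, lab, seed = 9))
})

test_that("LOOCV selects a single separating gene with AUROC 1", {
  set.seed(6)
  genes <- paste0("g", 1:5); pats <- paste0("p", 1:30)
  x <- matrix(rnorm(150), 5, 30, dimnames = list(genes, pats))
  lab <- setNames(rep(c("long", "short"), 15), pats)
  x["g1", lab == "short"] <- x["g1", lab == "short"] + 10
  sel <- loocv_select_k(toy_fc(x, genes, pats), lab, c("g1", "g2", "g3"))
  expect_equal(sel$k, 1)
  expect_equal(sel$auroc, 1)
  expect_equal(sel$architecture, "lasso_logistic")  # tie -> lasso first
  expect_equal(nrow(sel$curve), 3 * 3)
})

test_that("all-noise candidates give near-chance LOOCV AUROC", {
  set.seed(7)
  ok <- replicate(15, {
    pats <- paste0("p", 1:40)
    x <- matrix(rnorm(6 * 40), 6, 40,
                dimnames = list(paste0("g", 1:6), pats))
    lab <- setNames(sample(rep(c("a", "b"), 20)), pats)
    sel <- loocv_select_k(toy_fc(x, rownames(x), pats), lab,
                          paste0("g", 1:3),
                          architectures = "lasso_logistic")
    sel$auroc >= 0.3 && sel$auroc <= 0.7
  })
  expect_gte(mean(ok), 0.8)
})

test_that("final fits are deterministic and ridge shrinks monotonically", {
  set.seed(8)
  genes <- paste0("g", 1:4); pats <- paste0("p", 1:40)
  x <- matrix(rnorm(160), 4, 40, dimnames = list(genes, pats))
  lab <- setNames(rep(c("long", "short"), 20), pats)
  x["g1", lab == "short"] <- x["g1", lab == "short"] + 2
  fc <- toy_fc(x, genes, pats)
  m1 <- fit_final(fc, lab, genes, "lasso_logistic")
  m2 <- fit_final(fc, lab, genes, "lasso_logistic")
  expect_identical(m1$coefficients, m2$coefficients)
  expect_true(all(is.finite(m1$coefficients)))
  expect_lte(m1$k, 25)
  # ridge coefficient magnitude decreases as lambda grows
  xs <- t(unclass(fc)); y <- factor(lab[colnames(fc)])
  fits <- glmnet::glmnet(scale(xs), y, family = "binomial", alpha = 0,
                         lambda = c(10, 1, 0.1, 0.01))
  norms <- sqrt(colSums(as.matrix(fits$beta)^2))
  expect_true(all(diff(norms) >= 0))  # lambda stored decreasing
  # separable training data classified perfectly at threshold 0
  xsep <- x; xsep["g1", ] <- ifelse(lab == "short", 5, -5)
  msep <- fit_final(toy_fc(xsep, genes, pats), lab, genes,
                    "lasso_logistic")
  pred <- predict(msep, toy_fc(xsep, genes, pats), type = "class")
  expect_equal(as.character(pred), unname(lab[pats]))
})

test_that("evaluation reports per-subset AUROC and masks one-class subsets", {
  set.seed(9)
  genes <- paste0("g", 1:3); pats <- paste0("p", 1:30)
  x <- matrix(rnorm(90), 3, 30, dimnames = list(genes, pats))
  lab <- setNames(rep(c("long", "short"), 15), pats)
  x["g1", lab == "short"] <- x["g1", lab == "short"] + 6
  fc <- toy_fc(x, genes, pats)
  m <- fit_final(fc, lab, genes, "lasso_logistic")
  ev <- suppressWarnings(
    evaluate_model(m, fc, lab, list(all = pats,
                                    single = pats[lab == "long"])))
  expect_equal(ev$report$auroc[ev$report$subset == "all"], 1)
  expect_true(is.na(ev$report$auroc[ev$report$subset == "single"]))
  rp <- ev$roc$all
  expect_equal(rp$fpr[1], 0); expect_equal(rp$tpr[1], 0)
  expect_equal(rp$fpr[nrow(rp)], 1); expect_equal(rp$tpr[nrow(rp)], 1)
})

test_that("feature selection and LOOCV never touch hold-out patients", {
  sim <- generate_cohort(small_config(seed = 61L))
  meta <- sim$meta
  co <- sim$cohorts$RS1
  fc <- compute_log2fc(normalize_expression(co$pre, "CPM"),
                       normalize_expression(co$post, "CPM"),
                       meta[meta$mini_cohort == "RS1", ])
  co2 <- sim$cohorts$NS1
  fc2 <- compute_log2fc(normalize_expression(co2$pre, "CPM"),
                        normalize_expression(co2$post, "CPM"),
                        meta[meta$mini_cohort == "NS1", ])
  shared <- intersect(rownames(fc), rownames(fc2))
  fc_all <- paired_l2fc(cbind(unclass(fc)[shared, ],
                              unclass(fc2)[shared, ]), 1, "CPM")
  lab <- pfs_class_labels(meta)
  sp <- make_holdout_split(meta[meta$patient_id %in% colnames(fc_all), ],
                           lab, seed = 3)
  fc_tr <- paired_l2fc(unclass(fc_all)[, sp$train], 1, "CPM")
  cohort_of <- setNames(meta$mini_cohort[match(colnames(fc_all),
                                               meta$patient_id)],
                        colnames(fc_all))
  pft <- bootstrap_predictive_frequency(fc_tr, lab, cohort_of, B = 20,
                                        top_m = 10, seed = 1)
  cand <- rank_candidates(pft, max_features = 5)
  sel <- loocv_select_k(fc_tr, lab, cand,
                        architectures = "lasso_logistic",
                        k_grid = c(1, 3, 5))
  m <- fit_final(fc_tr, lab, cand[seq_len(sel$k)], sel$architecture)
  expect_length(intersect(m$training_ids, sp$holdout), 0)
  expect_true(all(colnames(fc_tr) %in% sp$train))
})
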