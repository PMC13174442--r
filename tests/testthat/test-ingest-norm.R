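test_that("TSV and MTX round-trips preserve ids and values", {
  m <- toy_expr(matrix(c(1, 2, 3, 4), 2), genes = c("gB", "gA"))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, p)
  m2 <- read_expression(p, "tsv_matrix", unit = "raw_count",
                        assay = "rnaseq")
  expect_identical(gene_ids(m2), c("gB", "gA"))  # file order kept
  expect_equal(m2$values, m$values)

  # MTX with an implicit zero
  sm <- Matrix::sparseMatrix(i = c(1, 1, 2), j = c(1, 2, 2),
                             x = c(5, 1, 2), dims = c(2, 2))
  mp <- withr::local_tempfile(fileext = ".mtx")
  rp <- withr::local_tempfile(); cp <- withr::local_tempfile()
  Matrix::writeMM(sm, mp)
  writeLines(c("g1", "g2"), rp); writeLines(c("c1", "c2"), cp)
  m3 <- read_expression(mp, "mtx_triplet", unit = "raw_count",
                        assay = "scrnaseq", row_ids = rp, col_ids = cp)
  expect_equal(unname(m3$values), matrix(c(5, 0, 1, 2), 2))
})

test_that("duplicate gene rows are rejected by name", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1", "gX\t1", "gX\t2"), p)
  expect_error(read_expression(p, "tsv_matrix", unit = "raw_count",
                               assay = "rnaseq"), "gX")
})

test_that("expr_mat validates unit constraints", {
  expect_error(toy_expr(matrix(-1:2, 2)), "negative")
  expect_error(toy_expr(matrix(c(1, NA, 2, 3), 2)), "missing")
  tpm <- matrix(c(4e5, 6e5, 5e5, 5e5), 2)
  expect_s3_class(toy_expr(tpm, unit = "TPM"), "expr_mat")
  expect_error(toy_expr(tpm * 1.01, unit = "TPM"), "sum")
})

test_that("normalization closed forms hold", {
  m <- toy_expr(matrix(c(1, 1, 2), 3))
  cpm <- normalize_expression(m, "CPM")
  expect_equal(unname(cpm$values[, 1]), c(250000, 250000, 500000))

  m2 <- toy_expr(matrix(c(10, 1e6 - 10), 2))
  rpkm <- normalize_expression(m2, "RPKM",
                               lengths = c(g1 = 1000, g2 = 500))
  expect_equal(unname(rpkm$values[1, 1]), 10)

  set.seed(1)
  m3 <- toy_expr(matrix(rpois(40, 50), 10))
  tpm <- normalize_expression(m3, "TPM",
                              lengths = setNames(runif(10, 200, 5000),
                                                 paste0("g", 1:10)))
  expect_equal(unname(colSums(tpm$values)), rep(1e6, 4))
  expect_equal(tpm$unit, "TPM")

  m0 <- toy_expr(matrix(c(1, 1, 0, 0), 2))
  expect_error(normalize_expression(m0, "CPM"), "library")
  expect_error(normalize_expression(m3, "RPKM"), "lengths")
})

test_that("within-assay scaling follows the documented conventions", {
  m <- toy_expr(matrix(c(3, 1, 2, 5, 5, 5), 2, byrow = TRUE),
                samples = c("a", "b", "c"))
  pc <- within_assay_scale(m, "percentile")
  expect_equal(unname(pc$values[1, ]), c(1, 0, 0.5))
  expect_equal(unname(pc$values[2, ]), c(0.5, 0.5, 0.5))  # constant gene
  zs <- within_assay_scale(m, "zscore")
  expect_equal(unname(zs$values[2, ]), c(0, 0, 0))
  # already standardized gene is unchanged
  x <- c(-1, 0, 1) / sd(c(-1, 0, 1))
  m2 <- suppressWarnings(toy_expr(rbind(x, x), unit = "scaled"))
  expect_equal(unname(within_assay_scale(m2, "zscore")$values[1, ]),
               unname(x))
  expect_equal(pc$unit, "scaled")
})

test_that("percentile scaling is invariant to monotone transforms", {
  set.seed(7)
  v <- matrix(rexp(60), 6, 10)
  m <- toy_expr(v)
  m_t <- toy_expr(exp(2 * v + 1))
  expect_equal(within_assay_scale(m, "percentile")$values,
               within_assay_scale(m_t, "percentile")$values)
})

test_that("paired log2FC matches its closed form and is antisymmetric", {
  pats <- paste0("p", 1:3)
  meta <- toy_meta(pats)
  pre <- toy_expr(matrix(c(1, 2, 4, 8, 16, 32), 2),
                  samples = paste0(pats, "_pre"))
  post <- toy_expr(2 * pre$values, samples = paste0(pats, "_post"))
  fc <- compute_log2fc(pre, post, meta, pseudocount = 0)
  expect_equal(unname(unclass(fc)), matrix(1, 2, 3), ignore_attr = TRUE)
  fc0 <- compute_log2fc(pre, pre2 <- toy_expr(pre$values,
                          samples = paste0(pats, "_post")), meta)
  expect_equal(max(abs(fc0)), 0)
  # pre = 0, post = pseudocount -> log2(2 eps / eps) = 1
  eps <- 0.25
  prez <- toy_expr(matrix(0, 1, 3), samples = paste0(pats, "_pre"))
  postz <- toy_expr(matrix(eps, 1, 3), samples = paste0(pats, "_post"))
  expect_equal(unname(unclass(compute_log2fc(prez, postz, meta,
                                             pseudocount = eps))[1, ]),
               rep(1, 3))
  # antisymmetry under swapping pre and post, random inputs
  set.seed(3)
  a <- toy_expr(matrix(rexp(30), 10), samples = paste0(pats, "_pre"))
  b <- toy_expr(matrix(rexp(30), 10), samples = paste0(pats, "_post"))
  swap <- function(m, suf) toy_expr(m$values, samples = paste0(pats, suf))
  f1 <- compute_log2fc(a, b, meta)
  f2 <- compute_log2fc(swap(b, "_pre"), swap(a, "_post"), meta)
  expect_equal(unclass(f1), -unclass(f2))
})

test_that("log2FC rejects mismatched or unpaired input", {
  pats <- paste0("p", 1:3)
  meta <- toy_meta(pats)
  pre <- toy_expr(matrix(1, 2, 3), samples = paste0(pats, "_pre"))
  post <- toy_expr(matrix(1, 2, 3), samples = paste0(pats, "_post"),
                   unit = "CPM")
  expect_error(compute_log2fc(pre, post, meta), "mismatch")
  meta2 <- meta[meta$sample_id != "p3_post", ]
  post2 <- toy_expr(matrix(1, 2, 3), samples = paste0(pats, "_post"))
  expect_error(compute_log2fc(pre, post2, meta2), "unpaired")
})

test_that("pseudobulk sums cells within sample and group", {
  counts <- matrix(c(1, 2, 3, 4, 10, 20), 2,
                   dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  labs <- data.frame(cell_id = c("c1", "c2", "c3"),
                     sample_id = c("s1", "s1", "s2"),
                     cell_type = c("T", "T", "B"))
  pb <- pseudobulk(counts, labs, "cell_type")
  expect_equal(unname(pb$values[, "s1|T"]), c(4, 6))
  expect_equal(unname(pb$values[, "s2|B"]), c(10, 20))
  # group=all equals summing the per-type columns
  pb_all <- pseudobulk(counts, labs, "all")
  agg <- t(rowsum(t(pb$values), sub("\\|.*", "", colnames(pb$values))))
  expect_equal(pb_all$values[, colnames(agg)], agg)
  expect_equal(pb_all$assay, "scrnaseq_pseudobulk")
  expect_error(pseudobulk(counts, labs[-1, ], "all"), "c1")
})

test_that("counting modes pick the documented isoforms", {
  exons <- data.frame(
    gene = "gA", isoform = rep(c("gA.1", "gA.2"), each = 2),
    contig = "chr1", start = c(0, 500, 0, 900),
    end = c(200, 700, 200, 1100))
  probes <- data.frame(gene = "gA", contig = "chr1",
                       start = 950, end = 1050)
  gm <- gene_model(exons, probes)
  # isoform A.1 highest expressed; probe sits on A.2's distal exon
  iso <- toy_expr(matrix(c(100, 10, 120, 12), 2),
                  genes = c("gA.1", "gA.2"))
  expect_equal(unname(aggregate_counts(iso, gm, "all_isoforms")$values),
               matrix(c(110, 132), 1))
  expect_equal(unname(aggregate_counts(iso, gm,
                                       "highest_expressed_isoform")$values),
               matrix(c(100, 120), 1))
  expect_equal(unname(aggregate_counts(iso, gm,
                                       "probe_matched_isoform")$values),
               matrix(c(10, 12), 1))
  exon_counts <- matrix(c(60, 40, 4, 6, 70, 50, 5, 7), 4,
                        dimnames = list(c("gA.1:1", "gA.1:2", "gA.2:1",
                                          "gA.2:2"), c("s1", "s2")))
  expect_equal(unname(aggregate_counts(iso, gm, "probe_matched_exon",
                                       exon_counts = exon_counts)$values),
               matrix(c(6, 7), 1))
})

test_that("single-isoform single-exon genes agree across modes; ties logged", {
  exons <- data.frame(gene = "gB", isoform = "gB.1", contig = "chr1",
                      start = 0, end = 300)
  probes <- data.frame(gene = "gB", contig = "chr1", start = 100,
                       end = 200)
  gm <- gene_model(exons, probes)
  iso <- toy_expr(matrix(c(7, 9), 1), genes = "gB.1")
  ec <- matrix(c(7, 9), 1, dimnames = list("gB.1:1", c("s1", "s2")))
  res <- lapply(c("all_isoforms", "highest_expressed_isoform",
                  "probe_matched_isoform", "probe_matched_exon"),
                function(md) aggregate_counts(iso, gm, md,
                                              exon_counts = ec)$values)
  for (r in res[-1]) expect_equal(r, res[[1]])

  # equal probe overlap on two isoforms -> lexicographically smallest
  exons2 <- data.frame(gene = "gC", isoform = c("gC.2", "gC.1"),
                       contig = "chr1", start = 0, end = 300)
  probes2 <- data.frame(gene = "gC", contig = "chr1", start = 0, end = 100)
  gm2 <- gene_model(exons2, probes2)
  iso2 <- toy_expr(matrix(c(5, 50), 2, 1), genes = c("gC.1", "gC.2"))
  expect_message(
    out <- aggregate_counts(iso2, gm2, "probe_matched_isoform"),
    "tie")
  expect_equal(unname(out$values[1, 1]), 5)  # gC.1 chosen
})

test_that("gene_model validates exon and probe geometry", {
  bad <- data.frame(gene = "g", isoform = "g.1", contig = "c",
                    start = c(0, 100), end = c(150, 200))
  expect_error(gene_model(bad), "overlap")
  ok <- data.frame(gene = "g", isoform = "g.1", contig = "c",
                   start = 0, end = 100)
  expect_error(gene_model(ok, data.frame(gene = "g", contig = "c",
                                         start = 500, end = 600)),
               "probe")
  expect_equal(unname(isoform_lengths(gene_model(ok))["g.1"]), 100)
})
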