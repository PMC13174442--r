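#' Expression matrix with unit and assay tags
#'
#' Lightweight container for a gene x sample expression matrix on a pre-log
#' scale, carrying the measurement unit and the assay that produced it.  It
#' is the universal carrier between pipeline stages: normalization, scaling,
#' counting-mode aggregation and paired fold-change computation all consume
#' and return `expr_mat` objects.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).  Values must be
#'   non-negative for all units except `"scaled"`.
#' @param unit one of `"raw_count"`, `"CPM"`, `"RPKM"`, `"TPM"`,
#'   `"intensity"`, `"scaled"`.
#' @param assay one of `"rnaseq"`, `"nanostring"`, `"microarray"`,
#'   `"scrnaseq"`, `"scrnaseq_pseudobulk"`.
#' @return an object of class `expr_mat` with elements `values`, `unit`,
#'   `assay`.
#' @export
expr_mat <- function(values, unit, assay) {
  unit <- match.arg(unit, c("raw_count", "CPM", "RPKM", "TPM",
                            "intensity", "scaled"))
  assay <- match.arg(assay, c("rnaseq", "nanostring", "microarray",
                              "scrnaseq", "scrnaseq_pseudobulk"))
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicated gene id(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(values))
    stop("expression matrix contains missing values")
  if (unit != "scaled" && any(values < 0))
    stop("negative values are not allowed for unit '", unit, "'")
  if (unit == "TPM") {
    cs <- colSums(values)
    if (any(abs(cs - 1e6) > 1e-6 * 1e6))
      stop("TPM columns must sum to 1e6")
  }
  structure(list(values = values, unit = unit, assay = assay),
            class = "expr_mat")
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("expr_mat: %d genes x %d samples [unit=%s, assay=%s]\n",
              nrow(x$values), ncol(x$values), x$unit, x$assay))
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param x an `expr_mat`
#' @return character vector of ids
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read an expression matrix from disk
#'
#' Supports a plain TSV matrix (genes in rows, header row of sample ids,
#' first column gene ids) and MatrixMarket triplet format accompanied by
#' row- and column-id files (one id per line).
#'
#' @param path file path (for `mtx_triplet`, the `.mtx` file).
#' @param format `"tsv_matrix"` or `"mtx_triplet"`.
#' @param unit,assay tags for the resulting [expr_mat()]; typically read
#'   from a sidecar config (see [read_sidecar()]).
#' @param row_ids,col_ids paths to id files for `mtx_triplet`.
#' @return an [expr_mat()]
#' @export
read_expression <- function(path, format = c("tsv_matrix", "mtx_triplet"),
                            unit, assay, row_ids = NULL, col_ids = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv_matrix") {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    ids <- as.character(tab[[1L]])
    dup <- ids[duplicated(ids)]
    if (length(dup))
      stop("duplicate gene row(s) in ", path, ": ",
           paste(unique(dup), collapse = ", "))
    m <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric (ragged?) matrix in ", path)
    rownames(m) <- ids
  } else {
    if (is.null(row_ids) || is.null(col_ids))
      stop("mtx_triplet requires row_ids and col_ids files")
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(row_ids)
    colnames(m) <- readLines(col_ids)
  }
  expr_mat(m, unit = unit, assay = assay)
}

#' Write an expression matrix as TSV
#' @param x an `expr_mat`
#' @param path output path
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene_id = gene_ids(x), x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a YAML sidecar declaring unit and assay for data files
#' @param path YAML file with fields `unit` and `assay`
#' @return named list
#' @export
read_sidecar <- function(path) {
  sc <- yaml::read_yaml(path)
  if (is.null(sc$unit) || is.null(sc$assay))
    stop("sidecar must declare 'unit' and 'assay'")
  sc
}
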