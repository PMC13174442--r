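#' Soft-thresholded adjacency from expression
#'
#' Unsigned weighted network: `a_ij = |cor_ij|^beta` over samples, with
#' unit diagonal.  Constant genes are dropped with a message.
#'
#' @param expr an [expr_mat()] or gene x sample matrix with >= 4 samples.
#' @param beta soft-threshold power (default 6).
#' @return symmetric adjacency matrix in \[0, 1\].
#' @export
build_adjacency <- function(expr, beta = 6) {
  v <- if (inherits(expr, "expr_mat")) expr$values else as.matrix(expr)
  if (ncol(v) < 4L) stop("need >= 4 samples")
  keep <- apply(v, 1L, stats::sd) > 0
  if (!any(keep)) stop("all genes constant")
  if (any(!keep))
    message(sum(!keep), " constant gene(s) dropped")
  v <- v[keep, , drop = FALSE]
  a <- abs(stats::cor(t(v)))^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix similarity
#'
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) /
#' (min(k_i, k_j) + 1 - a_ij)` with `k_i = sum_{u != i} a_iu`, diagonal
#' fixed at 1.  Measures interconnectedness by combining the direct edge
#' with the shared neighborhood.
#'
#' @param adjacency symmetric matrix in \[0, 1\] with unit diagonal.
#' @return TOM similarity matrix in \[0, 1\].
#' @export
tom_similarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  diag(a) <- 1
  k <- rowSums(a) - 1
  # (A^2)_ij counts u over ALL indices; remove u = i and u = j (each
  # contributes a_ij because the diagonal is 1), then add back the edge
  numer <- a %*% a - 2 * a + a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- numer / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Contrast a focal gene's TOM neighborhood between two conditions
#'
#' For every gene, the change in TOM similarity with the focal gene
#' between the post- and pre-treatment networks and the maximum of the
#' two.  Genes whose maximum similarity exceeds the `shared_q` quantile
#' of all maxima are the focal gene's partners; among partners, those
#' whose |delta| stays below the `shared_q` quantile of partner |delta|
#' are classified `shared`, the rest `post_only` (delta > 0) or
#' `pre_only`; non-partners are `none`.
#'
#' @param pre,post TOM matrices over the same gene space.
#' @param focal focal gene id, present in both.
#' @param shared_q quantile defining partners and shared-vs-specific
#'   (default 0.9).
#' @return data.frame per gene: `delta_tom`, `max_tom`, `class`.
#' @export
focal_delta <- function(pre, post, focal, shared_q = 0.9) {
  if (!focal %in% rownames(pre) || !focal %in% rownames(post))
    stop("focal gene absent from a network")
  genes <- intersect(rownames(pre), rownames(post))
  genes <- setdiff(genes, focal)
  d <- post[focal, genes] - pre[focal, genes]
  mx <- pmax(pre[focal, genes], post[focal, genes])
  part_cut <- stats::quantile(mx, shared_q)
  partner <- mx > part_cut
  cls <- rep("none", length(genes))
  if (any(partner)) {
    d_cut <- stats::quantile(abs(d[partner]), shared_q)
    cls[partner] <- ifelse(abs(d[partner]) <= d_cut, "shared",
                           ifelse(d[partner] > 0, "post_only", "pre_only"))
  }
  data.frame(gene = genes, delta_tom = unname(d), max_tom = unname(mx),
             class = factor(cls, levels = c("shared", "pre_only",
                                            "post_only", "none")),
             row.names = NULL, stringsAsFactors = FALSE)
}
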