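# The cells x genes expression container and the standard preprocessing
# steps (per-cell log-normalization, highly-variable-gene selection).

#' Construct a cells x genes expression matrix
#'
#' Lightweight container for a cells x genes matrix with cell/gene
#' identifiers and a layer tag recording what the values are (raw `counts`,
#' `lognorm` after [lognormalize()], or `scaled`).
#'
#' @param values numeric matrix or sparse `Matrix`, cells in rows, genes in
#'   columns.
#' @param cell_ids,gene_ids character identifiers; default to dimnames or
#'   `cell1..n` / `gene1..p`.
#' @param layer one of `"counts"`, `"lognorm"`, `"scaled"`.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, cell_ids = NULL, gene_ids = NULL,
                              layer = c("counts", "lognorm", "scaled")) {
  layer <- match.arg(layer)
  if (!(is.matrix(values) || inherits(values, "Matrix")))
    stopf("`values` must be a matrix")
  if (nrow(values) < 1 || ncol(values) < 1) stopf("`values` must have positive dimensions")
  if (is.null(cell_ids)) cell_ids <- rownames(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- colnames(values)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids); gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values)) stopf("cell_ids length != nrow(values)")
  if (length(gene_ids) != ncol(values)) stopf("gene_ids length != ncol(values)")
  if (anyDuplicated(cell_ids)) stopf("duplicate cell identifiers")
  if (anyDuplicated(gene_ids)) stopf("duplicate gene identifiers")
  if (layer == "counts") {
    v <- if (inherits(values, "Matrix")) values@x else values
    if (length(v) && (min(v) < 0 || any(v != round(v))))
      stopf("counts layer must contain nonnegative integers")
  }
  rownames(values) <- cell_ids
  colnames(values) <- gene_ids
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
                 layer = layer),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d cells x %d genes, layer = %s\n",
              nrow(x$values), ncol(x$values), x$layer))
  invisible(x)
}

#' Per-cell log-normalization of counts
#'
#' Scales every cell to a common total count (`target_sum`) and applies
#' `log(1 + x)`. This is the transformation that defines the "ambient" space
#' used as the reference for all distortion metrics (together with HVG
#' selection, see [select_hvg()]). Cells with zero total counts cannot be
#' normalized; they are dropped with a warning.
#'
#' @param counts an `expression_matrix` with layer `"counts"`.
#' @param target_sum per-cell total after scaling (default `1e4`).
#' @return an `expression_matrix` with layer `"lognorm"` (dense).
#' @export
lognormalize <- function(counts, target_sum = 1e4) {
  if (!inherits(counts, "expression_matrix")) stopf("`counts` must be an expression_matrix")
  if (counts$layer != "counts") stopf("lognormalize() expects the counts layer, got %s", counts$layer)
  if (!is.finite(target_sum) || target_sum <= 0) stopf("`target_sum` must be positive")
  v <- counts$values
  if (inherits(v, "Matrix")) v <- as.matrix(v)
  totals <- rowSums(v)
  keep <- totals > 0
  if (!all(keep)) {
    warnf("excluding %d cell(s) with zero total counts", sum(!keep))
    v <- v[keep, , drop = FALSE]
    totals <- totals[keep]
  }
  if (nrow(v) == 0) stopf("no cells left after excluding zero-total cells")
  out <- log1p(v / totals * target_sum)
  expression_matrix(out, cell_ids = counts$cell_ids[keep],
                    gene_ids = counts$gene_ids, layer = "lognorm")
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of the (log-normalized) values and keeps the
#' top `n_top`, preserving the input gene order among the selected genes.
#' Ties are broken by gene position.
#'
#' @param matrix an `expression_matrix` (intended layer: `"lognorm"`).
#' @param n_top number of genes to keep; must be `<= n_genes`.
#' @return an `expression_matrix` restricted to the selected genes.
#' @export
select_hvg <- function(matrix, n_top) {
  if (!inherits(matrix, "expression_matrix")) stopf("`matrix` must be an expression_matrix")
  n_top <- check_positive_int(n_top, "n_top")
  p <- ncol(matrix$values)
  if (n_top > p) stopf("n_top (%d) exceeds the number of genes (%d)", n_top, p)
  v <- matrix$values
  if (inherits(v, "Matrix")) v <- as.matrix(v)
  vars <- apply(v, 2, stats::var)
  ord <- order(-vars, seq_along(vars))          # variance desc, ties by position
  keep <- sort(ord[seq_len(n_top)])             # preserve input gene order
  expression_matrix(v[, keep, drop = FALSE], cell_ids = matrix$cell_ids,
                    gene_ids = matrix$gene_ids[keep], layer = matrix$layer)
}
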