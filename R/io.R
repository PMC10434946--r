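# File interfaces: Matrix Market counts with sidecar ID files, TSV
# annotations, CSV embeddings with JSON provenance sidecars, CSV shapes,
# and an HDF5 single-cell container dialect (matrix at /X, per-cell labels
# under /obs).

#' Write counts to Matrix Market with sidecar ID files
#'
#' Writes `<prefix>.mtx` (genes stored cell-major as cells x genes),
#' `<prefix>.cells.txt` and `<prefix>.genes.txt` (one identifier per line).
#'
#' @param counts an `expression_matrix` (layer `"counts"`).
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
write_counts_mtx <- function(counts, prefix) {
  if (!inherits(counts, "expression_matrix")) stopf("`counts` must be an expression_matrix")
  m <- counts$values
  if (!inherits(m, "Matrix")) m <- Matrix::Matrix(m, sparse = TRUE)
  paths <- paste0(prefix, c(".mtx", ".cells.txt", ".genes.txt"))
  Matrix::writeMM(m, paths[1])
  writeLines(counts$cell_ids, paths[2])
  writeLines(counts$gene_ids, paths[3])
  invisible(paths)
}

#' Read counts from Matrix Market with sidecar ID files
#'
#' @param prefix path prefix as used by [write_counts_mtx()], or the path of
#'   the `.mtx` file itself.
#' @param cells,genes optional explicit paths to the identifier files.
#' @return an `expression_matrix` (layer `"counts"`).
#' @export
read_counts_mtx <- function(prefix, cells = NULL, genes = NULL) {
  mtx <- if (grepl("\\.mtx$", prefix)) prefix else paste0(prefix, ".mtx")
  base <- sub("\\.mtx$", "", mtx)
  if (is.null(cells)) cells <- paste0(base, ".cells.txt")
  if (is.null(genes)) genes <- paste0(base, ".genes.txt")
  m <- as(Matrix::readMM(mtx), "CsparseMatrix")
  expression_matrix(m,
                    cell_ids = if (file.exists(cells)) readLines(cells) else NULL,
                    gene_ids = if (file.exists(genes)) readLines(genes) else NULL,
                    layer = "counts")
}

#' Write / read a cell annotation table
#'
#' TSV with columns `cell_id`, `type`, `condition`, `batch`.
#'
#' @param annotations data.frame with at least a `cell_id` column.
#' @param path file path.
#' @return `write_annotations` returns the path invisibly;
#'   `read_annotations` returns the data.frame.
#' @export
write_annotations <- function(annotations, path) {
  if (!"cell_id" %in% names(annotations)) stopf("annotations need a cell_id column")
  utils::write.table(annotations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' Write / read an embedding as CSV with a JSON provenance sidecar
#'
#' CSV columns: `cell_id`, `dim1..dimd`; provenance is written next to it as
#' `<path>.json`.
#'
#' @param embedding an `embedding_matrix`.
#' @param path CSV file path.
#' @return `write_embedding_csv` returns the two paths invisibly;
#'   `read_embedding_csv` returns an `embedding_matrix`.
#' @export
write_embedding_csv <- function(embedding, path) {
  if (!inherits(embedding, "embedding_matrix")) stopf("`embedding` must be an embedding_matrix")
  df <- data.frame(cell_id = rownames(embedding$coords), embedding$coords,
                   check.names = FALSE)
  names(df) <- c("cell_id", paste0("dim", seq_len(embedding$d)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- paste0(path, ".json")
  jsonlite::write_json(embedding$provenance, side, auto_unbox = TRUE, null = "null",
                       na = "null", digits = NA)
  invisible(c(path, side))
}

#' @rdname write_embedding_csv
#' @export
read_embedding_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  coords <- as.matrix(df[, -1, drop = FALSE])
  rownames(coords) <- df$cell_id
  side <- paste0(path, ".json")
  prov <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  prov <- lapply(prov, function(x) if (is.null(x)) NA else x)
  embedding_matrix(coords, provenance = prov)
}

#' Write / read a 2D shape as a CSV point list
#'
#' @param shape a [shape2d()].
#' @param path CSV file path (columns `x`, `y`).
#' @param name,closed metadata used when reading back.
#' @return `write_shape_csv` returns the path invisibly; `read_shape_csv`
#'   returns a `shape2d`.
#' @export
write_shape_csv <- function(shape, path) {
  if (!inherits(shape, "shape2d")) stopf("`shape` must be a shape2d")
  utils::write.csv(as.data.frame(shape$points), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_shape_csv
#' @export
read_shape_csv <- function(path, name = "shape", closed = TRUE) {
  df <- utils::read.csv(path)
  shape2d(name, as.matrix(df[, c("x", "y")]), closed = closed)
}

#' Read counts from an HDF5 single-cell container
#'
#' Reads the dialect with a dense or CSR matrix at `/X` (cells x genes),
#' cell identifiers at `/obs/cell_id` (plus optional label columns under
#' `/obs`) and gene identifiers at `/var/gene_id`. Requires the `rhdf5`
#' package.
#'
#' @param path HDF5 file path.
#' @return list with `counts` (an `expression_matrix`) and `annotations`
#'   (data.frame of whatever label columns `/obs` holds).
#' @export
read_h5_counts <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stopf("reading HDF5 containers requires the rhdf5 package")
  ls <- rhdf5::h5ls(path)
  obs <- rhdf5::h5read(path, "obs")
  var <- rhdf5::h5read(path, "var")
  cell_ids <- as.character(obs$cell_id)
  gene_ids <- as.character(var$gene_id)
  if ("/X" %in% paste0(ls$group, "/", ls$name)[ls$otype == "H5I_GROUP"] ||
      any(ls$group == "/X")) {
    # CSR: data / indices / indptr, row = cell
    xd <- rhdf5::h5read(path, "X")
    m <- Matrix::sparseMatrix(j = as.integer(xd$indices) + 1L,
                              p = as.integer(xd$indptr),
                              x = as.numeric(xd$data),
                              dims = c(length(cell_ids), length(gene_ids)))
  } else {
    m <- rhdf5::h5read(path, "X")
    # HDF5 stores column-major; our writer stores cells x genes transposed
    m <- t(m)
  }
  ann <- as.data.frame(lapply(obs, as.character), stringsAsFactors = FALSE)
  list(counts = expression_matrix(m, cell_ids = cell_ids, gene_ids = gene_ids,
                                  layer = "counts"),
       annotations = ann)
}

#' @rdname read_h5_counts
#' @param counts an `expression_matrix` to write.
#' @param annotations data.frame with `cell_id` plus label columns.
#' @export
write_h5_counts <- function(counts, annotations, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stopf("writing HDF5 containers requires the rhdf5 package")
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  v <- counts$values
  if (inherits(v, "Matrix")) v <- as.matrix(v)
  rhdf5::h5write(t(unname(v)), path, "X")
  obs <- as.list(annotations)
  if (is.null(obs$cell_id)) obs$cell_id <- counts$cell_ids
  rhdf5::h5write(obs, path, "obs")
  rhdf5::h5write(list(gene_id = counts$gene_ids), path, "var")
  if (exists("h5closeAll", where = asNamespace("rhdf5"))) rhdf5::h5closeAll()
  invisible(path)
}
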