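#' Read a labeled expression dataset from disk
#'
#' Supported formats:
#' * `csv` / `tsv`: dense matrix, cells in rows, genes in columns; the first
#'   column holds the cell id, a column named `population` (if present)
#'   holds the label, the remaining columns are genes.
#' * `mtx`: MatrixMarket triplets (cells as rows) with sidecar text files
#'   `<stem>.cells.txt`, `<stem>.genes.txt` and optionally
#'   `<stem>.population.txt` (one entry per line).
#' * `h5ad`: AnnData container with expression in `X` (dense or CSR),
#'   population label in the per-cell annotation column `population`, and
#'   optional coordinates in the per-cell matrix `obsm/spatial`.
#'
#' @param path File path.
#' @param format One of `"auto"`, `"csv"`, `"tsv"`, `"mtx"`, `"h5ad"`.
#'   `"auto"` dispatches on the file extension.
#' @return An [expression_dataset()]. For h5ad files carrying coordinates,
#'   the matching [spatial_assignment()] is attached as attribute
#'   `"assignment"`.
#' @export
read_dataset <- function(path, format = c("auto", "csv", "tsv", "mtx", "h5ad")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", txt = "tsv",
                     mtx = "mtx", h5ad = "h5ad",
                     stop("cannot infer format from extension: ", path,
                          call. = FALSE))
  }
  switch(format,
         csv = read_dataset_delim(path, ","),
         tsv = read_dataset_delim(path, "\t"),
         mtx = read_dataset_mtx(path),
         h5ad = read_dataset_h5ad(path))
}

read_dataset_delim <- function(path, sep) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  cell_ids <- as.character(df[[1L]])
  df <- df[-1L]
  if ("population" %in% names(df)) {
    population <- as.character(df[["population"]])
    df <- df[setdiff(names(df), "population")]
  } else {
    population <- rep("population1", length(cell_ids))
  }
  coord_cols <- intersect(c("x", "y", "z"), names(df))
  coords <- NULL
  if (all(c("x", "y") %in% coord_cols)) {
    coords <- df[coord_cols]
    df <- df[setdiff(names(df), coord_cols)]
  }
  m <- as.matrix(df)
  rownames(m) <- cell_ids
  ds <- expression_dataset(m, population = population)
  if (!is.null(coords)) {
    attr(ds, "assignment") <- spatial_assignment(
      cell_id = cell_ids, x = coords$x, y = coords$y,
      population = population,
      z = if ("z" %in% names(coords)) coords$z)
  }
  ds
}

mtx_sidecar <- function(path, kind) {
  stem <- sub("\\.mtx$", "", path)
  paste0(stem, ".", kind, ".txt")
}

read_dataset_mtx <- function(path) {
  cells_f <- mtx_sidecar(path, "cells")
  genes_f <- mtx_sidecar(path, "genes")
  for (f in c(cells_f, genes_f)) {
    if (!file.exists(f))
      stop("missing MTX sidecar file: ", f, call. = FALSE)
  }
  m <- as.matrix(Matrix::readMM(path))
  cell_ids <- readLines(cells_f)
  gene_names <- readLines(genes_f)
  if (nrow(m) != length(cell_ids) || ncol(m) != length(gene_names))
    stop(sprintf(
      "MTX shape %dx%d does not match sidecars (%d cells, %d genes)",
      nrow(m), ncol(m), length(cell_ids), length(gene_names)),
      call. = FALSE)
  pop_f <- mtx_sidecar(path, "population")
  population <- if (file.exists(pop_f)) readLines(pop_f)
                else rep("population1", length(cell_ids))
  rownames(m) <- cell_ids
  colnames(m) <- gene_names
  expression_dataset(m, population = population)
}

#' Write a labeled expression dataset to disk
#'
#' Inverse of [read_dataset()]; the same format conventions apply.
#'
#' @param ds An [expression_dataset()].
#' @param path Output file path (extension decides nothing; see `format`).
#' @param format One of `"csv"`, `"tsv"`, `"mtx"`, `"h5ad"`.
#' @param assignment Optional [spatial_assignment()] for the same cells;
#'   written to `obsm/spatial` for h5ad, as extra coordinate columns for
#'   csv/tsv.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, format = c("csv", "tsv", "mtx", "h5ad"),
                          assignment = NULL) {
  format <- match.arg(format)
  switch(format,
         csv = write_dataset_delim(ds, path, ",", assignment),
         tsv = write_dataset_delim(ds, path, "\t", assignment),
         mtx = write_dataset_mtx(ds, path),
         h5ad = write_dataset_h5ad(ds, path, assignment))
  invisible(path)
}

write_dataset_delim <- function(ds, path, sep, assignment = NULL) {
  df <- data.frame(cell_id = ds$cell_ids,
                   population = unname(ds$population),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(assignment)) {
    idx <- match(ds$cell_ids, assignment$cell_id)
    df$x <- assignment$x[idx]
    df$y <- assignment$y[idx]
    if ("z" %in% names(assignment)) df$z <- assignment$z[idx]
  }
  df <- cbind(df, as.data.frame(ds$matrix, check.names = FALSE))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
}

write_dataset_mtx <- function(ds, path) {
  Matrix::writeMM(methods::as(methods::as(ds$matrix, "CsparseMatrix"),
                              "generalMatrix"), path)
  writeLines(ds$cell_ids, mtx_sidecar(path, "cells"))
  writeLines(ds$gene_names, mtx_sidecar(path, "genes"))
  writeLines(unname(ds$population), mtx_sidecar(path, "population"))
}

# -- AnnData (h5ad) -----------------------------------------------------------
# Minimal writer/reader for the AnnData on-disk schema: X as a dense array,
# obs as a dataframe group holding the population column, var as the gene
# index, obsm/spatial for coordinates. Sparse CSR/CSC X is handled on read.

h5_set_enc <- function(file, name, type, version = "0.2.0") {
  fid <- rhdf5::H5Fopen(file)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  obj <- rhdf5::H5Oopen(fid, name)
  on.exit(rhdf5::H5Oclose(obj), add = TRUE)
  rhdf5::h5writeAttribute(type, obj, "encoding-type", asScalar = TRUE,
                          variableLengthString = TRUE, encoding = "UTF-8")
  rhdf5::h5writeAttribute(version, obj, "encoding-version", asScalar = TRUE,
                          variableLengthString = TRUE, encoding = "UTF-8")
}

h5_write_string_array <- function(file, name, values) {
  rhdf5::h5write(values, file, name,
                 variableLengthString = TRUE, encoding = "UTF-8")
  h5_set_enc(file, name, "string-array")
}

write_dataset_h5ad <- function(ds, path, assignment = NULL) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  # AnnData is obs x var; h5py sees the transposed R matrix, so write t().
  rhdf5::h5write(t(ds$matrix), path, "X")
  h5_set_enc(path, "X", "array")
  rhdf5::h5createGroup(path, "obs")
  h5_write_string_array(path, "obs/_index", ds$cell_ids)
  h5_write_string_array(path, "obs/population", unname(ds$population))
  h5_set_enc(path, "obs", "dataframe", "0.2.0")
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, "obs")
  rhdf5::h5writeAttribute("_index", gid, "_index", asScalar = TRUE,
                          variableLengthString = TRUE, encoding = "UTF-8")
  rhdf5::h5writeAttribute("population", gid, "column-order",
                          variableLengthString = TRUE, encoding = "UTF-8")
  rhdf5::H5Gclose(gid); rhdf5::H5Fclose(fid)
  rhdf5::h5createGroup(path, "var")
  h5_write_string_array(path, "var/_index", ds$gene_names)
  h5_set_enc(path, "var", "dataframe", "0.2.0")
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, "var")
  rhdf5::h5writeAttribute("_index", gid, "_index", asScalar = TRUE,
                          variableLengthString = TRUE, encoding = "UTF-8")
  # zero-length column-order needs the low-level API
  sid <- rhdf5::H5Screate_simple(0L)
  tid <- rhdf5::H5Tcopy("H5T_C_S1")
  aid <- rhdf5::H5Acreate(gid, "column-order", tid, sid)
  rhdf5::H5Aclose(aid); rhdf5::H5Sclose(sid)
  rhdf5::H5Gclose(gid); rhdf5::H5Fclose(fid)
  for (grp in c("obsm", "uns", "obsp", "varm", "varp", "layers")) {
    rhdf5::h5createGroup(path, grp)
    h5_set_enc(path, grp, "dict", "0.1.0")
  }
  if (!is.null(assignment)) {
    idx <- match(ds$cell_ids, assignment$cell_id)
    coords <- cbind(assignment$x[idx], assignment$y[idx])
    if ("z" %in% names(assignment)) coords <- cbind(coords, assignment$z[idx])
    rhdf5::h5write(t(coords), path, "obsm/spatial")
    h5_set_enc(path, "obsm/spatial", "array")
  }
  h5_set_enc(path, "/", "anndata", "0.1.0")
}

h5_read_matrix <- function(path, name) {
  x <- rhdf5::h5read(path, name)
  if (is.list(x) && all(c("data", "indices", "indptr") %in% names(x))) {
    attrs <- rhdf5::h5readAttributes(path, name)
    enc <- attrs[["encoding-type"]] %||% "csr_matrix"
    shape <- as.integer(attrs[["shape"]])
    if (enc == "csr_matrix") {
      # CSR (obs x var) is the CSC of its transpose: same slots, dims
      # reversed, transpose back
      m <- Matrix::sparseMatrix(i = as.integer(x$indices) + 1L,
                                p = as.integer(x$indptr),
                                x = as.double(x$data),
                                dims = rev(shape))
      return(t(as.matrix(m)))
    }
    m <- Matrix::sparseMatrix(i = as.integer(x$indices) + 1L,
                              p = as.integer(x$indptr),
                              x = as.double(x$data), dims = shape)
    return(as.matrix(m))
  }
  # dense: stored obs x var row-major; rhdf5 returns the reversed dims
  t(as.matrix(x))
}

h5ad_read_column <- function(x) {
  # categorical columns arrive as list(categories, codes); plain as vector
  if (is.list(x) && all(c("categories", "codes") %in% names(x))) {
    as.character(x$categories)[as.integer(x$codes) + 1L]
  } else {
    as.character(x)
  }
}

read_dataset_h5ad <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  full <- paste0(ifelse(contents$group == "/", "", contents$group), "/",
                 contents$name)
  m <- h5_read_matrix(path, "X")
  obs <- rhdf5::h5read(path, "obs")
  cell_ids <- as.character(obs[["_index"]] %||% obs[["index"]] %||%
                           seq_len(nrow(m)))
  population <- if (!is.null(obs[["population"]]))
    h5ad_read_column(obs[["population"]])
  else rep("population1", nrow(m))
  var <- rhdf5::h5read(path, "var")
  gene_names <- as.character(var[["_index"]] %||% var[["index"]] %||%
                             seq_len(ncol(m)))
  rownames(m) <- cell_ids
  colnames(m) <- gene_names
  ds <- expression_dataset(m, population = population)
  if ("/obsm/spatial" %in% full) {
    coords <- t(as.matrix(rhdf5::h5read(path, "obsm/spatial")))
    ds_attr <- spatial_assignment(cell_id = cell_ids,
                                  x = coords[, 1L], y = coords[, 2L],
                                  population = population,
                                  z = if (ncol(coords) >= 3L) coords[, 3L])
    attr(ds, "assignment") <- ds_attr
  }
  ds
}

#' Read a spatial reference
#'
#' Accepts an h5ad file (coordinates in `obsm/spatial`, group label in the
#' per-cell column `group` or `population`) or a CSV/TSV with columns
#' `x`, `y`, `group` followed by gene columns.
#'
#' @param path File path.
#' @param format `"auto"`, `"csv"`, `"tsv"` or `"h5ad"`.
#' @return A [spatial_reference()].
#' @export
read_reference <- function(path, format = c("auto", "csv", "tsv", "h5ad")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", h5ad = "h5ad",
                     stop("cannot infer format: ", path, call. = FALSE))
  }
  if (format == "h5ad") {
    on.exit(rhdf5::h5closeAll(), add = TRUE)
    m <- h5_read_matrix(path, "X")
    obs <- rhdf5::h5read(path, "obs")
    grp <- obs[["group"]] %||% obs[["population"]]
    if (is.null(grp)) stop("reference h5ad lacks a 'group' column",
                           call. = FALSE)
    var <- rhdf5::h5read(path, "var")
    colnames(m) <- as.character(var[["_index"]] %||% seq_len(ncol(m)))
    coords <- t(as.matrix(rhdf5::h5read(path, "obsm/spatial")))
    return(spatial_reference(
      coordinates = tibble::tibble(x = coords[, 1L], y = coords[, 2L]),
      group = h5ad_read_column(grp), expression = m))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("x", "y", "group") %in% names(df)))
  expr <- as.matrix(df[setdiff(names(df), c("x", "y", "group"))])
  spatial_reference(coordinates = df[c("x", "y")], group = df$group,
                    expression = expr)
}

#' Write a spatial reference as CSV
#' @param ref A [spatial_reference()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  df <- cbind(ref$coordinates, group = ref$group,
              as.data.frame(ref$expression, check.names = FALSE))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
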