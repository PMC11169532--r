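#' Labeled expression dataset
#'
#' The universal currency of the simulator: a dense cells-by-genes matrix of
#' non-negative (typically library-size scaled and log1p-transformed)
#' expression values, plus one categorical population label per cell.
#' Populations are the groupings whose expression is learned and whose
#' spatial patterns are simulated -- cell types, spatial domains,
#' pathological regions and the like.
#'
#' @param matrix Numeric cells-by-genes matrix with no negative entries.
#'   Row names are taken as cell ids and column names as gene names when
#'   `cell_ids` / `gene_names` are not given.
#' @param population Character (or factor) vector, one label per cell.
#' @param gene_names,cell_ids Optional explicit names; must be unique.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `matrix`, `gene_names`, `cell_ids`, `population`.
#' @export
expression_dataset <- function(matrix, population,
                               gene_names = colnames(matrix),
                               cell_ids = rownames(matrix)) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(matrix)))
  if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(ncol(matrix)))
  population <- as.character(population)
  rownames(matrix) <- cell_ids
  colnames(matrix) <- gene_names
  ds <- structure(
    list(matrix = matrix,
         gene_names = gene_names,
         cell_ids = cell_ids,
         population = stats::setNames(population, cell_ids)),
    class = "expression_dataset")
  issues <- validate_dataset(ds)
  if (nrow(issues) > 0L) {
    stop("invalid expression dataset: ",
         paste(issues$message, collapse = "; "), call. = FALSE)
  }
  ds
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d cells x %d genes, %d populations\n",
              nrow(x$matrix), ncol(x$matrix),
              length(unique(x$population))))
  tab <- sort(table(x$population), decreasing = TRUE)
  cat("  ", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

#' Population labels of a dataset
#' @param ds An `expression_dataset`.
#' @return Character vector of labels, one per cell, named by cell id.
#' @export
populations <- function(ds) ds$population

#' Validate an expression dataset
#'
#' Checks every structural invariant the simulator relies on and reports
#' all violations instead of stopping at the first. An empty report means
#' the dataset is valid.
#'
#' @param ds An object shaped like an [expression_dataset()].
#' @return A tibble with columns `check` and `message`, one row per
#'   violated invariant (zero rows when valid).
#' @export
validate_dataset <- function(ds) {
  issues <- list()
  add <- function(check, message) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(check = check,
                                                     message = message)
  }
  m <- ds$matrix
  if (!is.matrix(m) || !is.numeric(m)) {
    add("matrix", "expression matrix is not a numeric matrix")
    return(dplyr::bind_rows(issues))
  }
  if (anyNA(m)) add("finite", "expression matrix contains NA values")
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    i <- neg[1L, ]
    add("non_negative",
        sprintf("negative entry at cell '%s', gene '%s' (%d total)",
                ds$cell_ids[i[1L]], ds$gene_names[i[2L]], nrow(neg)))
  }
  if (nrow(m) != length(ds$cell_ids))
    add("cell_ids", "row count does not match number of cell ids")
  if (ncol(m) != length(ds$gene_names))
    add("gene_names", "column count does not match number of gene names")
  if (anyDuplicated(ds$gene_names))
    add("gene_names_unique",
        sprintf("duplicated gene name(s): %s",
                paste(unique(ds$gene_names[duplicated(ds$gene_names)]),
                      collapse = ", ")))
  if (anyDuplicated(ds$cell_ids))
    add("cell_ids_unique", "duplicated cell id(s)")
  if (length(ds$population) != nrow(m))
    add("population", "population labels do not cover every cell exactly once")
  if (anyNA(ds$population))
    add("population", "missing population label(s)")
  dplyr::bind_rows(issues)
}

#' Library-size normalize and log-transform a count matrix
#'
#' Scales every cell (row) to a common library size, then applies
#' `log(1 + x)`. This is the standard preprocessing the simulator expects
#' its inputs to have received; raw counts from the fixture generator are
#' passed through it before training. Rows with zero total are left
#' untouched (all zero).
#'
#' @param raw Non-negative numeric matrix of counts, cells in rows.
#' @param target_size Common library size to scale to. Defaults to the
#'   median of the per-cell totals (over cells with nonzero totals).
#' @return Matrix of the same shape, normalized and log1p-transformed.
#' @export
normalize_expression <- function(raw, target_size = NULL) {
  raw <- as.matrix(raw)
  if (any(raw < 0)) stop("counts must be non-negative", call. = FALSE)
  totals <- rowSums(raw)
  if (is.null(target_size)) {
    nz <- totals[totals > 0]
    target_size <- if (length(nz)) stats::median(nz) else 1
  }
  scale <- ifelse(totals > 0, target_size / totals, 0)
  log1p(raw * scale)
}

#' Subset a dataset to a set of cells
#' @param ds An `expression_dataset`.
#' @param cells Cell ids or logical/integer index.
#' @return A new `expression_dataset`.
#' @export
subset_cells <- function(ds, cells) {
  if (is.character(cells)) cells <- match(cells, ds$cell_ids)
  expression_dataset(ds$matrix[cells, , drop = FALSE],
                     population = ds$population[cells])
}

#' Subset a dataset to a gene panel
#' @param ds An `expression_dataset`.
#' @param genes Gene names or index.
#' @return A new `expression_dataset` restricted to `genes`, in the given order.
#' @export
subset_genes <- function(ds, genes) {
  if (is.character(genes)) genes <- match(genes, ds$gene_names)
  expression_dataset(ds$matrix[, genes, drop = FALSE],
                     population = ds$population)
}

# -- spatial containers -------------------------------------------------------

#' Construct a spatial assignment
#'
#' A spatial assignment records where every cell sits: 2-D or 3-D
#' coordinates plus the population label. It is a plain tibble (class
#' `spatial_assignment`) so it pipes through dplyr directly.
#'
#' @param cell_id Character vector of cell ids.
#' @param x,y Numeric coordinates.
#' @param population Character labels.
#' @param z Optional third coordinate for 3-D assignments.
#' @return A tibble of class `spatial_assignment` with columns
#'   `cell_id`, `x`, `y`, (`z`,) `population`.
#' @export
spatial_assignment <- function(cell_id, x, y, population, z = NULL) {
  stopifnot(length(cell_id) == length(x), length(x) == length(y),
            length(y) == length(population))
  out <- tibble::tibble(cell_id = as.character(cell_id),
                        x = as.double(x), y = as.double(y))
  if (!is.null(z)) {
    stopifnot(length(z) == length(x))
    out$z <- as.double(z)
  }
  out$population <- as.character(population)
  class(out) <- c("spatial_assignment", class(out))
  out
}

#' Construct a spatial reference
#'
#' Reference positions with a group label and measured (or previously
#' simulated) expression at each position; the target of reference-based
#' mapping.
#'
#' @param coordinates Tibble/data frame with columns `x`, `y`.
#' @param group Character vector of group labels, one per position.
#' @param expression Positions-by-genes numeric matrix.
#' @return An object of class `spatial_reference`.
#' @export
spatial_reference <- function(coordinates, group, expression) {
  coordinates <- tibble::as_tibble(coordinates)
  stopifnot(all(c("x", "y") %in% names(coordinates)))
  expression <- as.matrix(expression)
  n <- nrow(coordinates)
  if (length(group) != n || nrow(expression) != n)
    stop("coordinates, group and expression must have one row per position",
         call. = FALSE)
  if (n == 0L || length(unique(group)) == 0L)
    stop("reference must contain at least one position and group",
         call. = FALSE)
  structure(list(coordinates = coordinates,
                 group = as.character(group),
                 expression = expression),
            class = "spatial_reference")
}

#' @export
print.spatial_reference <- function(x, ...) {
  cat(sprintf("<spatial_reference> %d positions, %d genes, groups: %s\n",
              nrow(x$coordinates), ncol(x$expression),
              paste(sort(unique(x$group)), collapse = ", ")))
  invisible(x)
}
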