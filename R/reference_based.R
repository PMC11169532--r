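#' Simulate SRT data on the coordinates of a spatial reference
#'
#' For every group in the reference, generates as many new cells of the
#' matching population as the group has positions, then maps generated
#' cells onto the group's positions by exact optimal transport on the
#' squared-Euclidean expression cost (uniform marginals) followed by a
#' greedy maximum-mass bijection. The mapping uses expression only; the
#' reference coordinates enter solely as the destinations.
#'
#' @param model A trained [train_vae()] model whose populations cover the
#'   reference groups.
#' @param ref A [spatial_reference()].
#' @param seed Integer seed (per-group generation seeds derived by offset).
#' @param min_shared_genes Minimum size of the gene intersection between
#'   model and reference before the cost is considered meaningful.
#' @return A list with elements `dataset` (the generated
#'   [expression_dataset()]) and `assignment` (a [spatial_assignment()]
#'   placing each generated cell on one reference position; every position
#'   is covered exactly once and keeps its group label).
#' @export
simulate_reference_based <- function(model, ref, seed = 1L,
                                     min_shared_genes = 10L) {
  stopifnot(inherits(ref, "spatial_reference"))
  groups <- sort(unique(ref$group))
  missing <- setdiff(groups, names(model$latent_summaries))
  if (length(missing))
    stop("reference group(s) without a matching model population: ",
         paste(missing, collapse = ", "), call. = FALSE)

  ref_genes <- colnames(ref$expression)
  if (is.null(ref_genes)) ref_genes <- model$gene_names
  shared <- sort(intersect(model$gene_names, ref_genes))
  if (length(shared) < min_shared_genes)
    stop("only ", length(shared), " genes shared between model and ",
         "reference (need >= ", min_shared_genes, ")", call. = FALSE)

  parts <- purrr::map(seq_along(groups), function(gi) {
    g <- groups[gi]
    pos_idx <- which(ref$group == g)
    m_g <- length(pos_idx)
    gen <- generate_cells(model, g, m_g,
                          seed = (seed + 7919L * gi) %% .Machine$integer.max,
                          id_prefix = "ref")
    gen_expr <- gen$matrix[, shared, drop = FALSE]
    ref_expr <- ref$expression[pos_idx, shared, drop = FALSE]
    M <- cost_matrix(gen_expr, ref_expr)
    plan <- solve_ot(M)
    cell_of_pos <- assign_positions(plan)
    tibble::tibble(cell_id = gen$cell_ids[cell_of_pos],
                   x = ref$coordinates$x[pos_idx],
                   y = ref$coordinates$y[pos_idx],
                   population = g,
                   ref_position = pos_idx,
                   dataset = list(gen))
  })
  assign_tbl <- dplyr::bind_rows(
    purrr::map(parts, ~ dplyr::select(.x, -"dataset")))
  datasets <- purrr::map(parts, ~ .x$dataset[[1L]])
  m <- do.call(rbind, purrr::map(datasets, "matrix"))
  ds <- expression_dataset(
    m, population = unlist(purrr::map(datasets, ~ unname(.x$population))))
  assignment <- spatial_assignment(cell_id = assign_tbl$cell_id,
                                   x = assign_tbl$x, y = assign_tbl$y,
                                   population = assign_tbl$population)
  attr(assignment, "ref_position") <- assign_tbl$ref_position
  list(dataset = ds, assignment = assignment)
}
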