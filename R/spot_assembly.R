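# Spot assembly: aggregate single-cell assignments into spot-level SRT
# data with controllable resolution (average cells per spot n) and
# lattice geometry (random / hexagonal / square), merge high-resolution
# grids into low-resolution ones, split 3-D data into slices, and select
# targeted gene panels.

#' Declare a spot lattice
#'
#' @param arrangement `"random"` (bead-style, e.g. Slide-seq),
#'   `"hexagonal"` (e.g. 10X Visium) or `"square"` (e.g. ST).
#' @param cells_per_spot Target average number of cells per spot `n`; the
#'   spot spacing is derived from it and the realized cell density.
#' @param bounds Canvas bounds `c(xmin, xmax, ymin, ymax)`.
#' @return A list of class `lattice_spec`.
#' @export
lattice_spec <- function(arrangement = c("random", "hexagonal", "square"),
                         cells_per_spot = 10,
                         bounds = c(0, 1, 0, 1)) {
  arrangement <- match.arg(arrangement)
  stopifnot(cells_per_spot > 0, length(bounds) == 4L,
            bounds[2L] > bounds[1L], bounds[4L] > bounds[3L])
  structure(list(arrangement = arrangement,
                 cells_per_spot = cells_per_spot, bounds = bounds),
            class = "lattice_spec")
}

#' Platform presets for spot arrangement and resolution
#'
#' Convenience constructors mirroring the realized resolutions of the
#' three mainstream platforms: Slide-seq-like random beads (~2.34 cells
#' per spot), Visium-like hexagonal spots (~10.5) and ST-like square
#' spots (~34.01). Targets, not guarantees: the realized average depends
#' on the cell density of the assignment.
#'
#' @param platform `"slideseq"`, `"visium"` or `"st"`.
#' @param bounds Canvas bounds.
#' @return A [lattice_spec()].
#' @export
platform_preset <- function(platform = c("slideseq", "visium", "st"),
                            bounds = c(0, 1, 0, 1)) {
  platform <- match.arg(platform)
  switch(platform,
         slideseq = lattice_spec("random", 2.34, bounds),
         visium = lattice_spec("hexagonal", 10.5, bounds),
         st = lattice_spec("square", 34.01, bounds))
}

#' Generate spot centers for a lattice
#'
#' Square: axis-aligned grid with spacing `s = sqrt(n / density)` (each
#' catchment tile then holds `n` cells on average). Hexagonal: offset
#' rows with per-spot catchment area `n / density` (row pitch
#' `s * sqrt(3)/2`, odd rows shifted by `s/2`). Random: uniform centers,
#' one per `n / density` of canvas area.
#'
#' @param spec A [lattice_spec()].
#' @param cell_density Cells per unit canvas area.
#' @param seed Seed (random arrangement only).
#' @return Tibble with columns `spot_id`, `x`, `y` (and `row`, `col` for
#'   square lattices).
#' @export
generate_spot_lattice <- function(spec, cell_density, seed = 1L) {
  stopifnot(cell_density > 0)
  b <- spec$bounds
  W <- b[2L] - b[1L]; H <- b[4L] - b[3L]
  area_per_spot <- spec$cells_per_spot / cell_density
  if (area_per_spot > W * H)
    stop("cells_per_spot exceeds the total cell count of the canvas",
         call. = FALSE)
  if (spec$arrangement == "square") {
    s <- sqrt(area_per_spot)
    # fit an integer number of tiles to the canvas and rescale the
    # spacing, so edge tiles are full-sized and the realized cells/spot
    # stays close to the target
    nx <- max(1L, round(W / s)); ny <- max(1L, round(H / s))
    sx <- W / nx; sy <- H / ny
    g <- expand.grid(col = seq_len(nx), row = seq_len(ny))
    out <- tibble::tibble(
      spot_id = sprintf("spot%05d", seq_len(nrow(g))),
      x = b[1L] + (g$col - 0.5) * sx,
      y = b[3L] + (g$row - 0.5) * sy,
      row = g$row, col = g$col)
    attr(out, "spacing") <- sx
    attr(out, "spacing_y") <- sy
  } else if (spec$arrangement == "hexagonal") {
    # catchment hexagon area = s^2 * sqrt(3)/2 with nearest-neighbor
    # distance s  =>  s = sqrt(2 * area / sqrt(3))
    s <- sqrt(2 * area_per_spot / sqrt(3))
    pitch <- s * sqrt(3) / 2
    rows <- seq(b[3L] + pitch / 2, b[4L], by = pitch)
    pts <- purrr::map_dfr(seq_along(rows), function(r) {
      offset <- if (r %% 2L == 0L) s / 2 else 0
      xs <- seq(b[1L] + s / 2 + offset, b[2L], by = s)
      tibble::tibble(x = xs, y = rows[r])
    })
    out <- tibble::tibble(spot_id = sprintf("spot%05d", seq_len(nrow(pts))),
                          x = pts$x, y = pts$y)
    attr(out, "spacing") <- s
  } else {
    n_spots <- max(1L, round(W * H / area_per_spot))
    set.seed(seed)
    out <- tibble::tibble(spot_id = sprintf("spot%05d", seq_len(n_spots)),
                          x = stats::runif(n_spots, b[1L], b[2L]),
                          y = stats::runif(n_spots, b[3L], b[4L]))
  }
  attr(out, "arrangement") <- spec$arrangement
  attr(out, "bounds") <- b
  out
}

#' Aggregate cells into spots
#'
#' Attaches every cell to its catchment spot -- the containing tile for
#' square lattices (ties on an edge go to the lower-index tile), the
#' nearest center otherwise -- then sums member expression and derives
#' the ground-truth composition. Spots that capture no cell are dropped,
#' as real platforms only report tissue-covered spots.
#'
#' @param assign A [spatial_assignment()] (2-D).
#' @param expr An [expression_dataset()] aligned on `cell_id` (or
#'   containing the assignment's `source_cell`s -- see
#'   [realize_expression()]).
#' @param lattice Spot centers from [generate_spot_lattice()].
#' @param spec The [lattice_spec()] used to build the lattice.
#' @return A list of class `spot_dataset`: `spots` (tibble: `spot_id`,
#'   `x`, `y`, `n_cells`), `expression` (spots x genes, exact member
#'   sums), `composition` (spots x populations proportion matrix, rows
#'   sum to 1), `members` (named list of cell ids per spot).
#' @export
bin_cells_to_spots <- function(assign, expr, lattice, spec) {
  idx <- match(assign$cell_id, expr$cell_ids)
  if (anyNA(idx))
    stop("assignment and expression datasets are misaligned on cell ids",
         call. = FALSE)
  if (spec$arrangement == "square") {
    sx <- attr(lattice, "spacing")
    sy <- attr(lattice, "spacing_y") %||% sx
    b <- attr(lattice, "bounds")
    nx <- max(lattice$col)
    col <- pmin(pmax(floor((assign$x - b[1L]) / sx) + 1L, 1L), nx)
    row <- pmin(pmax(floor((assign$y - b[3L]) / sy) + 1L, 1L),
                max(lattice$row))
    key <- paste(row, col)
    spot_key <- paste(lattice$row, lattice$col)
    spot_of_cell <- match(key, spot_key)
  } else {
    d2 <- outer(assign$x, lattice$x, "-")^2 + outer(assign$y, lattice$y, "-")^2
    spot_of_cell <- max.col(-d2, ties.method = "first")
  }
  keep <- sort(unique(spot_of_cell))
  pops <- sort(unique(assign$population))
  n_spots <- length(keep)
  spot_expr <- matrix(0, nrow = n_spots, ncol = ncol(expr$matrix),
                      dimnames = list(lattice$spot_id[keep],
                                      expr$gene_names))
  comp <- matrix(0, nrow = n_spots, ncol = length(pops),
                 dimnames = list(lattice$spot_id[keep], pops))
  members <- vector("list", n_spots)
  for (si in seq_len(n_spots)) {
    rows <- which(spot_of_cell == keep[si])
    spot_expr[si, ] <- colSums(expr$matrix[idx[rows], , drop = FALSE])
    tab <- table(factor(assign$population[rows], levels = pops))
    comp[si, ] <- as.numeric(tab) / length(rows)
    members[[si]] <- assign$cell_id[rows]
  }
  names(members) <- lattice$spot_id[keep]
  spots <- tibble::tibble(spot_id = lattice$spot_id[keep],
                          x = lattice$x[keep], y = lattice$y[keep],
                          n_cells = lengths(members))
  if (spec$arrangement == "square") {
    spots$row <- lattice$row[keep]
    spots$col <- lattice$col[keep]
  }
  structure(list(spots = spots, expression = spot_expr,
                 composition = comp, members = members,
                 arrangement = spec$arrangement),
            class = "spot_dataset")
}

#' @export
print.spot_dataset <- function(x, ...) {
  cat(sprintf("<spot_dataset> %d spots (%s), %d genes, %.2f cells/spot\n",
              nrow(x$spots), x$arrangement, ncol(x$expression),
              mean(x$spots$n_cells)))
  invisible(x)
}

#' Per-spot composition in long form
#' @param x A `spot_dataset`.
#' @param ... Unused.
#' @return Tibble `spot_id`, `population`, `proportion`.
#' @method tidy spot_dataset
#' @export
tidy.spot_dataset <- function(x, ...) {
  comp <- tibble::as_tibble(x$composition, rownames = "spot_id")
  tidyr::pivot_longer(comp, -"spot_id", names_to = "population",
                      values_to = "proportion")
}

#' One-row summary of a spot dataset
#' @param x A `spot_dataset`.
#' @param ... Unused.
#' @return Tibble with spot/gene counts and realized resolution.
#' @method glance spot_dataset
#' @export
glance.spot_dataset <- function(x, ...) {
  tibble::tibble(n_spots = nrow(x$spots),
                 n_genes = ncol(x$expression),
                 arrangement = x$arrangement,
                 mean_cells_per_spot = mean(x$spots$n_cells),
                 total_expression = sum(x$expression))
}

#' Merge a square high-resolution grid into a coarser one
#'
#' Merges non-overlapping `factor x factor` blocks of a square-grid spot
#' dataset: expression is summed and the composition re-derived from the
#' pooled members, so a 33x33 grid with factor 3 yields exactly 121
#' spots. Mass is conserved exactly.
#'
#' @param spots_high A `spot_dataset` on a square grid (has `row`/`col`).
#' @param factor Positive integer block side; 1 returns the input.
#' @return A `spot_dataset` at the lower resolution.
#' @export
build_low_res_from_high <- function(spots_high, factor) {
  stopifnot(inherits(spots_high, "spot_dataset"))
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (!all(c("row", "col") %in% names(spots_high$spots)))
    stop("low-resolution merging requires a square-grid spot dataset",
         call. = FALSE)
  if (factor == 1L) return(spots_high)
  sp <- spots_high$spots
  block_row <- (sp$row - 1L) %/% factor + 1L
  block_col <- (sp$col - 1L) %/% factor + 1L
  key <- paste(block_row, block_col)
  blocks <- unique(key)
  pops <- colnames(spots_high$composition)
  expr <- matrix(0, nrow = length(blocks), ncol = ncol(spots_high$expression),
                 dimnames = list(NULL, colnames(spots_high$expression)))
  comp <- matrix(0, nrow = length(blocks), ncol = length(pops),
                 dimnames = list(NULL, pops))
  members <- vector("list", length(blocks))
  xs <- ys <- n_cells <- numeric(length(blocks))
  for (bi in seq_along(blocks)) {
    rows <- which(key == blocks[bi])
    expr[bi, ] <- colSums(spots_high$expression[rows, , drop = FALSE])
    cell_counts <- sp$n_cells[rows]
    comp[bi, ] <- colSums(spots_high$composition[rows, , drop = FALSE] *
                            cell_counts) / sum(cell_counts)
    members[[bi]] <- unlist(spots_high$members[rows], use.names = FALSE)
    xs[bi] <- mean(sp$x[rows]); ys[bi] <- mean(sp$y[rows])
    n_cells[bi] <- sum(cell_counts)
  }
  ids <- sprintf("spot%05d", seq_along(blocks))
  rownames(expr) <- ids; rownames(comp) <- ids; names(members) <- ids
  spots <- tibble::tibble(
    spot_id = ids, x = xs, y = ys, n_cells = as.integer(n_cells),
    row = as.integer(sub(" .*", "", blocks)),
    col = as.integer(sub(".* ", "", blocks)))
  structure(list(spots = spots, expression = expr, composition = comp,
                 members = members, arrangement = "square"),
            class = "spot_dataset")
}

#' Split a 3-D assignment into 2-D slices
#'
#' Cuts `k` equal-width bins along the chosen axis; every cell lands in
#' exactly one slice and each slice keeps the two remaining coordinates.
#'
#' @param assign3d A 3-D [spatial_assignment()] (has `z`).
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param k Number of slices (`k = 1` returns everything in one slice).
#' @return List of `k` 2-D [spatial_assignment()]s, in bin order; each
#'   carries its bin interval as attribute `"interval"`.
#' @export
split_3d <- function(assign3d, axis = c("z", "x", "y"), k = 1L) {
  axis <- match.arg(axis)
  if (!"z" %in% names(assign3d))
    stop("split_3d requires a 3-D assignment", call. = FALSE)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  vals <- assign3d[[axis]]
  if (k > length(unique(vals)))
    stop("k exceeds the number of distinct coordinates along ", axis,
         call. = FALSE)
  lo <- min(vals); hi <- max(vals)
  width <- (hi - lo) / k
  bin <- pmin(pmax(floor((vals - lo) / width) + 1L, 1L), k)
  keep_axes <- setdiff(c("x", "y", "z"), axis)
  purrr::map(seq_len(k), function(s) {
    rows <- which(bin == s)
    sl <- spatial_assignment(cell_id = assign3d$cell_id[rows],
                             x = assign3d[[keep_axes[1L]]][rows],
                             y = assign3d[[keep_axes[2L]]][rows],
                             population = assign3d$population[rows])
    attr(sl, "interval") <- c(lo + (s - 1L) * width, lo + s * width)
    sl
  })
}

#' Select a targeted gene panel
#'
#' `random`: uniform sample without replacement. `hvg`: top genes by
#' cross-cell variance of the normalized expression. `marker`: genes
#' ranked per population by one-vs-rest mean log-fold-change, collected
#' round-robin across populations until `count` genes are chosen.
#'
#' @param expr An [expression_dataset()].
#' @param mode `"random"`, `"hvg"` or `"marker"`.
#' @param count Panel size (<= gene count).
#' @param seed Seed (random mode).
#' @return Character vector of `count` gene names.
#' @export
select_gene_panel <- function(expr, mode = c("random", "hvg", "marker"),
                              count, seed = 1L) {
  mode <- match.arg(mode)
  genes <- expr$gene_names
  count <- as.integer(count)
  if (count > length(genes))
    stop("count exceeds the number of genes", call. = FALSE)
  if (count == length(genes)) return(genes)
  if (mode == "random") {
    set.seed(seed)
    return(sample(genes, count))
  }
  if (mode == "hvg") {
    v <- apply(expr$matrix, 2L, stats::var)
    return(genes[order(v, decreasing = TRUE)[seq_len(count)]])
  }
  # marker: per-population one-vs-rest mean log-FC ranking, round-robin
  pops <- sort(unique(expr$population))
  rankings <- purrr::map(pops, function(p) {
    inp <- expr$population == p
    lfc <- colMeans(expr$matrix[inp, , drop = FALSE]) -
      colMeans(expr$matrix[!inp, , drop = FALSE])
    genes[order(lfc, decreasing = TRUE)]
  })
  panel <- character(0)
  pos <- rep(1L, length(pops))
  while (length(panel) < count) {
    for (pi in seq_along(pops)) {
      while (pos[pi] <= length(genes) &&
             rankings[[pi]][pos[pi]] %in% panel)
        pos[pi] <- pos[pi] + 1L
      if (length(panel) < count && pos[pi] <= length(genes)) {
        panel <- c(panel, rankings[[pi]][pos[pi]])
        pos[pi] <- pos[pi] + 1L
      }
    }
  }
  panel
}
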