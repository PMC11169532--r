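# Reference-free spatial pattern synthesis.
#
# Random patterns: the canvas (unit square or cube) is divided into a
# regular grid; a Gaussian random field with squared-exponential
# covariance exp(-(D/delta)^2) is drawn over the grid centers and the
# top-ranked grids are claimed for each patterned population, giving
# spatially contiguous territories whose connectivity grows with delta.
# A clarity parameter lambda then randomly swaps the coordinates of a
# (1 - lambda) fraction of cells to blur the pattern.
#
# Customized patterns: mixed, cluster (ellipse), ring (elliptical
# annulus) and vessel (stripe) basis patterns with optional infiltrating
# populations, composable in painter's order.

#' Configuration for random (Gaussian-random-field) patterns
#'
#' @param grid_n Grids per side (the canvas is divided into
#'   `grid_n^dims` grids).
#' @param delta Autocorrelation length of the field; larger values give
#'   patterns with greater connectivity. Measured in grid-index units
#'   (adjacent grid centers are distance 1 apart).
#' @param lam Clarity in `[0, 1]`: the coordinates of a `(1 - lam)`
#'   fraction of cells are randomly swapped after allocation (1 = crisp,
#'   0 = fully shuffled).
#' @param patterned_populations Labels that receive their own contiguous
#'   territory, processed in the given order; remaining populations are
#'   spread over the leftover grids.
#' @param seed Integer seed.
#' @param dims 2 for a square canvas, 3 for a cube.
#' @return A list of class `random_pattern_config`.
#' @export
random_pattern_config <- function(grid_n = 20L, delta = 2, lam = 1,
                                  patterned_populations = character(0),
                                  seed = 1L, dims = 2L) {
  stopifnot(grid_n >= 2L, delta > 0, lam >= 0, lam <= 1, dims %in% c(2L, 3L))
  structure(list(grid_n = as.integer(grid_n), delta = delta, lam = lam,
                 patterned_populations = as.character(patterned_populations),
                 seed = as.integer(seed), dims = as.integer(dims)),
            class = "random_pattern_config")
}

#' Squared-exponential grid covariance
#'
#' `Sigma = exp(-(D / delta)^2)` where `D` is the Euclidean distance
#' matrix of the grid-center coordinates: unit diagonal, symmetric,
#' entries in (0, 1], and positive semi-definite (a Gaussian kernel).
#'
#' @param grid_coords Matrix of grid-center coordinates (rows = grids).
#' @param delta Positive autocorrelation length (same units as the
#'   coordinates).
#' @return The covariance matrix.
#' @export
build_covariance <- function(grid_coords, delta) {
  if (delta <= 0) stop("delta must be positive", call. = FALSE)
  grid_coords <- as.matrix(grid_coords)
  D <- as.matrix(stats::dist(grid_coords))
  exp(-(D / delta)^2)
}

#' Draw a Gaussian random field over the grid
#'
#' One draw of `V ~ MVN(0, Sigma)` by Cholesky factorization; a jitter of
#' `1e-8` is added to the diagonal before factorizing to absorb the
#' near-singularity of smooth kernels.
#'
#' @param Sigma Symmetric PSD covariance from [build_covariance()].
#' @param seed Integer seed; the draw is reproducible.
#' @return Numeric vector, one value per grid.
#' @export
sample_field <- function(Sigma, seed = 1L) {
  Sigma <- as.matrix(Sigma)
  n <- nrow(Sigma)
  L <- tryCatch(chol(Sigma + diag(1e-8, n)),
                error = function(e)
                  stop("covariance factorization failed after jitter: ",
                       conditionMessage(e), call. = FALSE))
  set.seed(seed)
  as.vector(crossprod(L, stats::rnorm(n)))
}

grid_centers <- function(grid_n, dims = 2L) {
  ax <- seq_len(grid_n) - 0.5  # grid-index units: neighbors 1 apart
  if (dims == 2L) {
    g <- expand.grid(x = ax, y = ax)
  } else {
    g <- expand.grid(x = ax, y = ax, z = ax)
  }
  as.matrix(g)
}

# uniform position inside grid cell `g` (1-based linear index, column-major
# over expand.grid order), canvas [0,1]^dims
position_in_grid <- function(g, grid_n, dims, n_pts) {
  idx <- g - 1L
  coords <- matrix(0, nrow = n_pts, ncol = dims)
  for (d in seq_len(dims)) {
    cell <- idx %% grid_n
    coords[, d] <- (cell + stats::runif(n_pts)) / grid_n
    idx <- idx %/% grid_n
  }
  coords
}

#' Allocate cells to random Gaussian-random-field patterns
#'
#' Each patterned population, in declared order, claims the top-ranked
#' still-unclaimed grids under a fresh field draw; the number of claimed
#' grids matches the population's proportion of cells. Cells are placed
#' uniformly inside their population's grids; unpatterned populations are
#' spread uniformly over the leftover grids. Finally the clarity step
#' swaps the coordinates of a `(1 - lam)` fraction of cells.
#'
#' @param ds An [expression_dataset()].
#' @param cfg A [random_pattern_config()].
#' @return A [spatial_assignment()] covering every cell of `ds` (3-D when
#'   `cfg$dims == 3`).
#' @export
allocate_random_patterns <- function(ds, cfg = random_pattern_config()) {
  pops_all <- unique(ds$population)
  unknown <- setdiff(cfg$patterned_populations, pops_all)
  if (length(unknown))
    stop("patterned population(s) not in dataset: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  N <- nrow(ds$matrix)
  G <- cfg$grid_n^cfg$dims
  centers <- grid_centers(cfg$grid_n, cfg$dims)
  Sigma <- build_covariance(centers, cfg$delta)

  claimed <- rep(NA_character_, G)
  for (pi in seq_along(cfg$patterned_populations)) {
    p <- cfg$patterned_populations[pi]
    q <- sum(ds$population == p) / N
    n_claim <- max(1L, round(q * G))
    open <- which(is.na(claimed))
    if (n_claim > length(open))
      stop("population proportions exceed available grids", call. = FALSE)
    field <- sample_field(Sigma,
                          seed = (cfg$seed + 131L * pi) %% .Machine$integer.max)
    take <- open[order(field[open], decreasing = TRUE)[seq_len(n_claim)]]
    claimed[take] <- p
  }

  set.seed(cfg$seed)
  grid_of_cell <- integer(N)
  for (p in cfg$patterned_populations) {
    rows <- which(ds$population == p)
    mine <- which(claimed == p)
    grid_of_cell[rows] <- sample(mine, length(rows), replace = TRUE)
  }
  rest_rows <- which(!(ds$population %in% cfg$patterned_populations))
  if (length(rest_rows)) {
    open <- which(is.na(claimed))
    if (!length(open)) open <- seq_len(G)  # everything claimed: reuse canvas
    grid_of_cell[rest_rows] <- sample(open, length(rest_rows), replace = TRUE)
  }
  coords <- position_in_grid(grid_of_cell, cfg$grid_n, cfg$dims, N)
  assign <- spatial_assignment(cell_id = ds$cell_ids,
                               x = coords[, 1L], y = coords[, 2L],
                               population = unname(ds$population),
                               z = if (cfg$dims == 3L) coords[, 3L])
  apply_fuzziness(assign, cfg$lam,
                  seed = (cfg$seed + 65537L) %% .Machine$integer.max)
}

#' Blur a spatial assignment by random coordinate swaps
#'
#' Exactly `round((1 - lam) * N)` cells participate; participants are
#' paired uniformly at random (an odd participant drops out) and each
#' pair exchanges coordinates. Population labels are untouched and the
#' coordinate multiset is preserved.
#'
#' @param assign A [spatial_assignment()].
#' @param lam Clarity in `[0, 1]`; `lam = 1` returns the input unchanged.
#' @param seed Integer seed.
#' @return The blurred [spatial_assignment()].
#' @export
apply_fuzziness <- function(assign, lam, seed = 1L) {
  stopifnot(lam >= 0, lam <= 1)
  N <- nrow(assign)
  n_part <- round((1 - lam) * N)
  if (n_part < 2L) return(assign)
  set.seed(seed)
  participants <- sample.int(N, n_part)
  if (n_part %% 2L == 1L) participants <- participants[-n_part]
  half <- length(participants) / 2L
  first <- participants[seq_len(half)]
  second <- participants[half + seq_len(half)]
  coord_cols <- intersect(c("x", "y", "z"), names(assign))
  tmp <- assign[first, coord_cols]
  assign[first, coord_cols] <- assign[second, coord_cols]
  assign[second, coord_cols] <- tmp
  assign
}

# -- geometric basis patterns -------------------------------------------------

#' Declare one spatial basis pattern
#'
#' Four kinds of biologically interpretable basis patterns:
#' * `mixed`: an unstructured mixture; a `proportion` of all positions is
#'   sampled and assigned the pattern's population(s).
#' * `cluster`: an ellipse (circle when `a == b`) centered at `center`,
#'   axes `a`, `b`, rotated by `theta`.
#' * `ring`: elliptical annulus(es) around the same center; `d` gives the
#'   ring width(s) (two widths = double ring), `population` one label per
#'   ring, `inner_population` optionally fills the inner cluster.
#' * `vessel`: a stripe of width `d` between two center endpoints
#'   `p1`, `p2`.
#'
#' `infiltration` is a named numeric vector (population -> proportion,
#' summing to < 1): member positions are reassigned to the infiltrating
#' populations with those probabilities.
#'
#' @param kind One of `"mixed"`, `"cluster"`, `"ring"`, `"vessel"`.
#' @param population Population label(s) assigned to member positions.
#' @param center,a,b,theta Ellipse parameters (cluster/ring).
#' @param d Ring width(s) or stripe width.
#' @param p1,p2 Stripe center endpoints (vessel).
#' @param proportion Sampling proportion (mixed).
#' @param infiltration Named numeric vector of infiltrating proportions.
#' @param inner_population Optional label for the region inside the inner
#'   ellipse of a ring.
#' @param symmetric Vessel only: if `TRUE`, drop the half-width offset of
#'   the stripe reference point so the stripe is centered on the segment
#'   `p1`--`p2` (the literal construction places it on one side).
#' @return A list of class `pattern_spec`.
#' @export
pattern_spec <- function(kind = c("mixed", "cluster", "ring", "vessel"),
                         population,
                         center = c(0.5, 0.5), a = 0.2, b = 0.2, theta = 0,
                         d = 0.1, p1 = c(0, 0.5), p2 = c(1, 0.5),
                         proportion = 0.5, infiltration = NULL,
                         inner_population = NULL, symmetric = FALSE) {
  kind <- match.arg(kind)
  stopifnot(a > 0, b > 0, all(d > 0), proportion > 0, proportion <= 1)
  if (kind == "vessel" && sqrt(sum((p2 - p1)^2)) == 0)
    stop("zero-length stripe", call. = FALSE)
  if (!is.null(infiltration)) {
    stopifnot(!is.null(names(infiltration)), all(infiltration > 0))
    if (sum(infiltration) >= 1)
      stop("infiltration proportions must sum to < 1", call. = FALSE)
  }
  structure(list(kind = kind, population = as.character(population),
                 center = center, a = a, b = b, theta = theta, d = d,
                 p1 = p1, p2 = p2, proportion = proportion,
                 infiltration = infiltration,
                 inner_population = inner_population,
                 symmetric = isTRUE(symmetric)),
            class = "pattern_spec")
}

#' Ellipse membership test
#'
#' Rotates each point into the ellipse frame
#' (`x_rot = (x - x0) cos(theta) + (y - y0) sin(theta)`,
#' `y_rot = -(x - x0) sin(theta) + (y - y0) cos(theta)`) and applies the
#' strict elliptical inequality `x_rot^2/a^2 + y_rot^2/b^2 < 1`
#' (boundary excluded).
#'
#' @param pts Two-column matrix (or length-2 vector) of positions.
#' @param spec A `pattern_spec` of kind cluster/ring (uses `center`, `a`,
#'   `b`, `theta`).
#' @return Logical vector.
#' @export
point_in_ellipse <- function(pts, spec) {
  ellipse_value(pts, spec$center, spec$a, spec$b, spec$theta) < 1
}

ellipse_value <- function(pts, center, a, b, theta) {
  pts <- rbind2cols(pts)
  dx <- pts[, 1L] - center[1L]
  dy <- pts[, 2L] - center[2L]
  xr <- dx * cos(theta) + dy * sin(theta)
  yr <- -dx * sin(theta) + dy * cos(theta)
  xr^2 / a^2 + yr^2 / b^2
}

rbind2cols <- function(pts) {
  if (is.null(dim(pts))) matrix(pts, ncol = 2L) else as.matrix(pts)
}

#' Stripe membership test
#'
#' Implements the stripe construction literally: with stripe length
#' `l = |p2 - p1|` and normalized perpendicular
#' `p = (-(y2 - y1)/l, (x2 - x1)/l)`, the reference point is offset to
#' `(x1 + d*p_x/2, y1 + d*p_y/2)` and each position's projections
#' `u` (along the stripe) and `v` (across it) are computed from that
#' reference. Membership: `0 <= u <= l` and `|v| <= d/2` (boundary
#' included). `spec$symmetric = TRUE` drops the offset, centering the
#' stripe on the segment.
#'
#' @param pts Two-column matrix (or length-2 vector) of positions.
#' @param spec A `pattern_spec` of kind vessel.
#' @return Logical vector.
#' @export
point_in_stripe <- function(pts, spec) {
  uv <- stripe_uv(pts, spec)
  l <- attr(uv, "l")
  uv[, 1L] >= 0 & uv[, 1L] <= l & abs(uv[, 2L]) <= spec$d / 2
}

stripe_uv <- function(pts, spec) {
  pts <- rbind2cols(pts)
  dx <- spec$p2[1L] - spec$p1[1L]
  dy <- spec$p2[2L] - spec$p1[2L]
  l <- sqrt(dx^2 + dy^2)
  if (l == 0) stop("zero-length stripe", call. = FALSE)
  p <- c(-dy / l, dx / l)
  ref <- if (spec$symmetric) spec$p1 else spec$p1 + spec$d * p / 2
  rx <- pts[, 1L] - ref[1L]
  ry <- pts[, 2L] - ref[2L]
  u <- rx * (dx / l) + ry * (dy / l)
  v <- -rx * (dy / l) + ry * (dx / l)
  out <- cbind(u = u, v = v)
  attr(out, "l") <- l
  out
}

#' Ring band membership
#'
#' Band `k` of a (possibly multi-)ring is the open elliptical annulus
#' between axes `(a + D[k-1], b + D[k-1])` and `(a + D[k], b + D[k])`
#' with `D = cumsum(d)` and `D[0] = 0`: a position is in band `k` when
#' its ellipse value is `> 1` for the inner boundary and `< 1` for the
#' outer one. Band 0 is the inner cluster (`< 1` for `(a, b)`), `-1` the
#' outside background.
#'
#' @param pts Two-column matrix of positions.
#' @param spec A `pattern_spec` of kind ring.
#' @return Integer vector of band indices.
#' @export
ring_band <- function(pts, spec) {
  widths <- cumsum(spec$d)
  band <- rep(-1L, nrow(rbind2cols(pts)))
  v_inner <- ellipse_value(pts, spec$center, spec$a, spec$b, spec$theta)
  band[v_inner < 1] <- 0L
  lo <- v_inner
  for (k in seq_along(widths)) {
    hi <- ellipse_value(pts, spec$center,
                        spec$a + widths[k], spec$b + widths[k], spec$theta)
    band[lo > 1 & hi < 1] <- k
    lo <- hi
  }
  band
}

# label positions according to one spec; NA = not claimed by this pattern
label_positions <- function(pts, spec) {
  pts <- rbind2cols(pts)
  n <- nrow(pts)
  lab <- rep(NA_character_, n)
  if (spec$kind == "mixed") {
    take <- sample.int(n, round(spec$proportion * n))
    lab[take] <- sample(spec$population, length(take), replace = TRUE)
  } else if (spec$kind == "cluster") {
    lab[point_in_ellipse(pts, spec)] <- spec$population[1L]
  } else if (spec$kind == "ring") {
    band <- ring_band(pts, spec)
    for (k in seq_along(spec$d)) {
      pk <- spec$population[min(k, length(spec$population))]
      lab[band == k] <- pk
    }
    if (!is.null(spec$inner_population)) lab[band == 0L] <- spec$inner_population
  } else {
    lab[point_in_stripe(pts, spec)] <- spec$population[1L]
  }
  # infiltration: members reassigned with the given probabilities
  if (!is.null(spec$infiltration)) {
    members <- which(!is.na(lab))
    if (length(members)) {
      probs <- c(1 - sum(spec$infiltration), spec$infiltration)
      draw <- sample(c("__keep__", names(spec$infiltration)),
                     length(members), replace = TRUE, prob = probs)
      reassign <- draw != "__keep__"
      lab[members[reassign]] <- draw[reassign]
    }
  }
  lab
}

#' Generate a single basis pattern
#'
#' Samples one position per cell uniformly over the unit square, labels
#' member positions by the pattern's geometric test (with infiltration),
#' labels the rest `background`, and attaches to every position a source
#' cell of the matching population drawn from `ds`.
#'
#' @param ds An [expression_dataset()] providing cells of every label
#'   used.
#' @param spec A [pattern_spec()].
#' @param background Population label for non-member positions.
#' @param seed Integer seed.
#' @param n_positions Number of positions (default: number of cells in
#'   `ds`).
#' @return A [spatial_assignment()] with one row per position; the column
#'   `source_cell` names the cell of `ds` realized at that position (use
#'   [realize_expression()] to materialize the expression matrix).
#' @export
generate_basis_pattern <- function(ds, spec, background, seed = 1L,
                                   n_positions = NULL) {
  combine_patterns(list(spec), ds, background, seed = seed,
                   n_positions = n_positions)
}

#' Combine basis patterns in painter's order
#'
#' All patterns share one set of uniform positions; each spec labels the
#' positions its geometry claims, later specs overwriting earlier ones.
#' Unclaimed positions get `background`.
#'
#' @param specs Non-empty list of [pattern_spec()]s (applied in order).
#' @param ds An [expression_dataset()] providing source cells.
#' @param background Population label for unclaimed positions.
#' @param seed Integer seed.
#' @param n_positions Number of positions (default `nrow(ds$matrix)`).
#' @return A [spatial_assignment()] with a `source_cell` column.
#' @export
combine_patterns <- function(specs, ds, background, seed = 1L,
                             n_positions = NULL) {
  stopifnot(length(specs) >= 1L)
  N <- n_positions %||% nrow(ds$matrix)
  set.seed(seed)
  pts <- cbind(stats::runif(N), stats::runif(N))
  lab <- rep(background, N)
  for (spec in specs) {
    this <- label_positions(pts, spec)
    lab[!is.na(this)] <- this[!is.na(this)]
  }
  used <- unique(lab)
  missing <- setdiff(used, unique(ds$population))
  if (length(missing))
    stop("no cells available for population(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  source_cell <- character(N)
  for (p in used) {
    rows <- which(lab == p)
    pool <- ds$cell_ids[ds$population == p]
    source_cell[rows] <- sample(pool, length(rows),
                                replace = length(rows) > length(pool))
  }
  out <- spatial_assignment(cell_id = sprintf("pos%05d", seq_len(N)),
                            x = pts[, 1L], y = pts[, 2L], population = lab)
  out$source_cell <- source_cell
  out
}

#' Materialize expression for a pattern assignment
#'
#' Copies the expression row of each position's `source_cell` into a new
#' dataset whose cells are the positions.
#'
#' @param assign A [spatial_assignment()] with a `source_cell` column.
#' @param ds The [expression_dataset()] the source cells come from.
#' @return An [expression_dataset()] aligned with `assign`.
#' @export
realize_expression <- function(assign, ds) {
  stopifnot("source_cell" %in% names(assign))
  idx <- match(assign$source_cell, ds$cell_ids)
  if (anyNA(idx)) stop("source cell(s) missing from dataset", call. = FALSE)
  m <- ds$matrix[idx, , drop = FALSE]
  rownames(m) <- assign$cell_id
  expression_dataset(m, population = assign$population)
}
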