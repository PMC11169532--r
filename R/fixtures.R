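#' Configuration for the synthetic scRNA-seq fixture generator
#'
#' The generator emulates a droplet-style single-cell experiment with a
#' known population structure: per-gene baseline means drawn from a
#' log-normal, negative-binomial counts around those means (giving the
#' zero inflation at low means that real droplet data shows), and a block
#' of planted marker genes per population whose mean is multiplied by a
#' fold change. Counts are then library-size normalized and
#' log1p-transformed with [normalize_expression()], matching the
#' pre-normalized inputs the simulator expects.
#'
#' @param n_populations Number of populations.
#' @param cells_per_population Cells generated for each population.
#' @param n_genes Total genes.
#' @param markers_per_population Planted marker genes per population;
#'   `markers_per_population * n_populations` must not exceed `n_genes`.
#' @param marker_fold_change Multiplicative elevation of a population's
#'   markers over the baseline (> 1 separates populations; 1 plants none).
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); larger is noisier.
#' @param mean_log,sd_log Location and scale of the log-normal baseline
#'   per-gene means. The defaults (-2, 2) reproduce the expression
#'   profile of QC-filtered droplet data: median gene mean around 0.1
#'   counts, means spanning roughly four orders of magnitude, and an
#'   overall zero fraction near 80%.
#' @param seed Integer seed; the whole fixture is reproducible from it.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_populations = 3L,
                           cells_per_population = 100L,
                           n_genes = 100L,
                           markers_per_population = 10L,
                           marker_fold_change = 8,
                           dispersion = 0.5,
                           mean_log = -2,
                           sd_log = 2,
                           seed = 1L) {
  stopifnot(n_populations >= 1L, cells_per_population >= 1L, n_genes >= 1L,
            markers_per_population >= 0L, marker_fold_change >= 1,
            dispersion > 0, sd_log > 0)
  if (markers_per_population * n_populations > n_genes)
    stop("marker blocks exceed the number of genes", call. = FALSE)
  structure(list(n_populations = as.integer(n_populations),
                 cells_per_population = as.integer(cells_per_population),
                 n_genes = as.integer(n_genes),
                 markers_per_population = as.integer(markers_per_population),
                 marker_fold_change = marker_fold_change,
                 dispersion = dispersion,
                 mean_log = mean_log,
                 sd_log = sd_log,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

#' Generate a synthetic labeled scRNA-seq dataset
#'
#' @param cfg A [fixture_config()].
#' @param normalize If `TRUE` (default) return normalized log-expression;
#'   otherwise raw counts.
#' @return An [expression_dataset()] with populations `pop1..popP` and the
#'   planted marker map attached as attribute `"markers"` (a named list of
#'   gene names per population).
#' @export
generate_fixture_scrnaseq <- function(cfg = fixture_config(),
                                      normalize = TRUE) {
  set.seed(cfg$seed)
  P <- cfg$n_populations
  G <- cfg$n_genes
  n <- cfg$cells_per_population
  base_mu <- exp(stats::rnorm(G, mean = cfg$mean_log, sd = cfg$sd_log))
  pops <- paste0("pop", seq_len(P))
  markers <- list()
  n_marker <- cfg$markers_per_population * P
  if (n_marker > 0L) {
    # marker genes are clearly detected (real markers are well-expressed
    # genes); draw their baselines from a moderate-expression regime
    base_mu[seq_len(n_marker)] <- exp(stats::rnorm(n_marker, 0, 0.5))
  }
  mu_pop <- matrix(rep(base_mu, each = P), nrow = P)  # P x G
  if (cfg$markers_per_population > 0L) {
    for (p in seq_len(P)) {
      idx <- ((p - 1L) * cfg$markers_per_population + 1L):
             (p * cfg$markers_per_population)
      mu_pop[p, idx] <- mu_pop[p, idx] * cfg$marker_fold_change
      markers[[pops[p]]] <- paste0("gene", idx)
    }
  }
  size <- 1 / cfg$dispersion
  counts <- matrix(0, nrow = P * n, ncol = G)
  for (p in seq_len(P)) {
    rows <- ((p - 1L) * n + 1L):(p * n)
    counts[rows, ] <- matrix(
      stats::rnbinom(n * G, size = size, mu = rep(mu_pop[p, ], each = n)),
      nrow = n)
  }
  rownames(counts) <- sprintf("cell%04d", seq_len(P * n))
  colnames(counts) <- paste0("gene", seq_len(G))
  m <- if (normalize) normalize_expression(counts) else counts
  ds <- expression_dataset(m, population = rep(pops, each = n))
  attr(ds, "markers") <- markers
  ds
}

#' Generate a synthetic spatial reference
#'
#' Builds a grid of reference positions with a known group structure and
#' NB-derived expression per group, emulating a layered cortex-style
#' section (`layout = "layers"`: horizontal bands, one per population) or
#' scattered domains (`layout = "blobs"`: one elliptical cluster per
#' population over a background of the last population).
#'
#' @param cfg A [fixture_config()]; `cells_per_population` is ignored, the
#'   grid side `grid_n` controls the number of positions.
#' @param layout `"layers"` or `"blobs"`.
#' @param grid_n Positions per side of the square grid.
#' @return A [spatial_reference()] whose groups are `pop1..popP`.
#' @export
generate_fixture_reference <- function(cfg = fixture_config(),
                                       layout = c("layers", "blobs"),
                                       grid_n = 30L) {
  layout <- match.arg(layout)
  P <- cfg$n_populations
  xy <- expand.grid(x = (seq_len(grid_n) - 0.5) / grid_n,
                    y = (seq_len(grid_n) - 0.5) / grid_n)
  xy <- tibble::tibble(x = xy$x, y = xy$y)
  pops <- paste0("pop", seq_len(P))
  if (layout == "layers") {
    band <- pmin(P, floor(xy$y * P) + 1L)
    group <- pops[band]
  } else {
    set.seed(cfg$seed + 211L)
    group <- rep(pops[P], nrow(xy))
    centers <- cbind(stats::runif(P - 1L, 0.2, 0.8),
                     stats::runif(P - 1L, 0.2, 0.8))
    for (p in seq_len(max(P - 1L, 0L))) {
      inside <- (xy$x - centers[p, 1L])^2 + (xy$y - centers[p, 2L])^2 <
        0.15^2
      group[inside] <- pops[p]
    }
  }
  # per-group expression from the same NB scheme as the cell fixture
  cfg_expr <- cfg
  cfg_expr$cells_per_population <- 1L  # unused
  set.seed(cfg$seed + 97L)
  G <- cfg$n_genes
  base_mu <- exp(stats::rnorm(G, cfg$mean_log, cfg$sd_log))
  n_marker <- cfg$markers_per_population * P
  if (n_marker > 0L)
    base_mu[seq_len(n_marker)] <- exp(stats::rnorm(n_marker, 0, 0.5))
  mu_pop <- matrix(rep(base_mu, each = P), nrow = P)
  if (cfg$markers_per_population > 0L) {
    for (p in seq_len(P)) {
      idx <- ((p - 1L) * cfg$markers_per_population + 1L):
             (p * cfg$markers_per_population)
      mu_pop[p, idx] <- mu_pop[p, idx] * cfg$marker_fold_change
    }
  }
  size <- 1 / cfg$dispersion
  gidx <- match(group, pops)
  counts <- matrix(stats::rnbinom(nrow(xy) * G, size = size,
                                  mu = mu_pop[gidx, ]),
                   nrow = nrow(xy))
  colnames(counts) <- paste0("gene", seq_len(G))
  spatial_reference(coordinates = xy, group = group,
                    expression = normalize_expression(counts))
}
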