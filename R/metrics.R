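# Ground-truth evaluation metrics: expression fidelity (per-gene Pearson
# correlation and mean absolute error, boosted-regression fidelity),
# composition/imputation agreement (PCC, Spearman, RMSE, Jensen-Shannon,
# accuracy score), clustering agreement (ARI, NMI, homogeneity,
# Fowlkes-Mallows), and Moran's I spatial autocorrelation.

pearson <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sx <- sqrt(sum(dx^2)); sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) return(NA_real_)  # undefined for constant vectors
  sum(dx * dy) / (sx * sy)
}

#' Per-gene expression fidelity
#'
#' Pearson correlation and mean absolute error between a gene's
#' normalized expression vector across positions in the ground-truth and
#' the simulated (or predicted) data. A constant vector makes the
#' correlation undefined; it is returned as `NA` so callers can decide
#' exclusion.
#'
#' @param x,y Equal-length numeric vectors (length >= 2), ground truth
#'   and prediction.
#' @return One-row tibble with columns `pcc` and `mae`.
#' @export
gene_vector_metrics <- function(x, y) {
  check_pair(x, y)
  tibble::tibble(pcc = pearson(x, y), mae = mean(abs(x - y)))
}

check_pair <- function(x, y) {
  if (length(x) != length(y))
    stop("vectors must have equal length", call. = FALSE)
  if (length(x) < 2L)
    stop("vectors must have length >= 2", call. = FALSE)
}

#' Spearman rank-order correlation
#'
#' Pearson correlation of mid-ranks; equal to the classical
#' `1 - 6*sum(d^2) / (n(n^2-1))` shortcut when there are no ties.
#'
#' @param x,y Equal-length numeric vectors.
#' @return Correlation in `[-1, 1]`, `NA` if either rank vector is
#'   constant.
#' @export
spearman_rho <- function(x, y) {
  check_pair(x, y)
  pearson(rank(x), rank(y))
}

#' Jensen-Shannon divergence
#'
#' `JS(P, Q) = 0.5*KL(P || M) + 0.5*KL(Q || M)` with `M = (P + Q)/2`,
#' after renormalizing both vectors to sum 1, using the convention
#' `0 * log(0 / .) = 0`. Natural log by default (bound `ln 2`); set
#' `base = 2` for the bit-scaled variant.
#'
#' @param p,q Non-negative vectors with positive sums.
#' @param base Logarithm base (`exp(1)` default).
#' @return Non-negative divergence, 0 iff the renormalized vectors are
#'   equal.
#' @export
js_divergence <- function(p, q, base = exp(1)) {
  check_pair(p, q)
  if (any(p < 0) || any(q < 0))
    stop("probability vectors must be non-negative", call. = FALSE)
  if (sum(p) <= 0 || sum(q) <= 0)
    stop("zero-sum composition vector", call. = FALSE)
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * (log(a[nz] / b[nz]) / log(base)))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Composition agreement metrics
#'
#' The four deconvolution metrics for one spot (or one gene): Pearson
#' correlation, Spearman rank correlation, root-mean-squared error, and
#' Jensen-Shannon divergence of the renormalized proportion vectors.
#'
#' @param x,y Equal-length vectors: ground-truth and predicted
#'   proportions (or expression, for imputation evaluation).
#' @param js_base Logarithm base for the JS divergence.
#' @return One-row tibble with columns `pcc`, `srcc`, `rmse`, `js`.
#' @export
compare_compositions <- function(x, y, js_base = exp(1)) {
  check_pair(x, y)
  tibble::tibble(pcc = pearson(x, y),
                 srcc = spearman_rho(x, y),
                 rmse = sqrt(mean((x - y)^2)),
                 js = js_divergence(x, y, base = js_base))
}

#' Accuracy score across methods
#'
#' Rank-aggregates the four composition metrics: per metric, methods are
#' ranked best to worst (higher better for PCC/SRCC, lower better for
#' RMSE/JS), rank `r` of `m` methods is normalized to `(m - r + 1)/m`
#' (best = 1, worst = 1/m; ties get mid-ranks), and the accuracy score is
#' the mean of the four normalized ranks.
#'
#' @param scores Tibble/data frame with columns `method`, `pcc`, `srcc`,
#'   `rmse`, `js` (one row per method).
#' @return Tibble `method`, `as`, sorted by decreasing score.
#' @export
accuracy_score <- function(scores) {
  scores <- tibble::as_tibble(scores)
  need <- c("method", "pcc", "srcc", "rmse", "js")
  if (!all(need %in% names(scores)))
    stop("scores must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyNA(scores[need]))
    stop("missing metric value(s) in scores", call. = FALSE)
  m <- nrow(scores)
  norm_rank <- function(v, higher_better) {
    r <- if (higher_better) rank(-v, ties.method = "average")
         else rank(v, ties.method = "average")
    (m - r + 1) / m
  }
  tibble::tibble(
    method = scores$method,
    as = (norm_rank(scores$pcc, TRUE) + norm_rank(scores$srcc, TRUE) +
          norm_rank(scores$rmse, FALSE) + norm_rank(scores$js, FALSE)) / 4
  ) |> dplyr::arrange(dplyr::desc(.data$as))
}

# -- clustering agreement -----------------------------------------------------

#' Clustering agreement metrics
#'
#' Computes, from the truth-by-prediction contingency table: the adjusted
#' Rand index, normalized mutual information (mutual information over
#' the arithmetic mean of the two label entropies), homogeneity score
#' `1 - H(C|K)/H(C)` (1 when every cluster contains a single class;
#' asymmetric in its arguments), and the Fowlkes-Mallows index
#' `TP / sqrt((TP+FP)(TP+FN))` over item pairs.
#'
#' @param truth,predicted Equal-length label vectors (length >= 2).
#' @return One-row tibble with columns `ari`, `nmi`, `hs`, `fmi`.
#' @export
compare_labelings <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("labelings must have equal length", call. = FALSE)
  n <- length(truth)
  if (n < 2L) stop("need at least two items", call. = FALSE)
  tab <- table(truth, predicted)
  a <- rowSums(tab); b <- colSums(tab)
  choose2 <- function(v) sum(choose(v, 2))
  # ARI (expected-index form)
  sum_ij <- choose2(as.vector(tab))
  exp_idx <- choose2(a) * choose2(b) / choose(n, 2)
  max_idx <- 0.5 * (choose2(a) + choose2(b))
  ari <- if (max_idx == exp_idx) 1 else (sum_ij - exp_idx) / (max_idx - exp_idx)
  # NMI, arithmetic-mean normalization
  pij <- tab / n
  pa <- a / n; pb <- b / n
  mi_terms <- pij * log(sweep(sweep(pij, 1L, pa, "/"), 2L, pb, "/"))
  mi <- sum(mi_terms[tab > 0])
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  nmi <- if (ha + hb == 0) 1 else mi / (0.5 * (ha + hb))
  # homogeneity
  h_ck <- -sum(vapply(seq_along(b), function(k) {
    col <- tab[, k]
    nz <- col > 0
    sum(col[nz] / n * log(col[nz] / b[k]))
  }, numeric(1)))
  hs <- if (ha == 0) 1 else 1 - h_ck / ha
  # Fowlkes-Mallows from pair counts
  tp <- sum_ij
  fp <- choose2(b) - tp
  fn <- choose2(a) - tp
  fmi <- if ((tp + fp) == 0 || (tp + fn) == 0) 0
         else tp / sqrt((tp + fp) * (tp + fn))
  tibble::tibble(ari = ari, nmi = nmi, hs = hs, fmi = fmi)
}

# -- Moran's I ----------------------------------------------------------------

#' Moran's I spatial autocorrelation
#'
#' Standard Moran's I with row-standardized k-nearest-neighbor weights:
#' `I = (N / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i -
#' xbar)^2`. Positive for spatially clustered values; expectation
#' `-1/(N-1)` under a random permutation. A constant field has no
#' spatial structure to measure and returns `NA`.
#'
#' @param values Numeric vector, one value per position.
#' @param coords Matrix/tibble of positions (2 or 3 columns).
#' @param k_neighbors Neighbors per position (default 6).
#' @param weights Optional pre-built spatial weight matrix overriding the
#'   k-NN construction (rows need not be standardized; they are used as
#'   given).
#' @return Scalar Moran's I, or `NA` for a constant field.
#' @export
morans_i <- function(values, coords, k_neighbors = 6L, weights = NULL) {
  coords <- as.matrix(coords)
  N <- length(values)
  if (N < 3L) stop("need at least 3 positions", call. = FALSE)
  if (nrow(coords) != N)
    stop("coords must have one row per value", call. = FALSE)
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0) return(NA_real_)
  if (is.null(weights)) {
    k <- min(k_neighbors, N - 1L)
    D <- as.matrix(stats::dist(coords))
    diag(D) <- Inf
    weights <- matrix(0, N, N)
    for (i in seq_len(N)) {
      nb <- order(D[i, ])[seq_len(k)]
      weights[i, nb] <- 1 / k
    }
  }
  s0 <- sum(weights)
  (N / s0) * as.numeric(t(z) %*% weights %*% z) / denom
}

#' Moran's I per population of an assignment
#'
#' Applies [morans_i()] to the membership indicator of each population
#' over the assignment's positions -- the per-cell-type spatial
#' autocorrelation used to quantify how patterned a layout is.
#'
#' @param assign A [spatial_assignment()].
#' @param k_neighbors Neighbors for the weight construction.
#' @return Tibble `population`, `morans_i`.
#' @export
population_morans_i <- function(assign, k_neighbors = 6L) {
  coord_cols <- intersect(c("x", "y", "z"), names(assign))
  coords <- as.matrix(assign[coord_cols])
  purrr::map_dfr(sort(unique(assign$population)), function(p) {
    tibble::tibble(
      population = p,
      morans_i = morans_i(as.numeric(assign$population == p), coords,
                          k_neighbors = k_neighbors))
  })
}

# -- boosted-regression expression fidelity -----------------------------------

#' Gradient-boosted-tree coordinate regressor
#'
#' Returns a deterministic, seedable regressor closure for
#' [pcc_gbm()]: gradient-boosted trees (xgboost) of depth 3, 100
#' rounds, single-threaded.
#'
#' @param nrounds,max_depth,eta Boosting rounds, tree depth, learning
#'   rate.
#' @param seed Integer seed.
#' @return Function `(coords, y, newdata) -> predictions`.
#' @export
gbm_regressor <- function(nrounds = 100L, max_depth = 3L, eta = 0.1,
                          seed = 1L) {
  function(coords, y, newdata) {
    set.seed(seed)
    dtrain <- xgboost::xgb.DMatrix(as.matrix(coords), label = y)
    fit <- xgboost::xgb.train(
      params = list(max_depth = max_depth, eta = eta, nthread = 1L,
                    objective = "reg:squarederror", seed = seed),
      data = dtrain, nrounds = nrounds, verbose = 0)
    as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(newdata))))
  }
}

#' k-nearest-neighbor coordinate regressor
#'
#' A fully deterministic alternative regressor (mean of the k nearest
#' training positions), useful to demonstrate the pluggable-regressor
#' contract of [pcc_gbm()].
#'
#' @param k Neighbors to average.
#' @return Function `(coords, y, newdata) -> predictions`.
#' @export
knn_regressor <- function(k = 5L) {
  function(coords, y, newdata) {
    coords <- as.matrix(coords); newdata <- as.matrix(newdata)
    kk <- min(k, nrow(coords))
    apply(newdata, 1L, function(pt) {
      d2 <- colSums((t(coords) - pt)^2)
      mean(y[order(d2)[seq_len(kk)]])
    })
  }
}

#' Smoothed expression fidelity via paired regressions
#'
#' Direct per-position comparison of real and simulated expression is
#' overly stringent when the two datasets are different draws. Instead,
#' one regressor is fit on the real data's (coordinates -> gene
#' expression) and a second on the simulated data's; both predict on the
#' simulated data's coordinates, and the Pearson correlation of the two
#' prediction vectors measures whether the simulated spatial expression
#' surface matches the real one.
#'
#' @param real,sim Lists with elements `coords` (positions x 2) and
#'   `expression` (positions x genes with the gene in `gene`), e.g.
#'   `spot_dataset`s (whose `spots` tibble supplies the coordinates).
#' @param gene Gene name (column of both expression matrices).
#' @param regressor A regressor closure such as [gbm_regressor()].
#' @return Scalar correlation.
#' @export
pcc_gbm <- function(real, sim, gene, regressor = gbm_regressor()) {
  get_parts <- function(d) {
    if (inherits(d, "spot_dataset"))
      list(coords = as.matrix(d$spots[c("x", "y")]), expr = d$expression)
    else
      list(coords = as.matrix(d$coords), expr = as.matrix(d$expression))
  }
  r <- get_parts(real); s <- get_parts(sim)
  if (!(gene %in% colnames(r$expr)) || !(gene %in% colnames(s$expr)))
    stop("gene not present in both datasets: ", gene, call. = FALSE)
  pred_real <- regressor(r$coords, r$expr[, gene], s$coords)
  pred_sim <- regressor(s$coords, s$expr[, gene], s$coords)
  pearson(pred_real, pred_sim)
}

#' Evaluate predicted spot compositions against ground truth
#'
#' Applies [compare_compositions()] row-wise to two aligned composition
#' matrices (spots x populations).
#'
#' @param truth,predicted Matrices with identical dimnames, rows summing
#'   to 1.
#' @return Tibble with one row per spot: `spot_id`, `pcc`, `srcc`,
#'   `rmse`, `js`.
#' @export
evaluate_deconvolution <- function(truth, predicted) {
  stopifnot(all(dim(truth) == dim(predicted)))
  ids <- rownames(truth) %||% sprintf("spot%05d", seq_len(nrow(truth)))
  purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    dplyr::bind_cols(tibble::tibble(spot_id = ids[i]),
                     compare_compositions(truth[i, ], predicted[i, ]))
  })
}
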