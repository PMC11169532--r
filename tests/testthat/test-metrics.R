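# independent summation oracles, written directly from the metric
# definitions (used nowhere in the implementation)
oracle_pcc <- function(x, y) {
  num <- sum((x - mean(x)) * (y - mean(y)))
  num / (sqrt(sum((x - mean(x))^2)) * sqrt(sum((y - mean(y))^2)))
}
oracle_mae <- function(x, y) sum(abs(x - y)) / length(x)
oracle_rmse <- function(x, y) sqrt(sum((x - y)^2) / length(x))
oracle_srcc_tiefree <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}
oracle_js <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q); m <- (p + q) / 2
  kl <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) if (a[i] > 0) s <- s + a[i] * log(a[i] / b[i])
    s
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

test_that("gene vector metrics match closed forms and the oracle", {
  x <- c(1, 2, 3, 4)
  res <- gene_vector_metrics(x, x)
  expect_equal(res$pcc, 1)
  expect_equal(res$mae, 0)
  expect_equal(gene_vector_metrics(c(1, 2, 3), c(3, 2, 1))$pcc, -1)
  y <- c(2, 4, 5, 4)
  res <- gene_vector_metrics(x, y)
  expect_equal(res$pcc, oracle_pcc(x, y), tolerance = 1e-12)
  expect_equal(res$mae, oracle_mae(x, y), tolerance = 1e-12)
  # constant vector -> flagged undefined, not zero
  expect_true(is.na(gene_vector_metrics(c(1, 1, 1), c(1, 2, 3))$pcc))
  expect_error(gene_vector_metrics(1, c(1, 2)), "equal length")
})

test_that("composition metrics match direct evaluation", {
  p <- c(0.5, 0.3, 0.2)
  res <- compare_compositions(p, p)
  expect_equal(unlist(res), c(pcc = 1, srcc = 1, rmse = 0, js = 0))
  # disjoint one-hot vectors: RMSE 1, JS ln 2
  res <- compare_compositions(c(1, 0), c(0, 1))
  expect_equal(res$rmse, 1)
  expect_equal(res$js, log(2), tolerance = 1e-12)
  q <- c(0.2, 0.3, 0.5)
  res <- compare_compositions(p, q)
  expect_equal(res$pcc, oracle_pcc(p, q), tolerance = 1e-12)
  expect_equal(res$srcc, oracle_srcc_tiefree(p, q), tolerance = 1e-12)
  expect_equal(res$rmse, oracle_rmse(p, q), tolerance = 1e-12)
  expect_equal(res$js, oracle_js(p, q), tolerance = 1e-12)
  expect_error(compare_compositions(c(0, 0), c(1, 0)), "zero-sum")
})

test_that("every metric matches its oracle on random instances", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    x <- runif(n); y <- runif(n)
    expect_equal(gene_vector_metrics(x, y)$pcc, oracle_pcc(x, y),
                 tolerance = 1e-10)
    expect_equal(gene_vector_metrics(x, y)$mae, oracle_mae(x, y),
                 tolerance = 1e-10)
    cc <- compare_compositions(x, y)
    expect_equal(cc$srcc, oracle_srcc_tiefree(x, y), tolerance = 1e-10)
    expect_equal(cc$rmse, oracle_rmse(x, y), tolerance = 1e-10)
    expect_equal(cc$js, oracle_js(x, y), tolerance = 1e-10)
  }
})

test_that("JS divergence is symmetric, bounded and definite", {
  set.seed(11)
  for (i in 1:30) {
    p <- runif(5); q <- runif(5)
    expect_equal(js_divergence(p, q), js_divergence(q, p),
                 tolerance = 1e-12)
    expect_gte(js_divergence(p, q), 0)
    expect_lte(js_divergence(p, q), log(2) + 1e-12)
    expect_equal(js_divergence(p, 3 * p), 0, tolerance = 1e-12)
  }
})

test_that("accuracy score follows the normalized-rank definition", {
  # best in all four of 8 methods scores exactly 1; worst scores 1/m
  set.seed(7)
  m <- 8L
  scores <- tibble::tibble(
    method = paste0("m", 1:m),
    pcc = sort(runif(m), decreasing = TRUE),
    srcc = sort(runif(m), decreasing = TRUE),
    rmse = sort(runif(m)),
    js = sort(runif(m)))
  as_tbl <- accuracy_score(scores)
  expect_equal(as_tbl$as[as_tbl$method == "m1"], 1)
  expect_equal(as_tbl$as[as_tbl$method == "m8"], 1 / 8)
  # single method scores 1
  expect_equal(accuracy_score(scores[1, ])$as, 1)
  # enumeration for m <= 5: worst-in-all always scores 1/m
  for (m2 in 2:5) {
    sc <- tibble::tibble(method = paste0("x", 1:m2),
                         pcc = m2:1, srcc = m2:1,
                         rmse = 1:m2, js = 1:m2)
    out <- accuracy_score(sc)
    expect_equal(out$as[out$method == paste0("x", m2)], 1 / m2)
  }
  # invariant to strictly monotone rescaling of one metric column
  resc <- scores
  resc$rmse <- exp(resc$rmse)
  expect_equal(accuracy_score(resc)$as, as_tbl$as)
  expect_error(accuracy_score(scores[, -2]), "columns")
})

test_that("clustering metrics match a pair-counting brute force", {
  res <- compare_labelings(c("A", "A", "B", "B"), c("x", "x", "y", "y"))
  expect_equal(unlist(res), c(ari = 1, nmi = 1, hs = 1, fmi = 1))
  # all-one-cluster prediction: H(C|K) = H(C), homogeneity 0
  res <- compare_labelings(c("A", "A", "B", "B"), rep("k", 4))
  expect_equal(res$hs, 0)
  # worked case against explicit pair enumeration over the 6 pairs
  truth <- c("A", "A", "B", "B")
  pred <- c(1, 1, 1, 2)
  res <- compare_labelings(truth, pred)
  pairs <- combn(4, 2)
  same_t <- apply(pairs, 2, function(ij) truth[ij[1]] == truth[ij[2]])
  same_p <- apply(pairs, 2, function(ij) pred[ij[1]] == pred[ij[2]])
  tp <- sum(same_t & same_p); fp <- sum(!same_t & same_p)
  fn <- sum(same_t & !same_p)
  expect_equal(res$fmi, tp / sqrt((tp + fp) * (tp + fn)),
               tolerance = 1e-12)
  # ARI from the pair-counting identity
  n_pairs <- ncol(pairs)
  exp_idx <- sum(same_t) * sum(same_p) / n_pairs
  max_idx <- 0.5 * (sum(same_t) + sum(same_p))
  expect_equal(res$ari, (tp - exp_idx) / (max_idx - exp_idx),
               tolerance = 1e-12)
  expect_error(compare_labelings("A", "B"), "two items")
})

test_that("ARI agrees with mclust and is label-permutation invariant", {
  skip_if_not_installed("mclust")
  set.seed(31)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    truth <- sample(letters[1:3], n, replace = TRUE)
    pred <- sample(1:4, n, replace = TRUE)
    res <- compare_labelings(truth, pred)
    expect_equal(res$ari, mclust::adjustedRandIndex(truth, pred),
                 tolerance = 1e-10)
    # permuting prediction labels leaves ARI unchanged
    relab <- c("4" = "w", "1" = "x", "2" = "y", "3" = "z")[as.character(pred)]
    expect_equal(compare_labelings(truth, relab)$ari, res$ari,
                 tolerance = 1e-12)
  }
})

test_that("homogeneity is asymmetric in its arguments", {
  truth <- c("A", "A", "B", "B")
  pred <- c("x", "y", "z", "z")   # over-split: perfectly homogeneous
  expect_equal(compare_labelings(truth, pred)$hs, 1)
  expect_lt(compare_labelings(pred, truth)$hs, 1)
})

test_that("Moran's I matches hand evaluation and the ape oracle", {
  # 2x2 checkerboard with rook (2-nearest) neighbors -> I = -1
  coords <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  vals <- c(1, 0, 0, 1)
  expect_equal(morans_i(vals, coords, k_neighbors = 2L), -1,
               tolerance = 1e-12)
  # constant field is flagged undefined
  expect_true(is.na(morans_i(rep(2, 4), coords)))
  skip_if_not_installed("ape")
  set.seed(17)
  N <- 40L
  xy <- cbind(runif(N), runif(N))
  v <- runif(N)
  k <- 6L
  D <- as.matrix(dist(xy)); diag(D) <- Inf
  W <- matrix(0, N, N)
  for (i in seq_len(N)) W[i, order(D[i, ])[1:k]] <- 1 / k
  expect_equal(morans_i(v, xy, k_neighbors = k),
               unname(ape::Moran.I(v, W, scaled = FALSE)$observed),
               tolerance = 1e-10)
})

test_that("Moran's I permutation null centers on -1/(N-1)", {
  set.seed(23)
  N <- 30L
  xy <- cbind(runif(N), runif(N))
  v <- runif(N)
  perms <- replicate(500, morans_i(sample(v), xy, k_neighbors = 4L))
  se <- sd(perms) / sqrt(length(perms))
  expect_lt(abs(mean(perms) - (-1 / (N - 1))), 3 * se + 1e-3)
})

test_that("patterned populations score higher spatial autocorrelation", {
  ds <- tiny_dataset(seed = 91L, P = 3L, n = 60L, G = 5L)
  cfg <- random_pattern_config(grid_n = 8L, delta = 2, lam = 1,
                               patterned_populations = "pop1", seed = 2L)
  assign <- allocate_random_patterns(ds, cfg)
  mi <- population_morans_i(assign)
  expect_gt(mi$morans_i[mi$population == "pop1"],
            max(mi$morans_i[mi$population != "pop1"]))
})

test_that("regression fidelity behaves on identical, noisy and null data", {
  set.seed(3)
  n <- 150L
  coords <- cbind(runif(n), runif(n))
  signal <- sin(4 * coords[, 1]) + cos(3 * coords[, 2])
  real <- list(coords = coords,
               expression = matrix(signal, ncol = 1,
                                   dimnames = list(NULL, "g")))
  # identical data and a deterministic regressor give exactly 1
  expect_equal(pcc_gbm(real, real, "g", regressor = knn_regressor(5L)), 1)
  # small added noise keeps the fitted surfaces nearly identical
  noisy <- real
  noisy$expression[, 1] <- signal + rnorm(n, sd = 0.1 * sd(signal))
  expect_gt(pcc_gbm(real, noisy, "g", regressor = knn_regressor(5L)), 0.9)
  # independent noise has no shared surface
  null <- real
  null$expression[, 1] <- rnorm(n)
  expect_lt(abs(pcc_gbm(real, null, "g", regressor = knn_regressor(5L))),
            0.35)
  # the boosted-tree default regressor is deterministic under its seed
  v1 <- pcc_gbm(real, noisy, "g", regressor = gbm_regressor(seed = 4L))
  v2 <- pcc_gbm(real, noisy, "g", regressor = gbm_regressor(seed = 4L))
  expect_identical(v1, v2)
  expect_gt(v1, 0.9)
  expect_error(pcc_gbm(real, noisy, "missing"), "gene")
})

test_that("deconvolution evaluation scores perfect agreement perfectly", {
  comp <- matrix(c(0.2, 0.8, 0.5, 0.5, 1, 0), ncol = 2, byrow = TRUE,
                 dimnames = list(paste0("s", 1:3), c("A", "B")))
  rep <- evaluate_deconvolution(comp, comp)
  expect_equal(rep$rmse, rep(0, 3))
  expect_equal(rep$js, rep(0, 3))
})
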