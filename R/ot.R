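# Exact optimal transport via the transportation simplex.
#
# The mapping step solves the discrete Monge-Kantorovich linear program
#   min <gamma, M>_F  s.t.  gamma 1 = a, gamma^T 1 = b, gamma >= 0
# exactly. The solver below is a classical transportation simplex:
# north-west-corner initial basis (kept as a spanning tree of m+n-1 arcs,
# padding with zero-flow arcs under degeneracy), dual variables (u, v) from
# the tree, Dantzig entering rule on reduced costs, and a cycle pivot.

#' Squared-Euclidean expression cost matrix
#'
#' `M[i, j]` is the squared Euclidean distance between generated cell `i`
#' and reference position `j` in expression space. Gene columns must match
#' in number and order; the mapping never sees coordinates, only
#' expression.
#'
#' @param gen_expr Generated cells x genes matrix.
#' @param ref_expr Reference positions x genes matrix.
#' @return A `nrow(gen_expr)` x `nrow(ref_expr)` non-negative matrix.
#' @export
cost_matrix <- function(gen_expr, ref_expr) {
  gen_expr <- as.matrix(gen_expr)
  ref_expr <- as.matrix(ref_expr)
  if (ncol(gen_expr) != ncol(ref_expr))
    stop("gene count mismatch: ", ncol(gen_expr), " vs ", ncol(ref_expr),
         call. = FALSE)
  if (!is.null(colnames(gen_expr)) && !is.null(colnames(ref_expr)) &&
      !identical(colnames(gen_expr), colnames(ref_expr)))
    stop("gene order differs between generated and reference matrices",
         call. = FALSE)
  g2 <- rowSums(gen_expr^2)
  r2 <- rowSums(ref_expr^2)
  M <- outer(g2, r2, "+") - 2 * gen_expr %*% t(ref_expr)
  pmax(M, 0)
}

#' Solve the exact optimal-transport problem
#'
#' @param M Cost matrix (sources x targets).
#' @param a Source weights (defaults to uniform). Must sum to `sum(b)`.
#' @param b Target weights (defaults to uniform).
#' @param tol Feasibility tolerance on the marginal sums.
#' @return A list of class `transport_plan`: `gamma` (the optimal plan),
#'   `objective` (`sum(gamma * M)`), and the marginals `a`, `b`.
#' @export
solve_ot <- function(M, a = NULL, b = NULL, tol = 1e-9) {
  M <- as.matrix(M)
  n <- nrow(M); m <- ncol(M)
  if (is.null(a)) a <- rep(1 / n, n)
  if (is.null(b)) b <- rep(1 / m, m)
  if (any(a < 0) || any(b < 0))
    stop("weights must be non-negative", call. = FALSE)
  if (abs(sum(a) - sum(b)) > 1e-8)
    stop("infeasible: sum(a) != sum(b)", call. = FALSE)
  gamma <- transport_simplex(M, a, b)
  structure(list(gamma = gamma, objective = sum(gamma * M), a = a, b = b),
            class = "transport_plan")
}

#' @export
print.transport_plan <- function(x, ...) {
  cat(sprintf("<transport_plan> %d x %d, objective %.6g\n",
              nrow(x$gamma), ncol(x$gamma), x$objective))
  invisible(x)
}

transport_simplex <- function(M, a, b, max_iter = NULL) {
  n <- length(a); m <- length(b)
  total <- sum(a)
  if (total <= 0) return(matrix(0, n, m))
  # scale to unit mass for numerical uniformity
  sa <- a / total; sb <- b / total
  if (is.null(max_iter)) max_iter <- 20L * (n + m) * max(n, m)

  flow <- matrix(0, n, m)
  basis <- matrix(FALSE, n, m)
  # north-west corner rule, recording m+n-1 basic arcs (zero arcs if needed)
  i <- 1L; j <- 1L
  ra <- sa; rb <- sb
  nbasic <- 0L
  while (nbasic < n + m - 1L) {
    q <- min(ra[i], rb[j])
    flow[i, j] <- q
    basis[i, j] <- TRUE
    nbasic <- nbasic + 1L
    ra[i] <- ra[i] - q
    rb[j] <- rb[j] - q
    if (nbasic == n + m - 1L) break
    if (ra[i] <= rb[j] && i < n) i <- i + 1L else j <- j + 1L
  }

  for (iter in seq_len(max_iter)) {
    duals <- ot_duals(M, basis, n, m)
    red <- M - outer(duals$u, rep(1, m)) - outer(rep(1, n), duals$v)
    red[basis] <- 0
    ent <- which.min(red)
    if (red[ent] >= -1e-11) break
    ei <- (ent - 1L) %% n + 1L
    ej <- (ent - 1L) %/% n + 1L
    cyc <- ot_cycle(basis, ei, ej, n, m)
    # alternate +/- along the cycle starting with + at the entering arc
    minus <- cyc[seq(2L, nrow(cyc), by = 2L), , drop = FALSE]
    theta_idx <- which.min(flow[minus])
    theta <- flow[minus][theta_idx]
    sgn <- rep_len(c(1, -1), nrow(cyc))
    for (r in seq_len(nrow(cyc)))
      flow[cyc[r, 1L], cyc[r, 2L]] <- flow[cyc[r, 1L], cyc[r, 2L]] +
        sgn[r] * theta
    leave <- minus[theta_idx, ]
    basis[leave[1L], leave[2L]] <- FALSE
    basis[ei, ej] <- TRUE
    flow[flow < 0] <- 0  # clamp floating-point negatives
  }
  flow * total
}

# dual variables from the spanning tree of basic arcs (u[1] = 0)
ot_duals <- function(M, basis, n, m) {
  u <- rep(NA_real_, n); v <- rep(NA_real_, m)
  u[1L] <- 0
  repeat {
    progressed <- FALSE
    for (i in which(!is.na(u))) {
      js <- which(basis[i, ] & is.na(v))
      if (length(js)) { v[js] <- M[i, js] - u[i]; progressed <- TRUE }
    }
    for (j in which(!is.na(v))) {
      is <- which(basis[, j] & is.na(u))
      if (length(is)) { u[is] <- M[is, j] - v[j]; progressed <- TRUE }
    }
    if (!anyNA(u) && !anyNA(v)) break
    if (!progressed) { # disconnected tree (shouldn't happen); root a new node
      u[which(is.na(u))[1L]] <- 0
      progressed <- TRUE
    }
  }
  list(u = u, v = v)
}

# Alternating cycle created by the entering arc (ei, ej): the entering arc
# plus the unique tree path between row ei and column ej in the basis
# forest. Nodes: rows 1..n, columns n+1..n+m.
ot_cycle <- function(basis, ei, ej, n, m) {
  start <- ei
  target <- n + ej
  prev <- rep(NA_integer_, n + m)
  visited <- rep(FALSE, n + m)
  stack <- start
  visited[start] <- TRUE
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (node == target) break
    nbrs <- if (node <= n) n + which(basis[node, ]) else which(basis[, node - n])
    for (nb in nbrs) {
      if (!visited[nb]) {
        visited[nb] <- TRUE
        prev[nb] <- node
        stack <- c(stack, nb)
      }
    }
  }
  path <- integer(0)
  node <- target
  while (!is.na(node)) {
    path <- c(node, path)
    node <- prev[node]
  }
  # path = ei ... n+ej; cycle = entering arc, then path arcs walked back
  # from the column end to the row end so consecutive arcs share a node
  k <- length(path)
  arcs <- matrix(0L, nrow = k, ncol = 2L)
  arcs[1L, ] <- c(ei, ej)
  r <- 2L
  for (s in seq(k - 1L, 1L)) {
    p <- path[s]; q <- path[s + 1L]
    arcs[r, ] <- if (p <= n) c(p, q - n) else c(q, p - n)
    r <- r + 1L
  }
  arcs
}

#' Extract a bijective cell-to-position mapping from a transport plan
#'
#' Concretizes "map each generated cell to the position with maximum
#' likelihood of spatial origin": repeatedly take the largest remaining
#' entry of the plan, fix that (cell, position) pair, and remove its row
#' and column; ties break toward the lowest (row, column) index. The
#' result is a deterministic bijection.
#'
#' @param plan A `transport_plan` (square: equal cell and position counts).
#' @return Integer vector `p` of length n: position `j` receives cell
#'   `p[j]`.
#' @export
assign_positions <- function(plan) {
  gamma <- if (inherits(plan, "transport_plan")) plan$gamma else as.matrix(plan)
  n <- nrow(gamma)
  if (n != ncol(gamma))
    stop("assign_positions requires a square plan", call. = FALSE)
  cell_of_position <- integer(n)
  g <- gamma
  for (step in seq_len(n)) {
    best <- which(g == max(g), arr.ind = TRUE)
    # lowest (row, column) among ties
    best <- best[order(best[, 1L], best[, 2L])[1L], , drop = FALSE]
    i <- best[1L, 1L]; j <- best[1L, 2L]
    cell_of_position[j] <- i
    g[i, ] <- -Inf
    g[, j] <- -Inf
  }
  cell_of_position
}
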