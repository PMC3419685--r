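#' Effective resistance distances between points on a cost surface
#'
#' Treats every non-NODATA cell as a circuit node and every 8-neighbour move
#' as a resistor of resistance `cellsize * (c_i + c_j)/2` (times `sqrt(2)`
#' for diagonals), i.e. conductance is the reciprocal of the least-cost edge
#' weight. Pairwise effective resistance is obtained from one sparse
#' symmetric solve per connected component: one point node is grounded, unit
#' injections are solved for the remaining point nodes, and
#' `R(i,j) = X[i,i] + X[j,j] - 2 X[i,j]` (with `R(i,ground) = X[i,i]`).
#' Pairs in different components get `Inf` with a warning. Residuals of
#' every solve are checked against `tol`.
#'
#' @param surface a [cost_surface()].
#' @param points two-column matrix/data.frame of x, y coordinates.
#' @param ids point labels.
#' @param tol residual tolerance of the linear solves.
#' @return list of class `resistance_result`: `resistance` (a
#'   [pairwise_matrix()] of kind `resistance`), `current` (`NULL` here; see
#'   [current_map()]), `tol`, `max_residual`.
#' @export
resistance_matrix <- function(surface, points, ids = NULL, tol = 1e-8) {
  points <- as.matrix(points)
  if (is.null(ids)) ids <- paste0("p", seq_len(nrow(points)))
  np <- nrow(points)
  nodes <- .snap_nodes(surface, points)
  ed <- .grid_edges(surface)
  cond <- 1 / ed$weight
  lap <- .laplacian(ed, cond)
  comp <- .node_components(ed)
  vals <- matrix(Inf, np, np)
  diag(vals) <- 0
  max_res <- 0
  for (cp in unique(comp[nodes])) {
    pidx <- which(comp[nodes] == cp)
    un <- unique(nodes[pidx])
    if (length(un) < 2) {
      vals[pidx, pidx] <- 0
      next
    }
    ground <- un[length(un)]
    others <- un[-length(un)]
    keep <- which(comp == cp)
    keep <- keep[keep != ground]
    Lred <- lap[keep, keep, drop = FALSE]
    B <- Matrix::sparseMatrix(i = match(others, keep),
                              j = seq_along(others), x = 1,
                              dims = c(length(keep), length(others)))
    X <- Matrix::solve(Lred, B)
    max_res <- max(max_res, max(abs(Lred %*% X - B)))
    V <- as.matrix(X[match(others, keep), , drop = FALSE])
    rmat <- matrix(0, length(un), length(un))
    no <- length(others)
    rmat[seq_len(no), seq_len(no)] <-
      outer(diag(V), diag(V), "+") - V - t(V)
    rmat[seq_len(no), no + 1] <- rmat[no + 1, seq_len(no)] <- diag(V)
    m <- match(nodes[pidx], un)
    vals[pidx, pidx] <- rmat[m, m]
  }
  .check(max_res <= tol,
         "resistance solve residual %.3g exceeds tolerance %.3g",
         max_res, tol)
  if (any(is.infinite(vals[upper.tri(vals)]))) {
    warning("point pair(s) in disconnected components: infinite resistance")
  }
  structure(list(resistance = pairwise_matrix(ids, vals, kind = "resistance"),
                 current = NULL, tol = tol, max_residual = max_res),
            class = "resistance_result")
}

# internal: sparse graph Laplacian from an edge list with conductances
.laplacian <- function(ed, cond) {
  n <- ed$n_nodes
  A <- Matrix::sparseMatrix(i = c(ed$from, ed$to), j = c(ed$to, ed$from),
                            x = c(cond, cond), dims = c(n, n))
  Matrix::Diagonal(n, Matrix::rowSums(A)) - A
}

# internal: connected-component label per node (isolated/NODATA cells get 0)
.node_components <- function(ed) {
  g <- igraph::make_empty_graph(n = ed$n_nodes, directed = FALSE)
  g <- igraph::add_edges(g, rbind(ed$from, ed$to))
  comp <- igraph::components(g)$membership
  deg <- igraph::degree(g)
  comp[deg == 0] <- 0L
  comp
}

#' Cumulative all-to-one current map over sampled groups
#'
#' For each focal group in turn, grounds its node and injects current at
#' every other group's node proportional to that group's size, solves the
#' circuit, and accumulates per-cell current magnitude (half the summed
#' absolute currents of a cell's incident resistors) across focal choices.
#' The analysed grid is clipped to a buffer around the bounding box of the
#' groups.
#'
#' @param surface a [cost_surface()].
#' @param groups data.frame with `x`, `y`, `size`.
#' @param buffer clip buffer around the groups' bounding box (m), default
#'   10 km (configurable 5-25 km).
#' @param tol residual tolerance of the solves.
#' @return a `resistance_result` whose `current` element is a list with the
#'   clipped `map` (matrix, NA at NODATA), the clip georeference (`xll`,
#'   `yll`, `cellsize`, `nrows`, `ncols`) and `conservation_error` (largest
#'   injected-vs-absorbed mismatch across solves).
#' @export
current_map <- function(surface, groups, buffer = 10000, tol = 1e-8) {
  .check(nrow(groups) >= 2, "need >= 2 groups")
  .check(all(c("x", "y", "size") %in% names(groups)),
         "groups needs columns x, y, size")
  # clip to buffered bounding box
  xr <- range(groups$x) + c(-buffer, buffer)
  yr <- range(groups$y) + c(-buffer, buffer)
  col_lo <- max(1L, floor((xr[1] - surface$xll) / surface$cellsize) + 1L)
  col_hi <- min(surface$ncols, ceiling((xr[2] - surface$xll) / surface$cellsize))
  row_lo <- max(1L, surface$nrows - ceiling((yr[2] - surface$yll) / surface$cellsize) + 1L)
  row_hi <- min(surface$nrows, surface$nrows - floor((yr[1] - surface$yll) / surface$cellsize))
  clip <- structure(list(
    costs = surface$costs[row_lo:row_hi, col_lo:col_hi, drop = FALSE],
    nrows = row_hi - row_lo + 1L, ncols = col_hi - col_lo + 1L,
    xll = surface$xll + (col_lo - 1L) * surface$cellsize,
    yll = surface$yll + (surface$nrows - row_hi) * surface$cellsize,
    cellsize = surface$cellsize, nodata = surface$nodata,
    provenance = surface$provenance), class = "cost_surface")
  nodes <- .snap_nodes(clip, cbind(groups$x, groups$y))
  ed <- .grid_edges(clip)
  cond <- 1 / ed$weight
  lap <- .laplacian(ed, cond)
  comp <- .node_components(ed)
  .check(length(unique(comp[nodes])) == 1,
         "groups span disconnected components")
  keep_all <- which(comp == comp[nodes[1]])
  acc <- numeric(ed$n_nodes)
  max_res <- 0; max_cons <- 0
  for (f in seq_along(nodes)) {
    ground <- nodes[f]
    keep <- keep_all[keep_all != ground]
    inj <- numeric(ed$n_nodes)
    for (j in seq_along(nodes)[-f]) inj[nodes[j]] <- inj[nodes[j]] + groups$size[j]
    b <- inj[keep]
    v <- numeric(ed$n_nodes)
    sol <- Matrix::solve(lap[keep, keep, drop = FALSE], b)
    max_res <- max(max_res, max(abs(lap[keep, keep] %*% sol - b)))
    v[keep] <- as.numeric(sol)
    iedge <- abs(v[ed$from] - v[ed$to]) * cond
    node_cur <- numeric(ed$n_nodes)
    tab_f <- tapply(iedge, ed$from, sum)
    tab_t <- tapply(iedge, ed$to, sum)
    node_cur[as.integer(names(tab_f))] <-
      node_cur[as.integer(names(tab_f))] + tab_f
    node_cur[as.integer(names(tab_t))] <-
      node_cur[as.integer(names(tab_t))] + tab_t
    node_cur <- node_cur / 2
    # Kirchhoff: all flow incident to the ground is inbound, so twice its
    # half-sum node current equals the total absorbed current
    absorbed <- node_cur[ground] * 2
    max_cons <- max(max_cons, abs(absorbed - sum(inj)))
    acc <- acc + node_cur
  }
  .check(max_res <= tol, "current solve residual %.3g exceeds tol %.3g",
         max_res, tol)
  map <- matrix(acc, clip$nrows, clip$ncols)
  map[is.na(clip$costs)] <- NA_real_
  structure(list(resistance = NULL,
                 current = list(map = map, xll = clip$xll, yll = clip$yll,
                                cellsize = clip$cellsize, nrows = clip$nrows,
                                ncols = clip$ncols,
                                conservation_error = max_cons),
                 tol = tol, max_residual = max_res),
            class = "resistance_result")
}
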