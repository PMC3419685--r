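#' Cost surfaces from a categorical raster
#'
#' `cost_surface()` assigns a positive traversal cost to every class;
#' `build_cost_surface()` is the one-class sweep form used throughout the
#' cost-sweep design: the focal class gets `cost`, every other class gets the
#' equal low cost 1.
#'
#' @param raster a [landscape_raster()].
#' @param costs named numeric vector class -> cost (> 0) covering every class
#'   present in the raster.
#' @return an object of class `cost_surface` (grid of per-cell costs, NODATA
#'   cells `NA`, plus the provenance map).
#' @export
cost_surface <- function(raster, costs) {
  .check(all(costs > 0) && all(is.finite(costs)), "costs must be positive")
  present <- names(raster$legend)[raster$legend %in% unique(as.vector(raster$codes))]
  .check(all(present %in% names(costs)),
         "costs missing for class(es): %s",
         paste(setdiff(present, names(costs)), collapse = ","))
  cmat <- matrix(NA_real_, raster$nrows, raster$ncols)
  for (cls in names(costs)) {
    if (!cls %in% names(raster$legend)) stop("unknown class: ", cls,
                                             call. = FALSE)
    cmat[raster$codes == raster$legend[[cls]]] <- costs[[cls]]
  }
  structure(list(costs = cmat, nrows = raster$nrows, ncols = raster$ncols,
                 xll = raster$xll, yll = raster$yll,
                 cellsize = raster$cellsize, nodata = raster$nodata,
                 provenance = costs),
            class = "cost_surface")
}

#' @rdname cost_surface
#' @param focal_class class whose cost is varied.
#' @param cost cost assigned to the focal class (>= 1).
#' @export
build_cost_surface <- function(raster, focal_class, cost) {
  .check(focal_class %in% names(raster$legend),
         "unknown class: %s", focal_class)
  .check(cost >= 1, "cost must be >= 1")
  if (!raster$legend[[focal_class]] %in% unique(as.vector(raster$codes))) {
    warning(sprintf("class '%s' absent from raster: uniform surface",
                    focal_class))
  }
  costs <- stats::setNames(rep(1, length(raster$legend)),
                           names(raster$legend))
  costs[focal_class] <- cost
  cost_surface(raster, costs)
}

# internal: 8-neighbour grid edges of a cost surface.
# Edge traversal cost = cellsize * (c_from + c_to)/2, times sqrt(2) for
# diagonal moves (the COSTDISTANCE convention). Returns node indices (column-
# major over the grid, NODATA cells excluded) and both the cost-length and
# the conductance (1/cost-length) of each edge.
.grid_edges <- function(surface) {
  cm <- surface$costs
  nr <- surface$nrows; nc <- surface$ncols
  idx <- matrix(seq_len(nr * nc), nr, nc)
  pair <- function(dr, dc) {
    rows <- seq_len(nr - abs(dr)) + max(-dr, 0)
    cols <- seq_len(nc - abs(dc)) + max(-dc, 0)
    from <- idx[rows, cols, drop = FALSE]
    to <- idx[rows + dr, cols + dc, drop = FALSE]
    cbind(as.vector(from), as.vector(to))
  }
  e <- rbind(pair(1, 0), pair(0, 1), pair(1, 1), pair(-1, 1))
  diagf <- c(rep(1, (nr - 1) * nc + nr * (nc - 1)),
             rep(sqrt(2), 2 * (nr - 1) * (nc - 1)))
  cfrom <- cm[e[, 1]]; cto <- cm[e[, 2]]
  keep <- !is.na(cfrom) & !is.na(cto)
  w <- surface$cellsize * (cfrom[keep] + cto[keep]) / 2 * diagf[keep]
  list(from = e[keep, 1], to = e[keep, 2], weight = w,
       n_nodes = nr * nc)
}

# internal: snap points (matrix/data.frame with x, y) to node indices
.snap_nodes <- function(surface, points) {
  points <- as.matrix(points)
  rc <- snap_to_cell(surface, points[, 1], points[, 2])
  node <- (rc$col - 1L) * surface$nrows + rc$row
  .check(all(!is.na(surface$costs[node])),
         "point(s) snap to NODATA cell(s): %s",
         paste(which(is.na(surface$costs[node])), collapse = ","))
  node
}

#' Least-cost distance matrix between points on a cost surface
#'
#' Builds the 8-connected grid graph (move cost = `cellsize * (c_from +
#' c_to) / 2`, `sqrt(2)` times that for diagonal moves) and returns all
#' pairwise shortest-path costs between the snapped points (Dijkstra).
#' Point pairs in disconnected components get `Inf` with a warning.
#'
#' @param surface a [cost_surface()].
#' @param points two-column matrix/data.frame of x, y coordinates.
#' @param ids point labels (default `p1..pn`).
#' @return a [pairwise_matrix()] of kind `least_cost`.
#' @export
least_cost_matrix <- function(surface, points, ids = NULL) {
  points <- as.matrix(points)
  if (is.null(ids)) ids <- paste0("p", seq_len(nrow(points)))
  ed <- .grid_edges(surface)
  g <- igraph::make_empty_graph(n = ed$n_nodes, directed = FALSE)
  g <- igraph::add_edges(g, rbind(ed$from, ed$to))
  nodes <- .snap_nodes(surface, points)
  un <- unique(nodes)
  dm <- igraph::distances(g, v = un, to = un, weights = ed$weight,
                          algorithm = "dijkstra")
  full <- dm[match(nodes, un), match(nodes, un), drop = FALSE]
  if (any(is.infinite(full[upper.tri(full)]))) {
    warning("point pair(s) in disconnected components: infinite distance")
  }
  pairwise_matrix(ids, full, kind = "least_cost")
}

#' Euclidean distance matrix between points
#' @param points two-column matrix/data.frame of x, y coordinates.
#' @param ids point labels.
#' @return a [pairwise_matrix()] of kind `euclidean`.
#' @export
euclidean_matrix <- function(points, ids = NULL) {
  points <- as.matrix(points)
  .check(all(is.finite(points)), "coordinates must be finite")
  if (is.null(ids)) ids <- paste0("p", seq_len(nrow(points)))
  pairwise_matrix(ids, as.matrix(stats::dist(points)), kind = "euclidean")
}

# internal: 8-connected component labelling of a logical matrix (BFS)
.label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]; queue <- queue[-length(queue)]
      r <- (v - 1L) %% nr + 1L; cc <- (v - 1L) %/% nr + 1L
      nb_r <- r + offs[, 1]; nb_c <- cc + offs[, 2]
      okn <- nb_r >= 1 & nb_r <= nr & nb_c >= 1 & nb_c <= nc
      nb <- (nb_c[okn] - 1L) * nr + nb_r[okn]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}

#' Classify residence clusters into the residential habitat class
#'
#' Applies the residential-area definition: residences less than 100 m apart
#' belong to one cluster (implemented raster-natively as single linkage via
#' dilation of each residence footprint by a 50 m radius: two dilated
#' footprints touching is equivalent to a gap under 100 m), and a cluster
#' whose total residence area exceeds 3 hectares (strictly) becomes the
#' residential class; smaller clusters fall to "other non-forest".
#'
#' @param residence_mask logical matrix (TRUE = residence cell).
#' @param cellsize cell edge (m).
#' @return list with `classes` (character matrix: `"residential"`, `"other"`
#'   or `NA` for non-residence cells), `cluster_id` (integer matrix over
#'   residence cells), `area_ha` (per-cluster residence area in hectares).
#' @export
classify_residential <- function(residence_mask, cellsize) {
  mask <- as.matrix(residence_mask)
  storage.mode(mask) <- "logical"
  nr <- nrow(mask); nc <- ncol(mask)
  rad <- ceiling(50 / cellsize)
  offs <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  offs <- offs[sqrt(offs$dr^2 + offs$dc^2) * cellsize <= 50, ]
  dil <- matrix(FALSE, nr, nc)
  cells <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(offs))) {
    r <- cells[, 1] + offs$dr[k]; cc <- cells[, 2] + offs$dc[k]
    okn <- r >= 1 & r <= nr & cc >= 1 & cc <= nc
    dil[cbind(r[okn], cc[okn])] <- TRUE
  }
  lab <- .label_components(dil)
  cluster_id <- matrix(0L, nr, nc)
  cluster_id[mask] <- lab[mask]
  nclust <- max(lab)
  area_ha <- vapply(seq_len(nclust), function(k) {
    sum(cluster_id == k) * cellsize^2 / 1e4
  }, numeric(1))
  keep <- which(area_ha > 0)
  area_ha <- area_ha[keep]
  classes <- matrix(NA_character_, nr, nc)
  for (j in seq_along(keep)) {
    classes[cluster_id == keep[j]] <-
      if (area_ha[j] > 3) "residential" else "other"
  }
  cluster_id[cluster_id > 0] <- match(cluster_id[cluster_id > 0], keep)
  list(classes = classes, cluster_id = cluster_id, area_ha = area_ha)
}
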