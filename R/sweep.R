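#' One-class cost sweep of Mantel tests over habitat classes
#'
#' The core sensitivity design: for every habitat class and every cost value,
#' build the one-class cost surface ([build_cost_surface()]), compute the
#' least-cost distance matrix between the sampled individuals, and run a
#' simple Mantel test of each genetic matrix against it plus a partial Mantel
#' test controlling for Euclidean distance. Tails follow the expected sign of
#' each metric: `greater` for the a-hat distance, `less` for the Moran's I
#' similarity. The Euclidean baselines (simple Mantel of each genetic matrix
#' against straight-line distance) are computed once.
#'
#' @param genetic named list of [pairwise_matrix()] objects, e.g.
#'   `list(rousset_a = ..., morans_i = ...)`; masks (e.g. from
#'   [restrict_pairs()]) are honoured.
#' @param raster a [landscape_raster()].
#' @param points two-column matrix of x, y per individual, aligned with the
#'   genetic matrix ids.
#' @param classes habitat classes to sweep (default: all legend classes
#'   except forest... pass explicitly to include forest).
#' @param costs cost values of the sweep.
#' @param n_perm Mantel permutations.
#' @param seed integer seed.
#' @return list of class `sweep_result`: `grid` (data.frame class, cost,
#'   metric, kind, r, p), `baseline` (data.frame metric, r, p), `costs`,
#'   `classes`, `n_perm`.
#' @export
cost_sweep <- function(genetic, raster, points,
                       classes = setdiff(names(raster$legend), "forest"),
                       costs = c(10, 50, 100, 1000, 5000, 10000),
                       n_perm = 10000, seed = 1L) {
  .check(length(genetic) >= 1 && !is.null(names(genetic)),
         "genetic must be a named list of pairwise matrices")
  points <- as.matrix(points)
  ids <- genetic[[1]]$ids
  .check(nrow(points) == length(ids), "points must align with genetic ids")
  tails <- vapply(genetic, function(g) {
    if (g$kind == "morans_i") "less" else "greater"
  }, character(1))
  eu <- euclidean_matrix(points, ids = ids)
  # the Euclidean reference line is the simple Mantel of genetics against
  # straight-line distance; it is entered once per metric and test kind so
  # every sweep cell has a baseline row
  baseline <- do.call(rbind, lapply(names(genetic), function(met) {
    mt <- mantel(genetic[[met]], eu, n_perm = n_perm, tail = tails[[met]],
                 seed = derive_seed(seed, paste0("base_", met)))
    data.frame(metric = met, kind = c("simple", "partial"), r = mt$r,
               p = mt$p, stringsAsFactors = FALSE)
  }))
  rows <- list()
  for (cls in classes) {
    for (cost in costs) {
      surf <- build_cost_surface(raster, cls, cost)
      lc <- least_cost_matrix(surf, points, ids = ids)
      for (met in names(genetic)) {
        sseed <- derive_seed(seed, sprintf("%s_%g_%s", cls, cost, met))
        ms <- mantel(genetic[[met]], lc, n_perm = n_perm,
                     tail = tails[[met]], seed = sseed)
        # a degenerate surface (least-cost collinear with Euclidean) leaves
        # the partial undefined: record NA rather than abort the sweep
        mp <- tryCatch(
          partial_mantel(genetic[[met]], lc, eu, n_perm = n_perm,
                         tail = tails[[met]], seed = sseed + 1L),
          error = function(e) list(r = NA_real_, p = NA_real_))
        rows[[length(rows) + 1]] <- data.frame(
          class = cls, cost = cost, metric = met,
          kind = c("simple", "partial"), r = c(ms$r, mp$r),
          p = c(ms$p, mp$p), stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(grid = do.call(rbind, rows), baseline = baseline,
                 costs = costs, classes = classes, n_perm = n_perm),
            class = "sweep_result")
}

#' Barrier verdicts from a cost sweep
#'
#' A habitat class is flagged as a barrier candidate iff at some cost value
#' the absolute Mantel r against its least-cost distances exceeds the
#' absolute Euclidean-baseline r with a significant p, *simultaneously* for
#' every genetic metric and for both the simple and the partial test. The
#' qualifying cost values are reported per class.
#'
#' @param sweep a `sweep_result` from [cost_sweep()].
#' @param alpha significance level for the Mantel p-values.
#' @return data.frame per class: `class`, `barrier` (logical),
#'   `qualifying_costs` (comma-separated string, `""` if none).
#' @export
barrier_call <- function(sweep, alpha = 0.05) {
  base <- sweep$baseline[sweep$baseline$kind == "simple", ]
  base_r <- stats::setNames(abs(base$r), base$metric)
  g <- sweep$grid
  cells_per_cost <- length(unique(g$metric)) * length(unique(g$kind))
  out <- lapply(sweep$classes, function(cls) {
    quals <- c()
    for (cost in sweep$costs) {
      cells <- g[g$class == cls & g$cost == cost, ]
      if (nrow(cells) < cells_per_cost) next
      beats <- abs(cells$r) > base_r[cells$metric] & cells$p <= alpha
      beats[is.na(beats)] <- FALSE  # undefined partials never qualify
      if (all(beats)) quals <- c(quals, cost)
    }
    data.frame(class = cls, barrier = length(quals) > 0,
               qualifying_costs = paste(quals, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result: %d classes x %d costs x %d metrics (%d perms)\n",
              length(x$classes), length(x$costs),
              length(unique(x$grid$metric)), x$n_perm))
  bl <- x$baseline[x$baseline$kind == "simple", ]
  for (i in seq_len(nrow(bl)))
    cat(sprintf("  baseline %-10s r = %+.4f (p = %.4g)\n",
                bl$metric[i], bl$r[i], bl$p[i]))
  invisible(x)
}
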