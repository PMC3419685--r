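test_that("least-cost distances follow the COSTDISTANCE edge conventions", {
  surf <- uniform_surface(7, 7, cost = 1, cellsize = 20)
  # two points 5 cells apart on one row
  p <- rbind(c(10, 50), c(110, 50))
  expect_equal(least_cost_matrix(surf, p)$values[1, 2], 100)
  # pure diagonal separation of 3 cells
  pd <- rbind(c(10, 10), c(70, 70))
  expect_equal(least_cost_matrix(surf, pd)$values[1, 2], 3 * sqrt(2) * 20)
})

test_that("uniform-cost least-cost distance equals the chamfer metric exactly", {
  surf <- uniform_surface(9, 11, cost = 1, cellsize = 20)
  cc <- cell_centers(surf)
  set.seed(5)
  pick <- cc[sample(nrow(cc), 8), ]
  pm <- least_cost_matrix(surf, cbind(pick$x, pick$y))
  for (i in 1:7) for (j in (i + 1):8) {
    dc <- abs(pick$col[i] - pick$col[j]); dr <- abs(pick$row[i] - pick$row[j])
    chamfer <- 20 * (max(dc, dr) + (sqrt(2) - 1) * min(dc, dr))
    expect_equal(pm$values[i, j], chamfer, tolerance = 1e-12)
  }
})

test_that("Dijkstra distances equal a brute-force oracle on random surfaces", {
  set.seed(10)
  for (rep in 1:3) {
    cm <- matrix(exp(runif(400, 0, 3)), 20, 20)
    ras <- landscape_raster(matrix(1L, 20, 20), cellsize = 10)
    surf <- cost_surface(ras, c(forest = 1))
    surf$costs <- cm
    cc <- cell_centers(surf)
    pick <- cc[sample(nrow(cc), 10), ]
    pm <- least_cost_matrix(surf, cbind(pick$x, pick$y))
    ed <- oracle_grid_edges(cm, 10)
    for (i in 1:5) {
      src <- (pick$col[i] - 1) * 20 + pick$row[i]
      d <- oracle_dijkstra(ed$n, ed$from, ed$to, ed$w, src)
      for (j in 1:10) {
        node <- (pick$col[j] - 1) * 20 + pick$row[j]
        expect_equal(pm$values[i, j], if (i == j) NA_real_ else d[node],
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("one-class sweep surfaces assign the focal cost against a unit background", {
  codes <- matrix(c(1L, 2L, 3L, 1L), 2, 2)
  ras <- landscape_raster(codes)
  s <- build_cost_surface(ras, "oil_palm", 100)
  expect_equal(sort(unique(as.vector(s$costs))), c(1, 100))
  expect_equal(s$costs[codes == 2L], 100)
  expect_warning(build_cost_surface(ras, "river", 10), "absent")
  expect_error(build_cost_surface(ras, "swamp", 10), "unknown class")
  expect_error(build_cost_surface(ras, "oil_palm", 0.5), ">= 1")
  surfs <- lapply(c(10, 50, 100, 1000, 5000, 10000), function(cst)
    build_cost_surface(ras, "oil_palm", cst))
  expect_equal(vapply(surfs, function(s) max(s$costs), numeric(1)),
               c(10, 50, 100, 1000, 5000, 10000))
})

test_that("Euclidean matrices are planar distances with isometry invariance", {
  pm <- euclidean_matrix(rbind(c(0, 0), c(3, 4), c(0, 0)))
  expect_equal(pm$values[1, 2], 5)
  expect_equal(pm$values[1, 3], 0)
  pts <- cbind(runif(6), runif(6))
  th <- 0.7
  rot <- pts %*% rbind(c(cos(th), -sin(th)), c(sin(th), cos(th))) + 10
  expect_equal(euclidean_matrix(rot)$values, euclidean_matrix(pts)$values,
               tolerance = 1e-12)
})

test_that("effective resistance obeys the series and parallel laws", {
  # series: 1 x N corridor
  surf <- uniform_surface(1, 8, cost = 3, cellsize = 20)
  cc <- cell_centers(surf)
  ends <- cc[c(1, 8), ]
  rr <- resistance_matrix(surf, cbind(ends$x, ends$y))
  expect_equal(rr$resistance$values[1, 2], 7 * 20 * 3, tolerance = 1e-8)

  # parallel: octagonal ring, two opposite nodes, each arc 2(1+sqrt(2))sc
  codes <- matrix(-9999L, 4, 4)
  ring <- rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4), c(4, 3), c(4, 2),
                c(3, 1), c(2, 1))
  codes[ring] <- 1L
  ras <- landscape_raster(codes, cellsize = 20)
  surf2 <- cost_surface(ras, c(forest = 2))
  cc2 <- cell_centers(surf2)
  a <- cc2[cc2$row == 1 & cc2$col == 2, ]
  b <- cc2[cc2$row == 4 & cc2$col == 3, ]
  rr2 <- resistance_matrix(surf2, rbind(c(a$x, a$y), c(b$x, b$y)))
  arc <- 2 * (1 + sqrt(2)) * 20 * 2
  expect_equal(rr2$resistance$values[1, 2], arc / 2, tolerance = 1e-8)
})

test_that("resistance never exceeds least-cost distance and rises with cost", {
  set.seed(11)
  for (rep in 1:5) {
    cm <- matrix(exp(runif(144, 0, 2)), 12, 12)
    ras <- landscape_raster(matrix(1L, 12, 12), cellsize = 10)
    surf <- cost_surface(ras, c(forest = 1)); surf$costs <- cm
    cc <- cell_centers(surf)
    pick <- cc[sample(nrow(cc), 5), ]
    pts <- cbind(pick$x, pick$y)
    lc <- least_cost_matrix(surf, pts)$values
    rs <- resistance_matrix(surf, pts)$resistance$values
    off <- upper.tri(lc)
    expect_true(all(rs[off] <= lc[off] + 1e-8))
  }
  # raising cost on the only path strictly increases resistance
  corridor <- uniform_surface(1, 6, cost = 1, cellsize = 20)
  cc <- cell_centers(corridor)
  ends <- cbind(cc$x[c(1, 6)], cc$y[c(1, 6)])
  r1 <- resistance_matrix(corridor, ends)$resistance$values[1, 2]
  corridor$costs[1, 3] <- 50
  r2 <- resistance_matrix(corridor, ends)$resistance$values[1, 2]
  expect_gt(r2, r1)
})

test_that("current maps conserve charge, respect symmetry and a dense oracle", {
  surf <- uniform_surface(3, 3, cost = 1, cellsize = 10)
  cc <- cell_centers(surf)
  g <- data.frame(x = cc$x[cc$row == 2 & cc$col %in% c(1, 3)],
                  y = cc$y[cc$row == 2 & cc$col %in% c(1, 3)],
                  size = c(1, 1))
  res <- current_map(surf, g, buffer = 100)
  expect_lt(res$current$conservation_error, 1e-8)
  # mirror symmetry: left-right symmetric landscape and sources
  m <- res$current$map
  expect_equal(m, m[, 3:1], tolerance = 1e-8)

  # dense explicit solve on the same 3 x 3 grid, focal = node (2,3)
  ed <- oracle_grid_edges(surf$costs, 10)
  L <- matrix(0, 9, 9)
  for (e in seq_along(ed$from)) {
    i <- ed$from[e]; j <- ed$to[e]; gcond <- 1 / ed$w[e]
    L[i, j] <- L[i, j] - gcond; L[j, i] <- L[j, i] - gcond
    L[i, i] <- L[i, i] + gcond; L[j, j] <- L[j, j] + gcond
  }
  ground <- (3 - 1) * 3 + 2  # col 3, row 2
  src <- (1 - 1) * 3 + 2     # col 1, row 2
  inj <- numeric(9); inj[src] <- 1
  v <- numeric(9)
  v[-ground] <- solve(L[-ground, -ground], inj[-ground])
  node_cur <- numeric(9)
  for (e in seq_along(ed$from)) {
    ie <- abs(v[ed$from[e]] - v[ed$to[e]]) / ed$w[e]
    node_cur[ed$from[e]] <- node_cur[ed$from[e]] + ie / 2
    node_cur[ed$to[e]] <- node_cur[ed$to[e]] + ie / 2
  }
  # a run whose second source is negligible isolates the focal = group-2
  # solve, which the dense computation above reproduces cell by cell
  one <- current_map(surf, data.frame(x = g$x, y = g$y, size = c(1, 1e-12)),
                     buffer = 100)
  expect_equal(one$current$map, matrix(node_cur, 3, 3), tolerance = 1e-6)
})

test_that("residential classification merges near clusters and applies the 3 ha cut", {
  # 20 m cells: a 2 ha block is 50 cells (e.g. 5 x 10)
  mk <- function(gap_cells) {
    m <- matrix(FALSE, 12, 30)
    m[4:8, 1:10] <- TRUE                       # 2 ha
    m[4:8, (11 + gap_cells):(20 + gap_cells)] <- TRUE  # 2 ha
    m
  }
  near <- classify_residential(mk(3), cellsize = 20)   # 80 m gap
  expect_equal(length(near$area_ha), 1)
  expect_equal(near$area_ha, 4)
  expect_true(all(near$classes[mk(3)] == "residential"))

  far <- classify_residential(mk(5), cellsize = 20)    # 120 m gap
  expect_equal(length(far$area_ha), 2)
  expect_true(all(far$classes[mk(5)] == "other"))

  # exactly 3.0 ha is not residential (strictly greater required)
  m3 <- matrix(FALSE, 10, 15)
  m3[2:6, 2:16 - 1] <- TRUE  # 5 x 15 = 75 cells = 3.0 ha
  ex <- classify_residential(m3, cellsize = 20)
  expect_equal(ex$area_ha, 3)
  expect_true(all(ex$classes[m3] == "other"))
})
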