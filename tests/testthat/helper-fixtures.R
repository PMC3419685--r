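# small builders used across test files

# a genotype table from explicit allele rows: g[[i]] = c(a1_l1, a2_l1, a1_l2, ...)
tiny_table <- function(genos, groups = NULL, x = NULL, y = NULL, pop = NULL) {
  n <- length(genos)
  L <- length(genos[[1]]) / 2
  gm <- do.call(rbind, genos)
  a1 <- gm[, seq(1, 2 * L, 2), drop = FALSE]
  a2 <- gm[, seq(2, 2 * L, 2), drop = FALSE]
  if (is.null(groups)) groups <- rep("g1", n)
  if (is.null(x)) x <- seq_len(n)
  if (is.null(y)) y <- rep(0, n)
  genotype_table(paste0("i", seq_len(n)), groups, x, y, a1, a2, pop_id = pop)
}

# genotype table drawn from HW with given per-locus allele frequencies
hw_table <- function(freq_list, n, group = "g1", seed = 1) {
  set.seed(seed)
  L <- length(freq_list)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    al <- as.integer(names(freq_list[[l]]))
    a1[, l] <- sample(al, n, TRUE, prob = freq_list[[l]])
    a2[, l] <- sample(al, n, TRUE, prob = freq_list[[l]])
  }
  genotype_table(paste0(group, "_", seq_len(n)), rep(group, n),
                 seq_len(n), rep(0, n), pmin(a1, a2), pmax(a1, a2))
}

# uniform-cost surface on an r x c grid
uniform_surface <- function(nr, nc, cost = 1, cellsize = 20) {
  ras <- landscape_raster(matrix(1L, nr, nc), cellsize = cellsize)
  build_cost_surface(ras, "forest", 1)  # all cells cost 1
  surf <- cost_surface(ras, c(forest = cost))
  surf
}

# random pairwise matrix of a given kind
random_pm <- function(n, kind = "euclidean", seed = 1) {
  set.seed(seed)
  v <- matrix(0, n, n)
  v[upper.tri(v)] <- runif(n * (n - 1) / 2)
  pairwise_matrix(paste0("u", seq_len(n)), v + t(v), kind = kind)
}
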