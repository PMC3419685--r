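# independent oracles, written from first principles and kept free of the
# package's own graph/statistics code paths

# O(V^2) Dijkstra over an explicit edge list (no igraph, no heaps)
oracle_dijkstra <- function(n_nodes, from, to, w, source) {
  dist <- rep(Inf, n_nodes)
  done <- rep(FALSE, n_nodes)
  adj <- vector("list", n_nodes)
  for (e in seq_along(from)) {
    adj[[from[e]]] <- rbind(adj[[from[e]]], c(to[e], w[e]))
    adj[[to[e]]] <- rbind(adj[[to[e]]], c(from[e], w[e]))
  }
  dist[source] <- 0
  repeat {
    u <- which(!done & is.finite(dist))
    if (!length(u)) break
    u <- u[which.min(dist[u])]
    done[u] <- TRUE
    for (r in seq_len(NROW(adj[[u]]))) {
      v <- adj[[u]][r, 1]; wt <- adj[[u]][r, 2]
      if (dist[u] + wt < dist[v]) dist[v] <- dist[u] + wt
    }
  }
  dist
}

# explicit 8-neighbour edge list of a cost matrix, built cell by cell
oracle_grid_edges <- function(cm, cellsize) {
  nr <- nrow(cm); nc <- ncol(cm)
  from <- to <- integer(0); w <- numeric(0)
  id <- function(r, c) (c - 1L) * nr + r
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (is.na(cm[r, c])) next
      for (d in list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))) {
        r2 <- r + d[1]; c2 <- c + d[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || is.na(cm[r2, c2])) next
        from <- c(from, id(r, c)); to <- c(to, id(r2, c2))
        w <- c(w, cellsize * (cm[r, c] + cm[r2, c2]) / 2 *
                 if (all(d != 0)) sqrt(2) else 1)
      }
    }
  }
  list(from = from, to = to, w = w, n = nr * nc)
}

# Weir & Cockerham (1984) per-allele components, coded independently:
# explicit loops over groups and alleles, no tapply
oracle_wc_theta <- function(a1, a2, grp) {
  num <- den <- 0
  for (l in seq_len(ncol(a1))) {
    ok <- !is.na(a1[, l])
    g <- grp[ok]; x1 <- a1[ok, l]; x2 <- a2[ok, l]
    gs <- unique(g)
    r <- length(gs)
    if (r < 2) next
    ni <- sapply(gs, function(u) sum(g == u))
    nbar <- mean(ni)
    if (nbar <= 1) next
    nc_ <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    for (al in unique(c(x1, x2))) {
      p_i <- h_i <- numeric(r)
      for (j in seq_len(r)) {
        in_g <- g == gs[j]
        p_i[j] <- sum((x1[in_g] == al) + (x2[in_g] == al)) / (2 * ni[j])
        h_i[j] <- mean((x1[in_g] == al) != (x2[in_g] == al))
      }
      pbar <- sum(ni * p_i) / sum(ni)
      s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * h_i) / sum(ni)
      a <- nbar / nc_ * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                hbar / 4) / (nbar - 1))
      b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a; den <- den + a + b + cc
    }
  }
  num / den
}

# recursive flood fill (8-connected) counting components of a logical matrix
oracle_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  ncomp <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    ncomp <- ncomp + 1L
    stack <- integer(sum(mask))  # preallocated linear-index stack
    top <- 1L; stack[1] <- (c0 - 1L) * nr + r0
    seen[r0, c0] <- TRUE
    while (top > 0L) {
      v <- stack[top]; top <- top - 1L
      vr <- (v - 1L) %% nr + 1L; vc <- (v - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r <- vr + dr; c <- vc + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          top <- top + 1L
          stack[top] <- (c - 1L) * nr + r
        }
      }
    }
  }
  ncomp
}

# Pearson correlation of masked upper triangles, by double loop
oracle_mantel_r <- function(A, B, mask = NULL) {
  n <- nrow(A)
  av <- bv <- numeric(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (!is.null(mask) && !mask[i, j]) next
    av <- c(av, A[i, j]); bv <- c(bv, B[i, j])
  }
  stats::cor(av, bv)
}

# exhaustive Mantel permutation p over all n! unit permutations
oracle_mantel_exact_p <- function(A, B, tail = "greater") {
  n <- nrow(A)
  perms <- .perms_all(n)
  r_obs <- oracle_mantel_r(A, B)
  rs <- apply(perms, 1, function(p) oracle_mantel_r(A[p, p], B))
  switch(tail,
         greater = mean(rs >= r_obs - 1e-12),
         less = mean(rs <= r_obs + 1e-12),
         two_sided = mean(abs(rs) >= abs(r_obs) - 1e-12))
}

.perms_all <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  out <- NULL
  for (k in seq_len(n)) {
    sub <- .perms_all(n - 1)
    rest <- seq_len(n)[-k]
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# brute-force Moran's I between two individuals (triple loop over loci/alleles)
oracle_morans_i <- function(a1, a2) {
  n <- nrow(a1)
  cols <- list()
  for (l in seq_len(ncol(a1))) {
    for (al in sort(unique(c(a1[, l], a2[, l])))) {
      p <- ((a1[, l] == al) + (a2[, l] == al)) / 2
      cols[[length(cols) + 1]] <- p - mean(p)
    }
  }
  Z <- do.call(cbind, cols)
  denom <- mean(apply(Z, 1, function(z) sum(z^2)))
  out <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n) if (i != j)
    out[i, j] <- sum(Z[i, ] * Z[j, ]) / denom
  out
}
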