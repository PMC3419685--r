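#' Simple Mantel test between two distance matrices
#'
#' `r` is the Pearson correlation of the unmasked off-diagonal upper-triangle
#' entries; the null distribution permutes the units of `A` (joint random
#' permutation of rows and columns, the pair mask staying attached to unit
#' pairs), and `p` carries the +1 correction so it is never exactly zero.
#'
#' @param A,B [pairwise_matrix()] objects on the same ids; masks are
#'   intersected.
#' @param n_perm number of permutations (10,000 in the full analysis).
#' @param tail `"two_sided"`, `"greater"` or `"less"`.
#' @param seed integer seed.
#' @return list of class `mantel_result`: `r`, `p`, `n_perm`, `tail`,
#'   `kind = "simple"`, `n_pairs`.
#' @export
mantel <- function(A, B, n_perm = 10000,
                   tail = c("two_sided", "greater", "less"), seed = 1L) {
  tail <- match.arg(tail)
  pm <- .mantel_pairs(list(A, B))
  av <- A$values[pm$pick]; bv <- B$values[pm$pick]
  .check(stats::sd(av) > 0 && stats::sd(bv) > 0,
         "zero variance in a matrix: Mantel r undefined")
  r_obs <- stats::cor(av, bv)
  set.seed(seed)
  rs <- vapply(seq_len(n_perm), function(k) {
    pr <- sample.int(pm$n)
    stats::cor(A$values[cbind(pr[pm$ii], pr[pm$jj])], bv)
  }, numeric(1))
  structure(list(r = r_obs, p = .perm_p(r_obs, rs, tail), n_perm = n_perm,
                 tail = tail, kind = "simple", controlled = NULL,
                 n_pairs = length(av)),
            class = "mantel_result")
}

#' Partial Mantel test controlling a third matrix
#'
#' First-order partial correlation
#' `r_AB.C = (r_AB - r_AC r_BC) / sqrt((1 - r_AC^2)(1 - r_BC^2))` on the
#' masked upper-triangle vectors. The null permutes the units of `A` only
#' (genetics as response, geography as fixed design), recomputing the partial
#' statistic each draw.
#'
#' @param A,B,C conformable [pairwise_matrix()] objects; `C` is controlled.
#' @inheritParams mantel
#' @return a `mantel_result` with `kind = "partial"`.
#' @export
partial_mantel <- function(A, B, C, n_perm = 10000,
                           tail = c("two_sided", "greater", "less"),
                           seed = 1L) {
  tail <- match.arg(tail)
  pm <- .mantel_pairs(list(A, B, C))
  av <- A$values[pm$pick]; bv <- B$values[pm$pick]; cv <- C$values[pm$pick]
  .check(stats::sd(av) > 0 && stats::sd(bv) > 0 && stats::sd(cv) > 0,
         "zero variance in a matrix")
  partial_r <- function(a) {
    rab <- stats::cor(a, bv); rac <- stats::cor(a, cv)
    rbc <- stats::cor(bv, cv)
    .check(abs(rac) < 1 - 1e-10 && abs(rbc) < 1 - 1e-10,
           "partial correlation undefined: |r| = 1 with the control matrix")
    (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
  }
  r_obs <- partial_r(av)
  set.seed(seed)
  rs <- vapply(seq_len(n_perm), function(k) {
    pr <- sample.int(pm$n)
    partial_r(A$values[cbind(pr[pm$ii], pr[pm$jj])])
  }, numeric(1))
  structure(list(r = r_obs, p = .perm_p(r_obs, rs, tail), n_perm = n_perm,
                 tail = tail, kind = "partial", controlled = C$kind,
                 n_pairs = length(av)),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%s Mantel%s: r = %.4f, p = %.4g (%s, %d perms, %d pairs)\n",
              x$kind,
              if (!is.null(x$controlled)) paste0(" | ", x$controlled) else "",
              x$r, x$p, x$tail, x$n_perm, x$n_pairs))
  invisible(x)
}

# internal: shared pair bookkeeping for (partial) Mantel tests
.mantel_pairs <- function(mats) {
  ids <- mats[[1]]$ids
  for (m in mats[-1]) .check(identical(m$ids, ids), "matrix ids differ")
  n <- length(ids)
  .check(n >= 4, "need >= 4 units")
  ut <- which(upper.tri(mats[[1]]$values), arr.ind = TRUE)
  use <- rep(TRUE, nrow(ut))
  for (m in mats) {
    if (!is.null(m$mask)) use <- use & m$mask[ut]
    use <- use & !is.na(m$values[ut])
  }
  .check(sum(use) >= 3, "fewer than 3 usable pairs after masking")
  list(ii = ut[use, 1], jj = ut[use, 2],
       pick = ut[use, , drop = FALSE], n = n)
}

# internal: one/two-sided permutation p with the +1 correction
.perm_p <- function(obs, null, tail) {
  eps <- 1e-12
  switch(tail,
         greater = (1 + sum(null >= obs - eps)) / (length(null) + 1),
         less = (1 + sum(null <= obs + eps)) / (length(null) + 1),
         two_sided = (1 + sum(abs(null) >= abs(obs) - eps)) /
           (length(null) + 1))
}

#' Mask a pairwise matrix to within-population pairs
#'
#' Restricts downstream Mantel tests to pairs of individuals sampled within
#' the same population, excluding every between-population pair (the
#' spatial-scale restriction of the sweep design).
#'
#' @param matrix a [pairwise_matrix()].
#' @param membership named vector mapping every id to its population.
#' @return the matrix with its mask intersected with same-population pairs.
#' @export
restrict_pairs <- function(matrix, membership) {
  .check(all(matrix$ids %in% names(membership)),
         "membership must cover all ids")
  pop <- membership[matrix$ids]
  same <- outer(pop, pop, "==")
  dimnames(same) <- list(matrix$ids, matrix$ids)
  mask <- if (is.null(matrix$mask)) same else matrix$mask & same
  pairwise_matrix(matrix$ids, matrix$values, kind = matrix$kind, mask = mask)
}
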